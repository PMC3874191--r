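# Replication-model config for `replidyn sim`.
# chromosomes: ordered list of {name, length (bp)}
# origins: list of {chrom, position (bp, 0-based), firingMean (min),
#          firingSD (min, optional, default 0),
#          competence (0..1, optional, default 1), name (optional)}
# forkVelocity: bp/min; sPhaseStart/sPhaseDuration: minutes.
chromosomes:
  - {name: chr1, length: 1000000}
  - {name: chr2, length: 1000000}
forkVelocity: 1500
sPhaseStart: 20
sPhaseDuration: 30
origins:
  - {chrom: chr1, position: 50000,  firingMean: 27, firingSD: 2, name: ori1_1}
  - {chrom: chr1, position: 150000, firingMean: 35, firingSD: 2, name: ori1_2}
  - {chrom: chr1, position: 260000, firingMean: 29, firingSD: 2, name: ori1_3}
  - {chrom: chr1, position: 360000, firingMean: 41, firingSD: 2, name: ori1_4}
  - {chrom: chr1, position: 450000, firingMean: 27, firingSD: 2, name: ori1_5}
  - {chrom: chr1, position: 560000, firingMean: 38, firingSD: 2, name: ori1_6}
  - {chrom: chr1, position: 650000, firingMean: 31, firingSD: 2, name: ori1_7}
  - {chrom: chr1, position: 760000, firingMean: 43, firingSD: 2, name: ori1_8}
  - {chrom: chr1, position: 850000, firingMean: 28, firingSD: 2, name: ori1_9}
  - {chrom: chr1, position: 950000, firingMean: 36, firingSD: 2, name: ori1_10}
  - {chrom: chr2, position: 55000,  firingMean: 30, firingSD: 2, name: ori2_1}
  - {chrom: chr2, position: 145000, firingMean: 42, firingSD: 2, name: ori2_2}
  - {chrom: chr2, position: 255000, firingMean: 27, firingSD: 2, name: ori2_3}
  - {chrom: chr2, position: 350000, firingMean: 37, firingSD: 2, name: ori2_4}
  - {chrom: chr2, position: 455000, firingMean: 32, firingSD: 2, name: ori2_5}
  - {chrom: chr2, position: 545000, firingMean: 28, firingSD: 2, name: ori2_6}
  - {chrom: chr2, position: 660000, firingMean: 40, firingSD: 2, name: ori2_7}
  - {chrom: chr2, position: 750000, firingMean: 33, firingSD: 2, name: ori2_8}
  - {chrom: chr2, position: 855000, firingMean: 27, firingSD: 2, name: ori2_9}
  - {chrom: chr2, position: 945000, firingMean: 39, firingSD: 2, name: ori2_10}
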