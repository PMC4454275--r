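# Example run configuration: one paired-end short-read set plus a long
# noisy read set, with the long reads down-weighted so they do not
# dominate the combined score through their length.
seed: 1
graph:
  kmerSize: 21
model:
  alpha: 3
readsets:
  - path: reads_1.fastq
    matePath: reads_2.fastq
    paired: true
    technology: short
    errorRate: 0.01
    insertMean: 1500
    insertSd: 150
    orientation: fr
    weight: 1
  - path: long.fastq
    technology: long
    errorRate: 0.12
    weight: 0.01
anneal:
  patience: 500
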