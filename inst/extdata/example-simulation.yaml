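# Example simulation configuration: autosomal-aneuploidy design with the
# six genotypes of the MSL2/trisomy-2L panel, two sequencing batches.
seed: 1
library_size: 5000000
genome:
  n_genes_per_arm: {X: 650, 2L: 900, 2R: 300, 3L: 250, 3R: 150, "4": 50}
  frac_sex_biased: 0.2
  frac_tf: 0.05
  frac_responsive: 0.8
model:
  msl2_factor: 0.6667
  sex_bias_mult: 4
  batch_log2_shift: {b1: 0.0, b2: 0.4}
design:
  - {sex: female, replicates: 3, batch: b1}
  - {sex: male, replicates: 3, batch: b1}
  - {sex: female, varied_arm: 2L, replicates: 3, batch: b1}
  - {sex: male, varied_arm: 2L, replicates: 3, batch: b1}
  - {sex: female, varied_arm: 2L, msl2: true, replicates: 3, batch: b2}
  - {sex: male, varied_arm: 2L, msl2: true, replicates: 3, batch: b2}
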