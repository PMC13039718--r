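seed: 1
n_accessions: 8
n_chromosomes: 2
chrom_length: 1000000
snv_rate: 0.005
small_indel_rate: 0.0005
sv_counts:
  DEL: 90
  INS_TE: 70
  INS_DUP: 20
  INS_SAT: 18
  TRA: 1
te_length_mode: 12000
inversion_spec:
  chrom: 1
  start: 300001
  length: 150000
  carrier_fraction: 0.5044
cnv_spec:
  chrom: 2
  eps_high_frac: 0.3621
  roq_high_frac: 0.2816
  eps_low:
  - 0
  - 1
  eps_high:
  - 3
  - 4
  roq_low:
  - 5
  - 6
  - 7
  - 8
  - 9
  - 10
  - 11
  roq_high:
  - 16
  - 17
  - 18
  - 19
trait_spec:
  carrier_exception_rate: 0.0348
  noncarrier_purple_rate: 0.4911
  incidence_means:
    TGG_Eplus_or_Rplus: 0.15
    TGG_EmRm: 0.5
    TGA_Eplus_or_Rplus: 0.6
    TGA_EmRm: 0.85
  n_batches: 4
  batch_effects:
  - -0.05
  - 0.0
  - 0.02
  - 0.03
  n_seedlings: 24
  incidence_sd: 0.05
n_genes: 240
outgroup_snv_rate: 0.003
n_outgroup_deletions: 20
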