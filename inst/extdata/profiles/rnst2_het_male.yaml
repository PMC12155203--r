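name: rnst2_het_male
class_fractions:
  rRNA_frag: 0.150
  tDR: 0.035
  miRNA: 0.120
  piRNA: 0.050
  endo_siRNA: 0.550
  mRNA_frag: 0.095
  unassigned: 0.0
fragment_model:
  five_prime_fraction: 0.623
  long_mode_weight: 0.35
  half_length_mean: 34
  half_length_sd: 1.5
  short_length_mean: 24
  short_length_sd: 3
  isoacceptor_weights:
    Gly-GCC: 0.28
    Glu-CTC: 0.22
    Ser-AGA: 0.20
    His-GTG: 0.06
    Lys-CTT: 0.06
    Asp-GTC: 0.05
    Val-AAC: 0.05
    Ala-AGC: 0.04
    Phe-GAA: 0.04
rrna_model:
  length_mean: 22
  length_sd: 4
sirna_model:
  length_weights:
    "22": 0.8
    "26": 0.2
  g_fraction: 0.8
read_count: 200000
seed: 1
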