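{
  "mrna_CSF1": 0.46764284023403,
  "mrna_STAT1": 1.21088049627509,
  "mrna_STAT3": 1.49282715153265,
  "mrna_IRF8": 0.58030690365423,
  "mrna_PU1": 1.85851892967225,
  "mrna_NFKB": 0.709858378860009,
  "mrna_CEBPA": 0.118841394652889,
  "mrna_IL6R": 0.477882470053881,
  "mrna_TNFR1": 0.84004677925035,
  "mrna_CSF1R": 1.24521806322594,
  "mrna_CSF3R": 0.299380043634388,
  "protein_inactive_STAT1": 3618.21182802457,
  "protein_inactive_STAT3": 4261.57018975764,
  "protein_inactive_NFKB": 1925.49421894056,
  "protein_inactive_CEBPA": 340.186562378687,
  "protein_inactive_CSF1R": 3381.04761733302,
  "protein_active_STAT1": 14.4296608006854,
  "protein_active_STAT3": 216.911264840302,
  "protein_active_NFKB": 204.080917639456,
  "protein_active_CEBPA": 16.3376215799785,
  "protein_active_CSF1R": 354.606572344743
}
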