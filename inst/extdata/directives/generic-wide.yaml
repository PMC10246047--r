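platform: generic-wide
orientation: wide
level: peptides
identifier_map:
  protein: protein
  peptide: peptide
  modification: modification
abundance_pattern: "^abundance_(.+)$"
annotation_map:
  description: description
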