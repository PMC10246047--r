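# Representative MaxQuant proteinGroups.txt dialect: protein-level table
# with one "Intensity <sample>" column per run. Not bit-compatible with any
# particular MaxQuant version; adjust column names via a custom directive
# if your export differs.
platform: maxquant-proteins
orientation: wide
level: proteins
identifier_map:
  protein: "Majority protein IDs"
abundance_pattern: "^Intensity (.+)$"
accounting_map:
  num_peptides: "Peptides"
  num_unique_peptides: "Unique peptides"
annotation_map:
  description: "Protein names"
replicate_pattern: "_([0-9]+)$"
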