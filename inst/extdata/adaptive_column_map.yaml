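# Column synonyms for Adaptive immunoSEQ-style TSV exports, in priority
# order. Pass as `column_map` to read_adaptive_tsv() after yaml::read_yaml().
v_gene:
  - vMaxResolved
  - v_resolved
  - vGeneName
  - v_gene
cdr3_aa:
  - aminoAcid
  - amino_acid
  - cdr3_amino_acid
  - aminoacid
count:
  - "count (templates/reads)"
  - templates
  - count
  - reads
frame:
  - sequenceStatus
  - frame_type
  - frameType
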