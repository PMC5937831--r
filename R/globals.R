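# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", "sequence", "library", "N", "category", "reads",
  "percent", "tag", "pri", "unique_tags", "total_reads", "unique_percent",
  "total_percent", "locus", "score", "mirna", "novel", "weight", "strand",
  "value", "treatment", "trait", "start", "gene", "source_id"))
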