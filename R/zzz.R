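.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "donor_id", "cancer_type", "chromosome", "start", "ref", "alt",
  "consequence", "gene", ".priority", "recurrence", "n_mutations",
  "n_donors", "N", "k", "mutation_fraction", "donor_fraction",
  "max_rec"))
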