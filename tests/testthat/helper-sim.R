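# Small shared fixtures, built in code.

one_sample_cfg <- function(seed, n, composition = NULL, ...) {
  sim_config(seed = seed, reads_per_sample = n,
             samples = data.frame(stage = "0-1h", fraction = "UF"),
             barcode_map = c("0-1h_UF" = "AACC"),
             composition = if (is.null(composition)) default_comp()
                           else composition,
             ...)
}

default_comp <- function() {
  c(miRNA = 0.30, rRNA = 0.20, tRNA = 0.15, transposon = 0.20,
    transcript = 0.10, intergenic = 0.05)
}

# records table from bare per-sample insert vectors
records_from <- function(...) {
  collapse_inserts(list(...))
}

# ground-truth category with the simulator's "miRNA" label mapped onto the
# annotation hierarchy's hairpin category
truth_category <- function(truth) {
  ifelse(truth$category == "miRNA", "miRNA_hairpin", truth$category)
}
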