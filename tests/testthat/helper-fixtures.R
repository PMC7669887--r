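# Shared fixtures: all built in code at test time.

# A trait table at the study design with optional per-trait truth
# overrides, e.g. make_table(mo2_min = list(ratio_pco2 = 1.167)).
make_table <- function(..., seed = 101, design = study_design(seed = seed)) {
  truths <- default_trait_truths()
  overrides <- list(...)
  for (tr in names(overrides)) {
    for (fld in names(overrides[[tr]])) {
      truths[[tr]][[fld]] <- overrides[[tr]][[fld]]
    }
  }
  roster <- generate_design(design)
  generate_trait_table(roster, truths, seed = seed)
}

# Noise-free truths: every trait collapses to its cell mean.
noiseless_truths <- function() {
  truths <- default_trait_truths()
  for (tr in names(truths)) {
    truths[[tr]]$group_sd <- 0
    truths[[tr]]$resid_sd <- 0
  }
  truths
}
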