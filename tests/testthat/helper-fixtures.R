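# shared fixtures, all generated in code

toy_profiles <- function(n = 6L, p = 3L, seed = 1L) {
  set.seed(seed)
  morph_table(matrix(rnorm(n * p), n, p,
                     dimnames = list(sprintf("prof%02d", seq_len(n)),
                                     sprintf("f%02d", seq_len(p)))))
}

# a small scenario that keeps selection and gate runtimes low while
# preserving the planted structure (3 planted readout/group pairs)
small_scenario <- function(seed = 1L, delta = 2.0) {
  sim_scenario(n_features = 40L, n_readouts = 4L, n_planted = 3L,
               subset_size = 5L, n_groups = 4L, group_size = 12L,
               controls = 20L, delta = delta, readout_noise = 0.5,
               n_compounds = 120L, prevalence = 0.4, seed = seed)
}

toy_registry <- function() {
  new_toy_term <- function(l1, l2, l3, l4, feats) {
    biomorph_term(l1, l2, l3, l4, feats)
  }
  terms <- list(
    new_toy_term("viability", "intensity", "pct_dead", "ROS",
                 c("f1", "f2", "f3", "f4")),
    new_toy_term("viability", "intensity", "pct_dead", "Apoptosis",
                 c("f5", "f6")),
    new_toy_term("cell_cycle", "count", "g2_arrest", "ROS",
                 c("f7", "f8", "f9", "f10")))
  biomorph:::new_registry(terms, feature_universe = paste0("f", 1:12))
}
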