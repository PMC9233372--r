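# Shared simulated cohorts, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

# Default desk-scale cohort (the generator's study conditions).
shared_sim <- function() {
  if (is.null(.sim_cache$default))
    .sim_cache$default <- simulate_cohort(sim_scenario(), seed = 7L)
  .sim_cache$default
}

# Small fast cohort for structural tests.
small_scenario <- function(...) {
  sim_scenario(n_individuals = 120L, n_genes_universe = 600L,
               n_set_a = 40L, n_set_b = 30L, n_overlap = 10L,
               n_cross_edges = 60L, n_noise_edges = 40L,
               n_target_genes = 20L, ...)
}

small_sim <- function() {
  if (is.null(.sim_cache$small))
    .sim_cache$small <- simulate_cohort(small_scenario(), seed = 11L)
  .sim_cache$small
}

fixtures <- function() {
  if (is.null(.sim_cache$fixtures))
    .sim_cache$fixtures <- make_fixture_suite()
  .sim_cache$fixtures
}

# A minimal variant table built in code.
toy_variants <- function(rows) {
  preds <- default_predictors()
  base <- data.frame(
    individual_id = "i1", gene_id = "g1", chrom = "chr1", pos = 100L,
    ref = "A", alt = "T", variant_class = "SNV", genotype = "het",
    vep_high = TRUE, depth = 50L, gq = 90L, inheritance = "unknown",
    stringsAsFactors = FALSE
  )
  for (p in preds) base[[p]] <- "damaging"
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) base))
  for (cl in names(rows)) out[[cl]] <- rows[[cl]]
  attr(out, "predictors") <- preds
  class(out) <- c("variant_table", "data.frame")
  out
}
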