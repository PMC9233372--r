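#' Run the full analysis pipeline on a (simulated or loaded) cohort
#'
#' Executes every stage in order: QC filter, per-variant PDV scoring
#' (including CNVs), per-gene burden aggregation, candidate-hit summary,
#' PDV restriction of the two candidate sets, cross-trait network
#' construction, topology-aware GO overrepresentation with the
#' full-candidate comparison column, DBP score matrix over the significant
#' terms, score diagnostics, and the association models for the process
#' with the highest evidence of dysfunction.
#'
#' @param sim A `sim_cohort` (or any list with the same elements:
#'   `variants`, `cnvs`, `par_regions`, `gene_models`, `gene_sets`,
#'   `id_map`, `edges`, `graph`, `annotations`, `phenotypes`, `sex`).
#' @param config A [run_config()].
#' @param enrich_method `"elim"` (default) or `"classic"`.
#' @return A list of class `pdvnet_run` with each stage's output and a
#'   `manifest` echoing the thresholds used.
#' @export
run_pipeline <- function(sim, config = run_config(),
                         enrich_method = c("elim", "classic")) {
  enrich_method <- match.arg(enrich_method)
  qc <- apply_qc_filter(sim$variants, config$min_depth, config$min_gq)
  records <- score_variants(qc, sim$sex, sim$par_regions, cnvs = sim$cnvs,
                            gene_models = sim$gene_models, config = config)
  burden <- gene_burden(records)
  hits <- summarize_candidate_hits(burden, sim$gene_sets$A,
                                   sim$gene_sets$B)
  restricted <- restrict_to_pdv(sim$gene_sets$A, sim$gene_sets$B, burden)
  network <- build_network(restricted, sim$edges,
                           min_score = config$min_string_score,
                           id_map = sim$id_map)

  annotations <- propagate_annotations(sim$graph, sim$annotations)
  universe <- unique(annotations$gene_id)
  study <- intersect(network_genes(network), universe)
  if (length(study) == 0L)
    stop("no network gene is annotated in the GO universe", call. = FALSE)
  study_full <- intersect(union(sim$gene_sets$A, sim$gene_sets$B),
                          universe)
  enrichment <- compare_universes(sim$graph, study, study_full, universe,
                                  annotations,
                                  fdr_alpha = config$fdr_alpha,
                                  method = enrich_method,
                                  alpha_elim = config$alpha_elim,
                                  min_node_size = config$min_node_size,
                                  propagate = FALSE)
  sig_terms <- enrichment$term_id[!is.na(enrichment$fdr) &
                                    enrichment$fdr < config$fdr_alpha]
  dbp <- NULL; diagnostics <- NULL; association <- NULL
  overlap_summary <- NULL
  if (length(sig_terms) > 0L) {
    overlap_summary <- term_overlap_summary(sig_terms, study, annotations)
    dbp <- dbp_matrix(burden, sig_terms, sim$graph, annotations,
                      universe = universe,
                      individuals = sim$phenotypes$individual_id,
                      ebp_parse = config$ebp_parse, propagate = FALSE)
    diagnostics <- dbp_diagnostics(dbp, seed = config$seed)
    top <- diagnostics$top_term
    scores <- stats::setNames(dbp[, top], rownames(dbp))
    association <- list(
      linear = fit_dbp_linear(sim$phenotypes, scores),
      extremely_long = tryCatch(
        fit_dbp_category(sim$phenotypes, scores, "extremely_long",
                         short_max = config$short_max,
                         long_min = config$long_min),
        error = function(e) conditionMessage(e)),
      interaction_age = fit_dbp_interaction(sim$phenotypes, scores,
                                            "age_years"),
      stratified = fit_dbp_stratified(sim$phenotypes, scores)
    )
  }
  structure(list(
    qc_variants = qc, pdv_records = records, burden = burden,
    candidate_hits = hits, restricted = restricted, network = network,
    enrichment = enrichment, significant_terms = sig_terms,
    term_overlap = overlap_summary,
    dbp = dbp, diagnostics = diagnostics, association = association,
    manifest = list(
      min_depth = config$min_depth, min_gq = config$min_gq,
      require_vep_high = config$require_vep_high,
      min_string_score = config$min_string_score,
      fdr_alpha = config$fdr_alpha, alpha_elim = config$alpha_elim,
      min_node_size = config$min_node_size, ebp_parse = config$ebp_parse,
      enrich_method = enrich_method, seed = config$seed,
      n_universe = length(universe), n_study = length(study))
  ), class = "pdvnet_run")
}

#' @export
print.pdvnet_run <- function(x, ...) {
  cat("pdvnet pipeline run\n")
  cat("  QC-passing variant rows:", nrow(x$qc_variants), "\n")
  cat("  scored variants:", nrow(x$pdv_records),
      "; gene burdens:", nrow(x$burden), "\n")
  cat("  PDV-bearing candidates: A =", length(x$restricted$A),
      ", B =", length(x$restricted$B),
      "; overlap =", x$candidate_hits$n_overlap, "\n")
  cat("  network:", nrow(x$network$nodes), "genes,",
      nrow(x$network$edges), "cross-set edges\n")
  cat("  significant processes:", length(x$significant_terms), "\n")
  if (!is.null(x$diagnostics))
    cat("  top process:", x$diagnostics$top_term, "\n")
  invisible(x)
}
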