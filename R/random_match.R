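#' Select a feature-matched random gene set
#'
#' Draws a random set of the same size as the candidate set from the
#' feature universe (excluding the candidate sets), accepting a draw when
#' the set-level mean of each feature — GC content, transcript size and
#' spliceoform count — lies within tolerance of the candidate set's mean.
#' Selection is seeded rejection sampling with a retry cap.
#'
#' @param candidate_set Character vector of candidate gene ids (must have
#'   features).
#' @param features Data frame `gene_id`, `gc_content`, `transcript_size`,
#'   `n_spliceoforms`.
#' @param exclude Gene ids never to sample (defaults to the candidate set;
#'   pass the union of both candidate sets for the published design).
#' @param tol_gc Absolute tolerance on mean GC content.
#' @param tol_size_rel Relative tolerance on mean transcript size.
#' @param tol_spliceoforms Absolute tolerance on mean spliceoform count.
#' @param seed Optional integer seed for reproducible selection.
#' @param max_retries Retry cap for rejection sampling.
#' @return Character vector of selected gene ids, with attribute `means`
#'   (achieved feature means).
#' @export
select_matched_random <- function(candidate_set, features,
                                  exclude = candidate_set,
                                  tol_gc = 0.01, tol_size_rel = 0.05,
                                  tol_spliceoforms = 0.5,
                                  seed = NULL, max_retries = 10000L) {
  feat <- features[stats::complete.cases(features), , drop = FALSE]
  cand <- feat[feat$gene_id %in% candidate_set, , drop = FALSE]
  if (nrow(cand) < 2L)
    stop("candidate set has fewer than 2 genes with features",
         call. = FALSE)
  pool <- feat[!feat$gene_id %in% exclude, , drop = FALSE]
  n <- length(unique(candidate_set))
  if (nrow(pool) < n)
    stop("feature universe minus exclusions smaller than candidate set",
         call. = FALSE)
  target <- c(gc = mean(cand$gc_content),
              size = mean(cand$transcript_size),
              spl = mean(cand$n_spliceoforms))
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  best_dev <- Inf
  for (i in seq_len(max_retries)) {
    idx <- sample.int(nrow(pool), n)
    m <- c(gc = mean(pool$gc_content[idx]),
           size = mean(pool$transcript_size[idx]),
           spl = mean(pool$n_spliceoforms[idx]))
    dev <- max(abs(m[["gc"]] - target[["gc"]]) / tol_gc,
               abs(m[["size"]] - target[["size"]]) /
                 (tol_size_rel * target[["size"]]),
               abs(m[["spl"]] - target[["spl"]]) / tol_spliceoforms)
    if (dev < best_dev) { best_dev <- dev; best <- m }
    if (dev <= 1) {
      out <- pool$gene_id[idx]
      attr(out, "means") <- m
      attr(out, "target_means") <- target
      return(out)
    }
  }
  stop("matched-random selection failed after ", max_retries,
       " retries; closest means: gc=", signif(best[["gc"]], 4),
       " size=", signif(best[["size"]], 5),
       " spliceoforms=", signif(best[["spl"]], 4), call. = FALSE)
}

#' Compare molecular features of two gene sets
#'
#' Welch two-sample t-tests per feature (GC content, transcript size,
#' spliceoform count).
#'
#' @param set1,set2 Character vectors of gene ids.
#' @param features Gene feature data frame.
#' @return Data frame with one row per feature: `t`, `df`, `p`, and the two
#'   set means.
#' @export
compare_features <- function(set1, set2, features) {
  cols <- c("gc_content", "transcript_size", "n_spliceoforms")
  f1 <- features[features$gene_id %in% set1, , drop = FALSE]
  f2 <- features[features$gene_id %in% set2, , drop = FALSE]
  if (nrow(f1) < 2L || nrow(f2) < 2L)
    stop("each set needs at least 2 genes with features", call. = FALSE)
  out <- lapply(cols, function(cl) {
    tt <- stats::t.test(f1[[cl]], f2[[cl]])
    data.frame(feature = cl, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean1 = mean(f1[[cl]]), mean2 = mean(f2[[cl]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Negative-control pipeline run on random gene sets
#'
#' Re-runs the network and enrichment stages with two (typically
#' feature-matched random) gene sets: restricts each to PDV-bearing genes,
#' builds the cross-set interaction network, and tests GO
#' overrepresentation of the network genes against the universe. Under a
#' null in which random genes carry no coordinated biology, the expected
#' number of FDR-significant processes is approximately zero.
#'
#' @param random_a,random_b Gene id vectors standing in for the two
#'   candidate sets.
#' @param burden A [gene_burden()] table for the cohort.
#' @param edges Interaction edge data frame.
#' @param graph A `go_graph`.
#' @param annotations Annotation data frame.
#' @param universe Gene universe for enrichment.
#' @param config A [run_config()].
#' @param id_map Optional gene-to-protein map.
#' @return List of class `control_report`: PDV gene counts, network size,
#'   number of FDR-significant terms, and the enrichment table (NULL when
#'   the network is empty).
#' @export
negative_control_run <- function(random_a, random_b, burden, edges, graph,
                                 annotations, universe,
                                 config = run_config(), id_map = NULL) {
  pdv_genes <- unique(burden$gene_id[burden$pdv_sum > 0])
  a <- intersect(random_a, pdv_genes)
  b <- intersect(random_b, pdv_genes)
  report <- list(n_pdv_a = length(a), n_pdv_b = length(b),
                 n_nodes = 0L, n_edges = 0L, n_significant = 0L,
                 enrichment = NULL)
  class(report) <- "control_report"
  if (length(a) == 0L || length(b) == 0L) return(report)
  restricted <- restrict_to_pdv(random_a, random_b, burden)
  net <- build_network(restricted, edges,
                       min_score = config$min_string_score,
                       id_map = id_map)
  report$n_nodes <- nrow(net$nodes)
  report$n_edges <- nrow(net$edges)
  study <- intersect(network_genes(net), universe)
  if (length(study) == 0L) return(report)
  enr <- decorrelated_enrich(graph, study, universe, annotations,
                             method = "elim",
                             alpha_elim = config$alpha_elim,
                             min_node_size = config$min_node_size)
  report$enrichment <- enr
  report$n_significant <- sum(enr$fdr < config$fdr_alpha, na.rm = TRUE)
  report
}

#' @export
print.control_report <- function(x, ...) {
  cat("negative-control run\n")
  cat("  PDV-bearing random genes: A =", x$n_pdv_a, ", B =", x$n_pdv_b, "\n")
  cat("  network:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat("  FDR-significant processes:", x$n_significant, "\n")
  invisible(x)
}
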