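#' One-sided Fisher (hypergeometric) overrepresentation test per GO term
#'
#' For each term with at least `min_node_size` annotated genes in the
#' universe, tests whether study genes are overrepresented among the term's
#' genes with the upper-tail hypergeometric probability
#' `P(X >= sig)`. Reports `anno` (annotated universe genes), `sig`
#' (annotated study genes), `exp = anno * |study| / |universe|` and
#' `fe = sig / exp`. Terms with no annotated study gene are returned as
#' non-tested (`tested = FALSE`, `p = NA`).
#'
#' @param study Character vector of study gene ids (must be a subset of the
#'   universe).
#' @param universe Character vector of universe gene ids.
#' @param annotations Propagated annotation data frame (`gene_id`,
#'   `term_id`, `evidence`).
#' @param min_node_size Minimum `anno` for a term to be considered.
#' @return Data frame of class `enrichment_result`, sorted by p then term
#'   id, with BH-adjusted `fdr` over tested terms.
#' @export
fisher_enrich <- function(study, universe, annotations, min_node_size = 1L) {
  .check_study(study, universe)
  term_genes <- .term_gene_lists(annotations, universe)
  .enrich_from_lists(term_genes, term_genes, study, universe, min_node_size)
}

.check_study <- function(study, universe) {
  bad <- setdiff(study, universe)
  if (length(bad) > 0L)
    stop("study genes outside the universe: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
}

.term_gene_lists <- function(annotations, universe) {
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  split(ann$gene_id, ann$term_id)
}

# term_genes: pruned gene lists used for the test;
# full_genes: unpruned lists used for reported anno/sig counts.
.enrich_from_lists <- function(term_genes, full_genes, study, universe,
                               min_node_size, p_override = NULL) {
  u <- length(unique(universe))
  s <- length(unique(study))
  ids <- sort(names(full_genes))
  anno <- vapply(full_genes[ids], length, 0L)
  sig <- vapply(full_genes[ids], function(g) sum(study %in% g), 0L)
  keep <- anno >= max(1L, min_node_size)
  ids <- ids[keep]; anno <- anno[keep]; sig <- sig[keep]
  expd <- anno * s / u
  fe <- ifelse(expd > 0, sig / expd, NA_real_)
  if (is.null(p_override)) {
    p <- rep(NA_real_, length(ids))
    tested <- sig >= 1L
    a_t <- vapply(term_genes[ids], length, 0L)
    s_t <- vapply(term_genes[ids], function(g) sum(study %in% g), 0L)
    p[tested] <- stats::phyper(s_t[tested] - 1L, a_t[tested],
                               u - a_t[tested], s, lower.tail = FALSE)
  } else {
    p <- unname(p_override[ids])
    tested <- !is.na(p)
  }
  fdr <- rep(NA_real_, length(ids))
  fdr[tested] <- bh_fdr(p[tested])
  out <- data.frame(term_id = ids, anno = anno, sig = sig, exp = expd,
                    fe = fe, p = p, fdr = fdr, tested = tested,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_universe") <- u
  attr(out, "n_study") <- s
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement and capping at 1;
#' delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Topology-aware GO overrepresentation (classic or elim)
#'
#' `method = "classic"` is the plain per-term Fisher test. `method =
#' "elim"` traverses the DAG bottom-up (deepest terms first); whenever a
#' term's test is significant at `alpha_elim`, its currently annotated
#' genes are removed from all of its ancestors before those are tested,
#' discounting parent terms for signal already explained by a significant
#' child. With `alpha_elim = 0` no child is ever eliminated and the
#' procedure reduces exactly to the classic test. Reported `anno`, `sig`,
#' `exp` and `fe` are always the unpruned counts; only the p-value reflects
#' elimination.
#'
#' @param graph A `go_graph`.
#' @param study,universe Gene id vectors (`study` within `universe`).
#' @param annotations Annotation data frame; propagated internally unless
#'   `propagate = FALSE`.
#' @param method `"classic"` or `"elim"`.
#' @param alpha_elim Child-term significance threshold for elimination.
#' @param min_node_size Minimum annotated-gene count for a term to be
#'   considered.
#' @param propagate Apply the true-path rule before testing.
#' @return An `enrichment_result` data frame (with a `name` column when
#'   term names are available).
#' @export
decorrelated_enrich <- function(graph, study, universe, annotations,
                                method = c("classic", "elim"),
                                alpha_elim = 0.01, min_node_size = 1L,
                                propagate = TRUE) {
  method <- match.arg(method)
  .check_study(study, universe)
  if (propagate) annotations <- propagate_annotations(graph, annotations)
  full <- .term_gene_lists(annotations, universe)

  if (method == "classic") {
    res <- .enrich_from_lists(full, full, study, universe, min_node_size)
  } else {
    u <- length(unique(universe))
    s <- length(unique(study))
    depths <- .term_depths(graph)
    ids <- names(full)
    ids <- ids[order(-depths[ids], ids)]        # deepest first, ties by id
    removed <- stats::setNames(vector("list", length(ids)), ids)
    pvals <- stats::setNames(rep(NA_real_, length(ids)), ids)
    for (t in ids) {
      genes_t <- setdiff(full[[t]], removed[[t]])
      a_t <- length(genes_t)
      s_t <- sum(study %in% genes_t)
      if (length(full[[t]]) < max(1L, min_node_size)) next
      if (sum(study %in% full[[t]]) < 1L) next
      p <- stats::phyper(s_t - 1L, a_t, u - a_t, s, lower.tail = FALSE)
      pvals[[t]] <- p
      if (p < alpha_elim) {
        for (anc in intersect(go_ancestors(graph, t), ids))
          removed[[anc]] <- union(removed[[anc]], genes_t)
      }
    }
    res <- .enrich_from_lists(full, full, study, universe, min_node_size,
                              p_override = pvals)
  }
  if (!is.null(graph$terms$name)) {
    atts <- attributes(res)[c("n_universe", "n_study")]
    res$name <- graph$terms$name[match(res$term_id, graph$terms$id)]
    res <- res[, c("term_id", "name", setdiff(names(res),
                                              c("term_id", "name")))]
    class(res) <- c("enrichment_result", "data.frame")
    attributes(res)[names(atts)] <- atts
  }
  attr(res, "method") <- method
  res
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat("enrichment_result:", nrow(x), "terms (",
      sum(x$tested, na.rm = TRUE), "tested ), study",
      attr(x, "n_study"), "of", attr(x, "n_universe"), "universe genes\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' Compare network-restricted and full-candidate enrichment
#'
#' Runs the same overrepresentation analysis with two study sets (the
#' cross-trait network genes and the entire candidate sets) and reports the
#' FDR columns side by side, flagging terms significant for the network
#' genes but not for the full candidate sets.
#'
#' @param graph A `go_graph`.
#' @param study_network,study_full Study gene sets (each within
#'   `universe`).
#' @param universe Universe gene ids.
#' @param annotations Annotation data frame.
#' @param fdr_alpha Significance threshold applied to both FDR columns.
#' @param ... Passed to [decorrelated_enrich()].
#' @return Data frame with `fdr` (network study set), `fdr_full`, and a
#'   logical `network_specific` flag.
#' @export
compare_universes <- function(graph, study_network, study_full, universe,
                              annotations, fdr_alpha = 0.05, ...) {
  res_net <- decorrelated_enrich(graph, study_network, universe,
                                 annotations, ...)
  res_full <- decorrelated_enrich(graph, study_full, universe,
                                  annotations, ...)
  m <- match(res_net$term_id, res_full$term_id)
  atts <- attributes(res_net)[c("n_universe", "n_study", "method")]
  res_net$fdr_full <- res_full$fdr[m]
  res_net$network_specific <- !is.na(res_net$fdr) &
    res_net$fdr < fdr_alpha &
    (is.na(res_net$fdr_full) | res_net$fdr_full >= fdr_alpha)
  attributes(res_net)[names(atts)] <- atts
  res_net
}

#' Membership of study genes in significant terms
#'
#' For each study gene annotated to at least one significant term, counts
#' the number of significant terms it belongs to, and tabulates the
#' distinct membership patterns (UpSet-style intersection counts).
#'
#' @param significant_terms Character vector of term ids.
#' @param study Study gene ids.
#' @param annotations Propagated annotation data frame.
#' @return List with `per_gene` (gene_id, n_terms), `mean`, `sd`, and
#'   `intersections` (pattern, n_genes).
#' @export
term_overlap_summary <- function(significant_terms, study, annotations) {
  ann <- unique(annotations[annotations$term_id %in% significant_terms &
                              annotations$gene_id %in% study,
                            c("gene_id", "term_id")])
  if (nrow(ann) == 0L) {
    return(list(per_gene = data.frame(gene_id = character(0),
                                      n_terms = integer(0)),
                mean = NA_real_, sd = NA_real_,
                intersections = data.frame(pattern = character(0),
                                           n_genes = integer(0))))
  }
  by_gene <- split(ann$term_id, ann$gene_id)
  n_terms <- vapply(by_gene, length, 0L)
  pattern <- vapply(by_gene, function(t) paste(sort(t), collapse = "&"), "")
  inter <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(inter) <- c("pattern", "n_genes")
  inter <- inter[order(-inter$n_genes, inter$pattern), , drop = FALSE]
  rownames(inter) <- NULL
  list(per_gene = data.frame(gene_id = names(by_gene),
                             n_terms = unname(n_terms),
                             stringsAsFactors = FALSE),
       mean = mean(n_terms), sd = stats::sd(n_terms),
       intersections = inter)
}
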