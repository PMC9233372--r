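#' Evidence-code frequencies of a GO term
#'
#' Frequencies are computed over all annotation records (distinct gene,
#' term, code triples after propagation) for the term:
#' `frequency(code) = records with that code / total records`. Frequencies
#' sum to one.
#'
#' @param term_id GO term id.
#' @param annotations Propagated annotation data frame (`gene_id`,
#'   `term_id`, `evidence`).
#' @return Named numeric vector of frequencies.
#' @export
evidence_code_frequencies <- function(term_id, annotations) {
  rec <- unique(annotations[annotations$term_id == term_id, , drop = FALSE])
  if (nrow(rec) == 0L)
    stop("no annotations for term ", term_id, call. = FALSE)
  tab <- table(rec$evidence)
  freq <- as.numeric(tab) / sum(tab)
  stats::setNames(freq, names(tab))
}

#' Evidence-based-process (EBP) weight of a gene for a term
#'
#' The weight has two components. The evidence component is the sum of the
#' term-level evidence-code frequencies over the distinct codes supporting
#' the gene's assignment to the term (each code counted once). The child
#' component is the fraction of the term's descendant terms to which the
#' gene is annotated, zero when the term has no descendants; under the
#' alternative `"whole-sum"` parse the division by the descendant count is
#' applied to the entire sum instead of the child count alone.
#'
#' @param gene_id Gene id (must be annotated to the term).
#' @param term_id GO term id.
#' @param graph A `go_graph`.
#' @param annotations Propagated annotation data frame.
#' @param ebp_parse `"child-fraction"` (default) or `"whole-sum"`.
#' @return List with `evidence_component`, `child_component`, `ebp`.
#' @export
compute_ebp <- function(gene_id, term_id, graph, annotations,
                        ebp_parse = c("child-fraction", "whole-sum")) {
  ebp_parse <- match.arg(ebp_parse)
  freq <- evidence_code_frequencies(term_id, annotations)
  codes <- unique(annotations$evidence[annotations$term_id == term_id &
                                         annotations$gene_id == gene_id])
  if (length(codes) == 0L)
    stop("gene ", gene_id, " is not annotated to term ", term_id,
         call. = FALSE)
  ev <- sum(freq[codes])
  desc <- go_descendants(graph, term_id)
  n_desc <- length(desc)
  hits <- if (n_desc == 0L) 0L else
    length(unique(annotations$term_id[annotations$gene_id == gene_id &
                                        annotations$term_id %in% desc]))
  if (ebp_parse == "child-fraction") {
    child <- if (n_desc == 0L) 0 else hits / n_desc
    ebp <- ev + child
  } else {
    child <- hits
    ebp <- if (n_desc == 0L) ev else (ev + hits) / n_desc
  }
  list(evidence_component = ev, child_component = child, ebp = ebp)
}

# EBP weights for every gene annotated to a term (vectorized over genes).
.term_ebp_weights <- function(term_id, graph, annotations, ebp_parse) {
  rec <- annotations[annotations$term_id == term_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no annotations for term ", term_id, call. = FALSE)
  freq <- evidence_code_frequencies(term_id, annotations)
  by_gene <- split(rec$evidence, rec$gene_id)
  ev <- vapply(by_gene, function(cds) sum(freq[unique(cds)]), 0)
  desc <- go_descendants(graph, term_id)
  n_desc <- length(desc)
  genes <- names(by_gene)
  if (n_desc == 0L) {
    hits <- rep(0L, length(genes))
  } else {
    sub <- unique(annotations[annotations$term_id %in% desc &
                                annotations$gene_id %in% genes,
                              c("gene_id", "term_id")])
    tab <- table(factor(sub$gene_id, levels = genes))
    hits <- as.integer(tab)
  }
  ebp <- if (ebp_parse == "child-fraction") {
    ev + if (n_desc == 0L) 0 else hits / n_desc
  } else {
    if (n_desc == 0L) ev else (ev + hits) / n_desc
  }
  data.frame(gene_id = genes, ebp = unname(ebp), stringsAsFactors = FALSE)
}

#' Per-individual dysfunction score for one biological process
#'
#' `DBP = sum over the individual's PDV-bearing genes assigned to the term
#' of (gene PDV burden x gene EBP weight) / nGenes`, where `nGenes` is the
#' number of genes assigned to the term in the analysis universe.
#'
#' @param burden_genes Named numeric vector: the individual's `pdv_sum` per
#'   gene.
#' @param ebp_weights Data frame `gene_id`, `ebp` for the term's genes.
#' @param n_genes_term Number of genes assigned to the term (> 0).
#' @return The DBP score (non-negative scalar).
#' @export
compute_dbp <- function(burden_genes, ebp_weights, n_genes_term) {
  if (n_genes_term <= 0L)
    stop("n_genes_term must be positive", call. = FALSE)
  shared <- intersect(names(burden_genes), ebp_weights$gene_id)
  if (length(shared) == 0L) return(0)
  w <- ebp_weights$ebp[match(shared, ebp_weights$gene_id)]
  sum(burden_genes[shared] * w) / n_genes_term
}

#' Individuals-by-terms DBP score matrix
#'
#' Computes the dysfunction score of every individual for every requested
#' biological process. Annotations are propagated (true-path rule) and
#' restricted to the analysis universe; `nGenes` per term counts all
#' annotated universe genes.
#'
#' @param burden A [gene_burden()] table.
#' @param terms Character vector of GO term ids (typically the significant
#'   terms from enrichment).
#' @param graph A `go_graph`.
#' @param annotations Annotation data frame (propagated internally unless
#'   `propagate = FALSE`).
#' @param universe Gene universe; defaults to all annotated genes.
#' @param individuals Individuals to include (rows); defaults to those in
#'   the burden table. Individuals without any scored gene get 0.
#' @param ebp_parse Passed to the EBP computation.
#' @param propagate Apply the true-path rule first.
#' @return Numeric matrix of class `dbp_matrix` (individuals x terms) with
#'   attributes `n_genes` (per term) and `ebp_weights`.
#' @export
dbp_matrix <- function(burden, terms, graph, annotations, universe = NULL,
                       individuals = NULL,
                       ebp_parse = c("child-fraction", "whole-sum"),
                       propagate = TRUE) {
  ebp_parse <- match.arg(ebp_parse)
  if (propagate) annotations <- propagate_annotations(graph, annotations)
  if (is.null(universe)) universe <- unique(annotations$gene_id)
  annotations <- annotations[annotations$gene_id %in% universe, ,
                             drop = FALSE]
  if (is.null(individuals)) individuals <- sort(unique(burden$individual_id))
  mat <- matrix(0, nrow = length(individuals), ncol = length(terms),
                dimnames = list(individuals, terms))
  n_genes <- stats::setNames(integer(length(terms)), terms)
  weights <- vector("list", length(terms))
  names(weights) <- terms
  for (t in terms) {
    w <- .term_ebp_weights(t, graph, annotations, ebp_parse)
    n_genes[[t]] <- nrow(w)
    weights[[t]] <- w
    sub <- burden[burden$gene_id %in% w$gene_id &
                    burden$individual_id %in% individuals, , drop = FALSE]
    if (nrow(sub) == 0L) next
    contrib <- sub$pdv_sum * w$ebp[match(sub$gene_id, w$gene_id)]
    agg <- rowsum(contrib, group = sub$individual_id)
    mat[rownames(agg), t] <- agg[, 1L] / n_genes[[t]]
  }
  structure(mat, n_genes = n_genes, ebp_weights = weights,
            ebp_parse = ebp_parse, class = c("dbp_matrix", "matrix", "array"))
}

#' @export
print.dbp_matrix <- function(x, ...) {
  cat("dbp_matrix:", nrow(x), "individuals x", ncol(x), "processes\n")
  cat("  genes per process:",
      paste(colnames(x), attr(x, "n_genes"), sep = "=", collapse = ", "),
      "\n")
  cat("  proportion with DBP > 0 per process:",
      paste(round(colMeans(x > 0), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Distribution diagnostics for DBP scores
#'
#' Per-process Shapiro-Wilk normality tests (skipped with a note for
#' constant columns; samples above 5000 are subsampled with `seed`),
#' pairwise Spearman rank correlations with p-values, the per-process
#' proportion of individuals with any evidence of dysfunction (DBP > 0),
#' the per-individual count of dysfunctional processes (mean, sd), and the
#' process with the highest proportion of dysfunction — the selection rule
#' for the association phenotype.
#'
#' @param mat A `dbp_matrix`.
#' @param seed Seed used only when subsampling for Shapiro-Wilk.
#' @return List of class `dbp_diagnostics`.
#' @export
dbp_diagnostics <- function(mat, seed = 1L) {
  if (nrow(mat) < 3L) stop("need at least 3 individuals", call. = FALSE)
  terms <- colnames(mat)
  shapiro <- data.frame(term_id = terms, W = NA_real_, p = NA_real_,
                        note = "", stringsAsFactors = FALSE)
  for (i in seq_along(terms)) {
    x <- mat[, i]
    if (length(unique(x)) < 2L) {
      shapiro$note[i] <- "constant column; normality test skipped"
      next
    }
    if (length(x) > 5000L) {
      if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
      old <- get(".Random.seed", envir = globalenv())
      set.seed(seed)
      x <- sample(x, 5000L)
      assign(".Random.seed", old, envir = globalenv())
      shapiro$note[i] <- "subsampled to 5000"
    }
    sw <- stats::shapiro.test(x)
    shapiro$W[i] <- unname(sw$statistic)
    shapiro$p[i] <- sw$p.value
  }
  k <- length(terms)
  rho <- matrix(NA_real_, k, k, dimnames = list(terms, terms))
  rho_p <- rho
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { rho[i, j] <- 1; next }
      if (stats::sd(mat[, i]) == 0 || stats::sd(mat[, j]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(mat[, i], mat[, j], method = "spearman"))
      rho[i, j] <- unname(ct$estimate)
      rho_p[i, j] <- ct$p.value
    }
  }
  prop_pos <- colMeans(mat > 0)
  n_dys <- rowSums(mat > 0)
  structure(list(
    shapiro = shapiro, spearman_rho = rho, spearman_p = rho_p,
    prop_dysfunction = prop_pos,
    n_processes_per_individual = n_dys,
    mean_processes = mean(n_dys), sd_processes = stats::sd(n_dys),
    prop_any_dysfunction = mean(n_dys > 0),
    top_term = terms[which.max(prop_pos)]
  ), class = "dbp_diagnostics")
}

#' @export
print.dbp_diagnostics <- function(x, ...) {
  cat("DBP diagnostics\n")
  cat("  proportion with any dysfunction:",
      round(x$prop_any_dysfunction, 4), "\n")
  cat("  dysfunctional processes per individual: mean",
      round(x$mean_processes, 3), "sd", round(x$sd_processes, 3), "\n")
  cat("  process with highest evidence of dysfunction:", x$top_term,
      "(", round(max(x$prop_dysfunction), 3), ")\n")
  invisible(x)
}

#' Plot per-process DBP score distributions
#'
#' @param x A `dbp_matrix`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.dbp_matrix <- function(x, ...) {
  graphics::boxplot(as.data.frame(unclass(x)),
                    ylab = "DBP score", las = 2, ...)
  invisible(x)
}
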