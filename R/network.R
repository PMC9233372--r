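#' Restrict two candidate gene sets to PDV-bearing genes
#'
#' A gene is PDV-bearing if at least one individual carries a positive PDV
#' burden in it. Genes present in both candidate sets are labeled `both`.
#'
#' @param set_a,set_b Character vectors of candidate gene ids.
#' @param burden A [gene_burden()] table.
#' @return List with `A`, `B` (restricted sets) and `labels` (data frame
#'   `gene_id`, `label` with label in `A`/`B`/`both`).
#' @export
restrict_to_pdv <- function(set_a, set_b, burden) {
  pdv_genes <- unique(burden$gene_id[burden$pdv_sum > 0])
  a <- intersect(set_a, pdv_genes)
  b <- intersect(set_b, pdv_genes)
  if (length(a) == 0L)
    stop("no PDV-bearing genes remain in candidate set A", call. = FALSE)
  if (length(b) == 0L)
    stop("no PDV-bearing genes remain in candidate set B", call. = FALSE)
  genes <- sort(union(a, b))
  label <- ifelse(genes %in% a & genes %in% b, "both",
                  ifelse(genes %in% a, "A", "B"))
  list(A = sort(a), B = sort(b),
       labels = data.frame(gene_id = genes, label = label,
                           stringsAsFactors = FALSE))
}

#' Build the cross-trait protein-interaction subnetwork
#'
#' Retains interaction edges whose endpoints are both PDV-bearing candidate
#' genes and whose labels span the two sets: A-B, A-both, B-both or
#' both-both (a gene implicated in both sets can stand on either side).
#' Edges below `min_score` are dropped; self-loops and duplicate undirected
#' edges are collapsed. With `cross_only = FALSE` all edges among candidate
#' genes are kept (the full subgraph used for visualization).
#'
#' @param restricted Output of [restrict_to_pdv()] (or a list with `A`,
#'   `B`).
#' @param edges Data frame `protein1`, `protein2`, `combined_score`.
#' @param min_score Minimum combined score (default 400).
#' @param id_map Optional data frame `gene_id`, `protein_id`; defaults to
#'   identity (edge endpoints already gene ids). Genes without a mapping
#'   are dropped with a message.
#' @param cross_only Keep only edges connecting the A side to the B side.
#' @return A list of class `pleiotropy_network` with `nodes` (gene_id,
#'   label, has_pdv), `edges` (gene_u, gene_v, combined_score) and the
#'   retention parameters.
#' @export
build_network <- function(restricted, edges, min_score = 400,
                          id_map = NULL, cross_only = TRUE) {
  a <- restricted$A
  b <- restricted$B
  genes <- union(a, b)
  if (is.null(id_map)) {
    id_map <- data.frame(gene_id = genes, protein_id = genes,
                         stringsAsFactors = FALSE)
  }
  mapped <- genes[genes %in% id_map$gene_id]
  n_unmapped <- length(genes) - length(mapped)
  if (n_unmapped > 0L)
    message(n_unmapped, " candidate gene(s) without protein mapping dropped")
  p2g <- stats::setNames(id_map$gene_id, id_map$protein_id)

  e <- edges[edges$combined_score >= min_score, , drop = FALSE]
  gu <- unname(p2g[as.character(e$protein1)])
  gv <- unname(p2g[as.character(e$protein2)])
  keep <- !is.na(gu) & !is.na(gv) & gu %in% mapped & gv %in% mapped & gu != gv
  e <- data.frame(gene_u = pmin(gu[keep], gv[keep]),
                  gene_v = pmax(gu[keep], gv[keep]),
                  combined_score = e$combined_score[keep],
                  stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$gene_u, e$gene_v, sep = "\r")), , drop = FALSE]

  if (cross_only) {
    a_side <- function(g) g %in% a         # "both" genes qualify as either
    b_side <- function(g) g %in% b
    cross <- (a_side(e$gene_u) & b_side(e$gene_v)) |
      (b_side(e$gene_u) & a_side(e$gene_v))
    e <- e[cross, , drop = FALSE]
  }
  rownames(e) <- NULL
  node_ids <- sort(unique(c(e$gene_u, e$gene_v)))
  labels <- restricted$labels
  nodes <- data.frame(
    gene_id = node_ids,
    label = labels$label[match(node_ids, labels$gene_id)],
    has_pdv = rep(TRUE, length(node_ids)), stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = e, min_score = min_score,
                 cross_only = cross_only),
            class = "pleiotropy_network")
}

#' @export
print.pleiotropy_network <- function(x, ...) {
  cat("pleiotropy_network:", nrow(x$nodes), "genes,", nrow(x$edges),
      if (x$cross_only) "cross-set edges" else "edges",
      "(score >=", x$min_score, ")\n")
  if (nrow(x$nodes) > 0L) {
    tab <- table(x$nodes$label)
    cat("  node labels:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a pleiotropy network to an igraph object
#'
#' @param network A `pleiotropy_network`.
#' @return An undirected [igraph::graph] with `label` vertex attribute and
#'   `combined_score` edge attribute.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes
  )
}

#' Network gene universe for enrichment
#'
#' The union of retained network nodes: the study set used for GO
#' overrepresentation of cross-trait interacting genes.
#'
#' @param network A `pleiotropy_network`.
#' @return Character vector of gene ids.
#' @export
network_genes <- function(network) {
  network$nodes$gene_id
}
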