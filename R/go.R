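#' Construct a GO graph object
#'
#' A light container for a Gene Ontology DAG: a term table and child ->
#' parent edges (`is_a` and `part_of` are treated identically for
#' annotation propagation). The graph is checked for acyclicity.
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param parents Named list: for each term id, character vector of parent
#'   term ids (empty for roots).
#' @return A list of class `go_graph` with elements `terms`, `parents`,
#'   `children`.
#' @export
go_graph <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  ids <- terms$id
  parents <- parents[ids[ids %in% names(parents)]]
  missing <- setdiff(ids, names(parents))
  parents[missing] <- list(character(0))
  parents <- lapply(parents, function(p) intersect(p, ids))
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  g <- structure(list(terms = terms[, c("id", "name", "namespace")],
                      parents = parents[ids], children = children),
                 class = "go_graph")
  if (is.null(.topo_order(g)))
    stop("cycle detected in ontology graph", call. = FALSE)
  g
}

#' @export
print.go_graph <- function(x, ...) {
  roots <- sum(lengths(x$parents) == 0L)
  cat("go_graph with", nrow(x$terms), "terms (", roots, "root(s) ),",
      sum(lengths(x$parents)), "child->parent edges\n")
  invisible(x)
}

# Topological order (children before parents); NULL if cyclic.
.topo_order <- function(graph) {
  ids <- graph$terms$id
  indeg <- stats::setNames(lengths(graph$children)[ids], ids)
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, t)
    for (p in graph$parents[[t]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(ids)) NULL else out
}

#' Ancestors of a GO term (excluding the term itself)
#'
#' @param graph A `go_graph`.
#' @param term_id Term identifier.
#' @return Character vector of ancestor term ids.
#' @export
go_ancestors <- function(graph, term_id) {
  .reachable(graph$parents, term_id)
}

#' Descendants of a GO term (excluding the term itself)
#'
#' @param graph A `go_graph`.
#' @param term_id Term identifier.
#' @return Character vector of descendant term ids.
#' @export
go_descendants <- function(graph, term_id) {
  .reachable(graph$children, term_id)
}

.reachable <- function(adj, start) {
  if (!start %in% names(adj))
    stop("unknown term id: ", start, call. = FALSE)
  seen <- character(0)
  frontier <- adj[[start]]
  while (length(frontier) > 0L) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(adj[new], use.names = FALSE))
  }
  seen
}

# Longest-path depth from any root, per term (roots have depth 0).
.term_depths <- function(graph) {
  ord <- .topo_order(graph)                  # children first
  depth <- stats::setNames(rep(0L, length(ord)), ord)
  for (t in rev(ord)) {                      # parents first
    for (ch in graph$children[[t]])
      depth[[ch]] <- max(depth[[ch]], depth[[t]] + 1L)
  }
  depth
}

#' Read an OBO 1.2 ontology file
#'
#' Minimal parser for the `[Term]` stanzas of OBO 1.2: `id`, `name`,
#' `namespace`, `is_a` and `relationship: part_of` are honored; obsolete
#' terms are skipped. Both `is_a` and `part_of` edges enter the parent
#' relation used for true-path propagation.
#'
#' @param path Path to the OBO file.
#' @param namespace Keep only terms in this namespace (default
#'   `"biological_process"`; `NULL` keeps all).
#' @return A `go_graph`.
#' @export
read_obo <- function(path, namespace = "biological_process") {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      hit <- block[startsWith(block, paste0(key, ":"))]
      if (length(hit) == 0L) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", hit[1L]))
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) stop("OBO [Term] stanza without id near line ",
                        bounds[i], call. = FALSE)
    isa <- block[startsWith(block, "is_a:")]
    isa <- trimws(sub("!.*$", "", sub("^is_a:", "", isa)))
    rel <- block[startsWith(block, "relationship:")]
    rel <- trimws(sub("^relationship:", "", rel))
    partof <- rel[startsWith(rel, "part_of")]
    partof <- trimws(sub("!.*$", "", sub("^part_of", "", partof)))
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    nss <- c(nss, get1("namespace"))
    parents[[id]] <- unique(c(isa, partof))
  }
  terms <- data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE)
  if (!is.null(namespace)) {
    keep <- is.na(terms$namespace) | terms$namespace == namespace
    terms <- terms[keep, , drop = FALSE]
    parents <- parents[terms$id]
  }
  go_graph(terms, parents)
}

#' Write a `go_graph` as a minimal OBO 1.2 file
#'
#' @param graph A `go_graph`.
#' @param path Output path.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", graph$terms$name[i]), con)
    writeLines(paste0("namespace: ", graph$terms$namespace[i]), con)
    for (p in graph$parents[[id]])
      writeLines(paste0("is_a: ", p, " ! parent"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read gene annotations from a GAF 2.x file
#'
#' Keeps rows in the biological_process aspect (`P`), drops `NOT`-qualified
#' rows, and collapses duplicate (gene, term, evidence) triples.
#'
#' @param path Path to the GAF file (`!`-prefixed header lines are skipped).
#' @return Data frame with columns `gene_id`, `term_id`, `evidence`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L)
    return(data.frame(gene_id = character(0), term_id = character(0),
                      evidence = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 9L))
    stop("malformed GAF line ", which(nf < 9L)[1], call. = FALSE)
  df <- data.frame(
    gene_id = vapply(parts, `[[`, "", 2L),
    qualifier = vapply(parts, `[[`, "", 4L),
    term_id = vapply(parts, `[[`, "", 5L),
    evidence = vapply(parts, `[[`, "", 7L),
    aspect = vapply(parts, `[[`, "", 9L),
    stringsAsFactors = FALSE
  )
  df <- df[df$aspect == "P" & !grepl("NOT", df$qualifier), , drop = FALSE]
  out <- unique(df[, c("gene_id", "term_id", "evidence")])
  rownames(out) <- NULL
  out
}

#' Write annotations as a minimal GAF 2.2 file
#'
#' @param annotations Data frame with `gene_id`, `term_id`, `evidence`.
#' @param path Output path.
#' @export
write_gaf <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  if (nrow(annotations) > 0L) {
    rows <- paste("SIM", annotations$gene_id, annotations$gene_id, "involved_in",
                  annotations$term_id, "SIM:ref", annotations$evidence, "",
                  "P", annotations$gene_id, "", "protein", "taxon:9606",
                  "20200101", "SIM", sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' A gene annotated to a term is annotated, with the same evidence code, to
#' every ancestor of that term. The operation is idempotent.
#'
#' @param graph A `go_graph`.
#' @param annotations Data frame with `gene_id`, `term_id`, `evidence`.
#' @return Propagated annotation data frame (distinct triples).
#' @export
propagate_annotations <- function(graph, annotations) {
  annotations <- annotations[annotations$term_id %in% graph$terms$id, ,
                             drop = FALSE]
  if (nrow(annotations) == 0L) return(annotations)
  anc <- lapply(stats::setNames(nm = unique(annotations$term_id)),
                function(t) c(t, go_ancestors(graph, t)))
  reps <- lengths(anc[annotations$term_id])
  out <- data.frame(
    gene_id = rep(annotations$gene_id, reps),
    term_id = unlist(anc[annotations$term_id], use.names = FALSE),
    evidence = rep(annotations$evidence, reps),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  rownames(out) <- NULL
  out
}
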