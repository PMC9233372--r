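#' Hand-traceable fixtures with independently computed oracle answers
#'
#' Builds the small deterministic fixtures used across the test suite,
#' each accompanied by an oracle answer computed here by an independent
#' route (combinatorial arithmetic, closed-form algebra), not by the
#' pipeline functions under test.
#'
#' Fixtures:
#' \describe{
#'   \item{enrich20}{20-gene universe, 5 study genes, a term annotated to 4
#'     genes of which 3 are in the study; oracle upper-tail hypergeometric
#'     probability from binomial coefficients (496/15504).}
#'   \item{dag5}{5-term chain-and-branch DAG with annotations and evidence
#'     codes used by the elimination and EBP tests.}
#'   \item{reg6}{6-row regression design; oracle coefficients from the
#'     normal equations `(X'X)^{-1} X'y`.}
#'   \item{features4}{two 4-gene feature sets; oracle Welch t statistic for
#'     GC content from the closed-form formula.}
#' }
#'
#' @return Named list of fixtures.
#' @export
make_fixture_suite <- function() {
  ## enrich20: universe of 20, study of 5, anno 4, sig 3 -----------------
  universe <- sprintf("u%02d", 1:20)
  study <- universe[1:5]
  term_genes <- universe[c(1, 2, 3, 6)]            # 3 study, 1 non-study
  annotations <- data.frame(gene_id = term_genes, term_id = "GO:TEST",
                            evidence = "IEA", stringsAsFactors = FALSE)
  # oracle: P(X >= 3) for X ~ Hypergeom(N = 20, K = 4, n = 5)
  tail_p <- sum(vapply(3:4, function(k)
    choose(4, k) * choose(16, 5 - k), 0)) / choose(20, 5)
  enrich20 <- list(universe = universe, study = study,
                   annotations = annotations,
                   oracle_p = tail_p)               # = 496/15504

  ## dag5: root t1 <- t2 <- {t4, t5}; t1 <- t3 ---------------------------
  terms <- data.frame(
    id = paste0("GO:000000", 1:5),
    name = c("root", "mid", "branch", "leaf A", "leaf B"),
    namespace = "biological_process", stringsAsFactors = FALSE)
  parents <- list("GO:0000001" = character(0),
                  "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000001",
                  "GO:0000004" = "GO:0000002",
                  "GO:0000005" = "GO:0000002")
  graph <- go_graph(terms, parents)
  dag_universe <- sprintf("d%02d", 1:20)
  # leaf A holds the planted signal: genes d01..d04
  dag_ann <- data.frame(
    gene_id = c("d01", "d02", "d03", "d04",      # leaf A
                "d05", "d06",                     # leaf B
                "d07", "d08",                     # direct on mid
                "d09", "d10", "d11"),             # branch
    term_id = c(rep("GO:0000004", 4), rep("GO:0000005", 2),
                rep("GO:0000002", 2), rep("GO:0000003", 3)),
    evidence = c("IDA", "IDA", "IEA", "IEA", "IEA", "IEA",
                 "IEA", "IEA", "IEA", "IEA", "IEA"),
    stringsAsFactors = FALSE)
  dag_study <- c("d01", "d02", "d03", "d04", "d09")
  dag5 <- list(graph = graph, annotations = dag_ann,
               universe = dag_universe, study = dag_study)

  ## reg6: 6-row design, oracle via normal equations ---------------------
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(0, 1, 0, 1, 1, 0)
  y <- c(3.1, 5.2, 6.9, 9.4, 11.2, 12.8)
  X <- cbind(1, x1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  reg6 <- list(x1 = x1, x2 = x2, y = y, oracle_beta = unname(drop(beta)))

  ## features4: two small sets with a closed-form Welch t on GC ----------
  features <- data.frame(
    gene_id = c(paste0("fa", 1:4), paste0("fb", 1:4)),
    gc_content = c(0.40, 0.42, 0.44, 0.46, 0.50, 0.52, 0.54, 0.56),
    transcript_size = c(1000, 1200, 1400, 1600, 2000, 2200, 2400, 2600),
    n_spliceoforms = c(2, 3, 4, 5, 4, 5, 6, 7),
    stringsAsFactors = FALSE)
  g1 <- features$gc_content[1:4]
  g2 <- features$gc_content[5:8]
  tw <- (mean(g1) - mean(g2)) /
    sqrt(stats::var(g1) / 4 + stats::var(g2) / 4)
  features4 <- list(features = features,
                    set1 = paste0("fa", 1:4), set2 = paste0("fb", 1:4),
                    oracle_t_gc = tw)

  list(enrich20 = enrich20, dag5 = dag5, reg6 = reg6,
       features4 = features4)
}
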