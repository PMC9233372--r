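test_that("evidence-code frequencies normalize over term records", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g3"),
                    term_id = "t1",
                    evidence = c("IDA", "IEA", "IDA", "IEA"),
                    stringsAsFactors = FALSE)
  f <- evidence_code_frequencies("t1", ann)
  expect_equal(f[["IDA"]], 0.5)
  expect_equal(f[["IEA"]], 0.5)
  expect_equal(sum(f), 1)

  single <- data.frame(gene_id = "g1", term_id = "t2", evidence = "EXP")
  expect_equal(evidence_code_frequencies("t2", single), c(EXP = 1))
  expect_error(evidence_code_frequencies("t9", ann), "no annotations")
})

test_that("EBP weight adds evidence frequencies and the child fraction", {
  # term T with 4 descendants; gene hits 2 of them; freq(IDA) = 0.5
  terms <- data.frame(id = c("T", "c1", "c2", "c3", "c4"),
                      name = "x", namespace = "biological_process")
  parents <- list(T = character(0), c1 = "T", c2 = "T", c3 = "T", c4 = "T")
  g <- go_graph(terms, parents)
  ann <- data.frame(
    gene_id = c("g1", "g2", "g1", "g1"),
    term_id = c("T", "T", "c1", "c2"),
    evidence = c("IDA", "IEA", "IDA", "IDA"),
    stringsAsFactors = FALSE)
  prop <- propagate_annotations(g, ann)
  e <- compute_ebp("g1", "T", g, prop)
  expect_equal(e$evidence_component, 0.5)
  expect_equal(e$child_component, 0.5)        # 2 of 4 descendants
  expect_equal(e$ebp, 1.0)

  # no descendants: child component is zero
  lone <- go_graph(data.frame(id = "L", name = "x",
                              namespace = "biological_process"),
                   list(L = character(0)))
  ann_l <- data.frame(gene_id = "g1", term_id = "L", evidence = "EXP")
  el <- compute_ebp("g1", "L", lone, ann_l)
  expect_equal(el$child_component, 0)
  expect_equal(el$ebp, el$evidence_component)

  # symmetry: identical codes and descendant hits give identical weights
  ann2 <- rbind(ann, data.frame(gene_id = "g3", term_id = c("T", "c1", "c2"),
                                evidence = "IDA"))
  prop2 <- propagate_annotations(g, ann2)
  expect_equal(compute_ebp("g1", "T", g, prop2)$ebp,
               compute_ebp("g3", "T", g, prop2)$ebp)

  expect_error(compute_ebp("g2", "c1", g, prop), "not annotated")

  # alternative whole-sum parse divides everything by the child count
  ew <- compute_ebp("g1", "T", g, prop, ebp_parse = "whole-sum")
  expect_equal(ew$ebp, (0.5 + 2) / 4)
})

test_that("DBP equals the printed equation on hand-computed cases", {
  w <- data.frame(gene_id = c("gA", "gB"), ebp = c(0.8, 0.2))
  expect_equal(compute_dbp(c(gA = 1.5), data.frame(gene_id = "gA", ebp = 1),
                           3), 0.5)
  expect_equal(compute_dbp(c(gA = 1.0, gB = 2.0), w, 4), 0.3)
  expect_equal(compute_dbp(c(gZ = 5), w, 4), 0)      # no assigned gene
  expect_error(compute_dbp(c(gA = 1), w, 0), "positive")
})

test_that("single gene/variant/term DBP matches the closed form", {
  # one individual, one het variant called damaging by all 9 predictors in
  # the only annotated gene of a childless term
  tab <- toy_variants(data.frame(genotype = "hom"))
  rec <- score_variants(tab, c(i1 = "female"))
  burden <- gene_burden(rec)
  g <- go_graph(data.frame(id = "T", name = "x",
                           namespace = "biological_process"),
                list(T = character(0)))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"), term_id = "T",
                    evidence = c("IDA", "IEA", "IEA"))
  m <- dbp_matrix(burden, "T", g, ann)
  # fd = 1, Z = 2, ebp = freq(IDA) = 1/3, n = 3 genes
  expect_equal(m["i1", "T"], (1 * 2 * (1 / 3)) / 3)
})

test_that("DBP is linear, additive and monotone in gene burdens", {
  sim <- small_sim()
  qc <- apply_qc_filter(sim$variants)
  burden <- gene_burden(score_variants(qc, sim$sex, sim$par_regions))
  term <- sim$ledger$target_term
  m0 <- dbp_matrix(burden, term, sim$graph, sim$annotations)
  # zero iff no PDV in an assigned gene
  ann_prop <- propagate_annotations(sim$graph, sim$annotations)
  assigned <- unique(ann_prop$gene_id[ann_prop$term_id == term])
  has_hit <- vapply(rownames(m0), function(i) {
    any(burden$pdv_sum[burden$individual_id == i &
                         burden$gene_id %in% assigned] > 0)
  }, TRUE)
  expect_equal(unname(m0[, 1] > 0), unname(has_hit))

  set.seed(5)
  for (cc in c(0, 0.5, 2, 10)) {
    b2 <- burden
    b2$pdv_sum <- b2$pdv_sum * cc
    m2 <- dbp_matrix(b2, term, sim$graph, sim$annotations,
                     individuals = rownames(m0))
    expect_equal(unname(m2[, 1]), unname(cc * m0[, 1]), tolerance = 1e-12)
  }

  # monotonicity: adding burden to an assigned gene never decreases DBP
  for (i in 1:25) {
    b3 <- burden
    row <- sample(which(b3$gene_id %in% assigned), 1)
    b3$pdv_sum[row] <- b3$pdv_sum[row] + runif(1, 0, 2)
    m3 <- dbp_matrix(b3, term, sim$graph, sim$annotations,
                     individuals = rownames(m0))
    expect_true(all(m3[, 1] >= m0[, 1] - 1e-12))
  }
})

test_that("diagnostics report dysfunction proportions and correlations", {
  set.seed(21)
  x <- rexp(60)
  mat <- cbind(t1 = x, t2 = x + 1, t3 = rep(0, 60),
               t4 = c(rep(0, 30), rexp(30)))
  class(mat) <- c("dbp_matrix", "matrix", "array")
  attr(mat, "n_genes") <- c(t1 = 5L, t2 = 5L, t3 = 5L, t4 = 5L)
  d <- dbp_diagnostics(mat)
  expect_equal(d$spearman_rho["t1", "t2"], 1)     # rank-concordant
  expect_match(d$shapiro$note[3], "constant")
  expect_true(is.na(d$shapiro$W[3]))
  expect_equal(unname(d$prop_dysfunction["t4"]), 0.5)
  expect_equal(d$top_term, "t1")

  # Spearman equals a rank-and-correlate oracle
  oracle <- cor(rank(mat[, "t1"]), rank(mat[, "t4"]))
  expect_equal(d$spearman_rho["t1", "t4"], oracle, tolerance = 1e-12)

  expect_error(dbp_diagnostics(mat[1:2, ]), "3 individuals")
})
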