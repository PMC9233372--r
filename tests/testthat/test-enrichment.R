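test_that("true-path propagation closes annotations over ancestors", {
  fx <- fixtures()$dag5
  g <- fx$graph
  ann <- data.frame(gene_id = "x", term_id = "GO:0000004",
                    evidence = "IDA", stringsAsFactors = FALSE)
  prop <- propagate_annotations(g, ann)
  expect_setequal(prop$term_id, c("GO:0000004", "GO:0000002", "GO:0000001"))
  # idempotent
  expect_equal(nrow(propagate_annotations(g, prop)), nrow(prop))
  # annotation to the root is unchanged
  root <- data.frame(gene_id = "x", term_id = "GO:0000001",
                     evidence = "IEA")
  expect_equal(nrow(propagate_annotations(g, root)), 1L)

  # 3-level chain: closure size equals brute-force reachability
  chain <- go_graph(
    data.frame(id = c("t1", "t2", "t3"), name = "x",
               namespace = "biological_process"),
    list(t1 = character(0), t2 = "t1", t3 = "t2"))
  leaf_ann <- data.frame(gene_id = "g", term_id = "t3", evidence = "IEA")
  # independent oracle: DFS reachability from t3 through parent links
  reach <- function(adj, s) {
    seen <- character(0); stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v); stack <- c(stack, adj[[v]])
    }
    seen
  }
  oracle <- reach(list(t1 = character(0), t2 = "t1", t3 = "t2"), "t3")
  expect_setequal(propagate_annotations(chain, leaf_ann)$term_id, oracle)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  fx <- fixtures()$enrich20
  res <- fisher_enrich(fx$study, fx$universe, fx$annotations)
  expect_equal(res$anno, 4L)
  expect_equal(res$sig, 3L)
  expect_equal(res$p, fx$oracle_p)            # 496/15504
  expect_equal(res$p, 496 / 15504)
  expect_equal(res$exp, 4 * 5 / 20)
  expect_equal(res$fe, res$sig / res$exp)

  # a term with no study gene is reported as non-tested
  ann2 <- rbind(fx$annotations,
                data.frame(gene_id = c("u10", "u11"), term_id = "GO:NONE",
                           evidence = "IEA"))
  res2 <- fisher_enrich(fx$study, fx$universe, ann2)
  expect_false(res2$tested[res2$term_id == "GO:NONE"])
  expect_true(is.na(res2$p[res2$term_id == "GO:NONE"]))

  # degenerate table: term annotated to the whole universe has p = 1
  ann3 <- data.frame(gene_id = fx$universe, term_id = "GO:ALL",
                     evidence = "IEA")
  res3 <- fisher_enrich(fx$study, fx$universe, ann3)
  expect_equal(res3$p, 1)

  # study outside universe is fatal
  expect_error(fisher_enrich(c("zz"), fx$universe, fx$annotations),
               "universe")
})

test_that("Fisher p equals brute-force tail sums on random small tables", {
  # independent oracle: explicit sum of hypergeometric point masses
  brute_tail <- function(sig, anno, u, s) {
    ks <- sig:min(anno, s)
    sum(choose(anno, ks) * choose(u - anno, s - ks)) / choose(u, s)
  }
  set.seed(404)
  for (i in 1:200) {
    u <- sample(4:30, 1)
    s <- sample(1:u, 1)
    anno <- sample(1:u, 1)
    universe <- sprintf("g%02d", 1:u)
    study <- sample(universe, s)
    term_genes <- sample(universe, anno)
    sig <- length(intersect(study, term_genes))
    if (sig == 0) next
    ann <- data.frame(gene_id = term_genes, term_id = "T",
                      evidence = "IEA")
    res <- fisher_enrich(study, universe, ann)
    expect_equal(res$p, brute_tail(sig, anno, u, s), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches hand-computed step-up and is stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.003, 0.04, 0.2, 0.8, 0.012)
  expect_equal(sort(bh_fdr(p)), sort(bh_fdr(rev(p))))  # order-invariant
  expect_true(all(bh_fdr(p) >= p))
})

test_that("elim discounts parents for significant children", {
  fx <- fixtures()$dag5
  classic <- decorrelated_enrich(fx$graph, fx$study, fx$universe,
                                 fx$annotations, method = "classic",
                                 min_node_size = 1)
  elim <- decorrelated_enrich(fx$graph, fx$study, fx$universe,
                              fx$annotations, method = "elim",
                              alpha_elim = 0.01, min_node_size = 1)
  pc <- function(r, t) r$p[r$term_id == t]
  # leaf A is significant; its ancestors lose leaf-A genes, so their
  # elim p cannot be smaller than the classic p
  expect_lt(pc(elim, "GO:0000004"), 0.01)
  expect_gte(pc(elim, "GO:0000002"), pc(classic, "GO:0000002"))
  expect_gte(pc(elim, "GO:0000001"), pc(classic, "GO:0000001"))
  # the untouched branch is identical under both methods
  expect_equal(pc(elim, "GO:0000003"), pc(classic, "GO:0000003"))

  # with no significant children, elim == classic everywhere
  weak_study <- c("d01", "d09", "d10")
  c2 <- decorrelated_enrich(fx$graph, weak_study, fx$universe,
                            fx$annotations, method = "classic",
                            min_node_size = 1)
  e2 <- decorrelated_enrich(fx$graph, weak_study, fx$universe,
                            fx$annotations, method = "elim",
                            alpha_elim = 1e-6, min_node_size = 1)
  expect_equal(e2$p, c2$p)
})

test_that("elim with alpha 0 reduces exactly to classic on random DAGs", {
  set.seed(99)
  for (i in 1:10) {
    n_terms <- sample(5:12, 1)
    ids <- sprintf("t%02d", seq_len(n_terms))
    parents <- c(list(character(0)),
                 lapply(2:n_terms, function(j)
                   sample(ids[seq_len(j - 1)],
                          sample(1:min(2, j - 1), 1))))
    names(parents) <- ids
    g <- go_graph(data.frame(id = ids, name = ids,
                             namespace = "biological_process"), parents)
    universe <- sprintf("g%02d", 1:30)
    ann <- data.frame(
      gene_id = sample(universe, 60, replace = TRUE),
      term_id = sample(ids, 60, replace = TRUE),
      evidence = "IEA")
    study <- sample(universe, 8)
    classic <- decorrelated_enrich(g, study, universe, ann,
                                   method = "classic", min_node_size = 1)
    elim0 <- decorrelated_enrich(g, study, universe, ann, method = "elim",
                                 alpha_elim = 0, min_node_size = 1)
    expect_equal(elim0$p, classic$p)
    expect_equal(elim0$fdr, classic$fdr)
  }
})

test_that("exp and fe identities hold on simulated enrichment output", {
  sim <- small_sim()
  run <- run_pipeline(sim)
  res <- run$enrichment
  n_u <- attr(res, "n_universe")
  n_s <- attr(res, "n_study")
  expect_equal(res$exp, res$anno * n_s / n_u, tolerance = 1e-12)
  tested <- res$tested
  expect_equal(res$fe[tested], (res$sig / res$exp)[tested],
               tolerance = 1e-12)
  expect_true(all(res$fdr[tested] >= res$p[tested] - 1e-15))
})

test_that("network-specific terms are flagged against the full sets", {
  fx <- fixtures()$enrich20
  # identical study sets give identical FDR columns
  g1 <- go_graph(data.frame(id = "GO:TEST", name = "t",
                            namespace = "biological_process"),
                 list("GO:TEST" = character(0)))
  cmp <- compare_universes(g1, fx$study, fx$study, fx$universe,
                           fx$annotations, min_node_size = 1)
  expect_equal(cmp$fdr, cmp$fdr_full)
  expect_false(any(cmp$network_specific))

  # a diluted full set loses significance while the network set keeps it
  diluted <- c(fx$study[1:3], c("u15", "u16", "u17", "u18", "u19", "u20",
                                "u12", "u13", "u14", "u10", "u11"))
  cmp2 <- compare_universes(g1, fx$study, diluted, fx$universe,
                            fx$annotations, fdr_alpha = 0.05,
                            min_node_size = 1)
  expect_lt(cmp2$fdr, 0.05)
  expect_gt(cmp2$fdr_full, cmp2$fdr)
})

test_that("term overlap summary counts significant-term membership", {
  ann <- data.frame(gene_id = c("g1", "g2", "g2"),
                    term_id = c("t1", "t1", "t2"),
                    evidence = "IEA", stringsAsFactors = FALSE)
  s <- term_overlap_summary(c("t1", "t2"), c("g1", "g2"), ann)
  expect_equal(s$mean, 1.5)
  expect_equal(sort(s$per_gene$n_terms), c(1L, 2L))
  expect_equal(sum(s$intersections$n_genes), 2L)

  empty <- term_overlap_summary(character(0), c("g1"), ann)
  expect_equal(nrow(empty$per_gene), 0L)
})
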