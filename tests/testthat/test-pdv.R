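test_that("FD consensus score matches its defining formula and range", {
  expect_equal(compute_fd(0, 9, 9), -0.8)
  expect_equal(compute_fd(9, 0, 9), 1.0)
  expect_equal(compute_fd(0, 0, 0), 1.0)   # VEP-only variant, no calls
  expect_equal(compute_fd(4, 5, 9), 0.0)
  expect_error(compute_fd(3, 3, 9), "d \\+ b")

  # exhaustive enumeration over all (d, b) with d + b = n <= 9 against a
  # brute-force evaluation of ((d - b) + 1) / (n + 1)
  vals <- c()
  for (n in 0:9) {
    for (d in 0:n) {
      b <- n - d
      got <- compute_fd(d, b, n)
      expect_identical(got, ((d - b) + 1) / (n + 1))
      vals <- c(vals, got)
    }
  }
  expect_equal(length(vals), 55L)
  expect_equal(min(vals), -0.8)
  expect_equal(max(vals), 1.0)

  # monotone in d at fixed b, nonincreasing in b at fixed d
  expect_true(all(diff(sapply(0:5, function(d)
    compute_fd(d, 2, d + 2))) > 0))
  expect_true(all(diff(sapply(0:5, function(b)
    compute_fd(2, b, b + 2))) < 0))
})

test_that("negative FD scores truncate to zero", {
  expect_equal(truncate_fd(-0.8), 0)
  expect_equal(truncate_fd(0.3), 0.3)
  expect_equal(truncate_fd(0), 0)
  expect_equal(truncate_fd(c(-0.5, 0.2)), c(0, 0.2))
})

test_that("zygosity weights respect sex, chromosome and PAR membership", {
  par <- GenomicRanges::GRanges("chrX",
                                IRanges::IRanges(c(1, 5e6), c(1e6, 6e6)),
                                label = c("PAR1", "PAR2"))
  w <- function(sex, chrom, pos, gt)
    zygosity_weight(sex, chrom, pos, gt, par)
  expect_equal(w("male", "chrX", 500, "het"), 1L)     # inside PAR1
  expect_equal(w("male", "chrX", 2e6, "het"), 2L)     # outside PARs
  expect_equal(w("male", "chrX", 2e6, "hom"), 2L)     # genotype-invariant
  expect_equal(w("female", "chr7", 100, "hom"), 2L)
  expect_equal(w("female", "chrX", 2e6, "het"), 1L)
  expect_equal(w("male", "chr2", 100, "het"), 1L)
  expect_error(zygosity_weight("male", "chrX", 100, "het", NULL), "PAR")
})

test_that("CNVs score 1.0 against overlapped coding intervals only", {
  # gene G1: two exons; gene G2: one exon; intron of G1 is uncovered
  gm <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1"),
    IRanges::IRanges(c(100, 500, 900), c(200, 600, 1000)),
    label = c("G1", "G1", "G2"))
  mk_cnv <- function(s, e) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(s, e), label = "i1")

  hit <- cnv_pdv(mk_cnv(150, 260), gm)        # overlaps exon 1 of G1
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$gene_id, "G1")
  expect_equal(hit$pdv, 1)
  expect_equal(hit$Z, 1L)

  # intronic CNV between the two G1 exons: no record
  expect_equal(nrow(cnv_pdv(mk_cnv(250, 450), gm)), 0L)

  # CNV spanning exons of both genes: two records, one per gene
  span <- cnv_pdv(mk_cnv(550, 950), gm)
  expect_equal(sort(span$gene_id), c("G1", "G2"))

  # a CNV spanning both exons of G1 still yields one record for G1
  both <- cnv_pdv(mk_cnv(100, 700), gm)
  expect_equal(both$gene_id, "G1")
})

test_that("PDV = FD x Z stays in [0, 2] and is 0 iff fd_raw <= 0", {
  tab <- toy_variants(data.frame(genotype = c("het", "hom", "het", "hom")))
  preds <- default_predictors()
  # all damaging / all benign / mixed 4-5 / missing-only
  tab[2, preds] <- "damaging"
  tab[3, preds] <- c(rep("damaging", 4), rep("benign", 5))
  tab[4, preds] <- "missing"
  sex <- c(i1 = "female")
  rec <- score_variants(tab, sex)
  expect_equal(rec$pdv[1], 1.0)    # 9/9 damaging, het
  expect_equal(rec$pdv[2], 2.0)    # 9/9 damaging, hom
  expect_equal(rec$pdv[3], 0.0)    # fd_raw = 0
  expect_equal(rec$pdv[4], 2.0)    # no calls -> fd = 1, hom
  expect_true(all(rec$pdv >= 0 & rec$pdv <= 2))
  expect_true(all((rec$pdv == 0) == (rec$fd_raw <= 0)))
})

test_that("variants not flagged high-consequence are excluded by default", {
  tab <- toy_variants(data.frame(vep_high = c(TRUE, FALSE)))
  rec <- score_variants(tab, c(i1 = "female"))
  expect_equal(nrow(rec), 1L)
  cfg <- run_config(require_vep_high = FALSE)
  expect_equal(nrow(score_variants(tab, c(i1 = "female"), config = cfg)), 2L)
})

test_that("gene burden sums distinct variants and is order-invariant", {
  tab <- toy_variants(data.frame(
    pos = c(100L, 200L, 100L, 300L),
    gene_id = c("g1", "g1", "g1", "g2"),
    genotype = c("het", "hom", "het", "het")
  ))
  rec <- score_variants(tab, c(i1 = "female"))
  expect_warning(b <- gene_burden(rec), "duplicate")
  expect_equal(b$pdv_sum[b$gene_id == "g1"], 1 + 2)   # dup at pos 100 dropped
  expect_equal(b$pdv_sum[b$gene_id == "g2"], 1)

  # permutation invariance
  rec2 <- rec[rev(seq_len(nrow(rec))), ]
  expect_warning(b2 <- gene_burden(rec2), "duplicate")
  expect_equal(b, b2)

  # additivity over disjoint variant subsets
  rec_nodup <- rec[-3, ]
  parts <- rbind(gene_burden(rec_nodup[1:2, ]), gene_burden(rec_nodup[3, ]))
  whole <- gene_burden(rec_nodup)
  expect_equal(sum(parts$pdv_sum), sum(whole$pdv_sum))
})

test_that("candidate-hit summary reports per-set means and overlaps", {
  burden <- data.frame(
    individual_id = c("i1", "i1", "i2", "i2", "i2", "i3", "i3", "i3", "i3"),
    gene_id = c("g1", "g2", "g1", "g2", "g3", "g1", "g2", "g3", "g4"),
    pdv_sum = 1, stringsAsFactors = FALSE)
  s <- summarize_candidate_hits(burden, paste0("g", 1:4), character(0))
  expect_equal(s$mean_a, 3)                       # counts {2, 3, 4}

  s2 <- summarize_candidate_hits(
    data.frame(individual_id = "i1", gene_id = c("g1", "g2", "g3"),
               pdv_sum = 1), c("g1", "g2"), c("g2", "g3"))
  expect_equal(s2$overlap_genes, "g2")
  expect_equal(s2$n_overlap, 1L)
})
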