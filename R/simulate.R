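#' Simulation scenario for the synthetic cohort
#'
#' Describes every controlled quantity of the synthetic data: cohort shape,
#' gene universe, candidate set sizes and their overlap, variant rates,
#' predictor agreement, interaction edges, GO DAG shape, evidence-code
#' mixture, and the planted phenotype model
#' `sleep = intercept + beta_dbp * DBP + beta_age * age + beta_sex * male +
#' noise`. Defaults give a desk-scale cohort (500 individuals, 2000-gene
#' universe) whose composition mirrors the reference cohort: 86% male, 79%
#' of a two-level race majority group, and a 29-gene overlap between the
#' two candidate sets. `paper_scale = TRUE` switches to the full cohort
#' shape (2380 individuals).
#'
#' @param n_individuals Cohort size.
#' @param pct_male Proportion of males.
#' @param pct_majority_race Proportion of the majority race group.
#' @param n_genes_universe Protein-coding gene universe size.
#' @param n_set_a,n_set_b Candidate set sizes (trait A, trait B).
#' @param n_overlap Genes implicated in both sets.
#' @param rate_candidate,rate_background Per-individual, per-gene variant
#'   probabilities for candidate and non-candidate genes.
#' @param kappa Predictor-agreement: probability each predictor reports the
#'   variant's latent state.
#' @param miss_to_flip Given a predictor misses the latent state, the
#'   probability it reports the opposite call (otherwise missing).
#' @param p_damaging Latent probability that a variant is damaging.
#' @param frac_hom Fraction of homozygous genotypes.
#' @param frac_x X-linked fraction of universe genes.
#' @param frac_vep_high Fraction of variants flagged high-consequence.
#' @param frac_qc_fail Fraction of variants failing depth/GQ thresholds.
#' @param cnv_rate Expected CNV calls per individual.
#' @param n_cross_edges Planted cross-set interaction edges (score 700).
#' @param n_noise_edges Noise edges at score 200 (below threshold).
#' @param n_background_edges High-confidence edges (score 550) among
#'   non-candidate genes, for negative-control runs.
#' @param dag_depth,dag_fanout GO DAG shape (levels below the root, children
#'   per node).
#' @param n_genes_per_leaf Genes directly annotated per leaf term.
#' @param n_target_genes Network genes annotated to the planted target
#'   term.
#' @param evidence_mix Named probabilities over evidence codes.
#' @param beta_dbp Planted phenotype effect (minutes per DBP unit).
#' @param beta_age Age effect (minutes per year).
#' @param beta_sex Male-sex effect (minutes).
#' @param intercept Sleep intercept (minutes).
#' @param noise_sd Residual standard deviation (minutes).
#' @param frac_missing_sleep Fraction of individuals without sleep data.
#' @param paper_scale Use the full reference cohort size.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_individuals = 500L, pct_male = 0.86,
                         pct_majority_race = 0.79,
                         n_genes_universe = 2000L,
                         n_set_a = 120L, n_set_b = 100L, n_overlap = 29L,
                         rate_candidate = 0.08, rate_background = 0.01,
                         kappa = 0.9, miss_to_flip = 0.5,
                         p_damaging = 0.5,
                         frac_hom = 0.05, frac_x = 0.04,
                         frac_vep_high = 0.9, frac_qc_fail = 0.05,
                         cnv_rate = 0.02,
                         n_cross_edges = 150L, n_noise_edges = 100L,
                         n_background_edges = 0L,
                         dag_depth = 3L, dag_fanout = 3L,
                         n_genes_per_leaf = 20L, n_target_genes = 30L,
                         evidence_mix = c(EXP = 0.1, IDA = 0.2, IMP = 0.2,
                                          ISS = 0.2, IEA = 0.3),
                         beta_dbp = 1200, beta_age = -8, beta_sex = -5,
                         intercept = 640, noise_sd = 70,
                         frac_missing_sleep = 0.04,
                         paper_scale = FALSE) {
  if (paper_scale) n_individuals <- 2380L
  stopifnot(n_overlap <= min(n_set_a, n_set_b),
            n_set_a + n_set_b - n_overlap <= n_genes_universe,
            kappa >= 0, kappa <= 1, miss_to_flip >= 0, miss_to_flip <= 1,
            abs(sum(evidence_mix) - 1) < 1e-8, noise_sd >= 0)
  sc <- as.list(environment())
  sc$paper_scale <- NULL
  structure(sc, class = "sim_scenario")
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Generates every pipeline input in memory: an annotated variant table
#' with nine predictor calls, CNV and PAR interval sets, gene models, two
#' candidate gene sets with a planted overlap, a gene-to-protein id map, an
#' interaction edge list (planted cross-set edges plus sub-threshold
#' noise), a GO DAG with evidence-coded annotations and a target term
#' enriched for network genes, gene features for matched-random selection,
#' and phenotypes with a planted DBP effect. The "true" DBP driving the
#' phenotype is computed by running the actual scoring path (QC -> PDV ->
#' burden -> DBP) on the generated genotypes, so phenotype generation
#' cannot drift from the scorer. All planted quantities are recorded in the
#' returned `ledger`.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `sim_cohort` with elements `variants`, `cnvs`,
#'   `par_regions`, `gene_models`, `gene_sets`, `id_map`, `edges`, `graph`,
#'   `annotations`, `features`, `phenotypes`, `sex`, `true_dbp`, `ledger`.
#' @export
simulate_cohort <- function(scenario = sim_scenario(), seed = 1L) {
  set.seed(seed)
  sc <- scenario
  inds <- sprintf("ind%04d", seq_len(sc$n_individuals))
  genes <- sprintf("g%04d", seq_len(sc$n_genes_universe))

  ## -- gene placement: autosomes + an X-linked block (partly in PAR1) ----
  n_x <- max(2L, round(sc$frac_x * sc$n_genes_universe))
  chrom <- c(rep(paste0("chr", 1:22),
                 length.out = sc$n_genes_universe - n_x),
             rep("chrX", n_x))
  gene_start <- integer(sc$n_genes_universe)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    gene_start[i] <- 100000L + (seq_along(i) - 1L) * 50000L
  }
  gene_len <- 5000L
  # PAR1 covers the first quarter of X-linked genes
  x_idx <- which(chrom == "chrX")
  n_par <- max(1L, length(x_idx) %/% 4L)
  par1_end <- gene_start[x_idx[n_par]] + gene_len + 1000L
  par_regions <- GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(c(1L, 15000000L),
                             c(par1_end, 15050000L)),
    label = c("PAR1", "PAR2"))
  gene_models <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(gene_start, gene_start + gene_len - 1L),
    label = genes)

  ## -- candidate sets with planted overlap ------------------------------
  overlap <- genes[seq_len(sc$n_overlap)]
  rest <- setdiff(genes, overlap)
  only_a <- rest[seq_len(sc$n_set_a - sc$n_overlap)]
  only_b <- rest[sc$n_set_a - sc$n_overlap + seq_len(sc$n_set_b - sc$n_overlap)]
  set_a <- sort(c(overlap, only_a))
  set_b <- sort(c(overlap, only_b))
  candidates <- union(set_a, set_b)

  ## -- individuals -------------------------------------------------------
  sex <- stats::setNames(
    ifelse(stats::runif(sc$n_individuals) < sc$pct_male, "male", "female"),
    inds)

  ## -- variants ----------------------------------------------------------
  variants <- .sim_variants(sc, inds, genes, candidates, chrom, gene_start,
                            gene_len)

  ## -- CNVs --------------------------------------------------------------
  n_cnv <- stats::rpois(1L, sc$cnv_rate * sc$n_individuals)
  if (n_cnv > 0L) {
    cg <- sample.int(sc$n_genes_universe, n_cnv, replace = TRUE)
    cnvs <- GenomicRanges::GRanges(
      chrom[cg],
      IRanges::IRanges(gene_start[cg] + 500L, gene_start[cg] + 2500L),
      label = sample(inds, n_cnv, replace = TRUE))
  } else {
    cnvs <- GenomicRanges::GRanges(label = character(0))
  }

  ## -- gene features -----------------------------------------------------
  features <- data.frame(
    gene_id = genes,
    gc_content = pmin(pmax(stats::rnorm(length(genes), 0.45, 0.05), 0.3),
                      0.65),
    transcript_size = round(stats::rlnorm(length(genes), log(2500), 0.35)),
    n_spliceoforms = 1L + stats::rpois(length(genes), 4),
    stringsAsFactors = FALSE
  )

  ## -- realized PDV-bearing genes via the real scoring path --------------
  qc <- apply_qc_filter(variants)
  rec <- score_variants(qc, sex, par_regions, cnvs = cnvs,
                        gene_models = gene_models)
  burden <- gene_burden(rec)
  pdv_genes <- unique(burden$gene_id[burden$pdv_sum > 0])
  pdv_a <- sort(intersect(set_a, pdv_genes))
  pdv_b <- sort(intersect(set_b, pdv_genes))

  ## -- interaction edges (cross edges planted among PDV genes) ----------
  id_map <- data.frame(gene_id = genes, protein_id = paste0("P_", genes),
                       stringsAsFactors = FALSE)
  edges <- .sim_edges(sc, pdv_a, pdv_b, genes, candidates)

  ## -- GO DAG + annotations ---------------------------------------------
  go <- .sim_go(sc, genes, set_a, set_b, edges$planted_cross)
  graph <- go$graph
  annotations <- go$annotations
  target_term <- go$target_term

  ## -- true DBP of the target process ------------------------------------
  dbp <- dbp_matrix(burden, target_term, graph, annotations,
                    individuals = inds)
  true_dbp <- stats::setNames(dbp[, 1L], rownames(dbp))[inds]

  ## -- phenotypes --------------------------------------------------------
  age <- sample(4:18, sc$n_individuals, replace = TRUE)
  race <- ifelse(stats::runif(sc$n_individuals) < sc$pct_majority_race,
                 "white", "non_white")
  iq <- round(stats::rnorm(sc$n_individuals, 95, 16))
  sleep <- sc$intercept + sc$beta_dbp * true_dbp + sc$beta_age * age +
    sc$beta_sex * (sex == "male") +
    stats::rnorm(sc$n_individuals, 0, sc$noise_sd)
  sleep <- pmax(round(sleep), 120)
  miss <- stats::runif(sc$n_individuals) < sc$frac_missing_sleep
  sleep[miss] <- NA
  phenotypes <- data.frame(
    individual_id = inds, sleep_minutes = sleep, age_years = age,
    sex = unname(sex), race = race, iq = iq,
    social_comm = round(stats::rnorm(sc$n_individuals, 12, 4), 1),
    rrb = round(stats::rnorm(sc$n_individuals, 5, 2), 1),
    stringsAsFactors = FALSE
  )
  phenotypes$has_sleep <- !is.na(phenotypes$sleep_minutes)
  class(phenotypes) <- c("phenotype_table", "data.frame")

  ledger <- list(
    seed = seed, scenario = unclass(sc),
    set_a = set_a, set_b = set_b, overlap_genes = sort(overlap),
    n_overlap = sc$n_overlap,
    pdv_set_a = pdv_a, pdv_set_b = pdv_b,
    overlap_genes_pdv = sort(intersect(overlap, pdv_genes)),
    planted_cross_edges = edges$planted_cross,
    target_term = target_term,
    target_term_genes = go$target_genes,
    beta_dbp = sc$beta_dbp, beta_age = sc$beta_age,
    beta_sex = sc$beta_sex, intercept = sc$intercept,
    noise_sd = sc$noise_sd
  )

  structure(list(
    variants = variants, cnvs = cnvs, par_regions = par_regions,
    gene_models = gene_models,
    gene_sets = list(A = set_a, B = set_b),
    id_map = id_map, edges = edges$edges, graph = graph,
    annotations = annotations, features = features,
    phenotypes = phenotypes, sex = sex, true_dbp = true_dbp,
    ledger = ledger
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(x$sex), "individuals,",
      nrow(x$variants), "variant rows,",
      length(x$gene_sets$A), "+", length(x$gene_sets$B),
      "candidate genes (overlap", x$ledger$n_overlap, ")\n")
  cat("  target term:", x$ledger$target_term,
      " planted beta_dbp:", x$ledger$beta_dbp, "min/unit\n")
  invisible(x)
}

# Variant rows with latent damaging state and 9 predictor calls.
.sim_variants <- function(sc, inds, genes, candidates, chrom, gene_start,
                          gene_len) {
  gene_is_cand <- genes %in% candidates
  rate <- ifelse(gene_is_cand, sc$rate_candidate, sc$rate_background)
  # expected events per gene across the cohort; draw counts then assign
  counts <- stats::rpois(length(genes), rate * length(inds))
  gene_idx <- rep(seq_along(genes), counts)
  n <- length(gene_idx)
  if (n == 0L) stop("scenario produced no variants", call. = FALSE)
  ind_id <- sample(inds, n, replace = TRUE)
  offset <- sample.int(gene_len, n, replace = TRUE) - 1L
  pos <- gene_start[gene_idx] + offset
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  damaging <- stats::runif(n) < sc$p_damaging

  preds <- default_predictors()
  calls <- matrix("missing", n, length(preds),
                  dimnames = list(NULL, preds))
  for (j in seq_along(preds)) {
    u <- stats::runif(n)
    agree <- u < sc$kappa
    flip <- !agree & (u < sc$kappa + (1 - sc$kappa) * sc$miss_to_flip)
    calls[agree, j] <- ifelse(damaging[agree], "damaging", "benign")
    calls[flip, j] <- ifelse(damaging[flip], "benign", "damaging")
  }

  qc_fail <- stats::runif(n) < sc$frac_qc_fail
  depth <- ifelse(qc_fail, stats::rpois(n, 4),
                  8L + stats::rpois(n, 40))
  gq <- ifelse(qc_fail, pmax(0L, stats::rpois(n, 10)),
               20L + stats::rpois(n, 60))

  tab <- data.frame(
    individual_id = ind_id, gene_id = genes[gene_idx],
    chrom = chrom[gene_idx], pos = pos, ref = ref, alt = alt,
    variant_class = ifelse(stats::runif(n) < 0.85, "SNV", "INDEL"),
    genotype = ifelse(stats::runif(n) < sc$frac_hom, "hom", "het"),
    vep_high = stats::runif(n) < sc$frac_vep_high,
    depth = as.integer(depth), gq = as.integer(gq),
    inheritance = sample(c("de_novo", "inherited", "unknown"), n,
                         replace = TRUE, prob = c(0.1, 0.8, 0.1)),
    stringsAsFactors = FALSE
  )
  for (p in preds) tab[[p]] <- calls[, p]
  # deduplicate identical (individual, site) draws
  key <- paste(tab$individual_id, tab$chrom, tab$pos, tab$alt, sep = "\r")
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "predictors") <- preds
  class(tab) <- c("variant_table", "data.frame")
  tab
}

.sim_edges <- function(sc, set_a, set_b, genes, candidates) {
  # planted cross-set edges at score 700
  pairs <- expand.grid(u = setdiff(set_a, set_b), v = setdiff(set_b, set_a),
                       stringsAsFactors = FALSE)
  take <- sample.int(nrow(pairs), min(sc$n_cross_edges, nrow(pairs)))
  cross <- pairs[take, , drop = FALSE]
  planted <- data.frame(gene_u = pmin(cross$u, cross$v),
                        gene_v = pmax(cross$u, cross$v),
                        stringsAsFactors = FALSE)
  planted <- planted[order(planted$gene_u, planted$gene_v), , drop = FALSE]
  rownames(planted) <- NULL
  e <- data.frame(protein1 = paste0("P_", cross$u),
                  protein2 = paste0("P_", cross$v),
                  combined_score = 700, stringsAsFactors = FALSE)
  # noise edges below threshold
  if (sc$n_noise_edges > 0L) {
    nu <- sample(genes, sc$n_noise_edges, replace = TRUE)
    nv <- sample(genes, sc$n_noise_edges, replace = TRUE)
    keep <- nu != nv
    e <- rbind(e, data.frame(protein1 = paste0("P_", nu[keep]),
                             protein2 = paste0("P_", nv[keep]),
                             combined_score = 200,
                             stringsAsFactors = FALSE))
  }
  # optional high-confidence background edges among non-candidate genes
  if (sc$n_background_edges > 0L) {
    bg <- setdiff(genes, candidates)
    bu <- sample(bg, sc$n_background_edges, replace = TRUE)
    bv <- sample(bg, sc$n_background_edges, replace = TRUE)
    keep <- bu != bv
    e <- rbind(e, data.frame(protein1 = paste0("P_", bu[keep]),
                             protein2 = paste0("P_", bv[keep]),
                             combined_score = 550,
                             stringsAsFactors = FALSE))
  }
  list(edges = e, planted_cross = planted)
}

# GO DAG of configured depth/fanout rooted at a single BP term, with a
# target leaf term annotated to network (candidate) genes.
.sim_go <- function(sc, genes, set_a, set_b, planted_cross) {
  ids <- "GO:9000000"
  parents <- list("GO:9000000" = character(0))
  level <- list("GO:9000000")
  counter <- 0L
  for (d in seq_len(sc$dag_depth)) {
    this_level <- character(0)
    for (p in level[[d]]) {
      for (k in seq_len(sc$dag_fanout)) {
        counter <- counter + 1L
        id <- sprintf("GO:9%06d", counter)
        parents[[id]] <- p
        this_level <- c(this_level, id)
        ids <- c(ids, id)
      }
    }
    level[[d + 1L]] <- this_level
  }
  terms <- data.frame(id = ids,
                      name = c("biological_process_root",
                               sprintf("simulated process %03d",
                                       seq_len(length(ids) - 1L))),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  graph <- go_graph(terms, parents)
  leaves <- level[[sc$dag_depth + 1L]]

  # target term: annotated to genes on planted cross edges (network genes)
  target_term <- leaves[[1L]]
  net_genes <- unique(c(planted_cross$gene_u, planted_cross$gene_v))
  target_genes <- sample(net_genes, min(sc$n_target_genes,
                                        length(net_genes)))
  codes <- names(sc$evidence_mix)
  ann <- data.frame(gene_id = target_genes, term_id = target_term,
                    evidence = sample(codes, length(target_genes),
                                      replace = TRUE,
                                      prob = sc$evidence_mix),
                    stringsAsFactors = FALSE)
  # remaining leaves: random universe genes
  for (lf in leaves[-1L]) {
    g <- sample(genes, sc$n_genes_per_leaf)
    ann <- rbind(ann, data.frame(gene_id = g, term_id = lf,
                                 evidence = sample(codes,
                                                   length(g),
                                                   replace = TRUE,
                                                   prob = sc$evidence_mix),
                                 stringsAsFactors = FALSE))
  }
  # sprinkle direct annotations on mid-level terms
  for (md in level[[sc$dag_depth]]) {
    g <- sample(genes, max(3L, sc$n_genes_per_leaf %/% 4L))
    ann <- rbind(ann, data.frame(gene_id = g, term_id = md,
                                 evidence = sample(codes, length(g),
                                                   replace = TRUE,
                                                   prob = sc$evidence_mix),
                                 stringsAsFactors = FALSE))
  }
  ann <- unique(ann)
  rownames(ann) <- NULL
  list(graph = graph, annotations = ann, target_term = target_term,
       target_genes = sort(target_genes))
}

#' Write a simulated cohort to a directory of standard-format files
#'
#' Emits the annotated variant TSV, CNV and PAR BED files, gene-model BED,
#' candidate gene lists, id map TSV, interaction edge TSV, OBO ontology,
#' GAF annotations, gene feature TSV, phenotype CSV, and a JSON ledger of
#' every planted quantity.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_tsv(as.data.frame(sim$variants), fp("variants.tsv"))
  write_bed(sim$cnvs, fp("cnvs.bed"))
  write_bed(sim$par_regions, fp("par.bed"))
  write_bed(sim$gene_models, fp("gene_models.bed"))
  writeLines(sim$gene_sets$A, fp("genes_a.txt"))
  writeLines(sim$gene_sets$B, fp("genes_b.txt"))
  write_tsv(sim$id_map, fp("id_map.tsv"))
  write_tsv(sim$edges, fp("edges.tsv"))
  write_obo(sim$graph, fp("ontology.obo"))
  write_gaf(sim$annotations, fp("annotations.gaf"))
  write_tsv(sim$features, fp("gene_features.tsv"))
  utils::write.csv(as.data.frame(sim$phenotypes)[
    , c("individual_id", "sleep_minutes", "age_years", "sex", "race",
        "iq", "social_comm", "rrb")],
    fp("phenotypes.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$ledger, fp("ledger.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
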