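#' Frequency-of-damaging-predictions (FD) score
#'
#' Combines categorical calls from up to nine in-silico predictors into a
#' single consensus score, `FD = ((D - B) + 1) / (N + 1)`, where `D` is the
#' number of algorithms calling the variant damaging, `B` the number calling
#' it benign, `N = D + B` the number providing a prediction, and the `+1`
#' constant reflects pre-selection of high-consequence variants by VEP. With
#' nine predictors the score ranges from -0.8 (all benign) to 1.0 (all
#' damaging); a variant with no categorical predictions scores 1.0, the
#' VEP-only prior.
#'
#' @param d,b,n Integer vectors: damaging calls, benign calls, total calls.
#'   Algorithms with no call are treated as missing and excluded from `n`,
#'   so `d + b == n` is enforced.
#' @return Numeric vector of raw (untruncated) FD scores.
#' @export
compute_fd <- function(d, b, n) {
  if (any(d < 0L | b < 0L)) stop("negative call counts", call. = FALSE)
  if (any(d + b != n))
    stop("d + b must equal n (missing calls are excluded from n)",
         call. = FALSE)
  ((d - b) + 1) / (n + 1)
}

#' Truncate negative FD scores to zero
#'
#' Negative FD indicates a variant more often predicted benign than
#' damaging; for damage scoring it contributes nothing.
#'
#' @param fd_raw Numeric vector of raw FD scores.
#' @return `pmax(fd_raw, 0)`.
#' @export
truncate_fd <- function(fd_raw) {
  pmax(fd_raw, 0)
}

#' Zygosity weight with pseudoautosomal handling
#'
#' Heterozygous variants weigh 1 and homozygous 2. On the X chromosome,
#' male heterozygous variants inside PAR1/PAR2 are weighted as autosomal
#' (het = 1); male X variants outside the PARs are hemizygous and weigh 2
#' regardless of the called genotype. Male Y variants are likewise treated
#' as hemizygous.
#'
#' @param sex Character vector `"male"`/`"female"` per variant.
#' @param chrom Chromosome per variant.
#' @param pos 1-based position per variant.
#' @param genotype `"het"` or `"hom"` per variant.
#' @param par_regions `GRanges` of pseudoautosomal regions (required when
#'   any variant lies on the X chromosome).
#' @return Integer vector of weights in \{1, 2\}.
#' @export
zygosity_weight <- function(sex, chrom, pos, genotype, par_regions = NULL) {
  n <- length(chrom)
  stopifnot(length(sex) == n, length(pos) == n, length(genotype) == n)
  z <- ifelse(genotype == "hom", 2L, 1L)
  is_x <- chrom %in% c("chrX", "X")
  is_y <- chrom %in% c("chrY", "Y")
  male <- sex == "male"
  if (any(is_x & male)) {
    if (is.null(par_regions))
      stop("X-chromosome variants present but no PAR regions supplied",
           call. = FALSE)
    idx <- which(is_x & male)
    pts <- GenomicRanges::GRanges(chrom[idx],
                                  IRanges::IRanges(pos[idx], pos[idx]))
    in_par <- IRanges::overlapsAny(pts, par_regions)
    # outside PAR: hemizygous, weight 2 whatever the genotype call says
    z[idx][!in_par] <- 2L
  }
  z[is_y & male] <- 2L
  z
}

#' Score CNV calls against gene models
#'
#' A CNV that overlaps (by at least 1 bp) the coding, splice-site or
#' proximal-promoter (5'-UTR) intervals of a gene is assigned the strongest
#' damage weight (FD = 1) and assumed heterozygous (Z = 1), giving PDV = 1,
#' with at most one record per CNV per gene.
#'
#' @param cnvs `GRanges` of CNV calls with a `label` column holding the
#'   individual id.
#' @param gene_models `GRanges` of scoreable gene intervals (exons, splice
#'   sites, 5'-UTRs) with a `label` column holding the gene id. Intronic
#'   sequence must not be included.
#' @return Data frame of CNV-derived PDV records (possibly empty).
#' @export
cnv_pdv <- function(cnvs, gene_models) {
  empty <- data.frame(individual_id = character(0), gene_id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      variant_class = character(0), genotype = character(0),
                      inheritance = character(0),
                      fd_raw = numeric(0), fd = numeric(0), Z = integer(0),
                      pdv = numeric(0), stringsAsFactors = FALSE)
  if (length(cnvs) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(cnvs, gene_models)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ind <- S4Vectors::mcols(cnvs)$label[qi]
  gene <- S4Vectors::mcols(gene_models)$label[si]
  key <- paste(ind, gene,
               as.character(GenomicRanges::seqnames(cnvs))[qi],
               GenomicRanges::start(cnvs)[qi],
               GenomicRanges::end(cnvs)[qi], sep = "\r")
  keep <- !duplicated(key)
  data.frame(
    individual_id = ind[keep], gene_id = gene[keep],
    chrom = as.character(GenomicRanges::seqnames(cnvs))[qi][keep],
    pos = GenomicRanges::start(cnvs)[qi][keep],
    ref = NA_character_,
    alt = paste0("CNV_end_", GenomicRanges::end(cnvs)[qi][keep]),
    variant_class = "CNV", genotype = "het", inheritance = "unknown",
    fd_raw = 1, fd = 1, Z = 1L, pdv = 1, stringsAsFactors = FALSE
  )
}

#' Compute per-variant PDV scores
#'
#' Applies the scoring protocol to a QC-filtered variant table: keep
#' high-consequence variants (configurable), count damaging/benign predictor
#' calls, compute the FD consensus, truncate negatives to zero, weight by
#' zygosity with PAR-aware male X handling, and score CNVs against gene
#' models. PDV = FD x Z lies in `[0, 2]`.
#'
#' @param tab A `variant_table` (SNV/INDEL rows; CNV rows are ignored here —
#'   pass interval calls through `cnvs`).
#' @param sex Named character vector mapping individual ids to
#'   `"male"`/`"female"`.
#' @param par_regions `GRanges` of pseudoautosomal regions.
#' @param cnvs Optional `GRanges` of CNV calls (label = individual id).
#' @param gene_models Optional `GRanges` of scoreable gene intervals
#'   (label = gene id); required when `cnvs` is given.
#' @param config A [run_config()].
#' @return Data frame of class `pdv_records`: one row per scored variant
#'   with `fd_raw`, `fd`, `Z`, `pdv`.
#' @export
score_variants <- function(tab, sex, par_regions = NULL, cnvs = NULL,
                           gene_models = NULL, config = run_config()) {
  snv <- tab[tab$variant_class %in% c("SNV", "INDEL"), , drop = FALSE]
  if (config$require_vep_high)
    snv <- snv[!is.na(snv$vep_high) & snv$vep_high, , drop = FALSE]
  preds <- attr(tab, "predictors")
  if (is.null(preds)) preds <- config$predictors
  if (nrow(snv) > 0L) {
    calls <- as.matrix(snv[, preds, drop = FALSE])
    d <- rowSums(calls == "damaging")
    b <- rowSums(calls == "benign")
    n <- d + b
    fd_raw <- compute_fd(d, b, n)
    fd <- truncate_fd(fd_raw)
    sx <- unname(sex[snv$individual_id])
    if (any(is.na(sx)))
      stop("sex unknown for individual(s): ",
           paste(unique(snv$individual_id[is.na(sx)]), collapse = ", "),
           call. = FALSE)
    Z <- zygosity_weight(sx, snv$chrom, snv$pos, snv$genotype, par_regions)
    rec <- data.frame(
      individual_id = snv$individual_id, gene_id = snv$gene_id,
      chrom = snv$chrom, pos = snv$pos, ref = snv$ref, alt = snv$alt,
      variant_class = snv$variant_class, genotype = snv$genotype,
      inheritance = snv$inheritance,
      fd_raw = fd_raw, fd = fd, Z = Z, pdv = fd * Z,
      stringsAsFactors = FALSE
    )
  } else {
    rec <- cnv_pdv(GenomicRanges::GRanges(), GenomicRanges::GRanges())
  }
  if (!is.null(cnvs) && length(cnvs) > 0L) {
    if (is.null(gene_models))
      stop("gene_models required to score CNVs", call. = FALSE)
    rec <- rbind(rec, cnv_pdv(cnvs, gene_models))
  }
  rownames(rec) <- NULL
  class(rec) <- c("pdv_records", "data.frame")
  rec
}

#' @export
print.pdv_records <- function(x, ...) {
  cat("pdv_records:", nrow(x), "scored variants in",
      length(unique(x$individual_id)), "individuals,",
      length(unique(x$gene_id)), "genes\n")
  cat("  pdv > 0:", sum(x$pdv > 0), " mean pdv:",
      round(mean(x$pdv), 4), "\n")
  invisible(x)
}

#' Aggregate PDV scores into per-individual, per-gene burdens
#'
#' Sums PDV over distinct variants per (individual, gene). Distinctness is
#' keyed on (individual, chrom, pos, ref, alt); duplicate rows are dropped
#' with a warning.
#'
#' @param records A `pdv_records` data frame.
#' @return Data frame of class `gene_burden` with `individual_id`,
#'   `gene_id`, `pdv_sum`.
#' @export
gene_burden <- function(records) {
  key <- paste(records$individual_id, records$chrom, records$pos,
               records$ref, records$alt, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate variant row(s) removed before burden ",
            "aggregation", call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    out <- data.frame(individual_id = character(0), gene_id = character(0),
                      pdv_sum = numeric(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(records$pdv,
                            by = list(individual_id = records$individual_id,
                                      gene_id = records$gene_id),
                            FUN = sum)
    names(agg)[3L] <- "pdv_sum"
    out <- agg[order(agg$individual_id, agg$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("gene_burden", "data.frame")
  out
}

#' Summarize candidate-set hits per individual
#'
#' Reports, for each of two candidate gene sets, the per-individual count of
#' distinct PDV-bearing genes (mean and sd across individuals), and the
#' genes carrying PDVs that are implicated in both sets.
#'
#' @param burden A `gene_burden` table.
#' @param set_a,set_b Character vectors of candidate gene ids.
#' @return List with `per_individual` (data frame of counts), `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `overlap_genes`, `n_overlap`.
#' @export
summarize_candidate_hits <- function(burden, set_a, set_b) {
  hit <- burden[burden$pdv_sum > 0, , drop = FALSE]
  inds <- unique(burden$individual_id)
  count_in <- function(set) {
    sub <- hit[hit$gene_id %in% set, , drop = FALSE]
    tab <- table(factor(sub$individual_id, levels = inds))
    as.integer(tab)
  }
  n_a <- count_in(set_a)
  n_b <- count_in(set_b)
  pdv_genes <- unique(hit$gene_id)
  overlap <- intersect(intersect(set_a, set_b), pdv_genes)
  list(
    per_individual = data.frame(individual_id = inds, n_genes_a = n_a,
                                n_genes_b = n_b, stringsAsFactors = FALSE),
    mean_a = mean(n_a), sd_a = stats::sd(n_a),
    mean_b = mean(n_b), sd_b = stats::sd(n_b),
    overlap_genes = sort(overlap), n_overlap = length(overlap)
  )
}
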