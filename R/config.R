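#' Default names of the nine in-silico deleteriousness predictors
#'
#' Column names expected in an annotated variant table: SIFT, PolyPhen-2
#' HVAR, MutationTaster, MutationAssessor, LRT, FATHMM-MKL, PROVEAN, MetaLR
#' and M-CAP, as commonly emitted by ANNOVAR-style annotation.
#'
#' @return Character vector of length nine.
#' @export
default_predictors <- function() {
  c("SIFT", "Polyphen2_HVAR", "MutationTaster", "MutationAssessor",
    "LRT", "FATHMM_MKL", "PROVEAN", "MetaLR", "M_CAP")
}

#' Default token-to-call mapping for predictor columns
#'
#' Annotation tools encode categorical predictions with single-letter
#' tokens. The mapping is configurable because output dialects differ
#' between tool versions; this default covers the common ANNOVAR encodings.
#'
#' @return Named character vector mapping tokens to
#'   `"damaging"`, `"benign"` or `"missing"`.
#' @export
default_token_map <- function() {
  map <- c("D" = "damaging", "A" = "damaging", "H" = "damaging",
           "T" = "benign", "B" = "benign", "N" = "benign", "P" = "benign",
           "L" = "benign", "M" = "benign",
           "." = "missing", "NA" = "missing",
           "damaging" = "damaging", "benign" = "benign",
           "missing" = "missing")
  # an empty token (absent call) also maps to missing
  map <- c(map, stats::setNames("missing", ""))
  map
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one object so that a
#' run can be logged and reproduced. Defaults follow the analysis protocol:
#' read depth >= 8 and genotype quality >= 20 for SNV/indel QC, interaction
#' confidence >= 400 (the STRING "medium confidence" convention),
#' FDR alpha 0.05, elimination threshold 0.01, minimum GO node size 3, and
#' extreme sleep-duration cutoffs at 420 and 660 minutes.
#'
#' @param predictors Character vector of predictor column names.
#' @param token_map Named character vector mapping predictor tokens to calls.
#' @param min_depth Minimum read depth for SNV/indel rows.
#' @param min_gq Minimum genotype quality (phred) for SNV/indel rows.
#' @param require_vep_high Keep only variants flagged as high-consequence
#'   before scoring (splice, stop gain/loss, start loss, frameshift).
#' @param min_string_score Minimum interaction combined score (0-1000 scale).
#' @param fdr_alpha FDR-adjusted significance threshold for enrichment.
#' @param alpha_elim Child-term significance threshold of the elimination
#'   procedure.
#' @param min_node_size Minimum number of annotated universe genes for a GO
#'   term to be tested.
#' @param ebp_parse How the child-term clause of the EBP weight is parsed;
#'   see [compute_ebp()].
#' @param short_max,long_min Extreme sleep-duration cutoffs in minutes
#'   (inclusive on both boundaries).
#' @param seed Integer seed recorded in the run manifest.
#'
#' @return A list of class `pdvnet_config`.
#' @export
run_config <- function(predictors = default_predictors(),
                       token_map = default_token_map(),
                       min_depth = 8L,
                       min_gq = 20L,
                       require_vep_high = TRUE,
                       min_string_score = 400,
                       fdr_alpha = 0.05,
                       alpha_elim = 0.01,
                       min_node_size = 3L,
                       ebp_parse = c("child-fraction", "whole-sum"),
                       short_max = 420,
                       long_min = 660,
                       seed = 1L) {
  ebp_parse <- match.arg(ebp_parse)
  stopifnot(min_depth >= 0, min_gq >= 0, min_string_score >= 0,
            fdr_alpha > 0, fdr_alpha < 1, alpha_elim >= 0,
            short_max < long_min)
  structure(list(predictors = predictors, token_map = token_map,
                 min_depth = as.integer(min_depth),
                 min_gq = as.integer(min_gq),
                 require_vep_high = isTRUE(require_vep_high),
                 min_string_score = min_string_score,
                 fdr_alpha = fdr_alpha, alpha_elim = alpha_elim,
                 min_node_size = as.integer(min_node_size),
                 ebp_parse = ebp_parse,
                 short_max = short_max, long_min = long_min,
                 seed = as.integer(seed)),
            class = "pdvnet_config")
}

#' @export
print.pdvnet_config <- function(x, ...) {
  cat("pdvnet run configuration\n")
  cat("  predictors:      ", paste(x$predictors, collapse = ", "), "\n")
  cat("  QC:               depth >=", x$min_depth, ", GQ >=", x$min_gq, "\n")
  cat("  require VEP-high:", x$require_vep_high, "\n")
  cat("  PPI min score:   ", x$min_string_score, "\n")
  cat("  FDR alpha:       ", x$fdr_alpha,
      " elim alpha:", x$alpha_elim,
      " min node size:", x$min_node_size, "\n")
  cat("  EBP parse:       ", x$ebp_parse, "\n")
  cat("  duration cutoffs: <=", x$short_max, "min / >=", x$long_min, "min\n")
  cat("  seed:            ", x$seed, "\n")
  invisible(x)
}
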