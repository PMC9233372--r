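#' Categorize sleep durations into extreme/non-extreme classes
#'
#' Durations at or below `short_max` minutes are `extremely_short`, at or
#' above `long_min` minutes `extremely_long`, and strictly between the two
#' `non_extreme` (defaults 420 and 660 minutes, approximately the 5th and
#' 95th percentiles of parent-reported sleep in the reference cohort). In
#' percentile mode the thresholds are recomputed as the 5th/95th
#' percentiles of the supplied durations.
#'
#' @param durations Numeric vector of sleep durations in minutes.
#' @param short_max,long_min Category thresholds (both inclusive).
#' @param percentile_mode Recompute thresholds from the data.
#' @return Factor with levels `extremely_short`, `non_extreme`,
#'   `extremely_long` (NA durations stay NA); thresholds attached as
#'   attributes.
#' @export
categorize_durations <- function(durations, short_max = 420, long_min = 660,
                                 percentile_mode = FALSE) {
  if (percentile_mode) {
    qs <- stats::quantile(durations, c(0.05, 0.95), na.rm = TRUE,
                          names = FALSE)
    short_max <- qs[1L]
    long_min <- qs[2L]
  }
  stopifnot(short_max < long_min)
  out <- ifelse(is.na(durations), NA_character_,
                ifelse(durations <= short_max, "extremely_short",
                       ifelse(durations >= long_min, "extremely_long",
                              "non_extreme")))
  out <- factor(out, levels = c("extremely_short", "non_extreme",
                                "extremely_long"))
  attr(out, "short_max") <- short_max
  attr(out, "long_min") <- long_min
  out
}

# Build the complete-case model frame joining phenotypes with a DBP score.
.assoc_frame <- function(pheno, dbp_scores, covariates, extra = NULL) {
  df <- as.data.frame(pheno)
  df$dbp <- unname(dbp_scores[df$individual_id])
  df$sex <- factor(df$sex, levels = c("female", "male"))
  if ("race" %in% names(df)) {
    # reference coding against the largest reported group
    lv <- names(sort(table(df$race), decreasing = TRUE))
    df$race <- factor(df$race, levels = lv)
  }
  keep <- unique(c("individual_id", "sleep_minutes", "dbp", covariates,
                   extra))
  df[, intersect(keep, names(df)), drop = FALSE]
}

.check_rank <- function(fit) {
  al <- stats::alias(fit)
  if (!is.null(al$Complete) && nrow(al$Complete) > 0L)
    stop("rank-deficient design; collinear term(s): ",
         paste(rownames(al$Complete), collapse = ", "), call. = FALSE)
  invisible(fit)
}

.result_from_fit <- function(fit, n, outcome, stratum = NA_character_) {
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), beta = sm[, 1L], se = sm[, 2L],
                    t = sm[, 3L], p = sm[, 4L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "outcome") <- outcome
  attr(out, "stratum") <- stratum
  class(out) <- c("regression_result", "data.frame")
  out
}

#' @export
print.regression_result <- function(x, ...) {
  cat("regression of", attr(x, "outcome"),
      if (!is.na(attr(x, "stratum"))) paste0("[", attr(x, "stratum"), "]"),
      "on", nrow(x), "terms, n =", attr(x, "n"), "\n")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Linear association between a DBP score and sleep duration
#'
#' Ordinary least squares of sleep duration (minutes/night) on the DBP
#' score, adjusting for age at ascertainment, genetically determined sex,
#' reported race and full-scale IQ; optional symptom-severity covariates
#' (`social_comm`, `rrb`) can be appended. Complete-case analysis.
#'
#' @param pheno A `phenotype_table`.
#' @param dbp_scores Named numeric vector: DBP score per individual id.
#' @param covariates Covariate column names.
#' @param extra Additional covariate columns (e.g.,
#'   `c("social_comm", "rrb")`).
#' @return A `regression_result` data frame (one row per model term).
#' @export
fit_dbp_linear <- function(pheno, dbp_scores,
                           covariates = c("age_years", "sex", "race", "iq"),
                           extra = NULL) {
  df <- .assoc_frame(pheno, dbp_scores, covariates, extra)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  rhs <- paste(c("dbp", covariates, extra), collapse = " + ")
  if (nrow(df) < length(covariates) + length(extra) + 3L)
    stop("too few complete-case rows for the model", call. = FALSE)
  fit <- stats::lm(stats::as.formula(paste("sleep_minutes ~", rhs)),
                   data = df)
  .check_rank(fit)
  .result_from_fit(fit, nrow(df), "sleep_minutes")
}

#' Association between a DBP score and an extreme-duration category
#'
#' Regresses a 0/1 indicator of category membership on the DBP score and
#' covariates. The default is a linear probability model (least squares on
#' the indicator, coefficients on the probability scale); a logistic link
#' is available.
#'
#' @param pheno A `phenotype_table`.
#' @param dbp_scores Named numeric vector of DBP scores.
#' @param category Which category's indicator to model.
#' @param covariates Covariate columns.
#' @param link `"linear"` (probability scale) or `"logistic"`.
#' @param short_max,long_min Category thresholds in minutes.
#' @return A `regression_result`.
#' @export
fit_dbp_category <- function(pheno, dbp_scores,
                             category = c("extremely_long",
                                          "extremely_short", "non_extreme"),
                             covariates = c("age_years", "sex", "race",
                                            "iq"),
                             link = c("linear", "logistic"),
                             short_max = 420, long_min = 660) {
  category <- match.arg(category)
  link <- match.arg(link)
  df <- .assoc_frame(pheno, dbp_scores, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  cats <- categorize_durations(df$sleep_minutes, short_max, long_min)
  df$indicator <- as.integer(cats == category)
  if (all(df$indicator == 0L) || all(df$indicator == 1L))
    stop("category indicator is constant (all ",
         df$indicator[1L], ")", call. = FALSE)
  rhs <- paste(c("dbp", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("indicator ~", rhs))
  if (link == "linear") {
    fit <- stats::lm(fml, data = df)
    .check_rank(fit)
    res <- .result_from_fit(fit, nrow(df), paste0("P(", category, ")"))
  } else {
    fit <- stats::glm(fml, data = df, family = stats::binomial())
    sm <- summary(fit)$coefficients
    res <- data.frame(term = rownames(sm), beta = sm[, 1L], se = sm[, 2L],
                      t = sm[, 3L], p = sm[, 4L], stringsAsFactors = FALSE)
    attr(res, "n") <- nrow(df)
    attr(res, "outcome") <- paste0("logit P(", category, ")")
    attr(res, "stratum") <- NA_character_
    class(res) <- c("regression_result", "data.frame")
  }
  res
}

#' Effect-modification (interaction) model
#'
#' Adds a DBP-by-modifier product term (modifier: age or sex) to the linear
#' sleep-duration model, with both main effects and the covariates.
#'
#' @param pheno A `phenotype_table`.
#' @param dbp_scores Named numeric vector of DBP scores.
#' @param modifier `"age_years"` or `"sex"`.
#' @param covariates Covariate columns (the modifier is included
#'   automatically).
#' @return A `regression_result`; the product-term row is named
#'   `dbp:<modifier>`.
#' @export
fit_dbp_interaction <- function(pheno, dbp_scores,
                                modifier = c("age_years", "sex"),
                                covariates = c("age_years", "sex", "race",
                                               "iq")) {
  modifier <- match.arg(modifier)
  df <- .assoc_frame(pheno, dbp_scores, unique(c(covariates, modifier)))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df[[modifier]])) < 2L)
    stop("modifier ", modifier, " is constant; interaction not estimable",
         call. = FALSE)
  others <- setdiff(covariates, modifier)
  rhs <- paste(c(paste0("dbp * ", modifier), others), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("sleep_minutes ~", rhs)),
                   data = df)
  .check_rank(fit)
  .result_from_fit(fit, nrow(df), "sleep_minutes")
}

#' Age-stratified DBP-sleep association models
#'
#' Fits the covariate-adjusted linear model separately within age strata
#' (defaults: preschool 4-5, primary school 6-12, secondary school 13-18
#' years). Strata with too few complete-case rows are skipped with a note.
#'
#' @param pheno A `phenotype_table`.
#' @param dbp_scores Named numeric vector of DBP scores.
#' @param age_bins Named list of `c(min, max)` age bounds (inclusive).
#' @param covariates Covariate columns (age is retained within stratum).
#' @return Named list of `regression_result` objects (skipped strata carry
#'   a character note instead).
#' @export
fit_dbp_stratified <- function(pheno, dbp_scores,
                               age_bins = list(preschool = c(4, 5),
                                               primary = c(6, 12),
                                               secondary = c(13, 18)),
                               covariates = c("age_years", "sex", "race",
                                              "iq")) {
  out <- vector("list", length(age_bins))
  names(out) <- names(age_bins)
  for (nm in names(age_bins)) {
    bounds <- age_bins[[nm]]
    sub <- pheno[!is.na(pheno$age_years) & pheno$age_years >= bounds[1L] &
                   pheno$age_years <= bounds[2L], , drop = FALSE]
    df <- .assoc_frame(sub, dbp_scores, covariates)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    if (nrow(df) < length(covariates) + 3L) {
      out[[nm]] <- paste0("skipped: only ", nrow(df),
                          " complete-case rows")
      next
    }
    # drop covariates constant within the stratum (e.g., one race level)
    cov_use <- covariates[vapply(covariates, function(cl)
      length(unique(df[[cl]])) > 1L, TRUE)]
    rhs <- paste(c("dbp", cov_use), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste("sleep_minutes ~", rhs)),
                     data = df)
    .check_rank(fit)
    out[[nm]] <- .result_from_fit(fit, nrow(df), "sleep_minutes",
                                  stratum = nm)
  }
  out
}
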