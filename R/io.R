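#' Read an annotated variant table
#'
#' Ingests the flat TSV contract for annotated variants: one row per variant
#' call per individual, with coordinates, genotype, a high-consequence flag,
#' QC fields, and one column per in-silico predictor. Predictor tokens are
#' mapped to `damaging`/`benign`/`missing` through `config$token_map`.
#'
#' Required columns: `individual_id`, `gene_id`, `chrom`, `pos`,
#' `variant_class`, `genotype`, `vep_high`, `depth`, `gq`, plus every
#' configured predictor. Optional columns: `ref`, `alt`, `inheritance`,
#' `gt_pass`. Unknown columns are ignored with a warning.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param config A [run_config()] object.
#' @return A `data.frame` of class `variant_table` with predictor columns
#'   holding `damaging`/`benign`/`missing` strings.
#' @export
read_variant_table <- function(path, config = run_config()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  as_variant_table(raw, config)
}

#' Coerce a raw data.frame into a typed variant table
#'
#' @param raw Data frame with character columns as read from disk.
#' @param config A [run_config()] object.
#' @return A `variant_table` data frame.
#' @export
as_variant_table <- function(raw, config = run_config()) {
  required <- c("individual_id", "gene_id", "chrom", "pos", "variant_class",
                "genotype", "vep_high", "depth", "gq", config$predictors)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- c("ref", "alt", "inheritance", "gt_pass")
  known <- c(required, optional)
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    warning("ignoring unrecognized column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }

  nr <- nrow(raw)
  tab <- data.frame(
    individual_id = as.character(raw$individual_id),
    gene_id = as.character(raw$gene_id),
    chrom = as.character(raw$chrom),
    pos = as.integer(raw$pos),
    ref = if ("ref" %in% names(raw)) as.character(raw$ref) else
      rep(NA_character_, nr),
    alt = if ("alt" %in% names(raw)) as.character(raw$alt) else
      rep(NA_character_, nr),
    variant_class = as.character(raw$variant_class),
    genotype = as.character(raw$genotype),
    vep_high = .parse_logical(raw$vep_high),
    depth = suppressWarnings(as.integer(raw$depth)),
    gq = suppressWarnings(as.integer(raw$gq)),
    inheritance = if ("inheritance" %in% names(raw))
      as.character(raw$inheritance) else rep("unknown", nr),
    stringsAsFactors = FALSE
  )
  if ("gt_pass" %in% names(raw)) tab$gt_pass <- .parse_logical(raw$gt_pass)

  bad_class <- setdiff(unique(tab$variant_class), c("SNV", "INDEL", "CNV"))
  if (length(bad_class) > 0L)
    stop("unknown variant_class value(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  bad_gt <- setdiff(unique(tab$genotype), c("het", "hom"))
  if (length(bad_gt) > 0L)
    stop("unknown genotype value(s): ", paste(bad_gt, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) > 0L && any(tab$pos < 1L, na.rm = TRUE))
    stop("variant positions must be 1-based (pos >= 1)", call. = FALSE)

  for (p in config$predictors) {
    tok <- as.character(raw[[p]])
    tok[is.na(tok)] <- ""
    mapped <- unname(config$token_map[tok])
    bad <- unique(tok[is.na(mapped)])
    if (length(bad) > 0L) {
      stop("unmappable predictor token(s) in column ", p, ": ",
           paste(shQuote(bad), collapse = ", "), call. = FALSE)
    }
    tab[[p]] <- mapped
  }
  attr(tab, "predictors") <- config$predictors
  class(tab) <- c("variant_table", "data.frame")
  tab
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Apply depth / genotype-quality QC to a variant table
#'
#' SNV and indel rows must reach the depth and genotype-quality thresholds
#' (defaults: depth >= 8 reads, GQ >= 20); CNV rows carry no read-level QC
#' fields and bypass the filter. If a `gt_pass` column is present, rows
#' failing the upstream genotype filter are also dropped.
#'
#' @param tab A `variant_table`.
#' @param min_depth,min_gq QC thresholds (inclusive).
#' @param verbose Emit a message with the number of removed rows.
#' @return The filtered `variant_table`.
#' @export
apply_qc_filter <- function(tab, min_depth = 8L, min_gq = 20L,
                            verbose = FALSE) {
  is_cnv <- tab$variant_class == "CNV"
  ok <- is_cnv | (!is.na(tab$depth) & tab$depth >= min_depth &
                    !is.na(tab$gq) & tab$gq >= min_gq)
  if ("gt_pass" %in% names(tab)) ok <- ok & (is_cnv | !isFALSE_vec(tab$gt_pass))
  removed <- sum(!ok)
  if (verbose && removed > 0L)
    message("QC filter removed ", removed, " of ", nrow(tab), " rows")
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(tab)
  attr(out, "predictors") <- attr(tab, "predictors")
  out
}

isFALSE_vec <- function(x) !is.na(x) & !x

#' Read a BED file of genomic intervals
#'
#' BED convention: 0-based, half-open `[start, end)`. Intervals are returned
#' as a `GRanges` (1-based, closed), with the BED name column stored in the
#' `label` metadata column.
#'
#' @param path Path to a 3+-column BED file (tab- or space-separated).
#' @return A [GenomicRanges::GRanges] with a `label` column.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(label = character(0)))
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], call. = FALSE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (any(is.na(start0)) || any(is.na(end0)))
    stop("malformed BED line ",
         which(is.na(start0) | is.na(end0))[1], call. = FALSE)
  if (any(start0 >= end0))
    stop("BED interval with start >= end at line ",
         which(start0 >= end0)[1], call. = FALSE)
  label <- vapply(seq_along(parts), function(i)
    if (nf[i] >= 4L) parts[[i]][4L] else NA_character_, "")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               label = label)
  GenomicRanges::sort(gr)
}

#' Write genomic intervals to a BED file (0-based half-open)
#'
#' @param gr A `GRanges` with an optional `label` metadata column.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  label <- if ("label" %in% names(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr)$label else rep(".", length(gr))
  label[is.na(label)] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   label = label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' STRING-style TSV with columns `protein1`, `protein2`, `combined_score`
#' (0-1000). Edges below `min_score` are dropped at read time.
#'
#' @param path Path to the edge file.
#' @param min_score Minimum combined score to retain (default 400, the
#'   "medium confidence" convention).
#' @return Data frame with columns `protein1`, `protein2`, `combined_score`.
#' @export
read_edges <- function(path, min_score = 400) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("edge file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$combined_score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(df$combined_score)))
    stop("malformed combined_score at line ",
         which(is.na(df$combined_score))[1] + 1L, call. = FALSE)
  out <- df[df$combined_score >= min_score, need, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a phenotype table
#'
#' CSV with columns `individual_id`, `sleep_minutes`, `age_years`, `sex`,
#' `race`, `iq` and optional `social_comm`, `rrb`. Individuals without sleep
#' data are retained and flagged (`has_sleep = FALSE`) so that genotype-only
#' stages still see the full cohort.
#'
#' @param path Path to the CSV file.
#' @return Data frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "sleep_minutes", "age_years", "sex", "race", "iq")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("phenotype table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$individual_id <- as.character(df$individual_id)
  df$sleep_minutes <- suppressWarnings(as.numeric(df$sleep_minutes))
  if (any(df$sleep_minutes <= 0, na.rm = TRUE))
    stop("sleep_minutes must be positive when present", call. = FALSE)
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex) > 0L)
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  df$has_sleep <- !is.na(df$sleep_minutes)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a two-column gene-to-protein identifier map
#'
#' @param path TSV with columns `gene_id`, `protein_id`.
#' @return Data frame with the two columns.
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "protein_id") %in% names(df)))
    stop("id map must have columns gene_id, protein_id", call. = FALSE)
  df[, c("gene_id", "protein_id")]
}

#' Read a gene feature table for matched-random selection
#'
#' @param path TSV with columns `gene_id`, `gc_content`, `transcript_size`,
#'   `n_spliceoforms`.
#' @return Data frame with typed feature columns.
#' @export
read_gene_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "gc_content", "transcript_size", "n_spliceoforms")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("gene feature table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$gc_content <- as.numeric(df$gc_content)
  df$transcript_size <- as.numeric(df$transcript_size)
  df$n_spliceoforms <- as.numeric(df$n_spliceoforms)
  if (any(df$gc_content < 0 | df$gc_content > 1, na.rm = TRUE))
    stop("gc_content must lie in [0, 1]", call. = FALSE)
  df[, need]
}

#' Write a generic TSV artifact
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
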