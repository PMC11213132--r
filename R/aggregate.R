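EPITOPE_COLUMNS <- c("chromosome", "position", "gene", "transcript_id",
                     "mt_peptide", "wt_peptide", "hla_allele", "algorithm",
                     "ic50_mt", "ic50_wt", "percentile_mt", "percentile_wt",
                     "score_class")

SCORE_CLASSES <- c("binding", "elution", "immunogenicity")

# Shared validation for binding-record data.frames. For non-binding score
# classes the ic50_mt/ic50_wt columns are reinterpreted as scores in [0, 1].
validateBindingRecords <- function(records, requireColumns = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("mt_peptide", "hla_allele", "algorithm", "ic50_mt", "score_class")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop(sprintf("binding records lack column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("wt_peptide", "ic50_wt", "percentile_mt", "percentile_wt")) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col == "wt_peptide") NA_character_ else NA_real_
    }
  }
  badClass <- !records$score_class %in% SCORE_CLASSES
  if (any(badClass)) {
    stop(sprintf("unknown score_class value(s): %s",
                 paste(unique(records$score_class[badClass]), collapse = ", ")),
         call. = FALSE)
  }
  isBind <- records$score_class == "binding"
  if (any(isBind & !is.na(records$ic50_mt) & records$ic50_mt <= 0)) {
    stop("IC50 values must be strictly positive (nM)", call. = FALSE)
  }
  for (col in c("percentile_mt", "percentile_wt")) {
    v <- records[[col]][isBind]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop(sprintf("%s values must lie in [0, 100]", col), call. = FALSE)
    }
  }
  records
}

#' Summarize per-algorithm binding predictions for one MT/WT peptide pair
#'
#' Collapses the per-algorithm binding predictions of a single mutant
#' peptide into per-allele summaries: median and lowest mutant IC50, median
#' mutant percentile rank, the corresponding wild-type medians, and whether
#' the allele passes the configured binding cutoff. The median over an even
#' number of algorithms is the mean of the two central values; missing
#' algorithm scores are omitted rather than imputed. Wild-type medians are
#' reported only where the mutant metric passed the binding threshold.
#' Elution and immunogenicity records are ignored here (see
#' [assembleOrthogonalTable()]).
#'
#' @param records data.frame of prediction records for one MT/WT pair, with
#'   columns `mt_peptide`, `wt_peptide`, `hla_allele`, `algorithm`,
#'   `ic50_mt`, `ic50_wt`, `percentile_mt`, `percentile_wt`, `score_class`.
#' @param cfg an [AggregationConfig].
#' @return a [PeptideSummary].
#' @examples
#' rec <- data.frame(mt_peptide = "KLVVVGAVG", wt_peptide = "KLVVVGAGG",
#'                   hla_allele = "HLA-A*02:01",
#'                   algorithm = c("NetMHC", "NetMHCpan", "SMM"),
#'                   ic50_mt = c(100, 200, 400), ic50_wt = c(900, 1100, 1000),
#'                   percentile_mt = c(0.5, 1, 2), percentile_wt = 40,
#'                   score_class = "binding")
#' summarizePeptide(rec, AggregationConfig())
#' @export
summarizePeptide <- function(records, cfg = AggregationConfig()) {
  validObject(cfg)
  records <- validateBindingRecords(records)
  if (length(unique(records$mt_peptide)) != 1L) {
    stop("records must all concern a single mt_peptide", call. = FALSE)
  }
  bind <- records[records$score_class == "binding", , drop = FALSE]
  if (nrow(bind) == 0L) {
    stop("no binding-class records for this peptide", call. = FALSE)
  }
  mtPep <- bind$mt_peptide[[1]]
  wtPeps <- bind$wt_peptide[!is.na(bind$wt_peptide)]
  wtPep <- if (length(wtPeps)) wtPeps[[1]] else NA_character_

  byAllele <- split(bind, bind$hla_allele)
  pa <- do.call(rbind, lapply(names(byAllele), function(al) {
    b <- byAllele[[al]]
    data.frame(
      hla_allele = al,
      median_ic50_mt = medianOrNA(b$ic50_mt),
      lowest_ic50_mt = minOrNA(b$ic50_mt),
      median_percentile_mt = medianOrNA(b$percentile_mt),
      median_ic50_wt = medianOrNA(b$ic50_wt),
      median_percentile_wt = medianOrNA(b$percentile_wt),
      n_algorithms = sum(!is.na(b$ic50_mt)),
      stringsAsFactors = FALSE)
  }))
  pa <- pa[order(pa$hla_allele), , drop = FALSE]
  pa$metric_value <- if (cfg@metric == "median") pa$median_ic50_mt else
    pa$lowest_ic50_mt
  pass <- !is.na(pa$metric_value) & pa$metric_value <= cfg@ic50Threshold
  if (cfg@usePercentile) {
    pass <- pass | (!is.na(pa$median_percentile_mt) &
                      pa$median_percentile_mt <= cfg@percentileThreshold)
  }
  pa$passes_binding <- pass
  # WT medians are display values conditional on the MT peptide binding
  pa$median_ic50_wt[!pass] <- NA_real_
  pa$median_percentile_wt[!pass] <- NA_real_

  ok <- !is.na(pa$metric_value)
  best <- if (any(ok)) {
    cand <- pa$hla_allele[ok][pa$metric_value[ok] ==
                                min(pa$metric_value[ok])]
    sort(cand)[[1]]
  } else NA_character_
  rownames(pa) <- NULL
  new("PeptideSummary", mtPeptide = mtPep, wtPeptide = wtPep,
      perAllele = pa, bestAllele = best, metric = cfg@metric)
}

#' Bulk per-peptide aggregation over a full epitope table
#'
#' Vectorized counterpart of [summarizePeptide()] for whole prediction
#' tables: groups binding-class records by (grouping columns, mutant
#' peptide, allele) and computes the same per-allele summary statistics.
#' Used by the report pipeline and the fixture generator, where tables run
#' to millions of rows.
#'
#' @param records epitope prediction data.frame (see [summarizePeptide()]);
#'   may cover many peptides and variants.
#' @param cfg an [AggregationConfig].
#' @param by character vector of extra grouping columns present in
#'   `records` (e.g. `"variant_id"`); default none.
#' @return data.frame with one row per (grouping, mt_peptide, hla_allele):
#'   the columns of a [PeptideSummary] `perAllele` slot plus `mt_peptide`,
#'   `wt_peptide`, `length` and the grouping columns.
#' @export
summarizeEpitopes <- function(records, cfg = AggregationConfig(),
                              by = character()) {
  validObject(cfg)
  records <- validateBindingRecords(records)
  stopifnot(all(by %in% names(records)))
  dt <- data.table::as.data.table(
    records[records$score_class == "binding", , drop = FALSE])
  if (nrow(dt) == 0L) {
    stop("no binding-class records in the table", call. = FALSE)
  }
  keys <- c(by, "mt_peptide", "hla_allele")
  agg <- dt[, list(
    wt_peptide = {
      w <- wt_peptide[!is.na(wt_peptide)]
      if (length(w)) w[[1]] else NA_character_
    },
    median_ic50_mt = medianOrNA(ic50_mt),
    lowest_ic50_mt = minOrNA(ic50_mt),
    median_percentile_mt = medianOrNA(percentile_mt),
    median_ic50_wt = medianOrNA(ic50_wt),
    median_percentile_wt = medianOrNA(percentile_wt),
    n_algorithms = sum(!is.na(ic50_mt))
  ), by = keys]
  agg[, "metric_value" := if (cfg@metric == "median") median_ic50_mt else
    lowest_ic50_mt]
  pass <- !is.na(agg$metric_value) & agg$metric_value <= cfg@ic50Threshold
  if (cfg@usePercentile) {
    pass <- pass | (!is.na(agg$median_percentile_mt) &
                      agg$median_percentile_mt <= cfg@percentileThreshold)
  }
  agg[, "passes_binding" := pass]
  agg[!pass, c("median_ic50_wt", "median_percentile_wt") :=
        list(NA_real_, NA_real_)]
  agg[, "length" := nchar(mt_peptide)]
  data.table::setorderv(agg, keys)
  out <- as.data.frame(agg)
  rownames(out) <- NULL
  out
}

# internal: metric value of a summary at its best allele
summaryBestMetric <- function(s) {
  row <- s@perAllele[s@perAllele$hla_allele == s@bestAllele, , drop = FALSE]
  if (nrow(row) == 0L) NA_real_ else row$metric_value[[1]]
}

#' Select a variant's best peptide among its summaries
#'
#' Picks the summary whose best-allele metric (median or lowest mutant
#' IC50, per configuration) is smallest; ties are broken by lexicographic
#' mutant peptide so the choice is deterministic. Also counts how many of
#' the remaining peptides pass the binding cutoff on at least one allele —
#' the "additional passing peptides" figure reported per variant.
#'
#' @param summaries list of [PeptideSummary] objects for one variant.
#' @param cfg an [AggregationConfig].
#' @return list with elements `best` (a [PeptideSummary]) and
#'   `n_passing_others` (integer).
#' @export
selectBestPeptide <- function(summaries, cfg = AggregationConfig()) {
  if (length(summaries) == 0L) {
    stop("need at least one peptide summary", call. = FALSE)
  }
  stopifnot(all(vapply(summaries, is, TRUE, "PeptideSummary")))
  metr <- vapply(summaries, summaryBestMetric, 0)
  peps <- vapply(summaries, mtPeptide, "")
  ord <- order(metr, peps, na.last = TRUE)
  bestIdx <- ord[[1]]
  others <- summaries[-bestIdx]
  nPass <- sum(vapply(others, function(s) any(passesBinding(s)), TRUE))
  list(best = summaries[[bestIdx]], n_passing_others = as.integer(nPass))
}

#' Per-algorithm binding table for one MT/WT peptide pair
#'
#' One row per (allele, algorithm) with the numerical mutant and wild-type
#' IC50 and percentile values, the drill-down view behind each peptide.
#' When `restrictToPassing = TRUE` (default), alleles are restricted to
#' those with at least one predicted strong binder (any algorithm's mutant
#' IC50 at or below the configured cutoff). The full allele x algorithm
#' grid is emitted with explicit `NA` for combinations the predictors
#' declined.
#'
#' @param records prediction records for one MT/WT pair.
#' @param cfg an [AggregationConfig].
#' @param restrictToPassing restrict alleles as described above.
#' @return data.frame with columns `hla_allele`, `algorithm`, `ic50_mt`,
#'   `ic50_wt`, `percentile_mt`, `percentile_wt`.
#' @export
assembleBindingTable <- function(records, cfg = AggregationConfig(),
                                 restrictToPassing = TRUE) {
  validObject(cfg)
  if (nrow(records) == 0L) {
    return(data.frame(hla_allele = character(), algorithm = character(),
                      ic50_mt = numeric(), ic50_wt = numeric(),
                      percentile_mt = numeric(), percentile_wt = numeric(),
                      stringsAsFactors = FALSE))
  }
  records <- validateBindingRecords(records)
  if (length(unique(records$mt_peptide)) > 1L) {
    stop("records must all concern a single mt_peptide", call. = FALSE)
  }
  bind <- records[records$score_class == "binding", , drop = FALSE]
  alleles <- sort(unique(bind$hla_allele))
  if (restrictToPassing) {
    strong <- vapply(alleles, function(al) {
      v <- bind$ic50_mt[bind$hla_allele == al]
      any(!is.na(v) & v <= cfg@ic50Threshold)
    }, TRUE)
    alleles <- alleles[strong]
  }
  algorithms <- sort(unique(bind$algorithm))
  grid <- expand.grid(algorithm = algorithms, hla_allele = alleles,
                      stringsAsFactors = FALSE)[, c("hla_allele", "algorithm")]
  idx <- match(paste(grid$hla_allele, grid$algorithm),
               paste(bind$hla_allele, bind$algorithm))
  for (col in c("ic50_mt", "ic50_wt", "percentile_mt", "percentile_wt")) {
    grid[[col]] <- bind[[col]][idx]
  }
  rownames(grid) <- NULL
  grid
}

#' Orthogonal elution / immunogenicity score table for one peptide pair
#'
#' Collects the non-binding prediction classes — elution scores from
#' predictors trained on peptide elution mass spectrometry, and
#' immunogenicity scores — into a labeled table. Scores live in [0, 1]
#' (1 best); a score outside that range is a validation error naming the
#' offending record. These scores are advisory and never affect tiering.
#'
#' @param records prediction records for one MT/WT pair.
#' @return data.frame with columns `score_class`, `hla_allele`,
#'   `algorithm`, `score_mt`, `score_wt`, ordered by class then allele then
#'   algorithm.
#' @export
assembleOrthogonalTable <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(score_class = character(), hla_allele = character(),
                      algorithm = character(), score_mt = numeric(),
                      score_wt = numeric(), stringsAsFactors = FALSE))
  }
  records <- validateBindingRecords(records)
  orth <- records[records$score_class != "binding", , drop = FALSE]
  bad <- which(!is.na(orth$ic50_mt) & (orth$ic50_mt < 0 | orth$ic50_mt > 1))
  if (length(bad)) {
    b <- orth[bad[[1]], ]
    stop(sprintf(
      "%s score %g for (%s, %s, %s) outside [0, 1]", b$score_class,
      b$ic50_mt, b$mt_peptide, b$hla_allele, b$algorithm), call. = FALSE)
  }
  badWt <- which(!is.na(orth$ic50_wt) & (orth$ic50_wt < 0 | orth$ic50_wt > 1))
  if (length(badWt)) {
    b <- orth[badWt[[1]], ]
    stop(sprintf(
      "%s WT score %g for (%s, %s, %s) outside [0, 1]", b$score_class,
      b$ic50_wt, b$mt_peptide, b$hla_allele, b$algorithm), call. = FALSE)
  }
  out <- data.frame(score_class = orth$score_class,
                    hla_allele = orth$hla_allele,
                    algorithm = orth$algorithm,
                    score_mt = orth$ic50_mt,
                    score_wt = orth$ic50_wt,
                    stringsAsFactors = FALSE)
  out <- out[order(out$score_class, out$hla_allele, out$algorithm), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write epitope prediction tables
#'
#' Tab-delimited, one row per (peptide, HLA allele, algorithm) prediction.
#' Columns: `chromosome`, `position`, `gene`, `transcript_id`,
#' `mt_peptide`, `wt_peptide`, `hla_allele`, `algorithm`, `ic50_mt`,
#' `ic50_wt`, `percentile_mt`, `percentile_wt`, `score_class`; a
#' `variant_id` column is carried through when present. Missing values are
#' empty fields or `NA`.
#'
#' @param path file path.
#' @param records data.frame of prediction records.
#' @return `readEpitopes()` returns the validated data.frame.
#' @export
readEpitopes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  missing <- setdiff(EPITOPE_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("epitope table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  validateBindingRecords(df)
}

#' @rdname readEpitopes
#' @export
writeEpitopes <- function(records, path) {
  records <- validateBindingRecords(records)
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
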