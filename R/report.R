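## Aggregate report schema: column name -> storage type. Extra columns are
## carried through untouched (read and written verbatim as text).
AGGREGATE_SCHEMA <- c(
  "ID"                   = "character",
  "Gene"                 = "character",
  "AA Change"            = "character",
  "Pos"                  = "character",
  "Best Peptide"         = "character",
  "WT Peptide"           = "character",
  "Best Transcript Set"  = "character",
  "Allele"               = "character",
  "IC50 MT"              = "numeric",
  "IC50 WT"              = "numeric",
  "%ile MT"              = "numeric",
  "%ile WT"              = "numeric",
  "Num Passing Peptides" = "integer",
  "RNA Expr"             = "numeric",
  "RNA VAF"              = "numeric",
  "Allele Expr"          = "numeric",
  "RNA Depth"            = "integer",
  "DNA VAF"              = "numeric",
  "TSL"                  = "integer",
  "Anchor Residue"       = "character",
  "Tier"                 = "character",
  "Eval"                 = "character"
)

EVAL_LEVELS <- c("Pending", "Accept", "Reject", "Review")

METRICS_SCHEMA_VERSION <- "1.0"

#' Read and write the aggregate neoantigen report (TSV / spreadsheet)
#'
#' The aggregate report holds one row per variant: its best peptide and
#' transcript set, summarized binding scores, expression and VAF fields,
#' assigned tier and evaluation. The TSV form is tab-delimited with a
#' header; missing values are written as `NA`; numeric fields are written
#' with enough digits that a write/read round trip reproduces them exactly.
#' Columns outside the core schema are preserved verbatim. A `spreadsheet`
#' export (Excel 2003 SpreadsheetML, a single XML file Excel and
#' LibreOffice open directly) is provided for downstream viewing but is
#' write-only: evaluations can only be re-loaded from the TSV form.
#'
#' @param path file path.
#' @param rows aggregate report data.frame.
#' @param format `"tsv"` (round-trip capable) or `"spreadsheet"`
#'   (write-only).
#' @return `readAggregate()` returns the typed data.frame; writers return
#'   the path invisibly.
#' @export
readAggregate <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  missing <- setdiff(names(AGGREGATE_SCHEMA), names(df))
  if (length(missing)) {
    stop(sprintf("aggregate report lacks mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in names(AGGREGATE_SCHEMA)) {
    v <- df[[col]]
    v[v == "NA"] <- NA
    df[[col]] <- switch(AGGREGATE_SCHEMA[[col]],
                        numeric = as.numeric(v),
                        integer = as.integer(v),
                        v)
  }
  badEval <- !is.na(df$Eval) & !df$Eval %in% EVAL_LEVELS
  if (any(badEval)) {
    stop(sprintf("invalid Eval value(s): %s",
                 paste(unique(df$Eval[badEval]), collapse = ", ")),
         call. = FALSE)
  }
  df$Eval[is.na(df$Eval)] <- "Pending"
  df
}

#' @rdname readAggregate
#' @export
writeAggregate <- function(rows, path, format = c("tsv", "spreadsheet")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  missing <- setdiff(names(AGGREGATE_SCHEMA), names(rows))
  if (length(missing)) {
    stop(sprintf("aggregate report lacks mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (format == "spreadsheet") {
    return(writeSpreadsheetML(rows, path))
  }
  out <- rows
  for (col in names(out)) {
    type <- AGGREGATE_SCHEMA[col]
    if (identical(unname(type), "numeric")) {
      out[[col]] <- formatNumber(rows[[col]])
    } else if (identical(unname(type), "integer")) {
      out[[col]] <- as.character(as.integer(rows[[col]]))
    } else {
      out[[col]] <- as.character(rows[[col]])
    }
    out[[col]][is.na(out[[col]])] <- "NA"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L) {
    body <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

# Excel 2003 SpreadsheetML writer (single-file XML workbook).
writeSpreadsheetML <- function(rows, path) {
  header <- vapply(names(rows), function(nm) sprintf(
    "<Cell><Data ss:Type=\"String\">%s</Data></Cell>", xmlEscape(nm)), "")
  rowXml <- vapply(seq_len(nrow(rows)), function(i) {
    cells <- vapply(names(rows), function(nm) {
      v <- rows[[nm]][i]
      if (is.na(v)) {
        "<Cell><Data ss:Type=\"String\">NA</Data></Cell>"
      } else if (is.numeric(v)) {
        sprintf("<Cell><Data ss:Type=\"Number\">%s</Data></Cell>",
                formatNumber(v))
      } else {
        sprintf("<Cell><Data ss:Type=\"String\">%s</Data></Cell>",
                xmlEscape(as.character(v)))
      }
    }, "")
    sprintf("<Row>%s</Row>", paste(cells, collapse = ""))
  }, "")
  doc <- paste0(
    "<?xml version=\"1.0\"?>\n",
    "<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\"",
    " xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">",
    "<Worksheet ss:Name=\"Aggregate\"><Table>",
    sprintf("<Row>%s</Row>", paste(header, collapse = "")),
    paste(rowXml, collapse = ""),
    "</Table></Worksheet></Workbook>")
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

#' Read, write and validate the metrics document (JSON)
#'
#' The metrics document carries the transcript- and peptide-level detail
#' behind each aggregate row: per variant, its transcript sets (member
#' transcripts, summed expression, best TSL) and per-set peptides with the
#' full per-allele, per-algorithm score grid; plus the anchor-probability
#' matrices keyed by `"allele|length"`. The schema is versioned
#' (`schema_version`); [validateMetrics()] checks structure on load.
#'
#' @param path JSON file path.
#' @param doc metrics document (nested list, see [makeReportPair()]).
#' @return `readMetrics()` returns the validated document.
#' @export
readMetrics <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc <- canonicalizeMetrics(doc)
  validateMetrics(doc)
  doc
}

# Normalize a freshly parsed metrics document to the package's in-memory
# form: typed vectors, NA for JSON null, and per-peptide score grids as
# data.frames. write -> read -> canonicalize is the identity on documents
# built by makeReportPair().
canonicalizeMetrics <- function(doc) {
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  int <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  doc$alleles <- as.character(unlist(doc$alleles))
  doc$algorithms <- as.character(unlist(doc$algorithms))
  doc$anchor_matrices <- lapply(doc$anchor_matrices,
                                function(p) as.numeric(unlist(p)))
  doc$variants <- lapply(doc$variants, function(v) {
    for (f in c("dna_vaf", "rna_vaf", "gene_expr", "tumor_purity")) {
      v[[f]] <- num(v[[f]])
    }
    v$rna_depth <- int(v$rna_depth)
    v$transcript_sets <- lapply(v$transcript_sets, function(s) {
      s$transcript_ids <- as.character(unlist(s$transcript_ids))
      s$total_expression <- num(s$total_expression)
      s$best_tsl <- int(s$best_tsl)
      s$peptides <- lapply(s$peptides, function(p) {
        p$mt_peptide <- chr(p$mt_peptide)
        p$wt_peptide <- chr(p$wt_peptide)
        p$length <- int(p$length)
        p$mutation_positions <- as.integer(unlist(p$mutation_positions))
        sc <- p$scores
        if (!is.data.frame(sc)) {
          p$scores <- data.frame(
            hla_allele = vapply(sc, function(r) chr(r$hla_allele), ""),
            algorithm = vapply(sc, function(r) chr(r$algorithm), ""),
            score_class = vapply(sc, function(r) chr(r$score_class), ""),
            ic50_mt = vapply(sc, function(r) num(r$ic50_mt), 0),
            ic50_wt = vapply(sc, function(r) num(r$ic50_wt), 0),
            percentile_mt = vapply(sc, function(r) num(r$percentile_mt), 0),
            percentile_wt = vapply(sc, function(r) num(r$percentile_wt), 0),
            stringsAsFactors = FALSE)
        }
        p
      })
      s
    })
    v
  })
  doc
}

#' @rdname readMetrics
#' @export
writeMetrics <- function(doc, path) {
  validateMetrics(doc)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       na = "null", null = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname readMetrics
#' @export
validateMetrics <- function(doc) {
  if (!is.list(doc) || is.null(doc$variants)) {
    stop("metrics document must be a list with a `variants` element",
         call. = FALSE)
  }
  if (is.null(doc$schema_version)) {
    stop("metrics document lacks schema_version", call. = FALSE)
  }
  for (vid in names(doc$variants)) {
    v <- doc$variants[[vid]]
    if (is.null(v$transcript_sets)) {
      stop(sprintf("metrics entry %s lacks transcript_sets", vid),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Reconcile an aggregate report against its metrics document
#'
#' Every variant in the aggregate report should have a metrics entry and
#' vice versa; each side's misses produce one warning string. An empty
#' return value means the pair is consistent.
#'
#' @param rows aggregate report data.frame.
#' @param metrics metrics document.
#' @return character vector of reconciliation warnings (possibly empty).
#' @export
reconcileReport <- function(rows, metrics) {
  validateMetrics(metrics)
  aggIds <- rows$ID
  metIds <- names(metrics$variants)
  c(
    vapply(setdiff(aggIds, metIds), function(id)
      sprintf("variant %s present in aggregate report but not in metrics", id),
      ""),
    vapply(setdiff(metIds, aggIds), function(id)
      sprintf("variant %s present in metrics but not in aggregate report", id),
      "")
  )
}

## ---------------------------------------------------------------------------
## NeoantigenReport container
## ---------------------------------------------------------------------------

#' Container pairing an aggregate report with its metrics document
#'
#' Holds the variant-level aggregate table and the transcript/peptide-level
#' metrics document as one object, the unit the drill-down views operate
#' on.
#'
#' @slot aggregate aggregate report data.frame (see [readAggregate()]).
#' @slot metrics metrics document (see [readMetrics()]).
#'
#' @export
setClass("NeoantigenReport",
  representation(aggregate = "data.frame", metrics = "list"))

setValidity("NeoantigenReport", function(object) {
  msgs <- character()
  missing <- setdiff(names(AGGREGATE_SCHEMA), names(object@aggregate))
  if (length(missing)) {
    msgs <- c(msgs, sprintf("aggregate lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  if (length(object@metrics)) {
    ok <- tryCatch(validateMetrics(object@metrics),
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
  }
  if (length(msgs)) msgs else TRUE
})

#' @param aggregate,metrics see slots.
#' @rdname NeoantigenReport-class
#' @export
NeoantigenReport <- function(aggregate, metrics = list()) {
  new("NeoantigenReport", aggregate = aggregate, metrics = metrics)
}

#' Load an aggregate/metrics file pair as a NeoantigenReport
#'
#' Reads both files, reconciles them and reports any mismatched variants as
#' warnings.
#'
#' @param aggregatePath aggregate report TSV path.
#' @param metricsPath metrics JSON path (optional).
#' @return a [NeoantigenReport].
#' @export
loadReport <- function(aggregatePath, metricsPath = NULL) {
  rows <- readAggregate(aggregatePath)
  metrics <- if (is.null(metricsPath)) list() else readMetrics(metricsPath)
  if (length(metrics)) {
    warns <- reconcileReport(rows, metrics)
    for (w in warns) warning(w, call. = FALSE)
  }
  NeoantigenReport(rows, metrics)
}

setMethod("show", "NeoantigenReport", function(object) {
  agg <- object@aggregate
  cat(sprintf("NeoantigenReport: %d variant(s)\n", nrow(agg)))
  if (nrow(agg)) {
    tt <- table(factor(agg$Tier, levels = tierLevels()))
    cat("  tiers:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "),
        "\n")
    ev <- evaluationSummary(agg)
    cat(sprintf("  evaluations: accept=%d reject=%d review=%d pending=%d\n",
                ev[["accept"]], ev[["reject"]], ev[["review"]],
                ev[["pending"]]))
  }
  cat(sprintf("  metrics: %s\n",
              if (length(object@metrics))
                sprintf("%d variant entries", length(object@metrics$variants))
              else "absent"))
})

#' Accessors for NeoantigenReport
#'
#' @param x a [NeoantigenReport].
#' @name NeoantigenReport-accessors
#' @aliases aggregateReport reportMetrics
NULL

#' @rdname NeoantigenReport-accessors
#' @export
setGeneric("aggregateReport", function(x) standardGeneric("aggregateReport"))
#' @rdname NeoantigenReport-accessors
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))

setMethod("aggregateReport", "NeoantigenReport", function(x) x@aggregate)
setMethod("reportMetrics", "NeoantigenReport", function(x) x@metrics)

## ---------------------------------------------------------------------------
## Supplementary class merge, gene flags, evaluations
## ---------------------------------------------------------------------------

#' Merge supplementary other-class binding summaries into a report
#'
#' Left-joins median binding information from the other HLA class (class II
#' results while inspecting class I, or vice versa) onto the aggregate rows
#' by variant id. Row count and order are unchanged; variants absent from
#' the supplement get missing values in the added columns, which are
#' prefixed `"Supp. "`.
#'
#' @param rows aggregate report data.frame.
#' @param supp supplementary aggregate report (data.frame or TSV path).
#' @param columns supplement columns to carry over.
#' @return `rows` with the added `Supp. *` columns.
#' @export
mergeSupplementaryClass <- function(rows, supp,
                                    columns = c("Best Peptide", "Allele",
                                                "IC50 MT", "%ile MT")) {
  stopifnot(is.data.frame(rows))
  if (is.character(supp)) supp <- readAggregate(supp)
  missing <- setdiff(c("ID", columns), names(supp))
  if (length(missing)) {
    stop(sprintf("supplementary table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  idx <- match(rows$ID, supp$ID)
  for (col in columns) {
    rows[[paste("Supp.", col)]] <- supp[[col]][idx]
  }
  rows
}

#' Flag genes of interest in an aggregate report
#'
#' Marks rows whose gene symbol appears in a user-supplied gene list (one
#' symbol per line, or a character vector). Matching is exact and
#' case-sensitive; duplicate list entries are harmless. The number of
#' matched rows is reported as a message.
#'
#' @param rows aggregate report data.frame.
#' @param genes character vector of gene symbols, or path to a plain-text
#'   list (one symbol per line).
#' @return `rows` with a logical `Gene of Interest` column.
#' @export
flagGenesOfInterest <- function(rows, genes) {
  stopifnot(is.data.frame(rows))
  if (length(genes) == 1L && is.character(genes) && file.exists(genes)) {
    genes <- readLines(genes)
  }
  genes <- unique(genes[nzchar(genes)])
  rows[["Gene of Interest"]] <- rows$Gene %in% genes
  message(sprintf("%d of %d rows match the gene-of-interest list",
                  sum(rows[["Gene of Interest"]]), nrow(rows)))
  rows
}

#' Evaluation bookkeeping on aggregate rows
#'
#' `evaluationSummary()` counts the Accept / Reject / Review / Pending
#' evaluations (the counts always sum to the number of rows);
#' `setEvaluation()` records an evaluation for one variant, the only
#' mutation this module performs on report rows.
#'
#' @param x aggregate report data.frame or [NeoantigenReport].
#' @param variantId variant id (`ID` column value).
#' @param value one of `"Accept"`, `"Reject"`, `"Review"`, `"Pending"`.
#' @return `evaluationSummary()` a named integer vector
#'   (`accept`, `reject`, `review`, `pending`); `setEvaluation()` the
#'   modified object.
#' @export
setGeneric("evaluationSummary", function(x) standardGeneric("evaluationSummary"))

#' @rdname evaluationSummary
#' @export
setGeneric("setEvaluation",
           function(x, variantId, value) standardGeneric("setEvaluation"))

setMethod("evaluationSummary", "data.frame", function(x) {
  ev <- factor(x$Eval, levels = EVAL_LEVELS)
  tt <- table(ev)
  c(accept = unname(tt[["Accept"]]), reject = unname(tt[["Reject"]]),
    review = unname(tt[["Review"]]), pending = unname(tt[["Pending"]]))
})

setMethod("evaluationSummary", "NeoantigenReport",
          function(x) evaluationSummary(x@aggregate))

setMethod("setEvaluation", "data.frame", function(x, variantId, value) {
  value <- match.arg(value, EVAL_LEVELS)
  hit <- which(x$ID == variantId)
  if (length(hit) == 0L) {
    stop(sprintf("variant %s not found in the aggregate report", variantId),
         call. = FALSE)
  }
  x$Eval[hit] <- value
  x
})

setMethod("setEvaluation", "NeoantigenReport", function(x, variantId, value) {
  x@aggregate <- setEvaluation(x@aggregate, variantId, value)
  x
})

## ---------------------------------------------------------------------------
## Anchor heatmap data and custom-table semantics
## ---------------------------------------------------------------------------

#' Top MT/WT peptide pairs with anchor probabilities attached
#'
#' Orders a peptide table by the configured binding metric (best first,
#' ties broken by mutant peptide) and returns at most `k` pairs — the data
#' behind the anchor heatmap, which shows the top 30 MT/WT pairs by
#' default. Each returned pair carries the anchor-probability vector for
#' its (best allele, peptide length), or `NA` when no matrix is available,
#' plus its mutated positions.
#'
#' @param pairs data.frame with columns `mt_peptide`, `wt_peptide`,
#'   `hla_allele` (the pair's best allele), `length`, the metric column,
#'   and optionally `mutation_positions` (list column).
#' @param anchors named list of [AnchorMatrix] keyed `"allele|length"`
#'   (see [readAnchorMatrices()]).
#' @param k maximum number of pairs (default 30).
#' @param metricColumn name of the score column to order by (ascending).
#' @return the ordered head of `pairs` with an `anchor_probabilities` list
#'   column added.
#' @export
topAnchorPairs <- function(pairs, anchors, k = 30,
                           metricColumn = "metric_value") {
  stopifnot(is.data.frame(pairs))
  need <- c("mt_peptide", "hla_allele", "length", metricColumn)
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    stop(sprintf("pair table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ord <- order(pairs[[metricColumn]], pairs$mt_peptide, na.last = TRUE)
  out <- pairs[head(ord, k), , drop = FALSE]
  keys <- sprintf("%s|%d", out$hla_allele, out$length)
  out$anchor_probabilities <- lapply(keys, function(key) {
    m <- anchors[[key]]
    if (is.null(m)) NA_real_ else anchorProbabilities(m)
  })
  rownames(out) <- NULL
  out
}

#' Group a custom prediction table with one representative row per group
#'
#' Generic ingestion for arbitrary neoantigen prediction TSVs: rows are
#' grouped by one user-chosen column (e.g. the variant) and ordered within
#' each group by another (e.g. a binding score, ascending by default); the
#' best-sorted row represents its group. Displayed features default to all
#' columns except the grouping and sorting columns.
#'
#' @param table data.frame (any columns).
#' @param groupBy,sortBy column names.
#' @param displayCols columns shown in the detailed view; default all
#'   except `groupBy` and `sortBy`.
#' @param decreasing sort direction within groups.
#' @return list with `representatives` (one row per group: `groupBy`,
#'   `sortBy`, then `displayCols`) and `groups` (named list of per-group
#'   data.frames restricted to `displayCols`, sorted).
#' @export
groupCustomTable <- function(table, groupBy, sortBy, displayCols = NULL,
                             decreasing = FALSE) {
  stopifnot(is.data.frame(table))
  for (col in c(groupBy, sortBy)) {
    if (!col %in% names(table)) {
      stop(sprintf("column %s not present in the table", col), call. = FALSE)
    }
  }
  if (is.null(displayCols)) {
    displayCols <- setdiff(names(table), c(groupBy, sortBy))
  }
  keys <- unique(table[[groupBy]])
  groups <- lapply(keys, function(key) {
    g <- table[table[[groupBy]] == key, , drop = FALSE]
    g <- g[order(g[[sortBy]], decreasing = decreasing), , drop = FALSE]
    rownames(g) <- NULL
    g
  })
  names(groups) <- as.character(keys)
  reps <- do.call(rbind, lapply(groups, function(g) g[1, , drop = FALSE]))
  reps <- reps[, c(groupBy, sortBy, displayCols), drop = FALSE]
  rownames(reps) <- NULL
  list(representatives = reps,
       groups = lapply(groups, function(g)
         g[, displayCols, drop = FALSE]))
}

#' Write the drill-down tables of a report as static files
#'
#' Emits, per variant, the transcript-set table and per-peptide summaries,
#' plus the top anchor pairs, as plain TSV files under a directory — the
#' static counterpart of the interactive drill-down.
#'
#' @param report a [NeoantigenReport] with metrics.
#' @param dir output directory (created if needed).
#' @param k number of anchor pairs to export per variant.
#' @param cfg an [AggregationConfig].
#' @return invisibly, the vector of files written.
#' @export
exportDrilldown <- function(report, dir, k = 30, cfg = AggregationConfig()) {
  stopifnot(is(report, "NeoantigenReport"))
  if (!length(report@metrics)) {
    stop("report has no metrics document to drill into", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anchors <- metricsAnchorMatrices(report@metrics)
  written <- character()
  for (vid in names(report@metrics$variants)) {
    v <- report@metrics$variants[[vid]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", vid)
    sets <- v$transcript_sets
    setTab <- data.frame(
      set_id = vapply(sets, function(s) s$set_id, ""),
      n_transcripts = vapply(sets, function(s) length(s$transcript_ids), 0L),
      total_expression = vapply(sets, function(s) s$total_expression, 0),
      best_tsl = vapply(sets, function(s)
        as.integer(s$best_tsl %||% NA_integer_), 0L),
      stringsAsFactors = FALSE)
    f <- file.path(dir, sprintf("%s.transcript_sets.tsv", safe))
    write.table(setTab, f, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    written <- c(written, f)

    peps <- do.call(rbind, lapply(sets, function(s) {
      do.call(rbind, lapply(s$peptides, function(p) {
        scores <- p$scores
        bind <- scores[scores$score_class == "binding", , drop = FALSE]
        data.frame(set_id = s$set_id, mt_peptide = p$mt_peptide,
                   wt_peptide = p$wt_peptide %||% NA_character_,
                   length = p$length,
                   median_ic50_mt = medianOrNA(bind$ic50_mt),
                   lowest_ic50_mt = minOrNA(bind$ic50_mt),
                   stringsAsFactors = FALSE)
      }))
    }))
    f <- file.path(dir, sprintf("%s.peptides.tsv", safe))
    write.table(peps, f, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    written <- c(written, f)
  }
  invisible(written)
}

# Rehydrate AnchorMatrix objects from a metrics document.
metricsAnchorMatrices <- function(metrics) {
  am <- metrics$anchor_matrices
  if (is.null(am)) return(list())
  out <- lapply(names(am), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    AnchorMatrix(parts[[1]], as.integer(parts[[2]]), as.numeric(am[[key]]))
  })
  names(out) <- names(am)
  out
}
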