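TIER_LEVELS <- c("Pass", "Anchor", "Subclonal", "LowExpr", "NoExpr", "Poor")

#' Tier labels in rank order
#'
#' Tiers from best to worst: `Pass` (all criteria met), `Anchor` (mutation
#' confined to anchor positions with a well-binding wild-type peptide),
#' `Subclonal`, `LowExpr`, `NoExpr`, `Poor` (binding or transcript-support
#' failure).
#'
#' @return character vector of the six tier labels, best first.
#' @export
tierLevels <- function() TIER_LEVELS

#' Allele expression from gene expression and RNA VAF
#'
#' Expression attributable to the mutant allele: gene expression (TPM)
#' multiplied by the RNA variant allele fraction. Missing RNA VAF
#' propagates to a missing result. Vectorized.
#'
#' @param geneExpr gene expression, TPM (non-negative).
#' @param rnaVaf RNA variant allele fraction in [0, 1], or `NA`.
#' @return numeric vector of TPM-scaled allele expression.
#' @examples
#' computeAlleleExpr(10, 0.5)
#' @export
computeAlleleExpr <- function(geneExpr, rnaVaf) {
  if (any(!is.na(rnaVaf) & (rnaVaf < 0 | rnaVaf > 1))) {
    stop("rnaVaf must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(geneExpr) & geneExpr < 0)) {
    stop("geneExpr must be non-negative (TPM)", call. = FALSE)
  }
  geneExpr * rnaVaf
}

#' Anchor positions from a normalized probability vector
#'
#' Selects positions greedily by descending anchor probability (ties broken
#' by the lower position index) until the cumulative probability mass
#' reaches the contribution threshold. The result is the smallest prefix of
#' the greedy order meeting the bound: dropping any selected position would
#' break it.
#'
#' @param m an [AnchorMatrix], or a bare numeric probability vector.
#' @param contributionThreshold cumulative mass required, in (0, 1];
#'   default 0.8.
#' @return sorted integer vector of 1-based anchor positions.
#' @examples
#' determineAnchorPositions(c(0.45, 0.05, 0.05, 0.45), 0.8)
#' @export
determineAnchorPositions <- function(m, contributionThreshold = 0.8) {
  probs <- if (is(m, "AnchorMatrix")) {
    validObject(m)
    m@probabilities
  } else {
    as.numeric(m)
  }
  if (!isScalarNumber(contributionThreshold) ||
      contributionThreshold <= 0 || contributionThreshold > 1) {
    stop("contributionThreshold must be in (0, 1]", call. = FALSE)
  }
  ord <- order(-probs, seq_along(probs))
  cum <- cumsum(probs[ord])
  k <- which(cum >= contributionThreshold - 1e-12)[[1]]
  sort(ord[seq_len(k)])
}

#' Evaluate the anchor scenario for a mutated peptide
#'
#' Joint consideration of where the mutation sits relative to the allele's
#' anchor positions and how well the wild-type peptide binds. If no mutated
#' position is an anchor, the mutated residue faces the T-cell receptor and
#' the candidate is acceptable regardless of wild-type binding. If every
#' mutated position is an anchor and the wild-type peptide binds well, the
#' presented surface is effectively wild-type and the candidate is rejected
#' (`"reject_anchor"`). If the wild-type binds poorly, the mutation itself
#' creates binding and the candidate is acceptable; with no wild-type
#' measurement the call is `"unknown"`. Mutations spanning anchor and
#' non-anchor positions are acceptable.
#'
#' @param mutationPositions integer vector of 1-based mutated positions
#'   within the peptide.
#' @param anchors integer vector of anchor positions (non-empty).
#' @param wtIc50 wild-type IC50 in nM, or `NA` when unmeasured.
#' @param cfg a [TierConfig]; `wtIc50Threshold` defines "binds well".
#' @return one of `"accept"`, `"reject_anchor"`, `"unknown"`.
#' @examples
#' evaluateAnchorScenario(4, anchors = c(2, 9), wtIc50 = 50)
#' evaluateAnchorScenario(2, anchors = c(2, 9), wtIc50 = 50)
#' @export
evaluateAnchorScenario <- function(mutationPositions, anchors, wtIc50 = NA,
                                   cfg = TierConfig()) {
  validObject(cfg)
  if (length(anchors) == 0L) {
    stop("anchor position set must be non-empty", call. = FALSE)
  }
  mutationPositions <- as.integer(mutationPositions)
  stopifnot(length(mutationPositions) > 0L)
  inAnchor <- mutationPositions %in% as.integer(anchors)
  if (!any(inAnchor)) return("accept")
  if (!all(inAnchor)) return("accept")
  if (is.na(wtIc50)) return("unknown")
  if (wtIc50 <= cfg@wtIc50Threshold) "reject_anchor" else "accept"
}

#' Classify a variant as founding-clone or subclonal
#'
#' The reference (founding-clone) VAF is `tumorPurity / 2` — the
#' heterozygous diploid expectation — when purity is available, otherwise
#' the maximum somatic DNA VAF observed in the sample. A variant is
#' subclonal when its DNA VAF falls strictly below `clonalityFraction`
#' times the reference VAF (boundary inclusive on the founding side). With
#' neither reference available the call is `"unknown"`. Vectorized over
#' `dnaVaf`.
#'
#' @param dnaVaf DNA variant allele fraction(s) in [0, 1].
#' @param tumorPurity tumor purity in (0, 1], or `NA`.
#' @param cohortMaxVaf maximum somatic DNA VAF in the sample, used when
#'   purity is missing.
#' @param clonalityFraction fraction of the reference VAF below which a
#'   variant is subclonal; default 0.5.
#' @return character vector: `"founding"`, `"subclonal"` or `"unknown"`.
#' @examples
#' classifyClonality(c(0.25, 0.10), tumorPurity = 1.0)
#' @export
classifyClonality <- function(dnaVaf, tumorPurity = NA, cohortMaxVaf = NA,
                              clonalityFraction = 0.5) {
  if (any(!is.na(dnaVaf) & (dnaVaf < 0 | dnaVaf > 1))) {
    stop("dnaVaf must lie in [0, 1]", call. = FALSE)
  }
  reference <- if (!is.na(tumorPurity)) tumorPurity / 2 else cohortMaxVaf
  out <- rep("unknown", length(dnaVaf))
  if (!is.na(reference)) {
    cut <- clonalityFraction * reference
    known <- !is.na(dnaVaf)
    out[known & dnaVaf >= cut] <- "founding"
    out[known & dnaVaf < cut] <- "subclonal"
  }
  out
}

# Map each failing criterion name to its tier category.
CRITERION_CATEGORY <- c(
  binding        = "Poor",
  tsl            = "Poor",
  no_expression  = "NoExpr",
  low_expression = "LowExpr",
  rna_vaf        = "LowExpr",
  rna_depth      = "LowExpr",
  subclonal      = "Subclonal",
  anchor         = "Anchor"
)

# Core tier decision from already-evaluated criteria. `bindingPass` refers
# to the best allele of the variant's best peptide.
tierFromCriteria <- function(bindingPass, alleleExpr, rnaVaf, rnaDepth, tsl,
                             scenario, clonality, cfg) {
  failing <- character()
  if (!isTRUE(bindingPass)) failing <- c(failing, "binding")
  if (!is.na(tsl) && tsl > cfg@tslMax) failing <- c(failing, "tsl")
  if (!is.na(alleleExpr)) {
    if (alleleExpr == 0) {
      failing <- c(failing, "no_expression")
    } else if (alleleExpr < cfg@alleleExprThreshold) {
      failing <- c(failing, "low_expression")
    }
  }
  if (!is.na(rnaVaf) && rnaVaf < cfg@rnaVafMin) failing <- c(failing, "rna_vaf")
  if (!is.na(rnaDepth) && rnaDepth < cfg@rnaDepthMin) {
    failing <- c(failing, "rna_depth")
  }
  if (identical(clonality, "subclonal")) failing <- c(failing, "subclonal")
  if (identical(scenario, "reject_anchor")) failing <- c(failing, "anchor")

  tier <- if (length(failing) == 0L) "Pass" else {
    cats <- unique(unname(CRITERION_CATEGORY[failing]))
    cfg@tierPrecedence[min(match(cats, cfg@tierPrecedence))]
  }
  list(tier = tier, failing_criteria = failing)
}

#' Assign a variant its tier
#'
#' Evaluates the tiering criteria — binding of the best peptide at its best
#' allele, allele expression, optional RNA VAF/depth floors, transcript
#' support level, clonality, and the anchor scenario — collects every
#' failing criterion, and maps the most severe failing category to the tier
#' label. Severity follows `tierPrecedence` in the configuration (default
#' `Poor > NoExpr > LowExpr > Subclonal > Anchor`, the reverse of the rank
#' order in [tierLevels()]), so fixing any failing criterion never worsens
#' the assigned tier.
#'
#' @param summary a [PeptideSummary] for the variant's best peptide.
#' @param measurements named list or one-row data.frame with `gene_expr`,
#'   `rna_vaf`, `rna_depth`, `dna_vaf`, `tsl`, and optionally
#'   `tumor_purity` (elements may be `NA`).
#' @param scenario anchor-scenario call from [evaluateAnchorScenario()].
#' @param clonality clonality call from [classifyClonality()].
#' @param cfg a [TierConfig].
#' @return list with `tier` (one of [tierLevels()]) and `failing_criteria`
#'   (character vector, empty iff `tier == "Pass"`).
#' @export
assignTier <- function(summary, measurements, scenario = "accept",
                       clonality = "founding", cfg = TierConfig()) {
  validObject(cfg)
  stopifnot(is(summary, "PeptideSummary"))
  m <- as.list(measurements)
  alleleExpr <- computeAlleleExpr(m$gene_expr %||% NA_real_,
                                  m$rna_vaf %||% NA_real_)
  bindingPass <- {
    pb <- passesBinding(summary)
    !is.na(summary@bestAllele) && isTRUE(pb[[summary@bestAllele]])
  }
  tierFromCriteria(bindingPass, alleleExpr,
                   m$rna_vaf %||% NA_real_, m$rna_depth %||% NA_real_,
                   m$tsl %||% NA_integer_, scenario, clonality, cfg)
}

#' Re-tier an aggregate report under new thresholds or purity
#'
#' Recomputes the `Tier` column of an aggregate report as a pure function
#' of the stored row fields and the supplied configuration: binding is
#' re-checked against the configured cutoffs, the anchor scenario is
#' re-derived from the stored anchor-overlap call and wild-type IC50, and
#' clonality is re-derived from DNA VAF with the new purity (falling back
#' to the maximum DNA VAF in the table when purity is absent). Evaluations
#' (`Eval`) and every other column are left untouched. Applying the same
#' configuration twice is idempotent.
#'
#' @param rows aggregate report data.frame (see [readAggregate()]).
#' @param cfg a [TierConfig].
#' @param tumorPurity tumor purity in (0, 1], or `NA` to use the cohort
#'   maximum DNA VAF as the clonality reference.
#' @return `rows` with recomputed `Tier` (and `Ranking` order unchanged;
#'   call [orderAggregate()] to re-sort).
#' @export
retier <- function(rows, cfg = TierConfig(), tumorPurity = NA) {
  validObject(cfg)
  stopifnot(is.data.frame(rows))
  need <- c("IC50 MT", "%ile MT", "IC50 WT", "RNA Expr", "RNA VAF",
            "RNA Depth", "DNA VAF", "TSL", "Anchor Residue")
  missing <- setdiff(need, names(rows))
  if (length(missing)) {
    stop(sprintf("aggregate rows lack column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(rows) == 0L) return(rows)
  cohortMax <- suppressWarnings(max(rows[["DNA VAF"]], na.rm = TRUE))
  if (!is.finite(cohortMax)) cohortMax <- NA_real_
  bcfg <- cfg@binding
  tiers <- vapply(seq_len(nrow(rows)), function(i) {
    ic50 <- rows[["IC50 MT"]][i]
    pct <- rows[["%ile MT"]][i]
    bindingPass <- !is.na(ic50) && ic50 <= bcfg@ic50Threshold
    if (bcfg@usePercentile) {
      bindingPass <- bindingPass ||
        (!is.na(pct) && pct <= bcfg@percentileThreshold)
    }
    overlap <- rows[["Anchor Residue"]][i]
    scenario <- if (is.na(overlap) || overlap %in% c("none", "partial")) {
      "accept"
    } else {
      wt <- rows[["IC50 WT"]][i]
      if (is.na(wt)) "unknown" else
        if (wt <= cfg@wtIc50Threshold) "reject_anchor" else "accept"
    }
    clon <- classifyClonality(rows[["DNA VAF"]][i], tumorPurity, cohortMax,
                              cfg@clonalityFraction)
    alleleExpr <- computeAlleleExpr(rows[["RNA Expr"]][i],
                                    rows[["RNA VAF"]][i])
    tierFromCriteria(bindingPass, alleleExpr, rows[["RNA VAF"]][i],
                     rows[["RNA Depth"]][i], rows[["TSL"]][i],
                     scenario, clon, cfg)$tier
  }, "")
  rows$Tier <- tiers
  rows
}

#' Order aggregate rows by tier, allele expression and binding
#'
#' The default report ordering: tier rank (best first, see [tierLevels()]),
#' then allele expression descending, then the mutant binding metric
#' ascending, then variant id for a deterministic total order.
#'
#' @param rows aggregate report data.frame.
#' @param tierOrder tier labels, best first.
#' @return `rows`, reordered.
#' @export
orderAggregate <- function(rows, tierOrder = tierLevels()) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) return(rows)
  ord <- order(match(rows$Tier, tierOrder),
               -ifelse(is.na(rows[["Allele Expr"]]), -Inf,
                       rows[["Allele Expr"]]),
               rows[["IC50 MT"]], rows$ID)
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write anchor-matrix collections (JSON)
#'
#' The JSON file maps `"allele|length"` keys to per-position probability
#' arrays; each array is validated to have the stated length, non-negative
#' entries and unit sum (tolerance 1e-6) on load.
#'
#' @param path JSON file path.
#' @param matrices named list of [AnchorMatrix] objects keyed
#'   `"allele|length"`.
#' @return `readAnchorMatrices()` returns such a named list.
#' @export
readAnchorMatrices <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw))) {
    stop("anchor matrix file must be a JSON object keyed by \"allele|length\"",
         call. = FALSE)
  }
  out <- lapply(names(raw), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.integer(parts[[2]])))) {
      stop(sprintf("malformed anchor matrix key: %s", key), call. = FALSE)
    }
    AnchorMatrix(parts[[1]], as.integer(parts[[2]]), as.numeric(raw[[key]]))
  })
  names(out) <- names(raw)
  out
}

#' @rdname readAnchorMatrices
#' @export
writeAnchorMatrices <- function(matrices, path) {
  stopifnot(all(vapply(matrices, is, TRUE, "AnchorMatrix")))
  obj <- lapply(matrices, anchorProbabilities)
  names(obj) <- vapply(matrices, function(m)
    sprintf("%s|%d", anchorAllele(m), peptideLength(m)), "")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
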