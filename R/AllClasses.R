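#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## ProteinContext
## ---------------------------------------------------------------------------

#' Protein-level context of a somatic variant on one transcript
#'
#' A `ProteinContext` holds the wild-type and mutant protein sequences for a
#' single transcript carrying a somatic variant, together with the 1-based
#' span of the altered residues within the mutant sequence, transcript-level
#' expression (TPM) and the Ensembl transcript support level (TSL, 1 = best).
#' Peptide enumeration ([enumerateRegisters()]) operates on these objects.
#'
#' Mutant sequences containing a stop codon (`*`) are truncated at the first
#' stop by the constructor; for frameshift variants the altered span is
#' clipped to the truncated length (the last residue before the stop).
#'
#' @slot transcriptId single transcript identifier.
#' @slot wtSequence wild-type protein sequence (canonical amino-acid letters).
#' @slot mtSequence mutant protein sequence.
#' @slot variantType one of `"missense"`, `"inframe_indel"`, `"frameshift"`.
#' @slot variantStart,variantEnd 1-based first/last altered residue within
#'   `mtSequence` (for frameshift: through the last residue before the stop).
#' @slot expression transcript-level expression, TPM (non-negative).
#' @slot tsl transcript support level, positive integer or `NA`.
#'
#' @examples
#' ctx <- ProteinContext("ENST0001",
#'                       wtSequence = "MTEYKLVVVGAGGVGKSALTIQ",
#'                       mtSequence = "MTEYKLVVVGAVGVGKSALTIQ",
#'                       variantType = "missense",
#'                       variantStart = 12, variantEnd = 12,
#'                       expression = 12.5, tsl = 1)
#' ctx
#' @export
setClass("ProteinContext",
  representation(
    transcriptId = "character",
    wtSequence   = "character",
    mtSequence   = "character",
    variantType  = "character",
    variantStart = "integer",
    variantEnd   = "integer",
    expression   = "numeric",
    tsl          = "integer"
  )
)

VARIANT_TYPES <- c("missense", "inframe_indel", "frameshift")

setValidity("ProteinContext", function(object) {
  msgs <- character()
  if (length(object@transcriptId) != 1L || is.na(object@transcriptId) ||
      !nzchar(object@transcriptId)) {
    msgs <- c(msgs, "transcriptId must be a single non-empty string")
  }
  if (!object@variantType %in% VARIANT_TYPES) {
    msgs <- c(msgs, sprintf("variantType must be one of: %s",
                            paste(VARIANT_TYPES, collapse = ", ")))
  }
  mt <- object@mtSequence
  wt <- object@wtSequence
  for (s in list(c(mt, "mtSequence"), c(wt, "wtSequence"))) {
    chars <- strsplit(s[[1]], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), AA_LETTERS)
    if (length(bad) > 0L) {
      msgs <- c(msgs, sprintf("%s contains non-canonical residue(s): %s",
                              s[[2]], paste(bad, collapse = ", ")))
    }
  }
  s <- object@variantStart
  e <- object@variantEnd
  if (!(s >= 1L && s <= e && e <= nchar(mt))) {
    msgs <- c(msgs, "need 1 <= variantStart <= variantEnd <= nchar(mtSequence)")
  }
  if (object@variantType == "missense") {
    if (s != e) msgs <- c(msgs, "missense variants must have variantStart == variantEnd")
    if (nchar(wt) != nchar(mt)) {
      msgs <- c(msgs, "missense variants require equal-length wt/mt sequences")
    } else if (s <= nchar(mt) &&
               substring(wt, s, s) == substring(mt, s, s)) {
      msgs <- c(msgs, "missense wt and mt sequences must differ at the variant position")
    }
  }
  if (length(object@expression) != 1L || is.na(object@expression) ||
      object@expression < 0) {
    msgs <- c(msgs, "expression must be a single non-negative number (TPM)")
  }
  if (length(object@tsl) != 1L || (!is.na(object@tsl) && object@tsl < 1L)) {
    msgs <- c(msgs, "tsl must be a positive integer or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param transcriptId,wtSequence,mtSequence,variantType,variantStart,variantEnd,expression,tsl
#'   see slot descriptions.
#' @rdname ProteinContext-class
#' @export
ProteinContext <- function(transcriptId, wtSequence, mtSequence,
                           variantType = c("missense", "inframe_indel",
                                           "frameshift"),
                           variantStart, variantEnd = variantStart,
                           expression = 0, tsl = NA_integer_) {
  variantType <- match.arg(variantType)
  # stop codons truncate enumeration: keep residues before the first '*'
  truncAt <- function(s) sub("\\*.*$", "", s)
  mtSequence <- truncAt(mtSequence)
  wtSequence <- truncAt(wtSequence)
  variantEnd <- min(as.integer(variantEnd), nchar(mtSequence))
  new("ProteinContext",
      transcriptId = as.character(transcriptId),
      wtSequence   = as.character(wtSequence),
      mtSequence   = as.character(mtSequence),
      variantType  = variantType,
      variantStart = as.integer(variantStart),
      variantEnd   = as.integer(variantEnd),
      expression   = as.numeric(expression),
      tsl          = as.integer(tsl))
}

setMethod("show", "ProteinContext", function(object) {
  cat(sprintf("ProteinContext: %s (%s)\n", object@transcriptId,
              object@variantType))
  cat(sprintf("  mt: %d aa, altered residues %d-%d\n",
              nchar(object@mtSequence), object@variantStart,
              object@variantEnd))
  cat(sprintf("  expression: %.3g TPM; TSL: %s\n", object@expression,
              ifelse(is.na(object@tsl), "NA", object@tsl)))
})

## ---------------------------------------------------------------------------
## AnchorMatrix
## ---------------------------------------------------------------------------

#' Allele- and length-specific anchor-position probabilities
#'
#' Normalized per-position probabilities that each peptide position
#' participates in anchoring the peptide to a given HLA allele, for one
#' (allele, peptide length) combination. The vector has one entry per
#' peptide position, entries are non-negative, and they sum to 1 (within
#' 1e-6).
#'
#' @slot allele HLA allele name, e.g. `"HLA-A*02:01"`.
#' @slot peptideLength peptide length the probabilities refer to.
#' @slot probabilities numeric vector, one entry per position.
#'
#' @examples
#' m <- AnchorMatrix("HLA-A*02:01", 9,
#'                   c(.05, .40, .02, .02, .02, .02, .02, .05, .40))
#' determineAnchorPositions(m, 0.8)
#' @export
setClass("AnchorMatrix",
  representation(
    allele        = "character",
    peptideLength = "integer",
    probabilities = "numeric"
  )
)

setValidity("AnchorMatrix", function(object) {
  msgs <- character()
  if (length(object@allele) != 1L || !nzchar(object@allele)) {
    msgs <- c(msgs, "allele must be a single non-empty string")
  }
  if (length(object@probabilities) != object@peptideLength) {
    msgs <- c(msgs, "probabilities must have one entry per peptide position")
  }
  if (any(is.na(object@probabilities)) || any(object@probabilities < 0)) {
    msgs <- c(msgs, "probabilities must be non-negative and non-missing")
  } else if (abs(sum(object@probabilities) - 1) > 1e-6) {
    msgs <- c(msgs, "probabilities must sum to 1 (tolerance 1e-6)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param allele,peptideLength,probabilities see slot descriptions.
#' @rdname AnchorMatrix-class
#' @export
AnchorMatrix <- function(allele, peptideLength, probabilities) {
  new("AnchorMatrix", allele = as.character(allele),
      peptideLength = as.integer(peptideLength),
      probabilities = as.numeric(probabilities))
}

setMethod("show", "AnchorMatrix", function(object) {
  cat(sprintf("AnchorMatrix: %s, %d-mer\n", object@allele,
              object@peptideLength))
  cat(" ", paste(sprintf("%.3f", object@probabilities), collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## AggregationConfig
## ---------------------------------------------------------------------------

#' Configuration for binding-score aggregation
#'
#' Controls how per-algorithm MHC binding predictions are summarized per
#' peptide and which peptides count as predicted binders. Defaults follow
#' the commonly recommended cutoffs: IC50 of 500 nM or less and percentile
#' rank of 2 or less.
#'
#' @slot metric summary statistic across algorithms: `"median"` or
#'   `"lowest"`.
#' @slot ic50Threshold IC50 binding cutoff in nM (default 500).
#' @slot percentileThreshold percentile-rank cutoff (default 2).
#' @slot usePercentile when `TRUE`, a peptide also passes if its summarized
#'   percentile rank is at or below `percentileThreshold` (OR rule);
#'   default `FALSE`, i.e. IC50-only.
#'
#' @examples
#' AggregationConfig()
#' AggregationConfig(metric = "lowest", ic50Threshold = 1000)
#' @export
setClass("AggregationConfig",
  representation(
    metric              = "character",
    ic50Threshold       = "numeric",
    percentileThreshold = "numeric",
    usePercentile       = "logical"
  ),
  prototype(
    metric              = "median",
    ic50Threshold       = 500,
    percentileThreshold = 2,
    usePercentile       = FALSE
  )
)

setValidity("AggregationConfig", function(object) {
  msgs <- character()
  if (!object@metric %in% c("median", "lowest")) {
    msgs <- c(msgs, "metric must be \"median\" or \"lowest\"")
  }
  if (!isScalarNumber(object@ic50Threshold) || object@ic50Threshold <= 0) {
    msgs <- c(msgs, "ic50Threshold must be a positive number (nM)")
  }
  if (!isScalarNumber(object@percentileThreshold) ||
      object@percentileThreshold <= 0) {
    msgs <- c(msgs, "percentileThreshold must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param metric,ic50Threshold,percentileThreshold,usePercentile see slot
#'   descriptions.
#' @rdname AggregationConfig-class
#' @export
AggregationConfig <- function(metric = c("median", "lowest"),
                              ic50Threshold = 500,
                              percentileThreshold = 2,
                              usePercentile = FALSE) {
  metric <- match.arg(metric)
  new("AggregationConfig", metric = metric,
      ic50Threshold = as.numeric(ic50Threshold),
      percentileThreshold = as.numeric(percentileThreshold),
      usePercentile = isTRUE(usePercentile))
}

setMethod("show", "AggregationConfig", function(object) {
  cat(sprintf(
    "AggregationConfig: metric=%s, IC50 <= %g nM%s\n", object@metric,
    object@ic50Threshold,
    if (object@usePercentile)
      sprintf(" OR percentile <= %g", object@percentileThreshold) else ""))
})

## ---------------------------------------------------------------------------
## TierConfig
## ---------------------------------------------------------------------------

#' Configuration for variant tiering
#'
#' Thresholds and rules used by [assignTier()] and [retier()]. Binding
#' criteria are shared with [AggregationConfig]; the remaining slots control
#' the expression, transcript-support, clonality and anchor-scenario
#' criteria.
#'
#' @slot binding an [AggregationConfig] (metric and binding cutoffs).
#' @slot alleleExprThreshold minimum allele expression
#'   (gene TPM x RNA VAF) for full support; default 2.5.
#' @slot rnaVafMin,rnaDepthMin optional minimum RNA VAF / RNA read depth;
#'   default 0 (criterion disabled).
#' @slot tslMax worst acceptable transcript support level (default 1, the
#'   best-supported category).
#' @slot clonalityFraction a variant is subclonal when its DNA VAF falls
#'   below this fraction of the reference (founding-clone) VAF; default 0.5.
#' @slot anchorContributionThreshold cumulative anchor-probability mass that
#'   defines the anchor-position set; default 0.8.
#' @slot wtIc50Threshold IC50 below which the wild-type peptide counts as a
#'   binder in the anchor scenario; default equals the MT binding cutoff.
#' @slot tierPrecedence order (most severe first) in which failing
#'   categories claim the tier label.
#'
#' @examples
#' TierConfig()
#' TierConfig(alleleExprThreshold = 1)
#' @export
setClass("TierConfig",
  representation(
    binding                     = "AggregationConfig",
    alleleExprThreshold         = "numeric",
    rnaVafMin                   = "numeric",
    rnaDepthMin                 = "numeric",
    tslMax                      = "integer",
    clonalityFraction           = "numeric",
    anchorContributionThreshold = "numeric",
    wtIc50Threshold             = "numeric",
    tierPrecedence              = "character"
  ),
  prototype(
    alleleExprThreshold         = 2.5,
    rnaVafMin                   = 0,
    rnaDepthMin                 = 0,
    tslMax                      = 1L,
    clonalityFraction           = 0.5,
    anchorContributionThreshold = 0.8,
    wtIc50Threshold             = 500,
    tierPrecedence = c("Poor", "NoExpr", "LowExpr", "Subclonal", "Anchor")
  )
)

setValidity("TierConfig", function(object) {
  msgs <- character()
  v <- validObject(object@binding, test = TRUE)
  if (!isTRUE(v)) msgs <- c(msgs, v)
  pos <- c(alleleExprThreshold = object@alleleExprThreshold,
           clonalityFraction = object@clonalityFraction,
           wtIc50Threshold = object@wtIc50Threshold)
  if (any(is.na(pos)) || any(pos <= 0)) {
    msgs <- c(msgs,
      "alleleExprThreshold, clonalityFraction and wtIc50Threshold must be positive")
  }
  if (object@anchorContributionThreshold <= 0 ||
      object@anchorContributionThreshold > 1) {
    msgs <- c(msgs, "anchorContributionThreshold must be in (0, 1]")
  }
  if (object@rnaVafMin < 0 || object@rnaVafMin > 1) {
    msgs <- c(msgs, "rnaVafMin must be in [0, 1]")
  }
  if (object@rnaDepthMin < 0) msgs <- c(msgs, "rnaDepthMin must be >= 0")
  if (is.na(object@tslMax) || object@tslMax < 1L) {
    msgs <- c(msgs, "tslMax must be a positive integer")
  }
  if (!setequal(object@tierPrecedence,
                c("Poor", "NoExpr", "LowExpr", "Subclonal", "Anchor")) ||
      anyDuplicated(object@tierPrecedence)) {
    msgs <- c(msgs, paste("tierPrecedence must be a permutation of",
                          "Poor, NoExpr, LowExpr, Subclonal, Anchor"))
  }
  if (length(msgs)) msgs else TRUE
})

#' @param binding,alleleExprThreshold,rnaVafMin,rnaDepthMin,tslMax,clonalityFraction,anchorContributionThreshold,wtIc50Threshold,tierPrecedence
#'   see slot descriptions. `wtIc50Threshold = NULL` inherits the MT IC50
#'   cutoff from `binding`.
#' @rdname TierConfig-class
#' @export
TierConfig <- function(binding = AggregationConfig(),
                       alleleExprThreshold = 2.5,
                       rnaVafMin = 0, rnaDepthMin = 0,
                       tslMax = 1,
                       clonalityFraction = 0.5,
                       anchorContributionThreshold = 0.8,
                       wtIc50Threshold = NULL,
                       tierPrecedence = c("Poor", "NoExpr", "LowExpr",
                                          "Subclonal", "Anchor")) {
  if (is.null(wtIc50Threshold)) wtIc50Threshold <- binding@ic50Threshold
  new("TierConfig", binding = binding,
      alleleExprThreshold = as.numeric(alleleExprThreshold),
      rnaVafMin = as.numeric(rnaVafMin),
      rnaDepthMin = as.numeric(rnaDepthMin),
      tslMax = as.integer(tslMax),
      clonalityFraction = as.numeric(clonalityFraction),
      anchorContributionThreshold = as.numeric(anchorContributionThreshold),
      wtIc50Threshold = as.numeric(wtIc50Threshold),
      tierPrecedence = as.character(tierPrecedence))
}

setMethod("show", "TierConfig", function(object) {
  cat("TierConfig\n")
  cat(sprintf("  binding: metric=%s, IC50 <= %g nM\n",
              object@binding@metric, object@binding@ic50Threshold))
  cat(sprintf("  allele expression >= %g; TSL <= %d\n",
              object@alleleExprThreshold, object@tslMax))
  cat(sprintf("  subclonal below %g x reference VAF; anchor mass %g\n",
              object@clonalityFraction, object@anchorContributionThreshold))
})

## ---------------------------------------------------------------------------
## PeptideSummary
## ---------------------------------------------------------------------------

#' Per-allele summary of one MT/WT peptide pair
#'
#' Produced by [summarizePeptide()]. The `perAllele` slot is a data.frame
#' with one row per HLA allele: `hla_allele`, `median_ic50_mt`,
#' `lowest_ic50_mt`, `median_percentile_mt`, `median_ic50_wt`,
#' `median_percentile_wt`, `n_algorithms`, `metric_value` (the configured
#' metric) and `passes_binding`. Wild-type medians are reported only for
#' alleles where the mutant peptide passed the binding threshold.
#'
#' @slot mtPeptide,wtPeptide mutant and wild-type peptide (WT may be `NA`
#'   for frameshift-derived peptides).
#' @slot perAllele per-allele summary data.frame (see Description).
#' @slot bestAllele allele minimizing the configured mutant-binding metric.
#' @slot metric metric used (`"median"` or `"lowest"`).
#'
#' @export
setClass("PeptideSummary",
  representation(
    mtPeptide  = "character",
    wtPeptide  = "character",
    perAllele  = "data.frame",
    bestAllele = "character",
    metric     = "character"
  )
)

setValidity("PeptideSummary", function(object) {
  msgs <- character()
  need <- c("hla_allele", "median_ic50_mt", "lowest_ic50_mt",
            "median_percentile_mt", "median_ic50_wt", "median_percentile_wt",
            "n_algorithms", "metric_value", "passes_binding")
  missing <- setdiff(need, names(object@perAllele))
  if (length(missing)) {
    msgs <- c(msgs, sprintf("perAllele lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  } else {
    pa <- object@perAllele
    bad <- !is.na(pa$lowest_ic50_mt) & !is.na(pa$median_ic50_mt) &
      pa$lowest_ic50_mt > pa$median_ic50_mt + 1e-9
    if (any(bad)) msgs <- c(msgs, "lowest_ic50_mt exceeds median_ic50_mt")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PeptideSummary", function(object) {
  cat(sprintf("PeptideSummary: %s / %s\n", object@mtPeptide,
              ifelse(is.na(object@wtPeptide), "(no WT)", object@wtPeptide)))
  cat(sprintf("  best allele: %s (%s IC50 %.4g nM)\n", object@bestAllele,
              object@metric,
              object@perAllele$metric_value[
                object@perAllele$hla_allele == object@bestAllele]))
  cat(sprintf("  %d allele(s), %d passing binding\n",
              nrow(object@perAllele), sum(object@perAllele$passes_binding)))
})

#' Accessors for PeptideSummary
#'
#' @param x a [PeptideSummary].
#' @return `bestAllele()` the best allele name; `perAlleleSummary()` the
#'   per-allele data.frame; `mtPeptide()`/`wtPeptide()` the peptide strings;
#'   `passesBinding()` a named logical vector per allele.
#' @name PeptideSummary-accessors
#' @aliases bestAllele perAlleleSummary mtPeptide wtPeptide passesBinding
NULL

#' @rdname PeptideSummary-accessors
#' @export
setGeneric("bestAllele", function(x) standardGeneric("bestAllele"))
#' @rdname PeptideSummary-accessors
#' @export
setGeneric("perAlleleSummary", function(x) standardGeneric("perAlleleSummary"))
#' @rdname PeptideSummary-accessors
#' @export
setGeneric("mtPeptide", function(x) standardGeneric("mtPeptide"))
#' @rdname PeptideSummary-accessors
#' @export
setGeneric("wtPeptide", function(x) standardGeneric("wtPeptide"))
#' @rdname PeptideSummary-accessors
#' @export
setGeneric("passesBinding", function(x) standardGeneric("passesBinding"))

setMethod("bestAllele", "PeptideSummary", function(x) x@bestAllele)
setMethod("perAlleleSummary", "PeptideSummary", function(x) x@perAllele)
setMethod("mtPeptide", "PeptideSummary", function(x) x@mtPeptide)
setMethod("wtPeptide", "PeptideSummary", function(x) x@wtPeptide)
setMethod("passesBinding", "PeptideSummary", function(x)
  setNames(x@perAllele$passes_binding, x@perAllele$hla_allele))

## ---------------------------------------------------------------------------
## ProteinContext accessors
## ---------------------------------------------------------------------------

#' Accessors for ProteinContext
#'
#' @param x a [ProteinContext].
#' @name ProteinContext-accessors
#' @aliases transcriptId wtSequence mtSequence variantType variantStart
#'   variantEnd txExpression txSupportLevel
NULL

#' @rdname ProteinContext-accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname ProteinContext-accessors
#' @export
setGeneric("wtSequence", function(x) standardGeneric("wtSequence"))
#' @rdname ProteinContext-accessors
#' @export
setGeneric("mtSequence", function(x) standardGeneric("mtSequence"))
#' @rdname ProteinContext-accessors
#' @export
setGeneric("variantType", function(x) standardGeneric("variantType"))
#' @rdname ProteinContext-accessors
#' @export
setGeneric("variantStart", function(x) standardGeneric("variantStart"))
#' @rdname ProteinContext-accessors
#' @export
setGeneric("variantEnd", function(x) standardGeneric("variantEnd"))
#' @rdname ProteinContext-accessors
#' @export
setGeneric("txExpression", function(x) standardGeneric("txExpression"))
#' @rdname ProteinContext-accessors
#' @export
setGeneric("txSupportLevel", function(x) standardGeneric("txSupportLevel"))

setMethod("transcriptId", "ProteinContext", function(x) x@transcriptId)
setMethod("wtSequence", "ProteinContext", function(x) x@wtSequence)
setMethod("mtSequence", "ProteinContext", function(x) x@mtSequence)
setMethod("variantType", "ProteinContext", function(x) x@variantType)
setMethod("variantStart", "ProteinContext", function(x) x@variantStart)
setMethod("variantEnd", "ProteinContext", function(x) x@variantEnd)
setMethod("txExpression", "ProteinContext", function(x) x@expression)
setMethod("txSupportLevel", "ProteinContext", function(x) x@tsl)

## ---------------------------------------------------------------------------
## AnchorMatrix accessors
## ---------------------------------------------------------------------------

#' Accessors for AnchorMatrix
#'
#' @param x an [AnchorMatrix].
#' @name AnchorMatrix-accessors
#' @aliases anchorAllele peptideLength anchorProbabilities
NULL

#' @rdname AnchorMatrix-accessors
#' @export
setGeneric("anchorAllele", function(x) standardGeneric("anchorAllele"))
#' @rdname AnchorMatrix-accessors
#' @export
setGeneric("peptideLength", function(x) standardGeneric("peptideLength"))
#' @rdname AnchorMatrix-accessors
#' @export
setGeneric("anchorProbabilities",
           function(x) standardGeneric("anchorProbabilities"))

setMethod("anchorAllele", "AnchorMatrix", function(x) x@allele)
setMethod("peptideLength", "AnchorMatrix", function(x) x@peptideLength)
setMethod("anchorProbabilities", "AnchorMatrix", function(x) x@probabilities)
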