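#' @importFrom stats median rbeta rgamma rlnorm rpois runif setNames
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generator entry points funnel through this so that a
# FixtureSpec seed fully determines the output.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# NA-tolerant scalar median/min over a numeric vector; returns NA_real_
# when no non-missing value is present (an algorithm may legitimately
# decline an allele/length combination).
medianOrNA <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else stats::median(x)
}

minOrNA <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else min(x)
}

# 20 canonical amino-acid one-letter codes
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

assertCanonicalAA <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_LETTERS)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-canonical residue(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# %.17g formatting round-trips doubles exactly through as.numeric(),
# which the TSV round-trip contract relies on.
formatNumber <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}
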