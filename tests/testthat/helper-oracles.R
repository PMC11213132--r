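# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# Every distinct l-mer window of `mt` overlapping the altered span [s, e],
# by exhaustive scan.
oracleEnumerate <- function(mt, s, e, lengths) {
  peps <- character()
  for (l in lengths) {
    if (l > nchar(mt)) next
    for (i in seq_len(nchar(mt) - l + 1L)) {
      if (i <= e && i + l - 1L >= s) {
        peps <- c(peps, substring(mt, i, i + l - 1L))
      }
    }
  }
  unique(peps)
}

# Median by sort + middle element (mean of the two central values when the
# count is even); minimum by scan.
oracleMedian <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) x[(n + 1L) %/% 2L] else (x[n %/% 2L] + x[n %/% 2L + 1L]) / 2
}

oracleMin <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- x[[1]]
  for (v in x) if (v < m) m <- v
  m
}

# A missense ProteinContext with the variant at position flankLeft + 1.
missenseCtx <- function(flankLeft = 13, flankRight = flankLeft,
                        id = "TX1", expression = 10, tsl = 1,
                        seed = 1) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  wt <- paste(sample(aa, flankLeft + flankRight + 1L, replace = TRUE),
              collapse = "")
  pos <- flankLeft + 1L
  mt <- wt
  substring(mt, pos, pos) <- sample(setdiff(aa, substring(wt, pos, pos)), 1)
  ProteinContext(id, wt, mt, "missense", pos, expression = expression,
                 tsl = tsl)
}

# Binding records for one peptide: one row per allele x algorithm.
bindingRecords <- function(mt = "SIINFEKLM", wt = "SIINFEKLV",
                           alleles = "HLA-A*02:01",
                           algorithms = paste0("alg", 1:3),
                           ic50, ic50_wt = NA_real_,
                           percentile = NA_real_,
                           score_class = "binding") {
  grid <- expand.grid(algorithm = algorithms, hla_allele = alleles,
                      stringsAsFactors = FALSE)
  data.frame(mt_peptide = mt, wt_peptide = wt,
             hla_allele = grid$hla_allele, algorithm = grid$algorithm,
             ic50_mt = ic50, ic50_wt = ic50_wt,
             percentile_mt = percentile, percentile_wt = NA_real_,
             score_class = score_class, stringsAsFactors = FALSE)
}

# Synthetic aggregate rows covering the full schema, plus one extra
# pass-through column; used by the round-trip tests.
randomAggregateRows <- function(n, seed = 1) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  pep <- vapply(seq_len(n), function(i)
    paste(sample(aa, 9, replace = TRUE), collapse = ""), "")
  data.frame(
    "ID" = sprintf("chr%d-%d-%s-%s", sample(1:22, n, TRUE),
                   sample(1e6, n), sample(c("A", "C"), n, TRUE),
                   sample(c("G", "T"), n, TRUE)),
    "Gene" = sprintf("GENE%04d", seq_len(n)),
    "AA Change" = sprintf("A%dV", sample(500, n, TRUE)),
    "Pos" = as.character(sample(9, n, TRUE)),
    "Best Peptide" = pep,
    "WT Peptide" = ifelse(runif(n) < 0.1, NA, pep),
    "Best Transcript Set" = sprintf("TX%04d.1", seq_len(n)),
    "Allele" = sample(c("HLA-A*02:01", "HLA-B*07:02"), n, TRUE),
    "IC50 MT" = rlnorm(n, log(300), 1),
    "IC50 WT" = ifelse(runif(n) < 0.2, NA, rlnorm(n, log(4000), 1)),
    "%ile MT" = runif(n, 0, 100),
    "%ile WT" = ifelse(runif(n) < 0.2, NA, runif(n, 0, 100)),
    "Num Passing Peptides" = sample(0:40, n, TRUE),
    "RNA Expr" = rgamma(n, 2, 0.1),
    "RNA VAF" = runif(n),
    "Allele Expr" = rgamma(n, 2, 0.2),
    "RNA Depth" = rpois(n, 80),
    "DNA VAF" = runif(n, 0, 0.5),
    "TSL" = sample(1:5, n, TRUE),
    "Anchor Residue" = sample(c("none", "partial", "all", NA), n, TRUE),
    "Tier" = sample(tierLevels(), n, TRUE),
    "Eval" = sample(c("Pending", "Accept", "Reject", "Review"), n, TRUE),
    "Custom Note" = sprintf("note %d", seq_len(n)),
    check.names = FALSE, stringsAsFactors = FALSE)
}
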