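#' Default class I and class II peptide lengths
#'
#' Class I MHC molecules present short peptides of 8-11 residues; class II
#' presents longer peptides, here 12-18 by default (configurable wherever a
#' `lengths` argument is accepted).
#'
#' @return integer vector of peptide lengths.
#' @examples
#' classILengths()
#' @export
classILengths <- function() 8:11

#' @rdname classILengths
#' @export
classIILengths <- function() 12:18

#' Enumerate all mutant/wild-type peptide registers for one transcript
#'
#' Slides windows of each requested length along the mutant protein sequence
#' and keeps every window that lies fully within the sequence and contains
#' at least one altered residue. Each window position is one *register*:
#' the mutation occupies a different position within the fixed-length
#' peptide. For frame-preserving variants (missense, in-frame indel) the
#' wild-type partner is the same-coordinate window of the wild-type
#' sequence, reported when it differs from the mutant window; frameshift
#' windows have no wild-type partner. Windows yielding an identical mutant
#' peptide at the same length are merged, pooling their mutated positions.
#'
#' For a single interior missense variant with at least `max(lengths) - 1`
#' residues of flank on each side, every length `l` contributes exactly `l`
#' registers, so lengths 8-11 yield 8 + 9 + 10 + 11 = 38 distinct mutant
#' peptides.
#'
#' @param ctx a [ProteinContext].
#' @param lengths integer vector of peptide lengths (default class I, 8-11).
#' @return data.frame with one row per distinct mutant peptide:
#'   `mt_peptide`, `wt_peptide` (`NA` when absent), `length`,
#'   `mutation_positions` (list column of 1-based positions within the
#'   peptide), `transcript_ids` (list column).
#' @seealso [groupTranscriptSets()], [countPredictionSpace()]
#' @examples
#' ctx <- ProteinContext("tx1",
#'   wtSequence = paste(rep("A", 10), collapse = ""),
#'   mtSequence = "AAAAAKAAAA", variantType = "missense",
#'   variantStart = 6, expression = 1)
#' enumerateRegisters(ctx, lengths = 8)
#' @export
enumerateRegisters <- function(ctx, lengths = classILengths()) {
  stopifnot(is(ctx, "ProteinContext"))
  validObject(ctx)
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L || any(is.na(lengths)) || any(lengths < 1L)) {
    stop("`lengths` must be a non-empty set of positive integers",
         call. = FALSE)
  }
  lengths <- sort(unique(lengths))

  mt <- ctx@mtSequence
  wt <- ctx@wtSequence
  Lm <- nchar(mt)
  Lw <- nchar(wt)
  s <- ctx@variantStart
  e <- ctx@variantEnd
  inFrame <- ctx@variantType %in% c("missense", "inframe_indel")

  rows <- list()
  for (l in lengths) {
    if (l > Lm) next   # window longer than the protein: contributes nothing
    from <- max(1L, s - l + 1L)
    to <- min(e, Lm - l + 1L)
    if (from > to) next
    for (i in seq.int(from, to)) {
      mtPep <- substring(mt, i, i + l - 1L)
      wtPep <- NA_character_
      if (inFrame && i + l - 1L <= Lw) {
        cand <- substring(wt, i, i + l - 1L)
        if (cand != mtPep) wtPep <- cand
      }
      mut <- seq.int(max(s, i), min(e, i + l - 1L)) - i + 1L
      rows[[length(rows) + 1L]] <-
        list(mt_peptide = mtPep, wt_peptide = wtPep, length = l,
             mutation_positions = mut)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mt_peptide = character(), wt_peptide = character(),
                      length = integer(),
                      mutation_positions = I(list()),
                      transcript_ids = I(list()),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    mt_peptide = vapply(rows, `[[`, "", "mt_peptide"),
    wt_peptide = vapply(rows, `[[`, "", "wt_peptide"),
    length = vapply(rows, `[[`, 0L, "length"),
    stringsAsFactors = FALSE)
  out$mutation_positions <- lapply(rows, `[[`, "mutation_positions")

  # merge duplicate mutant peptides (repeat-rich sequences), pooling the
  # mutated positions; keep the first non-missing WT partner
  key <- paste(out$mt_peptide, out$length)
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    merged <- split(seq_len(nrow(out)), match(key, key[keep]))
    out2 <- out[keep, , drop = FALSE]
    out2$mutation_positions <- lapply(merged, function(idx)
      sort(unique(unlist(out$mutation_positions[idx]))))
    wtAll <- lapply(merged, function(idx) {
      w <- out$wt_peptide[idx]
      w <- w[!is.na(w)]
      if (length(w)) w[[1]] else NA_character_
    })
    out2$wt_peptide <- unlist(wtAll)
    out <- out2
  }
  out$transcript_ids <- rep(list(ctx@transcriptId), nrow(out))
  rownames(out) <- NULL
  out
}

#' Group a variant's transcripts into sets with identical peptide lists
#'
#' Transcripts of one variant whose enumerated mutant peptides form the
#' identical multiset are collapsed into a single transcript set; transcripts
#' yielding different peptides (e.g. because the variant lies near different
#' exon boundaries) form distinct sets. The sets partition the input
#' transcripts. Sets are ordered by decreasing total expression, then set id.
#'
#' @param contexts list of [ProteinContext] objects, all for one variant.
#' @param lengths peptide lengths passed to [enumerateRegisters()].
#' @return data.frame with one row per transcript set: `set_id` (sorted
#'   member transcript ids joined by `+`), `transcript_ids` (list column),
#'   `n_transcripts`, `total_expression` (TPM sum over members), `best_tsl`
#'   (minimum member TSL, `NA` if all missing), and `peptides` (list column
#'   of the set's enumeration data.frame, with `transcript_ids` expanded to
#'   all members).
#' @examples
#' mk <- function(id, mt) ProteinContext(id,
#'   wtSequence = "AAAAAAAAAAAA", mtSequence = mt,
#'   variantType = "missense", variantStart = 6, expression = 2, tsl = 1)
#' sets <- groupTranscriptSets(list(mk("t1", "AAAAAKAAAAAA"),
#'                                  mk("t2", "AAAAAKAAAAAA")), lengths = 9)
#' sets$set_id
#' @export
groupTranscriptSets <- function(contexts, lengths = classILengths()) {
  if (length(contexts) == 0L) {
    return(data.frame(set_id = character(), transcript_ids = I(list()),
                      n_transcripts = integer(), total_expression = numeric(),
                      best_tsl = integer(), peptides = I(list()),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(vapply(contexts, is, TRUE, "ProteinContext")))
  enums <- lapply(contexts, enumerateRegisters, lengths = lengths)
  # multiset signature of the mutant peptides
  sig <- vapply(enums, function(df)
    paste(sort(df$mt_peptide), collapse = "|"), "")
  groups <- split(seq_along(contexts), sig)

  rows <- lapply(groups, function(idx) {
    ids <- sort(vapply(contexts[idx], transcriptId, ""))
    tsls <- vapply(contexts[idx], txSupportLevel, 1L)
    peps <- enums[[idx[[1]]]]
    peps$transcript_ids <- rep(list(ids), nrow(peps))
    list(set_id = paste(ids, collapse = "+"),
         transcript_ids = ids,
         n_transcripts = length(idx),
         total_expression = sum(vapply(contexts[idx], txExpression, 0)),
         best_tsl = if (all(is.na(tsls))) NA_integer_
                    else min(tsls, na.rm = TRUE),
         peptides = peps)
  })
  out <- data.frame(
    set_id = vapply(rows, `[[`, "", "set_id"),
    n_transcripts = vapply(rows, `[[`, 0L, "n_transcripts"),
    total_expression = vapply(rows, `[[`, 0, "total_expression"),
    best_tsl = vapply(rows, `[[`, 0L, "best_tsl"),
    stringsAsFactors = FALSE)
  out$transcript_ids <- lapply(rows, `[[`, "transcript_ids")
  out$peptides <- lapply(rows, `[[`, "peptides")
  ord <- order(-out$total_expression, out$set_id)
  out <- out[ord, c("set_id", "transcript_ids", "n_transcripts",
                    "total_expression", "best_tsl", "peptides")]
  rownames(out) <- NULL
  out
}

#' Size of the peptide-MHC prediction space
#'
#' Number of (peptide, HLA allele, algorithm) tuples a prediction run
#' produces: the product of the three counts. A single missense variant
#' enumerated at lengths 8-11 gives 38 peptides; with 6 class I alleles and
#' 13 algorithms that is 2,964 predictions.
#'
#' @param nPeptides,nAlleles,nAlgorithms non-negative integers.
#' @return integer product.
#' @examples
#' countPredictionSpace(38, 6, 13)
#' @export
countPredictionSpace <- function(nPeptides, nAlleles, nAlgorithms) {
  args <- c(nPeptides = nPeptides, nAlleles = nAlleles,
            nAlgorithms = nAlgorithms)
  if (any(is.na(args)) || any(args < 0) || any(args != as.integer(args))) {
    stop("all arguments must be non-negative integers", call. = FALSE)
  }
  as.integer(nPeptides) * as.integer(nAlleles) * as.integer(nAlgorithms)
}

#' Read and write protein-context tables
#'
#' The on-disk form is a tab-delimited table with columns `transcript_id`,
#' `wt_sequence`, `mt_sequence`, `variant_type`, `mt_variant_start`,
#' `mt_variant_end`, `expression`, `tsl`, and optionally `variant_id`
#' grouping transcripts of one variant. Missing values are written as `NA`.
#'
#' @param path file path.
#' @return `readContexts()` returns a named list: one element per variant
#'   (named by `variant_id`, or `"variant"` when absent), each a list of
#'   [ProteinContext] objects.
#' @export
readContexts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "wt_sequence", "mt_sequence", "variant_type",
            "mt_variant_start", "mt_variant_end", "expression", "tsl")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("context table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vid <- if ("variant_id" %in% names(df)) df$variant_id else
    rep("variant", nrow(df))
  ctxs <- lapply(seq_len(nrow(df)), function(i) {
    ProteinContext(df$transcript_id[i], df$wt_sequence[i], df$mt_sequence[i],
                   df$variant_type[i], df$mt_variant_start[i],
                   df$mt_variant_end[i], df$expression[i],
                   tsl = df$tsl[i])
  })
  split(ctxs, factor(vid, levels = unique(vid)))
}

#' @param contexts named list of lists of [ProteinContext] (as returned by
#'   [readContexts()]), or a flat list for a single variant.
#' @rdname readContexts
#' @export
writeContexts <- function(contexts, path) {
  if (length(contexts) && is(contexts[[1]], "ProteinContext")) {
    contexts <- list(variant = contexts)
  }
  rows <- lapply(names(contexts), function(v) {
    do.call(rbind, lapply(contexts[[v]], function(ctx) {
      data.frame(variant_id = v, transcript_id = ctx@transcriptId,
                 wt_sequence = ctx@wtSequence, mt_sequence = ctx@mtSequence,
                 variant_type = ctx@variantType,
                 mt_variant_start = ctx@variantStart,
                 mt_variant_end = ctx@variantEnd,
                 expression = ctx@expression, tsl = ctx@tsl,
                 stringsAsFactors = FALSE)
    }))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
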