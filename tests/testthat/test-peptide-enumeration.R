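test_that("an interior missense with ample flank yields every register", {
  ctx <- missenseCtx(flankLeft = 13)
  pairs <- enumerateRegisters(ctx, lengths = 8:11)
  expect_equal(nrow(pairs), 38L)
  expect_equal(length(unique(pairs$mt_peptide)), 38L)
  # per length, l registers
  expect_equal(as.vector(table(pairs$length)), c(8L, 9L, 10L, 11L))
  # agreement with exhaustive window scan
  expect_setequal(pairs$mt_peptide,
                  oracleEnumerate(mtSequence(ctx), 14, 14, 8:11))
})

test_that("boundary variants restrict the register count", {
  aa20 <- paste(rep(c("G", "L"), 10), collapse = "")
  # variant at the first residue: only one in-bounds 8-mer contains it
  mt1 <- paste0("K", substring(aa20, 2))
  ctx1 <- ProteinContext("t1", aa20, mt1, "missense", 1)
  expect_equal(nrow(enumerateRegisters(ctx1, 8)), 1L)
  # variant at position 3 with a long right flank: window starts 1..3
  mt3 <- aa20
  substring(mt3, 3, 3) <- "K"
  ctx3 <- ProteinContext("t3", aa20, mt3, "missense", 3)
  pairs3 <- enumerateRegisters(ctx3, 8)
  expect_equal(nrow(pairs3), 3L)
  expect_setequal(pairs3$mt_peptide, oracleEnumerate(mt3, 3, 3, 8))
})

test_that("frameshift windows cover the novel tail and carry no WT partner", {
  wt <- paste(rep(c("A", "D", "E", "F"), 5), collapse = "")  # 20 aa
  mt <- paste0(substring(wt, 1, 15), "KWKWK")                # 5-residue tail
  ctx <- ProteinContext("fs1", wt, mt, "frameshift", 16, 20)
  pairs <- enumerateRegisters(ctx, 8)
  expect_equal(nrow(pairs), 5L)
  expect_true(all(is.na(pairs$wt_peptide)))
  expect_setequal(pairs$mt_peptide, oracleEnumerate(mt, 16, 20, 8))
})

test_that("windows and mutation positions honour the sequence coordinates", {
  set.seed(42)
  for (rep in 1:25) {
    flank <- sample(11:16, 1)   # at least max(lengths) - 1 on each side
    lengths <- sort(sample(6:12, sample(1:4, 1)))
    ctx <- missenseCtx(flankLeft = flank, seed = rep)
    pairs <- enumerateRegisters(ctx, lengths)
    # full flank: one register per length position
    expect_equal(nrow(pairs), sum(lengths))
    mt <- mtSequence(ctx)
    wt <- wtSequence(ctx)
    for (i in seq_len(nrow(pairs))) {
      p <- pairs$mt_peptide[i]
      at <- regexpr(p, mt, fixed = TRUE)
      expect_gte(at, 1)
      # WT partner is the same-coordinate substring of the WT sequence
      expect_equal(pairs$wt_peptide[i],
                   substring(wt, at, at + nchar(p) - 1))
      # MT and WT differ exactly at the mutated positions
      mtChars <- strsplit(p, "")[[1]]
      wtChars <- strsplit(pairs$wt_peptide[i], "")[[1]]
      expect_equal(which(mtChars != wtChars),
                   pairs$mutation_positions[[i]])
    }
  }
})

test_that("degenerate inputs behave as specified", {
  ctx <- missenseCtx(flankLeft = 10)
  expect_error(enumerateRegisters(ctx, integer()), "lengths")
  # window longer than the protein contributes zero pairs, not an error
  pairs <- enumerateRegisters(ctx, c(8, 100))
  expect_equal(unique(pairs$length), 8L)
})

test_that("duplicate mutant peptides from repeats are merged", {
  # the mutation restores a KA period, so shifted windows coincide:
  # wt has W at position 9, mt is fully periodic KAKA...
  mt <- strrep("KA", 10)
  wt <- mt
  substring(wt, 9, 9) <- "W"
  ctx <- ProteinContext("rep", wt, mt, "missense", 9)
  pairs <- enumerateRegisters(ctx, 8)
  # eight windows collapse onto the two distinct period phases
  expect_equal(nrow(pairs), 2L)
  expect_equal(anyDuplicated(pairs$mt_peptide), 0L)
  # merged windows pool their mutated positions
  expect_setequal(vapply(pairs$mutation_positions, length, 0L), 4L)
  expect_setequal(unlist(pairs$mutation_positions), 1:8)
})

test_that("stop codons truncate enumeration", {
  wt <- paste(rep("L", 30), collapse = "")
  mtFull <- paste0(substring(wt, 1, 14), "KWKWK*RRRRRR")
  ctx <- ProteinContext("fs2", wt, mtFull, "frameshift", 15, 25)
  expect_equal(nchar(mtSequence(ctx)), 19L)  # truncated before the stop
  pairs <- enumerateRegisters(ctx, 8)
  expect_true(all(!grepl("*", pairs$mt_peptide, fixed = TRUE)))
  expect_true(all(nchar(pairs$mt_peptide) == 8L))
})

test_that("transcripts with identical peptide lists share a set", {
  mk <- function(id, seed, expr, tsl = 1) {
    ctx <- missenseCtx(flankLeft = 12, id = id, expression = expr,
                       tsl = tsl, seed = seed)
    ctx
  }
  a <- mk("t1", seed = 5, expr = 3)
  b <- ProteinContext("t2", wtSequence(a), mtSequence(a), "missense",
                      variantStart(a), expression = 4, tsl = 2)
  sets <- groupTranscriptSets(list(a, b), 8:9)
  expect_equal(nrow(sets), 1L)
  expect_equal(sets$n_transcripts, 2L)
  expect_equal(sets$total_expression, 7)
  expect_equal(sets$best_tsl, 1L)
  expect_equal(sets$set_id, "t1+t2")
})

test_that("different flanks split transcripts into distinct sets", {
  a <- missenseCtx(flankLeft = 12, id = "t1", expression = 3, seed = 6)
  wt2 <- wtSequence(a)
  mt2 <- mtSequence(a)
  # alter a flank residue close enough to the variant (position 13) to
  # fall inside shared windows, with a letter guaranteed to differ
  repl <- setdiff(c("W", "M"), substring(wt2, 8, 8))[1]
  substring(wt2, 8, 8) <- repl; substring(mt2, 8, 8) <- repl
  b <- ProteinContext("t2", wt2, mt2, "missense", variantStart(a),
                      expression = 2)
  c3 <- ProteinContext("t3", wtSequence(a), mtSequence(a), "missense",
                       variantStart(a), expression = 5)
  sets <- groupTranscriptSets(list(a, b, c3), 8:11)
  expect_equal(nrow(sets), 2L)
  expect_setequal(sets$n_transcripts, c(2L, 1L))
  big <- sets[sets$n_transcripts == 2L, ]
  expect_equal(big$total_expression, 8)
  expect_setequal(big$transcript_ids[[1]], c("t1", "t3"))
})

test_that("transcript sets partition randomized multi-transcript variants", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    base <- missenseCtx(flankLeft = 11, id = "b", seed = 100 + rep)
    ctxs <- lapply(seq_len(n), function(j) {
      wt <- wtSequence(base); mt <- mtSequence(base)
      if (runif(1) < 0.5) {
        k <- sample(1:5, 1)
        substring(wt, k, k) <- "M"; substring(mt, k, k) <- "M"
      }
      ProteinContext(sprintf("tx%d", j), wt, mt, "missense",
                     variantStart(base), expression = runif(1, 0, 10))
    })
    sets <- groupTranscriptSets(ctxs, 8:9)
    members <- unlist(sets$transcript_ids)
    expect_setequal(members, sprintf("tx%d", seq_len(n)))
    expect_equal(anyDuplicated(members), 0L)
    # within each set, members enumerate the same peptide multiset
    for (s in seq_len(nrow(sets))) {
      ids <- sets$transcript_ids[[s]]
      sigs <- vapply(ctxs[match(ids, vapply(ctxs, transcriptId, ""))],
                     function(cc) paste(
                       sort(enumerateRegisters(cc, 8:9)$mt_peptide),
                       collapse = "|"), "")
      expect_equal(length(unique(sigs)), 1L)
    }
  }
})

test_that("empty context list yields an empty set table", {
  sets <- groupTranscriptSets(list(), 8:11)
  expect_equal(nrow(sets), 0L)
})

test_that("the prediction space is the product of the three counts", {
  expect_identical(countPredictionSpace(38, 6, 13), 2964L)
  expect_identical(countPredictionSpace(0, 6, 13), 0L)
  expect_identical(countPredictionSpace(10, 2, 4), 80L)
  expect_error(countPredictionSpace(-1, 2, 3), "non-negative")
})
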