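test_that("aggregate TSV write/read is the identity, extras included", {
  rows <- randomAggregateRows(100, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAggregate(rows, f)
  back <- readAggregate(f)
  expect_identical(names(back), names(rows))
  expect_equal(back, rows, tolerance = 0)
  # the pass-through column is byte-identical
  expect_identical(back[["Custom Note"]], rows[["Custom Note"]])
})

test_that("schema violations name the missing columns", {
  rows <- randomAggregateRows(5, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  broken <- rows[, setdiff(names(rows), "Tier")]
  write.table(broken, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAggregate(f), "Tier")
  expect_error(writeAggregate(broken, f), "Tier")
})

test_that("evaluations round-trip through the TSV form", {
  rows <- randomAggregateRows(20, seed = 5)
  rows$Eval <- "Pending"
  rows <- setEvaluation(rows, rows$ID[3], "Accept")
  rows <- setEvaluation(rows, rows$ID[7], "Reject")
  rows <- setEvaluation(rows, rows$ID[9], "Review")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAggregate(rows, f)
  back <- readAggregate(f)
  expect_identical(back$Eval, rows$Eval)
  ev <- evaluationSummary(back)
  expect_equal(unname(ev), c(1L, 1L, 1L, 17L))
})

test_that("the spreadsheet export is well-formed XML with all rows", {
  rows <- randomAggregateRows(10, seed = 8)
  f <- withr::local_tempfile(fileext = ".xml")
  writeAggregate(rows, f, format = "spreadsheet")
  doc <- xml2::read_xml(f)
  found <- xml2::xml_find_all(doc, "//*[local-name() = 'Row']")
  expect_length(found, nrow(rows) + 1L)  # header + data
})

test_that("metrics documents round-trip and reconcile", {
  spec <- fixtureSpec(seed = 17, nVariants = 4)
  rp <- makeReportPair(spec)
  expect_length(reconcileReport(rp$aggregate, rp$metrics), 0)

  f <- withr::local_tempfile(fileext = ".json")
  writeMetrics(rp$metrics, f)
  back <- readMetrics(f)
  expect_setequal(names(back$variants), names(rp$metrics$variants))
  # per-algorithm score grids are preserved
  for (vid in names(rp$metrics$variants)) {
    a <- rp$metrics$variants[[vid]]$transcript_sets[[1]]$peptides[[1]]$scores
    b <- back$variants[[vid]]$transcript_sets[[1]]$peptides[[1]]$scores
    expect_equal(b$ic50_mt, a$ic50_mt, tolerance = 1e-12)
    expect_identical(b$algorithm, a$algorithm)
    expect_identical(b$score_class, a$score_class)
  }

  # a variant present on one side only produces one warning
  m2 <- rp$metrics
  m2$variants[[1]] <- NULL
  warns <- reconcileReport(rp$aggregate, m2)
  expect_length(warns, 1)
  expect_match(warns, "not in metrics")
  expect_error(readMetrics({
    g <- withr::local_tempfile(fileext = ".json")
    writeLines("{not json", g)
    g
  }))
})

test_that("loadReport pairs the files and objects print sensibly", {
  spec <- fixtureSpec(seed = 19, nVariants = 3)
  dir <- withr::local_tempdir()
  rp <- makeReportPair(spec, dir = dir)
  rep <- loadReport(rp$aggregatePath, rp$metricsPath)
  expect_s4_class(rep, "NeoantigenReport")
  expect_equal(nrow(aggregateReport(rep)), 3)
  expect_output(show(rep), "NeoantigenReport: 3 variant")
  rep2 <- setEvaluation(rep, aggregateReport(rep)$ID[1], "Accept")
  expect_equal(unname(evaluationSummary(rep2)["accept"]), 1L)
})

test_that("supplementary class columns join by variant id", {
  rows <- randomAggregateRows(5, seed = 21)
  supp <- randomAggregateRows(5, seed = 22)

  supp$ID <- rows$ID                      # full overlap
  full <- mergeSupplementaryClass(rows, supp)
  expect_equal(nrow(full), 5)
  expect_equal(full[["Supp. IC50 MT"]], supp[["IC50 MT"]])

  supp$ID <- paste0("other-", seq_len(5)) # disjoint
  none <- mergeSupplementaryClass(rows, supp)
  expect_true(all(is.na(none[["Supp. IC50 MT"]])))

  supp$ID <- c(rows$ID[1:3], "x-1", "x-2") # partial overlap
  part <- mergeSupplementaryClass(rows, supp)
  expect_equal(nrow(part), 5)
  expect_equal(sum(!is.na(part[["Supp. IC50 MT"]])), 3)
})

test_that("genes of interest are flagged by exact symbol match", {
  rows <- randomAggregateRows(6, seed = 23)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(rows$Gene[2], rows$Gene[2], tolower(rows$Gene[4])), f)
  suppressMessages({
    flagged <- flagGenesOfInterest(rows, f)
    empty <- flagGenesOfInterest(rows, character())
    dedup <- flagGenesOfInterest(rows, c(rows$Gene[2], rows$Gene[2]))
  })
  expect_equal(which(flagged[["Gene of Interest"]]), 2L)  # case-sensitive
  expect_false(any(empty[["Gene of Interest"]]))
  expect_equal(flagged[["Gene of Interest"]], dedup[["Gene of Interest"]])
  expect_equal(nrow(flagged), nrow(rows))
})

test_that("evaluation bookkeeping counts always sum to the row count", {
  rows <- randomAggregateRows(5, seed = 24)
  rows$Eval <- "Pending"
  rows <- setEvaluation(rows, rows$ID[1], "Accept")
  rows <- setEvaluation(rows, rows$ID[2], "Accept")
  rows <- setEvaluation(rows, rows$ID[3], "Reject")
  ev <- evaluationSummary(rows)
  expect_equal(unname(ev), c(2L, 1L, 0L, 2L))
  expect_equal(sum(ev), nrow(rows))
  expect_error(setEvaluation(rows, "chr99-1-A-T", "Accept"), "not found")
})

test_that("top anchor pairs honour k and the metric ordering", {
  set.seed(25)
  n <- 45
  pairs <- data.frame(
    mt_peptide = vapply(seq_len(n), function(i)
      paste(sample(LETTERS[1:10], 9, TRUE), collapse = ""), ""),
    wt_peptide = "WWWWWWWWW",
    hla_allele = sample(c("HLA-A*02:01", "HLA-B*07:02"), n, TRUE),
    length = 9L,
    metric_value = rlnorm(n, log(300), 1),
    stringsAsFactors = FALSE)
  anchors <- makeAnchorMatrices(c("HLA-A*02:01", "HLA-B*07:02"), 9, seed = 1)
  top <- topAnchorPairs(pairs, anchors, k = 30)
  expect_equal(nrow(top), 30L)
  # ordering equals an independent sort
  oracle <- pairs[order(pairs$metric_value, pairs$mt_peptide), ][1:30, ]
  expect_equal(top$mt_peptide, oracle$mt_peptide)
  expect_true(all(vapply(top$anchor_probabilities, length, 0L) == 9L))

  few <- topAnchorPairs(pairs[1:5, ], anchors, k = 30)
  expect_equal(nrow(few), 5L)
})

test_that("custom tables group, sort and pick representatives", {
  set.seed(26)
  tab <- data.frame(
    variant = rep(c("v1", "v2", "v3"), times = c(4, 3, 3)),
    peptide = sprintf("PEP%02d", 1:10),
    score = runif(10, 0, 1000),
    expr = runif(10, 0, 50))
  g <- groupCustomTable(tab, groupBy = "variant", sortBy = "score")
  expect_length(g$groups, 3)
  # representative is the within-group minimum of the sort column
  for (key in names(g$groups)) {
    expect_equal(g$representatives$score[g$representatives$variant == key],
                 min(tab$score[tab$variant == key]))
  }
  # default display columns exclude the grouping and sorting columns
  expect_setequal(names(g$groups[[1]]), c("peptide", "expr"))
  expect_error(groupCustomTable(tab, "missing_col", "score"), "missing_col")
})

test_that("drill-down export writes per-variant tables", {
  spec <- fixtureSpec(seed = 27, nVariants = 2)
  dir <- withr::local_tempdir()
  rp <- makeReportPair(spec, dir = dir)
  rep <- loadReport(rp$aggregatePath, rp$metricsPath)
  out <- withr::local_tempdir()
  files <- exportDrilldown(rep, out)
  expect_length(files, 4)  # 2 variants x (transcript sets + peptides)
  peps <- read.delim(grep("peptides", files, value = TRUE)[1])
  expect_true(all(c("set_id", "mt_peptide", "median_ic50_mt") %in%
                    names(peps)))
})
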