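test_that("allele expression is gene expression scaled by RNA VAF", {
  expect_equal(computeAlleleExpr(10, 0.5), 5)
  expect_equal(computeAlleleExpr(7, 0), 0)
  expect_equal(computeAlleleExpr(0, 0.9), 0)
  expect_true(is.na(computeAlleleExpr(10, NA)))
  expect_error(computeAlleleExpr(10, 1.2), "\\[0, 1\\]")
})

test_that("anchor positions are the greedy minimal mass cover", {
  expect_equal(determineAnchorPositions(c(0.45, 0.05, 0.05, 0.45), 0.8),
               c(1L, 4L))
  expect_equal(determineAnchorPositions(rep(1 / 9, 9), 1.0), 1:9)
  expect_equal(determineAnchorPositions(c(0.05, 0.85, 0.05, 0.05), 0.8), 2L)
  expect_error(determineAnchorPositions(rep(0.25, 4), 1.5), "\\(0, 1\\]")
})

test_that("anchor sets meet the bound and are greedily minimal", {
  set.seed(13)
  for (rep in 1:200) {
    l <- sample(8:11, 1)
    g <- rgamma(l, shape = runif(l, 0.2, 5))
    p <- g / sum(g)
    thr <- runif(1, 0.3, 1)
    sel <- determineAnchorPositions(p, thr)
    expect_gte(sum(p[sel]), thr - 1e-9)
    # removing the smallest selected probability breaks the bound
    if (length(sel) > 1) {
      drop <- sel[which.min(p[sel])]
      expect_lt(sum(p[setdiff(sel, drop)]), thr)
    }
  }
})

test_that("anchor scenarios combine mutation location and WT binding", {
  cfg <- TierConfig()
  expect_equal(evaluateAnchorScenario(4, anchors = c(2, 9), wtIc50 = 50, cfg),
               "accept")
  expect_equal(evaluateAnchorScenario(2, anchors = c(2, 9), wtIc50 = 50, cfg),
               "reject_anchor")
  expect_equal(evaluateAnchorScenario(2, anchors = c(2, 9), wtIc50 = 5000,
                                      cfg), "accept")
  expect_equal(evaluateAnchorScenario(2, anchors = c(2, 9), wtIc50 = NA, cfg),
               "unknown")
  # mutation spanning anchor and non-anchor positions is acceptable
  expect_equal(evaluateAnchorScenario(c(2, 3), anchors = c(2, 9),
                                      wtIc50 = 50, cfg), "accept")
  expect_error(evaluateAnchorScenario(2, anchors = integer(), wtIc50 = 50),
               "non-empty")
})

test_that("clonality compares DNA VAF with the reference VAF", {
  expect_equal(classifyClonality(0.25, tumorPurity = 1.0), "founding")
  expect_equal(classifyClonality(0.10, tumorPurity = 1.0), "subclonal")
  expect_equal(classifyClonality(0.2, cohortMaxVaf = 0.4), "founding")
  expect_equal(classifyClonality(0.19, cohortMaxVaf = 0.4), "subclonal")
  expect_equal(classifyClonality(0.2), "unknown")
  expect_error(classifyClonality(1.4, tumorPurity = 1), "\\[0, 1\\]")
})

passingSummary <- function(ic50 = 50) {
  summarizePeptide(bindingRecords(ic50 = rep(ic50, 3)))
}

meas <- function(gene_expr = 10, rna_vaf = 0.5, rna_depth = 80,
                 dna_vaf = 0.35, tsl = 1) {
  list(gene_expr = gene_expr, rna_vaf = rna_vaf, rna_depth = rna_depth,
       dna_vaf = dna_vaf, tsl = tsl)
}

test_that("tier assignment maps failing categories to labels", {
  cfg <- TierConfig()
  ok <- assignTier(passingSummary(), meas(), "accept", "founding", cfg)
  expect_equal(ok$tier, "Pass")
  expect_length(ok$failing_criteria, 0)

  noExpr <- assignTier(passingSummary(), meas(rna_vaf = 0), "accept",
                       "founding", cfg)
  expect_equal(noExpr$tier, "NoExpr")

  low <- assignTier(passingSummary(), meas(gene_expr = 2, rna_vaf = 0.5),
                    "accept", "founding", cfg)
  expect_equal(low$tier, "LowExpr")

  anchor <- assignTier(passingSummary(), meas(), "reject_anchor",
                       "founding", cfg)
  expect_equal(anchor$tier, "Anchor")
  expect_equal(anchor$failing_criteria, "anchor")

  sub <- assignTier(passingSummary(), meas(), "accept", "subclonal", cfg)
  expect_equal(sub$tier, "Subclonal")

  poor <- assignTier(passingSummary(900), meas(), "accept", "founding", cfg)
  expect_equal(poor$tier, "Poor")

  tsl <- assignTier(passingSummary(), meas(tsl = 3), "accept", "founding",
                    cfg)
  expect_equal(tsl$tier, "Poor")
  expect_equal(tsl$failing_criteria, "tsl")

  # every failed criterion is listed, not only the tier-defining one
  multi <- assignTier(passingSummary(900), meas(gene_expr = 2), "accept",
                      "subclonal", cfg)
  expect_setequal(multi$failing_criteria,
                  c("binding", "low_expression", "subclonal"))
  expect_equal(multi$tier, "Poor")
})

randomCase <- function() {
  list(ic50 = exp(runif(1, log(10), log(5000))),
       gene_expr = runif(1, 0, 20), rna_vaf = runif(1),
       rna_depth = sample(0:120, 1), tsl = sample(1:5, 1),
       scenario = sample(c("accept", "reject_anchor", "unknown"), 1),
       clonality = sample(c("founding", "subclonal", "unknown"), 1))
}

caseTier <- function(cs, cfg = TierConfig()) {
  assignTier(passingSummary(cs$ic50),
             meas(cs$gene_expr, cs$rna_vaf, cs$rna_depth, tsl = cs$tsl),
             cs$scenario, cs$clonality, cfg)$tier
}

test_that("improving any single criterion never worsens the tier", {
  set.seed(21)
  rank <- function(t) match(t, tierLevels())
  for (rep in 1:200) {
    cs <- randomCase()
    before <- caseTier(cs)
    better <- cs
    move <- sample(c("ic50", "expr", "clonality", "scenario", "tsl"), 1)
    if (move == "ic50") better$ic50 <- cs$ic50 * runif(1, 0.01, 0.5)
    if (move == "expr") {
      better$gene_expr <- cs$gene_expr + runif(1, 1, 30)
      better$rna_vaf <- max(cs$rna_vaf, runif(1, 0.5, 1))
    }
    if (move == "clonality") better$clonality <- "founding"
    if (move == "scenario") better$scenario <- "accept"
    if (move == "tsl") better$tsl <- 1
    after <- caseTier(better)
    expect_lte(rank(after), rank(before))
  }
})

test_that("re-tiering responds to thresholds and purity and is idempotent", {
  spec <- fixtureSpec(seed = 31, nVariants = 15, binderFraction = 1,
                      fractionSubclonal = 0, exprRate = 0.05)
  rp <- makeReportPair(spec)
  rows <- rp$aggregate
  cfg <- TierConfig()

  expect_equal(retier(rows, cfg, tumorPurity = spec@purity)$Tier, rows$Tier)
  expect_equal(retier(retier(rows, cfg), cfg)$Tier, retier(rows, cfg)$Tier)

  # raising the allele-expression floor demotes passing rows
  passIdx <- rows$Tier == "Pass"
  high <- TierConfig(alleleExprThreshold = max(rows[["Allele Expr"]]) + 1)
  demoted <- retier(rows, high, tumorPurity = spec@purity)
  expect_true(all(demoted$Tier[passIdx] == "LowExpr"))

  # a draconian IC50 cutoff demotes exactly the rows it should
  tight <- TierConfig(binding = AggregationConfig(ic50Threshold = 10))
  strict <- retier(rows, tight, tumorPurity = spec@purity)
  shouldFail <- rows[["IC50 MT"]] > 10
  expect_equal(strict$Tier == "Poor", shouldFail)

  # evaluations are never touched
  rows2 <- setEvaluation(rows, rows$ID[1], "Accept")
  expect_equal(retier(rows2, tight)$Eval, rows2$Eval)
})

test_that("report ordering is deterministic and tier-major", {
  rows <- randomAggregateRows(50, seed = 3)
  ord1 <- orderAggregate(rows)
  ord2 <- orderAggregate(rows[sample(nrow(rows)), ])
  expect_equal(ord1, ord2)
  ranks <- match(ord1$Tier, tierLevels())
  expect_true(all(diff(ranks) >= 0))
})

test_that("anchor matrices survive a JSON round trip with validation", {
  ms <- makeAnchorMatrices(c("HLA-A*02:01", "HLA-B*07:02"), 8:9, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  writeAnchorMatrices(ms, f)
  back <- readAnchorMatrices(f)
  expect_setequal(names(back), names(ms))
  for (key in names(ms)) {
    expect_equal(anchorProbabilities(back[[key]]),
                 anchorProbabilities(ms[[key]]), tolerance = 1e-12)
  }
  # a broken vector is rejected on load
  bad <- jsonlite::fromJSON(f, simplifyVector = TRUE)
  bad[[1]] <- bad[[1]] * 2
  g <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, g, digits = NA)
  expect_error(readAnchorMatrices(g), "sum to 1")
})
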