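#' Default algorithm panels
#'
#' Named algorithm panels mirroring common practice: 8 class I and 4
#' class II IC50 binding predictors, 3 elution-based and 2
#' immunogenicity-based predictors. With the 8 class I binding and 5
#' orthogonal predictors, a class I run carries 13 algorithms per
#' peptide-allele pair.
#'
#' @return character vector of algorithm names.
#' @export
classIBindingAlgorithms <- function() {
  c("MHCflurry", "MHCnuggetsI", "NetMHC", "NetMHCcons", "NetMHCpan",
    "PickPocket", "SMM", "SMMPMBEC")
}

#' @rdname classIBindingAlgorithms
#' @export
classIIBindingAlgorithms <- function() {
  c("MHCnuggetsII", "NetMHCIIpan", "NNalign", "SMMalign")
}

#' @rdname classIBindingAlgorithms
#' @export
elutionAlgorithms <- function() c("BigMHC_EL", "MHCflurryEL", "NetMHCpanEL")

#' @rdname classIBindingAlgorithms
#' @export
immunogenicityAlgorithms <- function() c("BigMHC_IM", "DeepImmuno")

DEFAULT_ALLELES <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02",
                     "HLA-B*08:01", "HLA-C*07:01", "HLA-C*07:02")

#' Specification of a synthetic neoantigen dataset
#'
#' Parameters of the deterministic synthetic-data generator: number of
#' variants and transcripts, the HLA allele and algorithm panels, the
#' two-component log-normal IC50 mixture (binders centered well below the
#' 500 nM cutoff and floored away from it on the non-binder side, so
#' planted binder status is unambiguous), gamma-distributed gene
#' expression, tumor purity and the planted subclonal fraction. The same
#' seed always reproduces the same dataset.
#'
#' @slot seed RNG seed.
#' @slot nVariants number of somatic variants.
#' @slot transcriptsPerVariant possible transcript counts per variant
#'   (sampled uniformly).
#' @slot lengths peptide lengths to enumerate.
#' @slot alleles HLA allele panel.
#' @slot algorithms IC50 binding algorithm panel (at most 8, the class I
#'   cap; use [classIIBindingAlgorithms()] for a class II panel of 4).
#' @slot orthogonal elution/immunogenicity panels included per record
#'   (logical).
#' @slot binderFraction fraction of variants planted as binders.
#' @slot binderMeanlog,binderSdlog log-normal parameters of binder IC50s
#'   (nM; draws are capped at 490 nM).
#' @slot nonbinderMeanlog,nonbinderSdlog log-normal parameters of
#'   non-binder IC50s (nM; draws are offset by +600 nM).
#' @slot exprShape,exprRate gamma parameters of gene expression (TPM).
#' @slot purity tumor purity in (0, 1].
#' @slot fractionSubclonal fraction of variants planted subclonal.
#' @slot fractionFrameshift fraction of variants planted as frameshifts
#'   (the rest are missense).
#' @slot flank residues of flank on each side of a missense variant.
#'
#' @examples
#' fixtureSpec(seed = 1, nVariants = 5)
#' @export
setClass("FixtureSpec",
  representation(
    seed                 = "integer",
    nVariants            = "integer",
    transcriptsPerVariant = "integer",
    lengths              = "integer",
    alleles              = "character",
    algorithms           = "character",
    orthogonal           = "logical",
    binderFraction       = "numeric",
    binderMeanlog        = "numeric",
    binderSdlog          = "numeric",
    nonbinderMeanlog     = "numeric",
    nonbinderSdlog       = "numeric",
    exprShape            = "numeric",
    exprRate             = "numeric",
    purity               = "numeric",
    fractionSubclonal    = "numeric",
    fractionFrameshift   = "numeric",
    flank                = "integer"
  )
)

setValidity("FixtureSpec", function(object) {
  msgs <- character()
  fracs <- c(binderFraction = object@binderFraction,
             fractionSubclonal = object@fractionSubclonal,
             fractionFrameshift = object@fractionFrameshift)
  if (any(is.na(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  }
  if (is.na(object@purity) || object@purity <= 0 || object@purity > 1) {
    msgs <- c(msgs, "purity must lie in (0, 1]")
  }
  if (length(object@alleles) < 1L) msgs <- c(msgs, "need at least one allele")
  if (length(object@algorithms) < 1L || length(object@algorithms) > 8L) {
    msgs <- c(msgs, "need 1-8 binding algorithms (class caps)")
  }
  if (object@nVariants < 1L) msgs <- c(msgs, "need at least one variant")
  if (object@flank < max(object@lengths)) {
    msgs <- c(msgs, "flank must be at least the largest peptide length")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param seed,nVariants,transcriptsPerVariant,lengths,alleles,algorithms,orthogonal,binderFraction,binderMeanlog,binderSdlog,nonbinderMeanlog,nonbinderSdlog,exprShape,exprRate,purity,fractionSubclonal,fractionFrameshift,flank
#'   see slot descriptions.
#' @rdname FixtureSpec-class
#' @export
fixtureSpec <- function(seed = 42, nVariants = 25,
                        transcriptsPerVariant = 1:3,
                        lengths = classILengths(),
                        alleles = DEFAULT_ALLELES,
                        algorithms = classIBindingAlgorithms(),
                        orthogonal = TRUE,
                        binderFraction = 0.2,
                        binderMeanlog = log(50), binderSdlog = 0.6,
                        nonbinderMeanlog = log(5000), nonbinderSdlog = 0.8,
                        exprShape = 2, exprRate = 0.1,
                        purity = 0.8, fractionSubclonal = 0.2,
                        fractionFrameshift = 0.1, flank = 13) {
  new("FixtureSpec", seed = as.integer(seed),
      nVariants = as.integer(nVariants),
      transcriptsPerVariant = as.integer(transcriptsPerVariant),
      lengths = as.integer(lengths), alleles = as.character(alleles),
      algorithms = as.character(algorithms), orthogonal = isTRUE(orthogonal),
      binderFraction = as.numeric(binderFraction),
      binderMeanlog = as.numeric(binderMeanlog),
      binderSdlog = as.numeric(binderSdlog),
      nonbinderMeanlog = as.numeric(nonbinderMeanlog),
      nonbinderSdlog = as.numeric(nonbinderSdlog),
      exprShape = as.numeric(exprShape), exprRate = as.numeric(exprRate),
      purity = as.numeric(purity),
      fractionSubclonal = as.numeric(fractionSubclonal),
      fractionFrameshift = as.numeric(fractionFrameshift),
      flank = as.integer(flank))
}

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: seed=%d, %d variant(s), %d allele(s), %d algorithm(s)\n",
    object@seed, object@nVariants, length(object@alleles),
    length(object@algorithms)))
  cat(sprintf("  binder fraction %.2f, subclonal fraction %.2f, purity %.2f\n",
              object@binderFraction, object@fractionSubclonal, object@purity))
})

#' The canonical demo fixture specification
#'
#' Seed 42, 25 variants, 6 class I alleles, 8 binding algorithms — the
#' small synthetic dataset that anchors the documentation and examples.
#'
#' @return a [FixtureSpec].
#' @export
demoFixture <- function() fixtureSpec(seed = 42, nVariants = 25)

randomPeptide <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

#' Generate protein contexts with planted variants
#'
#' Draws random protein sequences and plants a missense substitution (or,
#' for a configurable fraction of variants, a frameshift with a novel
#' C-terminal tail) with the configured flank on each side. Each variant
#' gets 1-3 transcripts; additional transcripts either duplicate the first
#' (and will collapse into its transcript set) or carry an altered flank
#' (and will form a distinct set). Variant-level truths — planted binder
#' status, clonality, VAFs, expression — are returned alongside.
#'
#' @param spec a [FixtureSpec].
#' @return list with `contexts` (named list: variant id to list of
#'   [ProteinContext]) and `variants` (data.frame of per-variant truth:
#'   `ID`, `gene`, `aa_change`, `variant_type`, `binder`, `subclonal`,
#'   `dna_vaf`, `rna_vaf`, `rna_depth`, `gene_expr`, `purity`, `tsl`).
#' @export
makeContexts <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    flank <- spec@flank
    nTxChoices <- spec@transcriptsPerVariant
    variants <- list()
    contexts <- list()
    for (i in seq_len(spec@nVariants)) {
      type <- if (runif(1) < spec@fractionFrameshift) "frameshift" else
        "missense"
      wt <- randomPeptide(2L * flank + 1L)
      pos <- flank + 1L
      wtRes <- substring(wt, pos, pos)
      if (type == "missense") {
        mtRes <- sample(setdiff(AA_LETTERS, wtRes), 1L)
        mt <- wt
        substring(mt, pos, pos) <- mtRes
        vStart <- pos; vEnd <- pos
        aaChange <- sprintf("%s%d%s", wtRes, pos, mtRes)
      } else {
        tail <- randomPeptide(sample(5:12, 1L))
        mt <- paste0(substring(wt, 1L, pos - 1L), tail)
        vStart <- pos; vEnd <- nchar(mt)
        aaChange <- sprintf("%s%dfs", wtRes, pos)
      }
      chrom <- sprintf("chr%d", sample(1:22, 1L))
      gpos <- sample(1e4:1e8, 1L)
      ref <- sample(c("A", "C", "G", "T"), 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      vid <- sprintf("%s-%d-%s-%s", chrom, gpos, ref, alt)
      gene <- sprintf("GENE%03d", i)

      subclonal <- runif(1) < spec@fractionSubclonal
      ref_vaf <- spec@purity / 2
      dnaVaf <- if (subclonal) runif(1, 0.05, 0.4) * ref_vaf else
        runif(1, 0.6, 1.0) * ref_vaf
      rnaVaf <- min(1, max(0, dnaVaf * runif(1, 0.8, 1.2)))
      geneExpr <- rgamma(1, shape = spec@exprShape, rate = spec@exprRate)
      rnaDepth <- rpois(1, 80)
      binder <- runif(1) < spec@binderFraction

      nTx <- if (length(nTxChoices) == 1L) nTxChoices else
        sample(nTxChoices, 1L)
      wts <- runif(nTx)
      txExpr <- geneExpr * wts / sum(wts)
      txs <- vector("list", nTx)
      for (j in seq_len(nTx)) {
        wtJ <- wt; mtJ <- mt
        if (j > 1L && runif(1) < 0.5) {
          # altered flank: same variant, different splice context
          k <- sample(seq_len(flank - 1L), 3L)
          repl <- vapply(k, function(p) sample(
            setdiff(AA_LETTERS, substring(wtJ, p, p)), 1L), "")
          for (m in seq_along(k)) {
            substring(wtJ, k[m], k[m]) <- repl[m]
            substring(mtJ, k[m], k[m]) <- repl[m]
          }
        }
        # the representative transcript is well supported; alternates vary
        tsl <- if (j == 1L) 1L else
          sample(1:5, 1L, prob = c(0.6, 0.2, 0.1, 0.05, 0.05))
        txs[[j]] <- ProteinContext(
          sprintf("TX%03d.%d", i, j), wtJ, mtJ, type, vStart, vEnd,
          expression = txExpr[j], tsl = tsl)
      }
      contexts[[vid]] <- txs
      variants[[length(variants) + 1L]] <- data.frame(
        ID = vid, gene = gene, aa_change = aaChange, variant_type = type,
        binder = binder, subclonal = subclonal, dna_vaf = dnaVaf,
        rna_vaf = rnaVaf, rna_depth = rnaDepth, gene_expr = geneExpr,
        purity = spec@purity,
        tsl = min(vapply(txs, txSupportLevel, 1L)),
        stringsAsFactors = FALSE)
    }
    list(contexts = contexts, variants = do.call(rbind, variants))
  })
}

# Distinct peptides of one variant, pooled across its transcripts.
mergedEnumeration <- function(txs, lengths) {
  dfs <- lapply(txs, enumerateRegisters, lengths = lengths)
  all <- do.call(rbind, dfs)
  key <- paste(all$mt_peptide, all$length)
  keep <- !duplicated(key)
  out <- all[keep, , drop = FALSE]
  grp <- split(seq_len(nrow(all)), match(key, key[keep]))
  out$mutation_positions <- lapply(grp, function(idx)
    sort(unique(unlist(all$mutation_positions[idx]))))
  out$transcript_ids <- lapply(grp, function(idx)
    sort(unique(unlist(all$transcript_ids[idx]))))
  wt <- lapply(grp, function(idx) {
    w <- all$wt_peptide[idx]
    w <- w[!is.na(w)]
    if (length(w)) w[[1]] else NA_character_
  })
  out$wt_peptide <- unlist(wt)
  rownames(out) <- NULL
  out
}

#' Generate an epitope prediction table for planted contexts
#'
#' Emits one record per (peptide, HLA allele, algorithm). Binder variants
#' carry one planted binding allele on which at least one peptide draws
#' from the binder IC50 component (log-normal centered well below 500 nM,
#' capped at 490); all other combinations draw from the non-binder
#' component (600 nM + log-normal), so no non-binder record ever crosses
#' the 500 nM default cutoff. Percentile ranks are computed as rank
#' transforms of IC50 within each allele, hence monotone in IC50. When the
#' spec includes orthogonal panels, elution and immunogenicity records
#' (scores in [0, 1], correlated with planted binder status) are appended,
#' bringing the class I panel to 13 algorithms per peptide-allele pair.
#'
#' @param contexts the list returned by [makeContexts()].
#' @param spec the same [FixtureSpec].
#' @return epitope prediction data.frame (see [readEpitopes()]) with a
#'   `variant_id` column.
#' @export
makePredictions <- function(contexts, spec) {
  validObject(spec)
  stopifnot(is.list(contexts), !is.null(contexts$contexts))
  withSeed(spec@seed + 1L, {
    vtab <- contexts$variants
    chunks <- vector("list", nrow(vtab))
    for (i in seq_len(nrow(vtab))) {
      vid <- vtab$ID[i]
      pep <- mergedEnumeration(contexts$contexts[[vid]], spec@lengths)
      nPep <- nrow(pep)
      alleles <- spec@alleles
      algs <- spec@algorithms
      bindingAllele <- sample(alleles, 1L)
      pepBinder <- rep(FALSE, nPep)
      if (vtab$binder[i]) {
        pepBinder <- runif(nPep) < 0.5
        pepBinder[1L] <- TRUE
      }
      wtBinder <- runif(nPep) < 0.2

      grid <- expand.grid(algorithm = algs, hla_allele = alleles,
                          pidx = seq_len(nPep), stringsAsFactors = FALSE)
      n <- nrow(grid)
      isBind <- pepBinder[grid$pidx] & grid$hla_allele == bindingAllele
      ic50 <- numeric(n)
      ic50[isBind] <- pmin(
        rlnorm(sum(isBind), spec@binderMeanlog, spec@binderSdlog), 490)
      ic50[!isBind] <- 600 +
        rlnorm(sum(!isBind), spec@nonbinderMeanlog, spec@nonbinderSdlog)
      hasWt <- !is.na(pep$wt_peptide[grid$pidx])
      isWtBind <- wtBinder[grid$pidx] & hasWt
      ic50wt <- rep(NA_real_, n)
      ic50wt[isWtBind] <- rlnorm(sum(isWtBind), log(100), 0.6)
      ic50wt[hasWt & !isWtBind] <- 600 +
        rlnorm(sum(hasWt & !isWtBind), spec@nonbinderMeanlog,
               spec@nonbinderSdlog)
      bindDf <- data.frame(
        variant_id = vid,
        chromosome = sub("-.*$", "", vid),
        position = as.integer(strsplit(vid, "-", fixed = TRUE)[[1]][[2]]),
        gene = vtab$gene[i],
        transcript_id = vapply(pep$transcript_ids[grid$pidx],
                               function(x) x[[1]], ""),
        mt_peptide = pep$mt_peptide[grid$pidx],
        wt_peptide = pep$wt_peptide[grid$pidx],
        hla_allele = grid$hla_allele,
        algorithm = grid$algorithm,
        ic50_mt = ic50, ic50_wt = ic50wt,
        percentile_mt = NA_real_, percentile_wt = NA_real_,
        score_class = "binding", stringsAsFactors = FALSE)

      orthDf <- NULL
      if (spec@orthogonal) {
        oalgs <- c(elutionAlgorithms(), immunogenicityAlgorithms())
        oclass <- c(rep("elution", length(elutionAlgorithms())),
                    rep("immunogenicity", length(immunogenicityAlgorithms())))
        og <- expand.grid(aidx = seq_along(oalgs), hla_allele = alleles,
                          pidx = seq_len(nPep), stringsAsFactors = FALSE)
        om <- nrow(og)
        oBind <- pepBinder[og$pidx] & og$hla_allele == bindingAllele
        score <- numeric(om)
        score[oBind] <- rbeta(sum(oBind), 8, 2)
        score[!oBind] <- rbeta(sum(!oBind), 2, 8)
        oHasWt <- !is.na(pep$wt_peptide[og$pidx])
        scoreWt <- rep(NA_real_, om)
        scoreWt[oHasWt] <- rbeta(sum(oHasWt), 2, 8)
        orthDf <- data.frame(
          variant_id = vid, chromosome = bindDf$chromosome[[1]],
          position = bindDf$position[[1]], gene = vtab$gene[i],
          transcript_id = vapply(pep$transcript_ids[og$pidx],
                                 function(x) x[[1]], ""),
          mt_peptide = pep$mt_peptide[og$pidx],
          wt_peptide = pep$wt_peptide[og$pidx],
          hla_allele = og$hla_allele,
          algorithm = oalgs[og$aidx],
          ic50_mt = score, ic50_wt = scoreWt,
          percentile_mt = NA_real_, percentile_wt = NA_real_,
          score_class = oclass[og$aidx], stringsAsFactors = FALSE)
      }
      chunks[[i]] <- if (is.null(orthDf)) bindDf else rbind(bindDf, orthDf)
    }
    out <- as.data.frame(data.table::rbindlist(chunks))
    # percentile rank transform within allele, over binding records
    isB <- out$score_class == "binding"
    for (al in unique(out$hla_allele)) {
      sel <- isB & out$hla_allele == al
      r <- rank(out$ic50_mt[sel], ties.method = "average")
      out$percentile_mt[sel] <- 100 * (r - 0.5) / sum(sel)
      wsel <- sel & !is.na(out$ic50_wt)
      if (any(wsel)) {
        rw <- rank(out$ic50_wt[wsel], ties.method = "average")
        out$percentile_wt[wsel] <- 100 * (rw - 0.5) / sum(wsel)
      }
    }
    out
  })
}

#' Generate anchor-probability matrices with canonical anchors
#'
#' Dirichlet-style normalized probability vectors concentrated on position
#' 2 and the C-terminal position — the canonical class I anchor positions —
#' for every allele/length combination.
#'
#' @param alleles HLA allele names.
#' @param lengths peptide lengths.
#' @param seed RNG seed.
#' @param concentration Dirichlet weight placed on the two canonical
#'   anchors (larger = more concentrated); default 40.
#' @return named list of [AnchorMatrix] keyed `"allele|length"`.
#' @export
makeAnchorMatrices <- function(alleles, lengths, seed,
                               concentration = 40) {
  withSeed(seed, {
    out <- list()
    for (al in alleles) {
      for (l in as.integer(lengths)) {
        alpha <- rep(0.5, l)
        alpha[2L] <- concentration
        alpha[l] <- concentration
        g <- rgamma(l, shape = alpha)
        out[[sprintf("%s|%d", al, l)]] <- AnchorMatrix(al, l, g / sum(g))
      }
    }
    out
  })
}

#' Generate a matched aggregate report and metrics document
#'
#' Runs the full pipeline on a synthetic dataset: contexts are enumerated,
#' transcripts grouped into sets, per-algorithm predictions aggregated,
#' the best peptide selected per variant, anchor scenarios and clonality
#' evaluated, and tiers assigned. The resulting aggregate table and metrics
#' document reconcile with zero warnings, and can optionally be written
#' to disk as the TSV/JSON pair.
#'
#' @param spec a [FixtureSpec].
#' @param dir optional output directory; when given, `aggregate.tsv` and
#'   `metrics.json` are written there.
#' @param cfg an [AggregationConfig] for score aggregation.
#' @param tierCfg a [TierConfig] for tier assignment.
#' @return list with `aggregate` (data.frame), `metrics` (document),
#'   `predictions` (epitope records), `truth` (the planted variant table)
#'   and, when `dir` is given, `aggregatePath`/`metricsPath`.
#' @export
makeReportPair <- function(spec, dir = NULL, cfg = AggregationConfig(),
                           tierCfg = TierConfig()) {
  validObject(spec)
  ctx <- makeContexts(spec)
  preds <- makePredictions(ctx, spec)
  anchors <- makeAnchorMatrices(spec@alleles, spec@lengths, spec@seed + 2L)

  agg <- summarizeEpitopes(preds, cfg, by = "variant_id")
  vtab <- ctx$variants
  rows <- vector("list", nrow(vtab))
  variantsDoc <- list()

  for (i in seq_len(nrow(vtab))) {
    vid <- vtab$ID[i]
    va <- agg[agg$variant_id == vid, , drop = FALSE]
    # best allele per peptide, then best peptide per variant
    byPep <- split(va, va$mt_peptide)
    pepBest <- do.call(rbind, lapply(byPep, function(p) {
      ok <- !is.na(p$metric_value)
      j <- if (any(ok)) which(ok)[which.min(p$metric_value[ok])] else 1L
      cbind(p[j, , drop = FALSE],
            any_pass = any(p$passes_binding))
    }))
    ord <- order(pepBest$metric_value, pepBest$mt_peptide, na.last = TRUE)
    best <- pepBest[ord[[1]], ]
    nPassOthers <- sum(pepBest$any_pass[-ord[[1]]])

    pep <- mergedEnumeration(ctx$contexts[[vid]], spec@lengths)
    mutPos <- pep$mutation_positions[[
      match(best$mt_peptide, pep$mt_peptide)]]
    key <- sprintf("%s|%d", best$hla_allele, best$length)
    anchorSet <- if (!is.null(anchors[[key]])) {
      determineAnchorPositions(anchors[[key]],
                               tierCfg@anchorContributionThreshold)
    } else integer()
    overlap <- if (length(anchorSet) == 0L) NA_character_ else {
      inA <- mutPos %in% anchorSet
      if (!any(inA)) "none" else if (all(inA)) "all" else "partial"
    }
    scenario <- if (is.na(overlap) || overlap != "all") "accept" else {
      if (is.na(best$median_ic50_wt)) "unknown" else
        if (best$median_ic50_wt <= tierCfg@wtIc50Threshold) "reject_anchor"
        else "accept"
    }
    clon <- classifyClonality(vtab$dna_vaf[i], vtab$purity[i],
                              clonalityFraction = tierCfg@clonalityFraction)
    alleleExpr <- computeAlleleExpr(vtab$gene_expr[i], vtab$rna_vaf[i])
    tier <- tierFromCriteria(isTRUE(best$passes_binding), alleleExpr,
                             vtab$rna_vaf[i], vtab$rna_depth[i],
                             vtab$tsl[i], scenario, clon, tierCfg)$tier

    sets <- groupTranscriptSets(ctx$contexts[[vid]], spec@lengths)
    bestSet <- sets$set_id[[
      which(vapply(sets$peptides, function(p)
        best$mt_peptide %in% p$mt_peptide, TRUE))[1]]]

    rows[[i]] <- data.frame(
      "ID" = vid, "Gene" = vtab$gene[i], "AA Change" = vtab$aa_change[i],
      "Pos" = paste(mutPos, collapse = ","),
      "Best Peptide" = best$mt_peptide,
      "WT Peptide" = best$wt_peptide,
      "Best Transcript Set" = bestSet,
      "Allele" = best$hla_allele,
      "IC50 MT" = best$metric_value,
      "IC50 WT" = best$median_ic50_wt,
      "%ile MT" = best$median_percentile_mt,
      "%ile WT" = best$median_percentile_wt,
      "Num Passing Peptides" = as.integer(nPassOthers),
      "RNA Expr" = vtab$gene_expr[i], "RNA VAF" = vtab$rna_vaf[i],
      "Allele Expr" = alleleExpr,
      "RNA Depth" = as.integer(vtab$rna_depth[i]),
      "DNA VAF" = vtab$dna_vaf[i], "TSL" = as.integer(vtab$tsl[i]),
      "Anchor Residue" = overlap, "Tier" = tier, "Eval" = "Pending",
      check.names = FALSE, stringsAsFactors = FALSE)

    setsDoc <- lapply(seq_len(nrow(sets)), function(s) {
      pepDf <- sets$peptides[[s]]
      peptides <- lapply(seq_len(nrow(pepDf)), function(p) {
        mtp <- pepDf$mt_peptide[p]
        sc <- preds[preds$variant_id == vid & preds$mt_peptide == mtp,
                    c("hla_allele", "algorithm", "score_class", "ic50_mt",
                      "ic50_wt", "percentile_mt", "percentile_wt"),
                    drop = FALSE]
        rownames(sc) <- NULL
        list(mt_peptide = mtp, wt_peptide = pepDf$wt_peptide[p],
             length = pepDf$length[p],
             mutation_positions = pepDf$mutation_positions[[p]],
             scores = sc)
      })
      list(set_id = sets$set_id[s],
           transcript_ids = sets$transcript_ids[[s]],
           total_expression = sets$total_expression[s],
           best_tsl = sets$best_tsl[s],
           peptides = peptides)
    })
    variantsDoc[[vid]] <- list(
      gene = vtab$gene[i], aa_change = vtab$aa_change[i],
      dna_vaf = vtab$dna_vaf[i], rna_vaf = vtab$rna_vaf[i],
      rna_depth = as.integer(vtab$rna_depth[i]),
      gene_expr = vtab$gene_expr[i], tumor_purity = vtab$purity[i],
      transcript_sets = setsDoc)
  }

  aggregate <- do.call(rbind, rows)
  aggregate <- orderAggregate(aggregate)
  metrics <- list(
    schema_version = METRICS_SCHEMA_VERSION,
    alleles = spec@alleles,
    algorithms = spec@algorithms,
    anchor_matrices = lapply(anchors, anchorProbabilities),
    variants = variantsDoc)

  out <- list(aggregate = aggregate, metrics = metrics,
              predictions = preds, truth = vtab)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$aggregatePath <- file.path(dir, "aggregate.tsv")
    out$metricsPath <- file.path(dir, "metrics.json")
    writeAggregate(aggregate, out$aggregatePath)
    writeMetrics(metrics, out$metricsPath)
  }
  out
}
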