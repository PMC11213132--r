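# NeoTier

Tiered prioritization of tumor neoantigen candidates from ensemble MHC
binding predictions.

## The problem

Somatic mutations in a tumor can create peptides absent from the normal
proteome — neoantigens — that, when presented on MHC molecules, make
targets for personalized vaccines and adoptive cell therapies. Selecting
candidates is combinatorially messy: a single missense variant, read
through every register of the class I peptide lengths 8–11, already
yields 8 + 9 + 10 + 11 = 38 distinct mutant peptides, and with 6 HLA
class I alleles and a 13-algorithm prediction panel that is
38 × 6 × 13 = 2,964 predictions for one variant. Alternative transcripts
can change the peptide sequence around the variant, prediction
algorithms disagree, and binding alone says nothing about expression,
clonality, or whether the mutation faces the T-cell receptor at all.

NeoTier is the computational engine for working through that thicket. It
is aimed at cancer immunogenomics researchers who have per-variant
protein context and per-algorithm binding predictions (IC50 in nM and
percentile rank, plus optional elution and immunogenicity scores) and
need a defensible, reproducible, per-variant ranking.

## What it computes

* **Register enumeration** — every in-bounds window of each requested
  length containing an altered residue, paired with the same-coordinate
  wild-type window for frame-preserving variants; frameshift windows
  have no wild-type partner. Transcripts yielding identical peptide
  lists collapse into *transcript sets*.
* **Ensemble aggregation** — per-allele median and lowest mutant IC50
  across algorithms (median of an even count is the mean of the central
  pair; missing scores are omitted, not imputed), with a binding pass at
  the recommended cutoffs of IC50 ≤ 500 nM and percentile rank ≤ 2.
* **Tiering** — each variant is labeled `Pass`, `Anchor`, `Subclonal`,
  `LowExpr`, `NoExpr` or `Poor` from binding, allele expression
  (gene TPM × RNA VAF), transcript support level, clonality
  (DNA VAF against purity/2) and the anchor scenario: a mutation
  confined to anchor positions of a peptide whose wild-type form binds
  well presents a surface the thymus has already seen, and is rejected.
  Anchor positions are the smallest greedy set of per-position
  probabilities reaching 0.8 cumulative mass, per allele and length.
* **Report I/O** — the aggregate TSV and metrics JSON pair, with
  bit-exact TSV round-trip, evaluation (Accept/Reject/Review) tracking,
  supplementary other-class merging, gene-of-interest flagging, top-30
  anchor-heatmap data and generic grouped custom tables.
* **Synthetic data** — a deterministic generator
  (`fixtureSpec()`/`makeReportPair()`) producing matched aggregate and
  metrics files with planted binder/clonality truth, so the whole
  pipeline is testable offline.

## Worked example

A KRAS-like G12V missense context, enumerated over the class I lengths:

```r
library(NeoTier)

ctx <- ProteinContext("ENST0001",
  wtSequence  = "MTEYKLVVVGAGGVGKSALTIQLIQNHFV",
  mtSequence  = "MTEYKLVVVGAVGVGKSALTIQLIQNHFV",
  variantType = "missense", variantStart = 12,
  expression = 12.5, tsl = 1)

pairs <- enumerateRegisters(ctx, lengths = classILengths())
nrow(pairs)
#> [1] 38
head(pairs[, c("mt_peptide", "wt_peptide", "length")], 3)
#>   mt_peptide wt_peptide length
#> 1   KLVVVGAV   KLVVVGAG      8
#> 2   LVVVGAVG   LVVVGAGG      8
#> 3   VVVGAVGV   VVVGAGGV      8
countPredictionSpace(nrow(pairs), 6, 13)
#> [1] 2964
```

Each row is one register: the valine substitution slides through every
position of every window, and each mutant peptide is paired with the
wild-type sequence at the same coordinates. The full pipeline on the
shipped demo fixture (seed 42, 25 variants, 6 alleles, 8 binding
algorithms):

```r
rp <- makeReportPair(demoFixture())
table(rp$aggregate$Tier)
#>  Anchor LowExpr    Pass    Poor
#>       1       2       7      15
rp$aggregate[1:3, c("ID", "Gene", "Best Peptide", "Allele",
                    "IC50 MT", "Allele Expr", "Tier")]
#>                  ID    Gene Best Peptide      Allele  IC50 MT Allele Expr Tier
#>  chr12-34343806-A-T GENE015     SYGPQKNK HLA-A*02:01 35.64169   10.191091 Pass
#>   chr7-34097742-C-T GENE012     DAIWIWWC HLA-C*07:02 29.82780    6.778907 Pass
#>   chr10-6703618-A-G GENE007     WQTLFPVN HLA-A*02:01 32.95798    5.210121 Pass
```

`Pass` rows satisfy every criterion; the `Poor` rows here are planted
non-binders (the demo's binder fraction is 0.2), `LowExpr` rows fall
below the allele-expression floor of 2.5, and the `Anchor` row has its
mutation confined to anchor positions with a well-binding wild-type
peptide. Anchor sets come from normalized per-position probabilities;
for one generated HLA-A*02:01 9-mer matrix:

```r
m <- makeAnchorMatrices("HLA-A*02:01", 9, seed = 1)[[1]]
round(anchorProbabilities(m), 3)
#> [1] 0.001 0.486 0.001 0.007 0.002 0.004 0.047 0.000 0.451
determineAnchorPositions(m, 0.8)
#> [1] 2 9
```

Evaluations round-trip through the TSV export (`writeAggregate()` /
`readAggregate()`); the spreadsheet export is one-way, exactly so that
saved evaluations always travel via TSV.

A thin command-line wrapper is installed as `exec/neotier`
(subcommands `enumerate`, `aggregate`, `tier`, `export`, `view-data`,
`fixture`).

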