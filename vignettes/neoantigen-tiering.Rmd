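---
title: "Methods: register enumeration, score aggregation and variant tiering"
author: "NeoTier authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: register enumeration, score aggregation and variant tiering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeoTier)
```

# Scope and model

NeoTier turns two kinds of upstream evidence — per-transcript protein
context around a somatic variant, and per-algorithm peptide–MHC binding
predictions — into a per-variant, tiered aggregate report. It does not
run any binding predictor, translate cDNA, or call variants; those are
producers of its inputs. This vignette records the methods, the
defaults and the reasoning behind the choices that were genuinely open.

# Register enumeration

For a mutant protein sequence with altered residues spanning positions
$s..e$ (1-based), the enumeration emits every window of length
$l \in L$ that lies fully inside the sequence and overlaps $[s, e]$.
For an interior missense variant with at least $\max(L) - 1$ residues
of flank on each side, each length contributes exactly $l$ windows, so
the class I default $L = \{8, 9, 10, 11\}$ gives $38$ distinct mutant
peptides; with 6 class I alleles and a 13-algorithm panel that is
$38 \times 6 \times 13 = 2{,}964$ predictions for a single variant.

Decisions made where more than one convention is defensible:

* **Coordinates** are 1-based within the protein and within the
  peptide, matching amino-acid position conventions in reports.
* **Frameshifts** enumerate every window overlapping at least one novel
  residue, from the frameshift start through the last residue before
  the stop codon, and carry no wild-type partner: out of frame there is
  no meaningful same-coordinate wild-type window.
* **In-frame indels** are paired with the equal-length, same-coordinate
  wild-type window. An equally defensible alternative is a wild-type
  window of equal genomic span; we chose equal peptide length so that
  MT/WT pairs are always directly comparable, and the pair's
  `mutation_positions` record where they differ.
* **Stop codons** (`*`) truncate both sequences at construction time.
* **Duplicate windows** (possible when the mutation restores a repeat
  period) are merged by identical mutant peptide, pooling their mutated
  positions, so reported peptides are distinct.

Transcripts of one variant whose enumerated mutant-peptide multisets
are identical collapse into a single transcript set; the set id is the
sorted member ids joined with `+`, making grouping deterministic. Sets
partition the transcripts; total expression is summed and the best
(minimum) TSL retained.

# Score aggregation

Binding records are one row per (peptide, allele, algorithm) with
mutant/wild-type IC50 (nM) and percentile rank. Per allele we report
the median and the lowest mutant IC50 and the median percentile:

* the median over an even number of algorithms is the arithmetic mean
  of the two central values (conventional definition);
* missing algorithm scores are omitted from the median rather than
  imputed — predictors legitimately decline allele/length combinations;
* wild-type medians are reported only where the mutant peptide passed
  the binding cutoff, mirroring how reports display them.

A peptide passes binding on an allele when the configured metric
(median by default; lowest available) is at or below the IC50 cutoff,
500 nM by default. The percentile cutoff (default 2) can be enabled as
an OR-rule (`usePercentile`): the recommendation lists both cutoffs
without fixing a combination rule, so the combination is configuration,
and the IC50-only default is the conservative reading. Which metric
defines the "best-binding" epitope when IC50 and percentile disagree is
likewise configuration (`metric`), defaulting to IC50.

The best peptide of a variant minimizes the configured metric at its
best allele; ties break lexicographically on the mutant peptide so the
choice is reproducible. Elution and immunogenicity scores (in $[0,1]$,
1 best) are carried as an orthogonal, advisory table and never affect
tiering by default — they are trained on different data (peptide
elution mass spectrometry, T-cell response) and mixing them silently
into the binding decision would make the tier uninterpretable.

# Tiering

Six labels, ranked best to worst: `Pass`, `Anchor`, `Subclonal`,
`LowExpr`, `NoExpr`, `Poor`. Criteria are evaluated independently and
*all* failures are reported; the assigned tier is the most severe
failing category. Severity (default precedence
`Poor > NoExpr > LowExpr > Subclonal > Anchor`) is deliberately the
reverse of the rank order: with this alignment, fixing any single
criterion can only move a variant up the ranking, a monotonicity
property the test suite exercises under randomized single-criterion
improvements. Any precedence-max scheme whose precedence is *not*
aligned with the rank order violates that property (a variant failing
both expression and binding would improve its expression and fall in
rank), which is why the default is fixed this way; the precedence
remains configurable.

Criterion details and defaults:

* **Binding** (`Poor`): the best peptide's configured metric at its
  best allele against the 500 nM cutoff.
* **Transcript support** (`Poor`): TSL must be at most `tslMax`,
  default 1 — the best-supported Ensembl category. Guidance phrased as
  "TSL ≥ 1" excludes nothing if read literally, since 1 is the best
  level; we therefore implement a maximum. A missing TSL is treated as
  unevaluated rather than failing.
* **Expression** (`NoExpr`/`LowExpr`): allele expression is gene TPM ×
  RNA VAF. Zero allele expression with RNA evidence is `NoExpr`;
  positive but below `alleleExprThreshold` (default 2.5, a low bar in
  TPM-scaled units chosen to catch marginal expression without
  discarding moderately expressed candidates) is `LowExpr`. Optional
  RNA VAF and RNA depth floors (`rnaVafMin`, `rnaDepthMin`) default to
  0, i.e. disabled, and count as `LowExpr`-category criteria when
  enabled.
* **Clonality** (`Subclonal`): the founding-clone reference VAF is
  purity/2 — the heterozygous diploid expectation — or, without a
  purity estimate, the maximum somatic DNA VAF in the sample. A variant
  is subclonal below 0.5 × reference (boundary inclusive on the
  founding side). This is a deliberately simple screen, not a clonal
  deconvolution.
* **Anchor scenario** (`Anchor`): anchor positions are the smallest
  greedy set of per-position probabilities (ties to the lower index)
  whose mass reaches `anchorContributionThreshold`, default 0.8. If no
  mutated position is an anchor, the variant is acceptable regardless
  of wild-type binding; if all mutated positions are anchors and the
  wild-type peptide binds at or below `wtIc50Threshold` (default: the
  MT cutoff), the presented surface is effectively wild-type and the
  candidate is rejected; a poorly binding wild-type rescues it, and a
  missing wild-type measurement yields `unknown`, which does not fail.
  Mutations spanning anchor and non-anchor positions are acceptable.

`retier()` recomputes tiers as a pure function of the stored row fields
and a configuration (optionally a new purity), never touching
evaluations; it is idempotent, which the suite asserts.

# Report formats

The aggregate TSV uses the upstream-style headers (`IC50 MT`,
`%ile MT`, `RNA Expr`, `RNA VAF`, `Allele Expr`, `RNA Depth`,
`DNA VAF`, `TSL`, `Tier`, `Eval`, ...); unknown columns pass through
verbatim. Missing values serialize as `NA`; numerics are written with
17 significant digits so that write → read reproduces every double
bit-exactly, the property the evaluation round-trip relies on. Variant
ids are `chrom-pos-ref-alt` with 1-based positions — a deterministic
join key for the supplementary-class merge and the metrics document.

The metrics JSON is a versioned schema (`schema_version` 1.0) holding,
per variant, its transcript sets and per-peptide score grids, plus the
anchor matrices keyed `"allele|length"`. It is compatible in spirit,
not byte-compatible, with upstream pipelines' metrics files; loading
validates structure and reconciles variant ids against the aggregate
table, reporting each mismatch.

Spreadsheet export is Excel 2003 SpreadsheetML — a single XML file that
Excel and LibreOffice open directly — and is write-only; evaluations
re-load only from TSV. The anchor-heatmap data takes the top 30 MT/WT
pairs by the configured metric, with per-position probabilities matched
by (best allele, length).

# The synthetic-data generator

`fixtureSpec()` fixes the study conditions: 25 variants, 6 class I
alleles, the 8-algorithm class I binding panel plus 3 elution and 2
immunogenicity predictors (13 algorithms in all), binder fraction 0.2,
tumor purity 0.8, subclonal fraction 0.2, flank 13, gamma(2, 0.1) gene
expression (mean 20 TPM) — values chosen once as representative of a
small patient-scale class I run. Seed 42 with these defaults is the
`demoFixture()` that anchors the documentation, standing in for
demonstration data that would otherwise require external download.

Properties that make the generator useful as ground truth:

* **Determinism.** All draws run under an isolated, fixed-seed
  Mersenne-Twister state; the same spec always reproduces the same
  dataset, and the caller's RNG state is left untouched.
* **Hard class margins.** Binder IC50s are log-normal around 50 nM
  capped at 490; non-binders are 600 nM plus a log-normal. No draw can
  cross the 500 nM default cutoff, so planted binder labels are
  recoverable exactly and a binder-fraction-0 dataset passes nothing.
  Similarly, founding VAFs are drawn at 0.6–1.0 × (purity/2) and
  subclonal at 0.05–0.4 ×, straddling the 0.5 × classification boundary
  with a gap.
* **Rank-consistent percentiles.** Percentile ranks are a rank
  transform of IC50 within each allele, hence monotone in IC50.
* **Canonical anchors.** Generated anchor matrices are Dirichlet-style
  vectors concentrated on position 2 and the C-terminus.
* **Self-consistency.** `makeReportPair()` runs the full pipeline and
  emits an aggregate/metrics pair that reconciles with zero warnings.

What the generator does **not** emulate: correlated errors between
algorithms, allele-specific binding motifs (any peptide can bind the
planted allele), length preferences, realistic proteome sequence
composition, multi-nucleotide or splice-altering variants, and
continuous clonal architecture. Passing tests on this synthetic ground
truth therefore demonstrates that the bookkeeping, aggregation and
decision rules are correct — not that any upstream predictor is
accurate on real tumors.

# Numerical choices and problem sizes

Medians use the standard sort-based definition and are cross-checked
in the suite against an independent sort oracle on 10,000 random record
sets; tier monotonicity is checked under 1,000 randomized
single-criterion improvements, anchor-set minimality on 1,000 random
probability vectors, and parameter recovery (binder and subclonal
fractions within three binomial standard errors) on a 500-variant
dataset — sizes chosen to give the binomial checks resolving power
while keeping the default test run in tens of seconds. Greedy anchor
selection compares cumulative mass against the threshold with a 1e-12
slack to absorb floating-point summation; anchor vectors must sum to 1
within 1e-6 on load. Ties are broken deterministically everywhere:
lexicographic peptides for best-peptide selection, lower position index
for anchor selection, allele name for best-allele selection, and
variant id as the final sort key of the report ordering.

# Known limitations

Clonality is a VAF screen, not a subclonal reconstruction; copy-number
alterations distort the purity/2 reference. The anchor scenario is
binary per peptide-allele pair and does not grade partial anchor
overlap. Proteome-wide reference matching (excluding peptides that
also occur in the normal proteome) and manufacturability scoring are
out of scope. Class II support is limited to the generic lengths,
4-algorithm cap and supplementary-class merge; class II anchor
biology is not modeled.
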