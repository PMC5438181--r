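---
title: "Detecting conserved rare codon clusters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved rare codon clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`codonconserve` asks one question of a set of homolog families drawn from
many species: do clusters of synonymous *rare* codons sit at the same
alignment positions more often than chance allows, once the obvious
non-rarity explanations are removed? This vignette documents the models and
the choices behind each stage, in the order the pipeline runs them.

## Rarity and %MinMax profiles

Rarity is *relative*: a codon is rare in a species when its ORFeome usage
frequency is below the mean frequency of its synonymous set. This makes the
flag independent of amino acid composition — a codon for a rare amino acid is
not automatically "rare" — and invariant under rescaling of frequencies.
Frequencies are reported per 1000 codons; every downstream quantity is a
ratio, so the unit is cosmetic but fixed.

The %MinMax score of a window of `w` codons compares the mean usage
frequency of the actual codons (`Xact`) with three hypothetical encodings of
the same amino acids: all most-common (`Xmax`), all rarest (`Xmin`) and
average (`Xavg`, the mean of each set's mean). Scores are
`100·(Xact−Xavg)/(Xmax−Xavg)` above average and
`−100·(Xavg−Xact)/(Xavg−Xmin)` below, so +100 is exactly the all-most-common
encoding and −100 the all-rarest. The default window is `w = 17` codons,
roughly one ribosome footprint worth of mRNA; the resulting smoothing is
what turns pointwise rarity into *clusters*.

Numerical conventions:

* **Anchoring.** A window's score is anchored to its *first* codon. The
  ±2-column co-occurrence tolerance downstream absorbs small anchoring
  differences; centre-anchoring would shift every peak by the same 8 columns
  and change nothing else.
* **Degenerate windows.** A window whose amino acids are all encoded by a
  single codon (Met/Trp only) has `Xmax = Xavg = Xmin`; it carries no
  synonymous information and scores 0. Zero counts as non-negative: clusters
  require scores strictly below 0.
* **Clusters and peaks.** A rare codon cluster is a maximal run of
  consecutive negative windows; its peak is the window with the minimum
  score, ties broken toward the 5' end (deterministic, order-independent).
* Proteins shorter than the window yield an empty profile, not an error.

## ORFeome validation

Input CDS FASTA files are filtered rather than repaired: sequences whose
length is not a multiple of 3 are dropped (fragments, wrong frames);
sequences with ambiguous bases are dropped; a single trailing stop codon is
stripped and never counted; internal stop codons drop the record with a
warning. When one gene identifier carries several sequences (splice
isoforms), the longest is kept, the first encountered on ties. All dropped
counts are reported. These rules err toward discarding ambiguous material
because every downstream statistic assumes clean sense codons.

## Families, columns and co-occurrence

Families arrive as membership tables plus externally computed protein
alignments (the package never aligns). Members whose translated CDS does not
equal their ungapped alignment row are dropped with a warning — a mismatch
means the alignment and the ORFeome disagree and neither can be trusted for
that member. At most one member per species is kept; when paralogs are
present one representative is chosen uniformly at random (seedable).
Alignment columns containing a gap in *any* member are excluded from
consideration entirely; a peak sitting within tolerance of an excluded
column still counts toward its eligible neighbours.

For an eligible column where `m` of `n` members have a peak within ±2
columns (each member counted once), the p-value is the conditional binomial
tail `P(X ≥ m | X ≥ 1)`, `X ~ Binomial(n, p0)`. The per-member hit
probability is

```
p0 = min(1, (2·tol + 1) · P / (n · L_eligible))
```

with `P` the family's total peak count and `L_eligible` its gap-free column
count: the expected per-column, per-member rate of "a peak within ±tol".
Whether the tolerance factor belongs in `p0` was a genuinely open choice; we
include it because without it the test is strongly anti-conservative (the
binomial would predict far fewer hits than the ±2 matching actually
produces). With it, the test is *conservative*: the attained per-column
level sits below the nominal α, for two reasons we verified by simulation —
the conditional tail is discrete, and members differ in peak counts, so the
true count is a Poisson-binomial whose upper tail is thinner than the
matched binomial's. The test suite asserts the one-sided property (attained
level ≤ 1.5·α at α = 10⁻²,10⁻³ on shift-randomized families); exact
two-sided calibration is not attainable with a single pooled `p0`, and we
prefer the faithful conservative construction over a recalibrated one.

Family-level significance uses the per-column threshold 10⁻⁴ with an
any-usable-column rule, and no multiple-testing correction across columns or
families — faithfulness to the original procedure over improvement. The
reported best column is the minimum-p usable column, ties toward the most
N-terminal; note that with a ±2 tolerance the `m` counts (hence p-values)
are typically tied across a five-column neighbourhood, so the reported
column can sit two columns to the 5' side of the visual optimum.

The dataset-level test counts all cross-member peak pairs within ±2 columns
and compares against a null in which each member's peak vector is circularly
shifted by an independent uniform offset *within its own ungapped length*,
then re-mapped through its gap structure. Circular shifting preserves each
member's peak count and spacing while destroying cross-member alignment; the
choice of circular over truncated shifts keeps the marginal peak density
exactly uniform. The p-value is reported two ways: a normal-tail
approximation on the permutation z-score (the only way to express the
astronomically small values a strong signal produces) and the empirical
bound `(1 + #{null ≥ obs}) / (B + 1)`.

## The RRT null

Peaks can co-occur for reasons unrelated to rarity: conserved amino acid
composition, %GC3 matching, codon pair bias. Random reverse translations
(RRTs) are re-encodings of each protein drawn from a null that preserves
exactly those confounders:

* **%GC3 bins.** ORFeome CDS are binned by %GC3 into overlapping bins 10
  points wide advancing by 5 (0–10, 5–15, …). A CDS contributes its codon
  counts to *every* bin containing its %GC3 — that is what the overlap is
  for: each bin pools roughly twice the genes of a disjoint binning while
  adjacent bin means stay 5 points apart. For generation, a CDS draws from
  the bin whose midpoint is nearest its own %GC3 (ties toward the lower
  bin); empty bins fall back to the whole-ORFeome table.
* **Pair multipliers.** For an ordered codon pair (A, B), the multiplier is
  A's usage share within its amino acid at the −1 position of B, divided by
  the same share in 17-codon windows centred on B (excluding the −1 slot and
  B itself). Zero denominators default to 1; a pair never observed at −1
  although its amino acid is present gets multiplier 0 (real avoidance).
* **Generation.** RRTs are sampled 3'→5': the last codon proportionally to
  its bin count among synonyms, every earlier codon proportionally to bin
  count × multiplier against the codon already chosen 3' of it. If all
  candidate weights vanish (multiplier 0 across a set), the draw falls back
  to bin counts alone, then to uniform — translation fidelity is a hard
  invariant. The sampler is a small C++ kernel driven by R's RNG, so
  `set.seed()` governs it.

Each family is re-analysed on `n` replicate RRT families (default 200;
desk-scale analyses in this package's tests use 50), with peaks scored
against the *original* species usage tables — the null asks how rarity-free
re-encodings behave under identical scoring, not how a re-counted table
would behave. Among columns significant (p < 10⁻⁴) in at least one
replicate, the top 5% by replicate count are suspect — at least one column,
ties at the cutoff included, computed per family (the per-family reading of
"5% of positions" keeps families independent). Columns within ±8 of a
suspect are masked, ±8 being half the %MinMax window, applied in alignment
columns (equivalent to codons wherever the region is gap-free).

## Terminal trimming

Rare codons at sequence termini are conserved for reasons of their own
(translation initiation, mRNA structure), so the most N-terminal column
with no gaps in any member plus the following 50 columns are excluded, and
symmetrically the most C-terminal gap-free column and the 50 columns
preceding it. The C-side rule mirrors the N-side one. Gap columns outside
the boundaries are already excluded as gapped; alignments shorter than
about 100 gap-free columns are trimmed entirely (with a warning), and an
alignment with no gap-free column at all is fully trimmed.

## Enrichment analyses

GO enrichment uses two-sided Fisher's exact tests on family-level 2×2
tables (a family counts once per term), restricted by default to the 10
most common terms per GO class; degenerate margins report p = 1 with a
flag. The domain-boundary test compares the observed number of CRCCs within
10 residues of a domain start/end against a binomial null in which CRCCs
fall uniformly on the residues of domain-annotated proteins; "within 10" is
a configurable knob (`near_window`) because 10 and 20 are both defensible
readings of "near". All tests are two-sided. The N-versus-C windows test
counts CRCCs in fixed 50-residue windows that follow, are centred on, or
flank each boundary, and applies a sign test at p = ½; domains whose
windows overlap or overflow the protein are skipped and counted. Length
matching is greedy in input order, nearest length without replacement, ties
toward the shorter control — deterministic and a bijection onto its image.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
structure the analysis assumes, with known ground truth:

* **Species usage tables**: within-set codon frequencies one symmetric
  Dirichlet draw per synonymous set per species (concentration 0.5 —
  skewed, realistic sets with a strict rare/common order); uniform amino
  acid usage.
* **%GC3 heterogeneity**: each gene draws a target %GC3 from Beta(8, 8)
  (mean 50%, sd ≈ 12 points) and reaches it by exponential tilting of
  third-position G/C within synonymous sets (1-D root solve per gene,
  clamped at ±10 on the log scale).
* **Codon adaptation heterogeneity**: each gene tempers its species'
  within-set frequencies by a power drawn from Uniform(0, 0.5) — from
  neutral synonymous choice to moderate adaptation. This reproduces the
  empirical fact that rare codon clusters are widespread: with it, roughly
  a fifth to a quarter of windows score negative, matching the regime real
  ORFeomes show; without it, i.i.d. sampling from the usage table makes
  profiles almost uniformly positive and clusters unrealistically scarce.
* **Codon pair bias**: one shared 61×61 multiplier matrix with log-normal
  entries (sd configurable, 0 by default), applied during the same 3'→5'
  chain sampling the RRT generator uses.
* **Families**: a uniform ancestor protein (220–320 residues), i.i.d.
  substitutions to 85% identity per member (planted windows conserved),
  geometric terminal extensions (mean 25 residues) aligned right/left
  against the core — alignments come from this bookkeeping, never from an
  aligner, so alignment error cannot confound the statistics. A star
  phylogeny suffices to test the statistics; there is no tree.
* **Plants**: in a configured fraction of families, a 17-codon window at an
  interior column (at least 60 columns from the core ends, clear of
  trimming) is re-encoded in a configured fraction of species: each codon
  is, with probability `depth`, replaced by a synonymous codon from the
  rare side of its set, drawn with weight inverse to its frequency so that
  a full-depth plant approaches the all-rarest encoding (%MinMax → −100).

What the generator does *not* emulate: phylogenetic correlation between
species, within-gene autocorrelation of %GC3, mRNA-structure constraints,
indels inside the conserved core, and alignment error. Passing tests
therefore demonstrate the statistical machinery under the model's
assumptions, not robustness to misalignment or tree structure.

## Problem sizes and seeds

The test suite runs entirely on simulated data: the planted-recovery check
uses the generator defaults (20 species, 50 families, 60% planted at depth
0.8 carried by 80% of species) with 50 RRT replicates and 99 shift
permutations; calibration checks use 200 shift-randomized families and 60
small null datasets; RRT quality checks use a 1000-gene ORFeome. All
randomness flows through explicit seeds, and the pipeline is deterministic
under a fixed seed (identical tibbles across runs). `scripts/acceptance.R`
recomputes the same quantities from scratch for any seed.

## Known limitations

* The per-column test is conservative (see above); reported p-values
  understate significance slightly, and the 10⁻⁴ threshold is therefore
  strict in practice.
* `p0` pools peak density across members; families with highly uneven peak
  counts are tested more conservatively than homogeneous ones.
* The RRT suspect rule ("top 5% of ever-significant columns, per family")
  always marks at least one column in any family with at least one
  significant replicate column, so a handful of columns are masked even in
  clean families; the ±8 mask then removes up to 17 columns per suspect.
* Families are analysed independently; no information is shared across
  families except the dataset-level shift test.
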