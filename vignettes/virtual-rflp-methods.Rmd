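---
title: "Virtual RFLP profiling and diversity statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual RFLP profiling and diversity statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflptools)
```

## The procedure

RFLP ribotyping compares strains by the fragment patterns a set of
restriction enzymes produces from a marker gene. This package performs
the entire protocol in silico on an existing multiple alignment of 16S
rRNA gene sequences:

1. **Digestion.** Each enzyme is written catalogue-style as a recognition
   site with a cut mark (`AG'CT`). Gaps are stripped per sequence (sites
   are physical, not columnar), the ungapped sequence is scanned on one
   strand, and fragments are the intervals between cut points on the
   linear molecule.
2. **Profiling.** Site level: one binary character per enzyme (at least
   one site present). Band level: fragment lengths per enzyme are binned
   and each (enzyme, bin) is a character — the virtual-gel analogue.
3. **Comparison.** Jaccard similarity between binary rows, distance
   `1 − Sj`, UPGMA dendrogram.
4. **Ordination and consistency.** PCA of the binary matrix; Mandel's
   h/k statistics flag groups whose location or spread is inconsistent
   with the rest.
5. **Polymorphism.** DnaSP-style summary of the alignment after
   complete deletion, plus between-group diversity and the four-gamete
   recombination bound.

## Matching semantics and their assumptions

A window matches a recognition site when at every position the window
symbol's IUPAC base set is a **subset** of the recognition symbol's base
set. Degeneracy in the enzyme (the N in `C'TNAG`) therefore accepts any
base, while an N in the *sequence* never certifies a site: calling is
conservative, as in restriction mappers, so ambiguity can only remove
evidence, never create it. Overlapping matches are all reported.

Scanning is single-strand. All ten built-in enzymes (AluI, BstUI, DdeI,
HaeIII, HhaI, HinfI, MboI, MspI, RsaI, TaqI) have self-reverse-
complementary recognition sites under IUPAC equivalence — asserted in
the test suite — so single-strand scanning finds every double-strand
site and cut positions are unambiguous. A user-supplied non-palindromic
enzyme triggers a warning. Sequences are treated as linear amplicons,
digested one enzyme at a time.

Coordinates are 1-based throughout (an R package convention): a match
start is the index of the window's first residue and a cut point `c`
means `c` residues lie left of the cut, so cuts at 0 or at the sequence
length are dropped and fragments always partition the molecule — the
length-conservation identity is asserted inside `digest()` on every
call.

## Band binning

In-silico fragment lengths are exact, so the default binning tolerance
is 0 (bins are exact lengths). To emulate the resolution of a real gel,
`band_matrix(tolerance = 0.02)` chains sorted lengths by single linkage
while neighbouring lengths differ by at most 2% — 100 and 101 bp then
co-migrate. Tolerance only ever merges bins; it never splits a band.

## Jaccard and UPGMA: numerical choices

`Sj = a/(a+b+c)` ignores shared absences, which is the right convention
for banding patterns (a band absent everywhere is no evidence of
similarity). Two all-zero profiles return similarity 1 with a warning.
The similarity-to-distance conversion is `D = 1 − S`: the clustering
input is a similarity in [0, 1] and this conversion is standard and
order-preserving.

UPGMA is implemented as *unweighted* average linkage: the distance
between clusters is the arithmetic mean over all member pairs
(recomputed from the original matrix, not the Lance–Williams weighted
update), and the new node's height is half the merge distance, so the
tree is ultrametric by construction. Ties are broken by the
lexicographically smallest pair of cluster labels (a cluster is labelled
by its smallest leaf), making output deterministic and testable; the
test suite checks agreement with `stats::hclust(method = "average")`
cophenetic distances on random matrices, where tie probability is zero.
Newick branch lengths are parent height minus child height; labels with
metacharacters are single-quoted.

## PCA conventions

The binary matrix is column-centered but not scaled — all features share
the 0/1 scale, and scaling would overweight nearly-constant characters.
Scores and loadings come from the SVD of the centered matrix; explained
fractions are squared singular values over their total. Signs are fixed
by making the largest-magnitude loading in each component positive, so
results are reproducible across LAPACK builds. A matrix with zero total
variance (all profiles identical) is an error, not a degenerate result.

## Mandel's h and k

For p groups with replicate observations, `h_i = (x̄_i − x̿)/s`
standardizes each group mean by the between-group standard deviation
(divisor p − 1), and `k_i = s_i/s̄` compares each group's standard
deviation to the root-mean-square pooled value. Two identities hold
algebraically and are asserted on every report: `Σh_i = 0` and
`Σk_i² = p`; also `|h_i| ≤ (p−1)/√p`.

Critical values follow the Wilrich/ISO 5725 forms:
`h_crit(p, α) = (p−1)·t / sqrt(p(p−2+t²))` with t the two-sided Student
quantile on p − 2 df, and
`k_crit(p, n, α) = sqrt(p / (1 + (p−1)/F))` with F the upper-α F
quantile on (n − 1) and (p − 1)(n − 1) df (balanced designs; with
unequal replicate counts k_crit is omitted with a warning). Published
renderings of these formulas are frequently garbled by typesetting —
here they are validated against a 50,000-replicate Monte-Carlo null
(p = 10, n = 3) in the acceptance suite, and the per-group flag rate
under a simulated normal null reproduces α. Both are *per-group*
critical values, not familywise.

The replicate observable is deliberately configurable because no single
convention exists. The pipeline default is the per-enzyme mean fragment
count within each group: it is always available from the digestion
stage, balanced by construction (one replicate per enzyme, n = 10), and
measures exactly the property RFLP grouping relies on.

## Polymorphism statistics

Complete deletion keeps a column only when **every** sequence has an
unambiguous A/C/G/T there; the filter is global, so within-group,
between-group and total statistics are computed on the same L columns
and remain comparable. Conventions, all DnaSP-compatible:

- η (total mutations) = Σ over columns of (distinct states − 1); a
  three-state column contributes 2, which is how η can exceed S.
- Singleton variable sites are restricted to two-state columns with
  minor count 1; a three-state column carrying two singletons counts as
  neither singleton-site nor parsimony-informative unless two states
  have count ≥ 2.
- Hd = n(1 − Σf²)/(n − 1); k averages pairwise differences over all
  C(n, 2) pairs; π = k/L, so π·L = k holds *exactly* on any input and is
  asserted on every summary.
- Rm is the Hudson–Kaplan bound: biallelic site pairs exhibiting all
  four gametes define conflict intervals, and Rm is the maximum number
  of pairwise-disjoint intervals, found by the right-endpoint greedy
  scan (tested against an independent dynamic-programming oracle).
- Between-group output reports pooled-group η alongside the mean
  cross-group pairwise difference; a net/Dxy-style alternative exists in
  the literature but pooled η is the reported default.

## What the synthetic generator emulates — and what it does not

The generator's defaults describe the strain panel of
`example_site_profiles()`: 19 strains in 3 groups (4 isolated
*Pseudomonas*, 7 reference proteobacteria, 8 actinobacteria), a
458-column aligned region, and Jukes–Cantor-like
independent per-site substitution with `d_between = 0.30` from the
common ancestor to each group ancestor and `d_within = 0.01` from group
ancestor to member. Divergence between phyla-level 16S groups of ~40–50%
per site over a variable region and ~2% within a named group are
realistic for this marker. Ten gap columns and two ambiguity columns are
injected as alignment artifacts (one affected sequence each), matching
how the pipeline treats them — complete deletion — rather than modelling
indel evolution.

Structural simplifications, deliberate and documented:

- **Star topology within groups.** Every member is an independent draw
  from its group ancestor. This exercises every statistic but produces
  no within-group phylogenetic signal; a green group-recovery test
  establishes that clustering separates groups, not that it reconstructs
  fine structure.
- **No rate heterogeneity, no secondary-structure constraint, no
  indels.** Real 16S alignments violate all three; the generator's
  purpose is controlled truth, not realism.
- **Planted sites are exact truth.** Recognition sequences are written
  into carrying groups after member mutation, knockouts substitute the
  site's middle base, and — one step beyond the minimal design —
  accidental matches of *those same enzymes* elsewhere in any sequence
  are scrubbed deterministically. Without scrubbing, a 4-base site
  occurs by chance ≈ 458/256 ≈ 1.8 times per sequence and a knockout
  would be invisible in the site matrix; with it, the truth table equals
  the site matrix column exactly and is verified against an independent
  regex oracle in the tests.
- Gap/ambiguity columns avoid planted windows so artifacts never destroy
  a planted site.

Determinism: all draws flow from the single `seed`; the same seed yields
byte-identical FASTA output, which the test suite asserts.

One generator bug is worth recording as a cautionary tale: gap injection
originally wrote through `seqs[[sample(ids, 1)]][col] <- "-"`, and R
evaluates the index expression of a complex assignment twice — one
strain's sequence was silently copied onto another, destroying group
structure. The divergence-calibration test caught it.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `band_matrix(tolerance)` | 0 | relative length fraction | in-silico lengths exact; 0.02 emulates gels |
| `rflp_pca(n_components)` | min(n−1, p) | — | full decomposition; pipeline writes 2 |
| `mandel_report(alpha)` | 0.05 | significance | convention for consistency flags |
| `synth_config(d_within)` | 0.01 | per-site substitution prob. | within-group 16S divergence |
| `synth_config(d_between)` | 0.30 | per-site substitution prob. | between-group divergence (groups span phyla) |
| `synth_config(gap_columns)` | 10 | columns | alignment-artifact rate on 458 columns |
| `profile_level` (pipeline) | "band" | — | band profiles carry length information; site level has only 10 characters |

## Degenerate inputs and tie-breaks

Empty sequences cannot be digested; alignments need ≥ 2 rows; complete
deletion that removes every column is an error naming the cause;
all-equal group means (Mandel h) and all-zero group sds (k) are errors
rather than NaNs; unbalanced Mandel designs drop k_crit with a warning;
UPGMA rejects asymmetric or negative matrices. UPGMA ties and PCA signs
are fixed deterministically as described above.

## Known limitations

- Site-level profiles (10 characters) are weak for clustering; the
  pipeline defaults to band-level profiles; the group-recovery
  acceptance criterion (perfect recovery in at least 95 of 100 seeds) is
  met at band level in the packaged world.
- Mandel statistics assume approximately normal replicate observables;
  fragment counts are discrete, so with very few enzymes the flags are
  indicative, not calibrated.
- The four-gamete Rm is a lower bound and ignores back-mutation;
  gene-conversion-style estimators are out of scope.
- No bootstrap support on dendrograms, no tree drawing, and no network
  retrieval of sequences: inputs are pre-aligned FASTA files.
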