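---
title: "Deconvolving linear motifs at modified sites: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving linear motifs at modified sites: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linmotif)
```

## The problem

Protein-modifying enzymes recognize short linear sequence contexts around the
residue they modify. Given a set of fixed-width peptide windows aligned on
modified sites (the *foreground*) and a reference population of same-width
windows (the *background*), we want the minimal set of position-specific
residue preferences — *linear motifs* — that explains which sequences were
modified. A motif here is a set of fixed (offset, token) pairs, where the
offset is relative to the central (modified) position and the token is a
single residue or a compound physicochemical residue group.

## The statistical model

For a foreground of windows and a candidate pair (offset $i$, token $t$), let
$k$ be the number of foreground windows carrying $t$ at $i$, $n$ the number of
foreground windows with a counted residue at $i$, and $p_0$ the background
frequency of $t$ at $i$. The test statistic is the one-sided exact binomial
tail

$$P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, p_0),$$

evaluated through the survival form of `pbinom` (never as $1 - F(k-1)$ in
floating point, which cancels catastrophically in the far tail where all
decisions are made). A pair is significant when $p \le \alpha/m$ with
Bonferroni family size $m = w \times (20 + G)$ for width $w$ and $G$ enabled
compound groups; $m$ is recomputed at every scan because each subset is a
fresh family of tests. The frequency of a compound group is the sum of its
(disjoint) member frequencies.

Defaults are $\alpha = 0.001$ and a minimum motif support of 20 sequences,
the conventional settings of this algorithm family. Terminal padding `-` and
the ambiguity code `X` are excluded from numerator *and* denominator of every
frequency, so probabilities stay well defined for windows that overhang
protein termini.

## The recursion

At each node the engine scans all $w \times (20 + G)$ candidates and then:

1. selects **all** significant pairs tying the minimal p-value (equality of
   log p-values within a relative tolerance of $10^{-9}$ — exact float
   equality would break tie detection between mathematically identical
   configurations summed in different orders);
2. partitions the foreground into one subset per selected pair (subsets may
   **overlap**: a window carrying several selected pairs joins all of their
   subsets) plus the remainder of windows matching none;
3. re-compiles the background to the windows matching each branch's fixed
   pairs and recurses into each subset with the extended prefix, and into the
   remainder with the unchanged prefix.

A branch terminates when nothing further is significant; a pair-extension
branch then emits its accumulated prefix as a motif (provided support
$\ge$ `min_support`), while a remainder branch emits nothing on its own
termination, so each prefix is emitted exactly once per distinct extension
path. Exhausting the reduced background also terminates a branch, keeping
its motif. Simultaneous selection of tied maxima is what removes the
positional bias of greedy single-pair selection: when two pairs are
statistically identical but share sequences, fixing either one first captures
the shared sequences and can starve the other below the support threshold
(`tie_select = "greedy"` reproduces that failure mode as an ablation).

Three consequences of this design are load-bearing and covered by tests:

* **Counts only.** Every decision consumes counts, never input order, so the
  motif set is invariant under permutation of input lines and under appending
  versus prepending a window. All internal orderings (candidate iteration,
  motif output) use radix (C-locale) sorts so serialized output is
  byte-identical across locales.
* **Reversal equivariance.** Reversing every foreground and background window
  and negating offsets reproduces the motif set exactly.
* **Termination.** Each extension fixes a new offset, and offsets already in
  the prefix are excluded from re-candidacy. The exclusion matters under the
  pooled background option: a fixed pair's pooled frequency never saturates
  to 1, so without it the same pair would re-fire forever. Under the default
  position-specific background the exclusion is a semantic no-op (a fixed
  pair's reduced-background frequency is 1, hence $p = 1$).

### Where the support threshold is applied

`min_support` gates pair *selection*, not merely emission: a significant pair
with $k <$ `min_support` could only create a subset too small to emit, so it
is never fixed. Beyond economy, this prevents a real failure: in a small
reduced background a token can have frequency 0, making a single foreground
occurrence "infinitely" enriched ($p_0 = 0$, $p = 0$); without the gate such
singletons get fixed, their branch dies below support, and the legitimate
prefix motif is silently lost. With the gate, sub-threshold artifacts are
ignored and the branch emits its prefix.

Two further selection details: when a single residue and a compound group
containing it are both maximal with identical $k$, only the more specific
single residue is kept (the group adds no sequences); and maximal pairs whose
matched window sets are identical are fixed together in one branch — they
would each be fixed anyway along the path, and branching on them separately
would multiply identical motifs combinatorially (a foreground of identical
windows collapses to a single motif fixing every column).

Motifs are classified by complexity: class I fixes the central position and
at least one flank, class II only the central position, class III only
flanks. No central residue ever needs to be declared; an optional
`central_residue` filter is available for site-centered data.

## Backgrounds

A background is built either from pre-aligned windows or from a proteome, in
which case every residue position contributes one window of the requested
width, `-`-padded at the termini, optionally restricted to a given central
residue so that background and site-centered foreground are commensurate.
The package never silently substitutes the foreground for a missing
background — p-values against a foreground-derived null are meaningless, so
an explicit background is required.

`position_specific_background = TRUE` (the default) tests each offset against
that column's own frequencies; the pooled option tests against frequencies
aggregated over all positions, which is appropriate when the windows are too
few to estimate per-column frequencies. No minimum size is enforced for
reduced backgrounds; a branch whose reduced background is empty is
terminated and logged rather than silently falling back to pooled
frequencies.

## Multi-sample comparison

For labelled multi-sample input, motifs are extracted per sample, pooled into
a non-redundant set (de-duplicated on fixed-pair sets), and every sample's
windows are exactly matched against every motif. Each count is tested against
the expected match probability under the background — the product of the
per-offset background frequencies of the motif's fixed pairs, an independence
assumption across positions that is the natural extension of the per-position
test — with Bonferroni correction over motifs × samples. Significant counts
are converted to percentages of the sample size; non-significant cells are
masked (`NA`) and exported as 0 for clustering, with the mask preserved in
the percentage table.

Downstream summaries: positional load (per group, the percentage of motifs
fixing each offset), fixed-residue composition differentials between two
motif sets (log2 ratio of percentage frequencies, with explicit sentinel
statuses for pairs present in only one or neither set rather than infinite
values), mean matched-intensity matrices (missing, never zero, when a motif
matches nothing in a condition), the `ln(x+1)` / row-center / unit-variance
transform used before clustering (zero-variance rows become all-zero rows so
matrix shapes stay stable for joins), and average-linkage Euclidean
clustering exports (reordered matrix plus dendrogram merge lists) for heatmap
or embedding consumers. Rendering itself is out of scope; the exports are
the interface.

## Synthetic data and what it does (not) show

All validation data is generated in code:

* `generate_bias_demo()` builds the 39-sequence, width-15 tie construction:
  19 windows with D at offset −7, 19 with D at +7, one with both, S at every
  center, uniform random filler. Two generator choices make the demonstrated
  property exact rather than approximate: filler at the two terminal columns
  excludes D (so the planted counts are exactly 20/20), and the random
  S-centered background is mirror-symmetric — every window is included with
  its reverse — so the background frequency of D is bit-identical at ±7 and
  the two pairs tie exactly. The filler distribution is uniform over the 20
  standard residues.
* `generate_proteome()` draws i.i.d. residues (uniform by default) — a
  desk-scale stand-in for a reference proteome. Real proteomes have
  non-uniform composition, repeats and domain structure; passing the null
  experiment on uniform proteomes therefore bounds the false-positive rate
  of the *statistics*, not of biological confounders.
* `sample_null()` draws foregrounds uniformly **without replacement** from a
  background pool (sampling distinct subsequences, matching the semantics of
  drawing from a proteome). `null_fp_rate()` runs the full experiment:
  per-central-residue backgrounds, sample sizes 100 and 10,000, 25 replicates
  per (residue, size) stratum — 1,000 replicates — and reports the fraction
  with at least one motif. At these conditions the observed rate is 0 and the
  Bonferroni construction bounds it below 0.1%. Sampling 10,000 from a pool
  of ~15,000 is hypergeometric with roughly a third of the binomial variance,
  making the binomial test conservative there by construction.

Problem sizes used by the test-suite and the acceptance script (600 proteins
× 500 residues, 1,000 null replicates, backgrounds of a few thousand
windows) were chosen as the smallest sizes at which every pool supports the
10,000-sequence stratum and the per-column frequency estimates are stable;
all generators are pure functions of their seed.

## Numerical and degenerate-input choices

* p-values are compared, selected and thresholded in log space; ties use a
  relative tolerance on log p; `p0 = 1` (e.g. a fixed pair under a
  position-specific background) gives $p = 1$ and can never re-fire.
* Site positions are 1-based (proteomics convention); window offsets are
  reported as $-(w-1)/2 \dots +(w-1)/2$.
* Nonstandard residue codes (B, J, O, U, Z, `*`) normalize to `X` on input
  and are excluded from all counts, so ambiguity codes cannot appear
  enriched. Input is case-insensitive.
* Sequence-level redundancy elimination is off by default
  (`dedup_sequences`), matching its role as an analysis-specific option.
* Accessions are resolved against the proteome by first exact name match;
  unmapped sites, out-of-range positions and declared-residue mismatches are
  counted and reported separately, never silently dropped.

## Limitations

Motifs are fixed-width and ungapped; depleted (disfavored) residues are not
modeled; the multi-sample match test assumes independence across fixed
positions; and no correction for protein abundance or peptide detectability
is applied. The compound groups shipped as defaults (acidic, basic,
polar-uncharged, nonpolar-aliphatic, aromatic, tiny) are one standard
physicochemical partition — analyses sensitive to the grouping should supply
a custom group file.
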