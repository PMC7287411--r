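---
title: "Methods: conserved noncoding elements and their rapid evolution"
author: "cnsevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved noncoding elements and their rapid evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
scoring model behind CNS detection, the substitution-frequency statistic and
its tests, how the simulator is built and what it does and does not emulate,
and the design decisions taken where more than one construction was
defensible.

## 1. Rejected-substitutions scoring

A conserved noncoding element is a run of alignment columns that shows fewer
substitutions than expected under neutral evolution along the species tree.
For each column we compute:

* **O**, the observed substitution count: the Fitch parsimony length of the
  column on the fixed tree topology. Missing data (gaps, `N`) are treated as
  fully ambiguous states, which makes the Fitch count equal to the parsimony
  length of the tree restricted to the species actually present. The
  implementation is vectorized over columns with base bitmasks and is
  checked in the test suite against exhaustive minimization over all
  internal-node labelings.
* **E**, the neutral expectation: `lambda` times the branch-length sum of
  the tree restricted to the present species (edges that lie on a path
  between two present leaves). Restricting the tree, rather than using its
  full length, keeps E honest for columns with missing species.
* **RS = E − O**, the rejected-substitutions score. Positive RS means the
  column carries fewer substitutions than a neutral column of the same
  species coverage would.

The scale factor `lambda` maps tree units (substitutions/site) onto what
parsimony actually counts in the data at hand. It is estimated as the mean
parsimony count per fully-present, non-coding column divided by the total
tree length. Two effects push it away from 1: constrained columns in the
mixture lower it (which is desirable — it tightens E towards the data's own
neutral level only when estimated from neutral regions), and parsimony's
undercounting of multiple hits on deep branches lowers it further. On purely
neutral simulated data at shallow Oryza-like depths the estimate is within
a few percent of 1 (tested); on mixed or deeply diverged data it is
substantially smaller, which is the intended self-calibration. Only
fully-present columns enter the estimate so that the parsimony/tree-length
ratio is well defined. If every column is invariant the estimate is zero and
the function refuses to proceed (a `lambda > 0` is required; the error
suggests an explicit `lambda = 1` override for degenerate inputs).

**Coding mask.** Only CDS intervals are masked (merged union across genes
and transcripts). UTRs and introns stay eligible, since conserved noncoding
elements are expected precisely in regulatory and intronic space. Masked
columns are unusable (RS fixed at 0), as are columns with fewer than
`min_species` (default 4, half the eight-species panel) real bases.

**Element calling.** Elements are maximal runs of usable columns with
`RS > rs_floor`, allowing interior runs of at most `max_gap_run` columns
that fail the floor, kept if the summed RS is positive and the element spans
at least `min_element_length` reference bases. Coordinates are the reference
positions of the first and last non-gap reference base of the run (forward
strand, 0-based half-open); elements never cross block boundaries. The
defaults (`min_element_length = 10`, `max_gap_run = 3`, `rs_floor = 0`) are
deliberately permissive; the calibration study below motivates stricter
settings for deeply diverged data.

## 2. The substitution-frequency statistic and its tests

For an element covered by *n* species, with `d_ij` the pairwise distance in
substitutions per site, the nucleotide substitution frequency is

\[ f = \frac{2 \sum_{i<j} d_{ij}}{n\,(n-1)}, \]

the mean of the pairwise distances. Distances are Jukes–Cantor corrected by
default (`d = -3/4 \log(1 - 4p/3)` for mismatch proportion *p*); "number of
substitutions per site" implies a multiple-hit correction, but a raw
*p*-distance mode is available. Compared sites are columns where both
species have a real base. Numerical edge cases: a pair with zero compared
sites is *missing* and is excluded from both the sum and the pair count
(the statistic becomes the mean over defined pairs); a mismatch proportion
at or beyond the JC69 pole (p ≥ 0.75) falls back to the raw proportion with
a warning rather than producing infinities.

**Baseline.** The null frequency is the pooled ratio
`p0 = sum(diffs) / sum(sites)` over all elements and defined pairs —
count-weighted, so that the null for the count-based tests is coherent. The
unweighted mean of per-element frequencies is also reported (the two answer
slightly different questions; both appear in the run log). Per-species
baselines `p0_s` pool only pairs involving species *s*.

**Rapid regions.** An element with pooled counts (D, N) is tested against
p0 with the 1-df goodness-of-fit statistic
`(D − p0·N)²/(p0·N) + ((N−D) − (1−p0)·N)²/((1−p0)·N)`, and flagged rapid
when p < α (default 0.001) *and* D/N > p0. The direction filter makes the
test one-sided: only elevated divergence counts as rapid. Expected counts
below 5 set a low-expected-count flag but the test is still computed.

**Phylogenetic overdispersion.** The binomial assumption behind that
statistic is wrong on a tree: a single substitution on an internal branch
changes every pair that spans it, so one column can move D by 7–16 counts
at once in an eight-species panel. Measured on simulated eight-species
elements the variance inflation ("design effect") is around 7–8, and the
uncorrected test's type-I error at α = 0.001 is several percent — orders of
magnitude off. We therefore estimate the design effect from the data — the
ratio of the empirical variance of per-column pair-difference totals to the
binomial variance implied by p0 — and divide the chi-squared statistic by
it (a first-order Rao–Scott correction), per element globally and per
species for the species-specific tests. The factor is floored at 1 so the
correction can never be anti-conservative. With the correction the measured
false-positive rate on 2,000 null elements is at or below the nominal level
(0–0.05% in the packaged studies). The uncorrected statistic remains
available (`dispersion = 1`) and is the exact textbook formula. Note the
factor is estimated over *all* elements including any truly accelerated
ones, which inflates it slightly and makes the corrected test mildly
conservative; with the effect sizes of interest (several-fold rate
changes) this costs little power.

**Species-specific regions.** Within each rapid region, species *s* is
tested by pooling its counts `(D_s, N_s)` over defined pairs to the other
species against its own baseline `p0_s` (the per-species baseline absorbs
lineage-specific rate differences; a global-baseline mode exists for users
who want absolute elevation). The per-species frequency `f_s` — the mean of
*s*'s distances to the others — is reported alongside.

**Group contrasts.** Pooled counts over pairs involving any member of two
disjoint species groups (within the rapid set) are compared with a 2×2
Pearson chi-squared without continuity correction. The pipeline's default
contrast is outcrossing (*O. rufipogon*, *O. longistaminata*) versus the
selfing species, when those taxa are present.

**Multiple testing.** Mirroring the fixed p < 0.001 convention for calling
regions, no multiplicity gate is applied to the flags; a Benjamini–Hochberg
adjusted column is emitted in every report so users can apply one.

## 3. The simulator and the fixture suite

`simulate_blocks` draws a root sequence i.i.d. from the base composition
(uniform by default) and evolves each column independently down the tree
under JC69. Segments of a block carry rate classes: neutral (branch lengths
as-is), conserved (all branches × `r_c`), and rapid (conserved background
with one terminal branch additionally × `m`). Acceleration is restricted to
terminal branches, matching the species-specific design of the analysis.
Ground truth — segment intervals and realized substitution counts per
branch — is returned alongside, and toy gene models are placed so that
non-neutral segments fall in known context categories (intron for
even-numbered blocks, upstream-2kb for odd ones) while CDS stays in the
neutral flanks.

What the simulator deliberately does **not** emulate: indels and alignment
error (gap handling is exercised with hand-built fixtures instead),
incomplete lineage sorting, context-dependent mutation, GC bias, and
rate variation beyond the three-class structure. Passing the recovery and
calibration tests therefore demonstrates the correctness and calibration of
the *method* under its own model, not performance on real alignments, where
alignment error and model misspecification will dominate.

### Fixture design and power analysis

The packaged fixture (`make_fixture_suite`) must let element-level
properties be measured at desk scale. The printed Oryza tree is very
shallow: its total length of 0.057882 substitutions/site means a neutral
column carries ~0.06 expected substitutions, so ~94% of *neutral* columns
are invariant and per-column RS cannot separate conserved from neutral
sequence at any caller setting (the score threshold `RS > 0` is equivalent
to `O < E`, and with E ≪ 1 virtually all columns pass in both classes).
Desk-scale validation therefore uses the same topology with all branch
lengths multiplied by `tree_scale = 50`, giving a neutral expectation of
~2.9 substitutions per column — enough signal for per-column
discrimination while relative branch lengths, and hence the structure of
the statistics, are unchanged. The unscaled printed tree is still used
directly wherever the test has closed-form expectations (the JC69
divergence checks and the neutral-scale recovery test).

Fixture geometry: 900-column blocks with a 500-bp central segment (matching
the ~495 bp mean length of real CNSs) at `r_c = 0.2` between two 200-bp
neutral flanks; every fifth block's central segment is rapid with `m = 5`
on the *O. longistaminata* branch. At this depth the caller settings
`max_gap_run = 2`, `min_element_length = 30` were fixed by a pre-registered
power study over a parameter grid (200 blocks per setting) before any
acceptance test was written, with measured margins: conserved-base
coverage 0.994, neutral-base inclusion 0.023, rapid-detection power 0.975,
accelerated-species attribution 1.00. The packaged studies use 1,112 blocks
(~1 Mb per species) for the end-to-end run, 2,000 single-segment blocks for
null calibration, and 10^5 columns for the closed-form divergence checks;
a full pipeline pass on the 1 Mb fixture takes about a minute on one CPU.

## 4. Conventions and numerical choices

* All internal coordinates are 0-based half-open; GFF3 (1-based closed) is
  converted at the reading boundary, BED is emitted natively, and MAF
  minus-strand rows keep their reverse-strand starts with element
  coordinates always reported on the reference's forward strand.
* Species identifiers are the MAF source token before the first `.`; a
  species-map argument covers nonconforming inputs.
* Nucleotides are case-insensitive; `N` is missing data — never a match,
  never a mismatch.
* All writers are byte-stable: fixed column orders, fixed number formatting
  (≥ 6 significant digits), deterministic sort orders, and a log without
  timestamps, so identical inputs give byte-identical outputs.
* The only stochastic component is the simulator; every analysis stage is
  deterministic, and a single seed drives a fixture end to end.
* Degenerate inputs have defined behaviour: an alignment yielding zero
  elements completes the pipeline with header-only reports and a warning;
  a run aborts with a stage-named error when an input fails to parse.

## 5. Known limitations

* Parsimony undercounts multiple hits, so O is a lower bound and E is
  calibrated through `lambda` rather than through a per-column
  substitution model; at divergences far beyond the Oryza scale a
  likelihood-based rate estimate would be preferable.
* The dispersion correction matches the first two moments of the null but
  not its skewness; at extreme significance thresholds (far beyond
  p = 0.001) the corrected p-values should be treated as approximate.
* Element calling conditions on low substitution counts, which biases
  called fragments of genuinely accelerated segments toward their
  conserved columns; the power study quantifies the net effect at the
  fixture's conditions, but very short accelerated elements remain hard to
  flag.
* Enrichment is a flat hypergeometric test per term: no ontology-graph
  propagation, and the double-counting of multi-category regions in
  context summaries is a documented reporting convention, not a
  statistical correction.
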