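---
title: "Detecting branch-specific functional shifts with BLOSUM62-derived replacement scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting branch-specific functional shifts with BLOSUM62-derived replacement scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmshift)
```

## The question the package answers

When a protein subfamily splits off on a long internal branch of a family
tree — as the cytosolic ACOL subfamily does within the carotenoid cleavage
oxygenases, or as RPE65 did when it traded oxygenase activity for retinoid
isomerase activity — did the replacements on that branch change the
protein's function, or are they ordinary drift? A crude but useful signal
is how *radical* the replacements were. `bdmshift` scores every confident
amino-acid replacement on a branch with a BLOSUM62-derived difference
measure (BDM) and asks whether the focal branch accumulated
disproportionately radical change relative to its neighboring branches.

The procedure is:

1. take a protein alignment and a tree with branch lengths (supplied, or a
   neighbor-joining topology with branch lengths optimized by maximum
   likelihood);
2. reconstruct marginal ML ancestral sequences at every internal node
   under an empirical substitution model (WAG or JTT) with discrete-Gamma
   rate variation;
3. on the focal branch, count replacements `R1` between the two ancestral
   sequences, using only sites where both endpoint states have posterior
   probability above 0.5, and sum their BDM scores into `BDM1`;
4. pool the same quantities over the 3–4 internal branches sharing an
   endpoint with the focal branch (`BDM2`, `R2`); terminal branches are
   excluded because single-sequence tips make their reconstructions and
   replacement counts incomparable to internal contrasts;
5. compare `[[BDM1, R1], [BDM2, R2]]` with a one-tail Fisher exact test,
   alternative "focal branch enriched in BDM per replacement".

A small P flags the branch as a candidate functional shift. Two cautions
are built into the reporting: radical/conservative contrasts are known to
be sensitive to mutational and compositional confounders, so P values are
advisory; and the test is run on single chosen branches, so no
multiple-testing correction is applied (the output says so).

## The BDM matrix

BLOSUM62 is a similarity matrix; the test needs a difference measure. The
default derivation is

$$\mathrm{BDM}(a,b) = s(a,a) + s(b,b) - 2\,s(a,b),$$

which is zero on the diagonal, symmetric, nonnegative, and grows with
biochemical dissimilarity (BDM(D,E) = 7, BDM(W,G) large). This derivation
is a design choice of the package: published analyses of this kind print
their 2×2 tables and P values but matrices in appendices vary, so the
matrix is pluggable (`bdm_matrix_from_file()`), every report records which
matrix was used, and the published control tables are reproduced exactly
from the printed integers regardless of the matrix. As a magnitude sanity
check, the default derivation gives a mean BDM per replacement of roughly
9–13 on simulated family data, the same range as the printed control
tables (e.g. 1714/130 ≈ 13.2).

BDM sums are real-valued only through the matrix; the Fisher table is
defined on integers, so BDM sums are rounded to the nearest integer before
testing (published tables print integers).

## Likelihood machinery and its contracts

Likelihoods are computed by Felsenstein pruning with per-node, per-site
log scaling, so alignments of hundreds of sequences cannot underflow; the
reported log-likelihood is exact to ~1e-10, which the test suite verifies
against exhaustive enumeration over all internal-state assignments on 4-
and 5-taxon trees, and against an independent implementation (phangorn) on
mixture data. WAG and JTT are bundled as plain-text exchangeability files;
rate matrices are built as \(Q_{ij} = S_{ij}\pi_j\), scaled to one expected
substitution per site at equilibrium, and exponentiated through the
eigendecomposition of the \(\pi\)-symmetrized generator (reversibility
guarantees a real spectrum). Detailed balance, row sums, and the ergodic
limit are all asserted to tight tolerances.

Discrete-Gamma rates use the mean-of-equiprobable-bin discretization
(exact conditional means via the incomplete-gamma identity), which keeps
the mean rate at exactly 1; a median variant is available for
compatibility with tools that use it. Defaults are `alpha = 1.1990` with 2
categories, the settings fitted for the carotenoid-oxygenase family trees
this test was designed around.

Branch lengths on a fixed topology are optimized coordinate-wise by
Brent's method on [0, 20] substitutions/site, in post-order sweeps; the
surrounding conditional likelihoods are refreshed before each 1-D profile,
so every accepted update provably increases the likelihood, and sweeps
stop when the total improves by less than `tol`. Zero is probed explicitly
because boundary optima (identical flanking sequences) matter here.
Topology search is deliberately out of scope: the test consumes a tree,
and NJ on ML pairwise distances provides a starting topology when none is
given. Only classic Saitou–Nei NJ is implemented (not BioNJ); negative
intermediate branch lengths are clamped to zero with the excess moved to
the sibling so path lengths are preserved.

Model frequencies (not alignment counts) are the default; `+F` empirical
frequencies are available through the `frequencies` argument of
`subst_model()`.

## Ancestral reconstruction choices

Reconstruction is *marginal* (per node, per site), not joint: the
confidence rule "use sites with posterior > 0.5" is a marginal concept.
Posteriors are computed per rate category by the up–down algorithm and
mixed with each site's posterior category weights (empirical Bayes). The
0.5 cutoff is applied strictly (`prob > 0.5` keeps a site; exactly 0.5
masks it), with an `inclusive` switch since rounding conventions differ
between tools. Gap and unknown characters are missing data (all-ones
partial likelihoods): ancestral states above them are still estimated and
usually end up masked. Replacements are only counted where *both*
endpoints are confident; a leaf endpoint counts as probability 1 for an
observed residue and 0 for a gap.

## What the simulator emulates — and what it does not

`simulate_alignment()` evolves a root sequence drawn from the model's
stationary distribution down a tree, one discrete-Gamma category per site
(drawn once, as the inference model assumes), with every branch using the
exact model transition matrices. The default study conditions are a
16-taxon balanced tree, background branches of 0.15 substitutions/site,
one long internal branch of 0.6, and 450 columns — a deliberately benign
stand-in for a curated protein family of moderate divergence.

The "functional shift" alternative has no published generative model, so
the package defines a minimal one: on the designated branch the
conditional replacement distribution is tilted,
\(P'(b\mid a) \propto P(b \mid a)\, e^{\beta\,\mathrm{BDM}(a,b)/\mathrm{BDM}_{\max}}\).
Because BDM is zero on the diagonal, `beta = 0` recovers the null model
*exactly*, and increasing `beta` makes replacements more radical without
directly inflating their number — precisely the alternative the statistic
is meant to sense. The simulator records the full history (ancestral
sequences, per-branch replacement lists, site categories), and a test
replays the history to confirm it reproduces the emitted alignment
bit-for-bit.

What the simulator does not emulate: indels (alignments are generated
gap-free; gap handling is tested with fixtures that inject gaps),
alignment error, compositional drift across the tree, site-specific
profiles, or correlated sites. Tests passing on these simulations
therefore demonstrate internal correctness and the statistic's behavior
under its own assumptions — not robustness to the misspecification real
families carry.

## Operating characteristics

`null_calibration()` and `power_curve()` run the full pipeline
(simulate → reconstruct ancestors on the true tree → BDM test on the long
branch) per replicate. The null rejection fraction at 0.05 is *reported,
not asserted*: counts within a branch are treated as independent by the
Fisher test although replacements on the same branch share one history, so
exact nominal calibration is not expected — this is the standing caveat
about radical/conservative ratio tests, measured rather than hand-waved.
The power curve over `beta` in {0, 3, 10} (200 seeded replicates per point
in the test suite, 100 in the analysis driver) is required by the test
suite to have non-increasing median P and non-decreasing rejection
fraction.

Problem sizes used by the test suite were chosen to make each suite a
few minutes at most: enumeration oracles run on 4–6 columns, recovery
suites on one 450-column family, the distance oracle on one 5,000-column
pair, branch-length recovery on one 2,000-column six-taxon family.

## Numerical and degenerate-input decisions

* Underflow: per-site log scalers at every internal node; 64-taxon
  alignments are tested for finiteness and additivity.
* Zero-length branches: transition matrix is the identity; an adjacent
  leaf forces the ancestral posterior to the observed residue (tested
  exactly).
* A branch whose test table is empty (`R1 = R2 = 0`) yields `P = NA` with
  an explanation rather than an error or an arbitrary number.
* Fisher tails use `phyper` (log-space, exact); agreement with direct
  log-binomial enumeration is asserted for every 2×2 table with total
  ≤ 60, and the two one-sided tails are checked to overlap by exactly the
  point mass.
* Ties in the MAP ancestral state are broken toward the lower residue
  index (deterministic); node numbering is post-order with a configurable
  offset so reports can match MEGA-style node labels (e.g. 374–375).
* Unrooted trees get an arbitrary root; likelihoods and posteriors are
  proven root-invariant under these reversible models, so the choice is
  cosmetic.

## Known limitations

The statistic inherits the known fragilities of radical/conservative
replacement ratios: composition and mutation biases can mimic enrichment,
and small replacement counts make the Fisher contrast weak (the published
BCOL control, with R1 = 54, is a case in point). The default BDM
derivation is principled but not canonical — swap in your own matrix if
you have one. Topology error is outside the model: the test conditions on
the tree you give it. And masking at 0.5 discards real signal on very
long branches, where most sites fail the confidence cutoff; that is the
intended conservative trade-off.
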