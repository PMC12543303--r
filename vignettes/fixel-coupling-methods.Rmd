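---
title: "Fixel-based structure-function coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixel-based structure-function coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixelcouple)
```

## The scientific problem

White-matter structural connectivity (SC) constrains how brain regions can
communicate; resting-state functional connectivity (FC) records how they
actually co-activate. Their agreement — *structure-function coupling* — is a
distinct feature of brain-network organization that changes along the
neurocognitive aging spectrum (cognitively normal aging, mild cognitive
impairment, Alzheimer's disease). Most coupling work weights SC by streamline
counts from tensor-based tractography, which averages away crossing-fiber
information. Fixel-based analysis resolves distinct fiber populations
("fixels") within a voxel and yields edge weights with a physical reading:
fiber density (FD, microstructure, proportional to intra-axonal volume), the
log fiber-bundle cross-section (log(FbC), macrostructure), and their
combination (FDC). This package implements the statistical side of a
fixel-based coupling study: given per-subject SC matrices in those four
weightings and a signed Fisher-Z FC matrix on a common 119-node atlas
(100 cortical parcels in seven resting-state networks plus 19 subcortical
parcels), it quantifies coupling at four levels, tests group differences with
permutation nulls, and relates default-mode-network (DMN) coupling to
cognition.

Everything upstream of the connectome — fMRI preprocessing, fibre orientation
modeling, tractography, fixel template construction — is out of scope; the
package starts from matrices on disk or from its own synthetic cohorts.

## Connectome representation

An edge either exists (it received at least one streamline) or is *missing*;
missingness is carried as an explicit mask, never as a sentinel zero, because
a zero would silently corrupt means and correlations. A fixel edge weight is
the mean of the *nonzero* fixel values in the edge's fixel mask multiplied by
the streamline count of the edge, so two edges with the same average fixel
metric but different streamline support are weighted differently; an edge
whose fixel values are all zero has no usable support and is marked missing.
Matrices are symmetric with the diagonal excluded, and vectorize to the
row-major upper triangle — 7,021 edge positions for 119 nodes. FC is fully
connected and signed: negative correlations are kept as such, with
positive-only and negative-only variants available as sensitivity analyses
(edges with FC exactly 0 belong to neither signed variant).

Node *strength* is the plain signed sum of present incident edge weights (no
absolute value, no degree normalization). FC strength deliberately uses all
FC edges, not only those with SC support, so it reflects the node's full
functional embedding; the same whole-brain convention is applied to SC
strengths for symmetry.

## Coupling at four levels

Let $s_i$ and $f_i$ be subject $i$'s SC and FC edge vectors restricted to
edges present in SC (only direct connections are kept; no communication
models).

* **Subject-overall**: $r_i = \mathrm{cor}(s_i, f_i)$ across edges, optionally
  restricted to within-DMN or within-network edges.
* **Group-average**: edge values are averaged across a group's subjects
  (pairwise deletion per edge) and the two mean vectors are correlated — one
  $r$ per group, compared between groups with Fisher's r-to-Z using the edge
  count as the effective $n$ (the sampling unit of that correlation is the
  edge; the subject count is also reported).
* **Edge-wise**: for each edge, SC and FC values are correlated *across* a
  group's subjects — one $r$ per edge per group.
* **Node-wise**: the same across-subject correlation applied to nodal
  strengths — one $r$ per node per group.

Edge/node correlations computed from fewer than 10 subjects are reported as
missing: the analysis protocol is silent on a minimum, but tiny-$n$
correlations are numerically unstable and would dominate permutation tails.
Subject-level correlations require at least 3 usable pairs.

## Group inference

Group differences in edge- or node-wise coupling are tested by subtracting
the two groups' per-key $r$ values and comparing the difference to a
permutation null: the pooled subjects are reassigned to pseudo-groups of the
original sizes, keeping each subject's SC and FC paired, and the difference
is recomputed (5,000 permutations by default). The permutation unit is the
participant — a label exchange — because shuffling SC and FC independently
would break subject pairing and test a different null. Each key is compared
with its own null distribution (the protocol applies FDR afterwards, which
presupposes per-key p values) using the add-one estimator
$p = (1 + \#\{|d^\ast| \ge |d|\})/(1 + B)$, which cannot return zero and is
valid under exchangeability. Significance is flagged at $p < 0.01/4 =
0.0025$, Bonferroni-corrected over the four SC metrics, and
Benjamini-Hochberg FDR is applied across all edges of all group comparisons
pooled.

Subject-level coupling is compared across groups with a linear model
controlling for age and sex; the group effect is the partial F test and post
hoc comparisons are contrasts of estimated marginal means (covariates at
their means, sex averaged over) on the model's residual degrees of freedom —
387 for 392 subjects, three groups and two covariates. Demographics use a
Pearson chi-square with adjusted standardized residuals and one-way ANOVAs;
cognitive outcomes use one-way ANOVA with Tukey HSD plus pairwise Wilcoxon
rank-sum tests under FDR.

## Memory composite and cognition models

Verbal memory is summarized by a one-factor confirmatory factor analysis of
the four RAVLT scores (learning, immediate, 30-minute delay, recognition),
min-max scaled, fitted by maximum likelihood with the latent variance fixed
to 1 and all four loadings free — that identification makes loadings directly
comparable and parameter-recovery tests clean. The model has df = 2 (10
moments, 8 parameters); fit is reported as $\chi^2 = (n-1)F_{ML}$, CFI
against the independence baseline, RMSEA $= \sqrt{\max(0, (\chi^2 -
df)/(df\,(n-1)))}$ with a 90% noncentral interval, and SRMR. Factor scores
use the regression method and are min-max scaled to $[0,1]$, with the
scaling range recorded so held-out scoring is reproducible. The CFA is
complete-case (the emulated study conditions give 349 completers of 392).
Residual variances are optimized on the log scale; a solution at that
boundary indicates a Heywood tendency and is flagged with a warning rather
than silently clipped. Standard ML is used throughout; robust variants are
not implemented.

Coupling-on-cognition models regress MMSE and the memory composite on the
two subject-level DMN coupling measures (within-DMN edges; DMN nodal
strengths), controlling age, sex and intracranial volume, one model per SC
modality. The response and continuous predictors are z-scored so
coefficients are standardized betas. Collinearity is checked with VIF (> 10),
tolerance (< 0.02) and pairwise predictor correlations (> 0.8). The FDR
family for these models is the 16 coupling-term coefficients (4 modalities
x 2 outcomes x 2 terms); covariates are excluded from the family.

## What the synthetic generator emulates

The generator produces cohorts whose *statistical* structure matches the
analysis assumptions, with every planted parameter recorded as ground truth:

* **Group sizes and demographics** — 225 CN, 142 MCI, 25 AD; group-specific
  age means (72.3/73.9/74.7 years, SD 8), the female excess in CN
  (137/225 vs 63/142 and 7/25), and ICV with a male shift, so demographic
  tests exercise realistic imbalance.
* **SC sparsity** — one shared fixel-SC mask of 5,922 of 7,021 edges, because
  fixel edges derive from a single template tractogram; per-subject
  streamline-SC masks (subjects were tracked individually) with mean 5,838
  edges and across-subject jitter in density. The source protocol counts
  11,676 streamline edges (SD 1,093) in the full directed matrix; halving
  gives the undirected values used here. Bernoulli sampling alone would give
  an across-subject SD of about 31 edges, so the observed spread is emulated
  by jittering each subject's density.
* **Edge weights** — per-edge cohort-level FD and FbC means with log-normal
  subject noise (sigma 0.3); FDC is FD x FbC elementwise before log and
  streamline weighting, and every fixel weight follows the mean-nonzero x
  streamline-count construction. Log-normal forms are a modeling choice —
  the source protocol reports no distributional facts beyond sparsity — and
  are recorded in the ground-truth output, not claimed as properties of real
  data.
* **Within-subject coupling** — FC on SC-present edges is built as
  $\rho\,z(s_i) + \sqrt{1-\rho^2}\,\varepsilon$ against one reference
  modality (FD, the whole-connectome anchor $r = 0.24$ in every group).
  Because z-scoring is linear, the subject's Pearson coupling equals $\rho$
  in expectation *exactly*, regardless of the skewed SC distribution. One
  exact $\rho$ cannot be planted against four SC weightings simultaneously;
  the other fixel modalities inherit correlated coupling through the shared
  per-edge means and streamline counts.
* **Shared edge profile** — the non-coupled FC component mixes a
  cross-subject edge profile with subject noise (variance share 0.9). The
  share is chosen so the *group-average* coupling also equals the planted
  $\rho$: averaging over subjects shrinks the coupled component by the
  subject-noise attenuation factor, and a profile share equal to the square
  of that factor cancels the shrinkage.
* **Planted group effects** — designated within-DMN edges carry a
  cross-subject slope (standardized analytically from the log-normal
  moments, so no subject sees another's data) that differs by group; these
  drive edge-wise differences and are the recovery target for the
  permutation machinery.
* **Cognition** — a latent memory factor with group shifts (CN > MCI > AD)
  plus a standardized effect (0.3) of the subject's DMN nodal coupling;
  four RAVLT indicators load at (.9, .9, .8, .7); MMSE is linear in the
  latent and group, integer-rounded and clipped to 0-30. Missingness
  reproduces 349 RAVLT completers (203/127/19) and one missing MMSE.

The generator does **not** simulate BOLD time series, tractography, fixel
images, spatial autocorrelation on the cortical sheet, site/scanner effects,
or head motion. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated under the stated statistical model —
not that real acquisition artifacts are handled.

## Numerical choices and degenerate inputs

* Symmetry tolerance on read: 1e-8 relative — files written by this package
  are exactly symmetric; the tolerance only guards foreign files. Asymmetric
  masks or weights beyond tolerance are errors, not warnings.
* Node ids are 0-based internally (atlas files indexed from 1 can declare an
  offset on read); matrix rows map to `node_id + 1`.
* FC matrices are stored already Fisher-Z transformed; no r-to-z conversion
  happens on load, and the generator produces that scale directly
  (|FC| mostly < 1.5).
* Zero-variance edges/nodes and keys below the minimum subject count give
  `NA` coupling; permutation p values for such keys are `NA` and excluded
  from pooled FDR.
* The CFA optimizer is BFGS with an analytic gradient of the ML discrepancy;
  the sign indeterminacy of the loading vector is resolved toward positive
  loadings.
* Exhaustive permutation enumeration (used on toy cohorts) includes the
  identity assignment, giving the exact conditional p.

## Validation problem sizes

The test suite validates each estimator against independent oracles
(covariance-formula correlations, exhaustive strength sums, normal-equations
least squares, textbook Tukey-Kramer p values, full permutation enumeration)
on fixtures of at most 10 nodes, and runs recovery checks at moderate sizes:
permutation calibration on two groups of 50 with 200 edges and 500
permutations; planted-slope recovery at 200 subjects per group on a 40-node
atlas; CFA recovery at n = 349; ANCOVA degrees of freedom on the full
392-subject cohort at the default 119-node atlas. These sizes give stable
Monte-Carlo behavior while keeping the default validation run short.

## Known limitations

* Edge-wise and node-wise coupling are cross-sectional constructions — one
  correlation per group — because each subject contributes a single (SC, FC)
  pair per edge; individual edge-specific coupling would need longitudinal
  or time-resolved data.
* The Fisher r-to-Z comparison of group-average couplings treats edges as
  independent observations; spatially autocorrelated connectomes violate
  this, which is one reason the permutation tests, not the Fisher
  comparisons, carry the main inferential weight.
* The whole-brain strength convention for subject-level DMN node coupling is
  stated for FC only in the source protocol and extended to SC by symmetry;
  both conventions are trivial to compute from `cohort_strengths()` if a
  user prefers DMN-internal strengths.
* Streamline-SC density above the fixel mask is emulated, but the identity
  of which edges exist per subject is random rather than anatomically
  structured.
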