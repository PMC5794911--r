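---
title: "Persistent-homology analysis of band-power connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent-homology analysis of band-power connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phnet)
```

## The problem and the model

Resting-state electrophysiological studies (MEG/EEG) summarise each subject's
brain activity as a trial-by-ROI matrix of band power: `n` epochs by `p`
cortical regions, one matrix per subject and frequency band. Conventional
graph analyses then threshold a connectivity matrix at an arbitrary level to
obtain a binary network; the threshold choice is operator-dependent and
discards information. phnet implements the threshold-free alternative:
persistent homology of the weighted network, tracked across *all* thresholds.

**Distance.** For ROI columns $x_i, x_j$ across trials, connectivity is the
Pearson correlation $r_{ij}$ and the network distance is

$$c(x_i, x_j) = 1 - \max(r_{ij}, 0).$$

Negative correlations are clipped at zero so the distance saturates at 1.
"One minus positive correlation" does not prescribe behaviour for $r < 0$;
clipping (rather than taking $|r|$ or $1 - r$) keeps anticorrelated regions
maximally distant without letting them look connected, and is recorded here
as a deliberate design choice. The distance is applied to the power values as
given — any variance-stabilising transform is the caller's responsibility —
and constant columns raise an error naming the ROI rather than imputing a
value, so degenerate simulations cannot pass silently.

**Filtration.** Thresholding the distance matrix at $\varepsilon$ connects
every pair with $c \le \varepsilon$; increasing $\varepsilon$ yields a nested
sequence of binary graphs. The zeroth Betti number $N(\varepsilon)$ — the
number of connected components — is piecewise constant, right-continuous and
non-increasing, and is fully determined by the minimum spanning tree: the
merge events are exactly the MST edge weights. phnet computes everything in
one Kruskal/union-find sweep (edges sorted by weight, then lexicographically
by $(i,j)$ for determinism):

* the **barcode**: merge events $(\varepsilon_k, N_k)$ with
  $N_k = p - k$;
* the **single-linkage dendrogram**: the same merges as a hierarchical
  clustering;
* the **single-linkage matrix (SLM)**: entry $(i,j)$ is the single-linkage
  distance (SLD), the smallest $\varepsilon$ at which $i$ and $j$ join one
  component. This equals the minimax path distance — the largest edge on the
  MST path between $i$ and $j$ — and makes the SLM an ultrametric with
  $\mathrm{SLM} \le c$ entrywise (equality exactly when the input is already
  ultrametric). Longer SLD = later coupling = weaker connectivity.

Tie-breaking among equal-weight edges can change the MST and the dendrogram
*topology*, but the barcode and the SLM are invariant; only heights are
contractual, and the tests check this under permutation of node labels.

**Barcode slope.** Global connectivity is summarised by the ordinary
least-squares slope of $N$ (response) regressed on $\varepsilon$
(predictor), restricted to merge events whose component count lies in a
closed window, by default 11–66 (suited to 76-node cortical networks, where
the barcode is close to linear in that range). A more negative slope means
faster coupling, i.e. stronger global connectivity. Two choices here were
genuinely open and are fixed as follows:

* *Orientation*: $N$ on $\varepsilon$, matching how barcodes are plotted
  (components against filtration value); the inverse regression would give a
  different number.
* *Points*: the merge events themselves enter the regression. A uniform-grid
  sampling of the step function is exposed via the `grid` argument but off
  by default; on an exactly linear barcode both give the same slope.
* Slopes are computed **per subject** (one barcode per subject), because the
  downstream two-sample t test needs per-subject values; a group-mean-barcode
  variant is not implemented.

Degenerate windows raise errors: fewer than two in-window events, or
in-window events with zero variance in $\varepsilon$.

## Group inference

* **Slopes**: two-sided independent-samples t test, pooled-variance Student
  form by default ("independent t test" names no Welch correction; Welch is
  available via `var_equal = FALSE`). Identical constant groups error out on
  zero pooled variance.
* **SLM map**: per-edge permutation test. The observed statistic is the
  difference of group mean SLDs (group 2 minus group 1). The null is built by
  randomly reassigning *whole subjects* to pseudo-groups of the original
  sizes: reassigning subjects preserves the strong within-subject dependence
  between edges, which an entry-wise shuffle would destroy (the entry-wise
  variant is available as `method = "edgewise"` for sensitivity analysis
  only). The null is kept per edge, not pooled across edges, matching the
  per-edge null hypothesis that SLDs do not differ between the groups.
  P-values use the add-one estimator $(1 + \#\{|T^\ast| \ge |T|\})/(B + 1)$,
  which is valid and never exactly zero; with 3-vs-3 groups the smallest
  attainable two-sided p is therefore bounded below, and the tests verify
  Monte-Carlo agreement with the exhaustive 20-relabelling null. Default
  $B = 10000$ and uncorrected edge-wise $\alpha = 0.001$; both configurable.
  Note that with small groups the attainable minimum p (about
  $2/\binom{n}{n_2}$) can exceed 0.001, so small pilot cohorts need a larger
  $\alpha$.
* **Clinical correlations**: Pearson correlation between each selected
  edge's SLD and each covariate across subjects (typically the patient
  group), two-sided, with Bonferroni control at `alpha / family_size`. The
  family size is a required explicit argument — e.g. 6 edges x 6 clinical
  measures gives $0.05/36 \approx 0.0014$ — because inferring it silently
  from whatever happens to be significant would change the guarantee.
  Degenerate records (constant SLD or covariate) are returned flagged with
  `r = NA` rather than dropped.

A numerical note: the Monte-Carlo tie comparison $|T^\ast| \ge |T|$ is
evaluated with a $10^{-10}$ slack. Exact relabelling ties (the identity
assignment and its mirror) reproduce the observed statistic through a
different floating-point summation order; without the slack they would be
counted haphazardly, which biases p downward. Erring toward counting keeps
the estimator conservative and exactly reproduces the exhaustive null.

## The synthetic-cohort generator

No public band-power cohorts accompany this kind of study, so validation
runs on synthetic cohorts with known ground truth ([cohort_spec()],
[generate_cohort()]):

* **Latent structure**: a block (community) correlation matrix — `r_within`
  inside disjoint ROI blocks, `r_between` elsewhere, unit diagonal.
* **Planted effects**: group 2's latent correlation on chosen edges is
  multiplied by `1 - attenuation`. Attenuating a single edge inside a tight
  block can make the matrix non-positive-semi-definite (for a
  compound-symmetry block of size $m$ with correlation $\rho$ and planted
  entry $c$, feasibility requires
  $(1 + c)(1 + (m-3)\rho) \ge 2\rho^2(m-2)$); the generator then repairs by
  clipping negative eigenvalues at zero and rescaling to a unit diagonal.
  The repair is always reported (message + attribute) because it pulls the
  planted entry up and mildly perturbs edges incident to the planted nodes;
  the planted edge remains the weakest, but tests assert *monotone recovery
  and sign*, never exact equality of the planted value.
* **Power values**: latent multivariate-normal trials (symmetric eigen
  square root, so singular correlations are allowed), plus independent
  Gaussian noise of sd `noise_sd`, then exponentiated. Log-normality
  guarantees positivity like real band power; it also means the sample
  Pearson correlation of power is an attenuated monotone transform of the
  latent correlation (for unit-variance latents,
  $r_{\mathrm{power}} = (e^{\rho} - 1)/(e - 1)$), which the tests take into
  account.
* **Clinical coupling**: each group-2 subject draws an effect scalar
  $e \sim U(\texttt{effect\_range})$ (default $U(0,1)$) scaling the planted
  attenuation — a crude severity dial — and every subject's covariate is
  `U(baseline) + coefficient * e`. The default baseline for the bundled
  studies is 0.25–10 years, matching a typical chronic-pain eligibility
  window (at least 3 months, under 10 years).
* **Determinism**: the spec seed drives per-subject sub-seeds; identical
  specs reproduce cohorts bit for bit.

What the generator does *not* emulate: raw sensor time series, source
reconstruction, frequency-band structure (each cohort is one band),
heavy-tailed artifacts, or spatial autocorrelation of real parcellations.
Passing tests therefore demonstrate that the statistical machinery recovers
known effects under a faithful log-normal correlation model — not that any
particular clinical finding replicates.

## The bundled validation studies

Three study functions exercise the full generator-to-inference path; the
test suite and `scripts/acceptance.R` both run them at these sizes, chosen
so each study completes in well under a minute on one core while leaving
enough replicates for the binomial checks to have teeth:

* `calibration_study()`: 200 null cohorts (identical distributions in both
  groups: two 5-ROI blocks at `r_within = 0.6`, background 0.2, 20 ROIs, 10
  subjects/group, 100 trials, 500 permutations). The edge-wise rejection
  rate at $\alpha = 0.05$ should be 0.05 and the slope t test should reject
  in about 5% of cohorts. One statistical subtlety: edge-wise rejections
  within a cohort are strongly positively dependent (edges share subjects,
  and SLDs share MST structure; the between-cohort standard deviation of the
  per-cohort rejection rate is roughly eight times the independent-binomial
  value), so the calibration check treats the *cohort* as the independent
  unit and compares the pooled rate against 0.05 using the empirical
  between-cohort standard error; the slope test, one rejection per cohort,
  uses an exact binomial band.
* `recovery_study()`: 100 cohorts with one edge attenuated by 0.9 inside a
  6-ROI block at `r_within = 0.8` (15 subjects/group, 200 trials, 1000
  permutations). The planted edge should show a longer mean SLD in the
  attenuated group in at least 95 cohorts and attain the smallest p in the
  majority (ties at the attainable minimum p count as attaining it). The
  single small block is a deliberate power choice: the SLD of a planted edge
  is capped by its bypass paths, so large blocks dilute the observable
  effect; the generator's own documentation states that these defaults are
  set for test power, not clinical realism.
* `clinical_study()`: 100 cohorts with duration coupled to the planted
  effect (30 patients, coefficient 8 on a 0.25–2-year baseline so the
  coupling dominates the baseline spread); the planted edge's SLD–duration
  correlation should be positive in at least 90 of them.

## Known limitations

* Only $\beta_0$ (connected components) is tracked; no higher-order
  homology, and no conventional graph metrics (path length, clustering).
* Amplitude-based correlation only; phase-synchronisation connectivity is
  out of scope.
* The component-count window 11–66 is data-derived in origin; for networks
  far from 76 nodes it must be set explicitly (the pipeline exposes it).
* Monte-Carlo permutation p-values are invariant to subject order only up
  to resampling noise; observed statistics and the exhaustive null are
  exactly invariant.
* The bundled 76-ROI table is a reconstruction from standard AAL cortical
  labels with indicative network assignments, shipped for labelling
  convenience, not a study-specific atlas.
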