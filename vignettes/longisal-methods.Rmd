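---
title: "Models and methods in longisal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in longisal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longisal)
```

`longisal` analyzes longitudinal 16S microbiome studies in which subjects
(mice in the motivating design) are sampled repeatedly on a fixed week
grid — by default baseline and weeks 4, 8, 12, 16 and 22 — and carry
subject-level covariates: genotype (`WT` / `KO`), sex, and an endpoint
histopathology diagnosis (`ED/CIS` precancer vs `OSCC` carcinoma) applied
as a time-constant label.  This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices the
implementation makes.

## Compositional preprocessing

16S counts are compositional: only relative information is meaningful.
The package therefore works on the centered log-ratio (CLR) scale,
`clr(x)_i = log x_i - mean(log x)`, after two preparatory steps:

* **Prevalence filtering.** OTUs present (count > 0) in fewer than a
  configurable fraction of all samples are removed *first*; the rule is a
  strict "below", so a taxon exactly at the threshold is retained.  The
  differential-abundance stage defaults to 5%, the network stage to 10%.
* **Half-minimum zero replacement.** Within each sample, zeros among the
  retained OTUs are replaced by half the smallest nonzero count of that
  sample.  Because the replacement scales with the sample, the CLR values
  are invariant to per-sample rescaling of the counts.

By default the CLR input to the mixed model is computed on unrarefied
counts: zero replacement plus CLR already removes library-size effects,
whereas rarefaction discards reads.  Rarefaction (single seeded draw per
sample, without replacement; default depth 9484 reads) is applied for the
diversity and dissimilarity analyses, which operate on counts; a
configuration switch (`clr_on_rarefied`) runs the CLR on rarefied counts
instead for users who want one common table.  Whether the prevalence
filter should be computed before or after rarefaction is not determined
by the analyses this package mirrors; `longisal` computes it on the
table it is given, and the pipeline computes it before rarefaction.

## Ecology statistics

Community dissimilarity uses the Yue–Clayton theta measure on relative
abundances, `d(p, q) = 1 - sum(p q) / (sum(p^2) + sum(q^2) - sum(p q))`,
which is 0 for identical compositions and 1 for disjoint supports.
Group structure is tested by permutation AMOVA: the total sum of squared
pairwise distances is partitioned into among- and within-group terms
(within-group pair sums divided by group size), a pseudo-F ratio is
formed, and group labels are permuted wholesale.  The p-value uses the
add-one estimator `(#{F* >= F} + 1) / (B + 1)`, which cannot return an
exact zero.  Alpha diversity (inverse Simpson, observed richness) is
compared by pooled-variance t tests.  NMDS is deliberately thin plumbing
around `vegan::monoMDS` (classical-scaling start plus seeded random
restarts) since ordination here is a visualization device.

## The locally sparse varying coefficient mixed model

For one OTU with CLR abundance `y_ij` of mouse `i` at week `t_j`,

```
y_ij = sum_k x_ik * beta_k(t_j) + b_i + e_ij,
b_i ~ N(0, sigma_b^2),  e_ij ~ N(0, sigma_e^2),
```

a subject random intercept that induces compound symmetry: equal
correlation `sigma_b^2 / (sigma_b^2 + sigma_e^2)` between any two visits
of the same mouse.  Three variants are available: the full model
(intercept, KO, OSCC, KO:OSCC, Female — five coefficient functions), a
genotype-only and a diagnosis-only simplification (three functions each).
Reference levels are WT, ED/CIS and Male.  Mice contribute whatever
visits they have (likelihood-based handling of missingness, no
imputation); mice lacking a diagnosis label are rejected rather than
imputed.

**Representation.** Coefficient functions are represented pointwise on
the observed 6-week grid rather than in a spline basis: estimates and
significance are reported per observed week, and a 6-point grid leaves a
spline under-determined anyway.  Smoothness is encouraged by a
squared-difference penalty `lambda_smooth * sum_j (beta_k(t_{j+1}) -
beta_k(t_j))^2` on every coefficient function.

**Local sparsity.** Each (coefficient, week) value carries an adaptive
lasso penalty `lambda_sparsity * w_kj |beta_k(t_j)|`, with weights
`w_kj = 1 / |beta_tilde_kj|` from the unpenalized fit (capped at 1e6) and
the intercept unpenalized.  Proximal-gradient (FISTA) steps soft-threshold
the coefficients, producing *exact* zeros on sub-regions of the grid —
the locally sparse behavior the model is named for.

**Optimization.** The fit alternates FISTA updates of the coefficients
(given variance components, the loss is a generalized-least-squares
quadratic assembled from per-mouse sufficient statistics via the Woodbury
identity) with EM updates of `(sigma_b, sigma_e)` given the coefficients,
until the relative change of the penalized objective falls below 1e-8 or
100 alternations.  Plain maximum likelihood is used for the variance
components; at the cohort sizes involved (60+ mice) the REML correction
is negligible, and simulation shows both components recovered within 15%
at 200 mice.  When `lambda_sparsity = 0` the coefficient step is a direct
solve, and with `sigma_b` fixed at zero the fit reproduces per-week OLS
to numerical precision — the implementation's oracle check.

**Relaxed estimates.** Soft-thresholding shrinks retained coefficients as
well as zeroing others.  The reported coefficient matrix is therefore a
*relaxed* refit: unpenalized GLS restricted to the selected support, a
standard companion to the adaptive lasso that removes shrinkage bias
while keeping the exact zeros.  The penalized coefficients are kept
alongside (`beta_penalized`) because the bootstrap characterizes the
penalized estimator.

**Penalty selection.** The extended BIC,
`EBIC = -2 loglik + df log(N) + 2 gamma df log(P)` with `df` the number
of nonzero coefficient values, `N` the observations and `P` the number of
coefficient values, is evaluated on a grid — by default 20 log-spaced
sparsity penalties below the data-derived maximum and smoothness
penalties `{0, 1, 4.64, 21.5, 100}` — with `gamma = 0.5` (`gamma = 0`
recovers BIC).  Ties go to the sparser model.

**Simultaneous bands.** Inference uses a cluster bootstrap: mice are
resampled with replacement and the model refit at the selected penalty
and weights (the penalty is *not* re-selected per replicate, for
tractability).  Because each resampled mouse is its own cluster, a refit
only reweights the per-mouse sufficient statistics, making B = 1000 the
default (tests and examples use B = 200).  For each contrast — in the
full model, KO−WT within each diagnosis and OSCC−ED/CIS within each
genotype, obtained as sums of coefficient functions — the sup-t band is
`estimate ± q* SE_boot(t)` with `q*` the 95th percentile of the bootstrap
supremum of standardized deviations.  Weeks with a degenerate (zero)
bootstrap SE collapse to the point estimate with a warning.  Bands are
simultaneous across weeks within a contrast, not across contrasts or
OTUs; no cross-OTU multiplicity correction is applied beyond the per-OTU
band, mirroring per-taxon reporting practice.  An OTU is "reported" when
at least one (contrast, week) cell is significant.

Simulation at the study's design conditions (60 mice, effect +2 residual
SDs on KO at weeks 12–16 only, EBIC-selected penalty, B = 200) recovers
the exact zero/nonzero week pattern with week-16 significance in over 90%
of replicates, keeps the familywise any-week error at or below nominal on
null cohorts, and the sup-t band holds ≥ 0.92 simultaneous coverage at
nominal 0.95 over 500 Gaussian replicates.  These numbers are recomputed
by the test suite and `scripts/acceptance.R`, not quoted from elsewhere.

## Trajectory fPCA and diagnosis prediction

For each OTU, every mouse's CLR values form a 6-vector over the week
grid, possibly with missing entries; each trajectory is centered by its
observed-entry mean so only its *shape* remains.  Functional PCA is then
an eigendecomposition of the 6x6 trajectory covariance:

* complete data: the classical sample covariance — scores equal PCA
  scores exactly;
* missing entries: the covariance is estimated from pairwise-complete
  products (error if a week pair has fewer than two complete pairs),
  projected to positive semidefiniteness by clipping negative eigenvalues
  at zero, and scores are best linear predictions given the observed
  entries, which reduce to the classical scores for complete rows.

Eigenfunctions are signed so their largest-magnitude entry is positive,
making "positive fPC1" reproducible across runs.  The number of retained
components is the smallest count explaining 99% of variance.  fPCA is
fitted per OTU (Fig.-style shared shapes can be obtained by pooling, but
per-OTU fitting is the default since shapes need not be shared across
taxa).

The retained per-OTU scores become features in two L1-penalized logistic
regressions of diagnosis — one per genotype — with the regularization
chosen by stratified 5-fold cross-validation on binomial deviance, plain
minimum (no one-standard-error rule), seeded.  No class weighting is
applied despite the usual ED/CIS vs OSCC imbalance; strata where a class
has fewer than three mice are skipped with a warning.  "Predictive" OTUs
are those with any nonzero coefficient at the selected penalty.  Group
mean scores per (otu, component, genotype, diagnosis) are reported with a
shape-matching report: trend labels ("rise between weeks 8 and 16",
"dip bottoming near week 12") are attached only when the fitted
eigenfunction matches the reference shape (|cosine| ≥ 0.8).

## Conditional-dependence networks

Networks are estimated at the family or genus level per genotype and
week period (0–4, 8–12, 16–22), after a 10% prevalence filter within the
pooled period.  The pipeline is an in-package re-implementation of the
SPRING-style approach, kept small enough to be fully testable:

1. **Modified CLR.** Nonzero relative abundances are log-transformed and
   centered per sample; exact zeros stay zero; one *global* constant then
   shifts all nonzero values positive.  A global (not per-sample) shift
   is essential: a per-sample shift anchors every sample at its own
   minimum taxon, which destroys cross-sample comparability for rare taxa
   (in simulation it inverted a planted rho = 0.9 association).
2. **Confounder adjustment.** The Female indicator is regressed out of
   each taxon's nonzero values (zeros preserved so the truncation
   structure survives).  Sex is the one subject-level confounder present
   in every design cell; this choice is flagged in the report.
3. **Latent correlation.** Kendall's tau_a (ties from zeros included in
   the denominator) is mapped to the latent Pearson correlation of a
   truncated Gaussian copula through the bridge function, evaluated with
   4-dimensional normal CDFs and inverted numerically (tolerance 1e-6).
   Zero-free pairs use the closed form `sin(pi tau / 2)`.  The estimation
   path uses a session-cached interpolation table over (rho, zero
   proportions) for speed; the exact root-finding path is retained and
   verified to invert the forward bridge to 1e-4 across rho in [-0.9,
   0.9] and zero proportions up to 0.6.  The matrix is PSD-projected with
   unit diagonal.
4. **Neighborhood selection.** Nodewise lasso regressions on the
   correlation matrix (solved exactly via `glmnet` on its Cholesky
   factor), OR-rule edges, signs from the averaged coefficients.
5. **StARS tuning.** Edge-selection instability `mean(2 p (1 - p))` over
   subsamples without replacement (20 subsamples, size
   `min(floor(10 sqrt(n)), n - 1)`); the instability curve is monotonized
   toward denser graphs and the densest graph with instability ≤ 0.05 is
   selected.  If nothing is stable, the densest penalty is returned with
   a warning.

Edges are compared across the six genotype x period cells and
partitioned into *core* (all cells), *genotype-stable* (all periods of
exactly one genotype) and *period-specific* classes.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which every recovery property is verified.  Latent per-sample log
abundance is `baseline + sum(active effects) + mouse intercept + visit
noise`; counts are multinomial draws from the softmax of the latent
vector at a Poisson library size (default mean 20000 reads, so that
rarefaction to 9484 keeps essentially all samples), giving exact row
sums and — through the latent Gaussian noise — overdispersion relative
to a plain multinomial.  Defaults mirror the motivating cohort: arms
22/13/20/21 (WT/KO x M/F, 76 mice), weeks {0, 4, 8, 12, 16, 22},
~200 OTUs, `sigma_b = 0.7`, `sigma_e = 1` (intra-mouse correlation
0.33), per-mouse-x-OTU structural zeros at rate 0.3, and per-genotype
OSCC probabilities 0.35 (WT) / 0.65 (KO).  The published source reports
arm sizes and the week grid; noise levels, zero inflation, dropout and
the diagnosis split are not reported there, so these defaults are this
package's choices of a realistic murine oral-microbiome cohort and are
all overridable.  Dropout is missing completely at random (no mechanism
is described for the real cohort) with visits redrawn until every mouse
keeps at least two.  Two RNG streams separate cohort structure
(assignments, taxonomy, baseline, visit mask) from measurement (random
effects, noise, structural zeros, depths, counts), so injecting an
effect never changes which mice exist or when they were sampled.
Effects are additive on the log scale — matching the CLR-scale additivity
the downstream model assumes — may be zero on a strict subset of weeks
(the locally sparse signal), and may be conditioned on a subgroup (e.g.
present only in KO mice).  Planted latent correlations between taxon
pairs provide ground truth for the network stage.

What the generator does *not* emulate: read-level error, chimeras,
taxonomic misclassification, phylogenetic signal, time-varying diagnosis,
or informative dropout.  Passing recovery tests therefore demonstrates
correctness of the estimators under the stated statistical model, not
robustness to those real-data phenomena.

### Simulation sizes used by tests and the acceptance script

Recovery experiments run at the conditions stated above unless a
property fixes its own size: LSVCMM local-sparsity recovery uses 60 mice
and 50 OTUs with flat baselines and no structural zeros (the property
under test is the model's recovery, not zero-replacement robustness);
band coverage uses 500 Gaussian replicates of 60 mice (the acceptance
script reports a 150-replicate version); AMOVA calibration uses 500
(script: 200) null Dirichlet-multinomial datasets of 20 + 20 samples
with 999 permutations; the fPCA planted-shape experiment uses 21 OTUs
and a Gaussian-bump trajectory signal conditioned on the KO genotype;
chain-graph recovery uses 20 nodes at n = 400.  The script's replicate
counts are smaller than the suite's so that a full rerun stays fast;
each JSON entry records the size actually used.

## Numerical choices and degenerate inputs

* FISTA restarts on non-monotone steps; inner tolerance 1e-10, outer
  1e-8; penalized entries with adaptive weight 1e6 are numerically
  forced to zero at any positive penalty.
* EBIC ties break toward fewer nonzero values; equal-EBIC, equal-df grid
  points keep the first (largest-penalty) fit.
* All-zero samples are an error for single-row transforms, and are
  dropped with a warning (and recorded) by the matrix CLR.
* `mvtnorm`'s quasi-Monte-Carlo CDFs are evaluated under a fixed local
  RNG substate, so latent correlations are bit-reproducible without
  disturbing the caller's RNG.
* Degenerate bootstrap SEs collapse the band to the estimate with a
  warning; a week is then significant only if its estimate is nonzero.
* Every stochastic routine takes an explicit seed, and derived seeds stay
  below 2^31.

## Known limitations

* The penalty structure and band construction follow the published
  description of the method; the companion estimator's unpublished
  internals may differ in detail (basis, weighting, band calibration).
* Bands are simultaneous within (OTU, contrast) only; cross-OTU
  multiplicity is the reader's responsibility.
* The network stage is a simplified re-implementation of the SPRING
  idea, not numerically identical to the released package; its value is
  verified by bridge-inversion accuracy and graph-recovery simulations.
* Lasso-logistic selection with `lambda.min` on small strata is
  optimistic; the permutation-null selection rate is monitored in the
  acceptance checks instead of being corrected analytically.
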