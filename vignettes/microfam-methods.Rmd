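---
title: "Models and methods behind microfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`microfam` packages the statistical workflow of a family-based IBD gut
microbiome study: from raw sample-by-taxon count tables to dysbiosis
scores, community types, co-abundance networks and heritability
estimates. This vignette documents the models, their assumptions, the
tunable parameters, the synthetic-data generator that the test suite
relies on, and the numerical choices that were genuinely open.

## The synthetic family cohort

Real cohorts of this kind live in access-restricted biobanks, so the
package ships a generator whose draws have the statistical structure the
downstream analyses assume. One call produces a pedigree of nuclear
families, a count table, covariates, a biomarker panel, and a truth
record of everything planted.

The generative model, per sample $s$ and taxon $t$:

$$\eta_{st} = b_t + \log(2)\,f_t\,z_s + c_{k(s),t} + g_{it} + \varepsilon_{st}$$

* $b_t$ — baseline log-abundance (default $N(0, 1.8)$, sorted, giving the
  skewed rank-abundance profile typical of stool 16S data);
* $f_t$ — planted log2 fold change in IBD (by default 10% of taxa are up
  in IBD with $f_t \sim U(1, 2.5)$, labelled oral/Enterobacteriaceae-like,
  and 10% down, labelled SCFA-producer-like, matching the oralization /
  SCFA-loss signature of IBD guts);
* $z_s$ — the latent dysbiosis dose, $\max(0,\; \mathbb{1}[\text{IBD}] +
  N(0, 0.25))$: disease shifts are graded rather than binary, and the same
  $z_s$ drives the biomarker panel (ASCA, GP2, calprotectin on a log-linear
  scale; Bristol stool score clamped to 1–7), so biomarkers correlate with
  the realised community shift as they do in patients;
* $c_{k,t}$ — optional community-cluster centroids, scaled so the minimum
  pairwise Aitchison distance between cluster means equals the configured
  separation (the Aitchison distance between softmax-transformed means is
  exactly the Euclidean distance of the centred shifts);
* $g_{it}$ — per-subject genetic effect for heritable taxa, one
  multivariate-normal draw per taxon with covariance
  $\sigma_g^2 A$, where $A$ is the pedigree's additive relationship
  matrix and $\sigma_g^2$ is set from the target $h^2$ relative to the
  compositional noise, so the planted heritability is exact in
  expectation;
* $\varepsilon_{st}$ — compositional noise. Two models are available:
  logistic-normal (default; per-taxon SD 0.7, with the *variance*
  multiplied by `dispersion_inflation_ibd` — default 2 — in IBD samples,
  reproducing the inflated inter-individual dispersion of IBD
  communities) and Dirichlet (compositions drawn around the softmax mean
  with total concentration `dirichlet_concentration`; IBD inflation
  divides the concentration). Optional taxon couplings are injected
  through a Gaussian copula whose correlation graph is user-specified and
  ridge-bent to positive definiteness, which is how co-abundance
  structure is planted for the network stage.

Counts are then negative-binomial around $L_s \,
\mathrm{softmax}(\eta_s)$ with log-normal library sizes (default
meanlog $=\log 2\times10^4$, sdlog 0.35) and per-taxon NB size drawn
log-normally around 3. Diagnoses are i.i.d. per subject (prevalence 0.55,
split 0.54/0.43/0.03 CD/UC/uIBD, the composition typical of a
family-enriched IBD cohort); disease is *not* made familial by default, a
deliberate simplification — where familial disease matters (the
covariate-confounding analysis of heritability) the tests construct it
explicitly.

What the generator does **not** emulate: read-level artifacts (chimeras,
primer bias), longitudinal autocorrelation (additional time points are
independent redraws), taxon phylogeny, and familial clustering of
diagnosis. Passing tests therefore demonstrate statistical correctness of
the machinery under a realistic abundance model, not robustness to every
failure mode of real amplicon data.

## Normalisation and filtering

Size factors are DESeq-style medians of ratios to the geometric-mean
reference, rescaled to geometric mean one; when no taxon is present in
every sample a pseudo-reference over taxa present in at least half the
samples is available behind an explicit flag. The CLR transform uses a
configurable pseudocount (default 0.5, half the smallest nonzero count);
with pseudocount zero it is exactly scale-invariant, which the suite
checks. The prevalence filter keeps taxa with normalised counts of at
least 5 in at least `ceil(0.01 n)` samples; both boundaries are
inclusive, and the same size-factor vector is shared between filtering
and testing so the filter and the tests see the same scale.

## PERMANOVA and dispersion

`permanova()` implements the McArdle–Anderson partition directly: with
$G = -\tfrac12 J D^2 J$, sequential (Type I) sums of squares are traces
of hat-matrix differences against $G$, and pseudo-$F$ uses the residual
mean square. Conditioning terms are fitted first and permutation follows
the Freedman–Lane scheme — the reduced-model residual matrix
$R_Z G R_Z$ is permuted while the conditioning structure stays fixed.
The permutation scheme is a design choice; the conditioning literature
names several, and Freedman–Lane has the best empirical size in
published comparisons. vegan's `adonis2` serves as an independent
cross-check in the tests, never as the implementation. The dispersion
test delegates to vegan's `betadisper`/`permutest` (distance to group
*centroid*, matching the reporting convention of family cohort studies)
with groups of size one excluded.

PCoA negative eigenvalues are handled by dropping imaginary axes
(cmdscale's default), with the Lingoes additive correction behind a
flag; NMDS uses monoMDS with 20 random restarts, 300 iterations and a
stress tolerance of $10^{-7}$.

## Differential abundance

Per taxon, a log-link negative-binomial GLM with `log(size factor)`
offsets and covariates sex + scaled BMI + scaled age (+ time point when
several are present). Dispersion is estimated by maximising the Cox–Reid
adjusted profile likelihood, then shrunk log-normally toward a fitted
$a/\mu + b$ mean–dispersion trend with a weight derived from the spread
of the per-taxon estimates around the trend against the
$\psi'((n-p)/2)$ sampling variance. This is a deliberately simplified,
transparent version of the empirical-Bayes machinery of the established
differential-abundance tools; the contract is behavioural (type-I
calibration, effect recovery), not coefficient-identical output. uIBD
samples participate in fitting but in no pairwise contrast; the
Control-vs-IBD contrast refits with the collapsed two-level factor.
Benjamini–Hochberg runs within each contrast, over converged taxa only.

## The dysbiosis index and its diversity curve

The MD-index follows the log1p-ratio form (disease-set sum over
health-set sum). Two open points were resolved as follows: the abundance
basis is size-factor-normalised counts by default with relative
abundances behind a flag (the ratio is recorded in the output's `basis`
attribute), and no logarithm base is exposed because the ratio of
`log1p` terms is invariant to it. Health-set membership requires
significance in at least one of the CD/UC contrasts (the mirror of the
"either" rule for disease taxa); taxa significant in opposite directions
in the two contrasts are dropped with a warning so the sets stay
disjoint. A zero health-set sum makes the score undefined; such samples
are returned as `NA` and counted, never silently dropped.

The MD–diversity curve is fitted three ways — linear, quadratic,
segmented with one breakpoint — and selected by AIC. The breakpoint is
profiled on a 200-point grid between the 5th and 95th percentiles of the
observed MD values with the continuity constraint built into the hinge
basis. The segmented AIC charges **two** effective parameters for the
breakpoint: one for the parameter itself and one for the selection bias
of profiling over the grid. With a single charged parameter the
maximised hinge improvement (a Davies-type maximum over correlated
1-df tests) selects spurious breakpoints on linear truth far too often;
the two-parameter charge restores the intended exchange rate while
leaving genuine breakpoints (which carry large likelihood gains)
untouched. The profile confidence interval collects grid points within
the $\chi^2$ cutoff of the minimum RSS.

## Combined correlations

Partial correlations use the precision-matrix identity on the joint
correlation matrix of (x, y, covariates); Spearman and Kendall variants
apply the same identity to the rank-based correlation matrices — for
Kendall this is the usual approximation, documented as such. Brown's
method combines the three p-values with the Kost–McDermott cubic
approximation to the covariance of $-2\log p$ terms. The inter-method
correlation matrix is estimated empirically from the $-2\log p$ vectors
across taxa within each phenotype's scan (the dependence between the
three correlation tests on the same data is strong and roughly constant
across taxa); a fixed matrix can be supplied instead.

## Dirichlet-multinomial mixtures

`fit_dmm()` is a weighted-EM fit of a mixture of Dirichlet-multinomial
components (log-Beta form), with Minka-style fixed-point updates for the
component parameters and the best of `n_init` random initialisations
kept. The model is fitted on raw counts: a multinomial-family likelihood
needs counts, so applying it to CLR scores is internally inconsistent.
Because that literal reading exists in the field, a discouraged
`input = "clr_literal"` flag reproduces it by rounding min-shifted CLR
scores.

Model selection minimises the Laplace-approximate negative log evidence.
Three numerical points matter. First, the Hessian is evaluated in the
log-parameter basis (scale-free; each component block is diagonal plus
rank-one, so its determinant follows from the matrix determinant lemma).
Second, the approximation needs a prior: a diffuse $N(0, 3^2)$ prior on
each log-concentration and a uniform prior on the weights supply the
prior-volume term, without which diffuse or nearly-empty components are
spuriously rewarded. Third, taxa effectively absent from a component sit
at the $\alpha \to 0$ boundary and are not free parameters of that
optimum; they are excluded from the Laplace integral, and components
that collapse below an effective size of two samples mark the whole K as
degenerate (skipped in the selection trace with a warning, as are
non-positive-definite Hessian blocks).

## Networks

`infer_network()` CLR-transforms, then runs lasso neighborhood selection
per taxon over a shared log-spaced penalty path (20 values down to 5% of
the maximum absolute correlation), choosing the penalty by stability
selection: 50 subsamples of 80% of the samples (defaults), mean edge
instability $2\bar\xi(1-\bar\xi)$ monotonised from the sparse end, and
the densest penalty with instability at or below 0.05 retained. Edges
use the OR rule with signs from the averaged coefficients.

Centrality null models are degree-preserving double-edge swaps by
default — the natural question for a taxon is whether it is more central
than its degree alone implies. An Erdős–Rényi ensemble is available both
as an explicit option and as the fallback for graphs too sparse to
rewire; the two nulls answer different questions (a planted hub is
extreme against ER and unremarkable against the degree-preserving null,
and the test suite asserts both). The observed centrality can optionally
be averaged over edge subsamples; the default is no subsampling.

Graphlet profiles (the nine connected graphlets on 2–4 nodes) are
computed exactly from adjacency algebra: non-induced path, star, cycle,
paw, diamond and clique counts first, then inversion of the containment
multiplicities to induced counts; a brute-force subset enumerator in the
test suite verifies equality on graphs up to 30 nodes. Natural
connectivity is computed from the full adjacency spectrum via
log-sum-exp. Between-network distances are one minus the Spearman
correlation of normalised graphlet frequency vectors, or one minus the
Jaccard index of edge sets; either feeds `permanova()` directly.

## Heritability

Kinship is computed by the recursive tabular method in topological order
(cycles are detected and reported), and `A = 2\Phi` includes inbreeding
on the diagonal. The mixed model $y = X\beta + g + e$, $g \sim N(0,
\sigma_g^2 A)$, $e \sim N(0, \sigma_e^2 I)$, is fitted by REML after
rotating into the eigenbasis of $A$, which reduces the fit to a
one-dimensional search over the variance ratio; the ML fit is re-run for
AIC comparability between the covariate-free (null) and covariate (full:
age, sex, BMI, IBD status) models, on the identical subject set. When
$A$ is (numerically) proportional to the identity the two variance
components are not identifiable and the fit is flagged instead of
returning an arbitrary split; boundary estimates are clipped with a
flag. A single genetic random effect is used — a household component is a
natural extension but is deliberately not fitted by default. The
per-taxon scan gates taxa at 10% prevalence and works on baseline CLR
abundances.

## Problem sizes used in the checks

The acceptance checks run at sizes chosen to make their statistical
targets meaningful on a single CPU: 200 replicates for each permutation
type-I rate (99 permutations each, n = 30–40), 400 replicates for the NB
Wald rate, a 300-sample cohort for fold-change recovery, n = 500 for
breakpoint recovery, five seeded cohorts of 200 samples for DMM cluster
number recovery (strong separation defined as minimum Aitchison
centroid distance 10 under the Dirichlet composition model with
concentration 50), 100 replicates on 150 four-member families (600
subjects) for $h^2$ recovery, and five networks per condition for the
graphlet-distance PERMANOVA. The exhaustive natural-connectivity
monotonicity check covers all graphs on six labelled nodes in the test
suite (32,768 spectra) and five-node graphs in the acceptance script.

## Known limitations

* The NB dispersion shrinkage is a simplified trend-shrinkage, not a full
  empirical-Bayes posterior; extremely low-count taxa lean on the trend.
* The Kendall partial correlation is an approximation through the
  precision identity, not a true conditional Kendall tau.
* DMM evidence depends on EM finding the dominant optimum; restarts
  mitigate but do not guarantee this, and misspecified (strongly
  logistic-normal) data can still support more components than were
  planted — a property of the model class, not a bug in the fit.
* The segmented fit handles exactly one breakpoint.
* Network inference assumes i.i.d. samples; family structure is ignored
  at that stage (as it is in the field's standard tools).
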