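# microfam

Family-based 16S amplicon cohort studies of inflammatory bowel disease
(IBD) combine several analysis layers that are usually scattered across a
dozen packages and ad-hoc scripts: dysbiosis scoring, differential
abundance with covariates, diversity and community-variability testing,
community typing, biomarker correlation scans, co-abundance network
comparison, and pedigree-based heritability. `microfam` implements that
whole workflow as one composable, tested R package, together with a
synthetic family-cohort generator so every stage can be exercised — and
its statistical behaviour verified — without access-restricted patient
data.

The package is aimed at microbiome statisticians and bioinformaticians
analysing family or case-control gut cohorts with diagnosis labels
(Control / CD / UC / uIBD), serological and faecal biomarkers, and
(optionally) pedigree information.

## The core quantities

* **Modified microbial dysbiosis index.** From baseline differential
  abundance (negative-binomial Wald tests with sex, scaled BMI and scaled
  age as covariates; taxa pre-filtered to a normalised count of at least 5
  in at least 1% of samples), taxa significantly *up* in either CD or UC
  versus controls form the disease set `D`, taxa significantly *down* form
  the health set `H`, and each sample is scored as

  `MD = log1p( Σ_{t∈D} a_t ) / log1p( Σ_{t∈H} a_t )`

  on size-factor-normalised abundances `a`. The MD–diversity relationship
  is then fitted with linear, quadratic and one-breakpoint segmented
  models and selected by AIC.
* **Community ecology.** Chao1 (bias-corrected) and effective Shannon
  diversity; Bray–Curtis/Jaccard dissimilarity; PCoA and NMDS; a
  McArdle–Anderson PERMANOVA with sequential sums of squares, optional
  conditioning terms and Freedman–Lane residual permutation; and the
  multivariate homogeneity-of-dispersions test (distance to group
  centroid).
* **Community types.** Dirichlet-multinomial mixtures fitted by EM, with
  the number of clusters chosen by Laplace-approximate model evidence over
  K = 1–15.
* **Biomarker scans.** Covariate-adjusted partial correlations (Pearson,
  Spearman, Kendall) combined per taxon–phenotype pair with Brown's
  method (Kost–McDermott covariances) and FDR control.
* **Networks.** Sparse neighborhood-selection co-abundance networks on CLR
  data with StARS penalty selection; node centralities with degree-
  preserving permutation nulls; global statistics including natural
  connectivity `ln((1/n) Σ e^{λ_i})`; exact 2–4-node graphlet profiles;
  and graphlet-correlation / edge-sharing distances between networks that
  feed back into PERMANOVA.
* **Heritability.** Pedigree kinship (`A = 2Φ`) by the recursive tabular
  method and single-random-effect REML, reporting `h²` with and without
  fixed covariates plus the AIC difference.

## A worked example

```r
library(microfam)
library(dplyr)

cfg <- simulation_config(n_families = 100, n_taxa = 40, seed = 151)
cohort <- simulate_cohort(cfg)
cohort
#> <microfam_cohort> 393 samples x 40 taxa; 100 families
#>
#> Control      CD      UC    uIBD
#>     188     125      75       5

# differential abundance at baseline, then the dysbiosis index
res <- run_diffabund(cohort$counts, cohort$metadata,
                     contrasts = c("CD_vs_Control", "UC_vs_Control"))
sets <- derive_md_taxa(res)
sets
#> <microfam_mdsets> 4 IBD-associated, 9 control-associated taxa (FDR 0.05)

md <- md_index(cohort$counts, sets)   # warns if any denominator sum is zero
md |>
  inner_join(cohort$metadata, by = "sample_id") |>
  group_by(ibd = diagnosis != "Control") |>
  summarise(mean_md = mean(md, na.rm = TRUE))
#> # A tibble: 2 × 2
#>   ibd   mean_md
#>   <lgl>   <dbl>
#> 1 FALSE    1.32
#> 2 TRUE     1.53

# community variability: IBD samples sit further from their centroid
d <- dissimilarity(cohort$counts)
m <- count_matrix(cohort$counts)
grp <- cohort$metadata$diagnosis[match(rownames(m), cohort$metadata$sample_id)]
dispersion_test(d, ifelse(grp == "Control", "Control", "IBD"),
                n_perm = 199, seed = 1)
#> <microfam_dispersion> F = 29.017 , permutation p = 0.005
```

The numbers shown are what the code prints for this configuration and
seed: the generator plants oral/Enterobacteriaceae-like taxa up in IBD and
short-chain-fatty-acid producers up in controls, so the derived taxon sets
recover them, IBD samples score higher on the MD-index, and the
dispersion test detects the inflated inter-individual variability that the
generator builds into IBD samples.

Every fitted object has `tidy()`/`glance()` methods and most have
`autoplot()` (ordinations, dysbiosis curves, DMM evidence traces,
networks).

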