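# canopyfly

Analysis of butterfly communities along a grassland–savanna–forest
canopy-cover gradient, from raw line-transect observations to
distance-sampling densities, community statistics, ordinations,
permutation inference and canopy-response peak regressions — plus a
synthetic survey generator with full ground truth for estimator-recovery
testing.

## Who this is for

Community ecologists working with repeated line-transect surveys of
butterflies (or comparable insects) across a canopy or other habitat
gradient, who need the full chain from detections to defensible
gradient-level conclusions: where along the gradient richness, abundance
and conservation value peak, which species indicate which habitats, and
whether composition differs among habitat classes.

## The statistics at the core

* **Distance sampling.** Half-normal detection function
  g(x) = exp(−x²/2σ²); effective strip width ESW = ∫₀ʷ g(x) dx
  (= σ√(π/2) untruncated, closed-form MLE σ̂ = √(Σx²/n)); density
  D = 10⁴ n / (2 L · ESW) per survey and species. Sparse species pool
  detections along a genus → family → global ladder; records identified
  only to family are apportioned among same-site-same-day identified
  species.
* **Conservation value index.** CVI = Σ over species with reversed
  NatureServe rank r > 2 of r × density: abundance of vulnerable-or-worse
  species, per survey.
* **Community metrics.** ACE asymptotic richness, individual- and
  site-based species accumulation curves with z-test comparisons at
  common effort (Benjamini–Hochberg adjusted), under-canopy percentages
  by family, inverse-distance plot averaging.
* **Composition.** One-dimensional principal-curve ordination (smoothing
  splines, arc-length scores in [0,1]); Dufrêne–Legendre indicator values
  with permutation tests; predictive co-correspondence analysis with
  leave-one-out cross-validated fit.
* **Inference.** PERMANOVA (quantitative Sørensen / Bray–Curtis by
  default) with pairwise comparisons; Kruskal–Wallis with Dunn's test;
  Spearman correlation; Benjamini–Hochberg adjustment.
* **Gradient peaks.** Cubic vs 3-parameter Gaussian-peak regression of
  each response on canopy cover, winner by AICc, peak restricted to the
  observed canopy range; rank-averaged composite of richness, density and
  CVI; Moran spatial eigenvectors (SEVM) for spatial filtering.

## Worked example

Simulate a full survey campaign (25 sites × 21 rounds, 60 species with
Gaussian canopy niches), run the pipeline, and locate the canopy peaks:

```r
library(canopyfly)

cfg <- simulation_config(rng_seed = 1)
sim <- simulate_dataset(cfg)
obs <- apportion_unidentified(sim$observations, sim$traits)
det <- fit_detection(obs, sim$traits)
dt  <- estimate_densities(obs, sim$sites, det)    # 525 surveys x 60 species
met <- community_metrics(dt, sim$traits, obs = obs, sites = sim$sites)

st <- data.frame(canopy_cover_pct = met$site$canopy_cover_pct,
                 richness = met$site$ace_richness,
                 density  = met$site$mean_total_density,
                 cvi      = met$site$mean_cvi)
gradient_report(st)
#> Canopy cover (%) at peak response:
#>   richness  50.1  (gaussian_peak model)
#>   density   52.3  (gaussian_peak model)
#>   cvi       33.9  (gaussian_peak model)
#>   composite 47.5  (gaussian_peak model)
```

The generator's analytic ground truth for this seed puts the density peak
at 54.8% canopy and the CVI peak at 38.3%, so the fitted peaks land within
a few percentage points — the estimator-recovery property the test suite
checks systematically. Composition differs among habitat classes:

```r
m_site <- rowsum(density_matrix(dt), dt$site_id) / 21
hab <- sim$sites$habitat[match(rownames(m_site), sim$sites$site_id)]
permanova(m_site, hab, n_perm = 999, seed = 2, pairwise = FALSE)
#> PERMANOVA: pseudo-F(4,20) = 17.565, p = 0.001 (999 permutations)
```

A single detection fit, on the worked four-distance example:

```r
fit_halfnormal(c(1, 2, 2, 3))
#> Half-normal detection fit: sigma = 2.121 m, ESW = 2.659 m (n = 4)
```

The package also ships a read-only replica of the published 61-species
density table (`load_table2_fixture()`: 10,041 butterflies over 525
surveys, ESWs from 0.96 to 8.5 m) and the species' NatureServe ranks
(`load_natureserve_ranks()`), used for fixture arithmetic and range
checks.

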