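# minfluxpairs

Post-processing for 2D MINFLUX single-molecule localization data, built to
answer one question rigorously: **is a membrane receptor organized as
monomers, pairs, or small clusters, and at what spacing?** The motivating
application is receptor organization in immune-cell synapses, where pairs
separated by a few tens of nanometers sit right at the resolution limit of
conventional localization microscopy but are cleanly resolvable by MINFLUX.

MINFLUX data arrive as *localizations* grouped into *traces* (one trace =
one fluorophore emission event). The pipeline:

1. **filters** localizations on instrument quality metrics — background-
   corrected emission rate `efo` > 50,000 Hz or center frequency ratio
   `cfr` > 0.95 are removed (strict cuts), then traces with fewer than 3
   surviving localizations are dropped;
2. **condenses** each trace to a trace center with per-trace DBSCAN
   (4 nm radius, 3-localization threshold; center = mean of the largest
   cluster);
3. **detects isolated pairs** as DBSCAN clusters of exactly 2 trace
   centers at a 40 nm radius (chaining makes size-2 clusters mutually
   nearest and isolated — the package verifies this on every pair);
4. **characterizes clusters** (≥ 4 centers in 40 nm: composition, diameter,
   convex-hull area, density), computes exact **nearest-neighbor
   distances**, and estimates **Ripley K/L/H** with translation edge
   correction,

   K̂(r) = A/(n(n−1)) · Σ_{i≠j} e_ij · 1[d_ij ≤ r],  L = √(K/π),  H = L − r,

   where H(r) > 0 flags clustering at scale r;
5. **compares conditions** with a two-sided Mann–Whitney U test (exact for
   small tie-free samples).

Because measured pair distances are biased upward by localization noise —
the distance between two points observed with isotropic Gaussian error of
per-axis sd σ_c follows a **Rice distribution** with mean > true
separation d — the package also provides `expected_pair_distance(d, σ_c)`
and its inverse, so a measured mean distance can be converted into an
unbiased estimate of the true separation.

A synthetic-data module (`sim_config()`, `simulate_ground_truth()`,
`simulate_localizations()`) generates synapse-like fields of monomers,
dimers at a known separation, and small Gaussian clusters, with
sub-unit labeling efficiency, trace structure, localization noise, and
out-of-range background traces — so every stage has measurable error
rates via `evaluate_recovery()` (pair precision/recall, distance bias,
cluster recall).

## Worked example

Simulate one synapse-sized field at default study conditions (18 nm pair
separation, 2.5 nm localization precision, 70 % labeling efficiency) and
run the full chain:

```r
library(minfluxpairs)

cfg <- sim_config(seed = 7)                  # 5 x 5 um field, d = 18 nm
rep <- run_pipeline(pipeline_config(sim = cfg, seed = 7), quiet = TRUE)
print(rep)
#> MINFLUX pipeline report
#>   localizations: 469 in -> 428 kept; traces 59 -> 53; centers 52
#>   isolated pairs: 9 (mean 17.59 nm, median 17.12 nm)
#>   clusters: 0
#>   mean nearest-neighbor distance: 287.70 nm
#>   Ripley H peak: 224.11 at r = 45 nm
```

41 localizations were removed by the quality cuts and short-trace rule
(most belong to simulated background traces), 52 trace centers remain, and
9 isolated pairs are found. Scoring against the known ground truth:

```r
evaluate_recovery(NULL, rep)
#> Recovery: pair precision 0.778, recall 0.368 (7/19), bias -0.408 nm
```

Recall ≈ 0.37 against all 19 true dimers is expected, not a failure: with
70 % labeling only ~49 % of dimers can ever be seen as pairs, and a few
more are lost to crowding. On a single small field the mean pair distance
fluctuates around the Rice-biased expectation; pooled over cells the bias
becomes systematic and invertible:

```r
mbar <- 8 / (1 - exp(-8))                     # mean trace length
expected_pair_distance(18, 2.5 / sqrt(mbar))  # predicted measured mean
#> [1] 18.04344
invert_pair_distance(rep$pairs$mean_nm, 2.5 / sqrt(mbar))
#> [1] 17.54744
```

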