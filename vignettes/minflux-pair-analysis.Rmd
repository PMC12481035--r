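---
title: "Detecting receptor pairs in MINFLUX data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting receptor pairs in MINFLUX data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minfluxpairs)
```

## The measurement problem

MINFLUX nanoscopy localizes single fluorophores with nanometer precision by
probing them with the intensity zero of a structured beam. One fluorophore
emission event produces a *trace*: a short burst of localizations scattered
around the true fluorophore position. Deciding whether a membrane receptor
is organized as monomers, pairs, or small clusters therefore requires a
chain of reductions, each with its own failure modes:

1. discard low-quality localizations,
2. condense each trace into a single *trace center*,
3. ask how trace centers are arranged — isolated pairs, clusters of four or
   more, nearest-neighbor spacing, and second-order (Ripley) statistics.

`minfluxpairs` implements this chain and, because real MINFLUX data of this
kind are rarely public, ships a generator that produces fields with known
ground truth so each stage's error rates can be measured rather than
assumed.

## Quality filtering

Each localization carries two instrument metrics: `efo` (background-
corrected emission rate, Hz) and `cfr` (center frequency ratio). High efo
indicates background; cfr near or above 1 indicates a poor localization.
The filter removes localizations with efo > 50,000 Hz **or** cfr > 0.95
(strict inequalities — boundary values survive), and then removes every
trace left with fewer than 3 localizations. The order matters: the
trace-length rule is applied to the *survivors* of the per-localization
cuts, so a trace can be eliminated by losing rows to the quality cuts. The
filter is idempotent and records its removal counts.

## Trace centers

The center of each trace is found by DBSCAN run *within that trace only*
(search radius 4 nm, threshold 3 localizations, the point counting toward
its own neighborhood, inclusive distance test). The center is the
arithmetic mean of the largest cluster; noise localizations never
contribute. Conventions the upstream description leaves open were fixed as
follows:

* a trace whose localizations form no cluster yields no center and is
  dropped;
* if two clusters tie for largest, the one containing the earliest-time
  localization wins, making the result invariant to row order;
* DBSCAN is never run across traces: two genuinely distinct emitters
  4 nm apart must not be merged into one center.

One consequence worth knowing: with 2.5 nm per-axis noise, a 4 nm search
radius trims genuine outlying localizations from the averaged cluster, so
the effective center precision is slightly *worse* than the idealized
$\sigma/\sqrt{m}$ for a trace of $m$ localizations. The effect on measured
pair distances is of order 0.1 nm at short separations (see the bias
discussion below) and is visible in the validation suite.

## Isolated pairs

Pairs are detected as DBSCAN clusters of **exactly two** trace centers at
a 40 nm search radius with `min_pts = 2`. Because DBSCAN chains any point
within the radius into the cluster, a size-2 cluster already guarantees
isolation: no third center lies within 40 nm of either member, and the two
members are mutual nearest neighbors. The package treats the follow-up
nearest-neighbor check as a *verification pass* — it asserts the isolation
property on every detected pair and records the distance to the third-
nearest center — rather than as an additional cut, since no further
criterion is defined for one.

## Clusters, nearest neighbors, Ripley H

Clusters are DBSCAN components with at least 4 members in a 40 nm radius.
Because "size" and "density" of a cluster admit several definitions, the
package fixes: size = maximum pairwise member distance (diameter), area =
convex-hull area with a 1-nm ribbon fallback for degenerate (collinear)
member sets, density = composition / area; the definitions are carried in
the output so alternatives can be added unambiguously.

Nearest-neighbor distances use a uniform-grid spatial index with an
expanding-ring search that is exact (contractually identical to exhaustive
search, and tested against it).

Ripley's functions are estimated as

$$\hat K(r) = \frac{A}{n(n-1)} \sum_{i \neq j} e_{ij}\, \mathbf{1}[d_{ij} \le r],
\qquad L(r) = \sqrt{\hat K(r)/\pi}, \qquad H(r) = L(r) - r,$$

with translation edge correction
$e_{ij} = A/\bigl((w-|\Delta x_{ij}|)(h-|\Delta y_{ij}|)\bigr)$ on a
rectangular ROI by default (an uncorrected option exists for oracle
tests). $H > 0$ indicates clustering at scale $r$, $H < 0$ dispersion.
Radii are limited to half the shorter ROI side, where the translation
correction is well behaved; the default grid is 5–200 nm in 5 nm steps.
On complete spatial randomness the uncorrected estimator is biased low at
large radii while the corrected one stays inside the Monte-Carlo CSR
envelope — both behaviors are asserted in the test suite.

Condition-level comparisons (one statistic per cell) use the two-sided
Mann–Whitney U test: exact by enumeration for at most 8 observations per
group without ties, otherwise a normal approximation with tie and
continuity correction.

## The synthetic-data generator

The generator emulates what the analysis assumes about a flat,
synapse-sized membrane patch (defaults in parentheses):

* a 5000 × 5000 nm field;
* monomers as a homogeneous Poisson process (1.0 /µm²);
* dimers (1.0 /µm²): Poisson-placed anchor, partner at exactly
  `pair_separation_d` (18 nm) in a uniform random direction;
* clusters (0.08 /µm²): `cluster_size_n` = 4 members at isotropic Gaussian
  offsets, sd `cluster_sigma` = 15 nm;
* labeling efficiency 0.7: each molecule independently carries a detectable
  fluorophore or not — so only ~49 % of dimers can ever appear as pairs,
  and single-labeled dimers masquerade as monomers;
* one trace per labeled molecule, length from a ≥1-truncated Poisson
  (mean parameter 8), localization noise isotropic Gaussian, per-axis sd
  `sigma_loc` = 2.5 nm;
* optional re-activation (off by default): a duplicated trace from one
  fluorophore appears as a spurious ~0 nm "pair", which is why it exists
  as an explicit confound switch;
* background traces (0.2 /µm²) whose efo (log-normal, median 80 kHz) and
  cfr (uniform 0.9–1.2) mostly violate the quality filters — chosen so
  filter efficacy is measurable, not as an estimate of real background;
  signal efo is log-normal with median 20 kHz and cfr uniform 0.1–0.9.

The density mix is a deliberate choice: pairs are made the dominant
multi-molecule species and clusters rare (about two per field), matching
the qualitative picture the analysis is designed for — abundant candidate
pairs, a handful of small clusters, and a monomer/lone-center population
fed both by true monomers and by half-labeled dimers.

What the generator does **not** emulate: fluorophore photophysics (on/off
kinetics, bleaching), stage drift (instruments of this class actively
stabilize to a few nm), 3D structure (the z axis is projected away), and
empirically calibrated efo/cfr distributions, which are not publicly
characterized. Passing tests therefore demonstrate correctness of the
*analysis chain* under its stated model, not robustness to every
instrumental artifact.

## The distance bias and its inversion

Even with perfect detection, measured pair distances overestimate the true
separation. If two points truly $d$ apart are each estimated with
independent isotropic Gaussian error (per-axis sd $\sigma_c$), the
measured distance follows a Rice distribution with location $d$ and scale
$\sigma_c\sqrt{2}$, whose mean exceeds $d$ — at $d = 0$ it is the Rayleigh
mean $\sigma_c\sqrt{2}\sqrt{\pi/2}$, and for large $d$ the excess decays
like $\sigma_c^2/d$.

```{r bias}
mbar <- 8 / (1 - exp(-8))               # mean trace length
sigma_c <- 2.5 / sqrt(mbar)             # approximate center precision
expected_pair_distance(18, sigma_c)     # what the pipeline should measure
invert_pair_distance(18.34, sigma_c)    # and how to undo the bias
```

`expected_pair_distance()` evaluates the Rice mean by adaptive quadrature
(relative error below 1e-6, validated against the Rayleigh closed form and
a frozen 10⁷-draw Monte-Carlo oracle); `invert_pair_distance()` solves the
monotone inverse problem, mapping mean distances at or below the Rayleigh
floor to 0. The approximation $\sigma_c = \sigma_{loc}/\sqrt{\bar m}$
ignores two second-order effects — trace-length variability (Jensen) and
the DBSCAN trimming described above — which together shift predicted means
by ≲ 0.1 nm under default settings; the validation suite measures the
residual directly.

## Recovery scoring

`evaluate_recovery()` matches detected pairs to true dimers greedily,
closest first; a match requires each detected center within 10 nm (default
— about four times the center precision) of a distinct dimer member.
Greedy matching was chosen over optimal assignment deliberately: at the
simulated densities double-candidate conflicts are rare, and greedy is
deterministic and transparent. Recall is counted against *all* true
dimers, so sub-unit labeling efficiency $p$ caps recall near $p^2$ — the
quantitative form of the caveat that incompletely labeled pairs are
detected in isolation. With zero detections, precision is reported as 1
and flagged (`no_detections`): there are no false positives among zero
detections, and the flag keeps the convention from hiding.

Cluster recovery is scored by matching detected cluster centroids to the
centroid of each true cluster's labeled members. Note that exact cluster
*count* recovery at the default geometry (member sd 15 nm, DBSCAN 40 nm /
min 4) is not guaranteed even with full labeling: occasionally one member
strays too far to be density-reachable. The tests demonstrate exact
recovery on compact clusters and treat the default geometry's shortfall as
a property of the method, not a bug.

## Problem sizes and numerical choices

The validation suite runs on synthetic fields of roughly 50–250 molecules
(a few hundred to a few thousand localizations) per field, 12-field
batches for pipeline-level laws, 2,200 dimers per separation for the Rice
bias check, and 100 CSR fields of 500 points for the Ripley envelope —
sizes at which the brute-force O(n²) oracles remain feasible and the
statistical tolerances (3 standard errors throughout) are tight enough to
catch real defects. Distances are held as double-precision nm; CSV writers
emit full precision (`%.17g`) so round-trips are exact; DBSCAN uses an
inclusive (`d ≤ r`) neighborhood and deterministic lowest-index tie rules
throughout; all simulations are reproducible from a single integer seed,
with ground truth and localization noise on separate derived streams.

## Known limitations

* Strictly 2D: out-of-plane separation components are projected away, so
  measured distances are lower bounds in that respect (while localization
  noise biases them upward). The package quantifies only the latter.
* The pair definition is parametric in the 40 nm radius: at high center
  densities, chaining destroys pairs (two true dimers within 40 nm become
  a 4-cluster) and occasional monomer coincidences create false pairs;
  `evaluate_recovery()` exists to measure exactly these rates.
* The Mann–Whitney helper compares per-cell summaries only; it does not
  model within-cell correlation beyond the per-cell reduction.
* Vendor binary exports are not parsed; the documented CSV schema is the
  interchange contract.
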