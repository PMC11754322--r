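---
title: "Quantifying spatial exploration: measures, variable clustering, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajexplore)
```

## The problem

When a person (or an animal, or an agent) freely explores a bounded
environment — a virtual island, a campus, an arena — the raw record is a 2-D
trajectory: an ordered sequence of positions $(x_t, y_t)$ in the
environment's coordinate units ("virtual meters", vm), sampled at some rate.
Many scalar summaries of such trajectories have been proposed, each claiming
to capture something behaviorally meaningful: how *much* the subject moved,
how much *ground* it covered, how *twisty* its path was, how *efficiently*
it avoided retracing its own steps.  These measures are strongly
intercorrelated, and it is not obvious which of them are redundant and which
carry independent information.

This package implements the full chain: quality screening and resampling of
raw position logs, a suite of fourteen exploration measures, and a
hierarchical clustering *of the measures themselves* that groups them into
interpretable components of exploration behavior.  A seeded agent simulator
generates synthetic cohorts with known latent traits, so every stage of the
chain can be validated without access to human data.

## Preprocessing

Position logs from uninstrumented hardware often lack timestamps.  When the
session length is fixed and known, the mean sampling rate is recovered as
`n_points / total_time` (`infer_sampling_rate()`).  Three screens flag
suspect recordings (`qc_screen()`, `cohort_screen()`):

* **Step-length variability.**  With movement speed fixed by the task,
  variability in step length proxies within-session sampling-rate
  variability.  The coefficient of variation of nonzero step lengths is
  compared across the cohort; values above $Q_3 + 3\,\mathrm{IQR}$ are
  flagged.
* **Large lags.**  A step longer than 3 times the trajectory's median
  nonzero step is a recording lag; subjects with more than 0.1% lag steps
  are flagged.
* **Low movement.**  Subjects in motion for less than 30 s are flagged
  (zero-length steps are pauses, not movement).

Flags are advisory: the report says *why* a subject is suspect and the
caller decides what to drop.  Retained trajectories are linearly
interpolated to a common 10 Hz grid (`resample_temporal()`) — several
measures (path length, revisiting, roaming entropy) are sensitive to the
sampling rate — and leading idle time is trimmed up to the first movement,
keeping the last idle sample so the first movement step survives
(`trim_initial_idle()`).

## The measure suite

All parameters live in `measure_params()`; defaults are the free-exploration
profile (`param_profile("nemo")`), with a goal-directed variant
(`"silcton"`) differing only in bin size (15 vm) and rediscretization step
(0.50 vm).

| measure | definition | unit |
|---|---|---|
| `path_length` | sum of step lengths | vm |
| `pausing` | zero-length steps / sampling rate | s |
| `area_covered` | distinct occupancy-grid bins visited (14 vm bins) | bins |
| `roaming_entropy` | $-\sum_i p_i \ln p_i / \ln k$ over per-sample bin occupancy | — |
| `min_convex_polygon` | convex hull area of all samples | vm² |
| `fractal_dimension` | $1 - $ slope of $\ln L(\delta)$ on $\ln\delta$ (divider method) | — |
| `sinuosity` | $1.18\,\sigma/\sqrt{q}$ on the constant-step path | rad·vm$^{-1/2}$ |
| `landmark_visits` | distinct landmarks entered (20 vm discs) | count |
| `landmark_revisits` | landmark entries beyond the first per landmark | count |
| `revisiting` | mean returns to greedily placed 14 vm places | count |
| `turnarounds` | step-scale turning angles at 180° (±0.5°) | count |
| `flight_turnarounds` | turning angles ≥ 160° on the RDP-simplified path (ε = 6 vm) | count |
| `area_efficiency` | distinct bins / bin entries | — |
| `landmark_efficiency` | distinct landmarks / landmark entries | — |

Notes on the less standard choices:

* **Grid convention.**  Occupancy cells are half-open squares anchored at
  the lower-left corner of the bounds; the anchor is a convention the
  original method leaves open, fixed here so bin assignment is deterministic
  and testable.  The entropy normalization $k$ can be supplied (the
  environment's total size in bins) or left open, in which case
  `cohort_measures()` uses the number of unique bins the whole cohort
  explored.  Occupancy probabilities are per *sample* — time-weighted at the
  common rate — not per entry.
* **Rediscretization.**  Sinuosity's formula assumes constant step length
  $q$, so the path is first rediscretized by the classic chord construction:
  each emitted point is the first location along the path at Euclidean
  distance exactly $q$ from the previous emitted point.  Every emitted step
  is exactly $q$; the sub-step tail is dropped.  The default $q$ is the
  pooled median nonzero step of the cohort (0.48 vm for the free-exploration
  profile), falling back to the trajectory's own median when computed
  singly.  The dispersion $\sigma$ is the standard deviation (denominator
  $n-1$) of the *signed* turning angles in radians.
* **Divider method.**  $L(\delta)$ is measured with the same rediscretizer
  at 20 divider sizes log-spaced between 0.5 and 10 times the median nonzero
  step.  The measured length is (emitted steps) × δ *plus the partial last
  stride* to the path's endpoint; without that term a straight line loses up
  to one δ at coarse sizes and its fitted dimension is biased above 1.
  Sizes larger than half the path length are dropped; the fit needs at least
  3 valid sizes.
* **Flights.**  The flight-scale trajectory is the Ramer–Douglas–Peucker
  simplification at ε = 6 vm (perpendicular distance to the chord's line;
  the first maximal vertex is split on ties).  Step-scale turnarounds use a
  0.5° tolerance at the 180° cutoff because floating-point headings almost
  never reverse exactly; the flight-scale cutoff of 160° needs no tolerance.
  The legacy step-scale count is computed and exported but excluded from
  clustering by default: on jittered paths it counts strafing noise and
  misses genuine dead-end reversals, which is precisely the deficiency the
  flight-scale refinement addresses (the comb fixture in
  `fixture_trajectories()` demonstrates the contrast).
* **Revisiting.**  "Places" are not predefined, so they are constructed
  greedily along the trajectory: the first sample opens a place; each later
  sample farther than 14 vm from every existing place opens a new one.
  Entries are counted per place with full exit required before re-entry
  (as for landmarks), and the measure is the mean of (entries − 1).  This is
  one concrete reading of "returns to already visited places"; it is
  deterministic given the trajectory and isolated behind a single function
  so it can be swapped.
* **Undefined values.**  A subject that never enters any landmark disc has
  no defined landmark efficiency; the value is `NA` and the clustering stage
  drops incomplete subjects with a reported count rather than imputing.

## Clustering measures into components

Measures are standardized (mean 0, sd 1) and clustered as *variables*.  The
homogeneity of a cluster $C$ is the leading eigenvalue $\lambda_1$ of the
correlation matrix of its members — the variance explained by the cluster's
first principal component, equivalently the sum of squared Pearson
correlations of members with that component.  Agglomeration merges the pair
minimizing the homogeneity loss

$$d(A, B) = H(A) + H(B) - H(A \cup B) \ge 0,$$

recorded as the merge height.  For two single variables this reduces to
$1 - |r|$ (the eigenvalues of a 2×2 correlation matrix are $1 \pm |r|$).
Because everything is built on squared correlations, the tree is invariant
to sign flips and affine rescalings of any variable; ties in the merge
criterion are broken by the lexicographically smallest member name so
results are platform-stable.

Cutting the tree at $k$ (`varclust_cut()`) summarizes each cluster by its
*synthetic variable*: the first principal component of its standardized
members, scaled to unit variance and oriented so the mean correlation with
its members is positive (the criterion is orientation-blind, so a convention
is needed; displays conventionally flip "inverted" measures such as pausing
via `orient_measures()` so that higher always means more exploration).
Loadings are plain Pearson correlations of every measure with every
synthetic variable.

The number of clusters is chosen by inspecting the dendrogram and the curve
of aggregation heights against the number of clusters, supported by the
kneedle knee-point detector (`suggest_k()`): min–max normalize both axes,
flip the (decreasing, convex) curve to increasing–concave, and take the
local maximum of the difference curve $y - x$ that stays above a
sensitivity-adjusted threshold.  Sensitivity 1 and offline (exact, unsmoothed)
evaluation are the defaults; the curves here are short and noiseless, so no
smoothing spline is applied.  Small height inversions (the criterion is not
guaranteed monotone) are removed by an isotone envelope before knee
detection.  The final $k$ remains a user decision; the suggestion is a
default, not a verdict.

## The synthetic cohort model

`simulate_agent()` is a fixed-speed correlated random walk designed to
emulate position logs from a timed free-exploration session: 150 s at 10 Hz,
step 0.48 vm per moving sample, in a 140 × 140 vm bounded environment with
20 landmarks (the defaults of `make_environment()` and `sim_config()`).
Five latent traits control behavior:

* `activity` — per-sample pause probability (occasional zero-length
  samples, as real logs show);
* `tortuosity` — sd of wrapped-normal turning noise per moving step;
* `turnaround_rate` — per-sample probability of an instantaneous heading
  reversal (dead-end behavior on demand);
* `revisit_bias` — per-sample probability of starting a *return trip*: the
  agent steers back to the most recent position at least 25 vm away, then
  resumes wandering.  A trip retraces ground (raising revisiting, lowering
  area efficiency) and begins with a flight-scale reversal of the net
  heading (raising flight turnarounds);
* `landmark_attraction` — pull toward the nearest unvisited landmark.

Steering (toward trip targets, away from walls inside a 6 vm margin) is
rate-limited at 0.2 rad per step, so course corrections are smooth arcs of
roughly 2.4 vm radius — below the 6 vm flight-simplification scale — rather
than instantaneous spikes.  This matters: an instantaneous reversal injects
a single ~π turning angle into the step-scale angle sequence, which inflates
the sinuosity and fractal-dimension channel and entangles the efficiency
trait with the shape trait.  Walls fall back to mirror reflection only if
the smooth avoidance fails.  Agents are fully reproducible from
`(seed, agent_seed)`; cohorts derive per-agent seeds by a fixed counter
scheme, so growing `n_agents` preserves the shared prefix.

The default trait sampler draws three traits independently and uniformly
over ranges chosen to span a "none" to "dominant" regime of each behavior:
activity in $[0, 0.7]$ (up to two-thirds of the session idle), tortuosity in
$[0.02, 0.2]$ rad (near-straight to strongly winding, while keeping the
heading-decorrelation length $\sim q/\sigma^2$ above the 14 vm bin scale so
path shape does not dominate the area measures), and revisit bias in
$[0, 0.005]$ per sample (zero to roughly half a dozen return excursions per
session).  With these conditions, clustering the nine measures driven by the
three traits recovers the three blocks — activity-driven
{path length, pausing, area covered, roaming entropy}, shape-driven
{sinuosity, fractal dimension}, and efficiency-driven
{revisiting, area efficiency, flight turnarounds} — in ≥ 90% of seeded
200-agent cohorts, with the kneedle suggestion at 3 (the acceptance script
recomputes both rates over 20 replicates).

What the simulator does **not** emulate: wall-constrained street networks
(layout landmarks mark dead ends or loops, but walls beyond the outer bounds
are not enforced), goal-directed search instructions, speed variation, lag
artifacts, or any claim of human realism.  Passing the recovery test shows
the *pipeline* can separate independently manipulated behavioral axes; it
does not show that human exploration decomposes the same way.

## Numerical choices and degenerate inputs

* Coordinates are planar; 3-D game logs contribute their two horizontal
  axes via `column_map` and the vertical axis is never read.
* Natural logarithms throughout the entropy (the base cancels in the ratio).
* A step is a pause when its length ≤ 1e-9 vm; after linear resampling,
  exact zeros survive only within genuine idle runs.
* Rediscretization requires the path to be at least one step long; the
  divider fit requires the path to exceed 10 median steps; sinuosity
  requires ≥ 3 rediscretized points; all-idle trajectories are errors with
  the subject named.
* Samples outside the environment bounds are clamped into the boundary bins
  and counted, with a warning (falling off the map is an exclusion decision
  for QC, not for the binning).
* All simulations in the test suite and acceptance script use fixed seeds;
  cohort sizes there (200 agents × 20 replicates for recovery, 50 agents per
  condition for the monotone trait–measure checks) were chosen as the
  smallest sizes at which the stochastic checks are comfortably stable.

## Limitations

* The revisiting construction (greedy first-come places) is a convention;
  alternative place definitions (grid-based, density-based) would give
  different absolute values, though similar orderings.
* Landmark re-entry requires fully exiting the 20 vm disc; no refractory
  time is imposed.
* The homogeneity criterion handles quantitative variables only.
* Kneedle on very short curves (fewer than ~5 cluster counts) rarely finds
  a knee that passes the threshold; the functions then return `NA` and ask
  the caller to choose `k`.
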