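---
title: "Models and methods behind scpolarity"
author: "scpolarity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scpolarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpolarity)
```

Detached tumour cells in suspension are not the symmetric spheres they
were long assumed to be: many maintain a single ezrin- and actin-rich
membrane pole ("single-cell polarity"). This vignette explains the
models implemented in scpolarity, the assumptions behind them, the
tunable parameters that matter, and the choices we made where the
underlying procedures left room for design.

## 1. The seeding cascade model

### Model and assumptions

Metastatic seeding from the blood is modelled as a linear compartment
cascade, run in parallel for polarised and depolarised cells:

$$\text{circulating} \xrightarrow{k_{att}} \text{attached}
  \xrightarrow{k_{adh}} \text{adhered} \xrightarrow{k_{tiss}}
  \text{tissue}$$

All transfers follow first-order kinetics, so each arm is governed by
three rate constants (units 1/s; user-facing I/O also accepts %/s,
with 10.74 %/s stored as 0.1074 /s to avoid silent 100-fold errors).
The assumptions are deliberately minimal:

* the circulation outflow is exactly the attachment inflow (mass
  balance); there is no recirculation, so circulating populations decay
  to zero;
* no proliferation, death or detachment terms: the total population is
  conserved along every trajectory, which the test suite checks to
  within $10^{-9}$ relative;
* the tissue compartment is shared between the arms, because once a
  cell is tissue resident its previous polarity can no longer be
  observed. Internally the tissue inflow is nevertheless tracked per
  arm, so that pure-population tissue-residence fractions
  (`tissueResidenceFraction(traj, t, arm = "pol")`) remain well
  defined.

`simulateCascade()` integrates the system with a stiff-capable adaptive
method (`deSolve::lsoda`, defaults rtol $10^{-9}$, atol $10^{-12}$;
the rates span three orders of magnitude). `batemanClosedForm()`
evaluates the exact analytic solution of the linear chain (the
classical Bateman formulas) and serves as an independent oracle: the
two agree to better than $10^{-8}$ of the total population across
random rate sets. Numerical care in the closed form: divided
differences of exponentials use an `expm1` formulation where the rate
gap is small (cancellation) and the plain difference where it is large
(overflow); arms whose rates are closer than a relative $10^{-3}$ are
evaluated by a matrix exponential instead, and `degenerate = "error"`
turns that fallback into an explicit error for users who want the
strict Bateman form.

### The three in-silico experiments and the linked fit

The six rates are estimated exactly as the assays dictate, one pooled
least-squares problem across three designs:

| design | initial state | observed | identifies |
|---|---|---|---|
| i | pre-attached cells | adhered fraction over time | $k_{adh}^{pol}, k_{adh}^{dep}$ |
| ii | injected into flow | attached and adhered counts | $k_{att}$ (and $k_{adh}$) |
| iii | injected into circulation | tissue-resident fraction | $k_{tiss}^{pol}, k_{tiss}^{dep}$ |

Each design is run on a "polarised" and a "depolarised" preparation.
Neither preparation is pure: generic depolarisation lowers the
polarised fraction by about 30 percentage points, so the defaults are
65% and 35% polarised. The assays cannot see polarity once cells are
down, so all observables are sums over both arms, and only the linked
fit -- one residual vector pooling all three experiments -- makes the
six rates jointly identifiable.

**Observation grids.** The default observation times sample each
observable across its dynamic range: design i at 5--300 s, design ii
at 2--320 s, design iii at 300--3600 s. This is a deliberate
sampling-design choice: with attachment and adherence half-lives of
6--23 s (the fitted rates), an observable read out tens of minutes
after seeding is fully saturated -- $1 - e^{-kt}$ differs from 1 by
less than $e^{-20}$ -- and carries no information about the fast
rates. A rate can only be estimated from samples taken while its
transition is in progress, and the defaults guarantee several such
samples per rate.

**Optimiser.** Rates are fitted on a log10 scale (they span three
decades) within bounds ($10^{-8}$ to 1 /s) by trust-region
Levenberg--Marquardt least squares (`minpack.lm::nls.lm`), terminating
at RSS $\le 10^{-8}$ or 400 iterations. The raw problem has local
minima (a start with the attachment rate railed at its upper bound
fits the slow observables and strands the optimiser), so `linkedFit()`
first runs a staged warm start that walks down the cascade -- design i
alone identifies the adherence rates in a two-parameter subproblem,
design ii then the attachment rates, design iii the tissue-residence
rates -- and follows it with seeded log-uniform random restarts
(default 10). The warm start lands in the global basin in every
condition we exercise; the restarts guard against pathological data.
With noiseless observations all six rates are recovered to machine
precision; under 5% multiplicative noise the median error per rate
stays below 10%.

The published procedure used a "constrained mixed-effects" nonlinear
least-squares routine. We implement fixed-effects constrained least
squares: with one synthetic observation per design/time/preparation
there are no replicate-level random effects to estimate, and the
simplification changes nothing about the pooled objective. Residuals
are pooled on a common scale by normalising every preparation to an
initial population of 100.

**Uncertainty.** `bootstrapCI()` resamples the pooled fit residuals
with replacement, adds them to the fitted predictions (floored at
zero, as counts cannot be negative), refits from the point estimate
and reports percentile intervals. Noiseless data give degenerate
(zero-width) intervals; under 5% noise the 95% intervals cover the
generating rates at close to nominal rate in our scaled-down coverage
simulations.

## 2. Pole morphology: segmentation, aggregation score, peak model

### Segmentation

Fluorescence images of detached cells carry three intensity levels:
background, cell body, and bright ezrin clusters. Yen's
maximum-correlation threshold is known to isolate the bright class
first, so `segmentCells()` applies it hierarchically: the first pass
on the full image yields the cluster level; a second pass restricted
to the sub-threshold pixels separates cells from background. On a
bimodal image (no clusters brighter than the cells) that second pass
would land inside the background noise and flood the frame, so a
coverage check (foreground > 50% of the frame) falls back to the
first threshold. The background is first removed by a rolling-ball
style morphological opening whose structuring element (default radius
80 px, twice the expected cell radius) is computed on a downsampled
copy for speed. Cells touching the image border are excluded;
connected cluster objects smaller than 1% of their cell (configurable)
are ignored -- the score is defined on *large* clusters.

Degenerate inputs are handled explicitly: a blank image returns an
empty result with a warning; a cell of (near-)constant intensity has
no meaningful within-cell threshold and counts, whole, as its own
cluster, which lands the score exactly at 1.

### The aggregation score

$$\text{Aggregation} = \frac{I_{cluster}}{I_{cell}} \times
  \frac{A_{cell}}{A_{cluster}}$$

with $I$ the integrated intensity and $A$ the area in pixels. "Intensity"
could also be read as a region mean; we default to integrated intensity
because then $I_{cluster}/I_{cell}$ is the fraction of the cell's
signal captured by the clusters and a perfectly uniform cell scores
exactly 1; `intensity = "mean"` provides the other reading. The score
is invariant to multiplying the image by a positive constant, and
strictly increases as a fixed amount of signal concentrates into less
area -- high for spot-like poles, low for dispersed cap-like poles.

### Two subpopulations

`fitDoublePeak()` fits the score histogram with a sum of two peaks by
least squares on the bin counts. The default peak shape is the
exponentially modified Gaussian (aggregation scores are
right-skewed); a plain Gaussian is available. Cells are assigned to
the peak with the higher fitted density at their score, and the
decision boundary (density crossing between the two modes) is
reported. Three guards prevent a forced split of unimodal data: a
component whose amplitude share drops below 2% is discarded; a fitted
sum without a genuine valley between the component modes (valley above
80% of the lower mode) is treated as one population; and a nested
single-peak fit must be beaten by an F-ratio of at least 5, which
catches the classic failure mode of one narrow component soaking up
bin noise. These three thresholds are heuristics chosen once and
documented here; they are deliberately conservative in favour of the
single-population verdict.

## 3. The polarity caller and depolarisation kinetics

A cell is polarised when a *single, continuous* membrane region
covering *less than half* of the circumference is enriched *two-fold
or more* over the remaining membrane. The package operationalises the
rule on a 1-D circular profile of membrane intensity (64 angular bins
by default; `boundaryProfileFromMask()` reduces an image + mask to
such a profile by averaging a 3-px membrane band per angular bin).

`callPole()` searches all contiguous arcs of all lengths exhaustively
and takes the enrichment-maximising arc as the candidate pole; the
cell is polarised only if that candidate is both short enough
(< 0.5 of the circumference) and enriched enough (>= 2-fold).
Searching *all* lengths, not only the qualifying ones, is essential:
a 200-degree enriched region must disqualify the cell, not get
trimmed to its best 179-degree sub-arc. Ties break towards the
smaller arc, then the smaller start index, so calls are deterministic,
rotation-covariant and scale-invariant. The suite checks exact
agreement with a brute-force double-loop oracle. No minimum absolute
intensity is applied by default (none is part of the definition); a
configurable floor exists for noisy data.

### Depolarisation kinetics

The polarised fraction of suspended cells decays with a half-life of
about an hour, but a substantial fraction remains polarised for many
hours. A pure exponential cannot reconcile those two observations, so
`fitDecay()` uses a plateau-exponential:

$$f(t) = P + (f_0 - P)\,2^{-t/T_{1/2}}$$

with $f_0$ the initial fraction, $P$ the stably polarised plateau and
$T_{1/2}$ the half-life in hours, fitted by bounded least squares from
several half-life starting values. Flat or non-decaying courses
(amplitude $\approx$ 0, or half-life driven to its bound) are flagged
rather than silently parameterised.

The matching generator `genDecayTimecourse()` draws binomial counts
(default 200 cells per time point, the sampling depth of a manual
polarity assay) around the plateau-exponential mean with defaults
$f_0 = 1$, $P = 0.39$, $T_{1/2} = 1$ h. Its default 12-point, 0--6 h
schedule is front-loaded (four points within the first 1.5
half-lives), as one designs a kinetics assay: with even spacing only
two points fall inside the first half-life and the half-life estimate
becomes needlessly noisy. At this sampling depth the half-life
estimator is unbiased with a standard deviation near 0.1 h, so
individual seeded courses scatter accordingly; that scatter is a
property of the assay depth, not of the estimator.

## 4. Scoring utilities

* `gisScore()`: positivity grade (0 = negative, 1 = up to 10%,
  2 = 11--50%, 3 = 51--90%, 4 = > 90%) times intensity grade (0--2);
  scores >= 4 class as "high". Exactly 10% still grades 1; the next
  bracket starts strictly above 10%.
* `tmaGrade()`: a tissue-microarray spot is "polarised" from 3
  polarised cells up.
* `metastaticCapacity()`: $\log_{b}(\text{lung}/\text{blood})$,
  default base 10 (the conventional fold-capacity axis; correlations
  are identical in any base). Non-positive counts are excluded with a
  warning rather than propagated as infinities.
* `fisherExact()` / `pearsonChisq()` / `pearsonR()` delegate to the
  standard R implementations behind a validating surface; the test
  suite verifies `fisherExact()` against a full hypergeometric
  enumeration for every 2x2 table with total up to 30. Degenerate
  margins return p = 1 by convention.

## 5. Synthetic data: what it emulates, what it does not

Every pipeline input can be generated with ground truth:
`genCellImage()` (discs with a 3-px membrane band; cap poles are wide
arcs at 2--4x enrichment, spot poles narrow arcs at 6--12x; additive
Gaussian noise, optional Poisson shot noise), `genBoundaryProfiles()`
(circular intensity profiles with one enriched arc),
`genObservationSets()` (cascade predictions with multiplicative
noise), `genDecayTimecourse()` and `genScoreSample()` (labelled
two-peak mixtures). Every generator is a pure function of its
arguments including the seed.

The generators emulate the *structure* of the real data, not
microscopy physics: no point-spread function, no spectral
bleed-through, no out-of-focus light, no cell-shape irregularity, no
touching cells. Passing tests therefore demonstrate that the
algorithms are correct on data satisfying their stated assumptions --
they do not certify performance on real micrographs, where
segmentation quality will dominate.

Default problem sizes were chosen to exercise every code path at
comfortable statistical margins: 500 profiles for population
fractions, 600 scores for peak decomposition, about 40 pipeline
cells across seeds for the cap/spot ordering property, noiseless plus
5%-noise observation sets for rate recovery, and scaled-down bootstrap
coverage runs (a handful of replicates at 40 draws).

## 6. Known limitations

* The cascade model is deterministic; no stochastic (Gillespie)
  variant, recirculation, proliferation or vascular geometry.
* The fit treats residuals from different observables as
  exchangeable after the initial-population normalisation; no
  per-observable variance weighting.
* The peak decomposition fits histogram counts, so very small samples
  (a few dozen scores) are prone to the single-population verdict;
  mixture maximum likelihood on the raw scores would be the natural
  upgrade.
* Segmentation assumes non-touching, roughly convex cells; clumps are
  not split.
* SBML support covers exactly the seven-species mass-action model the
  package simulates (written and parsed with xml2), not general SBML.
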