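# scpolarity

Tumour cells that detach and travel through blood, lymph or ascites
fluid are not symmetric spheres: many maintain a single ezrin- and
actin-rich membrane pole. This **single-cell (sc) polarity** persists
in suspension, marks circulating tumour cells, and favours the early
steps of metastatic seeding — attachment, adhesion and entry into
tissue. `scpolarity` is an R package for researchers who want to
quantify this phenotype and model its consequences. It provides:

* **A compartmental model of metastatic seeding.** Polarised and
  depolarised cells move through
  `circulating → attached → adhered → tissue` with first-order
  kinetics,

  d(Attached)/dt = k_att·Circulating,  d(Adhered)/dt = k_adh·Attached,
  d(Tissue)/dt = k_tiss^pol·Adhered_pol + k_tiss^dep·Adhered_dep,

  simulated numerically (`simulateCascade`) and solved exactly by the
  Bateman closed form (`batemanClosedForm`). SBML Level 3
  export/import included.
* **Linked rate estimation.** `linkedFit` recovers all six transfer
  rates in one constrained least-squares fit pooled across three
  experiment designs (adherence-only; attachment+adherence in flow;
  full chain with tissue residence), with bootstrap confidence
  intervals (`bootstrapCI`).
* **Pole morphology scoring.** `segmentCells` segments cells and
  bright ezrin clusters by hierarchical Yen thresholding; the
  per-cell aggregation score
  `(I_cluster/I_cell) × (A_cell/A_cluster)` is high for spot-like and
  low for cap-like poles, and `fitDoublePeak` decomposes the score
  histogram into the two subpopulations.
* **The definitional polarity caller.** `callPole` applies the rule —
  a single contiguous membrane arc, shorter than half the
  circumference, enriched at least two-fold over the remaining
  membrane — exhaustively and deterministically on angular boundary
  profiles; `fitDecay` fits the plateau-exponential depolarisation
  kinetics `f(t) = P + (f0 − P)·2^(−t/T½)`.
* **Scoring utilities** (GIS immunoreactivity score, tissue-microarray
  polarity grading, log metastatic capacity, exact tests) and **seeded
  synthetic-data generators** for every input, with ground truth.

## Worked example

```r
library(scpolarity)

## the fitted seeding rates (quoted in %/s, stored in 1/s)
rates <- fittedSeedingRates()
rates
#> TransferRates (1/s):
#>             attachment adherence tissue
#> polarised       0.1074    0.0395  6e-04
#> depolarised     0.0381    0.0302  5e-04

## simulate pure populations for 250 min and compare seeding
traj <- simulateCascade(rates, compartmentState(circulatingPol = 100,
                                                circulatingDep = 100))
tissueResidenceFraction(traj, 1800, arm = "pol")   # 0.653
tissueResidenceFraction(traj, 1800, arm = "dep")   # 0.581
```

Polarised cells attach about three-fold faster and adhere about
1.3-fold faster, and after 30 minutes 65.3% of a pure polarised
population is tissue resident versus 58.1% of a pure depolarised one —
the cascade turns small kinetic advantages into a seeding difference.

```r
## recover the rates from noisy synthetic observations of the three assays
obs <- genObservationSets(rates, designDefaults(), noiseSd = 0.05, seed = 42)
fit <- linkedFit(obs, designs = designDefaults(), seed = 42)
round(rateVector(fit@rates, units = "pct_per_s"), 3)
#>  kAttPol  kAttDep  kAdhPol  kAdhDep kTissPol kTissDep
#>   10.655    3.986    4.072    3.134    0.060    0.053

## depolarisation kinetics from a binomial suspension assay
fitDecay(genDecayTimecourse(seed = 42))
#> DecayFit: f0 = 1.000, plateau = 0.401, T1/2 = 1.033 h (RSS 0.0162)

## polarity calls on synthetic membrane profiles
g <- genBoundaryProfiles(nProfiles = 200, seed = 42)
fractionPolarised(g$profiles)   # 0.8, matching the generator truth

## aggregation scores of segmented cells (spot-like cells score high)
img <- genCellImage(mix = c(cap = 0.5, spot = 0.5, none = 0), seed = 42)
head(scoreCells(img$image), 4)
#>   cell_id a_cell_px a_cluster_px   i_cell i_cluster    score
#> 1       1      3370           40 362037.4  32585.66 7.583035
#> 2       2      4219          229 470725.5  75977.37 2.973655
#> 3       3      4492          295 513975.8  98870.95 2.929164
#> 4       4      1988          179 227234.6  48951.62 2.392522
```

At five-percent measurement noise the six rates come back within a few
percent of the truth; the decay fit reads off a one-hour half-life
with a ~40% stably polarised plateau; and segmented spot cells (score
≈ 7.6) separate cleanly from cap cells (score ≈ 2.4–3).

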