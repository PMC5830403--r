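#' @import methods
NULL

## Canonical compartment order used throughout the package. The tissue
## compartment is shared between the two polarity arms; per-arm tissue
## attribution is tracked separately so pure-population fractions remain
## well defined.
.compartments <- c("circulating_pol", "circulating_dep",
                   "attached_pol",    "attached_dep",
                   "adhered_pol",     "adhered_dep",
                   "tissue")

.rateNames <- c("kAttPol", "kAttDep", "kAdhPol", "kAdhDep",
                "kTissPol", "kTissDep")

#' TransferRates: the six first-order transfer rates of the seeding cascade
#'
#' Holds the attachment, adherence and tissue-residence rate constants for
#' polarised and depolarised cells. Rates are stored internally as
#' fraction/s; the constructor accepts \code{"pct_per_s"} so that values
#' quoted as percent per second (e.g. 10.74 \%/s) convert to 0.1074 /s
#' without silent 100-fold errors.
#'
#' @slot rates Named numeric of length 6 (\code{kAttPol}, \code{kAttDep},
#'   \code{kAdhPol}, \code{kAdhDep}, \code{kTissPol}, \code{kTissDep}),
#'   units 1/s, all finite and non-negative.
#' @exportClass TransferRates
setClass("TransferRates", representation(rates = "numeric"))

setValidity("TransferRates", function(object) {
    r <- object@rates
    if (length(r) != 6L || !identical(names(r), .rateNames))
        return(sprintf("rates must be a named numeric of length 6 (%s)",
                       paste(.rateNames, collapse = ", ")))
    if (any(!is.finite(r)))
        return("all transfer rates must be finite")
    if (any(r < 0))
        return("all transfer rates must be non-negative")
    TRUE
})

#' Trajectory: compartment populations over time
#'
#' @slot times Numeric vector of time points (seconds), strictly
#'   increasing, starting at 0.
#' @slot states Numeric matrix, one row per time point, columns the seven
#'   compartments (\code{circulating_pol}, \code{circulating_dep},
#'   \code{attached_pol}, \code{attached_dep}, \code{adhered_pol},
#'   \code{adhered_dep}, \code{tissue}).
#' @slot tissueByArm Numeric matrix with columns \code{tissue_pol} and
#'   \code{tissue_dep}: tissue inflow attributed to each polarity arm
#'   (tissue present at t = 0 is attributed to neither arm).
#' @exportClass Trajectory
setClass("Trajectory",
         representation(times = "numeric", states = "matrix",
                        tissueByArm = "matrix"))

setValidity("Trajectory", function(object) {
    t <- object@times
    if (length(t) < 1L || t[1] < 0) return("times must start at >= 0")
    if (any(diff(t) <= 0)) return("times must be strictly increasing")
    if (nrow(object@states) != length(t))
        return("states must have one row per time point")
    if (!identical(colnames(object@states), .compartments))
        return("states columns must be the seven cascade compartments")
    TRUE
})

#' ExperimentDesign: what one in-silico seeding experiment observes
#'
#' The three designs mirror the study's assays: (i) pre-attached
#' populations whose adhered fraction is followed over time (adherence
#' only); (ii) populations injected into flow whose attached and adhered
#' cells are counted (attachment + adherence); (iii) populations injected
#' into circulation whose tissue-resident fraction is measured
#' (attachment + adherence + tissue residence). Each design is run on two
#' preparations, a "polarised" and a "depolarised" one, that are in
#' reality mixtures with different polarised fractions.
#'
#' @slot id One of \code{"i"}, \code{"ii"}, \code{"iii"}.
#' @slot observables Character subset of \code{"attached"},
#'   \code{"adhered"}, \code{"tissue"} (sums over both polarity arms --
#'   the assays cannot see polarity once the cells are down).
#' @slot times Observation times, seconds, strictly increasing.
#' @slot mixtures Named numeric: polarised fraction of each preparation.
#' @slot initialCompartment \code{"circulating"} or \code{"attached"}.
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
         representation(id = "character", observables = "character",
                        times = "numeric", mixtures = "numeric",
                        initialCompartment = "character"))

setValidity("ExperimentDesign", function(object) {
    if (!object@id %in% c("i", "ii", "iii"))
        return("design id must be 'i', 'ii' or 'iii'")
    if (length(object@times) < 1L || any(diff(object@times) <= 0) ||
        any(object@times <= 0))
        return("observation times must be positive and strictly increasing")
    if (!all(object@observables %in% c("attached", "adhered", "tissue")))
        return("observables must be among attached/adhered/tissue")
    if (any(object@mixtures < 0) || any(object@mixtures > 1))
        return("mixture fractions must lie in [0, 1]")
    if (is.null(names(object@mixtures)) || anyDuplicated(names(object@mixtures)))
        return("mixtures must carry unique preparation names")
    if (!object@initialCompartment %in% c("circulating", "attached"))
        return("initialCompartment must be 'circulating' or 'attached'")
    TRUE
})

#' ObservationSet: measured values for one experiment design
#'
#' @slot designId Design this set belongs to.
#' @slot data data.frame with columns \code{prep}, \code{observable},
#'   \code{time_s}, \code{value} (values on the same scale as the
#'   design's observable; preparations are normalised to an initial
#'   population of 100).
#' @exportClass ObservationSet
setClass("ObservationSet",
         representation(designId = "character", data = "data.frame"))

setValidity("ObservationSet", function(object) {
    need <- c("prep", "observable", "time_s", "value")
    if (!all(need %in% names(object@data)))
        return(sprintf("observation data must have columns %s",
                       paste(need, collapse = ", ")))
    v <- object@data$value
    if (any(!is.finite(v))) return("observed values must be finite")
    if (any(v < 0)) return("observed values must be non-negative")
    TRUE
})

#' FitResult: outcome of the linked least-squares fit
#'
#' @slot rates Estimated \linkS4class{TransferRates}.
#' @slot rss Pooled residual sum of squares at the optimum.
#' @slot converged Logical convergence flag of the best start.
#' @slot iterations Iterations used by the best start.
#' @slot nStarts Number of random restarts performed.
#' @slot startRss RSS reached by each restart.
#' @slot ci 6 x 2 matrix of bootstrap confidence limits (NA until
#'   \code{bootstrapCI} is run).
#' @slot unidentifiable Names of rates the data do not constrain.
#' @exportClass FitResult
setClass("FitResult",
         representation(rates = "TransferRates", rss = "numeric",
                        converged = "logical", iterations = "numeric",
                        nStarts = "numeric", startRss = "numeric",
                        ci = "matrix", unidentifiable = "character"))

#' PoleCall: the definitional polarity call on one boundary profile
#'
#' A cell is polarised when some contiguous arc of its membrane covering
#' less than half the circumference is enriched at least
#' \code{threshold}-fold over the remaining membrane.
#'
#' @slot polarised Logical call.
#' @slot arcStart 1-based index of the first bin of the best arc.
#' @slot arcLength Arc length as a fraction of the circumference.
#' @slot enrichment Mean intensity inside the arc over mean outside.
#' @slot threshold Enrichment threshold the call used.
#' @slot nBins Number of angular bins of the profile.
#' @exportClass PoleCall
setClass("PoleCall",
         representation(polarised = "logical", arcStart = "integer",
                        arcLength = "numeric", enrichment = "numeric",
                        threshold = "numeric", nBins = "integer"))

#' DecayFit: plateau-exponential depolarisation kinetics
#'
#' Model \eqn{f(t) = P + (f_0 - P)\,2^{-t/T_{1/2}}}: the polarised
#' fraction decays from \eqn{f_0} towards a plateau \eqn{P} of stably
#' polarised cells with half-life \eqn{T_{1/2}} (hours).
#'
#' @slot f0 Initial polarised fraction.
#' @slot plateau Plateau fraction P.
#' @slot halfLife Half-life in hours.
#' @slot rss Residual sum of squares of the fit.
#' @slot decaying FALSE when the data show no decay (flat, or half-life
#'   driven to its bound); parameter values are then not interpretable.
#' @slot data The fitted time course (time_h, fraction).
#' @exportClass DecayFit
setClass("DecayFit",
         representation(f0 = "numeric", plateau = "numeric",
                        halfLife = "numeric", rss = "numeric",
                        decaying = "logical", data = "data.frame"))

#' PeakFit: two-peak decomposition of an aggregation-score histogram
#'
#' @slot peaks data.frame with one row per peak (ordered cap then spot,
#'   i.e. by location): amplitude, mu, sigma, lambda, location (mode of
#'   the fitted peak) and weight (share of fitted area).
#' @slot boundary Decision boundary on the score axis (NA for a
#'   single-population fit).
#' @slot rss Residual sum of squares against the histogram counts.
#' @slot single TRUE when the histogram does not support two peaks.
#' @slot shape Peak shape used ("emg" or "gaussian").
#' @slot breaks,counts Histogram the fit was performed on.
#' @slot classes Factor (cap/spot) with one entry per input score.
#' @exportClass PeakFit
setClass("PeakFit",
         representation(peaks = "data.frame", boundary = "numeric",
                        rss = "numeric", single = "logical",
                        shape = "character", breaks = "numeric",
                        counts = "numeric", classes = "factor"))
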