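#' Construct a TransferRates object
#'
#' @param kAttPol,kAttDep Attachment rates (circulation to attached) for
#'   polarised and depolarised cells.
#' @param kAdhPol,kAdhDep Adherence rates (attached to adhered).
#' @param kTissPol,kTissDep Tissue-residence rates (adhered to tissue).
#' @param units \code{"per_s"} (fraction per second, the internal unit) or
#'   \code{"pct_per_s"} (percent per second, as rates are usually quoted;
#'   10.74 \%/s is stored as 0.1074 /s).
#'
#' @return A \linkS4class{TransferRates} object.
#' @examples
#' ## the fitted seeding rates of the melanoma cascade, quoted in %/s
#' transferRates(10.74, 3.81, 3.95, 3.02, 0.06, 0.05, units = "pct_per_s")
#' @export
transferRates <- function(kAttPol, kAttDep, kAdhPol, kAdhDep,
                          kTissPol, kTissDep,
                          units = c("per_s", "pct_per_s")) {
    units <- match.arg(units)
    r <- c(kAttPol = kAttPol, kAttDep = kAttDep,
           kAdhPol = kAdhPol, kAdhDep = kAdhDep,
           kTissPol = kTissPol, kTissDep = kTissDep)
    if (units == "pct_per_s") r <- r / 100
    new("TransferRates", rates = r)
}

#' Extract the rate vector of a TransferRates object
#'
#' @param object A \linkS4class{TransferRates}.
#' @param units \code{"per_s"} or \code{"pct_per_s"}.
#' @return Named numeric of length 6.
#' @export
rateVector <- function(object, units = c("per_s", "pct_per_s")) {
    stopifnot(is(object, "TransferRates"))
    units <- match.arg(units)
    r <- object@rates
    if (units == "pct_per_s") r <- r * 100
    r
}

#' @describeIn transferRates The study's fitted transfer rates (10.74,
#'   3.81, 3.95, 3.02, 0.06, 0.05 \%/s), convenient as a reference
#'   parameterisation for simulations and recovery experiments.
#' @export
fittedSeedingRates <- function() {
    transferRates(10.74, 3.81, 3.95, 3.02, 0.06, 0.05, units = "pct_per_s")
}

#' @export
setMethod("show", "TransferRates", function(object) {
    r <- object@rates
    cat("TransferRates (1/s):\n")
    m <- matrix(r, nrow = 2, byrow = FALSE,
                dimnames = list(c("polarised", "depolarised"),
                                c("attachment", "adherence", "tissue")))
    print(m)
    invisible(object)
})

#' Construct a compartment state vector
#'
#' @param circulatingPol,circulatingDep,attachedPol,attachedDep,adheredPol,adheredDep,tissue
#'   Non-negative populations (counts or percentages, consistent within a
#'   run).
#' @return Named numeric of length 7 in canonical compartment order.
#' @examples
#' compartmentState(circulatingPol = 100, circulatingDep = 100)
#' @export
compartmentState <- function(circulatingPol = 0, circulatingDep = 0,
                             attachedPol = 0, attachedDep = 0,
                             adheredPol = 0, adheredDep = 0, tissue = 0) {
    s <- c(circulatingPol, circulatingDep, attachedPol, attachedDep,
           adheredPol, adheredDep, tissue)
    names(s) <- .compartments
    .checkState(s)
    s
}

.checkState <- function(s) {
    if (length(s) != 7L)
        stop("a compartment state has exactly 7 entries")
    if (any(!is.finite(s)))
        stop("compartment populations must be finite")
    if (any(s < 0))
        stop("negative initial state: compartment populations must be >= 0")
    invisible(s)
}

## coerce a user-supplied state (named or positional) to canonical order
.asState <- function(init) {
    if (!is.null(names(init)) && all(names(init) %in% .compartments) &&
        !any(names(init) == "")) {
        s <- stats::setNames(numeric(7), .compartments)
        s[names(init)] <- init
    } else {
        if (length(init) != 7L)
            stop("init must be a length-7 state (see compartmentState())")
        s <- stats::setNames(as.numeric(init), .compartments)
    }
    .checkState(s)
    s
}

#' @export
setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: %d time points over [%g, %g] s\n",
                length(object@times), min(object@times), max(object@times)))
    cat("final state:\n")
    print(round(object@states[nrow(object@states), ], 4))
    invisible(object)
})

#' @export
as.data.frame.Trajectory <- function(x, ...) {
    data.frame(time_s = x@times, x@states, check.names = FALSE)
}

#' @export
setMethod("show", "PoleCall", function(object) {
    cat(sprintf(
        "PoleCall: %s (arc %.3f of circumference from bin %d, %.2f-fold, threshold %.2f)\n",
        if (object@polarised) "polarised" else "not polarised",
        object@arcLength, object@arcStart, object@enrichment,
        object@threshold))
    invisible(object)
})

#' @export
setMethod("show", "DecayFit", function(object) {
    if (!object@decaying) {
        cat("DecayFit: no decay detected (flat or non-decaying course)\n")
    } else {
        cat(sprintf(
            "DecayFit: f0 = %.3f, plateau = %.3f, T1/2 = %.3f h (RSS %.3g)\n",
            object@f0, object@plateau, object@halfLife, object@rss))
    }
    invisible(object)
})

#' @export
setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: RSS %.4g after %d iterations (%d starts)%s\n",
                object@rss, as.integer(object@iterations),
                as.integer(object@nStarts),
                if (object@converged) "" else " [not converged]"))
    show(object@rates)
    if (length(object@unidentifiable))
        cat("unidentifiable:", paste(object@unidentifiable, collapse = ", "),
            "\n")
    if (!all(is.na(object@ci))) {
        cat("bootstrap 95% CI (1/s):\n")
        print(object@ci)
    }
    invisible(object)
})

#' @export
setMethod("show", "PeakFit", function(object) {
    if (object@single) {
        cat("PeakFit: single population (no second peak supported)\n")
    } else {
        cat(sprintf(
            "PeakFit (%s): cap at %.3g, spot at %.3g, boundary %.3g (RSS %.3g)\n",
            object@shape, object@peaks$location[1], object@peaks$location[2],
            object@boundary, object@rss))
    }
    invisible(object)
})
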