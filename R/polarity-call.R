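## The definitional single-cell polarity call: a cell is polarised when a
## single contiguous membrane arc covering less than half of the
## circumference is enriched two-fold or more over the remaining
## membrane. Operationalised on 1-D circular profiles of membrane
## intensity (angular bins around the perimeter).

#' Call single-cell polarity on a boundary profile
#'
#' Exhaustively searches all contiguous circular arcs (any length up to
#' one bin short of the full circle) for the arc maximising the
#' enrichment, defined as the mean intensity inside the arc over the mean
#' intensity of the remaining membrane. That arc is the candidate pole:
#' the cell is called polarised when the candidate's enrichment reaches
#' \code{threshold} \emph{and} the candidate spans less than
#' \code{maxArc} of the circumference. Searching all lengths matters: an
#' enriched region wider than half the circumference must disqualify the
#' cell rather than be trimmed to a qualifying sub-arc. Ties are broken
#' towards the smallest arc, then the smallest start index, making the
#' call deterministic; the call is invariant to rotation (the start
#' index shifts accordingly) and to positive scaling of the profile.
#'
#' @param profile Numeric vector of n >= 16 equally spaced, non-negative
#'   angular samples of membrane intensity (circular topology).
#' @param threshold Enrichment threshold (default 2, i.e. two-fold).
#' @param maxArc Maximum arc length as a fraction of the circumference;
#'   qualifying arcs must be strictly shorter (default 0.5, "less than
#'   half of the circumference").
#' @param minIntensity Optional absolute floor: arcs whose mean intensity
#'   is at or below it cannot qualify (default 0, no floor).
#' @return A \linkS4class{PoleCall}. An all-zero profile yields an
#'   unpolarised call with undefined enrichment.
#' @examples
#' x <- rep(1, 64); x[10:25] <- 3      # 90-degree arc at 3x base level
#' callPole(x)
#' @export
callPole <- function(profile, threshold = 2, maxArc = 0.5,
                     minIntensity = 0) {
    x <- as.numeric(profile)
    n <- length(x)
    if (n < 16) stop("a boundary profile needs at least 16 angular bins")
    if (any(!is.finite(x)) || any(x < 0))
        stop("profile intensities must be finite and non-negative")
    total <- sum(x)
    cs <- c(0, cumsum(c(x, x)))
    bestE <- -Inf; bestS <- NA_integer_; bestL <- NA_real_
    for (L in seq_len(n - 1L)) {
        s <- seq_len(n)
        sumIn <- cs[s + L] - cs[s]
        meanIn <- sumIn / L
        meanOut <- (total - sumIn) / (n - L)
        e <- meanIn / meanOut
        e[meanIn <= minIntensity] <- -Inf
        e[is.nan(e)] <- -Inf          # 0/0: no signal anywhere
        i <- which.max(e)
        if (e[i] > bestE) { bestE <- e[i]; bestS <- s[i]; bestL <- L / n }
    }
    if (!is.finite(bestE) && bestE < 0) {   # nothing qualified at all
        return(new("PoleCall", polarised = FALSE, arcStart = NA_integer_,
                   arcLength = NA_real_, enrichment = NA_real_,
                   threshold = threshold, nBins = as.integer(n)))
    }
    new("PoleCall",
        polarised = bestE >= threshold && bestL < maxArc - 1e-12,
        arcStart = as.integer(bestS), arcLength = bestL,
        enrichment = bestE, threshold = threshold, nBins = as.integer(n))
}

#' Call polarity on many boundary profiles
#'
#' @param profiles Numeric matrix (one profile per row) or list of
#'   numeric vectors.
#' @inheritParams callPole
#' @return data.frame with columns \code{cell_id}, \code{polarised},
#'   \code{arc_start_frac}, \code{arc_len_frac}, \code{enrichment}.
#' @export
callPoles <- function(profiles, threshold = 2, maxArc = 0.5,
                      minIntensity = 0) {
    if (is.matrix(profiles))
        profiles <- split(profiles, row(profiles))
    if (!length(profiles)) stop("no profiles supplied")
    rows <- lapply(seq_along(profiles), function(i) {
        pc <- callPole(profiles[[i]], threshold, maxArc, minIntensity)
        data.frame(cell_id = i, polarised = pc@polarised,
                   arc_start_frac = (pc@arcStart - 1) / pc@nBins,
                   arc_len_frac = pc@arcLength, enrichment = pc@enrichment)
    })
    do.call(rbind, rows)
}

#' Fraction of polarised cells in a population
#'
#' @inheritParams callPoles
#' @return Fraction in [0, 1] of profiles called polarised.
#' @export
fractionPolarised <- function(profiles, threshold = 2, maxArc = 0.5,
                              minIntensity = 0) {
    calls <- callPoles(profiles, threshold, maxArc, minIntensity)
    mean(calls$polarised)
}

#' Reduce a cell image and mask to a boundary profile
#'
#' Samples a fixed-width membrane band (the outermost \code{band} pixels
#' of the mask) into \code{nBins} angular bins around the mask centroid
#' and averages the intensity per bin, yielding the circular profile the
#' polarity caller operates on. Empty bins are filled by circular linear
#' interpolation.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of the same dimension selecting one cell.
#' @param nBins Number of angular bins (default 64).
#' @param band Membrane band width in pixels (default 3).
#' @return Numeric vector of length \code{nBins}.
#' @export
boundaryProfileFromMask <- function(image, mask, nBins = 64, band = 3) {
    stopifnot(is.matrix(image), identical(dim(image), dim(mask)))
    mask <- mask > 0
    if (!any(mask)) stop("empty mask")
    er <- EBImage::erode(EBImage::Image(mask),
                         EBImage::makeBrush(2 * band + 1, "disc"))
    ring <- mask & !(EBImage::imageData(er) > 0)
    if (!any(ring)) ring <- mask
    idx <- which(ring, arr.ind = TRUE)
    cy <- mean(which(mask, arr.ind = TRUE)[, 1])
    cx <- mean(which(mask, arr.ind = TRUE)[, 2])
    ang <- atan2(idx[, 1] - cy, idx[, 2] - cx)
    bin <- pmin(nBins, floor((ang + pi) / (2 * pi) * nBins) + 1L)
    prof <- vapply(seq_len(nBins), function(b) {
        v <- image[ring][bin == b]
        if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    if (anyNA(prof)) {
        ## circular interpolation over empty bins
        ext <- c(prof, prof, prof)
        xi <- which(!is.na(ext))
        ext <- stats::approx(xi, ext[xi], xout = seq_along(ext))$y
        prof <- ext[nBins + seq_len(nBins)]
    }
    prof
}

#' Fit plateau-exponential depolarisation kinetics
#'
#' Fits \eqn{f(t) = P + (f_0 - P)\,2^{-t/T_{1/2}}} to a polarised-fraction
#' time course by bounded least squares: the fraction decays from
#' \eqn{f_0} with half-life \eqn{T_{1/2}} towards a plateau \eqn{P} of
#' stably polarised cells. A pure exponential (P = 0) cannot reconcile a
#' 1-hour half-life with a substantial polarised fraction remaining at
#' 6 hours, hence the plateau term.
#'
#' @param timeH Numeric times in hours (or a data.frame with columns
#'   \code{time_h} and \code{fraction_polarised}).
#' @param fraction Polarised fractions in [0, 1] (omit when a data.frame
#'   is given).
#' @param halfLifeMax Upper bound for the half-life (hours); a fit driven
#'   to this bound is flagged as non-decaying.
#' @return A \linkS4class{DecayFit}; evaluate it at any time with
#'   \code{predict(fit, t)}.
#' @examples
#' tc <- genDecayTimecourse(seed = 7)
#' fitDecay(tc)
#' @export
fitDecay <- function(timeH, fraction = NULL, halfLifeMax = 100) {
    if (is.data.frame(timeH)) {
        df <- timeH
        need <- c("time_h", "fraction_polarised")
        if (!all(need %in% names(df)))
            stop("data.frame input needs columns time_h, fraction_polarised")
        timeH <- df$time_h; fraction <- df$fraction_polarised
    }
    if (length(timeH) != length(fraction) || length(timeH) < 4)
        stop("need at least 4 (time, fraction) pairs")
    if (any(fraction < 0 | fraction > 1))
        stop("fractions must lie in [0, 1]")
    o <- order(timeH); timeH <- timeH[o]; fraction <- fraction[o]
    dat <- data.frame(time_h = timeH, fraction = fraction)

    modelFun <- function(p, t) p[2] + (p[1] - p[2]) * 2^(-t / p[3])
    resid <- function(p) modelFun(p, timeH) - fraction
    lo <- c(0, 0, 1e-3); hi <- c(1, 1, halfLifeMax)
    f0s <- fraction[1]; Ps <- min(fraction)
    startTh <- c(0.3, 1, 3, 10)
    best <- NULL
    for (th in startTh) {
        st <- pmin(pmax(c(f0s, Ps, th), lo), hi)
        f <- try(minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                                    fn = resid,
                                    control = minpack.lm::nls.lm.control(
                                        maxiter = 400)), silent = TRUE)
        if (inherits(f, "try-error")) next
        rss <- sum(f$fvec^2)
        if (is.null(best) || rss < best$rss) best <- list(par = f$par,
                                                          rss = rss)
    }
    if (is.null(best)) stop("decay fit failed")
    p <- best$par
    flat <- stats::sd(fraction) == 0
    nondecay <- flat || (p[1] - p[2]) < 1e-4 || p[3] >= 0.99 * halfLifeMax
    new("DecayFit", f0 = p[1], plateau = p[2], halfLife = p[3],
        rss = best$rss, decaying = !nondecay, data = dat)
}

#' @describeIn fitDecay Evaluate the fitted decay curve at times \code{t}
#'   (hours).
#' @param object A \linkS4class{DecayFit}.
#' @param t Times in hours.
#' @export
setMethod("predict", "DecayFit", function(object, t = object@data$time_h) {
    object@plateau + (object@f0 - object@plateau) *
        2^(-t / object@halfLife)
})
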