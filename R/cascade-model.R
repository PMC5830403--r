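## Deterministic simulation of the seeding cascade
##
##   circulating -> attached -> adhered -> tissue
##
## run independently for the polarised and depolarised arms, with
## first-order transfer kinetics throughout. The circulation outflow is
## exactly the attachment inflow (mass balance); there is no
## recirculation, proliferation or death, so the total population is
## conserved.

## right-hand side on the internal 8-state vector
## (circ, att, adh, tissue) x (pol, dep); tissue tracked per arm
.cascadeRHS <- function(t, y, parms) {
    k <- parms
    dy <- c(-k[1] * y[1],
            -k[2] * y[2],
             k[1] * y[1] - k[3] * y[3],
             k[2] * y[2] - k[4] * y[4],
             k[3] * y[3] - k[5] * y[5],
             k[4] * y[4] - k[6] * y[6],
             k[5] * y[5],
             k[6] * y[6])
    list(dy)
}

.toInternal <- function(init) {
    ## shared tissue at t = 0 is attributed to neither arm
    c(init[1:6], tissue_pol = 0, tissue_dep = 0)
}

.toTrajectory <- function(times, y8, tissue0) {
    states <- cbind(y8[, 1:6, drop = FALSE],
                    tissue = tissue0 + y8[, 7] + y8[, 8])
    colnames(states) <- .compartments
    new("Trajectory", times = times, states = states,
        tissueByArm = cbind(tissue_pol = y8[, 7], tissue_dep = y8[, 8]))
}

#' Simulate the metastatic seeding cascade
#'
#' Integrates the seven-compartment, six-rate model of circulation,
#' attachment, adherence and tissue residence for polarised and
#' depolarised cells under first-order transfer kinetics. Cells leave
#' circulation exactly as fast as they attach (no recirculation), so the
#' total population is conserved along the trajectory.
#'
#' @param rates A \linkS4class{TransferRates}.
#' @param init Initial state: a length-7 vector from
#'   \code{\link{compartmentState}} (or a named subset of compartments).
#' @param horizon Simulation horizon in seconds (default 15000 s, i.e.
#'   250 min).
#' @param dt Output grid spacing in seconds.
#' @param times Optional explicit output times (overrides
#'   \code{horizon}/\code{dt}); must be strictly increasing, starting
#'   at 0.
#' @param rtol,atol Integrator tolerances. The rates span three orders of
#'   magnitude, so a stiff-capable adaptive method (\code{deSolve::lsoda})
#'   at tight tolerances is used.
#'
#' @return A \linkS4class{Trajectory}.
#' @examples
#' tr <- simulateCascade(fittedSeedingRates(),
#'                       compartmentState(circulatingPol = 100,
#'                                        circulatingDep = 100))
#' tail(as.data.frame(tr), 1)
#' @seealso \code{\link{batemanClosedForm}} for the analytic solution,
#'   \code{\link{tissueResidenceFraction}}.
#' @export
simulateCascade <- function(rates, init, horizon = 15000, dt = 10,
                            times = NULL, rtol = 1e-9, atol = 1e-12) {
    stopifnot(is(rates, "TransferRates"))
    validObject(rates)
    s <- .asState(init)
    if (is.null(times)) {
        if (!is.finite(horizon) || horizon <= 0)
            stop("horizon must be a positive number of seconds")
        times <- seq(0, horizon, by = dt)
        if (times[length(times)] < horizon) times <- c(times, horizon)
    }
    if (times[1] != 0 || any(diff(times) <= 0))
        stop("output times must be strictly increasing and start at 0")
    if (rtol <= 0 || atol <= 0) stop("integrator tolerances must be > 0")
    k <- rateVector(rates)
    out <- deSolve::lsoda(y = .toInternal(s), times = times,
                          func = .cascadeRHS, parms = unname(k),
                          rtol = rtol, atol = atol)
    y8 <- unname(out[, -1, drop = FALSE])
    ## clip integrator jitter around zero
    y8[y8 < 0 & y8 > -atol * 10] <- 0
    .toTrajectory(times, y8, tissue0 = s[["tissue"]])
}

## stable divided difference (exp(-a t) - exp(-b t)) / (b - a): the
## expm1 form avoids cancellation where (b - a) t is small, the plain
## difference avoids overflow where it is large
.dd2 <- function(a, b, t) {
    d <- b - a
    out <- (exp(-a * t) - exp(-b * t)) / d
    small <- abs(d * t) < 1e-4
    if (any(small))
        out[small] <- -exp(-a * t[small]) * expm1(-d * t[small]) / d
    out
}

## closed-form solution of one arm (k1 -> k2 -> k3 chain), rates pairwise
## distinct; returns matrix with columns C, A, H, Tarm
.armClosedForm <- function(k1, k2, k3, C0, A0, H0, times) {
    e1 <- exp(-k1 * times); e2 <- exp(-k2 * times); e3 <- exp(-k3 * times)
    C <- C0 * e1
    A <- A0 * e2 + C0 * k1 * .dd2(k1, k2, times)
    S <- e1 / ((k2 - k1) * (k3 - k1)) +
         e2 / ((k1 - k2) * (k3 - k2)) +
         e3 / ((k1 - k3) * (k2 - k3))
    H <- H0 * e3 + A0 * k2 * .dd2(k2, k3, times) + C0 * k1 * k2 * S
    cbind(C, A, H, (C0 + A0 + H0) - C - A - H)
}

.armExpm <- function(k1, k2, k3, C0, A0, H0, times) {
    M <- matrix(c(-k1,  k1,   0,  0,
                    0, -k2,  k2,  0,
                    0,   0, -k3, k3,
                    0,   0,   0,  0), 4, 4, byrow = FALSE)
    y0 <- c(C0, A0, H0, 0)
    t(vapply(times, function(tt) {
        as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(M * tt))) %*% y0)
    }, numeric(4)))
}

#' Analytic (Bateman) solution of the seeding cascade
#'
#' Exact solution of the linear three-step chain for each polarity arm via
#' the classical Bateman formulas. When the three rates within an arm are
#' not pairwise distinct the Bateman form degenerates; a matrix-exponential
#' evaluation is then used (\code{degenerate = "expm"}, the default) or an
#' error is raised (\code{degenerate = "error"}). Near-coincident rates
#' (relative gap below 1e-3) take the matrix-exponential path as well to
#' avoid catastrophic cancellation.
#'
#' @inheritParams simulateCascade
#' @param times Evaluation times in seconds (strictly increasing, >= 0).
#' @param degenerate How to handle repeated rates within an arm.
#' @return A \linkS4class{Trajectory}.
#' @examples
#' batemanClosedForm(fittedSeedingRates(),
#'                   compartmentState(circulatingPol = 100),
#'                   times = c(0, 900, 1800))
#' @export
batemanClosedForm <- function(rates, init, times,
                              degenerate = c("expm", "error")) {
    stopifnot(is(rates, "TransferRates"))
    degenerate <- match.arg(degenerate)
    s <- .asState(init)
    if (any(times < 0) || any(diff(times) <= 0))
        stop("times must be non-negative and strictly increasing")
    k <- rateVector(rates)
    arm <- function(k1, k2, k3, C0, A0, H0) {
        ks <- c(k1, k2, k3)
        if (all(ks == 0))
            return(cbind(rep(C0, length(times)), A0, H0, 0))
        gaps <- abs(c(k1 - k2, k1 - k3, k2 - k3))
        if (min(gaps) <= 1e-3 * max(ks)) {
            if (degenerate == "error")
                stop("repeated (or near-repeated) rates within one arm: ",
                     "no Bateman form; use degenerate = \"expm\"")
            return(.armExpm(k1, k2, k3, C0, A0, H0, times))
        }
        .armClosedForm(k1, k2, k3, C0, A0, H0, times)
    }
    pol <- arm(k[["kAttPol"]], k[["kAdhPol"]], k[["kTissPol"]],
               s[["circulating_pol"]], s[["attached_pol"]], s[["adhered_pol"]])
    dep <- arm(k[["kAttDep"]], k[["kAdhDep"]], k[["kTissDep"]],
               s[["circulating_dep"]], s[["attached_dep"]], s[["adhered_dep"]])
    y8 <- cbind(pol[, 1], dep[, 1], pol[, 2], dep[, 2],
                pol[, 3], dep[, 3], pol[, 4], dep[, 4])
    .toTrajectory(times, y8, tissue0 = s[["tissue"]])
}

#' Tissue-residence fraction at a given time
#'
#' Fraction of the initial population that is tissue resident at time
#' \code{t}, optionally attributed to one polarity arm. For
#' \code{arm = "pol"} (resp. \code{"dep"}) the numerator is the tissue
#' inflow contributed by that arm and the denominator the arm's initial
#' population, so pure-population comparisons are well defined even
#' though the tissue compartment itself is shared.
#'
#' @param traj A \linkS4class{Trajectory}.
#' @param t Query time in seconds; must lie within the trajectory's time
#'   range (no extrapolation). Linear interpolation between grid points.
#' @param arm \code{"both"}, \code{"pol"} or \code{"dep"}.
#' @return Fraction in [0, 1].
#' @export
tissueResidenceFraction <- function(traj, t, arm = c("both", "pol", "dep")) {
    stopifnot(is(traj, "Trajectory"))
    arm <- match.arg(arm)
    tt <- traj@times
    if (any(t < tt[1]) || any(t > tt[length(tt)]))
        stop(sprintf("t outside the trajectory range [%g, %g] s",
                     tt[1], tt[length(tt)]))
    s0 <- traj@states[1, ]
    interp <- function(y) stats::approx(tt, y, xout = t)$y
    if (arm == "both") {
        num <- interp(traj@states[, "tissue"])
        den <- sum(s0)
    } else {
        col <- if (arm == "pol") "tissue_pol" else "tissue_dep"
        sfx <- if (arm == "pol") "_pol" else "_dep"
        num <- interp(traj@tissueByArm[, col])
        den <- sum(s0[paste0(c("circulating", "attached", "adhered"), sfx)]) +
            traj@tissueByArm[1, col]
    }
    if (den == 0) return(rep(0, length(t)))
    unname(pmin(pmax(num / den, 0), 1))
}
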