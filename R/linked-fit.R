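## Linked constrained least-squares estimation of the six transfer rates
## across the three in-silico experiment designs. One pooled residual
## vector constrains the shared rates to fit all experiments
## simultaneously ("linked fit").

#' Construct an experiment design
#'
#' Builds one of the three in-silico seeding experiments. Defaults follow
#' the assay logic of the study: design i starts with pre-attached cells
#' and follows the adhered fraction (adherence only; no tissue transfer in
#' vitro); design ii injects cells into flow and counts attached and
#' adhered cells (attachment + adherence; no tissue); design iii injects
#' cells into circulation and measures the tissue-resident fraction (full
#' chain). Each design is run on a "polarised" and a "depolarised"
#' preparation; the preparations are mixtures, the depolarised one with a
#' polarised fraction 0.30 lower (generic depolarisation reduces the
#' polarised fraction by 30 percentage points).
#'
#' Default observation times sample each observable across its dynamic
#' range under seconds-scale attachment/adherence kinetics and the slower
#' tissue transfer; see the package vignette for the rationale.
#'
#' @param id \code{"i"}, \code{"ii"} or \code{"iii"}.
#' @param times Observation times in seconds.
#' @param mixtures Named numeric, polarised fraction of each preparation.
#' @param observables Which summed quantities are measured.
#' @return An \linkS4class{ExperimentDesign}.
#' @examples
#' experimentDesign("i")
#' @export
experimentDesign <- function(id = c("i", "ii", "iii"), times = NULL,
                             mixtures = NULL, observables = NULL) {
    id <- match.arg(id)
    def <- switch(id,
        i   = list(times = c(5, 15, 30, 60, 120, 300),
                   observables = "adhered",
                   initial = "attached"),
        ii  = list(times = c(2, 5, 10, 20, 40, 80, 160, 320),
                   observables = c("attached", "adhered"),
                   initial = "circulating"),
        iii = list(times = c(300, 600, 900, 1200, 1800, 2700, 3600),
                   observables = "tissue",
                   initial = "circulating"))
    if (is.null(times)) times <- def$times
    if (is.null(observables)) observables <- def$observables
    if (is.null(mixtures)) mixtures <- c(polarised = 0.65, depolarised = 0.35)
    new("ExperimentDesign", id = id, observables = observables,
        times = as.numeric(times), mixtures = mixtures,
        initialCompartment = def$initial)
}

#' @describeIn experimentDesign The default list of all three designs.
#' @export
designDefaults <- function() {
    list(i = experimentDesign("i"), ii = experimentDesign("ii"),
         iii = experimentDesign("iii"))
}

## rates actually active in a design: in vitro designs have no tissue
## transfer, design i additionally starts past the attachment step
.designRates <- function(rates, design) {
    k <- rateVector(rates)
    if (design@id %in% c("i", "ii")) k[c("kTissPol", "kTissDep")] <- 0
    do.call(transferRates, as.list(k))
}

.identifiedRates <- function(design) {
    switch(design@id,
           i = c("kAdhPol", "kAdhDep"),
           ii = c("kAttPol", "kAttDep", "kAdhPol", "kAdhDep"),
           iii = .rateNames)
}

#' Model-implied observations for one experiment design
#'
#' Computes the observable trajectory a design would record under given
#' transfer rates: for each preparation, the initial population (100,
#' split between the polarity arms by the preparation's polarised
#' fraction) is placed in the design's initial compartment, the cascade is
#' evaluated, and the design's observables (sums over both arms, as the
#' assays cannot see polarity) are read off at the observation times.
#'
#' @param rates A \linkS4class{TransferRates}.
#' @param design An \linkS4class{ExperimentDesign}.
#' @param method \code{"closed_form"} evaluates the exact Bateman
#'   solution (with matrix-exponential fallback for degenerate rates);
#'   \code{"ode"} runs the numerical integrator. Both agree to integrator
#'   tolerance.
#' @return data.frame with columns \code{prep}, \code{observable},
#'   \code{time_s}, \code{value}.
#' @export
predictObservations <- function(rates, design,
                                method = c("closed_form", "ode")) {
    stopifnot(is(design, "ExperimentDesign"))
    validObject(design)
    method <- match.arg(method)
    dr <- .designRates(rates, design)
    times <- design@times
    out <- lapply(names(design@mixtures), function(prep) {
        f <- design@mixtures[[prep]]
        init <- if (design@initialCompartment == "circulating")
            compartmentState(circulatingPol = 100 * f,
                             circulatingDep = 100 * (1 - f))
        else
            compartmentState(attachedPol = 100 * f,
                             attachedDep = 100 * (1 - f))
        tr <- if (method == "closed_form")
            batemanClosedForm(dr, init, times = c(0, times))
        else
            simulateCascade(dr, init, times = c(0, times))
        st <- tr@states[-1, , drop = FALSE]
        vals <- vapply(design@observables, function(obs) {
            switch(obs,
                   attached = st[, "attached_pol"] + st[, "attached_dep"],
                   adhered  = st[, "adhered_pol"] + st[, "adhered_dep"],
                   tissue   = st[, "tissue"])
        }, numeric(length(times)))
        data.frame(prep = prep,
                   observable = rep(design@observables,
                                    each = length(times)),
                   time_s = rep(times, length(design@observables)),
                   value = as.numeric(vals))
    })
    do.call(rbind, out)
}

#' Construct an ObservationSet
#'
#' @param designId Design the observations belong to.
#' @param data data.frame with columns \code{prep}, \code{observable},
#'   \code{time_s}, \code{value}.
#' @return An \linkS4class{ObservationSet}.
#' @export
observationSet <- function(designId, data) {
    new("ObservationSet", designId = designId, data = data)
}

## pooled residual vector over all observation sets, rates on log10 scale
.pooledResiduals <- function(logk, observations, designs) {
    k <- 10^logk
    names(k) <- .rateNames
    rates <- do.call(transferRates, as.list(k))
    unlist(lapply(observations, function(obs) {
        design <- designs[[obs@designId]]
        pred <- predictObservations(rates, design)
        key <- function(d) paste(d$prep, d$observable, d$time_s)
        m <- match(key(obs@data), key(pred))
        if (anyNA(m))
            stop("observations do not match the design's observables/times")
        pred$value[m] - obs@data$value
    }), use.names = FALSE)
}

## staged warm start along the cascade: adherence from design i alone,
## then attachment from design ii, then tissue residence from design
## iii, each a low-dimensional subproblem fitted with the others held
## fixed; returns a log10 rate vector
.warmStart <- function(observations, designs, lo, hi) {
    par <- rep(-2.5, 6)
    ids <- vapply(observations, function(o) o@designId, character(1))
    maskedFit <- function(par, free, sel) {
        fn <- function(p) {
            full <- par; full[free] <- p
            .pooledResiduals(full, observations[sel], designs)
        }
        f <- try(minpack.lm::nls.lm(
            par = par[free], lower = lo[free], upper = hi[free], fn = fn,
            control = minpack.lm::nls.lm.control(maxiter = 200)),
            silent = TRUE)
        if (!inherits(f, "try-error")) par[free] <- f$par
        par
    }
    if (any(ids == "i"))
        par <- maskedFit(par, 3:4, ids == "i")
    if (any(ids == "ii"))
        par <- maskedFit(par, 1:2, ids == "ii")
    if (any(ids == "iii"))
        par <- maskedFit(par, 5:6, ids == "iii")
    par
}

#' Linked constrained least-squares fit of the six transfer rates
#'
#' Minimises the pooled squared residual across all supplied observation
#' sets simultaneously, constraining the shared rates to ranges that fit
#' every experiment at once. Rates are optimised on a log10 scale within
#' bounds by trust-region Levenberg--Marquardt least squares
#' (\code{minpack.lm}). The first start is a staged warm start that
#' walks down the cascade (adherence rates from design i, attachment
#' rates from design ii, tissue-residence rates from design iii);
#' \code{nStarts} seeded log-uniform random restarts follow, and the
#' best start is returned. Optimisation terminates at a residual sum of
#' squares at or below \code{rssTol} or after \code{maxIter} iterations,
#' whichever comes first.
#'
#' Rates whose residual sensitivity at the optimum is negligible (the
#' corresponding Jacobian column is numerically zero) are flagged as
#' unidentifiable rather than silently reported.
#'
#' @param observations List of \linkS4class{ObservationSet}s (at least
#'   one, non-empty).
#' @param designs Named list of \linkS4class{ExperimentDesign}s, names
#'   matching the observation sets' design ids.
#' @param lower,upper Rate bounds in 1/s.
#' @param nStarts Number of random restarts.
#' @param seed Integer seed making the restarts reproducible.
#' @param rssTol Terminal residual sum of squares (default 1e-8).
#' @param maxIter Iteration cap per restart (default 400).
#' @return A \linkS4class{FitResult}.
#' @examples
#' designs <- designDefaults()
#' truth <- fittedSeedingRates()
#' obs <- genObservationSets(truth, designs, noiseSd = 0, seed = 1)
#' fit <- linkedFit(obs, designs, nStarts = 4, seed = 1)
#' rateVector(fit@rates, units = "pct_per_s")
#' @export
linkedFit <- function(observations, designs = designDefaults(),
                      lower = 1e-8, upper = 1, nStarts = 10, seed = 1,
                      rssTol = 1e-8, maxIter = 400) {
    if (length(observations) == 0)
        stop("at least one observation set is required")
    observations <- lapply(observations, function(o) {
        stopifnot(is(o, "ObservationSet")); validObject(o); o
    })
    if (any(!vapply(observations, function(o) nrow(o@data) > 0, logical(1))))
        stop("empty observation set")
    ids <- vapply(observations, function(o) o@designId, character(1))
    if (!all(ids %in% names(designs)))
        stop("no design supplied for observation set(s): ",
             paste(setdiff(ids, names(designs)), collapse = ", "))
    if (lower <= 0 || upper <= lower)
        stop("bounds must satisfy 0 < lower < upper")

    lo <- rep(log10(lower), 6); hi <- rep(log10(upper), 6)
    set.seed(seed)
    starts <- rbind(.warmStart(observations, designs, lo, hi),
                    matrix(stats::runif(6 * nStarts, log10(1e-5), log10(1)),
                           nrow = nStarts))
    best <- NULL; startRss <- numeric(0)
    for (i in seq_len(nrow(starts))) {
        fit <- try(minpack.lm::nls.lm(
            par = pmin(pmax(starts[i, ], lo), hi),
            lower = lo, upper = hi,
            fn = .pooledResiduals,
            observations = observations, designs = designs,
            control = minpack.lm::nls.lm.control(
                maxiter = maxIter, ftol = 1e-15, ptol = 1e-15,
                gtol = 0)), silent = TRUE)
        if (inherits(fit, "try-error")) { startRss <- c(startRss, NA); next }
        rss <- sum(fit$fvec^2)
        startRss <- c(startRss, rss)
        if (is.null(best) || rss < best$rss)
            best <- list(fit = fit, rss = rss)
        if (rss <= rssTol) break
    }
    if (is.null(best)) stop("all restarts failed")
    k <- 10^best$fit$par
    names(k) <- .rateNames
    rates <- do.call(transferRates, as.list(k))

    ## identifiability: a rate whose perturbation leaves all residuals
    ## unchanged is unconstrained by the data
    J <- .fdJacobian(function(p) .pooledResiduals(p, observations, designs),
                     best$fit$par)
    cn <- sqrt(colSums(J^2))
    unident <- .rateNames[cn < 1e-6 * max(cn, 1e-300)]
    ## rates not touched by any supplied design are unidentifiable too
    touched <- unique(unlist(lapply(ids, function(id)
        .identifiedRates(designs[[id]]))))
    unident <- union(unident, setdiff(.rateNames, touched))

    ci <- matrix(NA_real_, 6, 2,
                 dimnames = list(.rateNames, c("lower", "upper")))
    new("FitResult", rates = rates, rss = best$rss,
        converged = best$fit$info %in% 1:4 || best$rss <= rssTol,
        iterations = as.numeric(best$fit$niter),
        nStarts = as.numeric(nStarts), startRss = startRss,
        ci = ci, unidentifiable = sort(unident))
}

.fdJacobian <- function(fn, par, h = 1e-6) {
    f0 <- fn(par)
    J <- matrix(0, length(f0), length(par))
    for (j in seq_along(par)) {
        p <- par; p[j] <- p[j] + h
        J[, j] <- (fn(p) - f0) / h
    }
    J
}

#' Residual-resampling bootstrap confidence intervals for the fitted rates
#'
#' Resamples the pooled fit residuals with replacement, adds them to the
#' fitted predictions (floored at zero), refits from the point estimate,
#' and returns per-rate percentile intervals.
#'
#' @inheritParams linkedFit
#' @param fit A converged \linkS4class{FitResult}.
#' @param nBoot Number of bootstrap draws (>= 2).
#' @param level Interval level (default 0.95).
#' @return The \code{fit} with its \code{ci} slot filled; bootstrap draws
#'   attached as attribute \code{"draws"} of the ci matrix.
#' @export
bootstrapCI <- function(observations, designs, fit, nBoot = 200, seed = 1,
                        level = 0.95) {
    stopifnot(is(fit, "FitResult"))
    if (nBoot < 2) stop("nBoot must be at least 2")
    logk0 <- log10(rateVector(fit@rates))
    resid0 <- .pooledResiduals(logk0, observations, designs)
    preds <- lapply(observations, function(o) {
        p <- predictObservations(fit@rates, designs[[o@designId]])
        key <- function(d) paste(d$prep, d$observable, d$time_s)
        p$value[match(key(o@data), key(p))]
    })
    lens <- vapply(observations, function(o) nrow(o@data), integer(1))
    lo <- rep(log10(1e-8), 6); hi <- rep(0, 6)
    set.seed(seed)
    draws <- matrix(NA_real_, nBoot, 6, dimnames = list(NULL, .rateNames))
    for (b in seq_len(nBoot)) {
        rstar <- sample(resid0, length(resid0), replace = TRUE)
        obsStar <- observations
        off <- 0
        for (j in seq_along(obsStar)) {
            v <- pmax(preds[[j]] + rstar[off + seq_len(lens[j])], 0)
            obsStar[[j]]@data$value <- v
            off <- off + lens[j]
        }
        refit <- try(minpack.lm::nls.lm(
            par = logk0, lower = lo, upper = hi,
            fn = .pooledResiduals,
            observations = obsStar, designs = designs,
            control = minpack.lm::nls.lm.control(maxiter = 200)),
            silent = TRUE)
        if (!inherits(refit, "try-error"))
            draws[b, ] <- 10^refit$par
    }
    a <- (1 - level) / 2
    ci <- t(apply(draws, 2, stats::quantile,
                  probs = c(a, 1 - a), na.rm = TRUE))
    dimnames(ci) <- list(.rateNames, c("lower", "upper"))
    attr(ci, "draws") <- draws
    fit@ci <- ci
    fit
}
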