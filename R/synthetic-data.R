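## Seeded synthetic-data generators. Every input the pipeline consumes
## can be generated with known ground truth: fluorescence images of
## detached cells with cap-like or spot-like ezrin poles, angular
## boundary profiles, observation sets from the seeding cascade,
## binomially sampled depolarisation time courses, and labelled
## aggregation-score samples. All generators are pure functions of their
## arguments including the seed.

#' Generate a synthetic fluorescence image of detached cells
#'
#' Draws non-overlapping disc-shaped cells with a membrane band on a dim
#' background. Polarised cells carry an ezrin pole occupying a
#' contiguous arc of the membrane band: cap-like poles are wide with
#' moderate enrichment, spot-like poles narrow with high enrichment.
#' Additive Gaussian noise (optionally on top of Poisson shot noise)
#' emulates camera noise. The per-cell ground truth (type, arc, pole
#' enrichment and pixel area) is returned alongside the image.
#'
#' @param nCells Number of cells.
#' @param imageSize Image side length in pixels.
#' @param radiusRange Cell radius range in pixels.
#' @param mix Named fractions of \code{cap}, \code{spot} and \code{none}
#'   cells; must sum to 1.
#' @param capEnrichment,spotEnrichment Pole enrichment ranges (fold over
#'   the membrane base level).
#' @param capArc,spotArc Pole arc-length ranges (fraction of
#'   circumference).
#' @param band Membrane band width in pixels.
#' @param baseline Cell base intensity; \code{background} the background
#'   level.
#' @param noiseSd Additive Gaussian noise standard deviation.
#' @param poisson Add Poisson shot noise before the Gaussian component.
#' @param seed Integer seed; identical arguments give identical output.
#' @param maxTries Placement attempts per cell before giving up.
#' @return List with \code{image} (numeric matrix) and \code{truth}
#'   (data.frame: cell_id, cx, cy, radius, type, arc_frac, enrichment,
#'   pole_area_px).
#' @export
genCellImage <- function(nCells = 12, imageSize = 512,
                         radiusRange = c(25, 40),
                         mix = c(cap = 0.4, spot = 0.4, none = 0.2),
                         capEnrichment = c(2, 4), spotEnrichment = c(6, 12),
                         capArc = c(0.30, 0.45), spotArc = c(0.05, 0.15),
                         band = 3, baseline = 100, background = 10,
                         noiseSd = 5, poisson = FALSE, seed = 1,
                         maxTries = 500) {
    if (abs(sum(mix) - 1) > 1e-9) stop("mix fractions must sum to 1")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    set.seed(seed)
    img <- matrix(background, imageSize, imageSize)
    centers <- matrix(numeric(0), 0, 3)
    truth <- NULL
    types <- sample(names(mix), nCells, replace = TRUE, prob = mix)
    rowIdx <- matrix(rep(seq_len(imageSize), imageSize), imageSize)
    colIdx <- t(rowIdx)
    for (i in seq_len(nCells)) {
        r <- stats::runif(1, radiusRange[1], radiusRange[2])
        placed <- FALSE
        for (try in seq_len(maxTries)) {
            cx <- stats::runif(1, r + band + 2, imageSize - r - band - 2)
            cy <- stats::runif(1, r + band + 2, imageSize - r - band - 2)
            if (!nrow(centers) ||
                all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                    centers[, 3] + r + 4)) { placed <- TRUE; break }
        }
        if (!placed)
            stop("could not place all cells: reduce nCells or radii")
        centers <- rbind(centers, c(cx, cy, r))
        d <- sqrt((rowIdx - cy)^2 + (colIdx - cx)^2)
        inCell <- d <= r
        img[inCell] <- baseline
        type <- types[i]
        arc <- NA_real_; enr <- NA_real_; poleArea <- 0L
        if (type != "none") {
            arc <- if (type == "cap") stats::runif(1, capArc[1], capArc[2])
                   else stats::runif(1, spotArc[1], spotArc[2])
            enr <- if (type == "cap")
                stats::runif(1, capEnrichment[1], capEnrichment[2])
            else stats::runif(1, spotEnrichment[1], spotEnrichment[2])
            theta0 <- stats::runif(1, -pi, pi)
            ring <- inCell & d >= r - band
            ang <- atan2(rowIdx - cy, colIdx - cx)
            dAng <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
            pole <- ring & dAng <= arc * pi
            img[pole] <- baseline * enr
            poleArea <- sum(pole)
        }
        truth <- rbind(truth, data.frame(
            cell_id = i, cx = cx, cy = cy, radius = r, type = type,
            arc_frac = arc, enrichment = enr, pole_area_px = poleArea))
    }
    if (poisson) img <- matrix(stats::rpois(length(img), lambda = img),
                               imageSize, imageSize)
    if (noiseSd > 0) img <- img + stats::rnorm(length(img), 0, noiseSd)
    img[img < 0] <- 0
    list(image = img, truth = truth)
}

#' Generate synthetic boundary profiles with known polarity
#'
#' Each profile is a circular vector of \code{nBins} membrane-intensity
#' samples at base level 1. Polarised profiles (cap or spot type) carry
#' one contiguous arc multiplied by the drawn enrichment, rotated to a
#' random start; multiplicative Gaussian noise is added. The truth table
#' records the drawn type, arc, enrichment and the definitional polarity
#' label (arc below half the circumference and enrichment at least
#' two-fold).
#'
#' @inheritParams genCellImage
#' @param nProfiles Number of profiles.
#' @param nBins Angular bins per profile.
#' @param noiseSd Multiplicative Gaussian noise sd (relative to the base
#'   level).
#' @return List with \code{profiles} (matrix, one row per cell) and
#'   \code{truth}.
#' @export
genBoundaryProfiles <- function(nProfiles = 100, nBins = 64,
                                mix = c(cap = 0.4, spot = 0.4, none = 0.2),
                                capEnrichment = c(2.5, 4),
                                spotEnrichment = c(6, 12),
                                capArc = c(0.30, 0.45),
                                spotArc = c(0.05, 0.15),
                                noiseSd = 0.05, seed = 1) {
    if (abs(sum(mix) - 1) > 1e-9) stop("mix fractions must sum to 1")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    set.seed(seed)
    types <- sample(names(mix), nProfiles, replace = TRUE, prob = mix)
    profiles <- matrix(1, nProfiles, nBins)
    truth <- data.frame(cell_id = seq_len(nProfiles), type = types,
                        arc_frac = NA_real_, enrichment = NA_real_,
                        arc_start = NA_integer_, polarised = FALSE)
    for (i in seq_len(nProfiles)) {
        if (types[i] != "none") {
            arc <- if (types[i] == "cap")
                stats::runif(1, capArc[1], capArc[2])
            else stats::runif(1, spotArc[1], spotArc[2])
            enr <- if (types[i] == "cap")
                stats::runif(1, capEnrichment[1], capEnrichment[2])
            else stats::runif(1, spotEnrichment[1], spotEnrichment[2])
            len <- max(1L, round(arc * nBins))
            start <- sample.int(nBins, 1)
            idx <- ((start - 1 + seq_len(len) - 1) %% nBins) + 1
            profiles[i, idx] <- enr
            truth$arc_frac[i] <- len / nBins
            truth$enrichment[i] <- enr
            truth$arc_start[i] <- start
            truth$polarised[i] <- (len / nBins) < 0.5 && enr >= 2
        }
    }
    if (noiseSd > 0)
        profiles <- pmax(profiles *
            (1 + matrix(stats::rnorm(length(profiles), 0, noiseSd),
                        nProfiles, nBins)), 0)
    list(profiles = profiles, truth = truth)
}

#' Generate observation sets from the seeding cascade
#'
#' Computes the model-implied observables for each design under the
#' given rates and adds multiplicative Gaussian noise (floored at zero),
#' emulating the three in-silico seeding experiments. The generating
#' rates are recorded as attribute \code{"truth"}.
#'
#' @param rates Ground-truth \linkS4class{TransferRates}.
#' @param designs Named list of \linkS4class{ExperimentDesign}s.
#' @param noiseSd Multiplicative noise sd (0 for noiseless data).
#' @param seed Integer seed.
#' @return Named list of \linkS4class{ObservationSet}s with attribute
#'   \code{"truth"}.
#' @export
genObservationSets <- function(rates = fittedSeedingRates(),
                               designs = designDefaults(),
                               noiseSd = 0, seed = 1) {
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    set.seed(seed)
    out <- lapply(names(designs), function(id) {
        pred <- predictObservations(rates, designs[[id]])
        if (noiseSd > 0)
            pred$value <- pmax(pred$value *
                (1 + stats::rnorm(nrow(pred), 0, noiseSd)), 0)
        observationSet(id, pred)
    })
    names(out) <- names(designs)
    attr(out, "truth") <- rates
    out
}

#' Generate a binomially sampled depolarisation time course
#'
#' At each time the expected polarised fraction follows the
#' plateau-exponential decay \eqn{f(t) = P + (f_0 - P)\,2^{-t/T_{1/2}}};
#' the observed fraction is a binomial draw of \code{nCells} cells around
#' that mean, emulating a suspension polarity assay counted at a fixed
#' sampling depth. Defaults reproduce the measured kinetics of
#' melanoma cells in suspension: half-life 1 h with 39\% of cells
#' stably polarised.
#'
#' @param f0 Initial polarised fraction.
#' @param plateau Plateau fraction P (stably polarised cells).
#' @param halfLife Half-life in hours.
#' @param nCells Cells counted per time point (>= 1).
#' @param times Sampling times in hours. The default 12-point schedule
#'   over 0--6 h is front-loaded, as kinetics assays are designed: four
#'   samples within the first 1.5 half-lives resolve the decay, the
#'   later samples pin the plateau.
#' @param seed Integer seed.
#' @return data.frame with columns \code{time_h},
#'   \code{fraction_polarised}, \code{n_cells}.
#' @export
genDecayTimecourse <- function(f0 = 1, plateau = 0.39, halfLife = 1,
                               nCells = 200,
                               times = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2,
                                         2.5, 3, 4, 5, 6),
                               seed = 1) {
    if (!(plateau >= 0 && plateau <= f0 && f0 <= 1))
        stop("need 0 <= plateau <= f0 <= 1")
    if (halfLife <= 0) stop("halfLife must be > 0")
    if (nCells < 1) stop("nCells must be >= 1")
    set.seed(seed)
    mean <- plateau + (f0 - plateau) * 2^(-times / halfLife)
    frac <- stats::rbinom(length(times), nCells, mean) / nCells
    data.frame(time_h = times, fraction_polarised = frac,
               n_cells = nCells)
}

#' Generate a labelled aggregation-score sample from a two-peak mixture
#'
#' Draws scores from a mixture of a cap-like and a spot-like peak
#' (Gaussian or exponentially modified Gaussian), truncated at zero,
#' with per-draw labels recording which peak generated each score.
#'
#' @param location Numeric length-2: peak locations (cap, spot).
#' @param sd Numeric length-2: peak scales.
#' @param weight Numeric length-2 mixture weights (sum to 1).
#' @param n Number of draws.
#' @param shape \code{"gaussian"} or \code{"emg"}; for \code{"emg"} an
#'   exponential tail with rate \code{lambda} is added to the right.
#' @param lambda EMG tail rates (length 2), used when
#'   \code{shape = "emg"}.
#' @param seed Integer seed.
#' @return data.frame with columns \code{score} and \code{label}
#'   (\code{cap}/\code{spot}).
#' @export
genScoreSample <- function(location = c(2, 20), sd = c(0.5, 3),
                           weight = c(0.5, 0.5), n = 500,
                           shape = c("gaussian", "emg"),
                           lambda = c(2, 0.5), seed = 1) {
    shape <- match.arg(shape)
    if (any(sd <= 0)) stop("peak scales must be positive")
    if (abs(sum(weight) - 1) > 1e-9) stop("weights must sum to 1")
    set.seed(seed)
    label <- sample(c("cap", "spot"), n, replace = TRUE, prob = weight)
    i <- ifelse(label == "spot", 2L, 1L)
    x <- stats::rnorm(n, location[i], sd[i])
    if (shape == "emg") x <- x + stats::rexp(n, lambda[i])
    ## aggregation scores are positive; redraw the rare negative tail
    bad <- which(x <= 0)
    while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), location[i[bad]], sd[i[bad]])
        if (shape == "emg")
            x[bad] <- x[bad] + stats::rexp(length(bad), lambda[i[bad]])
        bad <- bad[x[bad] <= 0]
    }
    data.frame(score = x, label = factor(label, levels = c("cap", "spot")))
}
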