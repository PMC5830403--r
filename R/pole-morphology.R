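## Pole-morphology pipeline: segment cells and bright ezrin clusters,
## compute per-cell aggregation scores and decompose the score histogram
## into the cap-like and spot-like subpopulations.

#' Yen threshold of an intensity sample
#'
#' Maximum-correlation (Yen) automatic threshold on a 256-bin histogram
#' spanning the data range. The returned value is the centre of the
#' criterion-maximising bin, so that pixels strictly above it form the
#' bright class.
#'
#' @param x Numeric vector, matrix or EBImage \code{Image} of
#'   intensities.
#' @param nBins Number of histogram bins (default 256).
#' @return The threshold value; for constant input the constant itself.
#' @references Yen, Chang & Chang (1995), IEEE Trans. Image Processing 4,
#'   370--378.
#' @export
yenThreshold <- function(x, nBins = 256) {
    x <- as.numeric(x)
    x <- x[is.finite(x)]
    if (!length(x)) stop("no finite intensities")
    rng <- range(x)
    if (diff(rng) == 0) return(rng[1])
    w <- diff(rng) / nBins
    idx <- pmin(nBins, floor((x - rng[1]) / w) + 1L)
    counts <- tabulate(idx, nBins)
    centers <- rng[1] + (seq_len(nBins) - 0.5) * w
    pmf <- counts / sum(counts)
    P1 <- cumsum(pmf)
    P1sq <- cumsum(pmf^2)
    P2sq <- rev(cumsum(rev(pmf^2)))
    n <- nBins
    crit <- 2 * log(pmax(P1[-n] * (1 - P1[-n]), 0)) -
        log(P1sq[-n]) - log(P2sq[-1])
    crit[!is.finite(crit)] <- -Inf
    centers[which.max(crit)]
}

## rolling-ball style background: grey-scale opening with a disc whose
## radius exceeds any cell, computed on a downsampled copy for speed
.estimateBackground <- function(img, radius) {
    d <- dim(img)
    f <- max(1, ceiling(radius / 12))
    small <- EBImage::resize(img, w = max(8, round(d[1] / f)),
                             h = max(8, round(d[2] / f)))
    r <- max(3, round(radius / f))
    op <- EBImage::opening(small, EBImage::makeBrush(2 * r + 1, "disc"))
    EBImage::resize(op, w = d[1], h = d[2])
}

#' Segment cells and bright ezrin clusters in a fluorescence image
#'
#' The background is estimated by a morphological (rolling-ball style)
#' opening and subtracted; a first Yen threshold separates cellular
#' regions from background, and a second Yen threshold within each cell
#' separates bright ezrin clusters from the cell body. Connected cluster
#' objects smaller than \code{minClusterFrac} of the cell area are
#' discarded ("large clusters" only). Cells touching the image border are
#' excluded. For a cell of (near-)constant intensity the within-cell
#' threshold is degenerate and the whole cell counts as its cluster.
#'
#' @param image Numeric matrix (intensities >= 0, at least 16 x 16) or
#'   EBImage \code{Image}.
#' @param bgRadius Radius (pixels) of the background structuring element;
#'   default 80, i.e. twice the expected 40-pixel cell radius. Set
#'   \code{bgMethod = "none"} to skip background subtraction.
#' @param bgMethod \code{"rolling"} (morphological opening) or
#'   \code{"none"}.
#' @param minCellArea Minimum cell size in pixels.
#' @param minClusterFrac Minimum cluster area as a fraction of its cell's
#'   area (default 0.01).
#' @param excludeBorder Drop cells touching the image border.
#' @return List with \code{cellMask} and \code{clusterMask} (labelled
#'   \code{Image}s) and \code{stats}, a data.frame with one row per kept
#'   cell: \code{cell_id}, \code{a_cell_px}, \code{a_cluster_px},
#'   \code{i_cell}, \code{i_cluster} (areas in pixels, integrated
#'   intensities on the background-subtracted image).
#' @export
segmentCells <- function(image, bgRadius = 80,
                         bgMethod = c("rolling", "none"),
                         minCellArea = 100, minClusterFrac = 0.01,
                         excludeBorder = TRUE) {
    bgMethod <- match.arg(bgMethod)
    m <- if (is(image, "Image")) EBImage::imageData(image) else image
    if (!is.matrix(m) || any(dim(m) < 16))
        stop("image must be a numeric matrix of at least 16 x 16 pixels")
    if (any(m < 0, na.rm = TRUE)) stop("intensities must be non-negative")
    img <- EBImage::Image(m)
    if (bgMethod == "rolling") {
        bg <- .estimateBackground(img, bgRadius)
        img <- img - pmin(EBImage::imageData(bg), EBImage::imageData(img))
    }
    ## hierarchical Yen: on images holding background, cell bodies and
    ## bright clusters the first pass isolates the bright clusters; a
    ## second pass on the remaining pixels then separates cells from
    ## background. On bimodal images (no clusters above the cells) the
    ## second pass would land inside the background noise and flood the
    ## frame, so a coverage check falls back to the first threshold.
    imat0 <- EBImage::imageData(img)
    thrHigh <- yenThreshold(imat0)
    lowVals <- imat0[imat0 <= thrHigh]
    thr <- if (length(lowVals) && diff(range(lowVals)) > 0)
        yenThreshold(lowVals) else thrHigh
    fg <- img > thr
    if (mean(fg) > 0.5) { thr <- thrHigh; fg <- img > thr }
    empty <- list(cellMask = EBImage::Image(matrix(0L, dim(m)[1], dim(m)[2])),
                  clusterMask = EBImage::Image(matrix(0L, dim(m)[1],
                                                      dim(m)[2])),
                  stats = data.frame(cell_id = integer(0),
                                     a_cell_px = numeric(0),
                                     a_cluster_px = numeric(0),
                                     i_cell = numeric(0),
                                     i_cluster = numeric(0)))
    if (!any(fg)) {
        warning("blank image: nothing above the Yen threshold")
        return(empty)
    }
    fg <- EBImage::fillHull(fg)
    lab <- EBImage::bwlabel(fg)
    labm <- EBImage::imageData(lab)
    keep <- sort(unique(as.integer(labm[labm > 0])))
    sizes <- tabulate(labm[labm > 0], max(keep))
    keep <- keep[sizes[keep] >= minCellArea]
    if (excludeBorder) {
        border <- unique(as.integer(c(labm[1, ], labm[nrow(labm), ],
                                      labm[, 1], labm[, ncol(labm)])))
        keep <- setdiff(keep, border)
    }
    if (!length(keep)) {
        warning("no usable cells (all too small or touching the border)")
        return(empty)
    }
    imat <- EBImage::imageData(img)
    cellMask <- matrix(0L, nrow(labm), ncol(labm))
    clusterMask <- matrix(0L, nrow(labm), ncol(labm))
    rows <- lapply(seq_along(keep), function(j) {
        id <- keep[j]
        inCell <- labm == id
        cellMask[inCell] <<- j
        vals <- imat[inCell]
        aCell <- sum(inCell)
        ## degenerate: a (near-)uniform cell is its own cluster
        if (diff(range(vals)) <= 1e-9 * max(abs(vals), 1e-300)) {
            clusterMask[inCell] <<- j
            return(data.frame(cell_id = j, a_cell_px = aCell,
                              a_cluster_px = aCell, i_cell = sum(vals),
                              i_cluster = sum(vals)))
        }
        thr2 <- yenThreshold(vals)
        clPix <- inCell & (imat > thr2)
        clLab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(clPix)))
        ids <- clLab[clLab > 0]
        aCl <- 0; iCl <- 0
        if (length(ids)) {
            szs <- tabulate(ids)
            big <- which(szs >= minClusterFrac * aCell)
            if (length(big)) {
                inBig <- clLab > 0 & (clLab %in% big)
                clusterMask[inBig] <<- j
                aCl <- sum(inBig)
                iCl <- sum(imat[inBig])
            }
        }
        data.frame(cell_id = j, a_cell_px = aCell, a_cluster_px = aCl,
                   i_cell = sum(vals), i_cluster = iCl)
    })
    list(cellMask = EBImage::Image(cellMask),
         clusterMask = EBImage::Image(clusterMask),
         stats = do.call(rbind, rows))
}

#' Per-cell ezrin aggregation score
#'
#' \deqn{\mathrm{Aggregation} = \frac{I_{cluster}}{I_{cell}} \times
#'   \frac{A_{cell}}{A_{cluster}}}
#'
#' where \eqn{I} is the (integrated) intensity and \eqn{A} the area of
#' the large ezrin clusters per cell. The score is maximised when ezrin
#' is confined to a single small cluster (spot-like) and minimised when
#' it is dispersed over the cell (cap-like); a perfectly uniform cell,
#' whose cluster is the whole cell, scores exactly 1. With
#' \code{intensity = "mean"} the intensity ratio uses region means
#' instead of integrals.
#'
#' @param stats data.frame as returned in \code{segmentCells()$stats}.
#' @param intensity \code{"integrated"} (default) or \code{"mean"}.
#' @return Numeric vector of scores, one per row; cells without any large
#'   cluster get \code{NA} with a warning (excluded, not crashed).
#' @export
aggregationScore <- function(stats, intensity = c("integrated", "mean")) {
    intensity <- match.arg(intensity)
    need <- c("a_cell_px", "a_cluster_px", "i_cell", "i_cluster")
    if (!all(need %in% names(stats)))
        stop("stats must have columns ", paste(need, collapse = ", "))
    bad <- stats$a_cluster_px <= 0 | stats$i_cell <= 0
    if (any(bad))
        warning(sprintf("%d cell(s) without a measurable cluster excluded",
                        sum(bad)))
    iFrac <- stats$i_cluster / stats$i_cell
    if (intensity == "mean")
        iFrac <- (stats$i_cluster / stats$a_cluster_px) /
            (stats$i_cell / stats$a_cell_px)
    score <- iFrac * stats$a_cell_px / stats$a_cluster_px
    score[bad] <- NA_real_
    score
}

#' @describeIn segmentCells Segment an image and return its per-cell
#'   statistics with aggregation scores appended (column \code{score}).
#' @param ... Passed to \code{segmentCells}.
#' @export
scoreCells <- function(image, ...) {
    seg <- segmentCells(image, ...)
    st <- seg$stats
    if (nrow(st))
        st$score <- suppressWarnings(aggregationScore(st))
    else st$score <- numeric(0)
    st
}

## exponentially modified Gaussian density, numerically stable log form
.demg <- function(x, mu, sigma, lambda) {
    z <- (mu + lambda * sigma^2 - x) / (sqrt(2) * sigma)
    logf <- log(lambda / 2) +
        (lambda / 2) * (2 * mu + lambda * sigma^2 - 2 * x) +
        log(2) + stats::pnorm(-z * sqrt(2), log.p = TRUE)
    exp(logf)
}

.peakDensity <- function(x, p, shape) {
    if (shape == "emg") .demg(x, p["mu"], p["sigma"], p["lambda"])
    else stats::dnorm(x, p["mu"], p["sigma"])
}

.peakMode <- function(p, shape, lo, hi) {
    g <- seq(lo, hi, length.out = 2048)
    g[which.max(.peakDensity(g, p, shape))]
}

#' Decompose an aggregation-score histogram into two subpopulations
#'
#' Fits a two-peak mixture (exponentially modified Gaussian peaks by
#' default, plain Gaussian optionally) to the histogram of aggregation
#' scores by least squares on the bin counts, orders the peaks by
#' location (cap-like low, spot-like high), assigns each cell to the peak
#' with the higher fitted density at its score, and reports the decision
#' boundary between the two modes. Histograms that do not support a
#' second peak (vanishing second amplitude, or degenerate input) are
#' flagged as single-population rather than force-split.
#'
#' @param scores Numeric aggregation scores (NA dropped; at least 50
#'   recommended).
#' @param nBins Number of histogram bins (>= 10).
#' @param shape \code{"emg"} or \code{"gaussian"}.
#' @param seed Seed for the k-means initialisation and restarts.
#' @return A \linkS4class{PeakFit}.
#' @export
fitDoublePeak <- function(scores, nBins = 50,
                          shape = c("emg", "gaussian"), seed = 1) {
    shape <- match.arg(shape)
    scores <- scores[is.finite(scores)]
    if (length(scores) < 10) stop("need at least 10 scores")
    if (nBins < 10) stop("nBins must be >= 10")
    h <- graphics::hist(scores, breaks = nBins, plot = FALSE)
    centers <- h$mids; counts <- h$counts
    w <- diff(h$breaks[1:2])
    emptyPeaks <- data.frame(amplitude = numeric(0), mu = numeric(0),
                             sigma = numeric(0), lambda = numeric(0),
                             location = numeric(0), weight = numeric(0))
    singleFit <- function() new("PeakFit", peaks = emptyPeaks,
                                boundary = NA_real_, rss = NA_real_,
                                single = TRUE, shape = shape,
                                breaks = h$breaks, counts = as.numeric(counts),
                                classes = factor(rep("cap", length(scores)),
                                                 levels = c("cap", "spot")))
    if (stats::sd(scores) == 0) return(singleFit())

    set.seed(seed)
    km <- stats::kmeans(scores, centers = 2, nstart = 5)
    ord <- order(km$centers)
    mu0 <- as.numeric(km$centers[ord])
    sd0 <- pmax(vapply(ord, function(i)
        stats::sd(scores[km$cluster == i]), numeric(1)), w / 2)
    sd0[!is.finite(sd0)] <- w
    n0 <- as.numeric(km$size[ord]) * w

    model <- function(p) {
        p1 <- c(mu = p[2], sigma = p[3], lambda = p[4])
        p2 <- c(mu = p[6], sigma = p[7], lambda = p[8])
        p[1] * .peakDensity(centers, p1, shape) +
            p[5] * .peakDensity(centers, p2, shape)
    }
    resid <- function(p) model(p) - counts
    rngS <- range(scores)
    lo <- c(0, rngS[1] - diff(rngS), w / 10, 1e-3,
            0, rngS[1] - diff(rngS), w / 10, 1e-3)
    hi <- c(Inf, rngS[2], diff(rngS), 1e4,
            Inf, rngS[2], diff(rngS), 1e4)
    starts <- list(c(n0[1], mu0[1], sd0[1], 2 / sd0[1],
                     n0[2], mu0[2], sd0[2], 2 / sd0[2]),
                   c(n0[1], mu0[1], sd0[1] / 2, 4 / sd0[1],
                     n0[2], mu0[2], sd0[2] / 2, 4 / sd0[2]),
                   c(sum(n0) / 2, mu0[1], sd0[1], 1 / sd0[1],
                     sum(n0) / 2, mu0[2], sd0[2] * 2, 1 / sd0[2]))
    best <- NULL
    for (st in starts) {
        f <- try(minpack.lm::nls.lm(par = pmin(pmax(st, lo), hi),
                                    lower = lo, upper = hi, fn = resid,
                                    control = minpack.lm::nls.lm.control(
                                        maxiter = 400)), silent = TRUE)
        if (inherits(f, "try-error")) next
        rss <- sum(f$fvec^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
    if (is.null(best)) return(singleFit())

    ## nested single-peak fit: the second peak must buy a substantial
    ## improvement, otherwise the histogram does not support two
    ## populations (guards against one peak soaking up bin noise)
    resid1 <- function(p) {
        p1 <- c(mu = p[2], sigma = p[3], lambda = p[4])
        p[1] * .peakDensity(centers, p1, shape) - counts
    }
    m0 <- mean(scores); s0 <- stats::sd(scores)
    rss1 <- Inf
    for (st in list(c(length(scores) * w, m0, s0, 2 / s0),
                    c(length(scores) * w, m0 - s0 / 2, s0 / 2, 1 / s0))) {
        f1 <- try(minpack.lm::nls.lm(
            par = pmin(pmax(st, lo[1:4]), hi[1:4]),
            lower = lo[1:4], upper = hi[1:4], fn = resid1,
            control = minpack.lm::nls.lm.control(maxiter = 400)),
            silent = TRUE)
        if (!inherits(f1, "try-error"))
            rss1 <- min(rss1, sum(f1$fvec^2))
    }
    m <- length(counts)
    fRatio <- ((rss1 - best$rss) / 4) / (best$rss / max(m - 8, 1))
    if (is.finite(fRatio) && fRatio < 5) return(singleFit())
    p <- best$fit$par
    peakList <- list(c(amplitude = p[1], mu = p[2], sigma = p[3],
                       lambda = p[4]),
                     c(amplitude = p[5], mu = p[6], sigma = p[7],
                       lambda = p[8]))
    locs <- vapply(peakList, function(pk)
        .peakMode(pk[c("mu", "sigma", "lambda")], shape,
                  rngS[1], rngS[2]), numeric(1))
    ord <- order(locs)
    peakList <- peakList[ord]; locs <- locs[ord]
    amps <- vapply(peakList, `[[`, numeric(1), "amplitude")
    weights <- amps / sum(amps)
    ## a vanishing second component means the histogram is unimodal
    if (min(weights) < 0.02 || any(!is.finite(weights)))
        return(singleFit())
    ## so does a fitted sum without a genuine valley between the modes:
    ## two heavily overlapping components are a re-parameterised single
    ## peak, not two populations
    mixDens <- function(x)
        Reduce(`+`, lapply(peakList, function(pk)
            pk[["amplitude"]] * .peakDensity(x, pk[c("mu", "sigma",
                                                     "lambda")], shape)))
    if (locs[2] > locs[1]) {
        grid <- seq(locs[1], locs[2], length.out = 256)
        valley <- min(mixDens(grid))
        if (valley > 0.8 * min(mixDens(locs[1]), mixDens(locs[2])))
            return(singleFit())
    } else return(singleFit())
    peaks <- data.frame(amplitude = amps,
                        mu = vapply(peakList, `[[`, numeric(1), "mu"),
                        sigma = vapply(peakList, `[[`, numeric(1), "sigma"),
                        lambda = vapply(peakList, `[[`, numeric(1), "lambda"),
                        location = locs, weight = weights)
    dens <- function(x, i)
        peaks$amplitude[i] * .peakDensity(x, c(mu = peaks$mu[i],
                                               sigma = peaks$sigma[i],
                                               lambda = peaks$lambda[i]),
                                          shape)
    classes <- factor(ifelse(dens(scores, 2) > dens(scores, 1),
                             "spot", "cap"), levels = c("cap", "spot"))
    boundary <- NA_real_
    if (locs[2] > locs[1]) {
        gfun <- function(x) dens(x, 1) - dens(x, 2)
        if (sign(gfun(locs[1])) != sign(gfun(locs[2])))
            boundary <- stats::uniroot(gfun, c(locs[1], locs[2]))$root
    }
    new("PeakFit", peaks = peaks, boundary = boundary, rss = best$rss,
        single = FALSE, shape = shape, breaks = h$breaks,
        counts = as.numeric(counts), classes = classes)
}
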