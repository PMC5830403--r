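## Independent oracles used across the suite. These deliberately avoid
## the package's own code paths: naive loops and direct enumeration
## instead of cumulative sums, closed forms and library calls.

## exhaustive arc search by direct indexing and mean(), mirroring the
## polarity definition: candidate pole = enrichment-maximising arc over
## all lengths, polarised iff short enough and enriched enough
oracleCallPole <- function(x, threshold = 2, maxArc = 0.5) {
    n <- length(x)
    bestE <- -Inf; bestS <- NA; bestL <- NA
    for (L in 1:(n - 1)) {
        for (s in 1:n) {
            idx <- ((s - 1 + 0:(L - 1)) %% n) + 1
            mIn <- mean(x[idx])
            mOut <- mean(x[-idx])
            e <- mIn / mOut
            if (is.nan(e)) e <- -Inf
            if (e > bestE) { bestE <- e; bestS <- s; bestL <- L }
        }
    }
    list(polarised = is.finite(bestE) && bestE >= threshold &&
             (bestL / n) < maxArc - 1e-12,
         start = bestS, lenFrac = bestL / n, enrichment = bestE)
}

## two-sided Fisher exact p by full enumeration of tables with the
## observed margins (hypergeometric probabilities summed over tables no
## more probable than the observed one, with the conventional 1e-7
## relative tolerance)
oracleFisherP <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    a <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(a, r1, r2, c1)
    pObs <- dhyper(tab[1, 1], r1, r2, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

## match segmented cells to generator truth by centroid distance
matchCellsToTruth <- function(cellMask, truth) {
    lab <- EBImage::imageData(cellMask)
    ids <- sort(unique(as.integer(lab[lab > 0])))
    vapply(ids, function(id) {
        idx <- which(lab == id, arr.ind = TRUE)
        ctr <- colMeans(idx)   # (row = cy, col = cx)
        d <- sqrt((truth$cy - ctr[1])^2 + (truth$cx - ctr[2])^2)
        truth$cell_id[which.min(d)]
    }, numeric(1))
}

## the six canonical rate names, in package order
rateNames <- c("kAttPol", "kAttDep", "kAdhPol", "kAdhDep",
               "kTissPol", "kTissDep")

randomRates <- function() {
    k <- 10^runif(6, -5, 0)
    names(k) <- rateNames
    do.call(transferRates, as.list(k))
}
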