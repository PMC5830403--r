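test_that("Yen threshold matches the reference implementation on frozen fixtures", {
    ## expected values computed once with scikit-image threshold_yen
    ## (nbins = 256) on the same deterministic vectors
    x1 <- round(100 * sin(1:4096)^2)
    x2 <- c(rep(10, 3000), rep(50, 800), rep(200, 200))
    i <- 1:2500
    x3 <- 10 + 5 * sin(i) + 90 * (cos(i)^2 > 0.8)
    expect_equal(yenThreshold(x1), 49.0234375, tolerance = 1e-10)
    expect_equal(yenThreshold(x2), 49.70703125, tolerance = 1e-10)
    expect_equal(yenThreshold(x3), 15.063957081868224, tolerance = 1e-10)
    expect_equal(yenThreshold(rep(7, 100)), 7)
})

test_that("segmentation handles uniform discs, blank frames and split cells", {
    mk <- function(fill) {
        img <- matrix(0, 96, 96)
        rr <- row(img); cc <- col(img)
        img[(rr - 48)^2 + (cc - 48)^2 <= 20^2] <- fill
        img
    }
    ## one uniform disc on zero background: cluster = whole cell, score 1
    seg <- segmentCells(mk(100), bgMethod = "none")
    expect_equal(nrow(seg$stats), 1)
    expect_equal(seg$stats$a_cluster_px, seg$stats$a_cell_px)
    expect_equal(aggregationScore(seg$stats), 1)
    ## blank image: empty result with a warning, not a crash
    expect_warning(s0 <- segmentCells(matrix(0, 64, 64), bgMethod = "none"),
                   "blank")
    expect_equal(nrow(s0$stats), 0)
    ## two non-touching discs: exactly two labels
    img2 <- matrix(0, 128, 128)
    rr <- row(img2); cc <- col(img2)
    img2[(rr - 34)^2 + (cc - 34)^2 <= 15^2] <- 100
    img2[(rr - 94)^2 + (cc - 94)^2 <= 15^2] <- 100
    seg2 <- segmentCells(img2, bgMethod = "none")
    expect_equal(nrow(seg2$stats), 2)
    expect_error(segmentCells(matrix(1, 8, 8)), "16 x 16")
})

test_that("a drawn bright spot is recovered with its area and intensities", {
    img <- matrix(5, 128, 128)
    rr <- row(img); cc <- col(img)
    cell <- (rr - 64)^2 + (cc - 64)^2 <= 30^2
    spot <- (rr - 64)^2 + (cc - 50)^2 <= 6^2
    img[cell] <- 100
    img[spot] <- 400
    seg <- segmentCells(img, bgMethod = "none")
    expect_equal(nrow(seg$stats), 1)
    expect_lt(abs(seg$stats$a_cluster_px / sum(spot) - 1), 0.10)
    sc <- aggregationScore(seg$stats)
    ## direct evaluation of the formula on the drawn masks
    expected <- (sum(img[spot]) / sum(img[cell])) *
        (sum(cell) / sum(spot))
    expect_equal(sc, expected, tolerance = 0.1)
})

test_that("aggregation score equals its formula, with its degenerate cases", {
    ## 5% of the area holding 50% of the intensity scores 0.5 x 20 = 10
    st <- data.frame(a_cell_px = 1000, a_cluster_px = 50,
                     i_cell = 1000, i_cluster = 500)
    expect_equal(aggregationScore(st), 10)
    ## halving the cluster area at fixed intensity fraction doubles it
    st2 <- st; st2$a_cluster_px <- 25
    expect_equal(aggregationScore(st2), 20)
    ## uniform cell scores exactly 1
    stU <- data.frame(a_cell_px = 500, a_cluster_px = 500,
                      i_cell = 800, i_cluster = 800)
    expect_equal(aggregationScore(stU), 1)
    ## mean-intensity mode agrees on the uniform case and scales the rest
    expect_equal(aggregationScore(stU, intensity = "mean"), 1)
    expect_equal(aggregationScore(st, intensity = "mean"), 200)
    ## no cluster: NA with a warning, not an error
    stBad <- data.frame(a_cell_px = 100, a_cluster_px = 0,
                        i_cell = 10, i_cluster = 0)
    expect_warning(sc <- aggregationScore(stBad), "excluded")
    expect_true(is.na(sc))
})

test_that("the score is scale invariant and increases as intensity concentrates", {
    gen <- genCellImage(nCells = 6, imageSize = 256, radiusRange = c(18, 24),
                        seed = 31)
    st1 <- scoreCells(gen$image, bgMethod = "none")
    st2 <- scoreCells(gen$image * 3.7, bgMethod = "none")
    expect_equal(st1$score, st2$score, tolerance = 1e-6)
    ## concentrating a fixed intensity fraction into less area raises the
    ## score monotonically (formula property on constructed stats)
    areas <- c(400, 200, 100, 50, 25)
    sc <- aggregationScore(data.frame(a_cell_px = 1000, a_cluster_px = areas,
                                      i_cell = 1000, i_cluster = 500))
    expect_true(all(diff(sc) > 0))
})

test_that("spot cells score above cap cells across seeded images", {
    pairs <- 0; wins <- 0
    for (s in 1:3) {
        gen <- genCellImage(nCells = 10, mix = c(cap = 0.5, spot = 0.5,
                                                 none = 0),
                            seed = 200 + s)
        seg <- segmentCells(gen$image)
        st <- seg$stats
        st$score <- suppressWarnings(aggregationScore(st))
        st$type <- gen$truth$type[matchCellsToTruth(seg$cellMask, gen$truth)]
        spots <- st$score[st$type == "spot" & !is.na(st$score)]
        caps <- st$score[st$type == "cap" & !is.na(st$score)]
        for (a in spots) { wins <- wins + sum(a > caps)
                           pairs <- pairs + length(caps) }
    }
    expect_gt(pairs, 20)
    expect_gte(wins / pairs, 0.95)
})

test_that("double-peak decomposition recovers well-separated mixtures", {
    s <- genScoreSample(location = c(2, 20), sd = c(0.5, 3), n = 600,
                        seed = 3)
    fit <- fitDoublePeak(s$score, seed = 1)
    expect_false(fit@single)
    expect_lt(abs(fit@peaks$location[1] / 2 - 1), 0.10)
    expect_lt(abs(fit@peaks$location[2] / 20 - 1), 0.10)
    expect_gte(mean(fit@classes == s$label), 0.95)
    expect_true(fit@boundary > 2 && fit@boundary < 20)
    ## the gaussian shape recovers the same structure
    fitG <- fitDoublePeak(s$score, shape = "gaussian", seed = 1)
    expect_false(fitG@single)
    expect_lt(abs(fitG@peaks$location[2] / 20 - 1), 0.10)
    ## assignments do not depend on input order
    fitR <- fitDoublePeak(rev(s$score), seed = 1)
    expect_equal(as.character(rev(fitR@classes)),
                 as.character(fit@classes))
})

test_that("unimodal score samples are flagged single-population", {
    expect_true(fitDoublePeak(rep(5, 100))@single)
    set.seed(4)
    one <- rnorm(400, 10, 1.5)
    expect_true(fitDoublePeak(one, seed = 2)@single)
    expect_error(fitDoublePeak(1:5), "at least 10")
    expect_error(fitDoublePeak(rnorm(100), nBins = 5), "nBins")
})
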