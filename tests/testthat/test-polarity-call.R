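test_that("the polarity definition is honoured on canonical profiles", {
    ## uniform membrane: enrichment 1 everywhere, not polarised
    expect_false(callPole(rep(2, 64))@polarised)
    ## 90-degree arc at 3x the base level
    x <- rep(1, 64); x[10:25] <- 3
    pc <- callPole(x)
    expect_true(pc@polarised)
    expect_equal(pc@arcLength, 16 / 64)
    expect_equal(pc@arcStart, 10L)
    expect_equal(pc@enrichment, 3, tolerance = 1e-9)
    ## a 200-degree enriched region exceeds half the circumference:
    ## unpolarised by definition, however bright
    y <- rep(1, 36); y[1:20] <- 3
    expect_false(callPole(y)@polarised)
    ## all-zero profile: enrichment undefined, not polarised
    z <- callPole(rep(0, 64))
    expect_false(z@polarised)
    expect_true(is.na(z@enrichment))
    expect_error(callPole(rep(1, 8)), "at least 16")
    expect_error(callPole(c(rep(1, 63), -1)), "non-negative")
})

test_that("the caller agrees exactly with the brute-force arc oracle", {
    set.seed(77)
    for (i in 1:40) {
        n <- sample(c(16, 24, 32, 48, 64), 1)
        ## integer-valued profiles make both sum orders exact in doubles
        x <- sample(0:9, n, replace = TRUE) +
            sample(c(0, 0, 5), n, replace = TRUE)
        if (sum(x) == 0) x[1] <- 1
        pc <- callPole(x)
        or <- oracleCallPole(x)
        expect_identical(pc@polarised, or$polarised)
        expect_equal(pc@arcLength, or$lenFrac)
        expect_equal(pc@arcStart, as.integer(or$start))
        expect_equal(pc@enrichment, or$enrichment, tolerance = 1e-12)
    }
})

test_that("calls are invariant to rotation and positive scaling", {
    set.seed(12)
    for (i in 1:10) {
        x <- rep(1, 48); L <- sample(4:20, 1); s <- sample(1:48, 1)
        x[((s - 1 + 0:(L - 1)) %% 48) + 1] <- runif(1, 2.5, 6)
        x <- x * (1 + rnorm(48, 0, 0.03))
        base <- callPole(x)
        r <- sample(1:47, 1)
        rot <- callPole(c(x[-(1:r)], x[1:r]))
        expect_identical(base@polarised, rot@polarised)
        expect_equal(base@arcLength, rot@arcLength)
        expect_equal(base@enrichment, rot@enrichment, tolerance = 1e-9)
        sc <- callPole(x * 13.5)
        expect_identical(base@polarised, sc@polarised)
        expect_equal(base@enrichment, sc@enrichment, tolerance = 1e-9)
    }
})

test_that("population fractions follow the generator truth", {
    expect_equal(fractionPolarised(matrix(1, 3, 64)), 0)
    x <- rep(1, 64); x[5:12] <- 4
    expect_equal(fractionPolarised(matrix(x, 1, byrow = TRUE)), 1)
    expect_error(fractionPolarised(list()), "no profiles")
    ## 40% true poles at comfortable enrichment, 500 cells: the called
    ## fraction must sit inside the binomial 95% band around the truth
    g <- genBoundaryProfiles(nProfiles = 500,
                             mix = c(cap = 0.2, spot = 0.2, none = 0.6),
                             seed = 5)
    p <- mean(g$truth$polarised)
    called <- fractionPolarised(g$profiles)
    expect_lt(abs(called - p), 1.96 * sqrt(p * (1 - p) / 500))
})

test_that("profiles reduced from image masks recover the drawn pole", {
    img <- matrix(0, 128, 128)
    rr <- row(img); cc <- col(img)
    cell <- (rr - 64)^2 + (cc - 64)^2 <= 40^2
    img[cell] <- 100
    ring <- cell & (rr - 64)^2 + (cc - 64)^2 >= 37^2
    ang <- atan2(rr - 64, cc - 64)
    img[ring & abs(ang) < 0.25 * pi] <- 320   # quarter-circle pole at 3.2x
    prof <- boundaryProfileFromMask(img, cell)
    pc <- callPole(prof)
    expect_true(pc@polarised)
    expect_lt(abs(pc@arcLength - 0.25), 0.06)
})

test_that("plateau-exponential decay fitting recovers and flags correctly", {
    tt <- seq(0, 6, length.out = 12)
    fr <- 0.39 + (1 - 0.39) * 2^(-tt / 1)
    fit <- fitDecay(tt, fr)
    expect_true(fit@decaying)
    expect_lt(abs(fit@f0 - 1), 0.01)
    expect_lt(abs(fit@plateau - 0.39), 0.01 * 0.39)
    expect_lt(abs(fit@halfLife - 1), 0.01)
    expect_equal(predict(fit, 0), 1, tolerance = 1e-6)
    ## flat course: flagged, not silently parameterised
    expect_false(fitDecay(tt, rep(0.5, 12))@decaying)
    expect_error(fitDecay(c(0, 1, 2), c(1, 0.8, 0.6)), "at least 4")
    expect_error(fitDecay(tt, fr * 2), "\\[0, 1\\]")
})

test_that("half-life recovery from binomial sampling is essentially unbiased", {
    est <- vapply(1:40, function(s)
        fitDecay(genDecayTimecourse(seed = s))@halfLife, numeric(1))
    expect_lt(abs(mean(est) - 1), 0.05)
    ## individual draws at this sampling depth stay in a sane band
    expect_true(all(est > 0.6 & est < 1.6))
})
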