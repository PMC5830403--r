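truth <- fittedSeedingRates()
designs <- designDefaults()

test_that("design predictions reduce to known closed forms", {
    ## no adherence transfer: nothing ever reaches the adhered state
    r0 <- transferRates(0.1, 0.1, 0, 0, 0, 0)
    p <- predictObservations(r0, designs$i)
    expect_true(all(p$value == 0))
    ## pure single-exponential adherence: half the population adhered
    ## after one half-life
    d <- experimentDesign("i", times = c(600, 1200),
                          mixtures = c(pure = 1))
    r <- transferRates(0, 0, log(2) / 600, 0.01, 0, 0)
    p <- predictObservations(r, d)
    expect_equal(p$value[1], 50, tolerance = 1e-9)
    expect_equal(p$value[2], 75, tolerance = 1e-9)
    ## design iii equals the analytic tissue output
    p3 <- predictObservations(truth, designs$iii)
    f <- designs$iii@mixtures[["polarised"]]
    bc <- batemanClosedForm(truth,
                            compartmentState(circulatingPol = 100 * f,
                                             circulatingDep = 100 * (1 - f)),
                            times = c(0, designs$iii@times))
    expect_equal(p3$value[p3$prep == "polarised"],
                 unname(bc@states[-1, "tissue"]), tolerance = 1e-9)
    ## closed-form and ODE prediction paths agree
    pODE <- predictObservations(truth, designs$iii, method = "ode")
    expect_equal(p3$value, pODE$value, tolerance = 1e-7)
})

test_that("noiseless linked fit recovers the generating rates to <1%", {
    obs <- genObservationSets(truth, designs, noiseSd = 0, seed = 1)
    fit <- linkedFit(obs, designs, nStarts = 10, seed = 1)
    expect_true(fit@converged)
    expect_length(fit@unidentifiable, 0)
    relErr <- abs(rateVector(fit@rates) / rateVector(truth) - 1)
    expect_true(all(relErr < 0.01))
    expect_lt(fit@rss, 1e-8)
})

test_that("single-design data leave the untouched rates flagged, not silent", {
    obs <- genObservationSets(truth, designs["i"], noiseSd = 0, seed = 2)
    fit <- linkedFit(obs, designs["i"], nStarts = 6, seed = 2)
    kerr <- abs(rateVector(fit@rates)[c("kAdhPol", "kAdhDep")] /
                    rateVector(truth)[c("kAdhPol", "kAdhDep")] - 1)
    expect_true(all(kerr < 0.01))
    expect_setequal(fit@unidentifiable,
                    c("kAttPol", "kAttDep", "kTissPol", "kTissDep"))
})

test_that("degenerate inputs are rejected", {
    expect_error(linkedFit(list(), designs), "at least one")
    empty <- observationSet("i", data.frame(prep = character(0),
                                            observable = character(0),
                                            time_s = numeric(0),
                                            value = numeric(0)))
    expect_error(linkedFit(list(empty), designs), "empty")
    obs <- genObservationSets(truth, designs, noiseSd = 0, seed = 1)
    fit <- linkedFit(obs, designs, nStarts = 2, seed = 1)
    expect_error(bootstrapCI(obs, designs, fit, nBoot = 1), "nBoot")
})

test_that("fits stay within 10% under 5% multiplicative noise", {
    errs <- sapply(1:5, function(s) {
        obs <- genObservationSets(truth, designs, noiseSd = 0.05, seed = s)
        f <- linkedFit(obs, designs, nStarts = 5, seed = s)
        abs(rateVector(f@rates) / rateVector(truth) - 1)
    })
    expect_true(all(apply(errs, 1, median) < 0.10))
})

test_that("pooled fit beats per-experiment fits on the pooled objective", {
    obs <- genObservationSets(truth, designs, noiseSd = 0.08, seed = 7)
    pooled <- linkedFit(obs, designs, nStarts = 5, seed = 7)
    pooledRSS <- function(rates)
        sum(unlist(lapply(names(obs), function(id) {
            pred <- predictObservations(rates, designs[[id]])
            (pred$value - obs[[id]]@data$value)^2
        })))
    expect_equal(pooledRSS(pooled@rates), pooled@rss, tolerance = 1e-6)
    for (id in names(obs)) {
        single <- linkedFit(obs[id], designs[id], nStarts = 5, seed = 7)
        expect_lte(pooled@rss, pooledRSS(single@rates) + 1e-9)
    }
})

test_that("bootstrap intervals cover the truth and collapse without noise", {
    ## noiseless: degenerate bootstrap, interval width ~ 0 around truth
    obs0 <- genObservationSets(truth, designs, noiseSd = 0, seed = 1)
    fit0 <- linkedFit(obs0, designs, nStarts = 6, seed = 1)
    fit0 <- bootstrapCI(obs0, designs, fit0, nBoot = 10, seed = 1)
    expect_true(all(fit0@ci[, "upper"] - fit0@ci[, "lower"] <
                        1e-4 * rateVector(truth)))
    ## 5% noise: truth inside the 95% interval for most rates/replicates
    hits <- 0; total <- 0
    for (s in 1:4) {
        obs <- genObservationSets(truth, designs, noiseSd = 0.05,
                                  seed = 100 + s)
        fit <- linkedFit(obs, designs, nStarts = 4, seed = s)
        fit <- bootstrapCI(obs, designs, fit, nBoot = 40, seed = s)
        k <- rateVector(truth)
        hits <- hits + sum(k >= fit@ci[, "lower"] & k <= fit@ci[, "upper"])
        total <- total + 6
    }
    expect_gte(hits / total, 0.75)
})
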