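test_that("zero rates leave the state constant and invalid inputs are rejected", {
    r0 <- transferRates(0, 0, 0, 0, 0, 0)
    init <- compartmentState(circulatingPol = 100)
    tr <- simulateCascade(r0, init, horizon = 100, dt = 10)
    expect_true(all(abs(tr@states[, "circulating_pol"] - 100) < 1e-9))
    expect_true(all(abs(tr@states[, colnames(tr@states) !=
                                      "circulating_pol"]) < 1e-9))
    bc <- batemanClosedForm(r0, init, times = c(0, 50, 100))
    expect_equal(unname(bc@states[, "circulating_pol"]), rep(100, 3))

    expect_error(transferRates(-1, 0, 0, 0, 0, 0), "non-negative")
    expect_error(transferRates(NaN, 0, 0, 0, 0, 0), "finite")
    expect_error(simulateCascade(r0, c(-1, rep(0, 6))), "negative")
    expect_error(simulateCascade(r0, init, horizon = -5), "horizon")
})

test_that("a single active attachment rate gives the textbook exponential", {
    r <- transferRates(log(2), 0, 0, 0, 0, 0)
    tr <- simulateCascade(r, compartmentState(circulatingPol = 100),
                          times = c(0, 1, 2))
    expect_equal(unname(tr@states[2, "circulating_pol"]), 50,
                 tolerance = 1e-8)
    expect_equal(unname(tr@states[2, "attached_pol"]), 50,
                 tolerance = 1e-8)
    expect_equal(unname(tr@states[3, "circulating_pol"]), 25,
                 tolerance = 1e-8)
    ## one-step chain in closed form
    bc <- batemanClosedForm(transferRates(0.01, 0, 0, 0, 0, 0),
                            compartmentState(circulatingPol = 100),
                            times = c(0, 30, 300))
    expect_equal(unname(bc@states[, "circulating_pol"]),
                 100 * exp(-0.01 * c(0, 30, 300)), tolerance = 1e-12)
})

test_that("numerical simulation matches the closed-form cascade at the fitted rates", {
    rates <- fittedSeedingRates()
    init <- compartmentState(circulatingPol = 100, circulatingDep = 100)
    tr <- simulateCascade(rates, init, rtol = 1e-11, atol = 1e-13)
    bc <- batemanClosedForm(rates, init, times = tr@times)
    expect_lt(max(abs(tr@states - bc@states)), 1e-8)
})

test_that("closed form handles degenerate rate sets as configured", {
    rEq <- transferRates(0.1, 0.2, 0.1, 0.2, 0.1, 0.2)
    init <- compartmentState(circulatingPol = 100, circulatingDep = 50)
    expect_error(batemanClosedForm(rEq, init, times = c(0, 10),
                                   degenerate = "error"), "repeated")
    ## expm fallback agrees with the integrator
    bc <- batemanClosedForm(rEq, init, times = c(0, 10, 100))
    tr <- simulateCascade(rEq, init, times = c(0, 10, 100),
                          rtol = 1e-11, atol = 1e-13)
    expect_lt(max(abs(bc@states - tr@states)), 1e-7)
})

test_that("population is conserved and compartments stay monotone", {
    set.seed(101)
    for (i in 1:20) {
        r <- randomRates()
        init <- compartmentState(circulatingPol = 60, circulatingDep = 40,
                                 attachedPol = 5)
        tr <- simulateCascade(r, init, horizon = 15000, dt = 500)
        tot <- sum(init)
        expect_lt(max(abs(rowSums(tr@states) - tot)), 1e-9 * tot)
        expect_true(all(tr@states > -1e-9))
        expect_true(all(diff(tr@states[, "tissue"]) > -1e-9))
        expect_true(all(diff(tr@states[, "circulating_pol"]) < 1e-9))
        expect_true(all(diff(tr@states[, "circulating_dep"]) < 1e-9))
    }
})

test_that("tissue residence fractions behave and order by polarity", {
    rates <- fittedSeedingRates()
    init <- compartmentState(circulatingPol = 100, circulatingDep = 100)
    tr <- simulateCascade(rates, init)
    expect_equal(tissueResidenceFraction(tr, 0), 0)
    expect_error(tissueResidenceFraction(tr, 20000), "outside")
    ## pure-population comparison at the 30-min in vivo read-out:
    ## polarised cells seed more
    fp <- tissueResidenceFraction(tr, 1800, arm = "pol")
    fd <- tissueResidenceFraction(tr, 1800, arm = "dep")
    expect_gt(fp, fd)
    ## exact value from the analytic oracle
    bc <- batemanClosedForm(rates, init, times = c(0, 1800))
    expect_equal(fp, unname(bc@tissueByArm[2, "tissue_pol"]) / 100,
                 tolerance = 1e-7)
    ## all-zero rates put nothing in tissue
    tr0 <- simulateCascade(transferRates(0, 0, 0, 0, 0, 0), init,
                           horizon = 100, dt = 10)
    expect_equal(tissueResidenceFraction(tr0, 50), 0)
    ## dominance at every time point when every polarised rate is larger
    expect_true(all(tr@tissueByArm[, "tissue_pol"] >=
                        tr@tissueByArm[, "tissue_dep"] - 1e-9))
})
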