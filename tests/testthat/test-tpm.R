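test_that("hillTheta matches the closed form and its symmetry", {
    # theta(K_D) = 1/2 for any Hill coefficient
    for (n in c(0.5, 1, 4, 6.5))
        expect_equal(hillTheta(6.1, kd = 6.1, n = n), 0.5)
    expect_equal(hillTheta(0, kd = 6.1, n = 6.5), 0)
    # direct evaluation: 1 / ((6.1/10)^6.5 + 1)
    expect_equal(hillTheta(10, kd = 6.1, n = 6.5), 0.9613, tolerance = 1e-4)
    # monotone non-decreasing in concentration
    cc <- seq(0, 20, by = 0.25)
    for (n in c(1, 3, 6.5))
        expect_true(all(diff(hillTheta(cc, 6.1, n)) >= 0))
    expect_error(hillTheta(-1, 6.1, 6.5), ">= 0")
    expect_error(hillTheta(5, kd = 0, n = 2), "kd")
})

test_that("single-component fit recovers a bare-DNA population", {
    x <- withr::with_seed(101, rnorm(500, 159, 15))
    fit <- fitRMSMixture(x, k = 1)
    expect_equal(components(fit)$mean, 159, tolerance = 2 / 159)
    expect_equal(components(fit)$weight, 1)
    expect_true(is.na(occupancy(fit)))
})

test_that("two-component fit recovers an equal-weight bare/bound mixture", {
    x <- withr::with_seed(202, c(rnorm(200, 105, 12), rnorm(200, 159, 12)))
    fit <- fitRMSMixture(x, k = 2)
    cmp <- components(fit)
    expect_equal(cmp$mean[1], 105, tolerance = 3 / 105)
    expect_equal(cmp$mean[2], 159, tolerance = 3 / 159)
    expect_equal(cmp$weight[1], 0.5, tolerance = 0.14)  # 0.5 +/- 0.07
    expect_equal(sum(cmp$weight), 1)
    # bound (lower-mean) component weight fraction is the occupancy
    expect_equal(occupancy(fit), cmp$weight[1] / sum(cmp$weight))
})

test_that("mixture log-likelihood and EM optimum agree with a grid oracle", {
    x <- withr::with_seed(33, c(rnorm(25, 105, 12), rnorm(25, 159, 12)))
    fit <- fitRMSMixture(x, k = 2)
    cmp <- components(fit)
    # reported log-likelihood equals an independent direct computation
    expect_equal(fit@logLik,
                 oracleMixtureLogLik(x, cmp$mean, cmp$sd, cmp$weight),
                 tolerance = 1e-6)
    # EM likelihood is at least as good as a coarse exhaustive grid search
    gridBest <- oracleGridMixture(x, means1 = seq(95, 115, 2),
                                  means2 = seq(150, 170, 2),
                                  sds = seq(8, 16, 1),
                                  weights = seq(0.3, 0.7, 0.05))
    expect_gte(fit@logLik, gridBest - 1e-6)
})

test_that("mixture fit agrees with an independent EM implementation", {
    suppressMessages(library(mclust))
    x <- withr::with_seed(77, c(rnorm(300, 105, 12), rnorm(300, 159, 12)))
    fit <- fitRMSMixture(x, k = 2)
    mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(components(fit)$mean),
                 sort(unname(mc$parameters$mean)), tolerance = 0.01)
})

test_that("mixture fit is invariant to input ordering", {
    x <- withr::with_seed(44, c(rnorm(150, 105, 12), rnorm(250, 159, 12)))
    f1 <- fitRMSMixture(x, k = 2)
    f2 <- fitRMSMixture(rev(x), k = 2)
    f3 <- fitRMSMixture(sample(x), k = 2)
    expect_equal(components(f1), components(f2), tolerance = 1e-8)
    expect_equal(components(f1), components(f3), tolerance = 1e-8)
})

test_that("mixture fit rejects degenerate input", {
    expect_error(fitRMSMixture(numeric(0), k = 1), "non-empty")
    expect_error(fitRMSMixture(rnorm(15, 100, 5), k = 2), "at least 20")
    expect_error(fitRMSMixture(rep(100, 50), k = 2), "identical")
    expect_error(fitRMSMixture(c(rnorm(10, 100, 5), -1), k = 1), "> 0")
    expect_error(fitRMSMixture(rnorm(50, 100, 5), k = 3), "1 or 2")
})

test_that("occupancyFromFit implements the peak-area ratio", {
    expect_equal(occupancyFromFit(c(3, 1), 1, 2), 0.75)
    expect_equal(occupancyFromFit(c(0, 1), 1, 2), 0)
    expect_equal(occupancyFromFit(c(0.6, 0.4), 1, 2), 0.6)
    expect_error(occupancyFromFit(c(0, 0), 1, 2), "zero")
    expect_error(occupancyFromFit(c(1, 1), 1, 1), "distinct")
    expect_error(occupancyFromFit(c(1, 1), 1, 3), "range")
})

test_that("occupancy curve from a synthetic titration tracks the Hill law", {
    beads <- simulateTPMTitration(c(0, 3:10), hillKd = 6.1, hillN = 6.5,
                                  nBeads = 400, seed = 5)
    curve <- buildOccupancyCurve(beads)
    truth <- hillTheta(as.data.frame(curve)$concentration_nM, 6.1, 6.5)
    # binomial error at n = 400 plus mixture-fit error
    expect_true(all(abs(as.data.frame(curve)$theta - truth) <
                    3 * sqrt(0.25 / 400) + 0.03))
    fit <- fitHill(curve)
    expect_equal(kd(fit), 6.1, tolerance = 0.1)
    expect_equal(hillCoefficient(fit), 6.5, tolerance = 0.25)
})

test_that("occupancy curve handles minor components and degenerate input", {
    beads <- simulateTPMTitration(c(0, 10), hillKd = 6.1, hillN = 6.5,
                                  nBeads = 300, seed = 8)
    curve <- buildOccupancyCurve(beads)
    df <- as.data.frame(curve)
    # at c = 0 no bound component survives the minor-population threshold
    expect_lt(df$theta[df$concentration_nM == 0], 0.05)
    # at saturation the unbound component is minor
    expect_gt(df$theta[df$concentration_nM == 10], 0.95)
    one <- beads[beads$concentration_nM == 0, ]
    expect_error(buildOccupancyCurve(one), "2 distinct")
})

test_that("Hill fit is the identity on noiseless model curves", {
    for (truth in list(c(6.1, 6.5), c(8.8, 5.7))) {
        cc <- 2:12
        curve <- OccupancyCurve(cc, hillTheta(cc, truth[1], truth[2]))
        fit <- fitHill(curve)
        expect_equal(kd(fit), truth[1], tolerance = 1e-6)
        expect_equal(hillCoefficient(fit), truth[2], tolerance = 1e-6)
        expect_lt(residualSS(fit), 1e-12)
    }
})

test_that("Hill fit rejects unidentifiable curves", {
    expect_error(fitHill(OccupancyCurve(c(2, 4), c(0.2, 0.8))), "3")
    expect_error(fitHill(OccupancyCurve(2:6, rep(0, 5))),
                 "non-identifiable")
    expect_error(fitHill(OccupancyCurve(2:6, rep(1, 5))),
                 "non-identifiable")
})
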