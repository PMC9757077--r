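test_that("fnorm is the hot/cold window ratio", {
    t <- seq(0, 40, by = 0.1)
    expect_equal(fnorm(t, rep(500, length(t))), 1)
    f <- ifelse(t < 5, 1000, 800)
    expect_equal(fnorm(t, f), 0.8)
    # hot window is centered 1.5 s after laser-on: a change landing only
    # inside [6, 7] s must drive the value
    f2 <- rep(1000, length(t))
    f2[t >= 6 & t <= 7] <- 700
    expect_equal(fnorm(t, f2), 0.7)
})

test_that("fnorm validates its trace windows", {
    t <- seq(10, 40, by = 0.1)  # starts after laser-on
    expect_error(fnorm(t, rep(1, length(t))), "pre-laser")
    t2 <- seq(0, 4, by = 0.1)   # ends before the hot window
    expect_error(fnorm(t2, rep(1, length(t2))), "hot window")
    expect_error(fnorm(c(0, 0, 1), c(1, 1, 1)), "strictly increasing")
})

test_that("deltaFnorm subtracts the DNA-only baseline and keeps order", {
    d <- deltaFnorm(c(1, 2, 4), c(0.9, 0.9, 0.9), dnaOnly = 0.9)
    expect_equal(as.data.frame(d)$dfnorm, c(0, 0, 0))
    fn <- c(0.95, 0.90, 0.85)
    d2 <- deltaFnorm(c(4, 1, 2), c(0.85, 0.95, 0.90), dnaOnly = 1)
    df <- as.data.frame(d2)
    expect_equal(df$conc_uM, c(1, 2, 4))        # sorted by concentration
    expect_equal(df$dfnorm, fn - 1)             # shift preserves order
    expect_true(all(diff(df$dfnorm) < 0))
})

test_that("mvhTheta agrees with a uniroot oracle and obeys its limits", {
    expect_equal(mvhTheta(0, 79.4, 30), 0)
    for (kdv in c(1, 34.6, 79.4, 500)) {
        for (n in c(1L, 10L, 30L)) {
            for (L in c(0.01, 0.125, 1, 16, 1000)) {
                expect_equal(mvhTheta(L, kdv, n),
                             oracleMvhTheta(L, kdv, n), tolerance = 1e-10)
            }
        }
    }
    # dilute limit theta -> n L / kd (checked where theta <= 1e-3)
    L <- 79.4 * 1e-3 / 30 / 2
    th <- mvhTheta(L, 79.4, 30)
    expect_lte(th, 1e-3)
    expect_equal(th, 30 * L / 79.4, tolerance = 0.01)
    # lattice saturation bound and monotonicity
    L <- c(0.125 * 2^(0:10), 1e4)
    th <- mvhTheta(L, 79.4, 30)
    expect_true(all(th < 1))
    expect_true(all(diff(th) > 0))
    weaker <- vapply(c(20, 50, 100), function(k) mvhTheta(1, k, 30),
                     numeric(1))
    expect_true(all(mvhTheta(1, 10, 30) > weaker))
    expect_error(mvhTheta(1, kd = 0, siteSize = 30), "kd")
    expect_error(mvhTheta(-1, kd = 10, siteSize = 30), ">= 0")
})

test_that("MvH fit is the identity on noiseless isotherms", {
    for (truth in c(79.4, 34.6)) {
        d <- simulateMSTDataset(kd = truth)  # 0.125-16 uM doubling series
        fit <- fitMvH(d)
        expect_equal(kd(fit), truth, tolerance = 1e-4)
        expect_equal(amplitude(fit), 1, tolerance = 1e-4)
        expect_equal(siteSize(fit), 30L)
    }
    # sign of the amplitude is unconstrained
    dNeg <- simulateMSTDataset(kd = 79.4, amplitude = -0.8)
    fitNeg <- fitMvH(dNeg)
    expect_equal(kd(fitNeg), 79.4, tolerance = 1e-4)
    expect_equal(amplitude(fitNeg), -0.8, tolerance = 1e-4)
})

test_that("MvH fit rejects unidentifiable data", {
    cc <- 0.125 * 2^(0:7)
    expect_error(fitMvH(MSTDataset(cc, rep(0, 8))), "flat")
    expect_error(fitMvH(MSTDataset(cc[1:3], c(0.1, 0.2, 0.3))),
                 "4 distinct")
    expect_error(fitMvH(MSTDataset(c(1, 1.5, 2, 3), c(0.1, 0.2, 0.3, 0.4))),
                 "10-fold")
})

test_that("MvH fit recovers the affinity from noisy data approximately", {
    d <- simulateMSTDataset(kd = 79.4, amplitude = 0.5, noiseSd = 0.005,
                            seed = 12)
    fit <- fitMvH(d)
    expect_equal(kd(fit), 79.4, tolerance = 0.25)
})
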