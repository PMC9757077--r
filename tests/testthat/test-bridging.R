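test_that("recoveryPercent implements the reference-normalized ratio", {
    expect_equal(as.numeric(recoveryPercent(4000, 8000)), 50)
    expect_equal(as.numeric(recoveryPercent(8000, 8000)), 100)
    # no protein, no recovered DNA
    expect_equal(as.numeric(recoveryPercent(0, 8000)), 0)
    # background subtraction
    expect_equal(as.numeric(recoveryPercent(4500, 8500, 500)), 50)
    # above-reference values are kept but flagged
    r <- recoveryPercent(9000, 8000)
    expect_equal(as.numeric(r), 112.5)
    expect_true(attr(r, "flagged"))
    # below-background signals clip to 0 and flag
    r0 <- recoveryPercent(100, 8000, background = 200)
    expect_equal(as.numeric(r0), 0)
    expect_true(attr(r0, "flagged"))
    expect_error(recoveryPercent(100, 200, background = 200), "exceed")
})

test_that("recoveryPercent is invariant to a common scale factor", {
    for (k in c(0.5, 2, 17)) {
        expect_equal(as.numeric(recoveryPercent(4100 * k, 8300 * k, 250 * k)),
                     as.numeric(recoveryPercent(4100, 8300, 250)))
    }
})

test_that("summarizeTitration reports per-condition mean and sample SD", {
    tab <- data.frame(label = rep(c("b", "a"), each = 3),
                      signal_cpm = c(4000, 4800, 5600, 800, 800, 800),
                      reference_cpm = 8000)
    s <- summarizeTitration(tab)
    expect_equal(s$label, c("b", "a"))  # first-appearance order preserved
    expect_equal(s$mean_recovery[1], 60)
    expect_equal(s$sd_recovery[1], 10)
    expect_equal(s$n_replicates, c(3L, 3L))
    expect_false(any(s$below_replication_standard))
    # permutation within a condition leaves the summary unchanged
    tabPerm <- tab[c(3, 5, 1, 6, 2, 4), ]
    expect_equal(summarizeTitration(tabPerm), s)
})

test_that("summarizeTitration flags sub-triplicate conditions", {
    one <- data.frame(label = "x", signal_cpm = 4000, reference_cpm = 8000)
    s <- summarizeTitration(one)
    expect_equal(s$mean_recovery, 50)
    expect_true(is.na(s$sd_recovery))
    expect_true(s$below_replication_standard)
    expect_error(summarizeTitration(data.frame()), "non-empty")
    expect_error(summarizeTitration(data.frame(label = "x")), "missing")
})

test_that("simulated bridging counts converge to the planted recovery", {
    z <- simulateBridging(c(none = 0), replicates = 50, seed = 3)
    expect_true(all(z$signal_cpm == 0))  # Poisson(0)
    big <- simulateBridging(c(half = 0.5), replicates = 1e4, seed = 4)
    s <- summarizeTitration(big)
    expect_equal(s$mean_recovery, 50, tolerance = 1 / 50)  # 50% +/- 1%
    # triplicate default
    d <- simulateBridging(c(a = 0.2, b = 0.8), seed = 5)
    expect_equal(nrow(d), 6L)
    expect_equal(sum(d$label == "a"), 3L)
    expect_error(simulateBridging(c(a = 1.2)), "\\[0, 1\\]")
})
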