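test_that("generators are bit-identical under a fixed seed", {
    b1 <- simulateTPMTitration(c(0, 6.1), nBeads = 50, seed = 42)
    b2 <- simulateTPMTitration(c(0, 6.1), nBeads = 50, seed = 42)
    expect_identical(b1, b2)
    expect_identical(simulateBridging(c(a = 0.5), seed = 7),
                     simulateBridging(c(a = 0.5), seed = 7))
    expect_identical(
        as.data.frame(simulateMSTDataset(79.4, noiseSd = 0.01, seed = 1)),
        as.data.frame(simulateMSTDataset(79.4, noiseSd = 0.01, seed = 1)))
    s1 <- simulateCountMatrix(nGenes = 100, seed = 5)
    s2 <- simulateCountMatrix(nGenes = 100, seed = 5)
    expect_identical(SummarizedExperiment::assay(s1, "counts"),
                     SummarizedExperiment::assay(s2, "counts"))
    expect_identical(as.character(simulateProteinSet(c(30, 40), seed = 3)),
                     as.character(simulateProteinSet(c(30, 40), seed = 3)))
    # generators do not disturb the global RNG stream
    withr::with_seed(1, {
        before <- runif(1)
        invisible(simulateTPMTitration(c(0, 5), nBeads = 10, seed = 99))
    })
    withr::with_seed(1, after <- runif(1))
    expect_identical(before, after)
})

test_that("TPM titration bound fractions follow the Hill law", {
    # at c = K_D half the beads come from the bound population
    beads <- simulateTPMTitration(6.1, hillKd = 6.1, hillN = 6.5,
                                  nBeads = 1e5, seed = 13)
    boundFrac <- mean(beads$rms_nm < 132)  # midpoint of 105/159
    expect_equal(boundFrac, 0.5, tolerance = 0.01 / 0.5)
    # at c = 0 every bead is bare DNA
    bare <- simulateTPMTitration(0, nBeads = 2000, seed = 14)
    expect_equal(mean(bare$rms_nm), 159, tolerance = 0.01)
    expect_lt(mean(bare$rms_nm < 132), 0.02)
    # empirical fractions converge to theta(c) within 3/sqrt(n)
    cc <- c(2, 5, 6.1, 7, 9)
    sim <- simulateTPMTitration(cc, nBeads = 4000, seed = 15)
    for (ci in cc) {
        emp <- mean(sim$rms_nm[sim$concentration_nM == ci] < 132)
        expect_lt(abs(emp - hillTheta(ci, 6.1, 6.5)),
                  3 / sqrt(4000) + 0.012)  # + population-overlap leakage
    }
})

test_that("TPM titration validates its parameters by name", {
    expect_error(simulateTPMTitration(c(0, 5), hillKd = -1), "hillKd")
    expect_error(simulateTPMTitration(c(0, 5), sdBare = 0), "sdBare")
    expect_error(simulateTPMTitration(c(0, 5), nBeads = 0), "nBeads")
    expect_error(simulateTPMTitration(c(-1, 5)), "concentrations")
})

test_that("count generator inverts the analysis transform", {
    # null generator: vanishing scale means strain means equal deletion
    # means up to integer rounding noise
    se <- simulateCountMatrix(nGenes = 3000, strains = "wt",
                              logisticLocation = 0, logisticScale = 1e-6,
                              depthRange = c(1, 1), seed = 21)
    prof <- diffProfile(se, "wt", "drok")
    expect_lt(abs(mean(prof$diff)), 0.05)
    expect_lt(max(abs(prof$diff)), 1.01)  # rounding never exceeds 1 count
    # counts are valid integers
    cts <- SummarizedExperiment::assay(se, "counts")
    expect_true(all(cts >= 0) && all(cts == round(cts)))
    # replicates present for every strain
    expect_equal(sum(SummarizedExperiment::colData(se)$strain == "drok"), 2L)
    expect_error(simulateCountMatrix(nGenes = 0), "nGenes")
    expect_error(simulateCountMatrix(nbDispersion = 0), "nbDispersion")
    expect_error(simulateCountMatrix(logisticScale = -1), "logisticScale")
})

test_that("protein set generator produces the requested sequences", {
    set <- simulateProteinSet(191, seed = 2)
    expect_length(set, 1L)
    expect_equal(Biostrings::width(set), 191L)
    two <- simulateProteinSet(c(190, 189), seed = 2)
    expect_equal(unname(classifyRokLength(two)), c("Rok", "sRok"))
    # alphabet is the 20 standard residues
    letters <- unique(strsplit(as.character(two[[1]]), "")[[1]])
    expect_true(all(letters %in% Biostrings::AA_STANDARD))
    expect_error(simulateProteinSet(0), ">= 1")
})
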