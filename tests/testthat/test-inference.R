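test_that("prior-only runs recover the prior for intercepts", {
    cov <- simulateCovariates(20, 6, seed = 71)
    sim <- simulateIndividuals(twoSpeciesConfigs(10, 10), cov,
                               defaultDetection(), nOccasions = 6,
                               seed = 72)
    post <- suppressWarnings(
        samplePosterior(sim$histories, priorOnly = TRUE, nChains = 4,
                        nIter = 8000, nWarmup = 2000, seed = 5))
    m <- posteriorMatrix(post)
    b0 <- m[, "b0_psi[Eurasian Blackbird]"]
    ## prior recovery within Monte-Carlo error of the chains
    expect_equal(mean(b0), 0, tolerance = 0.2)        # prior mean 0
    expect_equal(sd(b0), 1.5, tolerance = 0.25)       # prior sd 1.5
    slope <- m[, "bul_chi"]
    expect_equal(sd(slope), 1, tolerance = 0.2)       # prior sd 1
    ## detection probabilities: higher one uniform on (0, 1)
    expect_equal(mean(m[, "pX[ACT]"]), 0.5, tolerance = 0.1)
})

test_that("posterior sampling is deterministic given the seed", {
    cov <- simulateCovariates(30, 8, seed = 81)
    sim <- simulateIndividuals(twoSpeciesConfigs(15, 15), cov,
                               defaultDetection(), nOccasions = 8,
                               seed = 82)
    p1 <- suppressWarnings(samplePosterior(sim$histories, nChains = 2,
                                           nIter = 600, nWarmup = 300,
                                           seed = 4))
    p2 <- suppressWarnings(samplePosterior(sim$histories, nChains = 2,
                                           nIter = 600, nWarmup = 300,
                                           seed = 4))
    expect_identical(p1@draws, p2@draws)
    expect_identical(p1@diagnostics, p2@diagnostics)
})

test_that("every posterior draw respects the tag-power ordering", {
    cov <- simulateCovariates(40, 10, seed = 91)
    sim <- simulateIndividuals(twoSpeciesConfigs(20, 20), cov,
                               defaultDetection(), nOccasions = 10,
                               seed = 92)
    post <- suppressWarnings(samplePosterior(sim$histories, nChains = 2,
                                             nIter = 800, nWarmup = 400,
                                             seed = 3))
    m <- posteriorMatrix(post)
    expect_true(all(m[, "pX[ACT]"] >= m[, "pX[NTQB]"]))
    expect_true(all(m[, "pC[ACT]"] >= m[, "pC[NTQB]"]))
    expect_true(all(m[, c("pX[ACT]", "pX[NTQB]", "pC[ACT]",
                          "pC[NTQB]")] >= 0))
    expect_true(all(m[, c("pX[ACT]", "pX[NTQB]", "pC[ACT]",
                          "pC[NTQB]")] <= 1))
})

test_that("detection probabilities are recovered at moderate sample size", {
    ## the network sees nearly all onshore flights but only about half of
    ## the sea crossings; the model should recover that asymmetry
    cov <- simulateCovariates(500, 36, seed = 101)
    sim <- simulateIndividuals(twoSpeciesConfigs(250, 250), cov,
                               defaultDetection(), nOccasions = 36,
                               seed = 102)
    post <- suppressWarnings(
        samplePosterior(sim$histories, nChains = 4, nIter = 5000,
                        nWarmup = 1500, seed = 103))
    m <- posteriorMatrix(post)
    truth <- unlist(defaultDetection())
    got <- colMeans(m[, c("pX[ACT]", "pX[NTQB]", "pC[ACT]",
                          "pC[NTQB]")])
    expect_true(all(abs(got - truth) < 0.1))
    ## the asymmetry itself is unmistakable
    expect_gt(mean(m[, "pC[NTQB]"]), mean(m[, "pX[NTQB]"]) + 0.2)
})

test_that("posterior predictive checks are calibrated on model data", {
    cov <- simulateCovariates(120, 15, seed = 111)
    sim <- simulateIndividuals(twoSpeciesConfigs(60, 60), cov,
                               defaultDetection(), nOccasions = 15,
                               seed = 112)
    post <- suppressWarnings(
        samplePosterior(sim$histories, nChains = 4, nIter = 2500,
                        nWarmup = 1000, seed = 113))
    ppc <- posteriorPredictiveCheck(post, sim$histories, nDraws = 100,
                                    seed = 114)
    ## observed statistics inside the central 95% for >= 90% of stats
    expect_gte(mean(ppc$inside), 0.9)
    expect_equal(nrow(ppc$replicates) >= 100, TRUE)
})

test_that("predictive checks flag deliberately corrupted data", {
    cov <- simulateCovariates(120, 15, seed = 121)
    sim <- simulateIndividuals(twoSpeciesConfigs(60, 60), cov,
                               defaultDetection(), nOccasions = 15,
                               seed = 122)
    eh <- sim$histories
    ## corrupt: relabel every detected onshore flight as offshore
    cd <- encounterCodes(eh)
    cd[cd == 3L] <- 2L
    bad <- EncounterHistories(cd, species = speciesLabels(eh),
                              tagType = as.character(tagTypes(eh)),
                              distanceGroup = distanceGroups(eh),
                              covariates = list(
                                  u = SummarizedExperiment::assay(eh, "u"),
                                  v = SummarizedExperiment::assay(eh, "v"),
                                  dp = SummarizedExperiment::assay(eh, "dp"),
                                  h = SummarizedExperiment::assay(eh, "h"),
                                  rain = SummarizedExperiment::assay(eh,
                                                                     "rain")))
    ## posterior concentrated at the generating parameters (chi near 1/2):
    ## replicate offshore counts cannot reach the corrupted observation
    post <- degeneratePosterior(bad, sim$params)
    ppc <- posteriorPredictiveCheck(post, bad, nDraws = 100, seed = 123)
    offStats <- grep("^offshore", names(ppc$observed))
    expect_true(any(!ppc$inside[offStats]))
    ## and replicate means approach the expected counts under truth
    onTrue <- sum(encounterCodes(sim$histories) == 3L)
    expect_equal(mean(rowSums(
        ppc$replicates[, grep("^onshore", colnames(ppc$replicates)),
                       drop = FALSE])), onTrue, tolerance = 0.25 * onTrue)
})
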