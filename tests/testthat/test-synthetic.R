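test_that("covariate simulation is deterministic and respects parameters", {
    a <- simulateCovariates(2, 3, seed = 99)
    b <- simulateCovariates(2, 3, seed = 99)
    expect_identical(a, b)
    expect_equal(nrow(a), 6L)
    ## the global RNG state is untouched
    set.seed(1); x1 <- rnorm(1)
    set.seed(1); invisible(simulateCovariates(5, 5, seed = 3))
    expect_identical(rnorm(1), x1)
    norain <- simulateCovariates(10, 10,
                                 weatherParams(rainProb = 0), seed = 1)
    expect_true(all(norain$rain == 0))
    expect_error(simulateCovariates(0, 5), "nIndividuals")
    expect_error(simulateCovariates(5, 1), "nOccasions")
})

test_that("rain frequency matches its Bernoulli rate (10 nights in 128)", {
    p <- 10 / 128
    cov <- simulateCovariates(1280, 10, weatherParams(rainProb = p),
                              seed = 4)
    n <- nrow(cov)  # 12800 individual-occasions
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(cov$rain) - p), 3 * se)
})

test_that("state process respects absorbing structure and start state", {
    cfg <- twoSpeciesConfigs(20, 20)
    cov <- simulateCovariates(40, 8, seed = 31)
    sim <- simulateIndividuals(cfg, cov, defaultDetection(),
                               nOccasions = 8, seed = 32)
    z <- sim$z
    expect_true(all(z[, 1] == 1))
    for (i in seq_len(nrow(z))) {
        left <- which(z[i, ] != 1)
        if (length(left)) {
            d <- left[1]
            expect_true(z[i, d] %in% 2:3)
            if (d < ncol(z))
                expect_true(all(z[i, (d + 1):ncol(z)] == 4))
        }
    }
    ## flight observation codes occur only where the true state is a flight
    y <- encounterCodes(sim$histories)
    expect_true(all(y[y %in% 2:3] == z[y %in% 2:3]))
    ## identical seed, identical outputs
    sim2 <- simulateIndividuals(cfg, cov, defaultDetection(),
                                nOccasions = 8, seed = 32)
    expect_identical(encounterCodes(sim2$histories), y)
    expect_identical(sim2$z, z)
})

test_that("departure probability forced to the boundaries", {
    cfg <- twoSpeciesConfigs(10, 10)
    ## intercept -> -20: nobody ever departs
    for (k in 1:2) cfg[[k]]$betasDeparture <-
        c(b0 = -20, ul = 0, uq = 0, vl = 0, vq = 0, dp = 0, h = 0)
    cov <- simulateCovariates(20, 6, seed = 41)
    sim <- simulateIndividuals(cfg, cov, defaultDetection(),
                               nOccasions = 6, seed = 42, betaRain = 0)
    expect_true(all(sim$z == 1))
    expect_true(all(encounterCodes(sim$histories) == 1))
    ## psi -> 1, chi -> 1, pX = 1: everyone flies offshore on night one
    for (k in 1:2) {
        cfg[[k]]$betasDeparture["b0"] <- 20
        cfg[[k]]$beta0Routing <- 20
    }
    det1 <- list(pX = c(ACT = 1, NTQB = 1), pC = c(ACT = 1, NTQB = 1))
    sim <- simulateIndividuals(cfg, cov, det1, nOccasions = 6,
                               seed = 43, betaRain = 0,
                               betaChi = c(ul = 0, uq = 0, vl = 0,
                                           vq = 0))
    y <- encounterCodes(sim$histories)
    expect_true(all(y[, 1] == 1))
    expect_true(all(y[, 2] == 2))
    expect_true(all(y[, -(1:2)] == 4))
})

test_that("empirical departure frequency matches a constant psi", {
    cfg <- twoSpeciesConfigs(5000, 5000)
    for (k in 1:2) {
        cfg[[k]]$betasDeparture <- c(b0 = qlogis(0.3), ul = 0, uq = 0,
                                     vl = 0, vq = 0, dp = 0, h = 0)
        cfg[[k]]$beta0Routing <- 0
    }
    cov <- simulateCovariates(10000, 4, seed = 51)
    sim <- simulateIndividuals(cfg, cov, defaultDetection(),
                               nOccasions = 4, seed = 52, betaRain = 0)
    z <- sim$z
    for (t in 1:3) {
        atStop <- z[, t] == 1
        n <- sum(atStop)
        rate <- mean(z[atStop, t + 1] != 1)
        expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / n))
    }
})

test_that("perfect detection makes histories equal true states", {
    cfg <- twoSpeciesConfigs(25, 25)
    cov <- simulateCovariates(50, 10, seed = 61)
    det1 <- list(pX = c(ACT = 1, NTQB = 1), pC = c(ACT = 1, NTQB = 1))
    sim <- simulateIndividuals(cfg, cov, det1, nOccasions = 10,
                               seed = 62)
    expect_identical(unname(encounterCodes(sim$histories)),
                     unname(sim$z))
})

test_that("detection series reflect the flight geometry", {
    net <- data.frame(receiver_id = c("s1", "s2", "s3"),
                      lon = c(7.9, 8.1, 8.3), lat = c(53.6, 53.8, 54.0))
    fl <- list(start = c(7.9, 53.6), end = c(8.3, 54.0),
               startTime = t0utc, endTime = t0utc + 2 * 3600)
    d <- simulateDetectionSeries(fl, net, seed = 1)
    expect_setequal(unique(d$receiver_id), c("s1", "s2", "s3"))
    expect_true(!is.unsorted(d$timestamp))
    ## stationary tag: one station, no systematic terminal decline
    st <- simulateDetectionSeries(list(start = c(7.9, 53.6),
                                       end = c(7.9, 53.6),
                                       startTime = t0utc,
                                       endTime = t0utc + 3600),
                                  net, seed = 2)
    expect_equal(unique(st$receiver_id), "s1")
    dep <- detectDeparture(st)
    expect_false(dep$determined)
    expect_error(simulateDetectionSeries(fl, net[0, ]), "at least one")
    expect_error(simulateDetectionSeries(
        list(start = c(7.9, 53.6), end = c(8, 53.7),
             startTime = t0utc + 10, endTime = t0utc), net),
        "precede")
})

test_that("departure signature satisfies the last-five-below-peak rule", {
    stn <- data.frame(receiver_id = "stop", lon = 7.95, lat = 53.62)
    s <- simulateDepartureSeries(stn, t0utc + 20 * 3600, seed = 5)
    dep <- detectDeparture(s)
    expect_true(dep$determined)
    expect_equal(dep$time, t0utc + 20 * 3600)
    ## last-five mean sits below the peak-window mean by construction
    expect_lt(mean(tail(s$signal_strength, 5)),
              max(s$signal_strength))
    ## abrupt loss at constant strength is not scored as a departure
    s2 <- simulateDepartureSeries(stn, t0utc + 20 * 3600,
                                  departed = FALSE, seed = 5)
    expect_false(detectDeparture(s2)$determined)
})

test_that("study generator reproduces the field design margins", {
    st <- simulateStudy(seed = 8, nOccasions = 36)
    expect_equal(nrow(st$metadata), 289L)
    expect_equal(levels(speciesLabels(st$histories)),
                 vapply(defaultSpeciesConfigs(), `[[`, "", "name"))
    ndet <- sum(st$metadata$determined)
    ## dropout 105/289 plus late/no departures: modeled count near 184
    expect_gt(ndet, 150); expect_lt(ndet, 215)
    expect_equal(nrow(st$modeled), ndet)
    ## every modeled history departs within the grid
    cd <- encounterCodes(st$modeled)
    expect_true(all(apply(cd, 1, function(x) any(x != 1))))
    ## identical seeds give identical bundles
    st2 <- simulateStudy(seed = 8, nOccasions = 36)
    expect_identical(st2$detections, st$detections)
    expect_identical(encounterCodes(st2$modeled), cd)
})
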