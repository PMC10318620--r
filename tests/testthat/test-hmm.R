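test_that("transition matrix follows the four-state structure", {
    expect_equal(transitionMatrix(0, 0.5)[1, ],
                 c(stopover = 1, offshore = 0, onshore = 0, departed = 0))
    expect_equal(unname(transitionMatrix(1, 1)[1, ]), c(0, 1, 0, 0))
    expect_equal(unname(transitionMatrix(0.5, 0.4)[1, ]),
                 c(0.5, 0.2, 0.3, 0))
    for (i in 1:20) {
        m <- transitionMatrix(runif(1), runif(1))
        expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
    }
    expect_error(transitionMatrix(1.2, 0.5), "0, 1")
})

test_that("observation matrix encodes route-specific detection", {
    m <- observationMatrix(1, 1)
    expect_equal(unname(diag(m)[1:3]), c(1, 1, 1))
    expect_equal(unname(m[4, ]), c(0, 0, 0, 1))
    m0 <- observationMatrix(0, 0.5)
    expect_equal(unname(m0[2, ]), c(0, 0, 0, 1))  # offshore never seen
    for (i in 1:20) {
        m <- observationMatrix(runif(1), runif(1))
        expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
    }
})

test_that("departure probability matches an independent dot product", {
    p0 <- MultistateParams(matrix(0, 1, 7))
    expect_equal(unname(departureProbability(p0, 1, 0, 0, 0, 0, 0, 0, 0)),
                 0.5)
    set.seed(42)
    for (i in 1:25) {
        bp <- matrix(rnorm(14), 2, 7)
        br <- rnorm(1)
        pr <- MultistateParams(bp, betaRain = br)
        cv <- rnorm(7)
        s <- sample(1:2, 1)
        expected <- plogis(sum(c(1, cv[1:6]) * bp[s, ]) + br * cv[7])
        got <- departureProbability(pr, s, cv[1], cv[2], cv[3], cv[4],
                                    cv[5], cv[6], cv[7])
        expect_equal(unname(got), expected, tolerance = 1e-12)
    }
    ## rain flips the predictor by exactly the shared slope
    pr <- MultistateParams(matrix(rnorm(7), 1, 7), betaRain = -1.3)
    e0 <- qlogis(departureProbability(pr, 1, 0.2, 0.1, -0.3, 0, 1, 2, 0))
    e1 <- qlogis(departureProbability(pr, 1, 0.2, 0.1, -0.3, 0, 1, 2, 1))
    expect_equal(unname(e1 - e0), -1.3, tolerance = 1e-10)
})

test_that("routing probability uses species intercepts with shared slopes", {
    p0 <- MultistateParams(matrix(0, 2, 7), beta0Chi = c(0, 0))
    expect_equal(unname(routingProbability(p0, 1, 0, 0, 0, 0)), 0.5)
    set.seed(7)
    bc <- rnorm(4)
    pr <- MultistateParams(matrix(0, 2, 7), beta0Chi = c(0.4, -1.1),
                           betaChi = bc)
    cv <- rnorm(4)
    ## same covariates: predictors differ only by the intercepts
    d <- qlogis(routingProbability(pr, 1, cv[1], cv[2], cv[3], cv[4])) -
        qlogis(routingProbability(pr, 2, cv[1], cv[2], cv[3], cv[4]))
    expect_equal(unname(d), 0.4 - (-1.1), tolerance = 1e-10)
    expected <- plogis(0.4 + sum(bc * cv))
    expect_equal(unname(routingProbability(pr, 1, cv[1], cv[2], cv[3],
                                           cv[4])),
                 expected, tolerance = 1e-12)
})

test_that("forward log-likelihood reproduces hand-computed cases", {
    expect_equal(forwardLogLik(c(1, 1), 0.3, 0.5, 1, 1), log(0.7))
    expect_equal(forwardLogLik(c(1, 2), 0.5, 0.6, 1, 1), log(0.3))
    expect_equal(forwardLogLik(c(1, 4, 4), c(0.4, 0.4), c(0.5, 0.5),
                               0.6, 0.9),
                 enumLogLik(c(1, 4, 4), 0.4, 0.5, 0.6, 0.9),
                 tolerance = 1e-10)
})

test_that("forward recursion equals exhaustive enumeration (T <= 6)", {
    set.seed(11)
    for (T in 2:6) {
        for (rep in 1:4) {
            psi <- runif(T - 1, 0.05, 0.95)
            chi <- runif(T - 1, 0.05, 0.95)
            pX <- runif(1, 0.1, 0.95); pC <- runif(1, 0.1, 0.95)
            for (h in validHistories(T)) {
                expect_equal(
                    forwardLogLik(h, matrix(psi, 1), matrix(chi, 1),
                                  pX, pC),
                    enumLogLik(h, psi, chi, pX, pC),
                    tolerance = 1e-10)
            }
        }
    }
})

test_that("fully observed histories reduce to transition products", {
    ## with perfect detection the marginal likelihood is the product of
    ## the transition probabilities along the single compatible path
    psi <- c(0.2, 0.5, 0.7); chi <- c(0.3, 0.4, 0.9)
    expect_equal(forwardLogLik(c(1, 1, 1, 2), matrix(psi, 1),
                               matrix(chi, 1), 1, 1),
                 log(0.8) + log(0.5) + log(0.7 * 0.9))
    expect_equal(forwardLogLik(c(1, 1, 3, 4), matrix(psi, 1),
                               matrix(chi, 1), 1, 1),
                 log(0.8) + log(0.5 * 0.6))
})

test_that("impossible histories yield -Inf with a warning", {
    expect_warning(ll <- forwardLogLik(c(1, 2), 0, 0.5, 1, 1),
                   "impossible")
    expect_identical(ll, -Inf)
})

test_that("total log-likelihood is additive and order-invariant", {
    cov <- simulateCovariates(30, 8, seed = 5)
    sim <- simulateIndividuals(twoSpeciesConfigs(15, 15), cov,
                               defaultDetection(), nOccasions = 8,
                               seed = 6)
    md <- msModelData(sim$histories)
    lp <- migrateHMM:::linearPredictors(md, sim$params)
    per <- forwardLogLik(md$data$codes, lp$psi, lp$chi, lp$pX, lp$pC)
    expect_equal(totalLogLik(md, sim$params), sum(per),
                 tolerance = 1e-9)
    ## duplicated individual doubles its contribution
    i <- 3L
    expect_equal(forwardLogLik(md$data$codes[c(i, i), ],
                               lp$psi[c(i, i), ], lp$chi[c(i, i), ],
                               lp$pX[c(i, i)], lp$pC[c(i, i)]),
                 rep(per[i], 2), tolerance = 1e-12)
    ## permuting individuals leaves the total unchanged
    o <- sample(seq_along(per))
    expect_equal(sum(forwardLogLik(md$data$codes[o, ], lp$psi[o, ],
                                   lp$chi[o, ], lp$pX[o], lp$pC[o])),
                 sum(per), tolerance = 1e-9)
})

test_that("C++ likelihood with in-place predictors matches the R path", {
    cov <- simulateCovariates(24, 10, seed = 15)
    sim <- simulateIndividuals(twoSpeciesConfigs(12, 12), cov,
                               defaultDetection(), nOccasions = 10,
                               seed = 16)
    md <- msModelData(sim$histories)
    v <- migrateHMM:::paramsToVector(sim$params)
    expect_equal(migrateHMM:::cpp_ms_loglik(v, md$data),
                 totalLogLik(md, sim$params), tolerance = 1e-8)
    ## round trip through the parameter vector mapping
    back <- migrateHMM:::vectorToParams(v, rownames(sim$params@betaPsi))
    expect_equal(back@betaPsi, sim$params@betaPsi, tolerance = 1e-7)
    expect_equal(back@pX, sim$params@pX, tolerance = 1e-7)
})
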