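# Independent oracles and fixture builders used across the suite.

# Exhaustive-enumeration likelihood of one encounter history: sums the
# probability of every latent state sequence (z_1 = stopover fixed) under
# hand-written transition/observation matrices. Deliberately independent of
# the package's forward recursion.
enumLogLik <- function(codes, psi, chi, pX, pC) {
    T <- length(codes)
    psi <- rep_len(psi, T - 1)
    chi <- rep_len(chi, T - 1)
    grid <- as.matrix(expand.grid(rep(list(1:4), T - 1)))
    total <- 0
    for (k in seq_len(nrow(grid))) {
        z <- c(1L, as.integer(grid[k, ]))
        p <- 1
        for (t in seq_len(T - 1)) {
            Om <- rbind(
                c(1 - psi[t], psi[t] * chi[t], psi[t] * (1 - chi[t]), 0),
                c(0, 0, 0, 1), c(0, 0, 0, 1), c(0, 0, 0, 1))
            Th <- rbind(c(1, 0, 0, 0), c(0, pX, 0, 1 - pX),
                        c(0, 0, pC, 1 - pC), c(0, 0, 0, 1))
            p <- p * Om[z[t], z[t + 1]] * Th[z[t + 1], codes[t + 1]]
            if (p == 0) break
        }
        total <- total + p
    }
    log(total)
}

# every structurally valid encounter history of length T:
# all-stopover, or stopover up to d-1 then one of codes 2/3/4 at d
# followed by "not seen"
validHistories <- function(T) {
    out <- list(rep(1L, T))
    for (d in 2:T) for (cd in 2:4) {
        h <- rep(4L, T)
        h[seq_len(d - 1L)] <- 1L
        h[d] <- cd
        out[[length(out) + 1L]] <- h
    }
    out
}

# two-species configuration used by simulation-based tests (one ACT tag
# species, one NTQB), full departure/routing covariate structure
twoSpeciesConfigs <- function(n1 = 100L, n2 = 100L) {
    cfg <- defaultSpeciesConfigs()[c(2, 6)]  # Blackbird (ACT), GW (NTQB)
    cfg[[1]]$nIndividuals <- as.integer(n1)
    cfg[[2]]$nIndividuals <- as.integer(n2)
    cfg
}

defaultDetection <- function() {
    list(pX = c(ACT = 0.55, NTQB = 0.5), pC = c(ACT = 0.97, NTQB = 0.95))
}

# build a MultistatePosterior whose every draw equals the given parameter
# vector (degenerate posterior concentrated at one point); useful for
# testing summaries without running MCMC
degeneratePosterior <- function(eh, params, nDraws = 50L) {
    md <- msModelData(eh)
    v <- migrateHMM:::paramsToVector(params)
    con <- migrateHMM:::constrainDraws(matrix(v, 1), md$speciesLevels)
    draws <- array(rep(con, each = nDraws * 2L),
                   c(nDraws, 2L, length(v)),
                   dimnames = list(NULL, NULL, colnames(con)))
    dg <- tapply(as.character(distanceGroups(eh)),
                 as.character(speciesLabels(eh)),
                 function(x) x[1L])[md$speciesLevels]
    new("MultistatePosterior", draws = draws, diagnostics = data.frame(),
        modelInfo = list(md = md, seed = 0L, speciesDistance = dg))
}

# detection records helper: build a record data.frame quickly
recs <- function(times, receiver, lon, lat, strength, tag = "t1",
                 antenna = "a1") {
    data.frame(tag_id = tag, timestamp = times, receiver_id = receiver,
               receiver_lat = lat, receiver_lon = lon,
               antenna_id = antenna, signal_strength = strength)
}

t0utc <- as.POSIXct("2020-04-01 00:00:00", tz = "UTC")
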