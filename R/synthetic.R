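#' Weather generator settings
#'
#' Parameters of the synthetic sunset-weather generator. Defaults are
#' plausible coastal spring values chosen to exercise the quadratic wind
#' terms: wind components are zero-mean normal with sd 4 m/s, the 24-h
#' pressure change is zero-mean normal with sd 5 hPa, relative humidity is
#' uniform on 40--100\%, and rain falls on 10 of 128 nights on average.
#'
#' @param windSd sd (m/s) of the eastward and northward wind components.
#' @param pressureChangeSd sd (hPa/24 h) of the pressure change.
#' @param humidityRange two-element percent interval for relative humidity.
#' @param rainProb nightly rain probability.
#' @return validated list of class \code{"weatherParams"}.
#' @export
weatherParams <- function(windSd = 4, pressureChangeSd = 5,
                          humidityRange = c(40, 100), rainProb = 10 / 128) {
    stopifnot(windSd > 0, pressureChangeSd > 0,
              length(humidityRange) == 2L,
              humidityRange[1] < humidityRange[2],
              rainProb >= 0, rainProb <= 1)
    structure(list(windSd = windSd, pressureChangeSd = pressureChangeSd,
                   humidityRange = humidityRange, rainProb = rainProb),
              class = "weatherParams")
}

#' Species configuration for the synthetic study
#'
#' @param name species label.
#' @param distance migration distance group, \code{"short"} or
#'   \code{"long"}.
#' @param nIndividuals number of tagged individuals (>= 1).
#' @param betasDeparture named length-7 vector of departure coefficients
#'   (\code{b0, ul, uq, vl, vq, dp, h}) on the logit scale.
#' @param beta0Routing routing intercept (logit scale).
#' @param tagType \code{"ACT"} (more transmitting power, higher detection
#'   probability) or \code{"NTQB"}.
#' @return validated list of class \code{"speciesConfig"}.
#' @export
speciesConfig <- function(name, distance, nIndividuals, betasDeparture,
                          beta0Routing, tagType) {
    stopifnot(distance %in% .DISTANCE_GROUPS, nIndividuals >= 1,
              length(betasDeparture) == 7L, tagType %in% .TAG_TYPES)
    names(betasDeparture) <- c("b0", "ul", "uq", "vl", "vq", "dp", "h")
    structure(list(name = name, distance = distance,
                   nIndividuals = as.integer(nIndividuals),
                   betasDeparture = betasDeparture,
                   beta0Routing = beta0Routing, tagType = tagType),
              class = "speciesConfig")
}

#' Default species configurations emulating the field study
#'
#' Seven species -- five short-distance migrants (Dunnock, Eurasian
#' Blackbird, Song Thrush, Redwing, Blackcap) and two long-distance
#' migrants (Garden Warbler, Northern Wheatear) -- with the study's tagged
#' sample sizes (total 289). The three thrushes carry ACT tags, all other
#' species the lighter NTQB tags. Generating coefficients are chosen so
#' that departure probabilities span roughly 0.08 (thrushes) to 0.38
#' (Garden Warbler), most species prefer eastward and light winds (the
#' Northern Wheatear prefers westward winds), rain suppresses departure,
#' and offshore routing probabilities sit near one half with the Garden
#' Warbler low and the Northern Wheatear high.
#'
#' @return list of \code{\link{speciesConfig}} objects.
#' @export
defaultSpeciesConfigs <- function() {
    slopes <- c(ul = 0.5, uq = -0.4, vl = -0.2, vq = -0.4,
                dp = 0.15, h = 0.25)
    mk <- function(name, distance, n, b0, chi0, tag, ul = 0.5)
        speciesConfig(name, distance, n,
                      c(b0 = b0, replace(slopes, "ul", ul)),
                      chi0, tag)
    list(mk("Dunnock", "short", 33, -1.9, 0.0, "NTQB"),
         mk("Eurasian Blackbird", "short", 35, -2.4, 0.2, "ACT"),
         mk("Song Thrush", "short", 29, -2.4, 0.2, "ACT"),
         mk("Redwing", "short", 19, -2.4, 0.2, "ACT"),
         mk("Blackcap", "short", 82, -1.8, -0.3, "NTQB"),
         mk("Garden Warbler", "long", 51, -0.5, -0.9, "NTQB"),
         mk("Northern Wheatear", "long", 40, -1.3, 1.5, "NTQB",
            ul = -0.5))
}

#' Assemble generating model parameters from species configurations
#'
#' @param configs list of \code{\link{speciesConfig}}.
#' @param betaRain shared rain slope (logit scale).
#' @param betaChi shared routing wind slopes (\code{ul, uq, vl, vq}).
#' @param pX,pC named detection probabilities per tag type.
#' @return a \linkS4class{MultistateParams}.
#' @export
speciesParams <- function(configs, betaRain = -1.2,
                          betaChi = c(ul = -0.5, uq = -0.3, vl = 0.5,
                                      vq = -0.3),
                          pX = c(ACT = 0.55, NTQB = 0.5),
                          pC = c(ACT = 0.97, NTQB = 0.95)) {
    bp <- do.call(rbind, lapply(configs, `[[`, "betasDeparture"))
    rownames(bp) <- vapply(configs, `[[`, "", "name")
    MultistateParams(bp, betaRain = betaRain,
                     beta0Chi = vapply(configs, `[[`, 0, "beta0Routing"),
                     betaChi = betaChi, pX = pX, pC = pC)
}

#' Simulate sunset covariates
#'
#' One row per individual-occasion: wind components \code{u}, \code{v}
#' (zero-mean normal), 24-h pressure change \code{dp} (zero-mean normal),
#' relative humidity \code{h} (uniform) and binary \code{rain}
#' (Bernoulli). Deterministic given \code{seed}; the global RNG state is
#' left untouched.
#'
#' @param nIndividuals,nOccasions positive counts (\code{nOccasions >= 2}).
#' @param weather a \code{\link{weatherParams}} object.
#' @param seed integer seed.
#' @return data.frame with columns \code{individual}, \code{occasion},
#'   \code{u}, \code{v}, \code{dp}, \code{h}, \code{rain}.
#' @export
simulateCovariates <- function(nIndividuals, nOccasions,
                               weather = weatherParams(), seed = 1) {
    if (nIndividuals < 1 || nOccasions < 2)
        stop("need nIndividuals >= 1 and nOccasions >= 2")
    n <- nIndividuals * nOccasions
    withSeed(seed, data.frame(
        individual = rep(seq_len(nIndividuals), each = nOccasions),
        occasion = rep(seq_len(nOccasions), nIndividuals),
        u = rnorm(n, 0, weather$windSd),
        v = rnorm(n, 0, weather$windSd),
        dp = rnorm(n, 0, weather$pressureChangeSd),
        h = runif(n, weather$humidityRange[1], weather$humidityRange[2]),
        rain = rbinom(n, 1, weather$rainProb)))
}

## Run the categorical state and observation processes forward given
## per-transition probability matrices (n x T-1) and per-individual
## detection probabilities. Uses the current RNG state.
.simulateProcess <- function(psi, chi, pXi, pCi) {
    n <- nrow(psi); T <- ncol(psi) + 1L
    z <- matrix(NA_integer_, n, T)
    y <- matrix(NA_integer_, n, T)
    z[, 1L] <- .CODE_STOPOVER
    y[, 1L] <- .CODE_STOPOVER
    for (t in seq_len(T - 1L)) {
        cur <- z[, t]
        dep <- cur == 1L & runif(n) < psi[, t]
        off <- runif(n) < chi[, t]
        nxt <- ifelse(cur >= 2L, 4L,
                      ifelse(dep, ifelse(off, 2L, 3L), 1L))
        z[, t + 1L] <- nxt
        seen <- runif(n)
        y[, t + 1L] <- ifelse(nxt == 1L, 1L,
                       ifelse(nxt == 2L, ifelse(seen < pXi, 2L, 4L),
                       ifelse(nxt == 3L, ifelse(seen < pCi, 3L, 4L),
                              4L)))
    }
    list(z = z, y = y)
}

## covariate table (long) -> named list of n x T matrices
.covariateMatrices <- function(covariates, n, T) {
    need <- c("individual", "occasion", "u", "v", "dp", "h", "rain")
    if (!all(need %in% names(covariates)))
        stop("covariate table is missing columns: ",
             paste(setdiff(need, names(covariates)), collapse = ", "))
    key <- paste(covariates$individual, covariates$occasion)
    want <- paste(rep(seq_len(n), each = T), rep(seq_len(T), n))
    idx <- match(want, key)
    if (anyNA(idx))
        stop("covariate gaps: missing individual-occasion rows")
    lapply(setNames(c("u", "v", "dp", "h", "rain"),
                    c("u", "v", "dp", "h", "rain")),
           function(cn) matrix(covariates[[cn]][idx], n, T, byrow = TRUE))
}

#' Simulate latent state trajectories and encounter histories
#'
#' Runs the four-state process forward: every bird starts at stopover; on
#' each transition a bird at stopover departs with probability psi (from
#' the departure linear predictor on that night's covariates) and, if it
#' departs, flies offshore with probability chi; a flight state lasts one
#' occasion and is then absorbed in "departed". Observations follow the
#' detection model: flights are registered with the route- and tag-specific
#' detection probability, otherwise coded "not seen".
#'
#' @param configs list of \code{\link{speciesConfig}} (defines species,
#'   sample sizes, tag types and generating coefficients).
#' @param covariates covariate table covering all individual-occasions (see
#'   \code{\link{simulateCovariates}}).
#' @param detection list with named vectors \code{pX} and \code{pC}
#'   (detection probability per tag type).
#' @param nOccasions history length T.
#' @param seed integer seed.
#' @param betaRain,betaChi shared slopes passed to
#'   \code{\link{speciesParams}}.
#' @return list with \code{z} (true state matrix, individuals x T),
#'   \code{histories} (an \linkS4class{EncounterHistories} carrying the raw
#'   covariates as assays), and \code{params} (the generating
#'   \linkS4class{MultistateParams}).
#' @export
simulateIndividuals <- function(configs, covariates,
                                detection = list(pX = c(ACT = 0.55,
                                                        NTQB = 0.5),
                                                 pC = c(ACT = 0.97,
                                                        NTQB = 0.95)),
                                nOccasions, seed = 1, betaRain = -1.2,
                                betaChi = c(ul = -0.5, uq = -0.3,
                                            vl = 0.5, vq = -0.3)) {
    stopifnot(all(unlist(detection) >= 0), all(unlist(detection) <= 1))
    params <- speciesParams(configs, betaRain = betaRain,
                            betaChi = betaChi,
                            pX = detection$pX, pC = detection$pC)
    ns <- vapply(configs, `[[`, 0L, "nIndividuals")
    n <- sum(ns)
    T <- nOccasions
    species <- factor(rep(vapply(configs, `[[`, "", "name"), ns),
                      levels = vapply(configs, `[[`, "", "name"))
    tag <- rep(vapply(configs, `[[`, "", "tagType"), ns)
    cm <- .covariateMatrices(covariates, n, T)
    tr <- seq_len(T - 1L)
    bases <- covariateBases(cm$u[, tr], cm$v[, tr], cm$dp[, tr],
                            cm$h[, tr], cm$rain[, tr])
    spIdx <- as.integer(species)
    psi <- departureProbability(params, spIdx, bases$ul, bases$uq,
                                bases$vl, bases$vq, bases$dp, bases$h,
                                bases$r)
    chi <- routingProbability(params, spIdx, bases$ul, bases$uq,
                              bases$vl, bases$vq)
    psi <- matrix(psi, n, T - 1L)
    chi <- matrix(chi, n, T - 1L)
    pXi <- detection$pX[tag]
    pCi <- detection$pC[tag]
    sim <- withSeed(seed, .simulateProcess(psi, chi, pXi, pCi))
    z <- sim$z
    y <- sim$y
    dist <- rep(vapply(configs, `[[`, "", "distance"), ns)
    eh <- EncounterHistories(y, species = species, tagType = tag,
                             distanceGroup = dist,
                             covariates = cm)
    list(z = z, histories = eh, params = params)
}

#' Simulate a raw detection-record series for a moving or stationary tag
#'
#' Linear interpolation between the start and end coordinates; each
#' receiver within detection range registers time-ordered records whose
#' signal strength decreases with distance (rising then falling per station
#' pass) plus noise. A stationary tag yields fluctuating detections at the
#' nearest station without a systematic terminal decline.
#'
#' @param flight list with \code{start}, \code{end} (each
#'   \code{c(lon, lat)} in decimal degrees), \code{startTime},
#'   \code{endTime} (POSIXct, \code{startTime < endTime}).
#' @param receiverNetwork data.frame with columns \code{receiver_id},
#'   \code{lon}, \code{lat}.
#' @param tagId tag identifier.
#' @param seed integer seed.
#' @param intervalSec sampling interval of the tag position.
#' @param rangeKm detection range of a receiver.
#' @param noiseSd sd of the signal-strength noise.
#' @return data.frame of detection records (\code{tag_id}, \code{timestamp},
#'   \code{receiver_id}, \code{receiver_lat}, \code{receiver_lon},
#'   \code{antenna_id}, \code{signal_strength}), time-ordered.
#' @export
simulateDetectionSeries <- function(flight, receiverNetwork, tagId = "tag1",
                                    seed = 1, intervalSec = 120,
                                    rangeKm = 20, noiseSd = 1.5) {
    if (nrow(receiverNetwork) < 1L)
        stop("receiver network must contain at least one station")
    if (!flight$startTime < flight$endTime)
        stop("startTime must precede endTime")
    times <- seq(flight$startTime, flight$endTime, by = intervalSec)
    f <- seq(0, 1, length.out = length(times))
    lon <- flight$start[1] + f * (flight$end[1] - flight$start[1])
    lat <- flight$start[2] + f * (flight$end[2] - flight$start[2])
    withSeed(seed, {
        recs <- lapply(seq_len(nrow(receiverNetwork)), function(j) {
            d <- geosphere::distHaversine(
                cbind(lon, lat),
                c(receiverNetwork$lon[j], receiverNetwork$lat[j])) / 1000
            keep <- d < rangeKm
            if (!any(keep)) return(NULL)
            data.frame(tag_id = tagId,
                       timestamp = times[keep],
                       receiver_id = receiverNetwork$receiver_id[j],
                       receiver_lat = receiverNetwork$lat[j],
                       receiver_lon = receiverNetwork$lon[j],
                       antenna_id = "a1",
                       signal_strength = 120 - 2.5 * d[keep] +
                           rnorm(sum(keep), 0, noiseSd))
        })
        out <- do.call(rbind, recs)
        if (is.null(out)) out <- data.frame(
            tag_id = character(), timestamp = as.POSIXct(character()),
            receiver_id = character(), receiver_lat = numeric(),
            receiver_lon = numeric(), antenna_id = character(),
            signal_strength = numeric())
        out[order(out$timestamp), , drop = FALSE]
    })
}

#' Simulate the stopover-site signal signature of a departure
#'
#' Produces the canonical departure pattern used by the signal-strength
#' rule: a stable plateau, then five declining detections ending at the
#' departure time, then silence. With \code{departed = FALSE} the series
#' simply stops at full strength (an undetermined loss of signal).
#'
#' @param receiver one-row data.frame (\code{receiver_id}, \code{lon},
#'   \code{lat}).
#' @param lastTime time of the final detection (the departure time when
#'   \code{departed}).
#' @param tagId tag identifier.
#' @param departed emit the decline signature (otherwise an abrupt stop).
#' @param nPlateau number of plateau detections before the decline.
#' @param seed integer seed.
#' @return data.frame of detection records, time-ordered.
#' @export
simulateDepartureSeries <- function(receiver, lastTime, tagId = "tag1",
                                    departed = TRUE, nPlateau = 6,
                                    seed = 1) {
    withSeed(seed, {
        ## an undetermined loss of signal keeps full, steady strength to
        ## the end (no decline signature)
        strengths <- if (departed)
            c(100 + rnorm(nPlateau, 0, 1), c(90, 80, 70, 60, 50))
        else rep(100, nPlateau + 5L)
        k <- length(strengths)
        times <- lastTime - rev(seq_len(k) - 1L) * 120
        data.frame(tag_id = tagId, timestamp = times,
                   receiver_id = receiver$receiver_id,
                   receiver_lat = receiver$lat,
                   receiver_lon = receiver$lon,
                   antenna_id = "a1", signal_strength = strengths)
    })
}
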