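## End-to-end synthetic study generator: covariates, latent states,
## encounter histories, and the raw detection-record series from which the
## preprocessing rules re-derive flights, routes, departures and histories.

.STOPOVER_STATION <- data.frame(receiver_id = "stopover_main",
                                lon = 7.95, lat = 53.62)

#' Simulate a complete synthetic tracking study
#'
#' Generates sunset covariates, runs the four-state process for every
#' tagged bird, and materialises the observation layer as raw detection
#' records: daily stopover pings, the departure-night signal signature
#' (plateau then decline) for birds whose departure is determinable, flight
#' tracks past three receivers (via an offshore island station or along the
#' coast) for detected flights, and an abrupt constant-strength signal loss
#' for "undetermined" birds (tag failure, predation, battery death), whose
#' proportion is governed by \code{dropoutProb}. Birds still at stopover at
#' the end of the occasion grid are also treated as undetermined, mirroring
#' a field study in which every modeled bird departed.
#'
#' @param configs list of \code{\link{speciesConfig}} (default: the
#'   seven-species study emulation).
#' @param weather \code{\link{weatherParams}}.
#' @param detection list with \code{pX} and \code{pC} per tag type.
#' @param nOccasions occasion-grid length T.
#' @param seed integer seed (drives every random component).
#' @param dropoutProb per-individual probability of an undetermined fate.
#' @param deployTime deployment time (POSIXct UTC); all birds are deployed
#'   on the same morning on a single occasion grid.
#' @param relTimeOffshore,relTimeOnshore Student-t location of the relative
#'   departure time (fraction of night) per route.
#' @param sunriseSpecies species departing around sunrise instead (their
#'   location is 1).
#' @return list with \code{covariates}, \code{truth} (z matrix),
#'   \code{histories} (all birds), \code{modeled}
#'   (\linkS4class{EncounterHistories} of determined birds only),
#'   \code{metadata}, \code{detections}, \code{flights},
#'   \code{stopoverObs}, \code{departureTimeObs}, \code{params}.
#' @export
simulateStudy <- function(configs = defaultSpeciesConfigs(),
                          weather = weatherParams(),
                          detection = list(pX = c(ACT = 0.55, NTQB = 0.5),
                                           pC = c(ACT = 0.97,
                                                  NTQB = 0.95)),
                          nOccasions = 36, seed = 1,
                          dropoutProb = 105 / 289,
                          deployTime = as.POSIXct("2020-04-01 09:00:00",
                                                  tz = "UTC"),
                          relTimeOffshore = 0.25, relTimeOnshore = 0.296,
                          sunriseSpecies = "Dunnock") {
    n <- sum(vapply(configs, `[[`, 0L, "nIndividuals"))
    T <- nOccasions
    covariates <- simulateCovariates(n, T, weather, seed)
    sim <- simulateIndividuals(configs, covariates, detection, T,
                               seed = seed + 1L)
    eh <- sim$histories
    codes <- encounterCodes(eh)
    depOcc <- apply(codes, 1L, function(x) {
        w <- which(x != .CODE_STOPOVER); if (length(w)) w[1L] else NA
    })
    trueRoute <- ifelse(is.na(depOcc), NA,
                        ifelse(sim$z[cbind(seq_len(n),
                                           ifelse(is.na(depOcc), 1L,
                                                  depOcc))] ==
                               .CODE_OFFSHORE, "offshore", "onshore"))
    obsCode <- ifelse(is.na(depOcc), NA,
                      codes[cbind(seq_len(n),
                                  ifelse(is.na(depOcc), 1L, depOcc))])
    dayStart <- as.POSIXct(format(deployTime, "%Y-%m-%d"), tz = "UTC")
    meta <- withSeed(seed + 2L, {
        dropout <- runif(n) < dropoutProb
        determined <- !dropout & !is.na(depOcc)
        nightLen <- pmax(6, rnorm(n, 9.3, 1)) * 3600
        relLoc <- ifelse(speciesLabels(eh) %in% sunriseSpecies, 1,
                         ifelse(!is.na(trueRoute) &
                                trueRoute == "offshore",
                                relTimeOffshore, relTimeOnshore))
        relTime <- pmin(pmax(relLoc + 0.08 * rt(n, df = 5), 0.02), 1.1)
        sunset <- dayStart + (ifelse(is.na(depOcc), 2L, depOcc) - 1) *
            86400 + 19 * 3600
        departure <- sunset + relTime * nightLen
        data.frame(tag_id = rowData(eh)$tag_id,
                   species = as.character(speciesLabels(eh)),
                   tag_type = as.character(tagTypes(eh)),
                   distance_group = as.character(distanceGroups(eh)),
                   deploy_time = deployTime,
                   deploy_lon = .STOPOVER_STATION$lon,
                   deploy_lat = .STOPOVER_STATION$lat,
                   determined = determined,
                   departure_time = as.POSIXct(
                       ifelse(determined, departure, NA),
                       origin = "1970-01-01", tz = "UTC"),
                   sunset = sunset, sunrise = sunset + nightLen,
                   rel_time = ifelse(determined, relTime, NA),
                   departure_occasion = ifelse(determined, depOcc, NA),
                   route_observed = ifelse(determined & obsCode %in% 2:3,
                                           ifelse(obsCode == 2L,
                                                  "offshore", "onshore"),
                                           NA),
                   route_true = ifelse(determined, trueRoute, NA))
    })
    ## raw detection records
    detList <- list()
    flightRows <- list()
    withSeed(seed + 3L, {
        finalLatOff <- pmax(54.2, rnorm(n, 54.48, 0.31))
        finalLatOn <- pmin(54.1, rnorm(n, 53.80, 0.26))
        for (i in seq_len(n)) {
            id <- meta$tag_id[i]
            lastStopDay <- if (meta$determined[i]) depOcc[i] - 1L
                           else min(T, 10L)
            if (lastStopDay > 1L) {
                pingDays <- seq_len(lastStopDay - 1L)
                detList[[length(detList) + 1L]] <- data.frame(
                    tag_id = id,
                    timestamp = dayStart + (pingDays - 1) * 86400 +
                        12 * 3600,
                    receiver_id = .STOPOVER_STATION$receiver_id,
                    receiver_lat = .STOPOVER_STATION$lat,
                    receiver_lon = .STOPOVER_STATION$lon,
                    antenna_id = "a1",
                    signal_strength = 100)
            }
            lastTime <- if (meta$determined[i]) meta$departure_time[i]
                        else dayStart + (lastStopDay - 1) * 86400 +
                            12 * 3600
            detList[[length(detList) + 1L]] <- simulateDepartureSeries(
                .STOPOVER_STATION, lastTime, tagId = id,
                departed = meta$determined[i], seed = seed + 10L + i)
            if (!is.na(meta$route_observed[i])) {
                off <- meta$route_observed[i] == "offshore"
                recs <- if (off) data.frame(
                    receiver_id = c("Helgoland", "north_island"),
                    lon = c(7.89, 7.55),
                    lat = c(54.18, finalLatOff[i]))
                else data.frame(
                    receiver_id = c("coast_mid", "coast_east"),
                    lon = c(8.45, 8.90),
                    lat = c(53.75, finalLatOn[i]))
                ft <- lastTime + c(5400, 10800)
                detList[[length(detList) + 1L]] <- data.frame(
                    tag_id = id, timestamp = ft,
                    receiver_id = recs$receiver_id,
                    receiver_lat = recs$lat, receiver_lon = recs$lon,
                    antenna_id = "a1",
                    signal_strength = 95)
                flightRows[[length(flightRows) + 1L]] <- data.frame(
                    tag_id = id, species = meta$species[i],
                    start_time = lastTime, end_time = ft[2L],
                    start_lon = .STOPOVER_STATION$lon,
                    start_lat = .STOPOVER_STATION$lat,
                    final_lon = recs$lon[2L], final_lat = recs$lat[2L],
                    receiver_sequence = paste(
                        c(.STOPOVER_STATION$receiver_id,
                          recs$receiver_id), collapse = ";"),
                    n_receivers = 3L,
                    distance_km = geosphere::distHaversine(
                        c(.STOPOVER_STATION$lon, .STOPOVER_STATION$lat),
                        c(recs$lon[2L], recs$lat[2L])) / 1000,
                    route = meta$route_observed[i])
            }
        }
    })
    detections <- do.call(rbind, detList)
    detections <- detections[order(detections$tag_id,
                                   detections$timestamp), ]
    flights <- if (length(flightRows)) do.call(rbind, flightRows)
               else NULL
    keep <- which(meta$determined)
    modeled <- eh[keep, ]
    routed <- meta[!is.na(meta$route_observed), , drop = FALSE]
    stopoverObs <- data.frame(duration = routed$departure_occasion - 1L,
                              species = routed$species,
                              route = routed$route_observed,
                              distance_group = routed$distance_group)
    departureTimeObs <- data.frame(rel_time = routed$rel_time,
                                   species = routed$species,
                                   route = routed$route_observed)
    list(covariates = covariates, truth = sim$z, histories = eh,
         modeled = modeled, metadata = meta, detections = detections,
         flights = flights, stopoverObs = stopoverObs,
         departureTimeObs = departureTimeObs, params = sim$params)
}

#' Pool species labels in an EncounterHistories object
#'
#' Replaces the species labels of the listed members with a pooled label
#' (e.g. the three \emph{Turdus} species as "thrushes"), as is common when
#' per-species samples are small and migration ecology is shared.
#'
#' @param eh an \linkS4class{EncounterHistories}.
#' @param pooling named list: pooled label -> character vector of member
#'   species.
#' @return an \code{EncounterHistories} with re-levelled species.
#' @export
poolSpecies <- function(eh,
                        pooling = list(thrushes = c("Eurasian Blackbird",
                                                    "Song Thrush",
                                                    "Redwing"))) {
    sp <- as.character(speciesLabels(eh))
    for (lab in names(pooling)) sp[sp %in% pooling[[lab]]] <- lab
    rowData(eh)$species <- factor(sp)
    eh
}

.fmtTime <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a synthetic study bundle as delimited text
#'
#' Writes covariates, true states, encounter histories (wide, one column
#' per occasion), metadata, raw detections and flights as comma-separated
#' UTF-8 files with ISO-8601 UTC timestamps and WGS84 decimal-degree
#' coordinates.
#'
#' @param study output of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
        for (cn in names(df))
            if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- .fmtTime(df[[cn]])
        write.csv(df, file.path(dir, name), row.names = FALSE)
        name
    }
    cd <- encounterCodes(study$histories)
    hist <- data.frame(tag_id = rowData(study$histories)$tag_id,
                       species = as.character(
                           speciesLabels(study$histories)),
                       tag_type = as.character(tagTypes(study$histories)),
                       as.data.frame(cd))
    names(hist)[-(1:3)] <- paste0("occ", seq_len(ncol(cd)))
    truth <- data.frame(tag_id = rowData(study$histories)$tag_id,
                        as.data.frame(study$truth))
    names(truth)[-1] <- paste0("occ", seq_len(ncol(study$truth)))
    files <- c(w(study$covariates, "covariates.csv"),
               w(hist, "histories.csv"),
               w(truth, "truth.csv"),
               w(study$metadata, "metadata.csv"),
               w(study$detections, "detections.csv"))
    if (!is.null(study$flights))
        files <- c(files, w(study$flights, "flights.csv"))
    invisible(file.path(dir, files))
}
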