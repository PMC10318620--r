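## Rule-based preprocessing of raw receiver detections into flights, route
## labels, departure events and encounter histories.

#' Identify migratory flights in raw detection records
#'
#' Candidate movements are maximal runs of a tag's detections in which
#' consecutive detections are less than \code{maxSpanHours} apart (runs of a
#' single record are never flights). A candidate is a flight when it covered
#' at least \code{minDistanceKm} or was recorded by at least
#' \code{minReceivers} different receivers.
#'
#' @param records data.frame of detection records with columns
#'   \code{tag_id}, \code{timestamp} (POSIXct), \code{receiver_id},
#'   \code{receiver_lat}, \code{receiver_lon}; sorted internally.
#' @param minDistanceKm distance criterion (default 35 km).
#' @param minReceivers receiver-count criterion (default 3).
#' @param maxSpanHours maximum gap between consecutive detections (default
#'   7 h).
#' @param distanceMode \code{"endpoint"} (great-circle between the first
#'   and last detection; default) or \code{"track"} (summed great-circle
#'   legs between consecutive detections).
#' @return data.frame of flights, time-ordered: \code{tag_id},
#'   \code{start_time}, \code{end_time}, \code{start_lon}, \code{start_lat},
#'   \code{final_lon}, \code{final_lat}, \code{receiver_sequence}
#'   (identifiers joined by \code{";"}), \code{n_receivers},
#'   \code{distance_km}, \code{route} (\code{"unset"}).
#' @export
identifyFlights <- function(records, minDistanceKm = 35, minReceivers = 3,
                            maxSpanHours = 7,
                            distanceMode = c("endpoint", "track")) {
    distanceMode <- match.arg(distanceMode)
    empty <- data.frame(tag_id = character(), start_time =
                            as.POSIXct(character()),
                        end_time = as.POSIXct(character()),
                        start_lon = numeric(), start_lat = numeric(),
                        final_lon = numeric(), final_lat = numeric(),
                        receiver_sequence = character(),
                        n_receivers = integer(), distance_km = numeric(),
                        route = character())
    if (is.null(records) || nrow(records) == 0L) return(empty)
    out <- list()
    for (tg in unique(records$tag_id)) {
        r <- records[records$tag_id == tg, , drop = FALSE]
        r <- r[order(r$timestamp), , drop = FALSE]
        gaps <- diff(as.numeric(r$timestamp)) / 3600
        runId <- cumsum(c(0, gaps >= maxSpanHours))
        for (g in split(seq_len(nrow(r)), runId)) {
            if (length(g) < 2L) next
            s <- r[g, , drop = FALSE]
            pts <- cbind(s$receiver_lon, s$receiver_lat)
            dist <- if (distanceMode == "endpoint")
                geosphere::distHaversine(pts[1L, ],
                                         pts[nrow(pts), ]) / 1000
            else sum(geosphere::distHaversine(pts[-nrow(pts), ,
                                                  drop = FALSE],
                                              pts[-1L, , drop = FALSE])) /
                1000
            nRec <- length(unique(s$receiver_id))
            if (dist >= minDistanceKm || nRec >= minReceivers) {
                seqIds <- rle(as.character(s$receiver_id))$values
                out[[length(out) + 1L]] <- data.frame(
                    tag_id = tg, start_time = s$timestamp[1L],
                    end_time = s$timestamp[nrow(s)],
                    start_lon = s$receiver_lon[1L],
                    start_lat = s$receiver_lat[1L],
                    final_lon = s$receiver_lon[nrow(s)],
                    final_lat = s$receiver_lat[nrow(s)],
                    receiver_sequence = paste(seqIds, collapse = ";"),
                    n_receivers = nRec, distance_km = dist,
                    route = "unset")
            }
        }
    }
    if (!length(out)) return(empty)
    fl <- do.call(rbind, out)
    fl[order(fl$start_time), , drop = FALSE]
}

#' Classify a flight as offshore or onshore
#'
#' A flight is offshore when it began west of \code{lonThreshold} and ended
#' north of \code{latThreshold}, or when it included a detection at an
#' offshore receiver station (e.g. the Helgoland or FINO3 stations);
#' otherwise it is onshore.
#'
#' @param flights one or more flight rows from
#'   \code{\link{identifyFlights}}.
#' @param lonThreshold starting-longitude threshold (degrees E).
#' @param latThreshold final-latitude threshold (degrees N).
#' @param offshoreStationIds identifiers of offshore receiver stations.
#' @return character vector \code{"offshore"}/\code{"onshore"}.
#' @export
classifyRoute <- function(flights, lonThreshold = 8.08,
                          latThreshold = 54.135,
                          offshoreStationIds = c("Helgoland", "FINO3")) {
    atOffshoreStation <- vapply(
        strsplit(as.character(flights$receiver_sequence), ";"),
        function(ids) any(ids %in% offshoreStationIds), logical(1))
    ifelse((flights$start_lon < lonThreshold &
            flights$final_lat > latThreshold) | atOffshoreStation,
           "offshore", "onshore")
}

#' Detect a departure from the stopover-site signal-strength signature
#'
#' On the antenna with the latest detections, a departure is scored when
#' the mean of the last five detections falls below the mean of the highest
#' signal strength within the final \code{peakWindowMinutes} before signal
#' loss and its (up to) four temporally neighbouring values on the same
#' antenna. The last detection time is returned as the departure time.
#'
#' @param records one tag's stopover detections (columns \code{timestamp},
#'   \code{signal_strength}, \code{antenna_id}, \code{receiver_id});
#'   sorted internally.
#' @param peakWindowMinutes length of the terminal peak window.
#' @return list with \code{time} (POSIXct departure time or \code{NA}),
#'   \code{determined} (logical), and \code{antenna}. Undetermined when no
#'   antenna has at least five detections or the strict inequality fails.
#' @export
detectDeparture <- function(records, peakWindowMinutes = 10) {
    none <- list(time = as.POSIXct(NA), determined = FALSE,
                 antenna = NA_character_)
    if (is.null(records) || nrow(records) == 0L) return(none)
    records <- records[order(records$timestamp), , drop = FALSE]
    ant <- paste(records$receiver_id, records$antenna_id, sep = "/")
    counts <- table(ant)
    ok <- names(counts)[counts >= 5L]
    if (!length(ok)) return(none)
    lastPer <- vapply(ok, function(a)
        max(as.numeric(records$timestamp[ant == a])), numeric(1))
    pick <- ok[which.max(lastPer)]
    s <- records[ant == pick, , drop = FALSE]
    k <- nrow(s)
    A <- mean(tail(s$signal_strength, 5L))
    lastTime <- s$timestamp[k]
    inWin <- which(as.numeric(lastTime) - as.numeric(s$timestamp) <=
                       peakWindowMinutes * 60)
    peakIdx <- inWin[which.max(s$signal_strength[inWin])]
    nb <- intersect((peakIdx - 2L):(peakIdx + 2L), seq_len(k))
    B <- mean(s$signal_strength[nb])
    if (A < B) list(time = lastTime, determined = TRUE, antenna = pick)
    else none
}

#' Apply the study's exclusion rules
#'
#' Individual-level rules: drop birds whose minimum stopover exceeded
#' \code{maxStopoverDays} (whole days between deployment and departure,
#' strictly more), and drop departures of the listed nocturnal-migrant
#' species that occurred in the morning immediately after tag deployment.
#' Flight-level rules: drop short westward coastal flights (end longitude
#' west of start, below the flight distance criterion), then keep only each
#' individual's first remaining flight. Every exclusion is logged with its
#' rule; retained plus excluded counts equal the input counts at each
#' scope.
#'
#' @param individuals data.frame with one row per bird: \code{tag_id},
#'   \code{species}, \code{deploy_time}, \code{departure_time} (POSIXct,
#'   \code{NA} when undetermined).
#' @param flights flights with routes (rows from
#'   \code{\link{identifyFlights}} after \code{\link{classifyRoute}});
#'   may be \code{NULL}.
#' @param maxStopoverDays stopover-duration cut-off (days).
#' @param morningSpecies species whose morning-of-deployment departures
#'   are discarded.
#' @param morningEndHour end of "morning" (UTC hour).
#' @param shortFlightKm distance below which a westward coastal flight is
#'   discarded.
#' @return list with \code{individuals} (retained, with
#'   \code{stopover_days}), \code{flights} (retained), and \code{log}
#'   (\code{scope}, \code{id}, \code{rule}).
#' @export
applyExclusions <- function(individuals, flights = NULL,
                            maxStopoverDays = 40,
                            morningSpecies = c("Blackcap",
                                               "Garden Warbler"),
                            morningEndHour = 12, shortFlightKm = 35) {
    log <- data.frame(scope = character(), id = character(),
                      rule = character())
    addLog <- function(scope, id, rule) {
        log <<- rbind(log, data.frame(scope = scope, id = as.character(id),
                                      rule = rule))
    }
    ## flight-level rules
    if (!is.null(flights) && nrow(flights)) {
        westShort <- flights$final_lon < flights$start_lon &
            flights$distance_km < shortFlightKm &
            flights$route == "onshore"
        for (i in which(westShort))
            addLog("flight", flights$tag_id[i], "westward_coastal_flight")
        flights <- flights[!westShort, , drop = FALSE]
        if (nrow(flights)) {
            flights <- flights[order(flights$start_time), , drop = FALSE]
            dup <- duplicated(flights$tag_id)
            for (i in which(dup))
                addLog("flight", flights$tag_id[i], "later_flight")
            flights <- flights[!dup, , drop = FALSE]
        }
    }
    ## individual-level rules (first matching rule wins)
    keep <- rep(TRUE, nrow(individuals))
    dep <- individuals$departure_time
    stopDays <- floor(as.numeric(difftime(dep, individuals$deploy_time,
                                          units = "days")))
    sameDay <- !is.na(dep) &
        as.Date(dep) == as.Date(individuals$deploy_time)
    morning <- sameDay &
        as.integer(format(dep, "%H")) < morningEndHour &
        individuals$species %in% morningSpecies
    for (i in seq_len(nrow(individuals))) {
        if (morning[i]) {
            addLog("individual", individuals$tag_id[i],
                   "morning_of_deployment")
            keep[i] <- FALSE
        } else if (is.na(dep[i])) {
            addLog("individual", individuals$tag_id[i], "undetermined")
            keep[i] <- FALSE
        } else if (stopDays[i] > maxStopoverDays) {
            addLog("individual", individuals$tag_id[i],
                   paste0("stopover>", maxStopoverDays, "d"))
            keep[i] <- FALSE
        }
    }
    out <- individuals[keep, , drop = FALSE]
    out$stopover_days <- stopDays[keep]
    if (!is.null(flights))
        flights <- flights[flights$tag_id %in% out$tag_id, , drop = FALSE]
    list(individuals = out, flights = flights, log = log)
}

#' Build one encounter history from departure information
#'
#' Occasion 1 is the deployment day; the departure occasion is the number
#' of whole days between deployment and departure plus one (the occasion
#' grid is night-indexed, so an evening departure k days after deployment
#' lands on occasion k+1). Codes are stopover up to the departure occasion
#' minus one; at the departure occasion the route code (2 offshore, 3
#' onshore) when a flight was detected, otherwise "not seen" (4); 4
#' thereafter.
#'
#' @param deploymentDay deployment date-time (Date or POSIXct).
#' @param departureDay departure date-time, or \code{NULL}/\code{NA} when
#'   no departure was determined (no history is emitted then).
#' @param route \code{"offshore"}, \code{"onshore"} or \code{NA} (departure
#'   determined but flight undetected).
#' @param T number of occasions (default 36).
#' @return integer code vector of length \code{T}, or \code{NULL} when the
#'   departure is undetermined.
#' @examples
#' d0 <- as.POSIXct("2020-04-01 09:00", tz = "UTC")
#' buildEncounterHistory(d0, d0 + 3 * 86400 + 10 * 3600, "offshore", T = 6)
#' @export
buildEncounterHistory <- function(deploymentDay, departureDay = NULL,
                                  route = NA, T = 36) {
    if (is.null(departureDay) || is.na(departureDay)) return(NULL)
    dd <- as.numeric(difftime(as.POSIXct(departureDay),
                              as.POSIXct(deploymentDay), units = "days"))
    if (dd < 0) stop("departure precedes deployment")
    occ <- floor(dd) + 1L
    if (occ < 2L) stop("departure precedes the first modeled night")
    if (occ > T) stop("departure lies beyond the occasion grid (T = ",
                      T, ")")
    codes <- rep(.CODE_NOTSEEN, T)
    codes[seq_len(occ - 1L)] <- .CODE_STOPOVER
    codes[occ] <- if (is.na(route)) .CODE_NOTSEEN
                  else if (route == "offshore") .CODE_OFFSHORE
                  else .CODE_ONSHORE
    as.integer(codes)
}

#' Departure time as a fraction of night length
#'
#' \code{(departure - sunset) / (nextSunrise - sunset)}; 0 at sunset, 1 at
#' sunrise. May fall outside \[0, 1\] for diurnal departures (e.g. birds
#' leaving around or after sunrise).
#'
#' @param departure,sunset,nextSunrise POSIXct times with
#'   \code{sunset < nextSunrise}.
#' @return numeric fraction.
#' @export
relativeDepartureTime <- function(departure, sunset, nextSunrise) {
    night <- as.numeric(difftime(nextSunrise, sunset, units = "secs"))
    if (any(night <= 0)) stop("night length must be positive")
    as.numeric(difftime(departure, sunset, units = "secs")) / night
}

#' Descriptive summary of flights per route and species
#'
#' @param flights flights with \code{route}, \code{species} and
#'   \code{final_lat} columns.
#' @return data.frame with count, mean and sd of the final-detection
#'   latitude per route and species, plus per-route totals (species
#'   \code{"all"}). The sd is \code{NA} for a single flight.
#' @export
summarizeFlights <- function(flights) {
    grp <- interaction(flights$route, flights$species, drop = TRUE)
    rows <- lapply(levels(grp), function(g) {
        s <- flights[grp == g, , drop = FALSE]
        data.frame(route = s$route[1L], species = as.character(s$species[1L]),
                   n = nrow(s), mean_final_lat = mean(s$final_lat),
                   sd_final_lat = if (nrow(s) > 1L) sd(s$final_lat)
                                  else NA_real_)
    })
    tots <- lapply(unique(flights$route), function(rt) {
        s <- flights[flights$route == rt, , drop = FALSE]
        data.frame(route = rt, species = "all", n = nrow(s),
                   mean_final_lat = mean(s$final_lat),
                   sd_final_lat = if (nrow(s) > 1L) sd(s$final_lat)
                                  else NA_real_)
    })
    do.call(rbind, c(rows, tots))
}
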