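## Configuration, IO plumbing and the staged pipeline driver.

#' Default pipeline configuration
#'
#' One structured list drives every stage; values can be overridden by a
#' YAML file (\code{\link{readPipelineConfig}}) or by the \code{overrides}
#' argument of \code{\link{runPipeline}} (highest precedence).
#'
#' @return nested list: \code{paths} (output directory), \code{rules}
#'   (flight/route/departure/exclusion thresholds), \code{model} (occasion
#'   count, chains, iterations, warmup, seed, prior SDs), \code{summary}
#'   (HPDI mass, posterior-predictive draws), \code{simulate} (seed,
#'   dropout probability), \code{pooling} (species pooled for modeling).
#' @export
defaultPipelineConfig <- function() {
    list(paths = list(outDir = "migrateHMM_run"),
         rules = list(minDistanceKm = 35, minReceivers = 3,
                      maxSpanHours = 7, lonThreshold = 8.08,
                      latThreshold = 54.135,
                      offshoreStationIds = c("Helgoland", "FINO3",
                                             "north_island"),
                      maxStopoverDays = 40, stopoverRadiusKm = 20,
                      morningSpecies = c("Blackcap", "Garden Warbler")),
         model = list(T = 36, chains = 4, iterations = 2000,
                      warmup = 1000, seed = 1, interceptSd = 1.5,
                      slopeSd = 1),
         summary = list(hpdiMass = 0.9, ppcDraws = 100),
         simulate = list(seed = 1, dropoutProb = 105 / 289),
         pooling = list(thrushes = c("Eurasian Blackbird", "Song Thrush",
                                     "Redwing")))
}

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(override[[nm]]) && is.list(base[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

#' Read a pipeline configuration from YAML
#'
#' File values override the defaults; anything not set keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
    .mergeConfig(defaultPipelineConfig(), yaml::read_yaml(path))
}

.parseTime <- function(x) as.POSIXct(x, tz = "UTC",
                                     format = "%Y-%m-%dT%H:%M:%SZ")

#' Read detection records written by the pipeline
#' @param path CSV of detection records with ISO-8601 UTC timestamps.
#' @return data.frame with parsed \code{timestamp}.
#' @export
readDetections <- function(path) {
    d <- read.csv(path)
    d$timestamp <- .parseTime(d$timestamp)
    d
}

.logLine <- function(con, ...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, con)
    message(msg)
}

## raw detections + metadata (+ covariates) -> preprocessed tables
.preprocessStage <- function(detections, metadata, config) {
    rules <- config$rules
    flights <- identifyFlights(detections,
                               minDistanceKm = rules$minDistanceKm,
                               minReceivers = rules$minReceivers,
                               maxSpanHours = rules$maxSpanHours)
    if (nrow(flights))
        flights$route <- classifyRoute(flights, rules$lonThreshold,
                                       rules$latThreshold,
                                       rules$offshoreStationIds)
    ## departure scoring from stopover-site records (receivers within the
    ## stopover radius of the deployment location)
    individuals <- do.call(rbind, lapply(seq_len(nrow(metadata)),
                                         function(i) {
        m <- metadata[i, ]
        r <- detections[detections$tag_id == m$tag_id, , drop = FALSE]
        dist <- geosphere::distHaversine(
            cbind(r$receiver_lon, r$receiver_lat),
            c(m$deploy_lon, m$deploy_lat)) / 1000
        dep <- detectDeparture(r[dist <= rules$stopoverRadiusKm, ,
                                 drop = FALSE])
        data.frame(tag_id = m$tag_id, species = m$species,
                   tag_type = m$tag_type,
                   distance_group = m$distance_group,
                   deploy_time = m$deploy_time,
                   departure_time = dep$time)
    }))
    excl <- applyExclusions(individuals, flights,
                            maxStopoverDays = rules$maxStopoverDays,
                            morningSpecies = rules$morningSpecies,
                            shortFlightKm = rules$minDistanceKm)
    kept <- excl$individuals
    kept$route <- excl$flights$route[match(kept$tag_id,
                                           excl$flights$tag_id)]
    codes <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i)
        buildEncounterHistory(kept$deploy_time[i],
                              kept$departure_time[i],
                              kept$route[i], T = config$model$T)))
    list(individuals = kept, flights = excl$flights, log = excl$log,
         codes = codes)
}

## preprocessed individuals + covariate table -> EncounterHistories
.assembleHistories <- function(individuals, codes, covariates, metadata,
                               T) {
    idx <- match(individuals$tag_id, metadata$tag_id)
    cm <- .covariateMatrices(covariates, max(covariates$individual), T)
    rows <- idx  # covariate rows are in deployment order
    EncounterHistories(codes,
                       species = individuals$species,
                       tagType = individuals$tag_type,
                       distanceGroup = individuals$distance_group,
                       tagId = individuals$tag_id,
                       covariates = lapply(cm, function(m)
                           m[rows, , drop = FALSE]))
}

#' Run the analysis pipeline
#'
#' Stages: \code{"simulate"} writes a synthetic study bundle;
#' \code{"preprocess"} turns raw detections into flights, an exclusion log
#' and encounter histories; \code{"fit"} samples the multistate model
#' posterior; \code{"summarize"} writes departure/routing summaries,
#' distance contrasts, the detection-corrected offshore count, and the two
#' auxiliary regressions; \code{"ppc"} writes posterior-predictive check
#' statistics; \code{"all"} chains every stage. Each stage writes its
#' outputs and a run log (configuration echo, seed, in/out counts per
#' filter) under \code{config$paths$outDir}.
#'
#' @param command one of \code{"simulate"}, \code{"preprocess"},
#'   \code{"fit"}, \code{"summarize"}, \code{"ppc"}, \code{"all"}.
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param overrides optional list merged over \code{config} (highest
#'   precedence).
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(command = c("all", "simulate", "preprocess",
                                    "fit", "summarize", "ppc"),
                        config = defaultPipelineConfig(),
                        overrides = NULL) {
    command <- match.arg(command)
    if (!is.null(overrides)) config <- .mergeConfig(config, overrides)
    out <- config$paths$outDir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    logFile <- file(file.path(out, "run.log"), open = "at")
    on.exit(close(logFile))
    .logLine(logFile, "command=", command, " seed=", config$model$seed)
    writeLines(yaml::as.yaml(config), file.path(out, "config_echo.yaml"))
    res <- list(config = config)

    ## later stages pull their prerequisites (re-reading stage files where
    ## a previous in-memory result is absent)
    stages <- switch(command,
                     all = c("simulate", "preprocess", "fit", "summarize",
                             "ppc"),
                     simulate = "simulate",
                     preprocess = "preprocess",
                     fit = c("preprocess", "fit"),
                     summarize = c("preprocess", "fit", "summarize"),
                     ppc = c("preprocess", "fit", "ppc"))

    if ("simulate" %in% stages) {
        study <- simulateStudy(nOccasions = config$model$T,
                               seed = config$simulate$seed,
                               dropoutProb = config$simulate$dropoutProb)
        writeStudy(study, out)
        res$study <- study
        .logLine(logFile, "simulate: ", nrow(study$metadata), " tagged, ",
                 sum(study$metadata$determined), " determined, ",
                 nrow(study$detections), " detection records")
    }
    if ("preprocess" %in% stages) {
        detections <- res$study$detections %||%
            readDetections(file.path(out, "detections.csv"))
        metadata <- res$study$metadata %||% {
            m <- read.csv(file.path(out, "metadata.csv"))
            m$deploy_time <- .parseTime(m$deploy_time)
            m
        }
        covariates <- res$study$covariates %||%
            read.csv(file.path(out, "covariates.csv"))
        pp <- .preprocessStage(detections, metadata, config)
        eh <- .assembleHistories(pp$individuals, pp$codes, covariates,
                                 metadata, config$model$T)
        write.csv(pp$log, file.path(out, "exclusions.csv"),
                  row.names = FALSE)
        fl <- pp$flights
        for (cn in names(fl))
            if (inherits(fl[[cn]], "POSIXct")) fl[[cn]] <- .fmtTime(fl[[cn]])
        write.csv(fl, file.path(out, "flights_processed.csv"),
                  row.names = FALSE)
        write.csv(summarizeFlights(cbind(pp$flights,
                      species = pp$individuals$species[
                          match(pp$flights$tag_id,
                                pp$individuals$tag_id)])),
                  file.path(out, "flight_summary.csv"), row.names = FALSE)
        res$preprocessed <- pp
        res$histories <- eh
        .logLine(logFile, "preprocess: ", nrow(metadata), " in -> ",
                 nrow(pp$individuals), " modeled individuals, ",
                 nrow(pp$flights), " flights, ",
                 sum(pp$log$scope == "individual"),
                 " individual exclusions (accounting: ",
                 nrow(pp$individuals) +
                     sum(pp$log$scope == "individual"), " = ",
                 nrow(metadata), ")")
    }
    if ("fit" %in% stages) {
        eh <- poolSpecies(res$histories, config$pooling)
        post <- samplePosterior(eh,
                                priors = msPriors(config$model$interceptSd,
                                                  config$model$slopeSd),
                                nChains = config$model$chains,
                                nIter = config$model$iterations,
                                nWarmup = config$model$warmup,
                                seed = config$model$seed)
        m <- posteriorMatrix(post)
        drawsOut <- data.frame(
            chain = rep(seq_len(nChains(post)),
                        each = nIterations(post)),
            iteration = rep(seq_len(nIterations(post)), nChains(post)),
            m)
        names(drawsOut)[-(1:2)] <- colnames(m)
        write.csv(drawsOut, file.path(out, "draws.csv"),
                  row.names = FALSE)
        write.csv(post@diagnostics, file.path(out, "diagnostics.csv"),
                  row.names = FALSE)
        res$posterior <- post
        res$pooledHistories <- eh
        .logLine(logFile, "fit: ", nrow(eh), " histories, max Rhat ",
                 round(max(post@diagnostics$rhat, na.rm = TRUE), 3))
    }
    if ("summarize" %in% stages) {
        post <- res$posterior
        mass <- config$summary$hpdiMass
        dep <- speciesMeanDeparture(post, mass = mass)
        rou <- speciesMeanRouting(post, mass = mass)
        contr <- rbind(distanceContrast(post, "departure", mass = mass),
                       distanceContrast(post, "routing", mass = mass))
        attr(contr, "draws") <- NULL
        routes <- attributeUnknownRoutes(post, mass = mass,
                                         seed = config$model$seed)
        tabs <- list(departure_summary = dep, routing_summary = rou,
                     distance_contrasts = contr,
                     offshore_attribution = routes$summary)
        if (!is.null(res$study)) {
            ## pool the same small-sample species as in the state model
            poolMap <- function(df) {
                sp <- as.character(df$species)
                for (lab in names(config$pooling))
                    sp[sp %in% config$pooling[[lab]]] <- lab
                df$species <- factor(sp)
                df
            }
            so <- fitStopoverModel(poolMap(res$study$stopoverObs),
                                   seed = config$model$seed)
            dt <- fitDepartureTimeModel(
                poolMap(res$study$departureTimeObs),
                seed = config$model$seed)
            tabs$stopover_summary <- so$summary
            tabs$departure_time_summary <- dt$summary
            res$stopoverFit <- so
            res$departureTimeFit <- dt
        }
        for (nm in names(tabs)) {
            tb <- tabs[[nm]]
            attr(tb, "draws") <- NULL
            write.csv(tb, file.path(out, paste0(nm, ".csv")),
                      row.names = FALSE)
        }
        res$summaries <- tabs
        res$routeAttribution <- routes
        .logLine(logFile, "summarize: offshore count mean ",
                 round(routes$summary$mean[1L], 1), " of ",
                 routes$observed[["modeled"]], " modeled")
    }
    if ("ppc" %in% stages) {
        ppc <- posteriorPredictiveCheck(res$posterior,
                                        res$pooledHistories,
                                        nDraws = config$summary$ppcDraws,
                                        seed = config$model$seed)
        write.csv(data.frame(stat = names(ppc$observed),
                             observed = ppc$observed,
                             q025 = ppc$quantiles[1L, ],
                             q50 = ppc$quantiles[2L, ],
                             q975 = ppc$quantiles[3L, ],
                             inside = ppc$inside),
                  file.path(out, "ppc.csv"), row.names = FALSE)
        res$ppc <- ppc
        .logLine(logFile, "ppc: ", sum(ppc$inside), "/",
                 length(ppc$inside), " statistics inside 95% interval")
    }
    invisible(res)
}
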