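#' Weakly informative prior settings for the multistate model
#'
#' Normal(0, \code{interceptSd}) on logit-scale intercepts, Normal(0,
#' \code{slopeSd}) on slopes. The detection probabilities get a Uniform(0,1)
#' prior on the higher (ACT) probability, with the lower (NTQB) probability
#' expressed as the higher times an independent Uniform(0,1) fraction, which
#' encodes the tag-power ordering in every draw.
#'
#' @param interceptSd,slopeSd prior standard deviations (logit scale).
#' @return list of class \code{"msPriors"}.
#' @export
msPriors <- function(interceptSd = 1.5, slopeSd = 1) {
    stopifnot(interceptSd > 0, slopeSd > 0)
    structure(list(interceptSd = interceptSd, slopeSd = slopeSd),
              class = "msPriors")
}

## log prior density on the unconstrained parameter vector
.msLogPrior <- function(v, S, priors) {
    isIntercept <- c(seq_len(S),                       # b0_psi
                     7 * S + 1 + seq_len(S))           # b0_chi
    betas <- seq_len(8 * S + 5)
    slopes <- setdiff(betas, isIntercept)
    qs <- 8 * S + 5 + seq_len(4)
    sum(dnorm(v[isIntercept], 0, priors$interceptSd, log = TRUE)) +
        sum(dnorm(v[slopes], 0, priors$slopeSd, log = TRUE)) +
        sum(dlogis(v[qs], log = TRUE))  # Uniform(0,1) on each probability
}

#' Sample the posterior of the multistate departure/routing model
#'
#' Fits the four-state hidden Markov model by adaptive random-walk
#' Metropolis over the exact marginal forward log-likelihood (latent states
#' integrated out in C++) plus the weakly informative priors. The detection
#' ordering (ACT >= NTQB) holds in every draw by construction. Runs are
#' deterministic given \code{seed}.
#'
#' @param eh an \linkS4class{EncounterHistories} with covariate assays.
#' @param priors an \code{\link{msPriors}} object.
#' @param nChains,nIter,nWarmup run configuration (defaults: 4 chains of
#'   2000 iterations including 1000 adaptation steps).
#' @param seed integer seed.
#' @param priorOnly drop the likelihood (prior-recovery runs).
#' @param initJitter sd of the per-chain jitter on the starting point.
#' @return a \linkS4class{MultistatePosterior}; draws store detection
#'   probabilities on the probability scale. A warning is issued when any
#'   split-Rhat exceeds 1.05.
#' @export
samplePosterior <- function(eh, priors = msPriors(), nChains = 4,
                            nIter = 2000, nWarmup = 1000, seed = 1,
                            priorOnly = FALSE, initJitter = 2) {
    if (nrow(eh) < 1L) stop("need at least one encounter history")
    md <- msModelData(eh)
    S <- length(md$speciesLevels)
    init <- setNames(numeric(8 * S + 9), msParamNames(md$speciesLevels))
    logPost <- if (priorOnly)
        function(v) .msLogPrior(v, S, priors)
    else
        function(v) cpp_ms_loglik(v, md$data) + .msLogPrior(v, S, priors)
    ## posterior mode + curvature seed the proposal and the chain starts
    lap <- laplaceInit(logPost, init)
    fit <- sampleMetropolis(logPost, lap$par, nChains = nChains,
                            nIter = nIter, nWarmup = nWarmup, seed = seed,
                            initJitter = initJitter, initCov = lap$cov)
    ## transform detection parameters to the probability scale for storage
    keep <- dim(fit$draws)[1L]
    flat <- matrix(fit$draws, keep * nChains, 8 * S + 9)
    con <- constrainDraws(flat, md$speciesLevels)
    draws <- array(con, c(keep, nChains, ncol(con)),
                   dimnames = list(NULL, NULL, colnames(con)))
    ## species -> distance-group mapping (if recorded)
    dg <- tapply(as.character(distanceGroups(eh)),
                 as.character(speciesLabels(eh)),
                 function(x) x[1L])[md$speciesLevels]
    post <- new("MultistatePosterior", draws = draws,
                diagnostics = data.frame(),
                modelInfo = list(md = md, seed = seed,
                                 accept = fit$accept,
                                 priors = priors,
                                 speciesDistance = dg,
                                 nWarmup = nWarmup, nIter = nIter))
    post@diagnostics <- mcmcDiagnostics(post)
    bad <- post@diagnostics$rhat > 1.05
    if (any(bad, na.rm = TRUE))
        warning("possible non-convergence: split-Rhat > 1.05 for ",
                paste(post@diagnostics$param[which(bad)], collapse = ", "))
    post
}

## per-species observed summary statistics from a codes matrix
.ppcStats <- function(codes, species) {
    lv <- levels(species)
    stats <- c()
    for (sp in lv) {
        cd <- codes[species == sp, , drop = FALSE]
        offs <- sum(apply(cd == .CODE_OFFSHORE, 1L, any))
        ons <- sum(apply(cd == .CODE_ONSHORE, 1L, any))
        dep <- sum(apply(cd != .CODE_STOPOVER, 1L, any))
        stats <- c(stats, setNames(c(offs, ons, dep - offs - ons),
                                   paste0(c("offshore.", "onshore.",
                                            "unseen."), sp)))
    }
    stats
}

#' Graphical posterior predictive check statistics
#'
#' For a thinned subset of posterior draws, simulates replicated encounter
#' histories from the fitted model on the observed covariates and returns,
#' per species, the count of detected offshore flights, detected onshore
#' flights and undetected departures, together with the observed values and
#' replicate quantiles.
#'
#' @param post a \linkS4class{MultistatePosterior} from
#'   \code{\link{samplePosterior}}.
#' @param eh the fitted \linkS4class{EncounterHistories}.
#' @param nDraws number of posterior draws to replicate under.
#' @param seed integer seed for the replicate simulations.
#' @return list with \code{observed} (named vector), \code{replicates}
#'   (draws x statistics matrix), \code{quantiles} (2.5/50/97.5\% of the
#'   replicates) and \code{inside} (is each observed statistic inside the
#'   central 95\% replicate interval).
#' @export
posteriorPredictiveCheck <- function(post, eh, nDraws = 100, seed = 1) {
    md <- post@modelInfo$md
    species <- factor(md$speciesLevels[md$data$species + 1L],
                      levels = md$speciesLevels)
    observed <- .ppcStats(md$data$codes, species)
    m <- posteriorMatrix(post)
    idx <- unique(round(seq(1L, nrow(m), length.out = nDraws)))
    reps <- withSeed(seed, {
        t(vapply(idx, function(i) {
            params <- constrainedToParams(m[i, ], md$speciesLevels)
            lp <- linearPredictors(md, params)
            y <- .simulateProcess(lp$psi, lp$chi, lp$pX, lp$pC)$y
            .ppcStats(y, species)
        }, observed))
    })
    qs <- apply(reps, 2L, quantile, probs = c(0.025, 0.5, 0.975))
    inside <- observed >= qs[1L, ] & observed <= qs[3L, ]
    list(observed = observed, replicates = reps, quantiles = qs,
         inside = inside)
}
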