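## Auxiliary Bayesian regressions for the birds with known routing:
## minimum stopover duration (negative binomial, log link) and departure
## time relative to night length (Student-t), both with species + route +
## interaction structure, fitted with the same adaptive Metropolis engine
## as the multistate model.

.checkGroups <- function(obs) {
    obs$species <- droplevels(factor(obs$species))
    obs$route <- droplevels(factor(obs$route,
                                   levels = c("offshore", "onshore")))
    if (nlevels(obs$route) < 2L)
        stop("both routes must be present")
    obs
}

## design matrix and the species x route cell rows used for group means
.cellDesign <- function(obs) {
    X <- model.matrix(~ species * route, obs)
    cells <- expand.grid(species = levels(obs$species),
                         route = levels(obs$route))
    Xc <- model.matrix(~ species * route, cells)
    list(X = X, cells = cells, Xc = Xc)
}

#' Bayesian negative-binomial model of minimum stopover duration
#'
#' Log-mean linear in species, route and their interaction; a dispersion
#' parameter phi absorbs overdispersion (variance mu + mu^2 / phi). Priors:
#' Normal(0, 1.5) on the intercept, Normal(0, 1) on the other coefficients,
#' Normal(0, 1.5) on log phi. Reports posterior means of the fitted cell
#' means averaged over species within each migration-distance group, and
#' the short - long contrast, with HPDIs.
#'
#' @param obs data.frame with columns \code{duration} (non-negative
#'   integer days), \code{species}, \code{route} (\code{"offshore"} /
#'   \code{"onshore"}) and \code{distance_group} (\code{"short"} /
#'   \code{"long"}).
#' @param nChains,nIter,nWarmup,seed sampler configuration.
#' @param mass HPDI mass.
#' @return list with \code{draws} (array), \code{diagnostics},
#'   \code{summary} (group means and the short - long contrast),
#'   \code{cellMeans} (per-draw species x route means) and
#'   \code{contrastDraws}.
#' @export
fitStopoverModel <- function(obs, nChains = 4, nIter = 2000,
                             nWarmup = 1000, seed = 1, mass = 0.90) {
    if (any(obs$duration < 0) || any(obs$duration != round(obs$duration)))
        stop("durations must be non-negative integers")
    obs <- .checkGroups(obs)
    if (nlevels(obs$species) < 2L) stop("need at least 2 species")
    dd <- .cellDesign(obs)
    p <- ncol(dd$X)
    y <- obs$duration
    logPost <- function(v) {
        beta <- v[seq_len(p)]
        phi <- exp(v[p + 1L])
        mu <- exp(drop(dd$X %*% beta))
        sum(dnbinom(y, size = phi, mu = mu, log = TRUE)) +
            dnorm(beta[1L], 0, 1.5, log = TRUE) +
            sum(dnorm(beta[-1L], 0, 1, log = TRUE)) +
            dnorm(v[p + 1L], 0, 1.5, log = TRUE)
    }
    init <- setNames(c(log(mean(y) + 0.5), numeric(p - 1L), 0),
                     c(colnames(dd$X), "log_phi"))
    lap <- laplaceInit(logPost, init)
    fit <- sampleMetropolis(logPost, setNames(lap$par, names(init)),
                            nChains = nChains, nIter = nIter,
                            nWarmup = nWarmup, seed = seed,
                            initJitter = 2, initCov = lap$cov)
    diag <- mcmcDiagnostics(fit$draws)
    m <- matrix(fit$draws, prod(dim(fit$draws)[1:2]), p + 1L)
    cellMeans <- exp(m[, seq_len(p)] %*% t(dd$Xc))
    colnames(cellMeans) <- paste(dd$cells$species, dd$cells$route,
                                 sep = ".")
    spDist <- tapply(as.character(obs$distance_group),
                     as.character(obs$species), function(x) x[1L])
    grp <- spDist[as.character(dd$cells$species)]
    shortMean <- rowMeans(cellMeans[, grp == "short", drop = FALSE])
    longMean <- rowMeans(cellMeans[, grp == "long", drop = FALSE])
    contrast <- shortMean - longMean
    summary <- rbind(.summaryRow("short_mean_days", shortMean, mass),
                     .summaryRow("long_mean_days", longMean, mass),
                     .summaryRow("short_minus_long_days", contrast, mass),
                     .summaryRow("dispersion_phi", exp(m[, p + 1L]), mass))
    list(draws = fit$draws, diagnostics = diag, summary = summary,
         cellMeans = cellMeans, contrastDraws = contrast)
}

#' Bayesian Student-t model of relative departure time
#'
#' Location linear in species, route and their interaction; scale sigma
#' and degrees of freedom nu are estimated (nu = 1 + a Gamma(2, 0.1)
#' variable a priori, keeping the likelihood heavy-tailed but proper).
#' Reports the onshore - offshore location contrast averaged over species,
#' with its HPDI.
#'
#' @param obs data.frame with columns \code{rel_time} (departure time as a
#'   fraction of night length), \code{species} and \code{route}.
#' @param nChains,nIter,nWarmup,seed sampler configuration.
#' @param mass HPDI mass.
#' @return list with \code{draws}, \code{diagnostics}, \code{summary}
#'   (the route contrast plus sigma and nu), \code{contrastDraws} and
#'   \code{cellMeans}.
#' @export
fitDepartureTimeModel <- function(obs, nChains = 4, nIter = 2000,
                                  nWarmup = 1000, seed = 1, mass = 0.90) {
    obs <- .checkGroups(obs)
    dd <- .cellDesign(obs)
    p <- ncol(dd$X)
    y <- obs$rel_time
    logPost <- function(v) {
        beta <- v[seq_len(p)]
        sigma <- exp(v[p + 1L])
        nu <- 1 + exp(v[p + 2L])
        mu <- drop(dd$X %*% beta)
        sum(stats::dt((y - mu) / sigma, df = nu, log = TRUE)) -
            length(y) * log(sigma) +
            dnorm(beta[1L], 0, 1.5, log = TRUE) +
            sum(dnorm(beta[-1L], 0, 1, log = TRUE)) +
            ## sigma ~ half-Normal(0,1), nu - 1 ~ Gamma(2, 0.1); both with
            ## log-transform Jacobians
            dnorm(sigma, 0, 1, log = TRUE) + log(2) + v[p + 1L] +
            dgamma(nu - 1, 2, rate = 0.1, log = TRUE) + v[p + 2L]
    }
    init <- setNames(c(mean(y), numeric(p - 1L), log(sd(y) + 1e-3),
                       log(9)),
                     c(colnames(dd$X), "log_sigma", "log_num1"))
    lap <- laplaceInit(logPost, init)
    fit <- sampleMetropolis(logPost, setNames(lap$par, names(init)),
                            nChains = nChains, nIter = nIter,
                            nWarmup = nWarmup, seed = seed,
                            initJitter = 2, initCov = lap$cov)
    diag <- mcmcDiagnostics(fit$draws)
    m <- matrix(fit$draws, prod(dim(fit$draws)[1:2]), p + 2L)
    cellMeans <- m[, seq_len(p)] %*% t(dd$Xc)
    colnames(cellMeans) <- paste(dd$cells$species, dd$cells$route,
                                 sep = ".")
    on <- rowMeans(cellMeans[, dd$cells$route == "onshore",
                             drop = FALSE])
    off <- rowMeans(cellMeans[, dd$cells$route == "offshore",
                              drop = FALSE])
    contrast <- on - off
    summary <- rbind(
        .summaryRow("onshore_minus_offshore", contrast, mass),
        .summaryRow("sigma", exp(m[, p + 1L]), mass),
        .summaryRow("nu", 1 + exp(m[, p + 2L]), mass))
    list(draws = fit$draws, diagnostics = diag, summary = summary,
         contrastDraws = contrast, cellMeans = cellMeans)
}
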