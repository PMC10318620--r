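#' Highest posterior density interval (shortest window)
#'
#' The shortest contiguous interval containing \code{ceiling(mass * n)}
#' sorted samples; ties are broken toward the lowest-start window. Never
#' wider than the equal-tailed interval at the same mass.
#'
#' @param samples numeric draw vector (at least 20 values).
#' @param mass interval mass in (0, 1); default 0.90.
#' @return named numeric \code{c(lower, upper)}.
#' @examples
#' hpdi(1:100, 0.9)  # width 89, lowest-start window
#' @export
hpdi <- function(samples, mass = 0.90) {
    if (length(samples) < 20L)
        stop("need at least 20 samples for an HPDI")
    if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
    x <- sort(samples)
    n <- length(x)
    m <- ceiling(mass * n)
    starts <- seq_len(n - m + 1L)
    widths <- x[starts + m - 1L] - x[starts]
    i <- which.min(widths)  # first minimum = lowest start
    c(lower = x[i], upper = x[i + m - 1L])
}

.summaryRow <- function(name, draws, mass = 0.90) {
    iv <- hpdi(draws, mass)
    flag <- !(iv[["lower"]] <= mean(draws) && mean(draws) <= iv[["upper"]])
    data.frame(quantity = name, mean = mean(draws),
               hpdi_lower = iv[["lower"]], hpdi_upper = iv[["upper"]],
               mass = mass, flagged = flag)
}

## per-draw per-species mean psi (or chi) over the species' modeled
## individual-occasions; returns draws x species matrix plus the overall
## unweighted (or occasion-weighted) species mean
.speciesMeanDraws <- function(post, what = c("departure", "routing"),
                              weighted = FALSE, nDraws = Inf) {
    what <- match.arg(what)
    md <- post@modelInfo$md
    m <- posteriorMatrix(post)
    idx <- unique(round(seq(1L, nrow(m), length.out = min(nrow(m),
                                                          nDraws))))
    sp <- md$data$species + 1L
    S <- length(md$speciesLevels)
    rows <- lapply(seq_len(S), function(s) which(sp == s))
    out <- matrix(NA_real_, length(idx), S,
                  dimnames = list(NULL, md$speciesLevels))
    for (k in seq_along(idx)) {
        params <- constrainedToParams(m[idx[k], ], md$speciesLevels)
        lp <- linearPredictors(md, params)
        p <- if (what == "departure") lp$psi else lp$chi
        out[k, ] <- vapply(rows, function(rr)
            mean(p[rr, , drop = FALSE]), numeric(1))
    }
    overall <- if (weighted) {
        w <- vapply(rows, length, 0L)
        drop(out %*% (w / sum(w)))
    } else rowMeans(out)
    list(species = out, overall = overall)
}

#' Posterior species mean departure probability
#'
#' For each posterior draw, averages the day-to-day departure probability
#' psi over each species' modeled individual-occasions; the overall mean is
#' the unweighted mean across species (set \code{weighted = TRUE} to weight
#' by each species' number of individual-occasions). Summaries are
#' posterior means with 90\% HPDIs.
#'
#' @param post a \linkS4class{MultistatePosterior}.
#' @param weighted weight species by their individual-occasion counts.
#' @param mass HPDI mass.
#' @param nDraws optional thinning of the posterior draws.
#' @return data.frame (one row per species plus \code{"overall"}) with the
#'   per-draw values attached as attribute \code{"draws"}.
#' @export
speciesMeanDeparture <- function(post, weighted = FALSE, mass = 0.90,
                                 nDraws = Inf) {
    d <- .speciesMeanDraws(post, "departure", weighted, nDraws)
    out <- do.call(rbind, c(
        lapply(colnames(d$species), function(s)
            .summaryRow(s, d$species[, s], mass)),
        list(.summaryRow("overall", d$overall, mass))))
    attr(out, "draws") <- cbind(d$species, overall = d$overall)
    out
}

#' Posterior species mean offshore routing probability
#'
#' As \code{\link{speciesMeanDeparture}} but for the offshore routing
#' probability chi.
#'
#' @inheritParams speciesMeanDeparture
#' @return data.frame with attribute \code{"draws"}.
#' @export
speciesMeanRouting <- function(post, weighted = FALSE, mass = 0.90,
                               nDraws = Inf) {
    d <- .speciesMeanDraws(post, "routing", weighted, nDraws)
    out <- do.call(rbind, c(
        lapply(colnames(d$species), function(s)
            .summaryRow(s, d$species[, s], mass)),
        list(.summaryRow("overall", d$overall, mass))))
    attr(out, "draws") <- cbind(d$species, overall = d$overall)
    out
}

#' Long- minus short-distance migrant contrast
#'
#' Per posterior draw, the difference between the mean of the long-distance
#' species' means and the mean of the short-distance species' means, for
#' either the departure probability psi or the routing probability chi.
#'
#' @param post a \linkS4class{MultistatePosterior} fitted to histories
#'   whose \code{distance_group} metadata was set, or supply
#'   \code{grouping} explicitly.
#' @param what \code{"departure"} or \code{"routing"}.
#' @param grouping optional named character vector mapping species to
#'   \code{"short"}/\code{"long"}.
#' @param mass HPDI mass.
#' @param nDraws optional thinning.
#' @return one-row data.frame with the per-draw contrast attached as
#'   attribute \code{"draws"}.
#' @export
distanceContrast <- function(post, what = c("departure", "routing"),
                             grouping = NULL, mass = 0.90, nDraws = Inf) {
    what <- match.arg(what)
    if (is.null(grouping)) grouping <- post@modelInfo$speciesDistance
    d <- .speciesMeanDraws(post, what, nDraws = nDraws)
    g <- grouping[colnames(d$species)]
    if (!any(g == "long", na.rm = TRUE) ||
        !any(g == "short", na.rm = TRUE))
        stop("both distance groups must be non-empty")
    contrast <- rowMeans(d$species[, which(g == "long"), drop = FALSE]) -
        rowMeans(d$species[, which(g == "short"), drop = FALSE])
    out <- .summaryRow(paste0(what, "_long_minus_short"), contrast, mass)
    attr(out, "draws") <- contrast
    out
}

#' Probability that an undetected departure was an offshore flight
#'
#' Closed form from the observation model: an undetected flight is offshore
#' with probability \code{chi (1 - pX) / (chi (1 - pX) + (1 - chi)
#' (1 - pC))}. Reduces to \code{chi} when \code{pX == pC} and to 0 when
#' \code{pX == 1}.
#'
#' @param chi offshore routing probability.
#' @param pX,pC detection probabilities for offshore and onshore flights.
#' @return probability, vectorized over the inputs.
#' @export
routeAttributionProbability <- function(chi, pX, pC) {
    num <- chi * (1 - pX)
    den <- num + (1 - chi) * (1 - pC)
    ifelse(den == 0, 0, num / den)
}

#' Detection-corrected posterior offshore flight count and proportion
#'
#' Individuals observed offshore/onshore keep their route. For every
#' route-unknown departure, each posterior draw assigns an offshore route
#' with the closed-form attribution probability evaluated at that
#' individual's departure-night covariates and tag type; by default the
#' route is resampled per draw (full posterior propagation), with the
#' plug-in expectation also reported. Histories without any departure are
#' excluded with a warning.
#'
#' @param post a \linkS4class{MultistatePosterior}.
#' @param mass HPDI mass.
#' @param seed integer seed for the per-draw route resampling.
#' @return list with \code{summary} (posterior mean and HPDI of the total
#'   offshore count and the offshore proportion, sampled and expected
#'   versions), \code{draws} (per-draw counts), \code{observed}
#'   (offshore/onshore/unknown tallies).
#' @export
attributeUnknownRoutes <- function(post, mass = 0.90, seed = 1) {
    md <- post@modelInfo$md
    codes <- md$data$codes
    n <- nrow(codes)
    depOcc <- apply(codes, 1L, function(x) {
        w <- which(x != .CODE_STOPOVER)
        if (length(w)) w[1L] else NA_integer_
    })
    if (anyNA(depOcc)) {
        warning(sum(is.na(depOcc)),
                " histories without a departure excluded from route",
                " attribution")
    }
    use <- which(!is.na(depOcc))
    routeCode <- codes[cbind(use, depOcc[use])]
    nOff <- sum(routeCode == .CODE_OFFSHORE)
    nOn <- sum(routeCode == .CODE_ONSHORE)
    unk <- use[routeCode == .CODE_NOTSEEN]
    N <- length(use)
    m <- posteriorMatrix(post)
    counts <- matrix(NA_real_, nrow(m), 2,
                     dimnames = list(NULL, c("sampled", "expected")))
    withSeed(seed, {
        for (k in seq_len(nrow(m))) {
            params <- constrainedToParams(m[k, ], md$speciesLevels)
            lp <- linearPredictors(md, params)
            ## the departure decision at occasion d is driven by the
            ## sunset covariates of the preceding day (transition d-1 -> d)
            pOff <- routeAttributionProbability(
                lp$chi[cbind(unk, depOcc[unk] - 1L)],
                lp$pX[unk], lp$pC[unk])
            counts[k, "sampled"] <- nOff + sum(runif(length(unk)) < pOff)
            counts[k, "expected"] <- nOff + sum(pOff)
        }
    })
    summary <- rbind(
        .summaryRow("offshore_count", counts[, "sampled"], mass),
        .summaryRow("offshore_count_expected", counts[, "expected"], mass),
        .summaryRow("offshore_proportion", counts[, "sampled"] / N, mass),
        .summaryRow("offshore_proportion_expected",
                    counts[, "expected"] / N, mass))
    list(summary = summary, draws = counts,
         observed = c(offshore = nOff, onshore = nOn,
                      unknown = length(unk), modeled = N))
}
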