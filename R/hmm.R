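## The four-state model. Latent states: 1 stopover, 2 offshore flight,
## 3 onshore flight, 4 departed. Per transition the state matrix is
##   Omega = | 1-psi  psi*chi  psi*(1-chi)  0 |
##           |   0      0          0       1 |
##           |   0      0          0       1 |
##           |   0      0          0       1 |
## and the observation matrix (codes 1 stopover, 2 offshore, 3 onshore,
## 4 not seen) is
##   Theta = | 1   0    0     0    |
##           | 0   pX   0   1-pX   |
##           | 0   0    pC  1-pC   |
##           | 0   0    0     1    |
## psi is the day-to-day departure probability, chi the probability that a
## departure is an offshore flight, pX/pC the route-specific detection
## probabilities.

.STATE_NAMES <- c("stopover", "offshore", "onshore", "departed")
.OBS_NAMES <- c("stopover", "offshore", "onshore", "not_seen")

#' Day-to-day departure probability psi
#'
#' Inverse-logit of the departure linear predictor: a species intercept,
#' species-specific orthogonal linear/quadratic terms in both wind
#' components, species-specific pressure-change and humidity slopes, and a
#' rain slope shared across species.
#'
#' @param params a \linkS4class{MultistateParams}.
#' @param species species index (row of \code{betaPsi}) or label.
#' @param ul,uq orthogonal linear/quadratic eastward-wind basis values.
#' @param vl,vq same for the northward wind component.
#' @param dp standardized 24-h pressure change.
#' @param h standardized relative humidity.
#' @param r binary rain indicator.
#' @return psi in (0, 1); vectorized over the covariate arguments.
#' @examples
#' p <- MultistateParams(matrix(0, 1, 7))
#' departureProbability(p, 1, 0, 0, 0, 0, 0, 0, 0)  # 0.5
#' @export
departureProbability <- function(params, species, ul, uq, vl, vq, dp, h, r) {
    b <- params@betaPsi[species, , drop = FALSE]
    plogis(b[, "b0"] + b[, "ul"] * ul + b[, "uq"] * uq + b[, "vl"] * vl +
           b[, "vq"] * vq + b[, "dp"] * dp + b[, "h"] * h +
           params@betaRain * r)
}

#' Offshore routing probability chi
#'
#' Inverse-logit of the routing linear predictor: a species intercept plus
#' wind slopes shared across species (no pressure, humidity or rain terms).
#'
#' @inheritParams departureProbability
#' @return chi in (0, 1); vectorized over the covariate arguments.
#' @export
routingProbability <- function(params, species, ul, uq, vl, vq) {
    b <- params@betaChi
    drop(plogis(params@beta0Chi[species] + b[["ul"]] * ul +
                b[["uq"]] * uq + b[["vl"]] * vl + b[["vq"]] * vq))
}

#' State-transition matrix of the four-state model
#'
#' @param psi day-to-day departure probability.
#' @param chi probability that a departure is an offshore flight.
#' @return 4 x 4 row-stochastic matrix over (stopover, offshore, onshore,
#'   departed).
#' @examples
#' transitionMatrix(0.5, 0.4)[1, ]  # 0.5 0.2 0.3 0
#' @export
transitionMatrix <- function(psi, chi) {
    if (psi < 0 || psi > 1 || chi < 0 || chi > 1)
        stop("psi and chi must lie in [0, 1]")
    m <- rbind(c(1 - psi, psi * chi, psi * (1 - chi), 0),
               c(0, 0, 0, 1),
               c(0, 0, 0, 1),
               c(0, 0, 0, 1))
    dimnames(m) <- list(.STATE_NAMES, .STATE_NAMES)
    m
}

#' Observation matrix of the four-state model
#'
#' @param pX offshore detection probability.
#' @param pC onshore detection probability.
#' @return 4 x 4 row-stochastic matrix mapping latent states to observation
#'   codes (stopover, offshore, onshore, not seen).
#' @export
observationMatrix <- function(pX, pC) {
    if (pX < 0 || pX > 1 || pC < 0 || pC > 1)
        stop("detection probabilities must lie in [0, 1]")
    m <- rbind(c(1, 0, 0, 0),
               c(0, pX, 0, 1 - pX),
               c(0, 0, pC, 1 - pC),
               c(0, 0, 0, 1))
    dimnames(m) <- list(.STATE_NAMES, .OBS_NAMES)
    m
}

#' Exact marginal log-likelihood of encounter histories (forward algorithm)
#'
#' Marginalizes the latent state sequence by the forward recursion in log
#' space, conditioning on every bird starting in the stopover state. Returns
#' the per-individual log-probability of the observations from occasion 2
#' onward; \code{-Inf} (with a warning) marks a history impossible under the
#' supplied probabilities.
#'
#' @param codes integer matrix (individuals x occasions) or a single
#'   history vector, values in 1..4, first occasion 1.
#' @param psi,chi matrices (or vectors for one individual) of departure and
#'   routing probabilities for transitions 1..T-1.
#' @param pX,pC per-individual detection probabilities (recycled if scalar).
#' @return numeric vector of per-individual log-likelihoods.
#' @examples
#' forwardLogLik(c(1, 1), psi = 0.3, chi = 0.5, pX = 1, pC = 1)  # log(0.7)
#' @export
forwardLogLik <- function(codes, psi, chi, pX, pC) {
    if (is.vector(codes)) codes <- matrix(codes, nrow = 1L)
    codes <- as.matrix(codes)
    storage.mode(codes) <- "integer"
    n <- nrow(codes); T <- ncol(codes)
    if (any(codes[, 1L] != .CODE_STOPOVER))
        stop("histories must start at stopover (code 1)")
    toMat <- function(x) {
        if (is.matrix(x)) x
        else matrix(x, n, T - 1L, byrow = length(x) == T - 1L)
    }
    psi <- toMat(psi); chi <- toMat(chi)
    if (ncol(psi) < T - 1L || ncol(chi) < T - 1L)
        stop("psi/chi must cover transitions 1..T-1")
    ll <- cpp_forward_loglik(codes, psi[, seq_len(T - 1L), drop = FALSE],
                             chi[, seq_len(T - 1L), drop = FALSE],
                             rep_len(pX, n), rep_len(pC, n))
    if (any(!is.finite(ll)))
        warning(sum(!is.finite(ll)),
                " histories impossible under the supplied probabilities")
    ll
}

## psi/chi matrices (n x T-1) implied by params on a msModelData object
linearPredictors <- function(md, params) {
    d <- md$data
    n <- nrow(d$codes)
    sp <- d$species + 1L
    bp <- params@betaPsi
    eta <- bp[sp, "b0"] + bp[sp, "ul"] * d$ul + bp[sp, "uq"] * d$uq +
        bp[sp, "vl"] * d$vl + bp[sp, "vq"] * d$vq +
        bp[sp, "dp"] * d$dp + bp[sp, "h"] * d$h + params@betaRain * d$r
    bc <- params@betaChi
    etc <- params@beta0Chi[sp] + bc[["ul"]] * d$ul + bc[["uq"]] * d$uq +
        bc[["vl"]] * d$vl + bc[["vq"]] * d$vq
    list(psi = plogis(eta), chi = plogis(etc),
         pX = params@pX[as.character(.TAG_TYPES)][d$tag + 1L],
         pC = params@pC[as.character(.TAG_TYPES)][d$tag + 1L])
}

#' Total marginal log-likelihood over all individuals
#'
#' Sum of per-individual forward log-likelihoods; individuals are
#' independent given the parameters.
#'
#' @param md model data from \code{\link{msModelData}}.
#' @param params a \linkS4class{MultistateParams} whose coefficients refer
#'   to the basis stored in \code{md}.
#' @return single log-likelihood value.
#' @export
totalLogLik <- function(md, params) {
    lp <- linearPredictors(md, params)
    sum(forwardLogLik(md$data$codes, lp$psi, lp$chi, lp$pX, lp$pC))
}

## ---- parameter vector mapping (sampler <-> MultistateParams) ----------

## Unconstrained vector layout matching cpp_ms_loglik: per-column blocks of
## betaPsi, shared rain slope, routing intercepts, shared routing slopes,
## then logit(pX_ACT), logit(pX_NTQB/pX_ACT), logit(pC_ACT),
## logit(pC_NTQB/pC_ACT). The ratio parameterization enforces ACT >= NTQB.
msParamNames <- function(speciesLevels, constrained = FALSE) {
    S <- length(speciesLevels)
    psiBlocks <- c("b0_psi", "bul_psi", "buq_psi", "bvl_psi", "bvq_psi",
                   "bdp_psi", "bh_psi")
    nm <- c(as.vector(vapply(psiBlocks, function(b)
                paste0(b, "[", speciesLevels, "]"), character(S))),
            "brain_psi",
            paste0("b0_chi[", speciesLevels, "]"),
            "bul_chi", "buq_chi", "bvl_chi", "bvq_chi")
    if (constrained)
        c(nm, "pX[ACT]", "pX[NTQB]", "pC[ACT]", "pC[NTQB]")
    else
        c(nm, "qX_ACT", "qX_frac", "qC_ACT", "qC_frac")
}

.clampProb <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)

paramsToVector <- function(params) {
    bp <- params@betaPsi
    pX <- params@pX[.TAG_TYPES]; pC <- params@pC[.TAG_TYPES]
    v <- c(bp[, "b0"], bp[, "ul"], bp[, "uq"], bp[, "vl"], bp[, "vq"],
           bp[, "dp"], bp[, "h"], params@betaRain, params@beta0Chi,
           params@betaChi,
           qlogis(.clampProb(pX[["ACT"]])),
           qlogis(.clampProb(pX[["NTQB"]] / pX[["ACT"]])),
           qlogis(.clampProb(pC[["ACT"]])),
           qlogis(.clampProb(pC[["NTQB"]] / pC[["ACT"]])))
    names(v) <- msParamNames(rownames(bp) %||% seq_len(nrow(bp)))
    v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vectorToParams <- function(v, speciesLevels) {
    S <- length(speciesLevels)
    bp <- matrix(v[seq_len(7 * S)], S, 7,
                 dimnames = list(speciesLevels,
                                 c("b0", "ul", "uq", "vl", "vq", "dp", "h")))
    pXa <- plogis(v[[8 * S + 6]]); pXn <- pXa * plogis(v[[8 * S + 7]])
    pCa <- plogis(v[[8 * S + 8]]); pCn <- pCa * plogis(v[[8 * S + 9]])
    MultistateParams(bp, betaRain = v[[7 * S + 1]],
                     beta0Chi = unname(v[7 * S + 1 + seq_len(S)]),
                     betaChi = unname(v[8 * S + 1 + seq_len(4)]),
                     pX = c(ACT = pXa, NTQB = pXn),
                     pC = c(ACT = pCa, NTQB = pCn))
}

## constrained draw row (betas + probability-scale detection) -> params
constrainedToParams <- function(v, speciesLevels) {
    S <- length(speciesLevels)
    bp <- matrix(v[seq_len(7 * S)], S, 7,
                 dimnames = list(speciesLevels,
                                 c("b0", "ul", "uq", "vl", "vq", "dp", "h")))
    MultistateParams(bp, betaRain = v[[7 * S + 1]],
                     beta0Chi = unname(v[7 * S + 1 + seq_len(S)]),
                     betaChi = unname(v[8 * S + 1 + seq_len(4)]),
                     pX = c(ACT = v[[8 * S + 6]], NTQB = v[[8 * S + 7]]),
                     pC = c(ACT = v[[8 * S + 8]], NTQB = v[[8 * S + 9]]))
}

## unconstrained draw matrix -> constrained (probability-scale) draw matrix
constrainDraws <- function(m, speciesLevels) {
    S <- length(speciesLevels)
    out <- m
    pXa <- plogis(m[, 8 * S + 6]); pXn <- pXa * plogis(m[, 8 * S + 7])
    pCa <- plogis(m[, 8 * S + 8]); pCn <- pCa * plogis(m[, 8 * S + 9])
    out[, 8 * S + 6] <- pXa; out[, 8 * S + 7] <- pXn
    out[, 8 * S + 8] <- pCa; out[, 8 * S + 9] <- pCn
    colnames(out) <- msParamNames(speciesLevels, constrained = TRUE)
    out
}
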