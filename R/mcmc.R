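## Generic adaptive random-walk Metropolis engine used by the multistate
## model and the auxiliary regressions. During warmup the proposal is a
## multivariate normal whose covariance tracks the empirical covariance of
## the chain (scaled by 2.38^2/d) with a Robbins-Monro adjustment of a
## global step-size factor toward a target acceptance rate; after warmup
## the proposal is frozen so the retained draws form a genuine Markov
## chain with the posterior as invariant distribution.

## Evaluate expr under a temporary RNG state; global .Random.seed restored.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Adaptive random-walk Metropolis sampler
#'
#' Samples from an unnormalized log-density with chain-wise covariance
#' adaptation during warmup (frozen afterwards). Deterministic given
#' \code{seed}.
#'
#' @param logPost function of a parameter vector returning the log posterior
#'   density (up to a constant); may return \code{-Inf}.
#' @param init named initial parameter vector.
#' @param nChains number of chains (run sequentially).
#' @param nIter total iterations per chain, including warmup.
#' @param nWarmup adaptation iterations discarded from the front.
#' @param seed integer seed controlling all randomness.
#' @param initJitter sd of the normal jitter applied to \code{init} per
#'   chain (overdispersed starts); when \code{initCov} is supplied the
#'   jitter is \code{initJitter} times the implied scale per coordinate.
#' @param targetAccept target acceptance rate for the step-size adaptation.
#' @param initCov optional d x d covariance seeding the proposal (e.g. a
#'   Laplace approximation of the posterior); adaptation refines it.
#' @return list with \code{draws} (array, kept iterations x chains x
#'   parameters) and \code{accept} (post-warmup acceptance rate per chain).
#' @export
sampleMetropolis <- function(logPost, init, nChains = 4, nIter = 2000,
                             nWarmup = 1000, seed = 1, initJitter = 0.1,
                             targetAccept = 0.234, initCov = NULL) {
    stopifnot(nIter > nWarmup, nChains >= 1)
    d <- length(init)
    nKeep <- nIter - nWarmup
    draws <- array(NA_real_, c(nKeep, nChains, d),
                   dimnames = list(NULL, NULL,
                                   names(init) %||% paste0("p", seq_len(d))))
    accept <- numeric(nChains)
    cholS0 <- diag(0.1 / sqrt(d), d)
    jitterScale <- rep(initJitter, d)
    indep <- NULL
    if (!is.null(initCov)) {
        cholS0 <- tryCatch(chol(2.38^2 / d * (initCov + diag(1e-10, d))),
                           error = function(e)
                               diag(sqrt(pmax(diag(initCov), 1e-8)) *
                                    2.38 / sqrt(d)))
        jitterScale <- initJitter * sqrt(pmax(diag(initCov), 1e-8))
        ## independence kernel from the (inflated) approximation; mixed in
        ## occasionally it lets a chain stuck on a flat likelihood plateau
        ## jump back to the typical set, with the exact MH correction
        ci <- tryCatch(chol(1.5 * (initCov + diag(1e-10, d))),
                       error = function(e) NULL)
        if (!is.null(ci))
            indep <- list(center = init, chol = ci,
                          halfLogDet = sum(log(diag(ci))))
    }
    indepLogDens <- function(x) {
        z <- backsolve(indep$chol, x - indep$center, transpose = TRUE)
        -0.5 * sum(z^2) - indep$halfLogDet
    }
    withSeed(seed, {
        for (ch in seq_len(nChains)) {
            x <- init + rnorm(d, 0, jitterScale)
            lp <- logPost(x)
            tries <- 0L
            while (!is.finite(lp) && tries < 50L) {
                x <- init + rnorm(d, 0, jitterScale)
                lp <- logPost(x)
                tries <- tries + 1L
            }
            if (!is.finite(lp))
                stop("could not find a finite-density starting point")
            logLambda <- 0
            cholS <- cholS0
            hist <- matrix(NA_real_, nWarmup, d)
            nAcc <- 0L
            for (it in seq_len(nIter)) {
                useIndep <- !is.null(indep) && runif(1) < 0.1
                if (useIndep) {
                    prop <- indep$center +
                        drop(crossprod(indep$chol, rnorm(d)))
                    lpProp <- logPost(prop)
                    logRatio <- lpProp - lp +
                        indepLogDens(x) - indepLogDens(prop)
                } else {
                    prop <- x + exp(logLambda / 2) *
                        drop(crossprod(cholS, rnorm(d)))
                    lpProp <- logPost(prop)
                    logRatio <- lpProp - lp
                }
                alpha <- if (is.finite(lpProp))
                             min(1, exp(logRatio)) else 0
                if (runif(1) < alpha) {
                    x <- prop; lp <- lpProp
                    if (it > nWarmup) nAcc <- nAcc + 1L
                }
                if (useIndep) alpha <- NA  # step-size adaptation: RW only
                if (it <= nWarmup) {
                    hist[it, ] <- x
                    if (!is.na(alpha))
                        logLambda <- logLambda +
                            it^(-0.6) * (alpha - targetAccept)
                    ## with an informed covariance (Laplace curvature)
                    ## only the global step size adapts: an empirical
                    ## covariance from a short, slowly mixing warmup is
                    ## less reliable than the curvature itself
                    if (is.null(initCov) &&
                        it %% 100L == 0L && it >= 200L) {
                        use <- hist[max(1L, it %/% 2L):it, , drop = FALSE]
                        S <- 2.38^2 / d *
                            (stats::cov(use) + diag(1e-8, d))
                        cholS <- tryCatch(chol(S), error = function(e)
                            diag(sqrt(diag(S))))
                    }
                } else {
                    draws[it - nWarmup, ch, ] <- x
                }
            }
            accept[ch] <- nAcc / nKeep
        }
    })
    list(draws = draws, accept = accept)
}

#' Laplace (mode + curvature) approximation of a log posterior
#'
#' Finds the posterior mode by quasi-Newton optimisation and returns the
#' inverse Hessian as a covariance approximation, used to seed the
#' Metropolis proposal and starting points.
#'
#' @param logPost log posterior density function.
#' @param init starting parameter vector.
#' @param maxit optimiser iteration cap.
#' @return list with \code{par} (the mode) and \code{cov} (positive
#'   definite covariance approximation; diagonal fallback if the Hessian
#'   is not invertible).
#' @export
laplaceInit <- function(logPost, init, maxit = 500) {
    negLP <- function(v) {
        lp <- logPost(v)
        if (!is.finite(lp)) 1e10 else -lp
    }
    opt <- optim(init, negLP, method = "BFGS",
                 control = list(maxit = maxit), hessian = TRUE)
    Sig <- tryCatch({
        s <- solve(opt$hessian)
        (s + t(s)) / 2
    }, error = function(e) NULL)
    ok <- !is.null(Sig) && all(is.finite(Sig)) &&
        all(eigen(Sig, symmetric = TRUE,
                  only.values = TRUE)$values > 0)
    if (!ok)
        Sig <- diag(pmax(1 / pmax(diag(opt$hessian), 1e-4), 1e-6),
                    length(init))
    list(par = opt$par, cov = Sig)
}

## split each chain in half -> iter/2 x (2*chains) matrix per parameter
.splitChains <- function(m) {
    n <- nrow(m) %/% 2L
    cbind(m[seq_len(n), , drop = FALSE],
          m[n + seq_len(n), , drop = FALSE])
}

## rank-normalization over all draws jointly
.zScale <- function(m) {
    r <- rank(as.vector(m), ties.method = "average")
    z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
    matrix(z, nrow(m), ncol(m))
}

.rhatESS <- function(m) {
    ## m: iterations x chains for one parameter (already >= 2 chains)
    if (all(m == m[1L])) return(c(rhat = NA_real_, ess = NA_real_))
    z <- .zScale(.splitChains(m))
    N <- nrow(z); M <- ncol(z)
    W <- mean(apply(z, 2L, var))
    B <- N * var(colMeans(z))
    varPlus <- (N - 1) / N * W + B / N
    rhat <- sqrt(varPlus / W)
    ## bulk ESS via per-chain autocovariances and Geyer's initial positive
    ## sequence on the combined correlogram
    maxLag <- N - 2L
    acov <- vapply(seq_len(M), function(c)
        drop(acf(z[, c], lag.max = maxLag, type = "covariance",
                 plot = FALSE, demean = TRUE)$acf) * (N - 1) / N,
        numeric(maxLag + 1L))
    rho <- 1 - (W - rowMeans(acov)) / varPlus
    tau <- 1
    t <- 1L
    lastPair <- Inf
    while (t + 1L <= maxLag) {
        pair <- rho[t + 1L] + rho[t + 2L]
        if (!is.finite(pair) || pair <= 0) break
        pair <- min(pair, lastPair)  # enforce monotone decrease
        tau <- tau + 2 * pair
        lastPair <- pair
        t <- t + 2L
    }
    c(rhat = rhat, ess = N * M / tau)
}

#' Convergence diagnostics: split-Rhat and effective sample size
#'
#' Rank-normalized split-Rhat and bulk effective sample size per parameter,
#' computed from at least two chains. Parameters with Rhat > 1.01 or
#' ESS < 1000 are flagged; constant (degenerate) chains are flagged with
#' \code{NA} diagnostics.
#'
#' @param x a \linkS4class{MultistatePosterior} or an iterations x chains x
#'   parameters array.
#' @param rhatLimit,essLimit flag thresholds.
#' @return data.frame with columns \code{param}, \code{rhat}, \code{ess},
#'   \code{flag}.
#' @export
mcmcDiagnostics <- function(x, rhatLimit = 1.01, essLimit = 1000) {
    a <- if (is(x, "MultistatePosterior")) x@draws else x
    if (length(dim(a)) != 3L)
        stop("need an iterations x chains x parameters array")
    if (dim(a)[2L] < 2L)
        stop("diagnostics require at least 2 chains")
    res <- t(vapply(seq_len(dim(a)[3L]),
                    function(j) .rhatESS(a[, , j]), numeric(2)))
    out <- data.frame(param = dimnames(a)[[3L]] %||%
                          paste0("p", seq_len(dim(a)[3L])),
                      rhat = res[, 1L], ess = res[, 2L])
    out$flag <- is.na(out$rhat) | out$rhat > rhatLimit | out$ess < essLimit
    out
}
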