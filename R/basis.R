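#' Centre and scale a covariate column
#'
#' Continuous predictors are centred and scaled to one standard deviation
#' before entering the linear predictors; the centre and scale are kept so
#' the same transformation can be applied to new data at prediction time.
#'
#' @param x numeric vector with positive standard deviation.
#' @return list with \code{x} (standardized values), \code{center} and
#'   \code{scale}.
#' @examples
#' standardizeColumn(c(1, 2, 3))
#' @export
standardizeColumn <- function(x) {
    if (!is.numeric(x) || length(x) < 2L)
        stop("need a numeric column of length >= 2")
    s <- sd(x)
    if (!is.finite(s) || s == 0)
        stop("cannot standardize a zero-variance column")
    m <- mean(x)
    list(x = (x - m) / s, center = m, scale = s)
}

#' Apply a stored standardization to new values
#' @param x numeric vector.
#' @param center,scale transformation stored by
#'   \code{\link{standardizeColumn}}.
#' @return standardized values.
#' @export
applyStandardization <- function(x, center, scale) (x - center) / scale

#' Degree-2 orthogonal polynomial basis
#'
#' Builds the orthogonal linear and quadratic columns used for the wind
#' components (via \code{\link[stats]{poly}}): both columns are orthogonal
#' to the constant and to each other, and have unit norm. The projection
#' coefficients are stored so the identical basis can be evaluated at new
#' covariate values.
#'
#' @param x numeric vector with at least 3 distinct values.
#' @return list with \code{linear}, \code{quadratic} and \code{coefs}
#'   (pass to \code{\link{evalPolyBasis}}).
#' @examples
#' b <- orthogonalPolyBasis(c(-1, 0, 1))
#' b$linear       # (-1, 0, 1) / sqrt(2)
#' b$quadratic    # (1, -2, 1) / sqrt(6)
#' @export
orthogonalPolyBasis <- function(x) {
    if (length(unique(x)) < 3L)
        stop("orthogonal quadratic basis needs >= 3 distinct values")
    p <- poly(x, degree = 2)
    list(linear = p[, 1L], quadratic = p[, 2L],
         coefs = attr(p, "coefs"))
}

#' Evaluate a stored orthogonal polynomial basis at new values
#' @param x numeric vector.
#' @param coefs projection coefficients from
#'   \code{\link{orthogonalPolyBasis}}.
#' @return matrix with columns \code{linear}, \code{quadratic}.
#' @export
evalPolyBasis <- function(x, coefs) {
    p <- poly(x, degree = 2, coefs = coefs)
    colnames(p) <- c("linear", "quadratic")
    unclass(p)
}

## Build all model bases from raw covariate matrices (individuals x
## transitions). When `proj` is NULL the projections (poly coefficients,
## centres/scales) are fitted on the supplied values -- i.e. on the union of
## all modeled individual-occasions -- otherwise the stored projections are
## re-applied (prediction on new data).
covariateBases <- function(u, v, dp, h, rain, proj = NULL) {
    dims <- dim(as.matrix(u))
    shape <- function(x) matrix(x, dims[1], dims[2])
    if (is.null(proj)) {
        bu <- orthogonalPolyBasis(as.vector(u))
        bv <- orthogonalPolyBasis(as.vector(v))
        sdp <- standardizeColumn(as.vector(dp))
        sh <- standardizeColumn(as.vector(h))
        ## poly() columns have unit norm; rescale to ~unit SD so all slopes
        ## share the per-SD interpretation of the standardized covariates
        sf <- sqrt(length(as.vector(u)))
        proj <- list(uCoefs = bu$coefs, vCoefs = bv$coefs,
                     dpCenter = sdp$center, dpScale = sdp$scale,
                     hCenter = sh$center, hScale = sh$scale,
                     scaleFactor = sf)
        ulq <- cbind(bu$linear, bu$quadratic) * sf
        vlq <- cbind(bv$linear, bv$quadratic) * sf
        dps <- sdp$x
        hs <- sh$x
    } else {
        ulq <- evalPolyBasis(as.vector(u), proj$uCoefs) * proj$scaleFactor
        vlq <- evalPolyBasis(as.vector(v), proj$vCoefs) * proj$scaleFactor
        dps <- applyStandardization(as.vector(dp), proj$dpCenter,
                                    proj$dpScale)
        hs <- applyStandardization(as.vector(h), proj$hCenter, proj$hScale)
    }
    list(ul = shape(ulq[, 1L]), uq = shape(ulq[, 2L]),
         vl = shape(vlq[, 1L]), vq = shape(vlq[, 2L]),
         dp = shape(dps), h = shape(hs), r = shape(as.numeric(rain)),
         proj = proj)
}

#' Assemble model data from encounter histories
#'
#' Converts an \linkS4class{EncounterHistories} object (codes plus covariate
#' assays \code{u}, \code{v}, \code{dp}, \code{h}, \code{rain}) into the
#' internal structure consumed by the likelihood and sampler: orthogonal
#' wind bases and standardized covariates for the transition-driving sunsets
#' (occasions 1..T-1), 0-based species and tag indices, and the stored basis
#' projections for later prediction. The bases are fitted over the union of
#' all modeled individual-occasions.
#'
#' @param eh an \code{EncounterHistories} with covariate assays.
#' @param proj optional stored projections (re-apply instead of refit).
#' @return list with elements \code{data} (passed to the C++ likelihood),
#'   \code{proj}, \code{speciesLevels}, \code{tagLevels}.
#' @export
msModelData <- function(eh, proj = NULL) {
    T <- nOccasions(eh)
    if (T < 2L) stop("need at least 2 occasions")
    need <- c("u", "v", "dp", "h", "rain")
    if (!all(need %in% names(assays(eh))))
        stop("missing covariate assays: ",
             paste(setdiff(need, names(assays(eh))), collapse = ", "))
    tr <- seq_len(T - 1L)
    bases <- covariateBases(assay(eh, "u")[, tr, drop = FALSE],
                            assay(eh, "v")[, tr, drop = FALSE],
                            assay(eh, "dp")[, tr, drop = FALSE],
                            assay(eh, "h")[, tr, drop = FALSE],
                            assay(eh, "rain")[, tr, drop = FALSE],
                            proj = proj)
    sp <- droplevels(factor(speciesLabels(eh)))
    tg <- factor(as.character(tagTypes(eh)), levels = .TAG_TYPES)
    list(data = list(codes = encounterCodes(eh),
                     species = as.integer(sp) - 1L,
                     tag = as.integer(tg) - 1L,
                     ul = bases$ul, uq = bases$uq, vl = bases$vl,
                     vq = bases$vq, dp = bases$dp, h = bases$h,
                     r = bases$r, nSpecies = nlevels(sp)),
         proj = bases$proj,
         speciesLevels = levels(sp),
         tagLevels = .TAG_TYPES)
}
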