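## Observation / state codes used throughout: 1 stopover, 2 offshore flight,
## 3 onshore flight, 4 not seen (observation) / departed (latent state).
.CODE_STOPOVER <- 1L
.CODE_OFFSHORE <- 2L
.CODE_ONSHORE  <- 3L
.CODE_NOTSEEN  <- 4L

.TAG_TYPES <- c("ACT", "NTQB")
.DISTANCE_GROUPS <- c("short", "long")

#' EncounterHistories: capture-recapture encounter histories with covariates
#'
#' An S4 container (extending
#' \link[SummarizedExperiment]{SummarizedExperiment}) for multistate
#' encounter histories: rows are individuals, columns are daily occasions.
#' The \code{"codes"} assay holds the observation code for each
#' individual-occasion (1 = at stopover, 2 = offshore flight detected,
#' 3 = onshore flight detected, 4 = not seen). Additional assays carry the
#' sunset covariates driving the departure and routing models: \code{u},
#' \code{v} (eastward/northward wind, m/s), \code{dp} (24-h air-pressure
#' change, hPa), \code{h} (relative humidity, \%) and \code{rain}
#' (binary). \code{rowData} stores per-individual metadata: \code{tag_id},
#' \code{species}, \code{tag_type} ("ACT" or "NTQB"), and
#' \code{distance_group} ("short" or "long").
#'
#' Structural invariants enforced by the validity method: every history
#' starts at stopover; codes 2/3 (a detected flight) occur at most once per
#' individual; once a history leaves stopover it never returns -- all
#' subsequent codes are 4 (not seen).
#'
#' @aliases EncounterHistories
#' @export
setClass("EncounterHistories", contains = "SummarizedExperiment")

setValidity("EncounterHistories", function(object) {
    if (!"codes" %in% names(assays(object)))
        return("assay 'codes' is required")
    cd <- assay(object, "codes")
    if (!all(cd %in% 1:4))
        return("encounter codes must be integers in 1..4")
    if (ncol(cd) > 0 && !all(cd[, 1L] == .CODE_STOPOVER))
        return("every encounter history must start at stopover (code 1)")
    rd <- rowData(object)
    need <- c("species", "tag_type")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    if (!all(as.character(rd$tag_type) %in% .TAG_TYPES))
        return("tag_type must be 'ACT' or 'NTQB'")
    for (i in seq_len(nrow(cd))) {
        x <- cd[i, ]
        left <- which(x != .CODE_STOPOVER)
        if (length(left)) {
            d <- left[1L]
            if (d < length(x) && !all(x[(d + 1L):length(x)] == .CODE_NOTSEEN))
                return("codes after the departure occasion must all be 4")
        }
        if (sum(x %in% c(.CODE_OFFSHORE, .CODE_ONSHORE)) > 1L)
            return("at most one detected flight (code 2/3) per history")
    }
    TRUE
})

#' Construct an EncounterHistories object
#'
#' @param codes integer matrix, individuals x occasions, values in 1..4
#'   (1 stopover, 2 offshore, 3 onshore, 4 not seen); first column all 1.
#' @param species character/factor of species labels, one per individual.
#' @param tagType character, \code{"ACT"} or \code{"NTQB"}, per individual.
#' @param distanceGroup optional character, \code{"short"} or \code{"long"}.
#' @param tagId optional individual identifiers (default \code{id1..idn}).
#' @param covariates optional named list of numeric matrices with the same
#'   dimensions as \code{codes} (typically \code{u}, \code{v}, \code{dp},
#'   \code{h}, \code{rain}), stored as extra assays.
#' @return An \linkS4class{EncounterHistories} object.
#' @examples
#' cd <- rbind(c(1, 1, 2, 4), c(1, 4, 4, 4))
#' eh <- EncounterHistories(cd, species = c("A", "B"),
#'                          tagType = c("ACT", "NTQB"))
#' encounterCodes(eh)
#' @export
EncounterHistories <- function(codes, species, tagType, distanceGroup = NULL,
                               tagId = NULL, covariates = NULL) {
    codes <- as.matrix(codes)
    storage.mode(codes) <- "integer"
    n <- nrow(codes)
    if (is.null(tagId)) tagId <- paste0("id", seq_len(n))
    if (length(tagType) == 1L) tagType <- rep(tagType, n)
    if (is.null(distanceGroup)) distanceGroup <- rep(NA_character_, n)
    if (length(distanceGroup) == 1L) distanceGroup <- rep(distanceGroup, n)
    rd <- DataFrame(tag_id = as.character(tagId),
                    species = factor(species),
                    tag_type = factor(as.character(tagType),
                                      levels = .TAG_TYPES),
                    distance_group = distanceGroup,
                    row.names = make.unique(as.character(tagId)))
    al <- c(list(codes = codes), lapply(covariates, function(m) {
        m <- as.matrix(m)
        stopifnot(identical(dim(m), dim(codes)))
        m
    }))
    se <- SummarizedExperiment(assays = al, rowData = rd)
    colnames(se) <- paste0("t", seq_len(ncol(codes)))
    new("EncounterHistories", se)
}

#' @describeIn EncounterHistories the codes assay (individuals x occasions)
#' @param x an \code{EncounterHistories} object
#' @export
encounterCodes <- function(x) assay(x, "codes")

#' @describeIn EncounterHistories species factor, one entry per individual
#' @export
speciesLabels <- function(x) rowData(x)$species

#' @describeIn EncounterHistories tag type factor ("ACT"/"NTQB") per individual
#' @export
tagTypes <- function(x) rowData(x)$tag_type

#' @describeIn EncounterHistories migration distance group per individual
#' @export
distanceGroups <- function(x) rowData(x)$distance_group

#' @describeIn EncounterHistories number of occasions (history length T)
#' @export
nOccasions <- function(x) ncol(x)

setMethod("show", "EncounterHistories", function(object) {
    cd <- encounterCodes(object)
    dep <- apply(cd, 1L, function(x) any(x != .CODE_STOPOVER))
    cat("EncounterHistories:", nrow(cd), "individuals x", ncol(cd),
        "occasions\n")
    cat("  species:", paste(levels(speciesLabels(object)), collapse = ", "),
        "\n")
    cat("  detected offshore:", sum(apply(cd == .CODE_OFFSHORE, 1L, any)),
        " onshore:", sum(apply(cd == .CODE_ONSHORE, 1L, any)),
        " unrouted departures:",
        sum(dep) - sum(apply(cd == .CODE_OFFSHORE | cd == .CODE_ONSHORE,
                             1L, any)), "\n")
    cat("  covariate assays:",
        paste(setdiff(names(assays(object)), "codes"), collapse = ", "), "\n")
})

#' MultistateParams: parameters of the four-state departure/routing model
#'
#' Holds all coefficients of the departure (psi) and routing (chi) linear
#' predictors plus the route- and tag-specific detection probabilities.
#' The departure model has, per species, an intercept, orthogonal linear and
#' quadratic terms in each wind component, and linear pressure-change and
#' humidity slopes; the rain slope is shared across species. The routing
#' model has a species intercept and shared wind slopes. Detection
#' probabilities are indexed by tag type (ACT or NTQB) and route (offshore
#' \code{pX}, onshore \code{pC}); ACT tags transmit with more power, so the
#' ordering \code{ACT >= NTQB} is enforced.
#'
#' @slot betaPsi numeric matrix, species x 7, columns
#'   \code{b0, ul, uq, vl, vq, dp, h} (logit scale).
#' @slot betaRain single shared rain slope (logit scale).
#' @slot beta0Chi numeric, routing intercept per species.
#' @slot betaChi numeric length 4, shared routing wind slopes
#'   (\code{ul, uq, vl, vq}).
#' @slot pX named numeric, offshore detection probability for ACT and NTQB.
#' @slot pC named numeric, onshore detection probability for ACT and NTQB.
#' @export
setClass("MultistateParams",
         representation(betaPsi = "matrix", betaRain = "numeric",
                        beta0Chi = "numeric", betaChi = "numeric",
                        pX = "numeric", pC = "numeric"))

setValidity("MultistateParams", function(object) {
    S <- nrow(object@betaPsi)
    if (ncol(object@betaPsi) != 7L)
        return("betaPsi must have 7 columns (b0, ul, uq, vl, vq, dp, h)")
    if (length(object@beta0Chi) != S)
        return("beta0Chi must have one entry per species")
    if (length(object@betaChi) != 4L)
        return("betaChi must have 4 entries (ul, uq, vl, vq)")
    if (length(object@betaRain) != 1L)
        return("betaRain is a single shared slope")
    for (nm in c("pX", "pC")) {
        p <- slot(object, nm)
        if (!all(.TAG_TYPES %in% names(p)))
            return(paste(nm, "needs named entries for ACT and NTQB"))
        if (any(p < 0 | p > 1))
            return("detection probabilities must lie in [0, 1]")
        if (p[["ACT"]] < p[["NTQB"]])
            return("detection ordering violated: ACT must be >= NTQB")
    }
    TRUE
})

#' Construct a MultistateParams object
#'
#' @param betaPsi species x 7 matrix of departure coefficients
#'   (\code{b0, ul, uq, vl, vq, dp, h}), logit scale; row names are species.
#' @param betaRain shared rain slope (logit scale).
#' @param beta0Chi routing intercept per species (logit scale).
#' @param betaChi shared routing wind slopes (\code{ul, uq, vl, vq}).
#' @param pX,pC named detection probabilities (\code{ACT}, \code{NTQB}) for
#'   offshore and onshore flights; must satisfy ACT >= NTQB.
#' @return A \linkS4class{MultistateParams} object.
#' @export
MultistateParams <- function(betaPsi, betaRain = 0,
                             beta0Chi = numeric(nrow(betaPsi)),
                             betaChi = numeric(4),
                             pX = c(ACT = 0.55, NTQB = 0.5),
                             pC = c(ACT = 0.97, NTQB = 0.95)) {
    betaPsi <- as.matrix(betaPsi)
    colnames(betaPsi) <- c("b0", "ul", "uq", "vl", "vq", "dp", "h")
    names(betaChi) <- c("ul", "uq", "vl", "vq")
    new("MultistateParams", betaPsi = betaPsi, betaRain = betaRain,
        beta0Chi = beta0Chi, betaChi = betaChi, pX = pX, pC = pC)
}

setMethod("show", "MultistateParams", function(object) {
    cat("MultistateParams:", nrow(object@betaPsi), "species\n")
    cat("  detection pX:", paste(names(object@pX), round(object@pX, 3),
                                 collapse = "  "), "\n")
    cat("  detection pC:", paste(names(object@pC), round(object@pC, 3),
                                 collapse = "  "), "\n")
})

#' MultistatePosterior: MCMC draws from the multistate model posterior
#'
#' @slot draws numeric array, iterations x chains x parameters, with
#'   parameter names on the third dimension.
#' @slot diagnostics data.frame of split-Rhat and effective sample size per
#'   parameter (filled by \code{\link{mcmcDiagnostics}}).
#' @slot modelInfo list recording the species levels, tag types, covariate
#'   basis projections, run configuration and seed.
#' @export
setClass("MultistatePosterior",
         representation(draws = "array", diagnostics = "data.frame",
                        modelInfo = "list"))

setValidity("MultistatePosterior", function(object) {
    if (length(dim(object@draws)) != 3L)
        return("draws must be an iterations x chains x parameters array")
    if (is.null(dimnames(object@draws)[[3L]]))
        return("parameter names required on draws")
    TRUE
})

#' @describeIn MultistatePosterior draws flattened to a matrix with one row
#'   per retained draw (chains stacked) and one column per parameter
#' @param x a \code{MultistatePosterior}
#' @export
posteriorMatrix <- function(x) {
    d <- x@draws
    m <- matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
                dimnames = list(NULL, dimnames(d)[[3]]))
    m
}

#' @describeIn MultistatePosterior number of chains
#' @export
nChains <- function(x) dim(x@draws)[2]

#' @describeIn MultistatePosterior retained iterations per chain
#' @export
nIterations <- function(x) dim(x@draws)[1]

#' @describeIn MultistatePosterior the per-parameter diagnostics table
#' @export
posteriorDiagnostics <- function(x) x@diagnostics

setMethod("show", "MultistatePosterior", function(object) {
    d <- dim(object@draws)
    cat("MultistatePosterior:", d[2], "chains x", d[1], "iterations,",
        d[3], "parameters\n")
    if (nrow(object@diagnostics)) {
        cat("  max split-Rhat:",
            round(max(object@diagnostics$rhat, na.rm = TRUE), 3),
            " min ESS:",
            round(min(object@diagnostics$ess, na.rm = TRUE)), "\n")
    }
})
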