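.MODEL_FREE_DEFAULTS <- list(
    two_state = c("kIon", "kEon"),
    three_state = c("kIon", "kIoff", "kEon", "kEoff"),
    four_state = c("kIon", "kIoff", "kEon", "kEoff", "kNon", "kNoff"))

#' Specification of a kinetic model fit
#'
#' Describes which model to fit, which rate constants are free (with
#' bounds), which are fixed, the initial state and Ikaros schedule, and how
#' measured series map onto model state fractions. ChIP enrichment units
#' are arbitrary, so each measured series can optionally carry a free
#' multiplicative scale.
#'
#' @param modelId `"two_state"`, `"three_state"` or `"four_state"`.
#' @param free character vector of free rate names, or a named list of
#'   `c(lower, upper)` bounds. Defaults to the rates the model uses.
#' @param fixed [RateParameters()] supplying the values of all non-free
#'   rates (and the starting point for free ones).
#' @param init initial state (see [promoterState()]).
#' @param schedule [IkarosSchedule-class] driving the fit.
#' @param observables named character vector mapping series names to state
#'   fractions, e.g. `c(Ikaros = "dnaI", EBF1 = "dnaE")`.
#' @param fitScales logical; fit one multiplicative scale per series
#'   (default `TRUE`). With `FALSE` all scales are fixed at 1.
#' @param bounds default `c(lower, upper)` applied to free rates without
#'   explicit bounds.
#' @param scaleBounds bounds for the observable scales.
#' @return A list with class `"kineticFitSpec"`.
#' @examples
#' kineticFitSpec("three_state", schedule = stepSchedule(0.1, 1))
#' @export
kineticFitSpec <- function(modelId = c("three_state", "two_state",
                                       "four_state"),
                           free = NULL, fixed = RateParameters(),
                           init = promoterState(),
                           schedule = stepSchedule(),
                           observables = c(Ikaros = "dnaI", EBF1 = "dnaE"),
                           fitScales = TRUE,
                           bounds = c(1e-4, 10),
                           scaleBounds = c(1e-3, 1e3)) {
    modelId <- match.arg(modelId)
    stopifnot(is(fixed, "RateParameters"))
    if (is.null(free)) free <- .MODEL_FREE_DEFAULTS[[modelId]]
    if (is.character(free))
        free <- setNames(rep(list(bounds), length(free)), free)
    if (!all(names(free) %in% .RATE_NAMES))
        stop("unknown rate name in 'free'")
    usable <- if (modelId == "four_state") .RATE_NAMES
              else if (modelId == "three_state") .RATE_NAMES[1:4]
              else c("kIon", "kEon")
    if (!all(names(free) %in% usable))
        stop("free parameters ", paste(setdiff(names(free), usable),
             collapse = ", "), " are not used by the ", modelId, " model")
    lo <- vapply(free, `[`, numeric(1), 1L)
    hi <- vapply(free, `[`, numeric(1), 2L)
    if (any(lo < 0) || any(hi < lo))
        stop("bounds must satisfy 0 <= lower <= upper")
    if (!all(observables %in% .STATE_NAMES))
        stop("observables must map onto state fraction names")
    structure(list(modelId = modelId, free = free, fixed = fixed,
                   init = .asState(init), schedule = schedule,
                   observables = observables, fitScales = fitScales,
                   scaleBounds = scaleBounds),
              class = "kineticFitSpec")
}

## Normalise fit input to a long data.frame: series, time_min, replicate,
## value. Accepts such a data.frame, one ChIPTimeCourse, or a list of them
## (series = factorName).
.fitData <- function(data) {
    if (is(data, "ChIPTimeCourse")) data <- list(data)
    if (is.list(data) && !is.data.frame(data) &&
        all(vapply(data, is, logical(1), "ChIPTimeCourse"))) {
        data <- do.call(rbind, lapply(data, function(tc) {
            d <- enrichmentData(tc)
            data.frame(series = tc@factorName, time_min = d$time_min,
                       replicate = d$replicate, value = d$enrichment)
        }))
    }
    data <- as.data.frame(data)
    if ("enrichment" %in% names(data) && !"value" %in% names(data))
        names(data)[names(data) == "enrichment"] <- "value"
    need <- c("series", "time_min", "value")
    if (!all(need %in% names(data)))
        stop("fit data needs columns series, time_min, value/enrichment")
    if (!"replicate" %in% names(data)) data$replicate <- 1L
    data
}

.buildRates <- function(spec, freeValues) {
    v <- rateVector(spec$fixed)
    v[names(freeValues)] <- freeValues
    do.call(RateParameters, as.list(v))
}

.predictObservables <- function(spec, freeValues, scales, data) {
    params <- .buildRates(spec, freeValues)
    times <- sort(unique(data$time_min))
    tr <- simulatePromoter(spec$modelId, params, spec$schedule, spec$init,
                           times, rtol = 1e-7, atol = 1e-9)
    S <- trajectoryStates(tr)
    idx <- match(data$time_min, times)
    stateCol <- spec$observables[as.character(data$series)]
    sc <- scales[as.character(data$series)]
    sc[is.na(sc)] <- 1
    unname(sc * S[cbind(idx, match(stateCol, .STATE_NAMES))])
}

#' Fit a kinetic competition model to ChIP time courses
#'
#' Estimates the free rate constants (and optionally per-series scales) by
#' minimising the unweighted sum of squared residuals between model state
#' fractions and measured enrichments over all series jointly, using
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) from multiple seeded starting
#' points (log-uniform over the bounds) to mitigate local minima.
#' Deterministic given `seed`. Non-convergence is reported via the
#' `converged` flag, never as an error.
#'
#' @param data a long data.frame (`series`, `time_min`, `replicate`,
#'   `value`), a [ChIPTimeCourse-class], or a list of them.
#' @param spec a [kineticFitSpec()].
#' @param seed integer seed for the multi-start draws.
#' @param nStarts number of starting points (the first is the midpoint of
#'   the bounds on the log scale, seeded draws follow).
#' @param weights optional per-observation weights (e.g. `1/se^2`);
#'   default unweighted.
#' @return A [KineticFit-class].
#' @examples
#' spec <- kineticFitSpec("three_state", free = c("kIon", "kEon"),
#'                        schedule = stepSchedule(0.1, 1), fitScales = FALSE)
#' sim <- simulateChipTimeCourses(noiseSd = 0, seed = 1)
#' fitKineticModel(sim, spec, seed = 1, nStarts = 2)
#' @export
fitKineticModel <- function(data, spec, seed = 1L, nStarts = 10L,
                            weights = NULL) {
    stopifnot(inherits(spec, "kineticFitSpec"))
    data <- .fitData(data)
    series <- unique(as.character(data$series))
    if (!all(series %in% names(spec$observables)))
        stop("data series ", paste(setdiff(series, names(spec$observables)),
             collapse = ", "), " missing from spec observables")
    if (any(tapply(data$time_min, data$series,
                   function(t) length(unique(t))) < 2))
        stop("each observable needs measurements at >= 2 time points")
    n <- nrow(data)
    w <- if (is.null(weights)) rep(1, n) else sqrt(weights)

    freeNames <- names(spec$free)
    scaleNames <- if (spec$fitScales) paste0("scale_", series) else character(0)
    lo <- c(vapply(spec$free, `[`, numeric(1), 1L),
            rep(spec$scaleBounds[1], length(scaleNames)))
    hi <- c(vapply(spec$free, `[`, numeric(1), 2L),
            rep(spec$scaleBounds[2], length(scaleNames)))
    names(lo) <- names(hi) <- c(freeNames, scaleNames)
    k <- length(lo)

    splitPar <- function(par) {
        list(rates = setNames(par[seq_along(freeNames)], freeNames),
             scales = if (spec$fitScales)
                 setNames(par[-seq_len(length(freeNames))], series)
             else setNames(rep(1, length(series)), series))
    }
    residFun <- function(par) {
        p <- splitPar(par)
        pred <- tryCatch(
            .predictObservables(spec, p$rates, p$scales, data),
            error = function(e) rep(1e6, n))
        w * (pred - data$value)
    }
    makeFit <- function(par, ssr, converged, message) {
        p <- splitPar(par)
        pred <- tryCatch(.predictObservables(spec, p$rates, p$scales, data),
                         error = function(e) rep(NA_real_, n))
        est <- data.frame(
            parameter = c(freeNames, scaleNames),
            estimate = unname(par),
            se = rep(NA_real_, k), lower = unname(lo),
            upper = unname(hi), free = rep(TRUE, k),
            stringsAsFactors = FALSE)
        fixedNames <- setdiff(.MODEL_FREE_DEFAULTS[[spec$modelId]], freeNames)
        if (length(fixedNames))
            est <- rbind(est, data.frame(
                parameter = fixedNames,
                estimate = unname(rateVector(spec$fixed)[fixedNames]),
                se = NA_real_, lower = NA_real_, upper = NA_real_,
                free = FALSE))
        aic <- n * log(ssr / n) + 2 * k
        new("KineticFit", estimates = est, ssr = ssr, nObs = as.integer(n),
            aic = aic, converged = converged,
            residuals = data.frame(series = data$series,
                                   time_min = data$time_min,
                                   replicate = data$replicate,
                                   observed = data$value, fitted = pred,
                                   residual = data$value - pred),
            spec = unclass(spec), message = message)
    }

    # degenerate data: a flat series carries no kinetic information
    if (all(tapply(data$value, data$series,
                   function(v) diff(range(v)) == 0))) {
        par0 <- c(rateVector(spec$fixed)[freeNames],
                  setNames(rep(1, length(scaleNames)), scaleNames))
        ssr0 <- sum(residFun(par0)^2)
        return(makeFit(par0, ssr0, FALSE,
                       "unidentifiable: all observed values are identical"))
    }

    if (k == 0L) {
        ssr0 <- sum(residFun(numeric(0))^2)
        return(makeFit(numeric(0), ssr0, TRUE, "no free parameters"))
    }

    defaults <- rateVector(spec$fixed)[freeNames]
    starts <- withr::with_seed(seed, {
        lapply(seq_len(nStarts), function(i) {
            if (i == 1L) {
                st <- pmin(pmax(c(defaults,
                                  setNames(rep(1, length(scaleNames)),
                                           scaleNames)), lo), hi)
            } else {
                st <- exp(runif(k, log(pmax(lo, 1e-8)), log(hi)))
            }
            st
        })
    })

    best <- NULL
    for (st in starts) {
        res <- tryCatch(
            minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                               fn = residFun,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 200, ptol = 1e-10,
                                   ftol = 1e-12)),
            error = function(e) NULL)
        if (is.null(res)) next
        ssr <- sum(res$fvec^2)
        if (is.null(best) || ssr < best$ssr - 1e-12)
            best <- list(res = res, ssr = ssr)
    }
    if (is.null(best)) {
        par0 <- starts[[1]]
        return(makeFit(par0, sum(residFun(par0)^2), FALSE,
                       "optimiser failed from every starting point"))
    }
    res <- best$res
    converged <- res$info %in% 1:4
    fit <- makeFit(res$par, best$ssr, converged,
                   if (converged) "" else res$message)
    # approximate standard errors from the Gauss-Newton curvature
    se <- tryCatch({
        covm <- solve(res$hessian) * best$ssr / max(n - k, 1L)
        sqrt(pmax(diag(covm), 0))
    }, error = function(e) rep(NA_real_, k))
    fit@estimates$se[seq_len(k)] <- se
    fit
}

#' Rank competing kinetic models on the same data
#'
#' Fits each specification to the same data and orders them by AIC
#' (`n log(SSR/n) + 2k`, `k` = free rates + scales). Non-converged fits are
#' ranked last and flagged; ties are broken in favour of fewer parameters.
#'
#' @inheritParams fitKineticModel
#' @param specs a list of [kineticFitSpec()] objects.
#' @return A data.frame with one row per spec, ordered best first
#'   (`model`, `k`, `ssr`, `aic`, `converged`, `rank`), with the fits in
#'   `attr(, "fits")`.
#' @export
compareKineticModels <- function(data, specs, seed = 1L, nStarts = 10L) {
    if (inherits(specs, "kineticFitSpec")) specs <- list(specs)
    fits <- lapply(specs, function(sp)
        fitKineticModel(data, sp, seed = seed, nStarts = nStarts))
    k <- vapply(fits, function(f) sum(f@estimates$free), integer(1))
    tab <- data.frame(
        model = vapply(specs, function(sp) sp$modelId, character(1)),
        k = k,
        ssr = vapply(fits, fitSSR, numeric(1)),
        aic = vapply(fits, fitAIC, numeric(1)),
        converged = vapply(fits, function(f) f@converged, logical(1)))
    ord <- order(!tab$converged, tab$aic, tab$k)
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    attr(tab, "fits") <- fits[ord]
    tab
}
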