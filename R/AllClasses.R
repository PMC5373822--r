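#' @import methods
#' @importFrom stats sd setNames rnorm runif rbinom rnbinom p.adjust
#'   fisher.test t.test glm binomial coef anova pchisq pt optim complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

.STATE_NAMES <- c("dnaE", "dnaFree", "dnaI", "dnaN")
.MODEL_IDS <- c("two_state", "three_state", "four_state")
.RATE_NAMES <- c("kIon", "kIoff", "kEon", "kEoff", "kNon", "kNoff")

#' Mass-action rate constants of the promoter competition models
#'
#' Holds the six rate constants of the 2-, 3- and 4-state models of
#' repressor/activator/nucleosome competition for a promoter site. All
#' rates are per minute; `kIon` additionally multiplies the (time-varying)
#' nuclear Ikaros concentration, while the EBF1 and nucleosome on-rates are
#' pseudo-first-order constants with the constant partner concentration
#' folded in. The defaults are the published estimates for the Igll1
#' promoter system (Ikaros 0.3/0.052, EBF1 0.036/0.033, nucleosome
#' 0.13/0.003).
#'
#' @slot kIon Ikaros association rate constant (per min per unit Ikaros).
#' @slot kIoff Ikaros dissociation rate (per min).
#' @slot kEon effective EBF1 association rate (per min).
#' @slot kEoff EBF1 dissociation rate (per min).
#' @slot kNon effective nucleosome deposition rate (per min).
#' @slot kNoff nucleosome eviction rate (per min).
#' @export
setClass("RateParameters",
    slots = c(kIon = "numeric", kIoff = "numeric",
              kEon = "numeric", kEoff = "numeric",
              kNon = "numeric", kNoff = "numeric"),
    prototype = prototype(kIon = 0.3, kIoff = 0.052,
                          kEon = 0.036, kEoff = 0.033,
                          kNon = 0.13, kNoff = 0.003))

setValidity("RateParameters", function(object) {
    v <- rateVector(object)
    if (length(v) != 6L || anyNA(v))
        return("all six rate constants must be single non-missing numbers")
    if (any(v < 0))
        return("rate constants must be non-negative")
    TRUE
})

#' @describeIn RateParameters-class Constructor; defaults are the published
#'   estimates.
#' @param kIon,kIoff,kEon,kEoff,kNon,kNoff rate constants (per minute).
#' @return A `RateParameters` object.
#' @examples
#' RateParameters()                     # published defaults
#' RateParameters(kNon = 0, kNoff = 0)  # nucleosome step switched off
#' @export
RateParameters <- function(kIon = 0.3, kIoff = 0.052,
                           kEon = 0.036, kEoff = 0.033,
                           kNon = 0.13, kNoff = 0.003) {
    new("RateParameters", kIon = kIon, kIoff = kIoff,
        kEon = kEon, kEoff = kEoff, kNon = kNon, kNoff = kNoff)
}

#' Extract the rates of a RateParameters object as a named vector
#'
#' @param params A [RateParameters()] object.
#' @return Named numeric of length 6 (`kIon`, `kIoff`, `kEon`, `kEoff`,
#'   `kNon`, `kNoff`).
#' @export
rateVector <- function(params) {
    setNames(vapply(.RATE_NAMES, function(nm) slot(params, nm), numeric(1)),
             .RATE_NAMES)
}

#' @export
setMethod("show", "RateParameters", function(object) {
    v <- rateVector(object)
    cat("RateParameters (per min)\n")
    cat(sprintf("  Ikaros     on %.4g  off %.4g\n", v["kIon"], v["kIoff"]))
    cat(sprintf("  EBF1       on %.4g  off %.4g\n", v["kEon"], v["kEoff"]))
    cat(sprintf("  nucleosome on %.4g  off %.4g\n", v["kNon"], v["kNoff"]))
})

#' Piecewise-constant nuclear Ikaros concentration schedule
#'
#' Describes the nuclear Ikaros concentration as a non-decreasing,
#' piecewise-constant function of time (minutes). Three modes are
#' supported: a single `step` to a target level, and `incremental-additive`
#' / `incremental-multiplicative` schedules where the level changes at
#' every interval boundary for `nSteps` intervals. Interval boundaries are
#' right-closed: at a breakpoint the new level is already in force, so a
#' step at t = 0 applies to the whole simulation.
#'
#' @slot startConc initial nuclear concentration (arbitrary units).
#' @slot mode `"step"`, `"incremental-additive"` or
#'   `"incremental-multiplicative"`.
#' @slot targetOrIncrement target level (step mode) or per-interval
#'   increment/factor (incremental modes).
#' @slot intervalMin interval length in minutes; in step mode, the time at
#'   which the step occurs.
#' @slot nSteps number of increments (ignored in step mode).
#' @slot cap optional maximum level (default `Inf`).
#' @export
setClass("IkarosSchedule",
    slots = c(startConc = "numeric", mode = "character",
              targetOrIncrement = "numeric", intervalMin = "numeric",
              nSteps = "integer", cap = "numeric"),
    prototype = prototype(startConc = 0.1, mode = "step",
                          targetOrIncrement = 1, intervalMin = 0,
                          nSteps = 0L, cap = Inf))

setValidity("IkarosSchedule", function(object) {
    modes <- c("step", "incremental-additive", "incremental-multiplicative")
    if (!object@mode %in% modes)
        return(sprintf("mode must be one of %s", paste(modes, collapse = ", ")))
    if (object@startConc < 0)
        return("startConc must be non-negative")
    if (object@nSteps < 0L)
        return("invalid schedule: nSteps must be >= 0")
    if (object@nSteps > 0L && object@intervalMin <= 0)
        return("invalid schedule: intervalMin must be > 0 when nSteps > 0")
    if (object@mode == "step") {
        if (object@targetOrIncrement < object@startConc)
            return("step target must be >= startConc (non-decreasing input)")
        if (object@intervalMin < 0)
            return("step time must be >= 0")
    } else if (object@mode == "incremental-additive") {
        if (object@targetOrIncrement < 0)
            return("additive increment must be >= 0 (non-decreasing input)")
    } else {
        if (object@targetOrIncrement < 1)
            return("multiplicative factor must be >= 1 (non-decreasing input)")
    }
    if (object@cap <= 0)
        return("cap must be positive")
    TRUE
})

#' Step schedule: a one-off jump in nuclear Ikaros
#'
#' @param start level before the step (default 0.1, the published starting
#'   concentration).
#' @param target level from the step onwards.
#' @param at time of the step in minutes (default 0, i.e. the step is in
#'   force for the whole simulation).
#' @return An [IkarosSchedule-class] object.
#' @examples
#' stepSchedule(0.1, 1)            # step at t = 0
#' stepSchedule(0.1, 1, at = 15)   # delayed step
#' @export
stepSchedule <- function(start = 0.1, target = 1, at = 0) {
    new("IkarosSchedule", startConc = start, mode = "step",
        targetOrIncrement = target, intervalMin = at, nSteps = 0L, cap = Inf)
}

#' Incremental schedule: nuclear Ikaros rising at interval boundaries
#'
#' Mirrors the gradual nuclear translocation of Ikaros after induction: the
#' level starts at `start` and is incremented at every interval boundary
#' for `nSteps` intervals (additively or multiplicatively), then stays
#' constant. The published parameterisation is start 0.1 with increment 2.0
#' per interval; the interval length is taken as 5 min (the experimental
#' sampling interval) and the rise is complete by 60 min (12 intervals),
#' matching the saturation of nuclear translocation.
#'
#' @param start initial level.
#' @param increment per-interval additive increment or multiplicative
#'   factor, depending on `mode`.
#' @param intervalMin interval length in minutes.
#' @param nSteps number of increments.
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @param cap optional maximum level.
#' @return An [IkarosSchedule-class] object.
#' @examples
#' incrementalSchedule()   # published parameterisation, additive reading
#' @export
incrementalSchedule <- function(start = 0.1, increment = 2, intervalMin = 5,
                                nSteps = 12L, mode = c("additive",
                                                       "multiplicative"),
                                cap = Inf) {
    mode <- match.arg(mode)
    new("IkarosSchedule", startConc = start,
        mode = paste0("incremental-", mode),
        targetOrIncrement = increment, intervalMin = intervalMin,
        nSteps = as.integer(nSteps), cap = cap)
}

#' Constant schedule: nuclear Ikaros fixed at one level
#'
#' @param level the constant concentration.
#' @return An [IkarosSchedule-class] object.
#' @export
constantSchedule <- function(level) {
    new("IkarosSchedule", startConc = level, mode = "step",
        targetOrIncrement = level, intervalMin = 0, nSteps = 0L, cap = Inf)
}

#' @export
setMethod("show", "IkarosSchedule", function(object) {
    cat(sprintf("IkarosSchedule: %s, start %.4g", object@mode,
                object@startConc))
    if (object@mode == "step") {
        cat(sprintf(", target %.4g at t = %.4g min\n",
                    object@targetOrIncrement, object@intervalMin))
    } else {
        cat(sprintf(", %s %.4g every %.4g min x %d steps%s\n",
                    if (object@mode == "incremental-additive") "increment"
                    else "factor",
                    object@targetOrIncrement, object@intervalMin,
                    object@nSteps,
                    if (is.finite(object@cap))
                        sprintf(", cap %.4g", object@cap) else ""))
    }
})

#' Simulated promoter occupancy trajectory
#'
#' Output of [simulatePromoter()]: occupancy fractions of the four promoter
#' DNA states (`dnaE` bound by EBF1, `dnaFree` unbound, `dnaI` bound by
#' Ikaros, `dnaN` occluded by a nucleosome) at the requested times, plus
#' the model, parameters and Ikaros schedule that produced them.
#'
#' @slot times sample times (minutes), strictly increasing.
#' @slot states numeric matrix, one row per time, columns `dnaE`,
#'   `dnaFree`, `dnaI`, `dnaN`.
#' @slot modelId `"two_state"`, `"three_state"` or `"four_state"`.
#' @slot params the [RateParameters-class] used.
#' @slot schedule the [IkarosSchedule-class] used.
#' @export
setClass("PromoterTrajectory",
    slots = c(times = "numeric", states = "matrix", modelId = "character",
              params = "RateParameters", schedule = "IkarosSchedule"))

setValidity("PromoterTrajectory", function(object) {
    if (any(diff(object@times) <= 0))
        return("times must be strictly increasing")
    if (nrow(object@states) != length(object@times))
        return("states must have one row per time")
    if (!identical(colnames(object@states), .STATE_NAMES))
        return("state columns must be dnaE, dnaFree, dnaI, dnaN")
    if (!object@modelId %in% .MODEL_IDS)
        return("unknown modelId")
    if (any(object@states < -1e-8) || any(object@states > 1 + 1e-8))
        return("state fractions must lie in [0, 1]")
    tot <- rowSums(object@states)
    if (any(abs(tot - tot[1]) > 1e-6))
        return("total occupancy is not conserved along the trajectory")
    TRUE
})

#' @describeIn PromoterTrajectory-class Times at which states were sampled.
#' @param trajectory,x A `PromoterTrajectory`.
#' @export
trajectoryTimes <- function(trajectory) trajectory@times

#' @describeIn PromoterTrajectory-class State-fraction matrix (rows =
#'   times).
#' @export
trajectoryStates <- function(trajectory) trajectory@states

#' @describeIn PromoterTrajectory-class Model identifier of the trajectory.
#' @export
trajectoryModel <- function(trajectory) trajectory@modelId

#' @describeIn PromoterTrajectory-class Coerce to a data.frame with a
#'   `time_min` column followed by the four state fractions.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.PromoterTrajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
    data.frame(time_min = x@times, as.data.frame(x@states),
               row.names = row.names)
}

#' @export
setMethod("show", "PromoterTrajectory", function(object) {
    cat(sprintf("PromoterTrajectory: %s model, %d time points (%.4g-%.4g min)\n",
                object@modelId, length(object@times), min(object@times),
                max(object@times)))
    final <- object@states[nrow(object@states), ]
    cat("  final state:",
        paste(sprintf("%s %.4f", names(final), final), collapse = ", "), "\n")
})

#' Replicate kinetic-ChIP measurements for one factor at one locus
#'
#' Enrichment values (fold over the t = 0 baseline, so dimensionless and
#' strictly positive) for one antibody/factor at one amplicon, across
#' replicates and time points. The t = 0 point must be present.
#'
#' @slot target locus/amplicon label.
#' @slot factorName antibody/factor label (e.g. "Ikaros", "EBF1").
#' @slot data data.frame with columns `time_min`, `replicate`,
#'   `enrichment`.
#' @export
setClass("ChIPTimeCourse",
    slots = c(target = "character", factorName = "character",
              data = "data.frame"))

setValidity("ChIPTimeCourse", function(object) {
    d <- object@data
    need <- c("time_min", "replicate", "enrichment")
    if (!all(need %in% names(d)))
        return("data must have columns time_min, replicate, enrichment")
    if (nrow(d) == 0L)
        return("no measurements")
    bad <- which(!is.finite(d$enrichment) | d$enrichment <= 0)
    if (length(bad))
        return(sprintf("enrichment must be > 0 (first offending row: %d)",
                       bad[1]))
    if (!any(d$time_min == 0))
        return("the t = 0 baseline time point is required")
    TRUE
})

#' @describeIn ChIPTimeCourse-class Constructor.
#' @param target,factorName labels.
#' @param data data.frame with `time_min`, `replicate`, `enrichment`.
#' @export
ChIPTimeCourse <- function(target, factorName, data) {
    new("ChIPTimeCourse", target = target, factorName = factorName,
        data = as.data.frame(data))
}

#' @describeIn ChIPTimeCourse-class Measurement table of the time course.
#' @param tc A `ChIPTimeCourse`.
#' @export
enrichmentData <- function(tc) tc@data

#' @export
setMethod("show", "ChIPTimeCourse", function(object) {
    cat(sprintf("ChIPTimeCourse: %s @ %s - %d measurements, %d time points\n",
                object@factorName, object@target, nrow(object@data),
                length(unique(object@data$time_min))))
})

#' Result of a nonlinear least-squares kinetic model fit
#'
#' @slot estimates data.frame with one row per model parameter (free rates,
#'   then any observable scales): `parameter`, `estimate`, `se`, `lower`,
#'   `upper`, `free`.
#' @slot ssr sum of squared residuals at the optimum.
#' @slot nObs number of observations fitted.
#' @slot aic Akaike score, `nObs * log(ssr / nObs) + 2 k` with `k` the
#'   number of free parameters (rates plus scales).
#' @slot converged logical; `FALSE` on non-convergence or unidentifiable
#'   (degenerate) data — never an error.
#' @slot residuals data.frame `series`, `time_min`, `replicate`,
#'   `observed`, `fitted`, `residual`.
#' @slot spec the fit specification used (list, see [kineticFitSpec()]).
#' @slot message diagnostic message from the optimiser.
#' @export
setClass("KineticFit",
    slots = c(estimates = "data.frame", ssr = "numeric", nObs = "integer",
              aic = "numeric", converged = "logical",
              residuals = "data.frame", spec = "list",
              message = "character"))

setValidity("KineticFit", function(object) {
    if (length(object@ssr) != 1L || (is.finite(object@ssr) && object@ssr < 0))
        return("ssr must be a single non-negative number")
    est <- object@estimates
    free <- est[est$free, , drop = FALSE]
    bad <- !is.na(free$estimate) &
        (free$estimate < free$lower - 1e-9 | free$estimate > free$upper + 1e-9)
    if (any(bad))
        return("estimates outside their declared bounds")
    TRUE
})

#' @describeIn KineticFit-class Parameter estimate table.
#' @param fit A `KineticFit`.
#' @export
fitEstimates <- function(fit) fit@estimates

#' @describeIn KineticFit-class Named vector of fitted parameter values.
#' @export
fittedParameters <- function(fit) {
    setNames(fit@estimates$estimate, fit@estimates$parameter)
}

#' @describeIn KineticFit-class Sum of squared residuals.
#' @export
fitSSR <- function(fit) fit@ssr

#' @describeIn KineticFit-class Akaike score of the fit.
#' @export
fitAIC <- function(fit) fit@aic

#' @export
setMethod("show", "KineticFit", function(object) {
    cat(sprintf("KineticFit: %s model, %d observations\n",
                object@spec$modelId, object@nObs))
    cat(sprintf("  converged: %s  SSR: %.6g  AIC: %.4f\n",
                object@converged, object@ssr, object@aic))
    est <- object@estimates[object@estimates$free, , drop = FALSE]
    if (nrow(est))
        cat("  ", paste(sprintf("%s = %.4g (se %.2g)", est$parameter,
                                est$estimate, est$se), collapse = ", "),
            "\n", sep = "")
    if (nzchar(object@message)) cat("  note:", object@message, "\n")
})

#' Blacklist-normalised per-base coverage
#'
#' Per-chromosome per-base MNase fragment coverage, normalised per million
#' fragments whose midpoint falls outside the blacklist.
#'
#' @slot coverage an [IRanges::RleList] of normalised per-base values.
#' @slot scaleFactor the divisor applied to raw coverage (eligible
#'   fragments / 1e6).
#' @slot nEligible number of fragments with midpoint outside the blacklist.
#' @slot nTotal total number of fragments contributing coverage.
#' @export
setClass("CoverageTrack",
    slots = c(coverage = "ANY", scaleFactor = "numeric",
              nEligible = "numeric", nTotal = "numeric"))

setValidity("CoverageTrack", function(object) {
    if (object@scaleFactor <= 0)
        return("scaleFactor must be positive")
    if (any(min(object@coverage) < 0))
        return("coverage values must be >= 0")
    TRUE
})

#' @describeIn CoverageTrack-class Normalised per-base coverage as an
#'   `RleList`.
#' @param track A `CoverageTrack`.
#' @export
trackCoverage <- function(track) track@coverage

#' @describeIn CoverageTrack-class Normalisation divisor (eligible
#'   fragments per million).
#' @export
trackScaleFactor <- function(track) track@scaleFactor

#' @export
setMethod("show", "CoverageTrack", function(object) {
    cat(sprintf(
        "CoverageTrack: %d seqnames, %d/%d fragments eligible, scale %.4g\n",
        length(object@coverage), object@nEligible, object@nTotal,
        object@scaleFactor))
})
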