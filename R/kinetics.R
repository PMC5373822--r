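#' Nuclear Ikaros concentration at given times
#'
#' Evaluates a piecewise-constant [IkarosSchedule-class] at arbitrary
#' times. Interval boundaries are right-closed: at a breakpoint the new
#' level is already in force.
#'
#' @param schedule An [IkarosSchedule-class].
#' @param t numeric vector of times (minutes); must be finite.
#' @return Numeric vector of concentrations, same length as `t`.
#' @examples
#' ikarosConcentration(stepSchedule(0.1, 1, at = 0), c(0, 10))
#' ikarosConcentration(incrementalSchedule(0.1, 2, 5, 3), 7)  # 2.1
#' @export
ikarosConcentration <- function(schedule, t) {
    stopifnot(is(schedule, "IkarosSchedule"))
    validObject(schedule)
    if (any(!is.finite(t)))
        stop("times must be finite")
    level <- if (schedule@mode == "step") {
        ifelse(t >= schedule@intervalMin, schedule@targetOrIncrement,
               schedule@startConc)
    } else {
        k <- pmin(schedule@nSteps,
                  pmax(0, floor(t / schedule@intervalMin)))
        if (schedule@mode == "incremental-additive")
            schedule@startConc + k * schedule@targetOrIncrement
        else
            schedule@startConc * schedule@targetOrIncrement^k
    }
    pmin(level, schedule@cap)
}

#' Breakpoints of an Ikaros schedule
#'
#' Times (minutes) at which the piecewise-constant nuclear Ikaros level
#' changes; the integrator restarts at each of them so trajectories are
#' never smoothed across a concentration jump.
#'
#' @inheritParams ikarosConcentration
#' @return Sorted numeric vector of breakpoint times (possibly empty).
#' @export
scheduleBreakpoints <- function(schedule) {
    if (schedule@mode == "step") {
        if (schedule@targetOrIncrement != schedule@startConc)
            schedule@intervalMin
        else numeric(0)
    } else if (schedule@nSteps > 0L) {
        schedule@intervalMin * seq_len(schedule@nSteps)
    } else numeric(0)
}

#' Construct a promoter state vector
#'
#' @param dnaE,dnaFree,dnaI,dnaN occupancy fractions of the four promoter
#'   DNA states (EBF1-bound, unbound, Ikaros-bound, nucleosome-occluded).
#'   Fractions must lie in `[0, 1]` and sum to 1.
#' @return Named numeric of length 4.
#' @examples
#' promoterState(0.1, 0.8, 0.1)  # the published start conditions
#' @export
promoterState <- function(dnaE = 0.1, dnaFree = 0.8, dnaI = 0.1, dnaN = 0) {
    s <- c(dnaE = dnaE, dnaFree = dnaFree, dnaI = dnaI, dnaN = dnaN)
    if (any(s < -1e-9) || any(s > 1 + 1e-9))
        stop("state fractions must lie in [0, 1]")
    if (abs(sum(s) - 1) > 1e-9)
        stop("state fractions must sum to 1 (got ", format(sum(s)), ")")
    s
}

.asState <- function(state) {
    if (is.null(names(state))) names(state) <- .STATE_NAMES[seq_along(state)]
    out <- setNames(numeric(4), .STATE_NAMES)
    out[names(state)] <- state
    out
}

.checkModelState <- function(model, state) {
    if (model == "two_state" &&
        (abs(state["dnaFree"]) > 1e-12 || abs(state["dnaN"]) > 1e-12))
        stop("model mismatch: the two-state model has no free or ",
             "nucleosome-occluded DNA (dnaFree = dnaN = 0 required)")
    if (model == "three_state" && abs(state["dnaN"]) > 1e-12)
        stop("model mismatch: the three-state model has no ",
             "nucleosome-occluded DNA (dnaN = 0 required)")
    invisible(TRUE)
}

#' Time derivatives of the promoter occupancy states
#'
#' Right-hand side of the mass-action rate equations at a given nuclear
#' Ikaros concentration. In the two-state model the site is always
#' occupied, either by EBF1 or by Ikaros; the three-state model adds an
#' unbound state through which all exchange must pass (Ikaros and EBF1
#' compete for the site only while it is free); the four-state model
#' additionally lets nucleosomes occlude free sites reversibly. The
#' derivatives always sum to zero (conservation of promoter DNA).
#'
#' @param state named numeric state vector (see [promoterState()]); the
#'   two-state model requires `dnaFree = dnaN = 0`, the three-state model
#'   `dnaN = 0`.
#' @param params A [RateParameters()] object. The nucleosome rates are
#'   ignored by (and cannot affect) the 2- and 3-state models.
#' @param ikaros nuclear Ikaros concentration (arbitrary units).
#' @param model one of `"two_state"`, `"three_state"`, `"four_state"`.
#' @return Named numeric of length 4: d/dt of `dnaE`, `dnaFree`, `dnaI`,
#'   `dnaN` (per minute).
#' @examples
#' occupancyDerivatives(promoterState(0.1, 0.8, 0.1), RateParameters(),
#'                      ikaros = 0.1, model = "three_state")
#' @export
occupancyDerivatives <- function(state, params, ikaros,
                                 model = c("three_state", "two_state",
                                           "four_state")) {
    model <- match.arg(model)
    state <- .asState(state)
    .checkModelState(model, state)
    p <- rateVector(params)
    d <- setNames(numeric(4), .STATE_NAMES)
    if (model == "two_state") {
        # direct exchange: EBF-DNA + Ikaros <=> Ikaros-DNA + EBF1,
        # with [EBF1] folded into kEon
        dE <- -p["kIon"] * ikaros * state["dnaE"] + p["kEon"] * state["dnaI"]
        d["dnaE"] <- dE
        d["dnaI"] <- -dE
    } else {
        d["dnaE"] <- -p["kEoff"] * state["dnaE"] +
            p["kEon"] * state["dnaFree"]
        d["dnaI"] <- p["kIon"] * ikaros * state["dnaFree"] -
            p["kIoff"] * state["dnaI"]
        if (model == "four_state")
            d["dnaN"] <- p["kNon"] * state["dnaFree"] -
                p["kNoff"] * state["dnaN"]
        d["dnaFree"] <- -(d["dnaE"] + d["dnaI"] + d["dnaN"])
    }
    d
}

#' Simulate promoter occupancy under a nuclear Ikaros schedule
#'
#' Integrates the chosen mass-action model with a stiff-capable adaptive
#' integrator ([deSolve::lsoda]), restarting at every schedule breakpoint
#' so the piecewise-constant Ikaros input is never smoothed across a jump.
#'
#' @param model `"two_state"`, `"three_state"` or `"four_state"`.
#' @param params A [RateParameters()] object.
#' @param schedule An [IkarosSchedule-class].
#' @param init initial state (named numeric, see [promoterState()]),
#'   holding at `times[1]`.
#' @param times sorted output times in minutes, `times[1] >= 0`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return A [PromoterTrajectory-class].
#' @examples
#' simulatePromoter("three_state", RateParameters(), constantSchedule(1),
#'                  promoterState(0.1, 0.8, 0.1), times = c(0, 5, 15, 30))
#' @export
simulatePromoter <- function(model = c("three_state", "two_state",
                                       "four_state"),
                             params = RateParameters(),
                             schedule = stepSchedule(),
                             init = promoterState(),
                             times = c(0, 5, 15, 30, 60, 120),
                             rtol = 1e-8, atol = 1e-10) {
    model <- match.arg(model)
    stopifnot(is(params, "RateParameters"), is(schedule, "IkarosSchedule"))
    validObject(params); validObject(schedule)
    if (is.unsorted(times, strictly = TRUE))
        stop("times must be strictly increasing")
    if (times[1] < 0)
        stop("times must start at or after 0")
    init <- .asState(init)
    .checkModelState(model, init)
    p <- rateVector(params)

    # inlined right-hand sides (same equations as occupancyDerivatives,
    # without per-call validation: this is the hot loop of the fitter)
    rhs <- if (model == "two_state") {
        function(t, y, parms) {
            dE <- -p[["kIon"]] * parms * y[1] + p[["kEon"]] * y[3]
            list(c(dE, 0, -dE, 0))
        }
    } else if (model == "three_state") {
        function(t, y, parms) {
            dE <- -p[["kEoff"]] * y[1] + p[["kEon"]] * y[2]
            dI <- p[["kIon"]] * parms * y[2] - p[["kIoff"]] * y[3]
            list(c(dE, -(dE + dI), dI, 0))
        }
    } else {
        function(t, y, parms) {
            dE <- -p[["kEoff"]] * y[1] + p[["kEon"]] * y[2]
            dI <- p[["kIon"]] * parms * y[2] - p[["kIoff"]] * y[3]
            dN <- p[["kNon"]] * y[2] - p[["kNoff"]] * y[4]
            list(c(dE, -(dE + dI + dN), dI, dN))
        }
    }

    t0 <- times[1]
    tEnd <- times[length(times)]
    breaks <- scheduleBreakpoints(schedule)
    breaks <- breaks[breaks > t0 & breaks < tEnd]
    segBounds <- c(t0, breaks, tEnd)

    states <- matrix(NA_real_, nrow = length(times), ncol = 4,
                     dimnames = list(NULL, .STATE_NAMES))
    states[1, ] <- init
    y <- init
    if (tEnd > t0) for (i in seq_len(length(segBounds) - 1L)) {
        a <- segBounds[i]; b <- segBounds[i + 1L]
        ik <- ikarosConcentration(schedule, a)
        segTimes <- unique(c(a, times[times > a & times < b], b))
        out <- tryCatch(
            deSolve::lsoda(y, segTimes, rhs, parms = ik,
                           rtol = rtol, atol = atol),
            warning = function(w) stop(sprintf(
                "integration failed on interval [%g, %g]: %s", a, b,
                conditionMessage(w)), call. = FALSE))
        if (attr(out, "istate")[1] < 0)
            stop(sprintf("integration failed on interval [%g, %g]", a, b))
        fill <- intersect(times, segTimes[-1])  # requested times in (a, b]
        states[match(fill, times), ] <- out[match(fill, segTimes), -1,
                                            drop = FALSE]
        y <- setNames(out[nrow(out), -1], .STATE_NAMES)
    }
    # the integrator keeps totals conserved to ~atol; clip tiny excursions
    states[states < 0 & states > -1e-9] <- 0
    new("PromoterTrajectory", times = as.numeric(times), states = states,
        modelId = model, params = params, schedule = schedule)
}

#' Closed-form equilibrium occupancy at constant Ikaros
#'
#' Fixed point of the rate equations at a constant nuclear Ikaros
#' concentration. With association/dissociation ratios `KE = kEon/kEoff`,
#' `KI = kIon * ikaros / kIoff` and (4-state) `KN = kNon/kNoff`, the
#' equilibrium fractions are `(KE, 1, KI, KN)` divided by the partition
#' sum. For the two-state model the site is always occupied and
#' `dnaI/dnaE = kIon * ikaros / kEon`.
#'
#' @inheritParams occupancyDerivatives
#' @param model model identifier.
#' @return Named numeric state vector at equilibrium.
#' @examples
#' equilibriumOccupancy("three_state", RateParameters(), ikaros = 1)
#' @export
equilibriumOccupancy <- function(model = c("three_state", "two_state",
                                           "four_state"),
                                 params = RateParameters(), ikaros = 1) {
    model <- match.arg(model)
    p <- rateVector(params)
    if (model == "two_state") {
        if (p["kEon"] <= 0)
            stop("no finite equilibrium: kEon must be > 0 for the ",
                 "two-state model")
        r <- unname(p["kIon"] * ikaros / p["kEon"])
        return(promoterState(dnaE = 1 / (1 + r), dnaFree = 0,
                             dnaI = r / (1 + r), dnaN = 0))
    }
    offs <- c(p["kEoff"], p["kIoff"],
              if (model == "four_state") p["kNoff"])
    if (any(offs <= 0))
        stop("no finite equilibrium: all dissociation rates must be > 0")
    KE <- unname(p["kEon"] / p["kEoff"])
    KI <- unname(p["kIon"] * ikaros / p["kIoff"])
    KN <- if (model == "four_state") unname(p["kNon"] / p["kNoff"]) else 0
    Z <- 1 + KE + KI + KN
    promoterState(dnaE = KE / Z, dnaFree = 1 / Z, dnaI = KI / Z,
                  dnaN = KN / Z)
}
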