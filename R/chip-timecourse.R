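## Welch two-sample t on small replicate groups, with the degenerate cases
## a 3-replicate qPCR design actually produces: both groups constant and
## equal -> p = 1; constant but unequal -> p -> 0 (flagged by attribute).
.welchP <- function(x, y) {
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
        p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
        return(structure(p, degenerate = p == 0))
    }
    structure(t.test(x, y, var.equal = FALSE)$p.value, degenerate = FALSE)
}

#' Summarise replicate kinetic-ChIP enrichments
#'
#' Per time point, log2 is applied per replicate and the mean and standard
#' error (sd/sqrt(n)) of the log2 values are reported, together with a
#' Welch t-test of each time point against the t = 0 baseline
#' (log2 scale, two-sided). The mean-of-logs convention makes the SE
#' symmetric on the reported scale and matches the t-test; `logOfMean`
#' reproduces the alternative log-of-mean reading (SE then from the delta
#' method is not attempted: the SE column reports sd/sqrt(n) of the log2
#' replicate values in both conventions).
#'
#' @param tc A [ChIPTimeCourse-class].
#' @param logOfMean logical; report `log2(mean(replicates))` instead of
#'   `mean(log2(replicates))`.
#' @return data.frame with columns `time_min`, `log2_mean`, `se`, `n`,
#'   `p_vs_t0` (`NA` at t = 0).
#' @examples
#' tc <- ChIPTimeCourse("Igll1", "Ikaros",
#'     data.frame(time_min = rep(c(0, 5), each = 3), replicate = rep(1:3, 2),
#'                enrichment = c(1, 1, 1, 1.8, 2.2, 2.1)))
#' summarizeTimeCourse(tc)
#' @export
summarizeTimeCourse <- function(tc, logOfMean = FALSE) {
    stopifnot(is(tc, "ChIPTimeCourse"))
    validObject(tc)
    d <- tc@data
    times <- sort(unique(d$time_min))
    base <- log2(d$enrichment[d$time_min == 0])
    out <- lapply(times, function(tt) {
        lv <- log2(d$enrichment[d$time_min == tt])
        p <- if (tt == 0) NA_real_ else {
            if (length(lv) < 2L || length(base) < 2L)
                stop("replicate count must be >= 2 at any tested time point")
            as.numeric(.welchP(lv, base))
        }
        data.frame(time_min = tt,
                   log2_mean = if (logOfMean) log2(mean(2^lv)) else mean(lv),
                   se = if (length(lv) > 1L) sd(lv) / sqrt(length(lv)) else 0,
                   n = length(lv), p_vs_t0 = p)
    })
    do.call(rbind, out)
}

#' Welch t-test of one time point against the t = 0 baseline
#'
#' Two-sample Welch (unequal-variance) t-test on the log2 replicate
#' enrichments at time `t` versus t = 0, two-sided. With zero variance in
#' both groups the p-value is 1 for equal means; for unequal means the
#' limiting value 0 is returned with a `degenerate` attribute set.
#'
#' @param tc A [ChIPTimeCourse-class].
#' @param t the time point (minutes) to test.
#' @return Two-sided p-value (with attribute `degenerate`).
#' @export
ttestVsBaseline <- function(tc, t) {
    stopifnot(is(tc, "ChIPTimeCourse"))
    d <- tc@data
    x <- log2(d$enrichment[d$time_min == t])
    y <- log2(d$enrichment[d$time_min == 0])
    if (length(x) < 2L || length(y) < 2L)
        stop("need >= 2 replicates at both t and t = 0")
    .welchP(x, y)
}

#' Time of half-maximal change of a summary curve
#'
#' The half level is the midpoint between the value at the first time point
#' and the asymptotic value (taken as the last time point). Returns the
#' first crossing of that level, linearly interpolated between the
#' bracketing samples; an exact sample hit returns that sample time. The
#' result is invariant under affine rescaling of the value axis. Used for
#' quantities like the half-maximal binding of Ikaros (within ~5 min of
#' translocation) or half-maximal RNAP2 removal (within ~12 min).
#'
#' @param times sample times (minutes), increasing; or a summary
#'   data.frame with `time_min` and `log2_mean` columns (then `values` is
#'   ignored).
#' @param values curve values at `times`.
#' @return First crossing time in minutes.
#' @examples
#' timeToHalfChange(c(0, 10, 20, 30), c(1, 0.8, 0.2, 0.2))  # 13.33
#' @export
timeToHalfChange <- function(times, values = NULL) {
    if (is.data.frame(times)) {
        values <- times$log2_mean
        times <- times$time_min
    }
    if (length(times) < 2L)
        stop("need at least 2 points")
    if (is.unsorted(times, strictly = TRUE))
        stop("times must be strictly increasing")
    v <- values
    half <- (v[1] + v[length(v)]) / 2
    if (v[1] == v[length(v)])
        stop("net change is zero; no half-change time")
    for (i in seq_len(length(v) - 1L)) {
        if (v[i] == half) return(times[i])
        if ((v[i] - half) * (v[i + 1L] - half) < 0 ||
            (v[i + 1L] == half && v[i] != half))
            return(times[i] + (half - v[i]) / (v[i + 1L] - v[i]) *
                       (times[i + 1L] - times[i]))
    }
    stop("curve never crosses its half-change level")
}

#' Read / write kinetic time-course tables
#'
#' Tab-separated dialect: columns `target`, `factor`, `time_min`,
#' `replicate`, `enrichment`. Enrichment is fold over the t = 0 baseline
#' and must be positive; violations are reported with the offending row
#' number.
#'
#' @param path file path.
#' @return `readTimeCourseTable`: a named list of
#'   [ChIPTimeCourse-class] objects, one per target/factor combination.
#' @export
readTimeCourseTable <- function(path) {
    d <- .readStrict(path, c(target = "character", factor = "character",
                             time_min = "numeric", replicate = "character",
                             enrichment = "numeric"))
    bad <- which(d$enrichment <= 0)
    if (length(bad))
        stop(sprintf("%s: enrichment must be > 0 (row %d)", path, bad[1]))
    keys <- interaction(d$target, d$factor, drop = TRUE, sep = " / ")
    lapply(split(d, keys), function(g)
        ChIPTimeCourse(g$target[1], g$factor[1],
                       g[c("time_min", "replicate", "enrichment")]))
}

#' @rdname readTimeCourseTable
#' @param tcs a list of [ChIPTimeCourse-class] objects (or a single one).
#' @export
writeTimeCourseTable <- function(tcs, path) {
    if (is(tcs, "ChIPTimeCourse")) tcs <- list(tcs)
    d <- do.call(rbind, lapply(tcs, function(tc)
        data.frame(target = tc@target, factor = tc@factorName,
                   tc@data[c("time_min", "replicate", "enrichment")])))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
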