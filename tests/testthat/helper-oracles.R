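# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: linear-algebra propagation instead of the ODE
# integrator, exhaustive enumeration instead of fisher.test, position-wise
# loops instead of Rle coverage.

# Rate matrix A of the linear system dy/dt = A y at constant Ikaros,
# state order (dnaE, dnaFree, dnaI, dnaN).
rateMatrixOracle <- function(params, ikaros, model) {
    p <- rateVector(params)
    A <- matrix(0, 4, 4)
    if (model == "two_state") {
        A[1, 1] <- -p["kIon"] * ikaros; A[1, 3] <- p["kEon"]
        A[3, 1] <- p["kIon"] * ikaros;  A[3, 3] <- -p["kEon"]
        return(A)
    }
    A[1, 1] <- -p["kEoff"]; A[1, 2] <- p["kEon"]
    A[3, 2] <- p["kIon"] * ikaros; A[3, 3] <- -p["kIoff"]
    if (model == "four_state") {
        A[4, 2] <- p["kNon"]; A[4, 4] <- -p["kNoff"]
    }
    A[2, ] <- -colSums(A)
    A
}

# Trajectory at constant Ikaros via the matrix exponential.
expmTrajectoryOracle <- function(model, params, ikaros, init, times) {
    A <- rateMatrixOracle(params, ikaros, model)
    t(vapply(times, function(tt) {
        as.numeric(Matrix::expm(A * (tt - times[1])) %*% init)
    }, numeric(4)))
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive enumeration of
# all tables with the observed margins.
fisherEnumOracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    aRange <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(aRange, function(a)
        choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1),
        numeric(1))
    pObs <- probs[aRange == tab[1, 1]]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# First crossing of the midpoint between first and last value, linearly
# interpolated on a dense grid.
halfCrossOracle <- function(t, v) {
    h <- (v[1] + v[length(v)]) / 2
    i <- which((v[-length(v)] - h) * (v[-1] - h) <= 0 &
                   v[-length(v)] != v[-1])[1]
    t[i] + (h - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

# Per-base coverage of fragments on one contig by explicit counting.
coverageLoopOracle <- function(starts, ends, len) {
    cov <- numeric(len)
    for (i in seq_along(starts))
        cov[starts[i]:ends[i]] <- cov[starts[i]:ends[i]] + 1
    cov
}

randomRates <- function() {
    RateParameters(kIon = runif(1, 0.01, 1), kIoff = runif(1, 0.01, 0.5),
                   kEon = runif(1, 0.01, 0.5), kEoff = runif(1, 0.01, 0.5),
                   kNon = runif(1, 0.01, 0.5), kNoff = runif(1, 0.005, 0.2))
}
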