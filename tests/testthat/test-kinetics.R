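test_that("schedule evaluation follows the right-closed piecewise rule", {
    # constant after a step at t = 0
    expect_equal(ikarosConcentration(stepSchedule(0.1, 1, at = 0), 10), 1)
    expect_equal(ikarosConcentration(stepSchedule(0.1, 1, at = 0), 0), 1)
    # additive reading: start 0.1, +2.0 per 5 min, 3 steps
    sch <- incrementalSchedule(0.1, 2, 5, 3)
    expect_equal(ikarosConcentration(sch, 7), 2.1)
    expect_equal(ikarosConcentration(sch, 0), 0.1)
    expect_equal(ikarosConcentration(sch, c(4.999, 5)), c(0.1, 2.1))
    expect_equal(ikarosConcentration(sch, 1e4), 6.1)  # plateau after nSteps
    # multiplicative mode and cap
    schM <- incrementalSchedule(0.1, 2, 5, 4, mode = "multiplicative",
                                cap = 0.5)
    expect_equal(ikarosConcentration(schM, c(0, 6, 11, 100)),
                 c(0.1, 0.2, 0.4, 0.5))
    # schedules are non-decreasing in time
    tt <- seq(0, 100, by = 0.5)
    expect_true(all(diff(ikarosConcentration(sch, tt)) >= 0))
    expect_error(ikarosConcentration(sch, Inf), "finite")
    expect_error(incrementalSchedule(0.1, 2, intervalMin = 0, nSteps = 3),
                 "invalid schedule")
    expect_error(incrementalSchedule(0.1, 2, 5, nSteps = -1),
                 "invalid schedule")
})

test_that("two-state derivatives are exactly antisymmetric", {
    p <- RateParameters()
    d <- occupancyDerivatives(c(dnaE = 1, dnaFree = 0, dnaI = 0, dnaN = 0),
                              p, ikaros = 1, model = "two_state")
    expect_equal(unname(d[c("dnaI", "dnaE")]), c(0.3, -0.3))
    d2 <- occupancyDerivatives(c(dnaE = 0.5, dnaFree = 0, dnaI = 0.5,
                                 dnaN = 0), p, ikaros = 0, "two_state")
    expect_equal(unname(d2["dnaI"]), -0.018)
    # equilibrium ratio kIon*ik/kEon: derivatives vanish
    dEq <- occupancyDerivatives(c(dnaE = 0.1071, dnaFree = 0,
                                  dnaI = 0.8929, dnaN = 0), p, 1,
                                "two_state")
    expect_true(all(abs(dEq) < 1e-3))
    expect_error(
        occupancyDerivatives(promoterState(0.1, 0.8, 0.1), p, 1,
                             "two_state"),
        "model mismatch")
})

test_that("three- and four-state derivatives match direct substitution", {
    p <- RateParameters()
    s <- promoterState(0.1, 0.8, 0.1)
    d3 <- occupancyDerivatives(s, p, ikaros = 0.1, model = "three_state")
    expect_equal(unname(d3[c("dnaE", "dnaFree", "dnaI")]),
                 c(0.0255, -0.0443, 0.0188), tolerance = 1e-12)
    d4 <- occupancyDerivatives(s, p, ikaros = 0.1, model = "four_state")
    expect_equal(unname(d4), c(0.0255, -0.1483, 0.0188, 0.1040),
                 tolerance = 1e-12)
    # zero rates freeze the system
    z <- RateParameters(0, 0, 0, 0, 0, 0)
    expect_equal(unname(occupancyDerivatives(s, z, 5, "three_state")),
                 rep(0, 4))
    # conservation and model nesting hold for random states and rates
    withr::with_seed(42, for (i in 1:10) {
        rp <- randomRates()
        st <- runif(4); st <- st / sum(st)
        names(st) <- c("dnaE", "dnaFree", "dnaI", "dnaN")
        ik <- runif(1, 0, 5)
        expect_equal(sum(occupancyDerivatives(st, rp, ik, "four_state")), 0)
        st3 <- st; st3["dnaFree"] <- st3["dnaFree"] + st3["dnaN"]
        st3["dnaN"] <- 0
        expect_equal(sum(occupancyDerivatives(st3, rp, ik, "three_state")),
                     0)
        rp0 <- RateParameters(rateVector(rp)["kIon"],
                              rateVector(rp)["kIoff"],
                              rateVector(rp)["kEon"],
                              rateVector(rp)["kEoff"], 0, 0)
        expect_equal(occupancyDerivatives(st3, rp0, ik, "four_state"),
                     occupancyDerivatives(st3, rp0, ik, "three_state"))
    })
    expect_error(occupancyDerivatives(c(dnaE = 0.5, dnaFree = 0.2,
                                        dnaI = 0.2, dnaN = 0.1),
                                      p, 1, "three_state"),
                 "model mismatch")
})

test_that("simulated trajectories conserve occupancy and hit equilibria", {
    p <- RateParameters()
    tr <- simulatePromoter("three_state", p, constantSchedule(1),
                           promoterState(0.1, 0.8, 0.1),
                           times = c(0, 5, 15, 30, 60, 120, 500))
    S <- trajectoryStates(tr)
    expect_true(all(abs(rowSums(S) - 1) < 1e-9))
    expect_equal(unname(S[nrow(S), 1:3]), c(0.1388, 0.1272, 0.7340),
                 tolerance = 1e-4)
    # all rates zero: trajectory frozen at init
    z <- RateParameters(0, 0, 0, 0, 0, 0)
    trz <- simulatePromoter("three_state", z, constantSchedule(1),
                            promoterState(0.1, 0.8, 0.1), c(0, 10, 100))
    expect_true(all(abs(sweep(trajectoryStates(trz), 2,
                              promoterState(0.1, 0.8, 0.1))) < 1e-12))
    # 4-state with nucleosome rates zero reproduces the 3-state trajectory
    p0 <- RateParameters(kNon = 0, kNoff = 0)
    tr3 <- simulatePromoter("three_state", p0, incrementalSchedule(),
                            promoterState(0.1, 0.8, 0.1), c(0, 5, 15, 60))
    tr4 <- simulatePromoter("four_state", p0, incrementalSchedule(),
                            promoterState(0.1, 0.8, 0.1), c(0, 5, 15, 60))
    expect_equal(trajectoryStates(tr3), trajectoryStates(tr4),
                 tolerance = 1e-7)
    expect_error(simulatePromoter("three_state", p, constantSchedule(1),
                                  promoterState(0.1, 0.8, 0.1),
                                  times = c(5, 5, 10)),
                 "strictly increasing")
})

test_that("equilibria follow the closed-form partition and kill the
           derivatives", {
    p <- RateParameters()
    eq3 <- equilibriumOccupancy("three_state", p, 1)
    expect_equal(unname(eq3[1:3]), c(0.1388, 0.1272, 0.7340),
                 tolerance = 1e-4)
    eq4 <- equilibriumOccupancy("four_state", p, 1)
    expect_equal(unname(eq4), c(0.0213, 0.0195, 0.1127, 0.8465),
                 tolerance = 1e-4)
    # no Ikaros: no Ikaros-bound DNA, dnaE/dnaFree = KE
    eq0 <- equilibriumOccupancy("three_state", p, 0)
    expect_equal(unname(eq0["dnaI"]), 0)
    expect_equal(unname(eq0["dnaE"] / eq0["dnaFree"]), 0.036 / 0.033)
    # fixed-point consistency across random parameter sets
    withr::with_seed(7, for (i in 1:10) {
        rp <- randomRates()
        ik <- runif(1, 0.1, 5)
        for (m in c("two_state", "three_state", "four_state")) {
            eq <- equilibriumOccupancy(m, rp, ik)
            expect_true(all(abs(occupancyDerivatives(eq, rp, ik, m)) <
                                1e-10))
        }
    })
    expect_error(equilibriumOccupancy("three_state",
                                      RateParameters(kIoff = 0), 1),
                 "no finite equilibrium")
    expect_error(equilibriumOccupancy("two_state",
                                      RateParameters(kEon = 0), 1),
                 "no finite equilibrium")
})

test_that("the integrator matches a matrix-exponential oracle at constant
           input", {
    withr::with_seed(11, for (i in 1:10) {
        rp <- randomRates()
        ik <- runif(1, 0.1, 3)
        model <- sample(c("three_state", "four_state"), 1)
        init <- promoterState(0.1, 0.8, 0.1)
        times <- c(0, 2, 7, 20, 61, 150)
        sim <- trajectoryStates(simulatePromoter(model, rp,
                                                 constantSchedule(ik),
                                                 init, times))
        orc <- expmTrajectoryOracle(model, rp, ik, init, times)
        expect_lt(max(abs(sim - orc)), 1e-8)
    })
})

test_that("piecewise schedules are integrated segment-by-segment, matching
           chained matrix exponentials", {
    # oracle: propagate through each constant segment separately
    p <- RateParameters()
    sch <- incrementalSchedule(0.1, 2, 5, 3)
    times <- c(0, 2.5, 5, 7.5, 12, 15, 40)
    sim <- trajectoryStates(simulatePromoter("four_state", p, sch,
                                             promoterState(0.1, 0.8, 0.1),
                                             times))
    y <- promoterState(0.1, 0.8, 0.1)
    bounds <- c(0, 5, 10, 15, 40)
    out <- matrix(NA_real_, length(times), 4); out[1, ] <- y
    for (i in seq_len(length(bounds) - 1)) {
        a <- bounds[i]; b <- bounds[i + 1]
        A <- rateMatrixOracle(p, ikarosConcentration(sch, a), "four_state")
        for (tt in times[times > a & times <= b]) {
            out[match(tt, times), ] <-
                as.numeric(Matrix::expm(A * (tt - a)) %*% y)
        }
        y <- as.numeric(Matrix::expm(A * (b - a)) %*% y)
    }
    expect_lt(max(abs(sim - out)), 1e-8)
})

test_that("two-state dynamics are strictly complementary", {
    tr <- simulatePromoter("two_state", RateParameters(),
                           stepSchedule(0.1, 1, at = 0),
                           c(dnaE = 0.9, dnaFree = 0, dnaI = 0.1,
                             dnaN = 0), times = seq(0, 120, by = 1))
    S <- trajectoryStates(tr)
    expect_true(all(abs(S[, "dnaE"] + S[, "dnaI"] - 1) < 1e-9))
    expect_true(all(diff(S[, "dnaI"]) >= -1e-12))
    expect_true(all(diff(S[, "dnaE"]) <= 1e-12))
})

test_that("Ikaros binding leads and activator eviction lags after a step
           from the pre-induction steady state", {
    # brute-force dense simulation, then frozen crossing times
    p <- RateParameters()
    init <- equilibriumOccupancy("three_state", p, 0.1)
    dense <- seq(0, 300, by = 0.05)
    S <- trajectoryStates(simulatePromoter("three_state", p,
                                           stepSchedule(0.1, 1, at = 0),
                                           init, dense))
    tI <- halfCrossOracle(dense, S[, "dnaI"])
    tE <- halfCrossOracle(dense, S[, "dnaE"])
    expect_lt(tI, tE)
    # regression values from a 0.01-min grid
    expect_equal(tI, 5.571, tolerance = 0.01)
    expect_equal(tE, 22.554, tolerance = 0.01)
})

test_that("nucleosome occlusion lowers the equilibrium activator binding
           under the same incremental schedule", {
    p <- RateParameters()
    sch <- incrementalSchedule()
    init <- promoterState(0.1, 0.8, 0.1)
    f3 <- trajectoryStates(simulatePromoter("three_state", p, sch, init,
                                            c(0, 360)))[2, ]
    f4 <- trajectoryStates(simulatePromoter("four_state", p, sch, init,
                                            c(0, 360)))[2, ]
    expect_lt(f4[["dnaE"]], f3[["dnaE"]])
    # regression values from the dense brute-force run
    expect_equal(f3[["dnaE"]], 0.007732, tolerance = 1e-4)
    expect_equal(f4[["dnaE"]], 0.005485, tolerance = 1e-4)
})
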