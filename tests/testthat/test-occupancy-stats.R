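test_that("differential region test follows the documented arithmetic", {
    r0 <- differentialRegion(c(100, 100, 100), c(100, 100, 100))
    expect_equal(r0$log2fc, 0)
    expect_equal(r0$p, 1)
    r <- differentialRegion(c(100, 100, 100), c(25, 25, 25))
    expect_equal(r$log2fc, log2(25.5 / 100.5))   # ~ -2 with pseudocount
    expect_equal(r$log2fc, -2, tolerance = 0.02)
    rz <- differentialRegion(c(0, 0, 0), c(0, 0, 0))
    expect_true(rz$lowCount)
    expect_equal(rz$p, 1); expect_equal(rz$log2fc, 0)
    # size factors rescale the comparison
    rs <- differentialRegion(c(100, 100, 100), c(100, 100, 100),
                             sfBefore = 1, sfAfter = 2)
    expect_equal(rs$log2fc, log2(50.5 / 100.5))
    expect_error(differentialRegion(c(100), c(100, 100)), "replicates")
    expect_error(differentialRegion(c(1, 2), c(1, 2), sfBefore = 0),
                 "size factors")
})

test_that("median-of-ratios size factors agree with the reference
           implementation", {
    skip_if_not_installed("DESeq2")
    counts <- withr::with_seed(5, matrix(rnbinom(600, mu = 200, size = 20),
                                         ncol = 6))
    counts[, 4:6] <- counts[, 4:6] * 3L  # a 3x deeper library
    sf <- sizeFactorsMedianRatio(counts)
    ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
    expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
    expect_equal(unname(sf[4] / sf[1]), 3, tolerance = 0.1)
})

test_that("redistribution classes follow the alpha/delta rule by
           construction", {
    # three planted genes with unambiguous counts, plus nulls to give BH
    # something to adjust over
    mk <- function(gene, tssB, tssA, bodyB, bodyA) {
        expand.grid(gene = gene, region = c("TSS", "body"),
                    condition = c("before", "after"), replicate = 1:3,
                    stringsAsFactors = FALSE) |>
            transform(count = ifelse(region == "TSS",
                                     ifelse(condition == "before", tssB,
                                            tssA),
                                     ifelse(condition == "before", bodyB,
                                            bodyA)))
    }
    jitter3 <- function(x) x + c(-8, 0, 8)
    tabs <- list(mk("gGlobal", 800, 200, 800, 200),      # both -2
                 mk("gTssGtBody", 800, 695, 800, 140),   # -0.2 vs -2.5
                 mk("gUnchanged", 800, 800, 800, 800))
    nulls <- lapply(sprintf("null%02d", 1:20), function(g)
        mk(g, 800, 800, 800, 800))
    counts <- do.call(rbind, c(tabs, nulls))
    counts$count <- withr::with_seed(8, ave(counts$count, counts$gene,
                                            counts$region,
                                            counts$condition,
                                            FUN = jitter3))
    res <- classifyOccupancy(counts, alpha = 0.05, delta = 1,
                             sizeFactors = setNames(rep(1, 6), sort(
                                 unique(paste(counts$condition,
                                              counts$replicate,
                                              sep = ".")))))
    cls <- setNames(res$occupancy_class, res$gene)
    expect_equal(unname(cls["gGlobal"]), "reduced_global")
    expect_equal(unname(cls["gTssGtBody"]), "reduced_tss_gt_body")
    expect_equal(unname(cls["gUnchanged"]), "unchanged")
    # BH monotonicity: adjusted p respects the raw ordering
    ord <- order(res$p_global)
    expect_true(all(diff(res$padj_global[ord]) >= -1e-12))
    # incomplete gene rejected
    expect_error(classifyOccupancy(counts[counts$region == "TSS", ]),
                 "incomplete|both regions")
})

test_that("crosstab counts are conserved and reproduce planted labels", {
    occ <- simulateGeneOccupancy(seed = 2)
    ct <- occupancyCrosstab(occ$truth)
    # planted counts recovered exactly
    expect_equal(ct$n[ct$expression_class == "down" &
                          ct$direction == "reduced" &
                          ct$pattern %in% "global"], 150)
    # pattern counts sum to direction totals
    for (e in c("unchanged", "down", "up"))
        for (d in c("reduced", "increased")) {
            tot <- ct$n[ct$expression_class == e & ct$direction == d &
                            is.na(ct$pattern)]
            pats <- sum(ct$n[ct$expression_class == e &
                                 ct$direction == d & !is.na(ct$pattern)])
            expect_equal(pats, tot)
        }
    # direction totals sum to the expression-class size
    expect_equal(sum(ct$n[ct$expression_class == "down" &
                              is.na(ct$pattern)]),
                 sum(occ$truth$expression_class == "down"))
    empty <- occupancyCrosstab(data.frame(expression_class = character(0),
                                          occupancy_class = character(0)))
    expect_true(all(empty$n == 0))
})

test_that("overlap odds ratios are cross-product ratios with a Fisher
           exact p", {
    universe <- paste0("g", 1:1000)
    a <- universe[1:100]; b <- universe[51:150]
    res <- overlapOddsRatio(1000, a, b)
    expect_equal(unname(as.numeric(res$table)), c(50, 50, 50, 850))
    expect_equal(res$oddsRatio, 17)
    # independence
    u2 <- paste0("g", 1:100)
    res2 <- overlapOddsRatio(100, u2[1:50], u2[c(1:25, 51:75)])
    expect_equal(res2$oddsRatio, 1)
    # symmetry
    res3 <- overlapOddsRatio(1000, b, a)
    expect_equal(res3$oddsRatio, res$oddsRatio)
    expect_equal(res3$p, res$p)
    # Fisher p matches the exhaustive enumeration oracle
    a4 <- c("g1", "g2", "g3", "g4"); b4 <- c("g1", "g2", "g3", "g5")
    res4 <- overlapOddsRatio(8, a4, b4)
    expect_equal(res4$table[1, 1], 3)
    expect_equal(res4$p, fisherEnumOracle(res4$table), tolerance = 1e-10)
    expect_error(overlapOddsRatio(10, paste0("g", 1:8), paste0("h", 1:8)),
                 "inconsistent")
    # zero-cell table gets the Haldane-Anscombe correction
    res5 <- overlapOddsRatio(100, paste0("g", 1:10), paste0("g", 1:10))
    expect_true(is.finite(res5$oddsRatio))
})

test_that("the repositioning GLM behaves across identical, extreme and
           degenerate contrasts", {
    same <- data.frame(condition = rep(c("a", "b"), each = 3),
                       replicate = rep(1:3, 2),
                       associated = rep(100 / 3 * 3, 6) / 3 * 1,
                       total = 100)
    same$associated <- rep(c(33, 33, 34), 2)
    rSame <- repositioningTest(same)
    expect_gt(rSame$waldP[["b"]], 0.99)
    # 8% vs 78%: overwhelming and agreeing with Fisher in magnitude
    big <- data.frame(condition = rep(c("a", "b"), each = 3),
                      replicate = rep(1:3, 2),
                      associated = c(8, 8, 8, 78, 78, 78), total = 100)
    rBig <- repositioningTest(big)
    expect_lt(rBig$waldP[["b"]], 1e-15)
    fTab <- matrix(c(24, 276, 234, 66), 2, byrow = TRUE)
    fP <- fisher.test(fTab)$p.value
    expect_lt(abs(log10(rBig$lrP) - log10(fP)), 1)
    # complete separation is continuity-handled and flagged
    sep <- data.frame(condition = rep(c("a", "b"), each = 3),
                      replicate = rep(1:3, 2),
                      associated = c(0, 0, 0, 78, 78, 78), total = 100)
    rSep <- repositioningTest(sep)
    expect_true(rSep$separation)
    expect_true(is.finite(rSep$waldP[["b"]]))
    expect_error(repositioningTest(big[big$condition == "a", ]),
                 "insufficient contrast")
    expect_error(repositioningTest(transform(big, total = 0)), "totals")
})
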