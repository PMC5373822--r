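#' Simulate replicate kinetic-ChIP time courses from a competition model
#'
#' Simulates the chosen model under its Ikaros schedule, maps the
#' Ikaros-bound fraction to an "Ikaros" ChIP series and the EBF1-bound
#' fraction to an "EBF1" series (unit proportionality scale), and applies
#' independent multiplicative log-normal noise per replicate: each
#' measurement is the model value times `2^rnorm(0, noiseSd)`, matching
#' the log2 reporting convention of ChIP-qPCR. Deterministic per seed.
#'
#' @param model,params,schedule,init,times as in [simulatePromoter()]. The
#'   default times are the experimental sampling points
#'   0/5/15/30/60/120 min.
#' @param nReps number of biological replicates (default 3).
#' @param noiseSd standard deviation of the log2-scale noise (default
#'   0.1).
#' @param target locus label stamped on the output.
#' @param seed integer seed.
#' @return Named list of [ChIPTimeCourse-class] objects (`Ikaros`,
#'   `EBF1`), with the noiseless trajectory in `attr(, "trajectory")`.
#' @export
simulateChipTimeCourses <- function(model = "three_state",
                                    params = RateParameters(),
                                    schedule = stepSchedule(0.1, 1),
                                    init = promoterState(0.1, 0.8, 0.1),
                                    times = c(0, 5, 15, 30, 60, 120),
                                    nReps = 3L, noiseSd = 0.1,
                                    target = "Igll1", seed = 1L) {
    if (noiseSd < 0)
        stop("config error: noiseSd must be >= 0")
    if (nReps < 1L)
        stop("config error: nReps must be >= 1")
    tr <- simulatePromoter(model, params, schedule, init, times)
    S <- trajectoryStates(tr)
    series <- c(Ikaros = "dnaI", EBF1 = "dnaE")
    out <- withr::with_seed(seed, {
        lapply(series, function(stateCol) {
            d <- expand.grid(replicate = seq_len(nReps), time_min = times)
            mu <- S[match(d$time_min, times), stateCol]
            d$enrichment <- mu * 2^rnorm(nrow(d), 0, noiseSd)
            d[c("time_min", "replicate", "enrichment")]
        })
    })
    res <- lapply(names(series), function(nm)
        ChIPTimeCourse(target, nm, out[[nm]]))
    names(res) <- names(series)
    attr(res, "trajectory") <- tr
    res
}

.PLANTED_FC <- function(log2fc, deltaMargin) {
    half <- deltaMargin
    list(unchanged = c(tss = 0, body = 0),
         reduced_global = c(tss = -log2fc, body = -log2fc),
         reduced_tss_gt_body = c(tss = -log2fc + half, body = -log2fc - half),
         reduced_tss_lt_body = c(tss = -log2fc - half, body = -log2fc + half),
         increased_global = c(tss = log2fc, body = log2fc),
         increased_tss_gt_body = c(tss = log2fc + half, body = log2fc - half),
         increased_tss_lt_body = c(tss = log2fc - half, body = log2fc + half))
}

#' Simulate per-gene TSS/body count tables with planted occupancy classes
#'
#' Negative-binomial counts per gene, region (TSS/body), condition
#' (before/after) and replicate, with a class-specific log2 fold change
#' planted between conditions. The seven planted classes are those of
#' [classifyOccupancy()]; regional classes offset the TSS and body fold
#' changes by `+deltaMargin` and `-deltaMargin` around the shared effect
#' size (so the planted TSS-body separation is `2 * deltaMargin`). Truth
#' labels are always returned alongside the counts.
#'
#' @param nPerClass named integer vector of genes per class. The defaults
#'   (1000 genes: 500 unchanged, 150 per global changed class, 50 per
#'   regional class, directions balanced) keep the majority of genes
#'   unchanged — the assumption median-of-ratios normalisation relies on —
#'   while still planting enough regional genes to test pattern recovery.
#' @param baseMean mean count per region in the "before" condition.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param log2fc planted absolute whole-gene log2 fold change.
#' @param deltaMargin separation of TSS and body fold changes in the
#'   regional classes (log2 units).
#' @param nReps replicates per condition.
#' @param seed integer seed.
#' @return List with `counts` (long data.frame: `gene`, `region`,
#'   `condition`, `replicate`, `count`) and `truth` (`gene`,
#'   `expression_class`, `occupancy_class`). The planted expression class
#'   mirrors the occupancy direction (`down`, `up`, `unchanged`).
#' @export
simulateGeneOccupancy <- function(nPerClass = c(
                                      unchanged = 500L,
                                      reduced_global = 150L,
                                      reduced_tss_gt_body = 50L,
                                      reduced_tss_lt_body = 50L,
                                      increased_global = 150L,
                                      increased_tss_gt_body = 50L,
                                      increased_tss_lt_body = 50L),
                                  baseMean = 800, dispersion = 0.05,
                                  log2fc = 2, deltaMargin = 1.5,
                                  nReps = 3L, seed = 1L) {
    if (dispersion <= 0)
        stop("config error: dispersion must be > 0")
    if (any(nPerClass < 0) || sum(nPerClass) < 1)
        stop("config error: gene counts must be positive")
    if (!all(names(nPerClass) %in% .OCCUPANCY_CLASSES))
        stop("config error: unknown occupancy class in nPerClass")
    fcs <- .PLANTED_FC(log2fc, deltaMargin)
    classes <- rep(names(nPerClass), nPerClass)
    genes <- sprintf("gene%04d", seq_along(classes))
    grid <- expand.grid(gene = genes, region = c("TSS", "body"),
                        condition = c("before", "after"),
                        replicate = seq_len(nReps),
                        stringsAsFactors = FALSE)
    cls <- classes[match(grid$gene, genes)]
    fc <- mapply(function(cl, rg) fcs[[cl]][[rg]], cls,
                 ifelse(grid$region == "TSS", "tss", "body"))
    mu <- ifelse(grid$condition == "before", baseMean, baseMean * 2^fc)
    counts <- withr::with_seed(seed,
        rnbinom(nrow(grid), mu = mu, size = 1 / dispersion))
    grid$count <- counts
    direction <- sub("_(global|tss_gt_body|tss_lt_body)$", "", classes)
    truth <- data.frame(gene = genes,
                        expression_class = c(unchanged = "unchanged",
                                             reduced = "down",
                                             increased = "up")[direction],
                        occupancy_class = classes,
                        row.names = NULL)
    list(counts = grid[order(grid$gene, grid$region, grid$condition,
                             grid$replicate), ],
         truth = truth)
}

#' Simulate allele-repositioning scores per condition and replicate
#'
#' Binomial draws of the number of alleles scored as associated with
#' pericentromeric heterochromatin, per replicate, around fixed true
#' proportions per condition. The default proportions (8%, 78%, 55%, 13%)
#' and scoring depth (>= 300 alleles per condition across 3 replicates)
#' mirror the published 3D-FISH design: uninduced cells, induced cells,
#' induction under HDAC inhibition, and induction after CHD4 knockdown.
#'
#' @param proportions named vector of true association proportions per
#'   condition.
#' @param nAllelesPerRep alleles scored per replicate (default 100, so
#'   300 per condition).
#' @param nReps replicates per condition.
#' @param seed integer seed.
#' @return data.frame with columns `condition`, `replicate`, `associated`,
#'   `total`.
#' @export
simulateFishCounts <- function(proportions = c(control = 0.08,
                                               induced = 0.78,
                                               induced_tsa = 0.55,
                                               induced_shChd4 = 0.13),
                               nAllelesPerRep = 100L, nReps = 3L,
                               seed = 1L) {
    if (any(proportions < 0 | proportions > 1))
        stop("config error: proportions must lie in [0, 1]")
    if (nAllelesPerRep < 1L)
        stop("config error: nAllelesPerRep must be >= 1")
    d <- expand.grid(replicate = seq_len(nReps),
                     condition = names(proportions),
                     stringsAsFactors = FALSE)
    d$total <- nAllelesPerRep
    d$associated <- withr::with_seed(seed,
        rbinom(nrow(d), nAllelesPerRep, proportions[d$condition]))
    d[c("condition", "replicate", "associated", "total")]
}

#' Simulate mono-nucleosome fragments around planted dyads
#'
#' Places fragments centred on planted nucleosome dyads: per fragment, a
#' dyad is drawn uniformly from the active set, the midpoint is jittered
#' by `Normal(0, jitterSd)` and the length drawn from
#' `Normal(lengthMean, lengthSd)` truncated to `[50, 300]` bp. The
#' "before" condition omits dyads inside the declared nucleosome-free
#' interval (an open promoter); the "after" condition includes them (the
#' promoter occluded by nucleosomes after repressor translocation).
#'
#' @param dyads integer positions (bp, 0-based) of planted dyads.
#' @param contigLength length of the synthetic contig.
#' @param nfrInterval `c(start, end)` of the nucleosome-free interval
#'   (0-based half-open).
#' @param nFragments fragments per condition.
#' @param lengthMean,lengthSd fragment length distribution (bp); the
#'   147 bp default is the DNA content of a full nucleosome core.
#' @param jitterSd positional jitter of fragment midpoints around the
#'   dyad (bp).
#' @param contig contig name.
#' @param seed integer seed.
#' @return List of two `GRanges` (`before`, `after`).
#' @export
simulateMnaseFragments <- function(dyads = seq(200L, 4800L, by = 180L),
                                   contigLength = 5000L,
                                   nfrInterval = c(2300L, 2700L),
                                   nFragments = 5000L,
                                   lengthMean = 147, lengthSd = 15,
                                   jitterSd = 10, contig = "chrS",
                                   seed = 1L) {
    if (any(dyads < 0 | dyads >= contigLength))
        stop("config error: dyads must lie within the contig")
    if (nfrInterval[1] < 0 || nfrInterval[2] > contigLength ||
        nfrInterval[1] >= nfrInterval[2])
        stop("config error: nucleosome-free interval outside the contig")
    if (lengthSd < 0 || jitterSd < 0)
        stop("config error: standard deviations must be >= 0")
    inNfr <- dyads >= nfrInterval[1] & dyads < nfrInterval[2]
    dyadSets <- list(before = dyads[!inNfr], after = dyads)
    withr::with_seed(seed, {
        lapply(dyadSets, function(ds) {
            ctr <- ds[sample.int(length(ds), nFragments, replace = TRUE)] +
                round(rnorm(nFragments, 0, jitterSd))
            len <- round(rnorm(nFragments, lengthMean, lengthSd))
            len <- pmin(pmax(len, 50L), 300L)
            s0 <- pmax(ctr - floor(len / 2), 0L)
            e0 <- pmin(s0 + len, contigLength)
            GRanges(contig, IRanges(start = s0 + 1L, end = e0),
                    seqlengths = setNames(contigLength, contig))
        })
    })
}
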