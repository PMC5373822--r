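.OCCUPANCY_CLASSES <- c("unchanged",
                        "reduced_global", "reduced_tss_gt_body",
                        "reduced_tss_lt_body",
                        "increased_global", "increased_tss_gt_body",
                        "increased_tss_lt_body")
.PATTERNS <- c("global", "tss_gt_body", "tss_lt_body")

#' Median-of-ratios size factors
#'
#' The classical count normalisation: per sample, the median across
#' features of the ratio of its counts to the per-feature geometric mean
#' (features with a zero geometric mean are dropped).
#'
#' @param counts numeric matrix, features x samples.
#' @return Numeric vector of positive size factors, one per column.
#' @export
sizeFactorsMedianRatio <- function(counts) {
    counts <- as.matrix(counts)
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use))
        stop("no feature has all-positive counts; size factors undefined")
    sf <- apply(counts[use, , drop = FALSE], 2, function(col)
        exp(stats::median(log(col) - logGeo[use])))
    if (any(!is.finite(sf) | sf <= 0))
        stop("size factor estimation failed")
    sf
}

#' Differential occupancy of one region between two conditions
#'
#' Simplified count test used throughout the RNAP2 redistribution
#' analysis: counts are divided by their size factors, the log2 fold
#' change is computed on normalised means with pseudocount 0.5, and the
#' p-value comes from a Welch t-test on the log2 normalised replicate
#' counts (pseudocount 0.5). All-zero features in both conditions are
#' flagged low-count with `log2fc = 0`, `p = 1`.
#'
#' @param before,after non-negative replicate counts for the two
#'   conditions (>= 2 replicates each).
#' @param sfBefore,sfAfter positive size factors (recycled if scalar).
#' @return List with `log2fc`, `p`, `lowCount`.
#' @examples
#' differentialRegion(c(100, 100, 100), c(25, 25, 25))
#' @export
differentialRegion <- function(before, after, sfBefore = 1, sfAfter = 1) {
    if (length(before) < 2L || length(after) < 2L)
        stop("need >= 2 replicates per condition")
    if (any(c(sfBefore, sfAfter) <= 0))
        stop("size factors must be > 0")
    if (any(c(before, after) < 0))
        stop("counts must be non-negative")
    nb <- before / sfBefore
    na <- after / sfAfter
    if (all(before == 0) && all(after == 0))
        return(list(log2fc = 0, p = 1, lowCount = TRUE))
    log2fc <- log2((mean(na) + 0.5) / (mean(nb) + 0.5))
    p <- as.numeric(.welchP(log2(na + 0.5), log2(nb + 0.5)))
    list(log2fc = log2fc, p = p, lowCount = FALSE)
}

#' Classify RNAP2 redistribution between TSS and gene body
#'
#' Per gene, the whole-gene change (TSS + body counts pooled) is tested
#' with [differentialRegion()]; p-values are Benjamini-Hochberg adjusted
#' across all genes, and genes significant at `adj.p < alpha` are called
#' reduced or increased by the sign of the pooled log2 fold change. Within
#' those, the difference `d = log2fc_TSS - log2fc_body` assigns the
#' pattern: `|d| <= delta` is a global (TSS ~ body) change; `d > delta`
#' means occupancy is retained at the TSS relative to the body (the
#' elongation-block pattern, TSS > body); `d < -delta` the reverse.
#'
#' @param counts long data.frame with columns `gene`, `region` (`"TSS"` or
#'   `"body"`), `condition` (`"before"`/`"after"`), `replicate`, `count`;
#'   both regions must be present for every gene.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param delta log2 fold-change difference separating regional from
#'   global patterns (default 1.0).
#' @param sizeFactors optional named vector of size factors per
#'   `condition.replicate` sample; by default estimated by
#'   [sizeFactorsMedianRatio()] on the gene x sample TSS+body matrix.
#' @return data.frame with one row per gene: `gene`, `log2fc_tss`,
#'   `log2fc_body`, `log2fc_global`, `p_global`, `padj_global`,
#'   `occupancy_class`.
#' @export
classifyOccupancy <- function(counts, alpha = 0.05, delta = 1.0,
                              sizeFactors = NULL) {
    counts <- as.data.frame(counts)
    need <- c("gene", "region", "condition", "replicate", "count")
    if (!all(need %in% names(counts)))
        stop("counts needs columns ", paste(need, collapse = ", "))
    if (!all(counts$region %in% c("TSS", "body")))
        stop("region must be 'TSS' or 'body'")
    counts$sample <- paste(counts$condition, counts$replicate, sep = ".")
    genes <- unique(counts$gene)
    samples <- sort(unique(counts$sample))
    conditionOf <- vapply(strsplit(samples, ".", fixed = TRUE), `[`,
                          character(1), 1L)

    asMatrix <- function(region) {
        sub <- counts[counts$region %in% region, , drop = FALSE]
        agg <- tapply(sub$count, list(sub$gene, sub$sample), sum)
        if (is.null(dim(agg)) || !all(genes %in% rownames(agg)) ||
            !all(samples %in% colnames(agg)))
            stop("incomplete gene: every gene needs both regions in all ",
                 "samples")
        m <- agg[match(genes, rownames(agg)), samples, drop = FALSE]
        if (anyNA(m))
            stop("incomplete gene: every gene needs both regions in all ",
                 "samples")
        m
    }
    mTSS <- asMatrix("TSS")
    mBody <- asMatrix("body")
    mAll <- mTSS + mBody
    if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(mAll)
    sf <- sizeFactors[samples]
    bIdx <- conditionOf == "before"
    aIdx <- conditionOf == "after"

    one <- function(g) {
        glob <- differentialRegion(mAll[g, bIdx], mAll[g, aIdx],
                                   sf[bIdx], sf[aIdx])
        tss <- differentialRegion(mTSS[g, bIdx], mTSS[g, aIdx],
                                  sf[bIdx], sf[aIdx])
        body <- differentialRegion(mBody[g, bIdx], mBody[g, aIdx],
                                   sf[bIdx], sf[aIdx])
        c(tss$log2fc, body$log2fc, glob$log2fc, glob$p)
    }
    res <- t(vapply(seq_along(genes), one, numeric(4)))
    out <- data.frame(gene = genes, log2fc_tss = res[, 1],
                      log2fc_body = res[, 2], log2fc_global = res[, 3],
                      p_global = res[, 4])
    out$padj_global <- p.adjust(out$p_global, method = "BH")
    d <- out$log2fc_tss - out$log2fc_body
    pattern <- ifelse(abs(d) <= delta, "global",
                      ifelse(d > delta, "tss_gt_body", "tss_lt_body"))
    direction <- ifelse(out$padj_global >= alpha, "unchanged",
                        ifelse(out$log2fc_global < 0, "reduced",
                               "increased"))
    out$occupancy_class <- ifelse(direction == "unchanged", "unchanged",
                                  paste(direction, pattern, sep = "_"))
    out
}

#' Crosstab of expression class by RNAP2 occupancy class
#'
#' Tallies genes into the expression x occupancy layout of the published
#' redistribution table: per expression class, a direction total
#' (unchanged / reduced / increased) and, within each changed direction,
#' the three patterns (global i.e. TSS ~ body, TSS > body, TSS < body).
#' Pattern counts always sum to their direction total.
#'
#' @param genes data.frame with columns `gene`, `expression_class` (one of
#'   `"down"`, `"up"`, `"unchanged"`) and `occupancy_class` (one of the
#'   seven classes of [classifyOccupancy()]); alternatively pre-tallied
#'   counts with an `n` column.
#' @return data.frame with columns `expression_class`, `direction`,
#'   `pattern`, `n` over the complete grid (pattern `NA` rows carry the
#'   direction totals).
#' @export
occupancyCrosstab <- function(genes) {
    genes <- as.data.frame(genes)
    if (!all(c("expression_class", "occupancy_class") %in% names(genes)))
        stop("need columns expression_class and occupancy_class")
    if (!"n" %in% names(genes)) genes$n <- rep(1L, nrow(genes))
    if (nrow(genes) &&
        !all(genes$occupancy_class %in% .OCCUPANCY_CLASSES))
        stop("unknown occupancy class")
    direction <- sub("_(global|tss_gt_body|tss_lt_body)$", "",
                     genes$occupancy_class)
    pattern <- ifelse(direction == "unchanged", NA_character_,
                      sub("^(reduced|increased)_", "",
                          genes$occupancy_class))
    exprLevels <- c("unchanged", "down", "up")
    dirLevels <- c("unchanged", "reduced", "increased")
    grid <- expand.grid(expression_class = exprLevels,
                        direction = dirLevels,
                        pattern = c(NA, .PATTERNS),
                        stringsAsFactors = FALSE)
    grid <- grid[!(grid$direction == "unchanged" & !is.na(grid$pattern)), ]
    grid$n <- mapply(function(e, dd, p) {
        sel <- genes$expression_class == e & direction == dd &
            (if (is.na(p)) TRUE else !is.na(pattern) & pattern == p)
        sum(genes$n[sel])
    }, grid$expression_class, grid$direction, grid$pattern)
    rownames(grid) <- NULL
    grid[order(match(grid$expression_class, exprLevels),
               match(grid$direction, dirLevels),
               match(grid$pattern, .PATTERNS), na.last = FALSE), ]
}

#' Headline fractions of an occupancy crosstab
#'
#' Summary quantities of the redistribution table for one expression
#' class: the direction total, the percentage of that expression class in
#' the direction, and the percentage split of the direction across the
#' three patterns.
#'
#' @param crosstab output of [occupancyCrosstab()].
#' @param expressionClass,direction which cell block to summarise
#'   (defaults: down-regulated genes with reduced occupancy).
#' @return List with `nDirection`, `pctOfExpressionClass`, `pctGlobal`,
#'   `pctTssGtBody`, `pctTssLtBody`.
#' @export
crosstabFractions <- function(crosstab, expressionClass = "down",
                              direction = "reduced") {
    sel <- crosstab$expression_class == expressionClass
    total <- sum(crosstab$n[sel & is.na(crosstab$pattern)])
    dirTot <- crosstab$n[sel & crosstab$direction == direction &
                             is.na(crosstab$pattern)]
    pat <- function(p) crosstab$n[sel & crosstab$direction == direction &
                                      !is.na(crosstab$pattern) &
                                      crosstab$pattern == p]
    list(nDirection = dirTot,
         pctOfExpressionClass = 100 * dirTot / total,
         pctGlobal = 100 * pat("global") / dirTot,
         pctTssGtBody = 100 * pat("tss_gt_body") / dirTot,
         pctTssLtBody = 100 * pat("tss_lt_body") / dirTot)
}

#' Odds ratio and Fisher p for the overlap of two gene sets
#'
#' Builds the 2x2 table (in both / A only / B only / neither) over a
#' common universe. The odds ratio is the cross-product ratio, with the
#' Haldane-Anscombe 0.5 correction applied only when a cell is zero; the
#' p-value is the two-sided Fisher exact test.
#'
#' @param universeSize number of genes in the universe.
#' @param setA,setB character vectors of gene identifiers (subsets of the
#'   universe; duplicates are dropped).
#' @return List with `oddsRatio`, `p`, `table` (the 2x2 matrix).
#' @examples
#' overlapOddsRatio(1000, paste0("g", 1:100), paste0("g", 51:150))
#' @export
overlapOddsRatio <- function(universeSize, setA, setB) {
    setA <- unique(setA); setB <- unique(setB)
    nAB <- length(intersect(setA, setB))
    nA <- length(setA) - nAB
    nB <- length(setB) - nAB
    nNeither <- universeSize - nAB - nA - nB
    if (nNeither < 0)
        stop("inconsistent input: universe smaller than the union of the ",
             "sets")
    tab <- matrix(c(nAB, nA, nB, nNeither), 2, 2, byrow = TRUE,
                  dimnames = list(c("inA", "notA"), c("inB", "notB")))
    cells <- as.numeric(tab)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    p <- fisher.test(tab)$p.value
    list(oddsRatio = or, p = p, table = tab)
}

#' Binomial GLM for allele repositioning across conditions
#'
#' Fits a binomial GLM with logit link to replicate-level grouped counts
#' of alleles scored as associated with pericentromeric heterochromatin
#' (condition as a factor). Reports per-condition Wald p-values for the
#' contrast against the reference condition, and the likelihood-ratio
#' p-value for the condition term as a whole. Complete separation (a
#' condition with 0% or 100% associated alleles) is handled by adding 0.5
#' associated and 0.5 non-associated alleles to each replicate of the
#' separated condition (Haldane-style continuity handling) and flagged.
#'
#' @param counts data.frame with columns `condition`, `replicate`,
#'   `associated`, `total` (`associated <= total`, `total >= 1`).
#' @param reference condition level to use as baseline (default: first).
#' @return List with `waldP` (named, one per non-reference condition),
#'   `lrP`, `proportions` (pooled per condition), `separation` flag, and
#'   the fitted `model`.
#' @examples
#' d <- data.frame(condition = rep(c("control", "induced"), each = 3),
#'                 replicate = rep(1:3, 2),
#'                 associated = c(8, 9, 7, 77, 80, 76), total = 100)
#' repositioningTest(d)$lrP
#' @export
repositioningTest <- function(counts, reference = NULL) {
    counts <- as.data.frame(counts)
    need <- c("condition", "replicate", "associated", "total")
    if (!all(need %in% names(counts)))
        stop("counts needs columns ", paste(need, collapse = ", "))
    if (any(counts$total < 1))
        stop("totals must be >= 1")
    if (any(counts$associated < 0 | counts$associated > counts$total))
        stop("associated counts must lie in [0, total]")
    conds <- unique(as.character(counts$condition))
    if (length(conds) < 2L)
        stop("insufficient contrast: need >= 2 conditions")
    if (is.null(reference)) reference <- conds[1]
    counts$condition <- stats::relevel(factor(counts$condition), reference)

    pooled <- tapply(counts$associated, counts$condition, sum) /
        tapply(counts$total, counts$condition, sum)
    separated <- names(pooled)[pooled %in% c(0, 1)]
    separation <- length(separated) > 0L
    if (separation) {
        idx <- as.character(counts$condition) %in% separated
        counts$associated[idx] <- counts$associated[idx] + 0.5
        counts$total[idx] <- counts$total[idx] + 1
    }

    # continuity handling makes counts non-integer by design
    fit <- suppressWarnings(
        glm(cbind(associated, total - associated) ~ condition,
            family = binomial("logit"), data = counts))
    null <- suppressWarnings(
        glm(cbind(associated, total - associated) ~ 1,
            family = binomial("logit"), data = counts))
    sm <- summary(fit)$coefficients
    rows <- grep("^condition", rownames(sm))
    waldP <- setNames(sm[rows, "Pr(>|z|)"],
                      sub("^condition", "", rownames(sm)[rows]))
    lr <- anova(null, fit, test = "Chisq")
    list(waldP = waldP, lrP = lr$`Pr(>Chi)`[2],
         proportions = pooled, separation = separation, model = fit)
}
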