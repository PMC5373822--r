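#' @importFrom GenomicRanges GRanges seqnames start end width resize
#'   countOverlaps coverage
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- Rle
NULL

#' Reconstruct sequencing fragments from mate coordinate pairs
#'
#' Joins properly oriented read pairs into the full fragment they were
#' sequenced from: the fragment spans from the leftmost start to the
#' rightmost end of the pair. A pair is concordant when both mates are on
#' the same chromosome, on opposite strands, with the forward-strand mate
#' starting at or left of the reverse-strand mate (FR orientation).
#' Discordant pairs are skipped and counted.
#'
#' @param pairs data.frame with columns `chrom`, `start1`, `end1`,
#'   `strand1`, `start2`, `end2`, `strand2` (0-based half-open mate
#'   coordinates, as in BED).
#' @return A [GenomicRanges::GRanges] of fragments, with the number of
#'   skipped pairs in `metadata(...)$discarded` and as attribute
#'   `"discarded"`.
#' @examples
#' p <- data.frame(chrom = "chr1", start1 = 100, end1 = 150, strand1 = "+",
#'                 start2 = 200, end2 = 250, strand2 = "-")
#' reconstructFragments(p)  # one fragment [100, 250)
#' @export
reconstructFragments <- function(pairs) {
    pairs <- as.data.frame(pairs)
    need <- c("chrom", "start1", "end1", "strand1", "start2", "end2",
              "strand2")
    if (!all(need %in% names(pairs)))
        stop("pairs needs columns ", paste(need, collapse = ", "))
    fwdFirst <- pairs$strand1 == "+" & pairs$strand2 == "-" &
        pairs$start1 <= pairs$start2
    fwdSecond <- pairs$strand2 == "+" & pairs$strand1 == "-" &
        pairs$start2 <= pairs$start1
    ok <- (fwdFirst | fwdSecond) &
        pairs$end1 > pairs$start1 & pairs$end2 > pairs$start2
    kept <- pairs[ok, , drop = FALSE]
    gr <- GRanges(kept$chrom,
                  IRanges(start = pmin(kept$start1, kept$start2) + 1L,
                          end = pmax(kept$end1, kept$end2)))
    S4Vectors::metadata(gr)$discarded <- sum(!ok)
    attr(gr, "discarded") <- sum(!ok)
    gr
}

#' Filter fragments to the mono-nucleosome size range
#'
#' Keeps fragments whose length lies in `[minLen, maxLen]`, bounds
#' inclusive. The defaults (110-170 bp) select fragments protected by a
#' single nucleosome (core particle ~147 bp).
#'
#' @param frags a [GenomicRanges::GRanges] of fragments.
#' @param minLen,maxLen inclusive length bounds in bp.
#' @return The filtered `GRanges`.
#' @export
filterFragmentsByLength <- function(frags, minLen = 110, maxLen = 170) {
    if (minLen > maxLen)
        stop("invalid range: minLen must be <= maxLen")
    frags[width(frags) >= minLen & width(frags) <= maxLen]
}

#' Fragment midpoints
#'
#' Midpoint of each fragment under the 0-based half-open convention
#' (`floor((start0 + end0) / 2)`), returned as width-1 ranges.
#'
#' @inheritParams filterFragmentsByLength
#' @return A `GRanges` of width-1 midpoint positions.
#' @export
fragmentMidpoints <- function(frags) {
    mid0 <- floor((start(frags) - 1L + end(frags)) / 2)
    GRanges(seqnames(frags), IRanges(mid0 + 1L, width = 1L))
}

#' Blacklist-normalised per-base fragment coverage
#'
#' Raw per-base fragment coverage divided by the number of fragments whose
#' midpoint lies outside the blacklist, reported per million such
#' fragments (normalised = raw * 1e6 / n_eligible). All fragments
#' contribute coverage; the blacklist affects only the normalisation
#' denominator.
#'
#' @inheritParams filterFragmentsByLength
#' @param blacklist a `GRanges` of regions excluded from the
#'   normalisation count (default empty).
#' @param seqlengths optional named vector of contig lengths; defaults to
#'   the rightmost fragment end per contig.
#' @return A [CoverageTrack-class].
#' @export
normalizedCoverage <- function(frags, blacklist = GRanges(),
                               seqlengths = NULL) {
    if (length(frags) == 0L)
        stop("normalization error: no fragments")
    eligible <- countOverlaps(fragmentMidpoints(frags), blacklist) == 0L
    nEligible <- sum(eligible)
    if (nEligible == 0L)
        stop("normalization error: no fragment midpoint outside the ",
             "blacklist")
    rawCov <- if (is.null(seqlengths)) coverage(frags)
              else coverage(frags, width = seqlengths)
    scale <- nEligible / 1e6
    new("CoverageTrack", coverage = rawCov / scale, scaleFactor = scale,
        nEligible = nEligible, nTotal = length(frags))
}

#' Mean coverage profile over peak intervals
#'
#' Averages normalised coverage across windows of `+/- flank` bp around
#' the midpoints of the given peaks, orientation-agnostic (nucleosome
#' signal is unstranded). Windows extending beyond the track are clipped:
#' the out-of-bound positions are dropped from the average and the peak is
#' flagged.
#'
#' @param track a [CoverageTrack-class] (or a plain `RleList`).
#' @param peaks a `GRanges` of peak intervals.
#' @param flank half-window size in bp.
#' @return data.frame with columns `offset_bp` (-flank .. flank) and
#'   `mean_coverage`; the number of clipped peaks is in
#'   `attr(, "clipped")`.
#' @export
profileOverPeaks <- function(track, peaks, flank = 1000L) {
    cov <- if (is(track, "CoverageTrack")) trackCoverage(track) else track
    if (length(peaks) == 0L)
        stop("empty profile: no usable peaks")
    mids <- fragmentMidpoints(peaks)
    offsets <- seq.int(-flank, flank)
    acc <- numeric(length(offsets))
    cnt <- numeric(length(offsets))
    clipped <- 0L
    for (i in seq_along(mids)) {
        chr <- as.character(seqnames(mids)[i])
        if (!chr %in% names(cov)) { clipped <- clipped + 1L; next }
        rle <- cov[[chr]]
        pos <- start(mids)[i] + offsets
        inb <- pos >= 1L & pos <= length(rle)
        if (!all(inb)) clipped <- clipped + 1L
        if (!any(inb)) next
        vals <- as.numeric(rle[pos[inb]])
        acc[inb] <- acc[inb] + vals
        cnt[inb] <- cnt[inb] + 1
    }
    if (all(cnt == 0))
        stop("empty profile: no peak window overlaps the track")
    out <- data.frame(offset_bp = offsets,
                      mean_coverage = ifelse(cnt > 0, acc / cnt, NA_real_))
    attr(out, "clipped") <- clipped
    out
}
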