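## Strict TSV reader: required columns, per-column type coercion with
## row-numbered parse errors (rows are numbered in the data, header
## excluded).
.readStrict <- function(path, colspec) {
    if (!file.exists(path))
        stop("file not found: ", path)
    d <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
    missing <- setdiff(names(colspec), names(d))
    if (length(missing))
        stop(sprintf("%s: missing column(s) %s", path,
                     paste(missing, collapse = ", ")))
    for (col in names(colspec)) {
        if (colspec[[col]] %in% c("numeric", "integer")) {
            v <- suppressWarnings(as.numeric(d[[col]]))
            bad <- which(is.na(v) & !is.na(d[[col]]))
            if (length(bad))
                stop(sprintf("%s: row %d, column '%s': '%s' is not numeric",
                             path, bad[1], col, d[[col]][bad[1]]))
            if (colspec[[col]] == "integer" && any(v != round(v), na.rm = TRUE)) {
                bad <- which(v != round(v))
                stop(sprintf("%s: row %d, column '%s': expected an integer",
                             path, bad[1], col))
            }
            d[[col]] <- v
        }
    }
    d
}

#' Read / write per-gene region count tables
#'
#' Tab-separated dialect: `gene`, `region` (TSS/body), `condition`,
#' `replicate`, `count` (non-negative integers). Malformed rows are
#' reported with file, row and column.
#'
#' @param path file path.
#' @return `readRegionCounts`: a data.frame in the count-table dialect.
#' @export
readRegionCounts <- function(path) {
    d <- .readStrict(path, c(gene = "character", region = "character",
                             condition = "character",
                             replicate = "character", count = "integer"))
    bad <- which(d$count < 0)
    if (length(bad))
        stop(sprintf("%s: row %d, column 'count': negative count", path,
                     bad[1]))
    d
}

#' @rdname readRegionCounts
#' @param counts a count-table data.frame.
#' @export
writeRegionCounts <- function(counts, path) {
    write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write allele-count tables
#'
#' Tab-separated dialect: `condition`, `replicate`, `associated`, `total`.
#'
#' @param path file path.
#' @return `readFishCounts`: a data.frame in the allele-count dialect.
#' @export
readFishCounts <- function(path) {
    d <- .readStrict(path, c(condition = "character",
                             replicate = "character",
                             associated = "integer", total = "integer"))
    bad <- which(d$associated < 0 | d$associated > d$total | d$total < 1)
    if (length(bad))
        stop(sprintf("%s: row %d: need 0 <= associated <= total, total >= 1",
                     path, bad[1]))
    d
}

#' @rdname readFishCounts
#' @param counts an allele-count data.frame.
#' @export
writeFishCounts <- function(counts, path) {
    write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write mate-pair tables
#'
#' Tab-separated dialect: `chrom`, `start1`, `end1`, `strand1`, `start2`,
#' `end2`, `strand2`, with 0-based half-open mate coordinates.
#'
#' @param path file path.
#' @return `readPairsTable`: a data.frame in the mate-pair dialect.
#' @export
readPairsTable <- function(path) {
    d <- .readStrict(path, c(chrom = "character", start1 = "integer",
                             end1 = "integer", strand1 = "character",
                             start2 = "integer", end2 = "integer",
                             strand2 = "character"))
    d
}

#' @rdname readPairsTable
#' @param pairs a mate-pair data.frame.
#' @export
writePairsTable <- function(pairs, path) {
    write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write BED3 interval files
#'
#' Parsing and coordinate conversion are done by [rtracklayer::import];
#' zero- or negative-width records are rejected with their row number.
#'
#' @param path file path.
#' @return `readBed3`: a [GenomicRanges::GRanges].
#' @export
readBed3 <- function(path) {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 3L)
        stop(path, ": BED needs at least 3 columns")
    bad <- which(suppressWarnings(as.numeric(raw[[3]]) <=
                                      as.numeric(raw[[2]])))
    if (length(bad))
        stop(sprintf("%s: row %d: end must be > start", path, bad[1]))
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- NULL
    gr
}

#' @rdname readBed3
#' @param gr a `GRanges` to write (only chrom/start/end are emitted).
#' @export
writeBed3 <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write a simulated trajectory as TSV
#'
#' Columns `time_min`, `dnaE`, `dnaFree`, `dnaI`, `dnaN`.
#'
#' @param trajectory a [PromoterTrajectory-class].
#' @param path file path.
#' @export
writeTrajectoryTable <- function(trajectory, path) {
    write.table(as.data.frame(trajectory), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
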