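## Genomic region sets (panel targets, repeat masks) -------------------------

#' Construct a region set
#'
#' A `region_set` is a labelled collection of genomic intervals in 0-based
#' half-open (BED) convention, backed by a `GRanges`.  Its footprint
#' (`total_bases`) is always the length of the union of the intervals:
#' overlaps are merged before counting, so the footprint is invariant under
#' reordering and splitting of intervals.
#'
#' @param chrom Character vector of chromosome names (an optional `"chr"`
#'   prefix is stripped for matching).
#' @param start,end Integer vectors, 0-based half-open: `start < end`.
#' @param name Optional per-interval names (e.g. the targeted gene).
#' @param label A label for the set (e.g. `"panel"`, `"repeats"`).
#' @return An object of class `region_set` with elements `gr` (a 1-based
#'   `GRanges`), `label` and `total_bases`.
#' @export
region_set <- function(chrom, start, end, name = NULL, label = "regions") {
  start <- as.integer(start); end <- as.integer(end)
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop("region_set: interval ", bad[1], " has start >= end (",
         start[bad[1]], " >= ", end[bad[1]], ")")
  chrom <- sub("^chr", "", as.character(chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  if (!is.null(name)) names(gr) <- name
  structure(list(
    gr = gr, label = label,
    total_bases = sum(GenomicRanges::width(GenomicRanges::reduce(gr)))),
    class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s': %d intervals, %d bases (merged)>\n",
              x$label, length(x$gr), x$total_bases))
  invisible(x)
}

#' Footprint of a region set in bases
#'
#' @param regions A [region_set()].
#' @return The number of distinct bases covered (overlaps merged).
#' @export
total_bases <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  regions$total_bases
}

#' Read a BED file into a region set
#'
#' Reads a 3+ column BED (0-based half-open); a 4th column, when present,
#' is kept as interval names.
#'
#' @param path BED file.
#' @param label Label for the resulting set; defaults to the file name.
#' @return A [region_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 3) stop(path, ": BED needs at least 3 columns")
  start <- as.integer(raw[[2]]); end <- as.integer(raw[[3]])
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop(path, ": line ", bad[1], ": start >= end (", raw[[2]][bad[1]],
         " >= ", raw[[3]][bad[1]], ")")
  region_set(raw[[1]], start, end,
             name = if (ncol(raw) >= 4) raw[[4]] else NULL, label = label)
}

#' Write a region set as BED
#'
#' @param regions A [region_set()].
#' @param path Output file (0-based half-open coordinates).
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  gr <- regions$gr
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(names(gr))) df$name <- names(gr)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Which variants (1-based positions) fall inside a region set.
# Coordinate conversion happens only here.
positions_in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || length(regions$gr) == 0L)
    return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(
    seqnames = sub("^chr", "", as.character(chrom)),
    ranges = IRanges::IRanges(start = as.integer(pos),
                              end = as.integer(pos)))
  subj <- regions$gr
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(subj))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(subj) <- lv
  IRanges::overlapsAny(q, subj)
}
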