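## Panel-of-normals blacklist of recurrent sequencing artifacts --------------

#' Detection rule applied to normal-sample variants
#'
#' A variant counts as "detected" in a normal sample when it has at least
#' 3 mutant reads and a VAF strictly above 1%.  Both sub-rules follow the
#' blacklist-building convention: the read-count bound is inclusive, the
#' VAF bound strict.
#'
#' @param variants A variant table (or any data frame with `alt_reads`
#'   and `vaf` columns).
#' @param min_reads Inclusive mutant-read minimum (default 3).
#' @param min_vaf Strict VAF lower bound (default 0.01).
#' @return Logical vector, one element per row.
#' @export
detected_in_normal <- function(variants, min_reads = 3L, min_vaf = 0.01) {
  variants$alt_reads >= min_reads & variants$vaf > min_vaf
}

#' Build the recurrent-artifact blacklist from a cohort of normals
#'
#' Counts, per normalized variant key, in how many normal samples the
#' variant was detected (see [detected_in_normal()]); a key is blacklisted
#' when that fraction strictly exceeds `recurrence_fraction`.  A variant
#' appearing twice in one normal's table counts once: recurrence is across
#' samples.
#'
#' @param normal_tables List of variant tables, one per normal sample.
#' @param recurrence_fraction Strict recurrence threshold (default 0.20).
#' @param min_reads,min_vaf Detection thresholds passed to
#'   [detected_in_normal()].
#' @return An object of class `blacklist` with `n_normals`,
#'   `detection_counts` (named integer vector keyed by variant key) and
#'   `blacklisted_keys`.
#' @export
build_blacklist <- function(normal_tables, recurrence_fraction = 0.20,
                            min_reads = 3L, min_vaf = 0.01) {
  if (!length(normal_tables)) stop("build_blacklist: empty normal cohort")
  n_normals <- length(normal_tables)
  per_sample_keys <- lapply(normal_tables, function(tab) {
    det <- detected_in_normal(tab, min_reads, min_vaf)
    unique(variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)[det])
  })
  counts <- table(unlist(per_sample_keys))
  detection_counts <- stats::setNames(as.integer(counts), names(counts))
  blacklisted <- names(detection_counts)[
    detection_counts / n_normals > recurrence_fraction]
  structure(list(n_normals = n_normals,
                 recurrence_fraction = recurrence_fraction,
                 detection_counts = detection_counts,
                 blacklisted_keys = sort(blacklisted)),
            class = "blacklist")
}

#' @export
print.blacklist <- function(x, ...) {
  cat(sprintf(
    "<blacklist: %d keys over > %.0f%% of %d normals (%d keys seen)>\n",
    length(x$blacklisted_keys), 100 * x$recurrence_fraction, x$n_normals,
    length(x$detection_counts)))
  invisible(x)
}

#' Persist a blacklist as TSV
#'
#' Writes one row per key ever detected in a normal, with its detection
#' count, cohort size and blacklisted flag, for auditability.
#'
#' @param blacklist A [build_blacklist()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_blacklist <- function(blacklist, path) {
  stopifnot(inherits(blacklist, "blacklist"))
  keys <- names(blacklist$detection_counts)
  parts <- strsplit(keys, ":", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    n_detected = as.integer(blacklist$detection_counts),
    n_normals = blacklist$n_normals,
    blacklisted = keys %in% blacklist$blacklisted_keys)
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a persisted blacklist
#'
#' @param path TSV written by [write_blacklist()].
#' @param recurrence_fraction Recurrence threshold to re-derive the
#'   blacklisted set (default 0.20).
#' @return A `blacklist` object.
#' @export
read_blacklist <- function(path, recurrence_fraction = 0.20) {
  df <- utils::read.delim(path, colClasses = c(
    chrom = "character", pos = "integer", ref = "character",
    alt = "character", n_detected = "integer", n_normals = "integer",
    blacklisted = "logical"))
  if (!nrow(df)) stop(path, ": empty blacklist table")
  keys <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  counts <- stats::setNames(as.integer(df$n_detected), keys)
  n_normals <- unique(df$n_normals)
  if (length(n_normals) != 1L)
    stop(path, ": inconsistent n_normals column")
  structure(list(n_normals = n_normals,
                 recurrence_fraction = recurrence_fraction,
                 detection_counts = counts,
                 blacklisted_keys =
                   sort(names(counts)[counts / n_normals >
                                        recurrence_fraction])),
            class = "blacklist")
}
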