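## Copy-number calls from binned coverage log2 ratios ------------------------

coverage_columns <- c("chrom", "start", "end", "gene", "mean_coverage")

validate_coverage <- function(cov, what = "coverage table") {
  missing_cols <- setdiff(coverage_columns, names(cov))
  if (length(missing_cols))
    stop(what, " is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(cov$start >= cov$end))
    stop(what, ": bin start >= end")
  cov
}

#' Classify a log2 coverage ratio as gain / loss / neutral
#'
#' Calls a copy-number gain when the log2 tumor-to-reference ratio is at
#' least `cutoff` and a loss when it is at most `-cutoff` (default 0.6,
#' i.e. roughly a 1.5-fold gain or 0.66-fold loss); the boundary value
#' itself is a call.
#'
#' @param log2_ratio Numeric vector of finite log2 ratios.
#' @param cutoff Positive cutoff (default 0.6).
#' @return Character vector: `"gain"`, `"loss"` or `"neutral"`.
#' @export
classify_segment <- function(log2_ratio, cutoff = 0.6) {
  if (any(!is.finite(log2_ratio)))
    stop("classify_segment: non-finite log2 ratio")
  ifelse(log2_ratio >= cutoff, "gain",
         ifelse(log2_ratio <= -cutoff, "loss", "neutral"))
}

#' Convert a log2 ratio to a linear fold change
#'
#' @param log2_ratio Numeric vector.
#' @return `2 ^ log2_ratio`.
#' @export
log2_to_fold <- function(log2_ratio) 2 ^ log2_ratio

#' Per-gene copy-number segments from binned coverage
#'
#' Computes, per bin, `log2((tumor / tumor_median) / (ref / ref_median))`
#' where the medians are genome-wide per-sample medians (removing
#' library-size differences), then averages the bins of each gene into one
#' segment and classifies it at the `cutoff` (see [classify_segment()]).
#' Bins with zero or missing reference (or tumor) coverage are dropped
#' with a warning.
#'
#' @param tumor_cov,ref_cov Data frames with columns `chrom`, `start`,
#'   `end` (0-based half-open), `gene`, `mean_coverage`, covering the same
#'   bins in the same order.
#' @param patient_id Sample label for the output (default `"tumor"`).
#' @param cutoff Classification cutoff passed to [classify_segment()].
#' @return A data frame of segments: `patient_id`, `chrom`, `start`,
#'   `end`, `gene`, `n_bins`, `log2_ratio`, `call`.
#' @export
compute_log2_ratios <- function(tumor_cov, ref_cov, patient_id = "tumor",
                                cutoff = 0.6) {
  validate_coverage(tumor_cov, "tumor coverage")
  validate_coverage(ref_cov, "reference coverage")
  key_t <- paste(tumor_cov$chrom, tumor_cov$start, tumor_cov$end)
  key_r <- paste(ref_cov$chrom, ref_cov$start, ref_cov$end)
  if (nrow(tumor_cov) != nrow(ref_cov) || !all(key_t == key_r))
    stop("tumor and reference coverage tables must cover the same bins")
  usable <- !is.na(tumor_cov$mean_coverage) &
    !is.na(ref_cov$mean_coverage) & tumor_cov$mean_coverage > 0 &
    ref_cov$mean_coverage > 0
  if (any(!usable))
    warning(sum(!usable), " bin(s) with zero or missing coverage dropped")
  t_cov <- tumor_cov[usable, ]; r_cov <- ref_cov[usable, ]
  if (!nrow(t_cov)) stop("no usable bins")
  t_med <- stats::median(t_cov$mean_coverage)
  r_med <- stats::median(r_cov$mean_coverage)
  bin_log2 <- log2((t_cov$mean_coverage / t_med) /
                     (r_cov$mean_coverage / r_med))
  segs <- do.call(rbind, lapply(split(seq_len(nrow(t_cov)), t_cov$gene),
                                function(i) {
    data.frame(patient_id = patient_id, chrom = t_cov$chrom[i[1]],
               start = min(t_cov$start[i]), end = max(t_cov$end[i]),
               gene = t_cov$gene[i[1]], n_bins = length(i),
               log2_ratio = mean(bin_log2[i]), stringsAsFactors = FALSE)
  }))
  segs <- segs[order(segs$chrom, segs$start), ]
  rownames(segs) <- NULL
  segs$call <- classify_segment(segs$log2_ratio, cutoff)
  segs
}

#' Read a binned coverage table from TSV
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `gene`,
#'   `mean_coverage` (0-based half-open bins).
#' @return A validated coverage data frame.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cov <- utils::read.delim(path, colClasses = c(
    chrom = "character", start = "integer", end = "integer",
    gene = "character", mean_coverage = "numeric"))
  validate_coverage(cov, path)
}

#' Write a binned coverage table as TSV
#' @param cov A coverage data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  validate_coverage(cov)
  utils::write.table(cov[, coverage_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
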