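## The tumor-only somatic filtering cascade ----------------------------------
##
## Five independent predicates applied conjunctively.  The kept set is
## order-free; the printed order is used only for trace readability and for
## first-failing-filter attribution in the run manifest.

cascade_filters <- c("functional_class", "population_frequency",
                     "blacklist", "repeat_regions", "evidence_tier")

#' Functional-class keep-list filter
#'
#' Keeps missense, stopgain, frameshift and non-frameshift indel calls.
#' Splice-site calls are dropped by default; set `keep_splice = TRUE` to
#' retain them.
#'
#' @param variants A variant table.
#' @param keep_splice Also keep `splice` calls? Default `FALSE`.
#' @return Logical keep vector.
#' @export
filter_functional_class <- function(variants, keep_splice = FALSE) {
  keep <- keep_classes()
  if (keep_splice) keep <- c(keep, "splice")
  variants$variant_class %in% keep
}

#' Population-frequency filter
#'
#' Removes variants present at strictly more than `max_popfreq` (default
#' 1%) in either the 1000 Genomes Project or ExAC.  A missing frequency is
#' treated as 0 (never seen in the population).
#'
#' @param variants A variant table.
#' @param max_popfreq Strict upper bound on either population frequency.
#' @return Logical keep vector.
#' @export
filter_population_frequency <- function(variants, max_popfreq = 0.01) {
  p1 <- ifelse(is.na(variants$popfreq_1000g), 0, variants$popfreq_1000g)
  p2 <- ifelse(is.na(variants$popfreq_exac), 0, variants$popfreq_exac)
  !(p1 > max_popfreq | p2 > max_popfreq)
}

#' Panel-of-normals blacklist filter
#'
#' Removes variants whose normalized key is on the recurrent-artifact
#' blacklist.  Matching is allele-specific: a different alt allele at a
#' blacklisted site is kept.
#'
#' @param variants A variant table.
#' @param blacklist A [build_blacklist()] result, or `NULL` for no
#'   filtering.
#' @return Logical keep vector.
#' @export
filter_blacklist <- function(variants, blacklist) {
  if (is.null(blacklist)) return(rep(TRUE, nrow(variants)))
  stopifnot(inherits(blacklist, "blacklist"))
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  !(keys %in% blacklist$blacklisted_keys)
}

#' Repeat-masked-region filter
#'
#' Removes variants whose position lies inside a repeat-masked interval.
#'
#' @param variants A variant table (1-based positions).
#' @param repeats A [region_set()] of repeat-masked intervals (0-based
#'   half-open), or `NULL` for no filtering.
#' @return Logical keep vector.
#' @export
filter_repeat_regions <- function(variants, repeats) {
  if (is.null(repeats)) return(rep(TRUE, nrow(variants)))
  !positions_in_regions(variants$chrom, variants$pos, repeats)
}

#' COSMIC-tiered evidence filter
#'
#' A mutation is called out only when its VAF is strictly above 1% with at
#' least 5 mutant reads if it is a known COSMIC mutation, or strictly
#' above 2% with at least 8 mutant reads otherwise.  VAF bounds are
#' strict, read minima inclusive.
#'
#' @param variants A variant table.
#' @param cosmic_vaf,cosmic_reads Thresholds for COSMIC variants
#'   (defaults 0.01 and 5).
#' @param noncosmic_vaf,noncosmic_reads Thresholds for non-COSMIC
#'   variants (defaults 0.02 and 8).
#' @return Logical keep vector.
#' @export
filter_evidence_tier <- function(variants, cosmic_vaf = 0.01,
                                 cosmic_reads = 5L, noncosmic_vaf = 0.02,
                                 noncosmic_reads = 8L) {
  ifelse(variants$cosmic,
         variants$vaf > cosmic_vaf & variants$alt_reads >= cosmic_reads,
         variants$vaf > noncosmic_vaf &
           variants$alt_reads >= noncosmic_reads)
}

#' Run the full somatic filtering cascade
#'
#' Applies the five filters — functional class, population frequency,
#' panel-of-normals blacklist, repeat-masked regions, and the
#' COSMIC-tiered evidence rule — conjunctively and returns the kept set
#' together with a per-variant decision trace.  Because the filters are
#' independent predicates the kept set does not depend on their order.
#'
#' @param variants A variant table.
#' @param blacklist A [build_blacklist()] result or `NULL`.
#' @param repeats A repeat-mask [region_set()] or `NULL`.
#' @param keep_splice Passed to [filter_functional_class()].
#' @param min_depth Optional inclusive depth pre-filter (the primary
#'   caller's minimum read depth); `NULL` (default) disables it.
#' @return A list with `kept` (the surviving variant table) and `trace`
#'   (a long data frame: one row per variant per filter with `patient_id`,
#'   `key`, `filter`, `passed`, `reason`, `final_kept`).
#' @export
run_cascade <- function(variants, blacklist = NULL, repeats = NULL,
                        keep_splice = FALSE, min_depth = NULL) {
  validate_variants(variants)
  n <- nrow(variants)
  empty_trace <- data.frame(
    patient_id = character(), key = character(),
    filter = factor(character(), levels = cascade_filters),
    passed = logical(), reason = character(), final_kept = logical(),
    stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(kept = variants, trace = empty_trace))
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  decisions <- list(
    functional_class = filter_functional_class(variants, keep_splice),
    population_frequency = filter_population_frequency(variants),
    blacklist = filter_blacklist(variants, blacklist),
    repeat_regions = filter_repeat_regions(variants, repeats),
    evidence_tier = filter_evidence_tier(variants))
  if (!is.null(min_depth))
    decisions <- c(list(depth = variants$depth >= min_depth), decisions)
  reasons <- list(
    depth = "depth below primary-caller minimum",
    functional_class = "variant class not on keep-list",
    population_frequency = "population frequency above 1%",
    blacklist = "recurrent artifact in panel of normals",
    repeat_regions = "inside repeat-masked region",
    evidence_tier = "below tiered VAF/read-support threshold")
  final_kept <- Reduce(`&`, decisions, rep(TRUE, n))
  trace <- do.call(rbind, lapply(names(decisions), function(f) {
    data.frame(patient_id = variants$patient_id, key = keys, filter = f,
               passed = decisions[[f]],
               reason = ifelse(decisions[[f]], "ok", reasons[[f]]),
               final_kept = final_kept, stringsAsFactors = FALSE)
  }))
  trace$filter <- factor(trace$filter, levels = names(decisions))
  list(kept = variants[final_kept, , drop = FALSE], trace = trace)
}

# Attribute each removed variant to the first failing filter, in the
# configured order.  Manifest accounting only; semantics are order-free.
# Returns one filter name per removed variant (NA for kept variants).
first_failing_filter <- function(trace) {
  if (!nrow(trace)) return(character(0))
  filters <- levels(trace$filter)
  passed <- vapply(filters, function(f) trace$passed[trace$filter == f],
                   logical(sum(trace$filter == filters[1])))
  if (is.null(dim(passed))) passed <- matrix(passed, nrow = 1,
                                             dimnames = list(NULL, filters))
  apply(passed, 1L, function(p)
    if (all(p)) NA_character_ else filters[which(!p)[1]])
}
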