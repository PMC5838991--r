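## Tumor mutational burden ---------------------------------------------------

#' Tumor mutational burden per patient
#'
#' TMB is the number of non-synonymous and indel mutations per megabase
#' of the sequenced target.  Eligible mutations are the kept calls whose
#' class is on the cascade keep-list (missense, stopgain, frameshift and
#' non-frameshift indels — so stopgain counts as non-synonymous while
#' synonymous and splice calls do not); the denominator is the merged
#' unique panel footprint in Mb.  Copy-number events are never counted.
#'
#' @param kept A variant table of cascade-kept calls (possibly several
#'   patients).
#' @param panel The panel target [region_set()]; its merged footprint
#'   must be positive.
#' @param patients Optional character vector of patient ids to report
#'   (patients with zero eligible mutations get `tmb = 0`); defaults to
#'   the patients present in `kept`.
#' @return Data frame with `patient_id`, `eligible_count`, `panel_mb`,
#'   `tmb`.
#' @export
compute_tmb <- function(kept, panel, patients = NULL) {
  stopifnot(inherits(panel, "region_set"))
  if (total_bases(panel) <= 0) stop("compute_tmb: empty panel footprint")
  validate_variants(kept)
  if (is.null(patients)) patients <- unique(kept$patient_id)
  panel_mb <- total_bases(panel) / 1e6
  eligible <- kept[kept$variant_class %in% keep_classes(), , drop = FALSE]
  counts <- table(factor(eligible$patient_id, levels = patients))
  data.frame(patient_id = patients,
             eligible_count = as.integer(counts),
             panel_mb = panel_mb,
             tmb = as.integer(counts) / panel_mb,
             stringsAsFactors = FALSE)
}
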