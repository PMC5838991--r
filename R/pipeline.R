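## End-to-end orchestration --------------------------------------------------

#' Default pipeline thresholds
#'
#' All rule thresholds in one place: population-frequency bound 0.01;
#' normal-sample detection at 3 reads / 1% VAF with recurrence fraction
#' 0.20; evidence tiers 1% VAF / 5 reads (COSMIC) and 2% VAF / 8 reads
#' (non-COSMIC); CNV log2 cutoff 0.6.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(max_popfreq = 0.01, detect_min_reads = 3L, detect_min_vaf = 0.01,
       recurrence_fraction = 0.20, cosmic_vaf = 0.01, cosmic_reads = 5L,
       noncosmic_vaf = 0.02, noncosmic_reads = 8L, cnv_cutoff = 0.6,
       keep_splice = FALSE, min_depth = NULL)
}

#' Run the whole pipeline on a cohort bundle
#'
#' Orchestrates blacklist building, the per-tumor filtering cascade,
#' per-patient copy-number calls, TMB, the cohort alteration matrix and
#' actionability matching, exactly as running the stages individually,
#' and assembles a run manifest with per-stage record counts.  Removed
#' variants are attributed to the first failing filter in the printed
#' cascade order for accounting; the manifest checks the conservation
#' invariant `kept + removed = input` per patient.
#'
#' @param bundle A [generate_cohort()] result, or any list with the same
#'   elements (`normals`, `tumors`, `tumor_cov`, `ref_cov`, `panel`,
#'   `repeats`, `clinical`).
#' @param thresholds See [default_thresholds()].
#' @param knowledge_base Path or `"default"`, passed to
#'   [load_knowledge_base()].
#' @param out_dir Optional directory; when given, all stage outputs and
#'   the manifest (JSON) are written there.
#' @return List with `blacklist`, `kept` (combined variant table),
#'   `traces`, `cnv` (combined segments), `tmb`, `matrix`, `matches`,
#'   `actionable` and `manifest`.
#' @export
run_all <- function(bundle, thresholds = default_thresholds(),
                    knowledge_base = "default", out_dir = NULL) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  for (el in c("normals", "tumors", "panel", "clinical"))
    if (is.null(bundle[[el]]))
      stop("run_all: bundle is missing element '", el, "'")
  message("Building blacklist from ", length(bundle$normals), " normals")
  bl <- build_blacklist(bundle$normals, th$recurrence_fraction,
                        th$detect_min_reads, th$detect_min_vaf)
  per_patient <- list()
  kept_list <- list(); trace_list <- list()
  for (id in names(bundle$tumors)) {
    res <- run_cascade(bundle$tumors[[id]], bl, bundle$repeats,
                       keep_splice = th$keep_splice,
                       min_depth = th$min_depth)
    kept_list[[id]] <- res$kept
    trace_list[[id]] <- res$trace
    ff <- first_failing_filter(res$trace)
    removed <- table(factor(ff[!is.na(ff)],
                            levels = levels(res$trace$filter)))
    removed_list <- stats::setNames(as.list(as.integer(removed)),
                                    names(removed))
    per_patient[[id]] <- c(
      list(input = nrow(bundle$tumors[[id]]), kept = nrow(res$kept)),
      removed_list)
    total <- per_patient[[id]]$kept +
      sum(unlist(per_patient[[id]][names(removed)]))
    if (total != per_patient[[id]]$input)
      stop("manifest conservation violated for ", id)
  }
  kept <- do.call(rbind, kept_list); rownames(kept) <- NULL
  cnv <- NULL
  if (!is.null(bundle$tumor_cov) && !is.null(bundle$ref_cov)) {
    message("Computing copy-number segments")
    cnv <- do.call(rbind, lapply(names(bundle$tumor_cov), function(id)
      compute_log2_ratios(bundle$tumor_cov[[id]], bundle$ref_cov,
                          patient_id = id, cutoff = th$cnv_cutoff)))
    rownames(cnv) <- NULL
  }
  tmb <- compute_tmb(kept, bundle$panel,
                     patients = bundle$clinical$patient_id)
  m <- build_matrix(kept, cnv, bundle$clinical)
  kb <- load_knowledge_base(knowledge_base)
  matches <- match_alterations(kept, cnv, kb)
  manifest <- list(
    thresholds = th[!vapply(th, is.null, logical(1))],
    n_normals = length(bundle$normals),
    n_tumors = length(bundle$tumors),
    n_blacklisted_keys = length(bl$blacklisted_keys),
    panel_bases = total_bases(bundle$panel),
    per_patient = per_patient,
    n_kept_total = nrow(kept),
    n_cnv_events = if (is.null(cnv)) 0L else sum(cnv$call != "neutral"),
    n_actionable_patients = length(actionable_patients(matches)))
  out <- list(blacklist = bl, kept = kept,
              traces = do.call(rbind, trace_list), cnv = cnv, tmb = tmb,
              matrix = m, matches = matches,
              actionable = actionable_patients(matches),
              manifest = manifest)
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_blacklist(run$blacklist, file.path(out_dir, "blacklist.tsv"))
  write_variant_table(run$kept, file.path(out_dir, "kept.tsv"))
  utils::write.table(run$traces, file.path(out_dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$cnv))
    utils::write.table(run$cnv, file.path(out_dir, "cnv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(run$tmb, file.path(out_dir, "tmb.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(run$matrix, file.path(out_dir, "matrix.tsv"))
  utils::write.table(run$matches, file.path(out_dir, "matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
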