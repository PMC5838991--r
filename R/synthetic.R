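## Synthetic labelled cohorts ------------------------------------------------
##
## Generates everything the pipeline consumes — tumor and normal variant
## tables, binned coverage, panel and repeat-mask regions, a clinical table
## — with per-variant truth labels, so every stage is testable without
## patient data.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the targeted-panel cohort the
#' pipeline was designed around: 15 tumors and 53 normals, tumor depth
#' around 300x and normal depth around 700x, somatic VAFs Beta(2, 8)
#' (mean 0.2), and a scaled-down 60-gene panel (10 bins of 500 bp per
#' gene) standing in for the full 416-gene panel.  Artifact sites are
#' split into "recurrent" ones injected into 30% of normals (above the
#' 20% blacklist threshold) and "sporadic" ones injected into 10%
#' (below it).
#'
#' @param seed Integer seed; identical seed and config give identical
#'   cohorts.
#' @param n_tumors,n_normals Cohort sizes.
#' @param panel_genes Number of panel genes (the known cancer genes of
#'   [gene_groups()] first, then filler genes).
#' @param bins_per_gene,bin_size Panel geometry per gene.
#' @param germline_per_patient Mean germline variants per tumor sample.
#' @param common_germline_prob Probability a germline variant is common
#'   (population frequency 0.05, above the 1% filter) rather than rare
#'   (0.0001).
#' @param somatic_per_patient Mean true somatic variants per tumor.
#' @param somatic_vaf_shape `c(alpha, beta)` of the somatic VAF Beta
#'   distribution.
#' @param mean_depth,normal_depth Mean sequencing depth of tumors and
#'   normals.
#' @param hotspot_fraction Fraction of somatic variants flagged COSMIC.
#' @param artifact_sites Number of recurrent-error candidate sites.
#' @param recurrent_artifact_fraction Fraction of artifact sites made
#'   recurrent.
#' @param recurrent_normal_fraction,sporadic_normal_fraction Fraction of
#'   normals carrying a recurrent / sporadic artifact site.
#' @param artifact_tumor_fraction Fraction of tumors carrying each
#'   artifact site.
#' @param repeat_fraction Fraction of panel genes whose footprint is
#'   repeat-masked.
#' @param repeat_artifacts_per_patient Mean repeat-region false positives
#'   per tumor.
#' @param cnv_genes_per_patient Genes per patient given a copy-number
#'   shift of log2 +1 or -1.
#' @param cnv_noise_sd Standard deviation of multiplicative (log-normal)
#'   coverage noise.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_tumors = 15L, n_normals = 53L,
                             panel_genes = 60L, bins_per_gene = 10L,
                             bin_size = 500L, germline_per_patient = 10,
                             common_germline_prob = 0.6,
                             somatic_per_patient = 8,
                             somatic_vaf_shape = c(2, 8),
                             mean_depth = 300, normal_depth = 700,
                             hotspot_fraction = 0.3, artifact_sites = 30L,
                             recurrent_artifact_fraction = 0.5,
                             recurrent_normal_fraction = 0.30,
                             sporadic_normal_fraction = 0.10,
                             artifact_tumor_fraction = 0.3,
                             repeat_fraction = 0.10,
                             repeat_artifacts_per_patient = 2,
                             cnv_genes_per_patient = 3L,
                             cnv_noise_sd = 0.1) {
  cfg <- as.list(environment())
  counts <- c("n_tumors", "n_normals", "panel_genes", "bins_per_gene",
              "bin_size", "artifact_sites", "cnv_genes_per_patient")
  for (f in counts) if (cfg[[f]] < 0) stop("synthetic_config: ", f, " < 0")
  fracs <- c("common_germline_prob", "hotspot_fraction",
             "recurrent_artifact_fraction", "recurrent_normal_fraction",
             "sporadic_normal_fraction", "artifact_tumor_fraction",
             "repeat_fraction")
  for (f in fracs) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop("synthetic_config: ", f, " must be in [0,1]")
  if (cfg$sporadic_normal_fraction > 0.20)
    stop("synthetic_config: sporadic_normal_fraction must be <= 0.20 ",
         "(sporadic sites must stay below the blacklist threshold)")
  if (cfg$recurrent_normal_fraction <= 0.20)
    stop("synthetic_config: recurrent_normal_fraction must be > 0.20 ",
         "(recurrent sites must cross the blacklist threshold)")
  structure(cfg, class = "synthetic_config")
}

# Panel layout: known cancer genes first, then filler genes, one gene per
# megabase-spaced locus; the last floor(repeat_fraction * n) genes are
# repeat-masked filler genes.
synthetic_panel_layout <- function(config) {
  known <- unique(c(unlist(gene_groups()), "IDH1", "HNF1A"))
  n <- config$panel_genes
  genes <- if (n <= length(known)) known[seq_len(n)] else
    c(known, sprintf("GENE%02d", seq_len(n - length(known))))
  n_repeat <- floor(config$repeat_fraction * n)
  repeat_genes <- if (n_repeat > 0) utils::tail(genes, n_repeat) else
    character(0)
  gene_len <- config$bins_per_gene * config$bin_size
  layout <- data.frame(
    gene = genes,
    chrom = as.character(((seq_len(n) - 1L) %% 22L) + 1L),
    start = 1000000L * seq_len(n),          # 0-based
    stringsAsFactors = FALSE)
  layout$end <- layout$start + gene_len
  layout$is_repeat <- layout$gene %in% repeat_genes
  layout
}

# Bin table (0-based half-open) for the whole panel.
synthetic_bins <- function(config, layout) {
  b <- config$bins_per_gene
  do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    s <- layout$start[i] + (seq_len(b) - 1L) * config$bin_size
    data.frame(chrom = layout$chrom[i], start = s,
               end = s + config$bin_size, gene = layout$gene[i],
               stringsAsFactors = FALSE)
  }))
}

rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
rand_alt <- function(ref) vapply(ref, function(r)
  sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

# Draw a variant site inside a gene's footprint (1-based position).
draw_sites <- function(layout, genes, n) {
  i <- match(genes, layout$gene)
  pos <- layout$start[i] + sample.int(layout$end[1] - layout$start[1], n,
                                      replace = TRUE)
  ref <- rand_base(n)
  data.frame(chrom = layout$chrom[i], pos = pos, ref = ref,
             alt = rand_alt(ref), gene = genes, stringsAsFactors = FALSE)
}

# alt_reads = round(vaf * depth); stored vaf is alt_reads / depth so the
# two are exactly consistent.
evidence_fields <- function(vaf, depth) {
  depth <- pmax(20L, as.integer(round(depth)))
  alt <- pmin(depth, pmax(0L, as.integer(round(vaf * depth))))
  list(vaf = alt / depth, alt_reads = alt, depth = depth)
}

#' Generate a fully labelled synthetic cohort
#'
#' Emits tumor and normal variant tables, per-bin coverage, panel and
#' repeat-mask region sets, a clinical table, and per-variant truth
#' labels (`origin` in somatic / germline / artifact / repeat_artifact).
#' Recurrent artifact sites are injected into more than 20% of normals
#' (so the blacklist must catch exactly them), sporadic ones into at most
#' 20%; common germline variants carry population frequencies above 1%.
#' Random streams are split per component (clinical, variants, artifacts,
#' coverage) so changing one knob does not perturb the others; the whole
#' bundle is deterministic in `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `config`,
#'   `panel`, `repeats` ([region_set()]s), `clinical`, `normals` (list of
#'   variant tables), `tumors` (list of variant tables), `tumor_cov`
#'   (list of coverage tables), `ref_cov`, and `truth` (list with
#'   `variants`, `cnv`, `eligible_counts`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- synthetic_panel_layout(config)
  bins <- synthetic_bins(config, layout)
  panel <- region_set(bins$chrom, bins$start, bins$end, name = bins$gene,
                      label = "panel")
  rep_layout <- layout[layout$is_repeat, , drop = FALSE]
  repeats <- if (nrow(rep_layout))
    region_set(rep_layout$chrom, rep_layout$start, rep_layout$end,
               name = rep_layout$gene, label = "repeats")
  else region_set(character(), integer(), integer(), label = "repeats")
  host_genes <- layout$gene[!layout$is_repeat]
  if (config$artifact_sites > 0 && !length(host_genes))
    stop("generate_cohort: no non-repeat genes to host artifact sites")

  tumor_ids <- sprintf("T%02d", seq_len(config$n_tumors))
  normal_ids <- sprintf("N%02d", seq_len(config$n_normals))

  ## clinical stream ----------------------------------------------------
  set.seed(config$seed + 101L)
  clinical <- synthetic_clinical(tumor_ids)

  ## artifact-site stream ----------------------------------------------
  set.seed(config$seed + 202L)
  n_art <- config$artifact_sites
  art_sites <- draw_sites(layout,
                          sample(host_genes, n_art, replace = TRUE), n_art)
  n_recur <- round(config$recurrent_artifact_fraction * n_art)
  art_sites$recurrent <- seq_len(n_art) <= n_recur
  art_sites$key <- variant_key(art_sites$chrom, art_sites$pos,
                               art_sites$ref, art_sites$alt)
  # membership: which normals / tumors carry each site
  n_in_recur <- round(config$recurrent_normal_fraction * config$n_normals)
  n_in_spor <- round(config$sporadic_normal_fraction * config$n_normals)
  art_in_normal <- lapply(seq_len(n_art), function(i)
    sample(normal_ids, if (art_sites$recurrent[i]) n_in_recur else
      n_in_spor))
  art_in_tumor <- lapply(seq_len(n_art), function(i)
    sample(tumor_ids, round(config$artifact_tumor_fraction *
                              config$n_tumors)))

  ## variant stream -----------------------------------------------------
  set.seed(config$seed + 303L)
  truth_rows <- list()
  tumors <- stats::setNames(vector("list", config$n_tumors), tumor_ids)
  normals <- stats::setNames(vector("list", config$n_normals), normal_ids)

  make_variants <- function(sample_id, sites, vaf, depth, class, cosmic,
                            pf1, pfx) {
    ev <- evidence_fields(vaf, depth)
    variant_table(
      patient_id = sample_id, chrom = sites$chrom, pos = sites$pos,
      ref = sites$ref, alt = sites$alt, gene = sites$gene,
      variant_class = class, protein_change = "", cdna_change = "",
      vaf = ev$vaf, alt_reads = ev$alt_reads, depth = ev$depth,
      cosmic = cosmic, popfreq_1000g = pf1, popfreq_exac = pfx)
  }
  somatic_classes <- c("missense", "stopgain", "frameshift_indel",
                       "nonframeshift_indel", "synonymous", "splice")
  somatic_class_p <- c(0.50, 0.13, 0.13, 0.09, 0.10, 0.05)

  for (t in seq_len(config$n_tumors)) {
    id <- tumor_ids[t]
    parts <- list()
    # somatic
    n_som <- stats::rpois(1, config$somatic_per_patient)
    if (n_som > 0) {
      s <- draw_sites(layout, sample(host_genes, n_som, replace = TRUE),
                      n_som)
      vaf <- stats::rbeta(n_som, config$somatic_vaf_shape[1],
                          config$somatic_vaf_shape[2])
      cls <- sample(somatic_classes, n_som, replace = TRUE,
                    prob = somatic_class_p)
      cos <- stats::runif(n_som) < config$hotspot_fraction
      vt <- make_variants(id, s, vaf, stats::rnorm(n_som,
                          config$mean_depth, 30), cls, cos, NA, NA)
      parts$somatic <- vt
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = id, key = variant_key(vt$chrom, vt$pos, vt$ref,
                                           vt$alt),
        origin = "somatic", common_germline = FALSE, recurrent = FALSE,
        expected_kept = vt$variant_class %in% keep_classes() &
          as.logical(filter_evidence_tier(vt)), stringsAsFactors = FALSE)
    }
    # germline
    n_germ <- stats::rpois(1, config$germline_per_patient)
    if (n_germ > 0) {
      s <- draw_sites(layout, sample(host_genes, n_germ, replace = TRUE),
                      n_germ)
      common <- stats::runif(n_germ) < config$common_germline_prob
      pf <- ifelse(common, 0.05, 0.0001)
      vaf <- pmin(0.95, pmax(0.05, stats::rnorm(n_germ, 0.5, 0.05)))
      cls <- sample(variant_classes(), n_germ, replace = TRUE)
      vt <- make_variants(id, s, vaf, stats::rnorm(n_germ,
                          config$mean_depth, 30), cls, FALSE, pf, pf)
      parts$germline <- vt
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = id, key = variant_key(vt$chrom, vt$pos, vt$ref,
                                           vt$alt),
        origin = "germline", common_germline = common, recurrent = FALSE,
        expected_kept = FALSE, stringsAsFactors = FALSE)
    }
    # artifact sites present in this tumor
    art_here <- which(vapply(art_in_tumor, function(x) id %in% x,
                             logical(1)))
    if (length(art_here)) {
      s <- art_sites[art_here, c("chrom", "pos", "ref", "alt", "gene")]
      vaf <- stats::runif(length(art_here), 0.015, 0.05)
      vt <- make_variants(id, s, vaf, stats::rnorm(length(art_here),
                          config$mean_depth, 30), "missense", FALSE, NA, NA)
      parts$artifact <- vt
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = id, key = art_sites$key[art_here],
        origin = "artifact", common_germline = FALSE,
        recurrent = art_sites$recurrent[art_here],
        expected_kept = FALSE, stringsAsFactors = FALSE)
    }
    # repeat-region false positives
    n_rep <- if (nrow(rep_layout))
      stats::rpois(1, config$repeat_artifacts_per_patient) else 0L
    if (n_rep > 0) {
      s <- draw_sites(layout, sample(rep_layout$gene, n_rep,
                                     replace = TRUE), n_rep)
      vaf <- stats::runif(n_rep, 0.03, 0.15)
      vt <- make_variants(id, s, vaf, stats::rnorm(n_rep,
                          config$mean_depth, 30), "missense", FALSE, NA, NA)
      parts$repeats <- vt
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = id, key = variant_key(vt$chrom, vt$pos, vt$ref,
                                           vt$alt),
        origin = "repeat_artifact", common_germline = FALSE,
        recurrent = FALSE, expected_kept = FALSE, stringsAsFactors = FALSE)
    }
    tumors[[id]] <- if (length(parts)) do.call(rbind, parts) else
      empty_variant_table()
    rownames(tumors[[id]]) <- NULL
  }

  # normals: private germline plus injected artifact sites
  for (nn in seq_len(config$n_normals)) {
    id <- normal_ids[nn]
    parts <- list()
    n_germ <- stats::rpois(1, 5)
    if (n_germ > 0) {
      s <- draw_sites(layout, sample(host_genes, n_germ, replace = TRUE),
                      n_germ)
      vaf <- pmin(0.95, pmax(0.05, stats::rnorm(n_germ, 0.5, 0.05)))
      parts$germline <- make_variants(
        id, s, vaf, stats::rnorm(n_germ, config$normal_depth, 50),
        sample(variant_classes(), n_germ, replace = TRUE), FALSE,
        0.0001, 0.0001)
    }
    art_here <- which(vapply(art_in_normal, function(x) id %in% x,
                             logical(1)))
    if (length(art_here)) {
      s <- art_sites[art_here, c("chrom", "pos", "ref", "alt", "gene")]
      vaf <- stats::runif(length(art_here), 0.011, 0.05)
      parts$artifact <- make_variants(
        id, s, vaf, stats::rnorm(length(art_here), config$normal_depth,
                                 50), "missense", FALSE, NA, NA)
    }
    normals[[id]] <- if (length(parts)) do.call(rbind, parts) else
      empty_variant_table()
    rownames(normals[[id]]) <- NULL
  }

  ## coverage stream ----------------------------------------------------
  set.seed(config$seed + 404L)
  n_bins <- nrow(bins)
  bin_base <- config$mean_depth * exp(stats::rnorm(n_bins, 0, 0.3))
  ref_cov <- data.frame(bins, mean_coverage =
                          bin_base * exp(stats::rnorm(n_bins, 0,
                                                      config$cnv_noise_sd)),
                        stringsAsFactors = FALSE)
  cnv_truth <- list()
  tumor_cov <- stats::setNames(vector("list", config$n_tumors), tumor_ids)
  for (t in seq_len(config$n_tumors)) {
    id <- tumor_ids[t]
    shift_genes <- sample(host_genes, config$cnv_genes_per_patient)
    shifts <- stats::setNames(rep(0, nrow(layout)), layout$gene)
    shifts[shift_genes] <- sample(c(-1, 1),
                                  config$cnv_genes_per_patient,
                                  replace = TRUE)
    lib <- exp(stats::rnorm(1, 0, 0.2))
    cov <- bin_base * lib * 2 ^ shifts[bins$gene] *
      exp(stats::rnorm(n_bins, 0, config$cnv_noise_sd))
    tumor_cov[[id]] <- data.frame(bins, mean_coverage = cov,
                                  stringsAsFactors = FALSE)
    cnv_truth[[t]] <- data.frame(
      patient_id = id, gene = layout$gene,
      true_shift = unname(shifts[layout$gene]),
      true_call = c("loss", "neutral", "gain")[
        sign(shifts[layout$gene]) + 2],
      stringsAsFactors = FALSE)
  }

  truth_variants <- if (length(truth_rows)) do.call(rbind, truth_rows)
    else data.frame(patient_id = character(), key = character(),
                    origin = character(), common_germline = logical(),
                    recurrent = logical(), expected_kept = logical())
  rownames(truth_variants) <- NULL
  eligible <- vapply(tumor_ids, function(id)
    sum(truth_variants$expected_kept[truth_variants$patient_id == id]),
    integer(1))
  structure(list(
    config = config, panel = panel, repeats = repeats,
    clinical = clinical, normals = normals, tumors = tumors,
    tumor_cov = tumor_cov, ref_cov = ref_cov,
    truth = list(variants = truth_variants,
                 cnv = do.call(rbind, cnv_truth),
                 eligible_counts = eligible,
                 recurrent_artifact_keys =
                   sort(art_sites$key[art_sites$recurrent]),
                 sporadic_artifact_keys =
                   sort(art_sites$key[!art_sites$recurrent]))),
    class = "synthetic_cohort")
}

# Clinical covariates loosely matching the cohort margins: 12/15 male,
# stage I/II/III = 4/7/4, site upper/mid/lower = 1/7/7, macroscopic type
# polypoid/ulcerating/infiltrative = 10/1/4.
synthetic_clinical <- function(tumor_ids) {
  n <- length(tumor_ids)
  take <- function(pool) sample(rep_len(pool, n))
  sex <- take(c(rep("male", 12), rep("female", 3))[seq_len(min(15, n))])
  data.frame(
    patient_id = tumor_ids, sex = sex,
    age = sample(46:70, n, replace = TRUE),
    stage = take(c(rep("I", 4), rep("II", 7), rep("III", 4))),
    site = take(c("upper", rep("mid", 7), rep("lower", 7))),
    macroscopic_type = take(c(rep("polypoid", 10), "ulcerating",
                              rep("infiltrative", 4))),
    smoker = ifelse(sex == "male", stats::runif(n) < 0.75, FALSE),
    overall_survival_months = round(stats::runif(n, 1, 71), 1),
    alive = stats::runif(n) < 0.5, stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort: %d tumors, %d normals, ",
                     "%d-gene panel (%d bases), %d labelled variants>\n"),
              length(x$tumors), length(x$normals),
              x$config$panel_genes, total_bases(x$panel),
              nrow(x$truth$variants)))
  invisible(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits the same plain-text formats the readers consume: one variant TSV
#' per tumor and normal, coverage TSVs, panel and repeat BEDs, the
#' clinical table and the truth labels.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (d in file.path(dir, c("tumors", "normals", "coverage")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$tumors))
    write_variant_table(cohort$tumors[[id]],
                        file.path(dir, "tumors", paste0(id, ".tsv")))
  for (id in names(cohort$normals))
    write_variant_table(cohort$normals[[id]],
                        file.path(dir, "normals", paste0(id, ".tsv")))
  for (id in names(cohort$tumor_cov))
    write_coverage(cohort$tumor_cov[[id]],
                   file.path(dir, "coverage", paste0(id, ".tsv")))
  write_coverage(cohort$ref_cov, file.path(dir, "coverage",
                                           "reference.tsv"))
  write_bed(cohort$panel, file.path(dir, "panel.bed"))
  write_bed(cohort$repeats, file.path(dir, "repeats.bed"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$truth$variants,
                     file.path(dir, "truth_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$cnv, file.path(dir, "truth_cnv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score a kept-variant set against the generator's truth labels
#'
#' Computes, from the truth labels of a synthetic bundle: sensitivity for
#' somatic variants expected to survive the cascade (keep-list class and
#' above the tiered evidence thresholds), removal fractions for common
#' germline variants, recurrent artifacts and repeat-region artifacts,
#' and per-origin leakage counts (kept variants that were not expected to
#' be kept).  Somatic variants generated below the evidence thresholds
#' count as intended-removed, not as errors.
#'
#' @param kept A variant table (the union of kept calls across tumors).
#' @param truth The `truth` element of a [generate_cohort()] bundle.
#' @return List with `sensitivity`, `common_germline_removed`,
#'   `recurrent_artifact_removed`, `repeat_artifact_removed`,
#'   `leakage` (data frame of kept-but-not-expected counts by origin)
#'   and `n_kept`.
#' @export
evaluate_against_truth <- function(kept, truth) {
  tv <- truth$variants
  kept_id <- paste(kept$patient_id,
                   variant_key(kept$chrom, kept$pos, kept$ref, kept$alt))
  truth_id <- paste(tv$patient_id, tv$key)
  unknown <- setdiff(kept_id, truth_id)
  if (length(unknown))
    stop("kept variant(s) absent from truth labels: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  tv$kept <- truth_id %in% kept_id
  frac_removed <- function(sel)
    if (!any(sel)) NA_real_ else 1 - sum(tv$kept[sel]) / sum(sel)
  expected <- tv$origin == "somatic" & tv$expected_kept
  leak <- tv[tv$kept & !tv$expected_kept, ]
  list(
    sensitivity = if (!any(expected)) NA_real_ else
      sum(tv$kept[expected]) / sum(expected),
    common_germline_removed =
      frac_removed(tv$origin == "germline" & tv$common_germline),
    recurrent_artifact_removed =
      frac_removed(tv$origin == "artifact" & tv$recurrent),
    repeat_artifact_removed = frac_removed(tv$origin == "repeat_artifact"),
    leakage = as.data.frame(table(origin = leak$origin),
                            stringsAsFactors = FALSE),
    n_kept = length(kept_id))
}
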