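## Gene-by-patient cohort profiling ------------------------------------------

# Map variant functional classes to oncoprint alteration categories.
category_of_class <- c(missense = "missense", stopgain = "truncating",
                       frameshift_indel = "truncating",
                       nonframeshift_indel = "nonframeshift_indel",
                       splice = "splice")
category_of_cnv <- c(gain = "amplification", loss = "loss")

#' Build the gene-by-patient alteration matrix
#'
#' Combines kept small variants and copy-number calls into a co-mutation
#' ("oncoprint") structure: per (gene, patient) cell, the set of
#' alteration categories.  Stopgain and frameshift calls map to
#' `truncating`; CNV gains map to `amplification`, losses to `loss`.
#' Every patient of the clinical table gets a column even with zero
#' alterations; a variant or CNV for a patient missing from the clinical
#' table is an error.
#'
#' @param kept Variant table of cascade-kept calls.
#' @param cnvs Optional data frame of [compute_log2_ratios()] segments
#'   (neutral segments are ignored).
#' @param clinical A validated clinical table defining the patient set
#'   and column order.
#' @param groups A gene-group catalog (default [gene_groups()]).
#' @return An object of class `cohort_matrix`: list with `patients`,
#'   `genes` (ordered by decreasing altered-patient count), `alterations`
#'   (long data frame gene / patient_id / category) and `groups`.
#' @export
build_matrix <- function(kept, cnvs = NULL, clinical, groups = gene_groups()) {
  validate_clinical(clinical)
  validate_variants(kept)
  patients <- clinical$patient_id
  seen <- unique(c(kept$patient_id, cnvs$patient_id))
  unknown <- setdiff(seen, patients)
  if (length(unknown))
    stop("patient id(s) absent from clinical table: ",
         paste(unknown, collapse = ", "))
  var_alt <- kept[kept$variant_class %in% names(category_of_class),
                  c("gene", "patient_id", "variant_class")]
  alt <- data.frame(gene = var_alt$gene, patient_id = var_alt$patient_id,
                    category = unname(category_of_class[var_alt$variant_class]),
                    stringsAsFactors = FALSE)
  if (!is.null(cnvs) && nrow(cnvs)) {
    cnv_alt <- cnvs[cnvs$call %in% names(category_of_cnv), , drop = FALSE]
    alt <- rbind(alt, data.frame(
      gene = cnv_alt$gene, patient_id = cnv_alt$patient_id,
      category = unname(category_of_cnv[cnv_alt$call]),
      stringsAsFactors = FALSE))
  }
  alt <- unique(alt[alt$gene != "", , drop = FALSE])
  per_gene <- vapply(split(alt$patient_id, alt$gene),
                     function(p) length(unique(p)), integer(1))
  genes <- names(sort(per_gene, decreasing = TRUE))
  # stable tie-break: alphabetical within equal counts
  genes <- genes[order(-per_gene[genes], genes)]
  rownames(alt) <- NULL
  structure(list(patients = patients, genes = genes, alterations = alt,
                 groups = groups), class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix: %d genes x %d patients, %d alterations>\n",
              length(x$genes), length(x$patients), nrow(x$alterations)))
  invisible(x)
}

#' Alteration categories in one cell
#'
#' @param m A `cohort_matrix`.
#' @param gene,patient_id The cell to look up.
#' @return Character vector of categories (empty when unaltered).
#' @export
matrix_cell <- function(m, gene, patient_id) {
  stopifnot(inherits(m, "cohort_matrix"))
  a <- m$alterations
  sort(unique(a$category[a$gene == gene & a$patient_id == patient_id]))
}

#' Render the cohort matrix as a character matrix
#'
#' @param x A `cohort_matrix`.
#' @param ... Unused.
#' @return Gene-by-patient character matrix of semicolon-joined
#'   categories (`""` = unaltered).
#' @export
as.matrix.cohort_matrix <- function(x, ...) {
  out <- matrix("", length(x$genes), length(x$patients),
                dimnames = list(x$genes, x$patients))
  for (i in seq_len(nrow(x$alterations))) {
    g <- x$alterations$gene[i]; p <- x$alterations$patient_id[i]
    cur <- out[g, p]
    out[g, p] <- if (nzchar(cur))
      paste(sort(unique(c(strsplit(cur, ";")[[1]],
                          x$alterations$category[i]))), collapse = ";")
      else x$alterations$category[i]
  }
  out
}

#' Write the cohort matrix as TSV
#' @param m A `cohort_matrix`.
#' @param path Output file (genes as rows, patients as columns).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  mat <- as.matrix(m)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene alteration frequency
#'
#' @param m A `cohort_matrix`.
#' @param gene Gene symbol present in the matrix.
#' @return List with `gene`, `count` (patients altered), `n` (cohort
#'   size) and `fraction`.
#' @export
gene_frequency <- function(m, gene) {
  stopifnot(inherits(m, "cohort_matrix"))
  if (!gene %in% m$genes) stop("gene not in matrix: ", gene)
  count <- length(unique(
    m$alterations$patient_id[m$alterations$gene == gene]))
  list(gene = gene, count = count, n = length(m$patients),
       fraction = count / length(m$patients))
}

#' Per-pathway (gene-group) alteration frequency
#'
#' A patient counts once if at least one gene of the group is altered.
#'
#' @param m A `cohort_matrix`.
#' @param group_name Name of a group in the matrix's catalog.
#' @return List with `group`, `count`, `n`, `fraction` and the altered
#'   `patients`.
#' @export
pathway_frequency <- function(m, group_name) {
  stopifnot(inherits(m, "cohort_matrix"))
  if (!group_name %in% names(m$groups))
    stop("unknown gene group: ", group_name)
  genes <- m$groups[[group_name]]
  patients <- sort(unique(
    m$alterations$patient_id[m$alterations$gene %in% genes]))
  list(group = group_name, count = length(patients),
       n = length(m$patients),
       fraction = length(patients) / length(m$patients),
       patients = patients)
}

#' Patients altered in two or more of a set of genes
#'
#' Counts, by enumeration over patients, how many are altered in at least
#' two of the listed genes — zero for a perfectly mutually exclusive set.
#'
#' @param m A `cohort_matrix`.
#' @param genes Character vector of gene symbols.
#' @return Integer count.
#' @export
mutual_exclusivity_overlap <- function(m, genes) {
  stopifnot(inherits(m, "cohort_matrix"))
  a <- m$alterations[m$alterations$gene %in% genes, ]
  per_patient <- vapply(split(a$gene, a$patient_id),
                        function(g) length(unique(g)), integer(1))
  sum(per_patient >= 2L)
}

#' Triage kept variants in mismatch-repair / proofreading genes
#'
#' Lists every kept SNV/indel in the MMR + proofreading gene set with its
#' SIFT prediction and ClinVar assertions verbatim, plus a derived
#' `pathogenic` flag (see [has_pathogenic_assertion()]).
#'
#' @param kept A variant table of cascade-kept calls.
#' @param genes Gene set (default the `MMR_proofreading` group of
#'   [gene_groups()]).
#' @return Data frame: `patient_id`, `gene`, `protein_change`,
#'   `cdna_change`, `sift`, `clinvar_sig`, `pathogenic`.
#' @export
triage_mmr_variants <- function(kept,
                                genes = gene_groups()$MMR_proofreading) {
  validate_variants(kept)
  hits <- kept[kept$gene %in% genes,
               c("patient_id", "gene", "protein_change", "cdna_change",
                 "sift", "clinvar_sig"), drop = FALSE]
  hits <- hits[order(hits$patient_id, hits$gene, hits$protein_change), ]
  rownames(hits) <- NULL
  hits$pathogenic <- has_pathogenic_assertion(hits$clinvar_sig)
  hits
}

#' Does a ClinVar annotation assert pathogenicity?
#'
#' A record counts as pathogenic when at least one of its
#' semicolon-separated assertions is Pathogenic or Likely_pathogenic
#' (case-insensitive) and none is Benign or Likely_benign: records with
#' conflicting benign/pathogenic submissions are not asserted pathogenic.
#'
#' @param clinvar_sig Character vector of semicolon-joined assertions.
#' @return Logical vector.
#' @export
has_pathogenic_assertion <- function(clinvar_sig) {
  vapply(strsplit(tolower(clinvar_sig), ";", fixed = TRUE), function(a) {
    a <- trimws(a)
    any(a %in% c("pathogenic", "likely_pathogenic")) &&
      !any(a %in% c("benign", "likely_benign"))
  }, logical(1))
}

#' Compare an alteration frequency with a reference cohort
#'
#' Two-sided Fisher exact test on the 2x2 table of altered / unaltered
#' patients in this cohort versus a reference cohort.
#'
#' @param count,n Altered patients and cohort size here.
#' @param ref_count,ref_n Altered patients and size of the reference
#'   cohort.
#' @return Two-sided exact p-value.
#' @export
compare_to_reference <- function(count, n, ref_count, ref_n) {
  vals <- c(count = count, n = n, ref_count = ref_count, ref_n = ref_n)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("compare_to_reference: counts must be non-negative integers")
  if (count > n || ref_count > ref_n)
    stop("compare_to_reference: count exceeds cohort size")
  tab <- matrix(c(count, n - count, ref_count, ref_n - ref_count), nrow = 2)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}
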