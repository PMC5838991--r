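## Canonical variant-table schema --------------------------------------------

#' Recognised functional classes for a variant call
#'
#' The seven functional classes a variant call may carry.  The first four
#' (`missense`, `stopgain`, `frameshift_indel`, `nonframeshift_indel`) form
#' the keep-list of the somatic filtering cascade and the eligible classes
#' for tumor mutational burden.
#'
#' @return Character vector of class labels.
#' @export
variant_classes <- function() {
  c("missense", "stopgain", "frameshift_indel", "nonframeshift_indel",
    "splice", "synonymous", "other")
}

#' Functional classes kept by the cascade / counted by TMB
#'
#' @return Character vector: missense, stopgain, frameshift_indel,
#'   nonframeshift_indel.
#' @export
keep_classes <- function() {
  c("missense", "stopgain", "frameshift_indel", "nonframeshift_indel")
}

variant_columns <- c(
  "patient_id", "chrom", "pos", "ref", "alt", "gene", "variant_class",
  "protein_change", "cdna_change", "vaf", "alt_reads", "depth", "cosmic",
  "popfreq_1000g", "popfreq_exac", "sift", "clinvar_sig")

#' Construct a variant table
#'
#' Builds a validated data frame of annotated variant calls, one row per
#' observation.  This is the container every stage of the pipeline consumes:
#' evidence fields (`vaf`, `alt_reads`, `depth`), functional annotation
#' (`variant_class`, `protein_change`, `cdna_change`), population
#' frequencies, COSMIC membership, and SIFT / ClinVar annotations.
#'
#' @param patient_id,chrom,ref,alt,gene Character vectors (recycled to a
#'   common length).
#' @param pos 1-based genomic positions.
#' @param variant_class One of [variant_classes()].
#' @param protein_change,cdna_change Optional HGVS-style strings ("" if
#'   absent).
#' @param vaf Variant allele fraction in \[0, 1\].
#' @param alt_reads,depth Mutant-read count and total depth; `alt_reads`
#'   must not exceed `depth`.
#' @param cosmic Logical COSMIC-membership flag.
#' @param popfreq_1000g,popfreq_exac Population allele frequencies, `NA`
#'   when not observed.
#' @param sift `"deleterious"`, `"neutral"` or `NA`.
#' @param clinvar_sig Semicolon-joined ClinVar assertions, `""` when none.
#' @return A validated `data.frame` with the canonical columns.
#' @seealso [validate_variants()], [read_variant_table()]
#' @export
variant_table <- function(patient_id, chrom, pos, ref, alt, gene,
                          variant_class, protein_change = "",
                          cdna_change = "", vaf, alt_reads, depth,
                          cosmic = FALSE, popfreq_1000g = NA_real_,
                          popfreq_exac = NA_real_, sift = NA_character_,
                          clinvar_sig = "") {
  df <- data.frame(
    patient_id = as.character(patient_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), variant_class = as.character(variant_class),
    protein_change = as.character(protein_change),
    cdna_change = as.character(cdna_change), vaf = as.numeric(vaf),
    alt_reads = as.integer(alt_reads), depth = as.integer(depth),
    cosmic = as.logical(cosmic),
    popfreq_1000g = as.numeric(popfreq_1000g),
    popfreq_exac = as.numeric(popfreq_exac), sift = as.character(sift),
    clinvar_sig = as.character(clinvar_sig),
    stringsAsFactors = FALSE)
  validate_variants(df)
}

#' An empty variant table with the canonical columns
#' @return Zero-row variant table.
#' @export
empty_variant_table <- function() {
  variant_table(character(), character(), integer(), character(),
                character(), character(), character(), character(),
                character(), numeric(), integer(), integer(), logical(),
                numeric(), numeric(), character(), character())
}

#' Validate a variant table against its invariants
#'
#' Checks column presence and the per-row invariants: `0 <= vaf <= 1`,
#' `alt_reads <= depth`, `ref != alt`, `pos >= 1`, `variant_class` among
#' [variant_classes()] and `sift` among deleterious / neutral / missing.
#' Errors name the offending row and field.
#'
#' @param variants A data frame.
#' @return The input, invisibly usable, on success.
#' @export
validate_variants <- function(variants) {
  missing_cols <- setdiff(variant_columns, names(variants))
  if (length(missing_cols))
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  fail <- function(rows, field, why) {
    stop(sprintf("invalid variant table: row %s, field '%s': %s",
                 paste(utils::head(rows, 5), collapse = ","), field, why))
  }
  bad <- function(x) which(x)
  with(variants, {
    if (length(r <- bad(is.na(vaf) | vaf < 0 | vaf > 1)))
      fail(r, "vaf", "must be in [0,1]")
    if (length(r <- bad(is.na(alt_reads) | alt_reads < 0)))
      fail(r, "alt_reads", "must be a non-negative integer")
    if (length(r <- bad(is.na(depth) | depth < 0)))
      fail(r, "depth", "must be a non-negative integer")
    if (length(r <- bad(alt_reads > depth)))
      fail(r, "alt_reads", "exceeds depth")
    if (length(r <- bad(is.na(pos) | pos < 1)))
      fail(r, "pos", "must be >= 1 (1-based)")
    if (length(r <- bad(ref == alt)))
      fail(r, "ref", "ref and alt alleles are identical")
    if (length(r <- bad(!variant_class %in% variant_classes())))
      fail(r, "variant_class", "not a recognised functional class")
    if (length(r <- bad(!is.na(sift) & !sift %in% c("deleterious", "neutral"))))
      fail(r, "sift", "must be deleterious, neutral or missing")
    if (length(r <- bad(!is.na(popfreq_1000g) &
                          (popfreq_1000g < 0 | popfreq_1000g > 1))))
      fail(r, "popfreq_1000g", "must be in [0,1] or missing")
    if (length(r <- bad(!is.na(popfreq_exac) &
                          (popfreq_exac < 0 | popfreq_exac > 1))))
      fail(r, "popfreq_exac", "must be in [0,1] or missing")
  })
  variants
}

## Variant identity keys ------------------------------------------------------

# Trim the shared ref/alt prefix (advancing pos) and then any shared
# suffix, so equivalent representations of an indel map to one key.
normalize_allele <- function(pos, ref, alt) {
  # prefix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalized variant identity key
#'
#' Builds the `chrom:pos:ref:alt` key used for blacklist matching across
#' samples.  Chromosome names are compared after stripping an optional
#' `"chr"` prefix; shared ref/alt suffixes then prefixes are trimmed with
#' the position advanced accordingly, so equivalent representations of an
#' indel map to one key.
#'
#' @param chrom,pos,ref,alt Vectors describing variants (1-based `pos`).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  n <- length(pos)
  out <- character(n)
  for (i in seq_len(n)) {
    z <- normalize_allele(as.integer(pos[i]), ref[i], alt[i])
    out[i] <- paste(chrom[i], z$pos, z$ref, z$alt, sep = ":")
  }
  out
}

## TSV reading / writing ------------------------------------------------------

#' Read a variant table
#'
#' Reads annotated variant calls from either the canonical tab-separated
#' layout (header row with the columns of [variant_table()]) or a VCF.
#' Missing annotation cells (`popfreq_*`, `sift`) become `NA`; an empty
#' `clinvar_sig` cell becomes `""`.  Rows are validated and errors name the
#' offending line.
#'
#' @param path File to read.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param patient_id For VCF input, the patient to assign (defaults to the
#'   single sample name in the VCF).
#' @return A validated variant table.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               patient_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "vcf") return(read_variant_vcf(path, patient_id))
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE)
  missing_cols <- setdiff(variant_columns, names(raw))
  if (length(missing_cols))
    stop(path, ": missing columns: ", paste(missing_cols, collapse = ", "))
  num <- function(x) as.numeric(ifelse(x == "", NA, x))
  int <- function(x) as.integer(ifelse(x == "", NA, x))
  df <- data.frame(
    patient_id = raw$patient_id, chrom = raw$chrom, pos = int(raw$pos),
    ref = raw$ref, alt = raw$alt, gene = raw$gene,
    variant_class = raw$variant_class,
    protein_change = raw$protein_change, cdna_change = raw$cdna_change,
    vaf = num(raw$vaf), alt_reads = int(raw$alt_reads),
    depth = int(raw$depth), cosmic = as.logical(raw$cosmic),
    popfreq_1000g = num(raw$popfreq_1000g),
    popfreq_exac = num(raw$popfreq_exac),
    sift = ifelse(raw$sift == "", NA_character_, raw$sift),
    clinvar_sig = raw$clinvar_sig, stringsAsFactors = FALSE)
  tryCatch(validate_variants(df), error = function(e)
    stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: `read(write(v))` reproduces `v`
#' field-for-field.  Missing numeric annotations are written as empty
#' cells.
#'
#' @param variants A validated variant table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  out <- variants[, variant_columns]
  out$sift[is.na(out$sift)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

## VCF reading ----------------------------------------------------------------

# INFO keys carrying annotations when variants arrive as VCF.
vcf_info_keys <- c(GENE = "gene", VARCLASS = "variant_class",
                   PCHANGE = "protein_change", CCHANGE = "cdna_change",
                   PF1KG = "popfreq_1000g", PFEXAC = "popfreq_exac",
                   SIFT = "sift", CLNSIG = "clinvar_sig")

read_variant_vcf <- function(path, patient_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) return(empty_variant_table())
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop(path, ": multi-allelic records are not supported; split them first")
  samples <- colnames(v@gt)[-1]
  if (is.null(patient_id)) {
    if (length(samples) != 1L)
      stop(path, ": give patient_id explicitly for multi-sample VCFs")
    patient_id <- samples[1]
  }
  gt_col <- if (length(samples)) samples[1] else NULL
  get_fmt <- function(el) {
    x <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = FALSE),
                  error = function(e) NULL)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else as.character(x[, 1])
  }
  ad <- get_fmt("AD")
  dp <- suppressWarnings(as.integer(get_fmt("DP")))
  af <- suppressWarnings(as.numeric(get_fmt("AF")))
  alt_reads <- suppressWarnings(
    as.integer(vapply(strsplit(ad, ","), function(p)
      if (length(p) >= 2) p[2] else NA_character_, character(1))))
  vaf <- ifelse(!is.na(alt_reads) & !is.na(dp) & dp > 0,
                alt_reads / dp, af)
  info <- fix[, "INFO"]
  info_val <- function(key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  gene <- info_val("GENE"); gene[is.na(gene)] <- ""
  vclass <- info_val("VARCLASS"); vclass[is.na(vclass)] <- "other"
  pch <- info_val("PCHANGE"); pch[is.na(pch)] <- ""
  cch <- info_val("CCHANGE"); cch[is.na(cch)] <- ""
  clnsig <- info_val("CLNSIG"); clnsig[is.na(clnsig)] <- ""
  cosmic <- grepl("(^|;)COSMIC(;|=|$)", info)
  variant_table(
    patient_id = patient_id, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = gene, variant_class = vclass, protein_change = pch,
    cdna_change = cch, vaf = vaf, alt_reads = alt_reads, depth = dp,
    cosmic = cosmic, popfreq_1000g = num_or_na(info_val("PF1KG")),
    popfreq_exac = num_or_na(info_val("PFEXAC")),
    sift = info_val("SIFT"), clinvar_sig = clnsig)
}
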