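## Clinical actionability matching -------------------------------------------

kb_pattern_types <- c("amplification", "exact_protein_change",
                      "truncation_class", "splice_disruption",
                      "any_deleterious")

#' Normalize a protein-change notation for matching
#'
#' Strips a leading `"p."`, removes whitespace and upper-cases, so
#' `"p.M1043 V"` and `"p.m1043v"` compare equal.
#'
#' @param x Character vector of protein changes.
#' @return Normalized character vector.
#' @export
normalize_protein_change <- function(x) {
  toupper(gsub("[[:space:]]+", "", sub("^[Pp]\\.", "", x)))
}

#' Load an actionability knowledge base
#'
#' The knowledge base is a flat TSV (editable without code changes) with
#' columns `gene`, `pattern_type`, `pattern_value`, `therapy`,
#' `evidence_note`, `citation_tag`.  Pattern types: `amplification`
#' (copy-number gain of the gene), `exact_protein_change` (value is the
#' protein notation), `truncation_class` (value `nonsense` or
#' `frameshift`), `splice_disruption` (intronic splice-site notation in
#' the cDNA change) and `any_deleterious` (any SIFT-deleterious call in
#' the gene).  `"default"` loads the knowledge base shipped with the
#' package, which encodes the clinically actionable alterations reported
#' for the 15-patient esophageal sarcomatoid carcinoma cohort.
#'
#' @param path A TSV path or `"default"`.
#' @return Data frame of rules with a `rule_id` column.
#' @export
load_knowledge_base <- function(path = "default") {
  if (identical(path, "default"))
    path <- system.file("extdata", "actionability_kb.tsv",
                        package = "oncosieve", mustWork = TRUE)
  if (!file.exists(path)) stop("no such file: ", path)
  kb <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  need <- c("gene", "pattern_type", "pattern_value", "therapy")
  missing_cols <- setdiff(need, names(kb))
  if (length(missing_cols))
    stop(path, ": knowledge base is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"evidence_note" %in% names(kb)) kb$evidence_note <- ""
  if (!"citation_tag" %in% names(kb)) kb$citation_tag <- ""
  for (i in seq_len(nrow(kb))) {
    if (!nzchar(kb$gene[i]))
      stop(path, ": rule ", i, ": empty gene field")
    if (!kb$pattern_type[i] %in% kb_pattern_types)
      stop(path, ": rule ", i, ": unknown pattern_type '",
           kb$pattern_type[i], "'")
    if (kb$pattern_type[i] == "exact_protein_change" &&
        !nzchar(kb$pattern_value[i]))
      stop(path, ": rule ", i, ": exact_protein_change needs a value")
    if (kb$pattern_type[i] == "truncation_class" &&
        !kb$pattern_value[i] %in% c("nonsense", "frameshift"))
      stop(path, ": rule ", i,
           ": truncation_class value must be nonsense or frameshift")
  }
  kb$rule_id <- seq_len(nrow(kb))
  kb
}

# Intronic splice-site notation, e.g. "c.A3975-2T" or "c.1234+1G>A".
is_splice_notation <- function(cdna_change) {
  grepl("c\\..*[0-9][+-][0-9]+", cdna_change)
}

#' Match kept alterations against actionability rules
#'
#' Scans every (alteration, rule) pair.  Matching semantics:
#' `exact_protein_change` compares [normalize_protein_change()]d strings;
#' `truncation_class` `nonsense` matches stopgain calls and `frameshift`
#' matches frameshift indels; `amplification` matches a copy-number gain
#' segment of the gene; `splice_disruption` matches a cDNA change with
#' intronic splice notation; `any_deleterious` matches a SIFT-deleterious
#' call.  One match is emitted per (patient, rule, alteration).
#'
#' @param kept Variant table of kept calls (may be empty).
#' @param cnvs Optional [compute_log2_ratios()] segment data frame.
#' @param rules A [load_knowledge_base()] data frame.
#' @return Data frame of matches: `patient_id`, `gene`, `alteration`,
#'   `pattern_type`, `therapy`, `rule_id`.
#' @export
match_alterations <- function(kept, cnvs = NULL, rules) {
  validate_variants(kept)
  out <- list()
  emit <- function(patient_id, gene, alteration, rule) {
    data.frame(patient_id = patient_id, gene = gene,
               alteration = alteration, pattern_type = rule$pattern_type,
               therapy = rule$therapy, rule_id = rule$rule_id,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    if (rule$pattern_type == "amplification") {
      if (is.null(cnvs) || !nrow(cnvs)) next
      hit <- cnvs$gene == rule$gene & cnvs$call == "gain"
      if (any(hit))
        out[[length(out) + 1L]] <- emit(cnvs$patient_id[hit], rule$gene,
                                        "amplification", rule)
      next
    }
    v <- kept[kept$gene == rule$gene, , drop = FALSE]
    if (!nrow(v)) next
    hit <- switch(rule$pattern_type,
      exact_protein_change =
        normalize_protein_change(v$protein_change) ==
          normalize_protein_change(rule$pattern_value),
      truncation_class =
        v$variant_class == c(nonsense = "stopgain",
                             frameshift = "frameshift_indel")[
                               rule$pattern_value],
      splice_disruption = is_splice_notation(v$cdna_change),
      any_deleterious = !is.na(v$sift) & v$sift == "deleterious")
    if (any(hit)) {
      desc <- ifelse(nzchar(v$protein_change[hit]), v$protein_change[hit],
                     ifelse(nzchar(v$cdna_change[hit]), v$cdna_change[hit],
                            v$variant_class[hit]))
      out[[length(out) + 1L]] <- emit(v$patient_id[hit], rule$gene, desc,
                                      rule)
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), gene = character(),
                      alteration = character(), pattern_type = character(),
                      therapy = character(), rule_id = integer(),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$patient_id, res$gene, res$rule_id), ]
  rownames(res) <- NULL
  res
}

#' Patients with at least one actionable alteration
#'
#' @param matches A [match_alterations()] result.
#' @return Sorted character vector of distinct patient ids.
#' @export
actionable_patients <- function(matches) {
  sort(unique(as.character(matches$patient_id)))
}
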