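## Clinical records and gene-group catalog -----------------------------------

clinical_columns <- c("patient_id", "sex", "age", "stage", "site",
                      "macroscopic_type", "smoker",
                      "overall_survival_months", "alive")

#' Validate a clinical table
#'
#' One row per patient: sex (male/female), age in years (> 0), clinical
#' stage (I/II/III), primary tumor site along the esophagus
#' (upper/mid/lower thoracic), macroscopic type
#' (polypoid/ulcerating/infiltrative), and optional smoking / survival
#' fields.  Patient ids must be unique.
#'
#' @param clinical A data frame with the columns above.
#' @return The validated data frame.
#' @export
validate_clinical <- function(clinical) {
  missing_cols <- setdiff(clinical_columns, names(clinical))
  if (length(missing_cols))
    stop("clinical table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(clinical$patient_id))
    stop("clinical table: duplicated patient_id: ",
         paste(unique(clinical$patient_id[duplicated(clinical$patient_id)]),
               collapse = ", "))
  if (any(is.na(clinical$age) | clinical$age <= 0))
    stop("clinical table: age must be > 0")
  chk <- function(x, lv, f) if (any(!is.na(x) & !x %in% lv))
    stop("clinical table: field '", f, "' must be one of ",
         paste(lv, collapse = "/"))
  chk(clinical$sex, c("male", "female"), "sex")
  chk(clinical$stage, c("I", "II", "III"), "stage")
  chk(clinical$site, c("upper", "mid", "lower"), "site")
  chk(clinical$macroscopic_type,
      c("polypoid", "ulcerating", "infiltrative"), "macroscopic_type")
  clinical
}

#' Read a clinical table from TSV
#'
#' @param path Tab-separated file with the columns of
#'   [validate_clinical()].
#' @return A validated clinical data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character", na.strings = "")
  raw$age <- as.integer(raw$age)
  raw$smoker <- as.logical(raw$smoker)
  raw$overall_survival_months <- as.numeric(raw$overall_survival_months)
  raw$alive <- as.logical(raw$alive)
  validate_clinical(raw)
}

#' Write a clinical table as TSV
#' @param clinical A validated clinical data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.table(clinical[, clinical_columns], path, sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)
  invisible(path)
}

#' Default gene-group catalog for pathway profiling
#'
#' Groups panel genes by protein function: receptor tyrosine kinases
#' (RTK), the downstream RAS / PI3-kinase axis, histone-modification
#' genes, cell-cycle and DNA-repair genes, the NOTCH pathway, and the
#' mismatch-repair plus polymerase-proofreading set whose lesions relate
#' to hypermutation.  A gene may belong to more than one group.
#'
#' @return Named list of character vectors of gene symbols.
#' @export
gene_groups <- function() {
  list(
    RTK = c("MET", "CSF1R", "FLT3", "FLT1", "ERBB2", "FGFR4", "PDGFRB"),
    RAS_PI3K = c("PIK3CA", "AKT1", "PTEN", "NF1"),
    histone_modification = c("EP300", "CREBBP", "KMT2A", "KMT2B", "KDM5A"),
    cell_cycle_dna_repair = c("TP53", "RB1", "CCND1", "CDKN2A"),
    NOTCH = c("NOTCH1", "FBXW7"),
    MMR_proofreading = c("MSH2", "MLH1", "PMS1", "PMS2", "POLE"))
}
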