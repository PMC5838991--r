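# Builders shared across tests.  All fixtures are constructed in code.

mk_var <- function(patient_id = "P1", chrom = "1", pos = 1000L, ref = "A",
                   alt = "T", gene = "TP53", variant_class = "missense",
                   protein_change = "", cdna_change = "", vaf = 0.10,
                   alt_reads = 30L, depth = 300L, cosmic = FALSE,
                   popfreq_1000g = NA_real_, popfreq_exac = NA_real_,
                   sift = NA_character_, clinvar_sig = "") {
  variant_table(patient_id, chrom, pos, ref, alt, gene, variant_class,
                protein_change, cdna_change, vaf, alt_reads, depth, cosmic,
                popfreq_1000g, popfreq_exac, sift, clinvar_sig)
}

mk_clinical <- function(ids) {
  data.frame(patient_id = as.character(ids), sex = "male", age = 65L,
             stage = "II", site = "mid", macroscopic_type = "polypoid",
             smoker = TRUE, overall_survival_months = NA_real_,
             alive = NA, stringsAsFactors = FALSE)
}

# Random valid variant tables for round-trip / property tests.  Numeric
# fields are rounded so text serialization is exact.
rand_variants <- function(n, patient_id = "P1") {
  depth <- sample(50:500, n, replace = TRUE)
  alt_reads <- vapply(depth, function(d) sample(0:d, 1L), integer(1))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  variant_table(
    patient_id = patient_id,
    chrom = sample(c("1", "7", "17", "X"), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = ref, alt = alt,
    gene = sample(c("TP53", "PIK3CA", "MET", "EP300"), n, replace = TRUE),
    variant_class = sample(variant_classes(), n, replace = TRUE),
    protein_change = ifelse(runif(n) < 0.5, "", "p.E545K"),
    cdna_change = "", vaf = round(runif(n), 6), alt_reads = alt_reads,
    depth = depth, cosmic = runif(n) < 0.5,
    popfreq_1000g = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.2), 6)),
    popfreq_exac = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.2), 6)),
    sift = sample(c("deleterious", "neutral", NA), n, replace = TRUE),
    clinvar_sig = sample(c("", "Benign", "Pathogenic;Benign"), n,
                         replace = TRUE))
}

# Fix alt_reads/vaf consistency is not needed above: vaf is independent of
# alt_reads in the schema (both are reported fields).

load_fixture_variants <- function(name) {
  read_variant_table(system.file("extdata", name, package = "oncosieve"))
}
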