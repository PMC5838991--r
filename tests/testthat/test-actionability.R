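# Naive (alteration x rule) scan used as an oracle for the matcher.
oracle_matches <- function(kept, cnvs, rules) {
  hits <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (r$pattern_type == "amplification") {
      for (j in seq_len(NROW(cnvs)))
        if (cnvs$gene[j] == r$gene && cnvs$call[j] == "gain")
          hits[[length(hits) + 1]] <- c(cnvs$patient_id[j], r$gene,
                                        r$rule_id)
      next
    }
    for (j in seq_len(nrow(kept))) {
      v <- kept[j, ]
      if (v$gene != r$gene) next
      ok <- switch(r$pattern_type,
        exact_protein_change = normalize_protein_change(v$protein_change) ==
          normalize_protein_change(r$pattern_value),
        truncation_class = (r$pattern_value == "nonsense" &&
                              v$variant_class == "stopgain") ||
          (r$pattern_value == "frameshift" &&
             v$variant_class == "frameshift_indel"),
        splice_disruption = grepl("c\\..*[0-9][+-][0-9]+", v$cdna_change),
        any_deleterious = !is.na(v$sift) && v$sift == "deleterious")
      if (ok) hits[[length(hits) + 1]] <- c(v$patient_id, r$gene, r$rule_id)
    }
  }
  unique(do.call(rbind, hits))
}

test_that("the default knowledge base covers the nine actionable genes", {
  kb <- load_knowledge_base()
  expect_gte(nrow(kb), 14L)
  expect_setequal(unique(kb$gene),
                  c("AKT1", "CREBBP", "HNF1A", "IDH1", "MET", "NF1",
                    "PIK3CA", "PTEN", "TP53"))
  e545k <- kb[kb$gene == "PIK3CA" &
                kb$pattern_value == "p.E545K", ]
  expect_equal(nrow(e545k), 1L)
  expect_match(e545k$therapy, "PI3K/AKT/mTOR")
  met <- kb[kb$gene == "MET", ]
  expect_equal(met$pattern_type, "amplification")
  expect_match(met$therapy, "c-MET")
  expect_setequal(kb$pattern_value[kb$pattern_type == "truncation_class"],
                  c("nonsense", "frameshift"))
})

test_that("malformed knowledge bases fail with the rule index", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tpattern_type\tpattern_value\ttherapy",
               "TP53\texact_protein_change\tp.R175H\tx",
               "\tamplification\t\ty"), path)
  expect_error(load_knowledge_base(path), "rule 2")
  writeLines(c("gene\tpattern_type\tpattern_value\ttherapy",
               "TP53\tbogus_pattern\t\tx"), path)
  expect_error(load_knowledge_base(path), "pattern_type")
  writeLines(c("gene\ttherapy", "TP53\tx"), path)
  expect_error(load_knowledge_base(path), "missing columns")
})

test_that("matching semantics cover exact, class, amplification and splice", {
  kb <- load_knowledge_base()
  kept <- rbind(
    mk_var(patient_id = "12", gene = "TP53",
           variant_class = "frameshift_indel", protein_change = "p.K139fs"),
    mk_var(patient_id = "8", gene = "IDH1", variant_class = "missense",
           protein_change = "p.R132H", pos = 2000L),
    # protein notation with a stray space still matches
    mk_var(patient_id = "2", gene = "PIK3CA", variant_class = "missense",
           protein_change = "p.M1043 V", pos = 3000L),
    # an unlisted TP53 missense matches no exact-change or class rule
    mk_var(patient_id = "11", gene = "TP53", variant_class = "missense",
           protein_change = "p.P152L", pos = 4000L))
  matches <- match_alterations(kept, NULL, kb)
  expect_true(any(matches$patient_id == "12" & matches$gene == "TP53" &
                    matches$pattern_type == "truncation_class"))
  m8 <- matches[matches$patient_id == "8", ]
  expect_match(m8$therapy, "pan-IDH")
  expect_true(any(matches$patient_id == "2" & matches$gene == "PIK3CA"))
  expect_false("11" %in% matches$patient_id)
  # amplification matches through CNV segments only
  cnv <- data.frame(patient_id = "7", chrom = "7", start = 1L, end = 10L,
                    gene = "MET", n_bins = 5L, log2_ratio = 1.2,
                    call = "gain")
  m_amp <- match_alterations(empty_variant_table(), cnv, kb)
  expect_equal(m_amp$patient_id, "7")
  expect_equal(m_amp$pattern_type, "amplification")
  # a neutral segment does not match
  cnv$call <- "neutral"
  expect_equal(nrow(match_alterations(empty_variant_table(), cnv, kb)), 0L)
  # splice-disruption rule keys on intronic cDNA notation
  splice <- mk_var(patient_id = "6", gene = "NF1", variant_class = "splice",
                   cdna_change = "c.A3975-2T")
  expect_true("6" %in% match_alterations(splice, NULL, kb)$patient_id)
})

test_that("the reported actionable-alteration fixture yields nine patients", {
  kept <- load_fixture_variants("esc_actionable_variants.tsv")
  cnv <- read.delim(system.file("extdata", "esc_actionable_cnv.tsv",
                                package = "oncosieve"),
                    colClasses = "character")
  kb <- load_knowledge_base()
  matches <- match_alterations(kept, cnv, kb)
  pts <- actionable_patients(matches)
  expect_setequal(pts, as.character(c(2, 3, 5, 6, 7, 8, 9, 12, 13)))
  expect_length(pts, 9L)
  # the matcher agrees with a naive (alteration x rule) scan
  om <- oracle_matches(kept, cnv, kb)
  expect_setequal(paste(matches$patient_id, matches$gene, matches$rule_id),
                  paste(om[, 1], om[, 2], om[, 3]))
})

test_that("actionable patient sets are distinct and monotone in rules", {
  expect_equal(actionable_patients(
    data.frame(patient_id = character())), character(0))
  expect_equal(actionable_patients(
    data.frame(patient_id = c("3", "3", "1"))), c("1", "3"))
  kept <- load_fixture_variants("esc_actionable_variants.tsv")
  kb <- load_knowledge_base()
  # adding rules never removes matches
  for (i in c(3, 7, 11)) {
    sub_kb <- kb[seq_len(i), ]
    m_sub <- match_alterations(kept, NULL, sub_kb)
    m_all <- match_alterations(kept, NULL, kb)
    expect_true(all(paste(m_sub$patient_id, m_sub$rule_id) %in%
                      paste(m_all$patient_id, m_all$rule_id)))
  }
})
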