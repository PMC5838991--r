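fix_clin <- mk_clinical(1:15)

test_that("matrix cells map variant classes and CNV calls to categories", {
  kept <- rbind(
    mk_var(patient_id = "9", gene = "TP53", variant_class = "missense"),
    mk_var(patient_id = "2", gene = "TP53", variant_class = "stopgain",
           pos = 2000L),
    mk_var(patient_id = "5", gene = "PTEN",
           variant_class = "frameshift_indel", pos = 3000L))
  cnv <- data.frame(patient_id = "13", chrom = "3", start = 1L,
                    end = 100L, gene = "PIK3CA", n_bins = 10L,
                    log2_ratio = 1.0, call = "gain")
  m <- build_matrix(kept, cnv, fix_clin)
  expect_equal(matrix_cell(m, "TP53", "9"), "missense")
  expect_equal(matrix_cell(m, "TP53", "2"), "truncating")
  expect_equal(matrix_cell(m, "PTEN", "5"), "truncating")
  expect_equal(matrix_cell(m, "PIK3CA", "13"), "amplification")
  expect_equal(matrix_cell(m, "TP53", "7"), character(0))
  # every clinical patient has a column even when unaltered
  expect_equal(m$patients, fix_clin$patient_id)
  # no calls -> all cells empty
  m0 <- build_matrix(empty_variant_table(), NULL, fix_clin)
  expect_equal(nrow(m0$alterations), 0L)
  expect_true(all(as.matrix(m0) == "") || length(as.matrix(m0)) == 0)
  # unknown patient id is an error listing the offender
  expect_error(build_matrix(mk_var(patient_id = "P99"), NULL, fix_clin),
               "P99")
})

test_that("gene and pathway frequencies count patients, not alterations", {
  kept <- do.call(rbind, c(
    lapply(1:5, function(p) mk_var(patient_id = as.character(p),
                                   gene = "PIK3CA", pos = 1000L + p)),
    lapply(1:15, function(p) mk_var(patient_id = as.character(p),
                                    gene = "TP53", pos = 2000L + p)),
    # patient 1 altered twice in one MMR gene and once in another
    list(mk_var(patient_id = "1", gene = "MSH2", pos = 3000L),
         mk_var(patient_id = "1", gene = "MSH2", pos = 3001L),
         mk_var(patient_id = "1", gene = "MLH1", pos = 3002L))))
  m <- build_matrix(kept, NULL, fix_clin)
  f <- gene_frequency(m, "PIK3CA")
  expect_equal(f$count, 5L)
  expect_equal(round(100 * f$fraction), 33)
  expect_equal(gene_frequency(m, "TP53")$fraction, 1.0)
  expect_error(gene_frequency(m, "NOGENE"), "NOGENE")
  # set semantics: patient 1 counted once for the MMR group
  pf <- pathway_frequency(m, "MMR_proofreading")
  expect_equal(pf$count, 1L)
  expect_equal(pf$patients, "1")
  expect_error(pathway_frequency(m, "NOGROUP"), "NOGROUP")
  # a singleton group behaves exactly like the gene frequency
  m$groups$solo <- "PIK3CA"
  expect_equal(pathway_frequency(m, "solo")$count,
               gene_frequency(m, "PIK3CA")$count)
  # multiset inequality: per-gene counts sum to >= patients altered anywhere
  per_gene <- vapply(m$genes, function(g) gene_frequency(m, g)$count,
                     integer(1))
  expect_gte(sum(per_gene), length(unique(m$alterations$patient_id)))
})

test_that("mutual-exclusivity overlap equals brute-force enumeration", {
  rtk <- gene_groups()$RTK
  # perfectly exclusive: one RTK gene per patient
  kept <- do.call(rbind, lapply(1:7, function(p)
    mk_var(patient_id = as.character(p), gene = rtk[p], pos = 100L + p)))
  m <- build_matrix(kept, NULL, fix_clin)
  expect_equal(mutual_exclusivity_overlap(m, rtk), 0L)
  # one patient with two RTK genes
  kept2 <- rbind(kept, mk_var(patient_id = "1", gene = rtk[2],
                              pos = 999L))
  m2 <- build_matrix(kept2, NULL, fix_clin)
  expect_equal(mutual_exclusivity_overlap(m2, rtk), 1L)
  # random matrices vs enumeration over all patients
  set.seed(61)
  for (i in 1:5) {
    n_alt <- sample(5:25, 1)
    kept_r <- do.call(rbind, lapply(seq_len(n_alt), function(j)
      mk_var(patient_id = as.character(sample(1:15, 1)),
             gene = sample(rtk, 1), pos = 1000L + j)))
    mr <- build_matrix(kept_r, NULL, fix_clin)
    brute <- sum(vapply(fix_clin$patient_id, function(p)
      length(unique(kept_r$gene[kept_r$patient_id == p &
                                  kept_r$gene %in% rtk])) >= 2,
      logical(1)))
    expect_equal(mutual_exclusivity_overlap(mr, rtk), brute)
  }
})

test_that("matrix build is invariant under input row permutation", {
  set.seed(62)
  kept <- rand_variants(40)
  kept$patient_id <- as.character(sample(1:15, 40, replace = TRUE))
  kept$gene <- sample(c("TP53", "MET", "EP300"), 40, replace = TRUE)
  m1 <- build_matrix(kept, NULL, fix_clin)
  m2 <- build_matrix(kept[sample(nrow(kept)), ], NULL, fix_clin)
  expect_equal(as.matrix(m1), as.matrix(m2))
  expect_equal(m1$genes, m2$genes)
})

test_that("MMR triage reports SIFT/ClinVar verbatim with one pathogenic row", {
  mmr <- load_fixture_variants("esc_mmr_variants.tsv")
  tri <- triage_mmr_variants(mmr)
  expect_equal(nrow(tri), 9L)
  expect_setequal(unique(tri$patient_id), as.character(1:5))
  # the stopgain MSH2 variant carries the Pathogenic assertion
  r929 <- tri[tri$protein_change == "p.R929X", ]
  expect_equal(r929$clinvar_sig, "Pathogenic")
  expect_true(r929$pathogenic)
  # conflicting benign/pathogenic submissions are not asserted pathogenic
  expect_equal(sum(tri$pathogenic), 1L)
  expect_equal(nrow(triage_mmr_variants(empty_variant_table())), 0L)
})

test_that("pathogenicity rule handles conflicts and case", {
  expect_true(has_pathogenic_assertion("Pathogenic"))
  expect_true(has_pathogenic_assertion("Likely_pathogenic"))
  expect_false(has_pathogenic_assertion("Likely_benign;pathogenic"))
  expect_false(has_pathogenic_assertion("Benign"))
  expect_false(has_pathogenic_assertion(""))
  expect_false(has_pathogenic_assertion("Not_provided;benign"))
})

test_that("cohort-vs-reference comparison equals exact enumeration", {
  # identical proportions give p = 1
  expect_equal(compare_to_reference(3, 10, 3, 10), 1.0)
  # total separation at n = 15 is overwhelmingly significant
  expect_lt(compare_to_reference(15, 15, 0, 15), 1e-6)
  # random tables with n <= 30 against the hypergeometric oracle
  set.seed(63)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    expect_equal(compare_to_reference(a, n1, b, n2),
                 oracle_fisher(a, n1, b, n2), tolerance = 1e-8,
                 label = sprintf("(%d/%d vs %d/%d)", a, n1, b, n2))
  }
  expect_error(compare_to_reference(-1, 10, 1, 10), "non-negative")
  expect_error(compare_to_reference(11, 10, 1, 10), "exceeds")
  expect_error(compare_to_reference(1.5, 10, 1, 10), "integer")
})
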