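test_that("functional-class filter keeps exactly the four keep-list classes", {
  classes <- variant_classes()
  v <- do.call(rbind, lapply(classes, function(cl)
    mk_var(variant_class = cl)))
  expect_equal(filter_functional_class(v),
               classes %in% c("missense", "stopgain", "frameshift_indel",
                              "nonframeshift_indel"))
  # splice is excluded by default but retained with keep_splice
  expect_equal(filter_functional_class(v, keep_splice = TRUE),
               classes %in% c("missense", "stopgain", "frameshift_indel",
                              "nonframeshift_indel", "splice"))
})

test_that("population-frequency filter is strict at 1% with missing-as-zero", {
  expect_false(filter_population_frequency(mk_var(popfreq_exac = 0.02)))
  expect_true(filter_population_frequency(mk_var()))  # both missing
  expect_true(filter_population_frequency(mk_var(popfreq_1000g = 0.01)))
  expect_false(filter_population_frequency(mk_var(popfreq_1000g = 0.0101)))
  expect_false(filter_population_frequency(
    mk_var(popfreq_1000g = 0.001, popfreq_exac = 0.5)))
})

test_that("blacklist filter removes by normalized allele-specific key", {
  bl <- build_blacklist(lapply(1:2, function(i)
    mk_var(patient_id = sprintf("N%d", i), pos = 500L, alt = "T",
           vaf = 0.05, alt_reads = 20L)), recurrence_fraction = 0.2)
  expect_false(filter_blacklist(mk_var(pos = 500L, alt = "T"), bl))
  expect_true(filter_blacklist(mk_var(pos = 501L, alt = "T"), bl))
  # same site, different alt allele -> kept
  expect_true(filter_blacklist(mk_var(pos = 500L, alt = "G"), bl))
  # chr-prefixed chromosome still matches
  expect_false(filter_blacklist(mk_var(chrom = "chr1", pos = 500L,
                                       alt = "T"), bl))
})

test_that("repeat-region filter respects half-open BED boundaries", {
  rep_rs <- region_set("1", 100, 200, label = "repeats")
  expect_false(filter_repeat_regions(mk_var(pos = 150L), rep_rs))
  # 1-based 201 corresponds to 0-based 200, outside [100,200)
  expect_true(filter_repeat_regions(mk_var(pos = 201L), rep_rs))
  expect_false(filter_repeat_regions(mk_var(pos = 101L), rep_rs))
  expect_true(filter_repeat_regions(mk_var(pos = 100L), rep_rs))
  expect_true(filter_repeat_regions(
    mk_var(), region_set(character(), integer(), integer())))
  expect_true(filter_repeat_regions(mk_var(), NULL))
})

test_that("evidence tiers: 1%/5 reads for COSMIC, 2%/8 reads otherwise", {
  tier <- function(cosmic, vaf, reads) filter_evidence_tier(
    mk_var(cosmic = cosmic, vaf = vaf, alt_reads = as.integer(reads),
           depth = 2000L))
  expect_true(tier(TRUE, 0.015, 6))
  expect_false(tier(FALSE, 0.015, 20))   # VAF not > 2%
  expect_false(tier(TRUE, 0.05, 4))      # read minimum binds independently
  # exhaustive boundary grid against the predicate table
  for (vaf in c(0.0099, 0.01, 0.0101, 0.02, 0.0201))
    for (reads in c(4, 5, 7, 8))
      for (cosmic in c(TRUE, FALSE)) {
        expected <- if (cosmic) vaf > 0.01 && reads >= 5
                    else vaf > 0.02 && reads >= 8
        expect_identical(tier(cosmic, vaf, reads), expected,
                         label = sprintf("cosmic=%s vaf=%s reads=%s",
                                         cosmic, vaf, reads))
      }
})

test_that("cascade equals the intersection of the five predicates, in any order", {
  set.seed(31)
  v <- rand_variants(60)
  # salt in boundary cases around the tiers
  v$vaf[1:8] <- rep(c(0.0099, 0.0101, 0.02, 0.0201), 2)
  bl <- build_blacklist(lapply(1:3, function(i) {
    x <- rand_variants(10, patient_id = sprintf("N%d", i))
    x$pos <- sample(v$pos, 10); x$chrom <- "1"; x$ref <- "A"; x$alt <- "T"
    validate_variants(x)
  }), recurrence_fraction = 0.2)
  reps <- region_set("1", min(v$pos), min(v$pos) + 1000, label = "repeats")
  preds <- list(
    function(x) filter_functional_class(x),
    function(x) filter_population_frequency(x),
    function(x) filter_blacklist(x, bl),
    function(x) filter_repeat_regions(x, reps),
    function(x) filter_evidence_tier(x))
  res <- run_cascade(v, bl, reps)
  # brute-force conjunction
  keep <- Reduce(`&`, lapply(preds, function(p) p(v)))
  expect_equal(res$kept, v[keep, ], ignore_attr = TRUE)
  # order invariance: apply predicates sequentially in permuted orders
  for (i in 1:5) {
    ord <- sample(5)
    surviving <- v
    for (j in ord) surviving <- surviving[preds[[j]](surviving), ,
                                          drop = FALSE]
    expect_equal(sort(rownames(surviving)), sort(rownames(v[keep, ])))
  }
  # idempotence
  again <- run_cascade(res$kept, bl, reps)
  expect_equal(again$kept, res$kept, ignore_attr = TRUE)
})

test_that("the trace records one decision per filter with consistent final_kept", {
  v <- rbind(mk_var(popfreq_exac = 0.05),        # fails only popfreq
             mk_var(pos = 2000L, vaf = 0.30, alt_reads = 90L))
  res <- run_cascade(v)
  tr <- res$trace
  expect_setequal(as.character(unique(tr$filter)),
                  c("functional_class", "population_frequency", "blacklist",
                    "repeat_regions", "evidence_tier"))
  expect_equal(sum(tr$filter == "population_frequency"), 2L)
  k1 <- variant_key(v$chrom[1], v$pos[1], v$ref[1], v$alt[1])
  t1 <- tr[tr$key == k1, ]
  expect_false(unique(t1$final_kept))
  expect_equal(as.character(t1$filter[!t1$passed]), "population_frequency")
  expect_match(t1$reason[!t1$passed], "population frequency")
  # final_kept is the conjunction of the per-filter flags
  agg <- tapply(tr$passed, tr$key, all)
  fin <- tapply(tr$final_kept, tr$key, unique)
  expect_equal(agg[names(fin)], fin)
  # empty input -> empty output
  res0 <- run_cascade(empty_variant_table())
  expect_equal(nrow(res0$kept), 0L)
  expect_equal(nrow(res0$trace), 0L)
})

test_that("optional depth pre-filter participates in trace when enabled", {
  v <- mk_var(depth = 15L, alt_reads = 8L, vaf = 0.53)
  res_off <- run_cascade(v)
  expect_equal(nrow(res_off$kept), 1L)
  res_on <- run_cascade(v, min_depth = 20)
  expect_equal(nrow(res_on$kept), 0L)
  expect_true("depth" %in% res_on$trace$filter)
})
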