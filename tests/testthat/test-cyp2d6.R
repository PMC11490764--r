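test_that("call QC keeps quality >= 20 and strand bias <= 0.90, inclusively", {
  cases <- tibble::tribble(
    ~qual, ~sb,   ~keep,
    19,    0.5,   FALSE,   # quality below 20 excluded
    50,    0.95,  FALSE,   # strand bias above 90% excluded
    20,    0.90,  TRUE,    # both boundaries kept
    40,    0.6,   TRUE)
  expect_equal(qc_filter(cases$qual, cases$sb), cases$keep)
  expect_error(qc_filter(-1, 0.6), "negative")
  expect_error(qc_filter(30, 0.3), "strand bias")
})

test_that("strand bias derives from alt-read counts", {
  expect_equal(strand_bias_from_counts(9, 1), 0.9)
  expect_equal(strand_bias_from_counts(5, 5), 0.5)
  expect_error(strand_bias_from_counts(0, 0), "no alt")
})

test_that("allele assignment follows the VAF copy rules with *1 as default", {
  tbl <- cyp2d6_allele_table(warn_conflicts = FALSE)
  het <- assign_alleles(tibble::tibble(rsid = "rs3892097", vaf = 0.48), tbl)
  expect_equal(het, c("*1", "*4"))
  expect_equal(assign_alleles(tibble::tibble(rsid = character(),
                                             vaf = double()), tbl),
               c("*1", "*1"))
  hom <- assign_alleles(tibble::tibble(rsid = "rs3892097", vaf = 0.95), tbl)
  expect_equal(hom, c("*4", "*4"))
  # sub-threshold VAF treated as absent
  expect_equal(assign_alleles(tibble::tibble(rsid = "rs3892097", vaf = 0.1),
                              tbl),
               c("*1", "*1"))
  # two homozygous defining calls exceed diplotype capacity
  expect_error(
    assign_alleles(tibble::tibble(rsid = c("rs3892097", "rs28371717"),
                                  vaf = c(0.95, 0.95)), tbl),
    "ambiguous")
  # het *4 + het *33 fills both positions
  both <- assign_alleles(tibble::tibble(rsid = c("rs3892097", "rs28371717"),
                                        vaf = c(0.5, 0.5)), tbl)
  expect_equal(both, c("*33", "*4"))
})

test_that("phenotype prediction matches the enumerated rule table", {
  # hand-derived expectations for every activity multiset of size 2 and 3
  lvl <- c(F = "full", S = "semi", N = "null")
  table16 <- tibble::tribble(
    ~combo,  ~phenotype, ~extrapolated,
    "FF",    "EM",  FALSE,
    "FS",    "EM",  FALSE,
    "FN",    "IM",  FALSE,
    "SS",    "IM",  FALSE,
    "SN",    "IM",  TRUE,    # not covered verbatim by the diplotype rules
    "NN",    "PM",  FALSE,
    "FFF",   "UM",  FALSE,
    "FFS",   "EM",  TRUE,
    "FFN",   "EM",  TRUE,
    "FSS",   "EM",  TRUE,
    "FSN",   "EM",  TRUE,
    "FNN",   "IM",  TRUE,
    "SSS",   "IM",  TRUE,
    "SSN",   "IM",  TRUE,
    "SNN",   "IM",  TRUE,
    "NNN",   "PM",  TRUE)
  for (i in seq_len(nrow(table16))) {
    acts <- unname(lvl[strsplit(table16$combo[i], "")[[1]]])
    got <- predict_phenotype(acts)
    expect_equal(as.character(got), table16$phenotype[i],
                 info = table16$combo[i])
    expect_equal(attr(got, "extrapolated"), table16$extrapolated[i],
                 info = table16$combo[i])
  }
})

test_that("phenotype examples from named star alleles", {
  expect_equal(as.character(predict_phenotype(c("*4", "*4"))), "PM")
  expect_equal(as.character(predict_phenotype(c("*1", "*4"))), "IM")
  expect_equal(as.character(predict_phenotype(c("*1", "*10"))), "EM")
  expect_equal(as.character(predict_phenotype(c("*1", "*1", "*2"))), "UM")
  expect_equal(as.character(predict_phenotype(c("*1", "*33"))), "EM")
  expect_error(predict_phenotype("*1"), "at least two")
  expect_error(predict_phenotype(c("*1", "*999")), "without an activity")
})

test_that("degrading one allele never increases the phenotype rank", {
  rank <- c(PM = 1, IM = 2, EM = 3, UM = 4)
  lvls <- c("full", "semi", "null")
  degrade <- list(full = c("semi", "null"), semi = "null",
                  null = character())
  for (a in lvls) for (b in lvls) {
    base <- rank[[as.character(predict_phenotype(c(a, b)))]]
    for (worse in degrade[[a]]) {
      expect_lte(rank[[as.character(predict_phenotype(c(worse, b)))]], base)
    }
  }
})

test_that("the dual-listed alleles keep their first listing and warn", {
  expect_warning(tbl <- cyp2d6_allele_table(), "first listing")
  expect_equal(tbl$activity[tbl$allele == "*53"], "full")
  expect_equal(tbl$activity[tbl$allele == "*41"], "semi")
  expect_equal(tbl$defining_rsids[tbl$allele == "*1"], "")
})

test_that("sample calling recovers planted diplotypes through QC decoys", {
  dips <- list(A = c("*1", "*4"), B = c("*1", "*1"), C = c("*4", "*4"),
               D = c("*1", "*33"))
  og <- generate_organoid_calls(dips, qc_decoy_rate = 0.5, n_decoys = 4,
                                seed = 17)
  res <- call_samples(og$calls)
  res <- res[order(res$sample), ]
  expect_equal(res$status, rep("ok", 4))
  expect_equal(res$diplotype,
               c("*1/*4", "*1/*1", "*4/*4", "*1/*33"))
  expect_equal(res$phenotype, og$diplotype_truth$phenotype)
})

test_that("a sample whose every call fails QC falls back to *1/*1 EM", {
  calls <- tibble::tibble(sample = "X", rsid = "rs3892097", qual = 5,
                          strand_bias = 0.99, vaf = 0.5)
  res <- call_samples(calls)
  expect_equal(res$diplotype, "*1/*1")
  expect_equal(res$phenotype, "EM")
  expect_equal(res$n_retained, 0L)
})

test_that("ambiguous samples are reported by status, not by a crash", {
  calls <- tibble::tibble(sample = c("X", "X", "Y"),
                          rsid = c("rs3892097", "rs28371717", "rs3892097"),
                          qual = 50, strand_bias = 0.6,
                          vaf = c(0.95, 0.95, 0.5))
  res <- call_samples(calls)
  expect_match(res$status[res$sample == "X"], "ambiguous")
  expect_equal(res$phenotype[res$sample == "Y"], "IM")
})
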