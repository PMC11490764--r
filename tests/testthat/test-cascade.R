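test_that("gene classification maps mechanism multisets to the five classes", {
  expect_equal(classify_gene("splice_snv"), 2L)
  expect_equal(classify_gene(c("stop_snv", "splice_snv")), 5L)
  expect_equal(classify_gene("frameshift_indel"), 3L)
  expect_error(classify_gene(character()), "empty")
  expect_error(classify_gene("none"), "invalid mechanism")
})

test_that("gene classification is total and deterministic over small multisets", {
  mechs <- c("stop_snv", "splice_snv", "frameshift_indel", "splice_indel")
  single_class <- c(stop_snv = 1L, splice_snv = 2L, frameshift_indel = 3L,
                    splice_indel = 4L)
  combos <- unlist(lapply(1:3, function(k) {
    apply(expand.grid(rep(list(mechs), k)), 1, function(r) list(as.character(r)))
  }), recursive = FALSE)
  for (ms in combos) {
    ms <- ms[[1]]
    got <- classify_gene(ms)
    expected <- if (length(unique(ms)) >= 2) 5L else single_class[[ms[1]]]
    expect_equal(got, expected)
    expect_equal(classify_gene(rev(ms)), got)  # order-independent
  }
})

test_that("planted decoys drop at their designed stage and survivors are exact", {
  spec <- cohort_spec(demo_cohort_variants(), seed = 42)
  co <- simulate_cohort(spec)
  res <- run_cascade(co$variants, co$transcripts, co$expression, co$loh,
                     co$families)
  v <- dplyr::left_join(res$variants,
                        co$truth[, c("rsid", "designed_fate")], by = "rsid")
  pass <- v$designed_fate == "pass_all"
  expect_true(all(is.na(v$stage_dropped[pass])))
  expect_equal(v$stage_dropped[!pass], unname(FATE_STAGE[v$designed_fate[!pass]]))
  expect_setequal(res$candidates$rsid,
                  co$truth$rsid[co$truth$designed_fate == "pass_all"])
  expect_true(all(res$candidates$supporting_cancers != ""))
})

test_that("cascade stage counts are monotone non-increasing", {
  co <- simulate_cohort(cohort_spec(demo_cohort_variants(), seed = 7))
  res <- run_cascade(co$variants, co$transcripts, co$expression, co$loh,
                     co$families)
  expect_true(all(diff(res$stage_summary$total) <= 0))
  for (m in c("stop_snv", "splice_snv", "frameshift_indel", "splice_indel")) {
    expect_true(all(diff(res$stage_summary[[m]]) <= 0))
  }
})

test_that("cascade survivors equal independent brute-force filter evaluation", {
  for (s in c(3, 19)) {
    co <- simulate_cohort(cohort_spec(demo_cohort_variants(), seed = s))
    res <- run_cascade(co$variants, co$transcripts, co$expression, co$loh,
                       co$families)
    expect_setequal(res$candidates$rsid, brute_force_survivors(co))
  }
})

test_that("final candidate set is invariant to filter application order", {
  co <- simulate_cohort(cohort_spec(demo_cohort_variants(), seed = 5))
  res <- run_cascade(co$variants, co$transcripts, co$expression, co$loh,
                     co$families)
  # sequentially subset by the per-variant predicate outcomes in shuffled
  # stage orders; pure predicates must give the same survivor set
  stages <- c("family", "af", "het", "position", "expression", "loh",
              "all_transcripts")
  v <- res$variants
  set.seed(1)
  for (i in 1:5) {
    ord <- sample(stages)
    surv <- v
    for (st in ord) {
      surv <- surv[is.na(surv$stage_dropped) | surv$stage_dropped != st, ]
    }
    expect_setequal(surv$rsid[is.na(surv$stage_dropped)], res$candidates$rsid)
  }
})

test_that("empty input yields an empty candidate list and zero summary", {
  res <- run_cascade(tibble::tibble(chrom = character(), pos = integer(),
                                    rsid = character(), ref = character(),
                                    alt = character(), af = double(),
                                    het = double()),
                     list(), tibble::tibble(), tibble::tibble())
  expect_equal(nrow(res$candidates), 0)
  expect_true(all(res$stage_summary$total == 0))
})

test_that("validation stage keeps only independently supported rsIDs", {
  co <- simulate_cohort(cohort_spec(demo_cohort_variants(), seed = 9))
  pass_rs <- co$truth$rsid[co$truth$designed_fate == "pass_all"]
  # both pass variants validated in at least one set -> both retained
  res_all <- run_cascade(co$variants, co$transcripts, co$expression, co$loh,
                         co$families,
                         validation = list(pass_rs[1], pass_rs[2]))
  expect_setequal(res_all$candidates$rsid, pass_rs)
  # only one supported -> the other drops at the validation stage
  res_one <- run_cascade(co$variants, co$transcripts, co$expression, co$loh,
                         co$families, validation = list(pass_rs[1]))
  expect_equal(res_one$candidates$rsid, pass_rs[1])
  dropped <- res_one$variants$stage_dropped[res_one$variants$rsid == pass_rs[2]]
  expect_equal(dropped, "validation")
})

test_that("heterozygosity fallback from allele frequency is applied when asked", {
  co <- simulate_cohort(cohort_spec(demo_cohort_variants(), seed = 13))
  co$variants$het <- NA_real_
  expect_message(
    res <- run_cascade(co$variants, co$transcripts, co$expression, co$loh,
                       co$families, het_from_af = TRUE),
    "2\\*af")
  pass_rs <- co$truth$rsid[co$truth$designed_fate == "pass_all"]
  expect_setequal(res$candidates$rsid, pass_rs)
})

test_that("stage count totals sum the mechanism columns", {
  df <- tibble::tibble(stage = c("a", "b"), snv = c(3L, 1L), indel = c(2L, 0L))
  out <- stage_counts(df)
  expect_equal(out$total, c(5L, 1L))
})
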