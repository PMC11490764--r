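test_that("Hardy-Weinberg genotype simulation matches closed-form heterozygosity", {
  # p = 0: degenerate, all homozygous reference
  expect_equal(simulate_genotypes(0, 50, seed = 1), rep(0L, 50))
  # observed het fraction within 3 SE of 2p(1-p)
  for (p in c(0.5, 0.1)) {
    g <- simulate_genotypes(p, 1e5, seed = 42)
    expected <- 2 * p * (1 - p)
    se <- sqrt(expected * (1 - expected) / 1e5)
    expect_lt(abs(mean(g == 1) - expected), 3 * se)
  }
  expect_error(simulate_genotypes(1.5, 10), "\\[0, 1\\]")
  expect_error(simulate_genotypes(0.5, 0), ">= 1")
})

test_that("replicate cohorts at p = 0.2 average to the theoretical heterozygosity", {
  set.seed(99)
  het <- replicate(1000, mean(rbinom(100, 2, 0.2) == 1))
  expect_lt(abs(mean(het) - 0.32), 0.01)
})

test_that("genotype simulation is reproducible under a fixed seed", {
  expect_identical(simulate_genotypes(0.3, 1000, seed = 7),
                   simulate_genotypes(0.3, 1000, seed = 7))
})

test_that("cohort generation writes a valid VCF with the planted frequency", {
  spec <- cohort_spec(tibble::tibble(gene = "GENEA", mechanism = "stop_snv",
                                     af = 0.2), seed = 5)
  out <- withr::local_tempdir()
  gen <- generate_cohort_vcf(spec, out)
  v <- read_vcf(gen$paths$vcf)
  expect_equal(nrow(v), 1)
  se <- sqrt(0.2 * 0.8 / (2 * spec$n_samples))
  expect_lt(abs(v$af - 0.2), 3 * se)
  # het recomputed from GT by the reader equals the generator's observation
  expect_equal(v$het, gen$cohort$variants$het)
  truth <- readr::read_tsv(gen$paths$truth, show_col_types = FALSE)
  expect_equal(truth$designed_fate, "pass_all")
})

test_that("cohort with no planted variants yields a header-only VCF", {
  spec <- cohort_spec(tibble::tibble(gene = character(),
                                     mechanism = character()), seed = 1)
  out <- withr::local_tempdir()
  gen <- generate_cohort_vcf(spec, out)
  expect_equal(nrow(read_vcf(gen$paths$vcf)), 0)
})

test_that("designed fates are recorded and fail_af plants a rare allele", {
  spec <- cohort_spec(tibble::tibble(gene = "DEC", mechanism = "stop_snv",
                                     designed_fate = "fail_af"), seed = 2)
  expect_equal(spec$variants$af, 5e-4)
  co <- simulate_cohort(spec)
  expect_equal(co$truth$designed_fate, "fail_af")
  expect_error(cohort_spec(tibble::tibble(gene = "X", mechanism = "stop_snv",
                                          designed_fate = "fail_everything")),
               "unknown designed_fate")
  expect_error(cohort_spec(tibble::tibble(gene = "X", mechanism = "splice_snv",
                                          designed_fate = "fail_position")),
               "truncating")
})

test_that("cohort generation is byte-identical under a fixed seed", {
  spec <- cohort_spec(demo_cohort_variants(), n_samples = 50, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort_vcf(spec, d1)
  generate_cohort_vcf(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("screen generator hits the logistic midpoint without noise", {
  # IC50 placed on a grid point: viability there must be exactly 50%
  spec2 <- screen_spec(n_compounds = 1, n_hits = 1, ic50_lof_um = 1.25,
                       ic50_ratio = 4, hill = 1, noise_sd = 0, seed = 3)
  sc2 <- generate_screen(spec2)
  row <- dplyr::filter(sc2$plate, line == "line_lof",
                       concentration_nM == 1250)
  v <- normalize_viability(row$signal, row$background, row$dmso_signal)
  expect_equal(unique(round(v, 10)), 50)
})

test_that("screen generator validates its specification", {
  expect_error(screen_spec(n_compounds = 5, n_hits = 6), "n_hits")
  expect_error(screen_spec(noise_sd = -1), "non-negative")
  expect_error(screen_spec(concentrations_nM = c(40, 80)), "DMSO")
  sc0 <- generate_screen(screen_spec(n_compounds = 0, n_hits = 0))
  expect_equal(nrow(sc0$plate), 0)
})

test_that("screen generation is deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- screen_spec(n_compounds = 10, n_hits = 2, seed = 21)
  generate_screen(spec, out_dir = d1)
  generate_screen(spec, out_dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "plate.tsv"))),
                   unname(tools::md5sum(file.path(d2, "plate.tsv"))))
})

test_that("organoid call sets carry defining SNVs at copy-consistent VAF", {
  og <- generate_organoid_calls(list(A = c("*1", "*4")), n_decoys = 0,
                                seed = 4)
  expect_equal(og$calls$rsid, "rs3892097")
  expect_true(og$calls$vaf > 0.2 && og$calls$vaf < 0.8)
  expect_false("rs28371717" %in% og$calls$rsid)
  # reference diplotype: no allele-defining calls at all
  og_ref <- generate_organoid_calls(list(B = c("*1", "*1")), n_decoys = 0,
                                    seed = 4)
  expect_equal(nrow(og_ref$calls), 0)
  # homozygous *4: VAF near 1
  og_hom <- generate_organoid_calls(list(C = c("*4", "*4")), n_decoys = 0,
                                    seed = 4)
  expect_gt(og_hom$calls$vaf, 0.8)
  expect_error(generate_organoid_calls(list(c("*1", "*999"))),
               "unknown star allele")
})

test_that("the requested fraction of organoid decoys fails QC", {
  og <- generate_organoid_calls(list(A = c("*1", "*1"), B = c("*1", "*4")),
                                qc_decoy_rate = 0.5, n_decoys = 4, seed = 6)
  dec <- dplyr::filter(og$truth, is_decoy)
  expect_equal(nrow(dec), 8)
  expect_equal(sum(dec$fails_qc), 4)
  failing <- dplyr::semi_join(og$calls, dplyr::filter(dec, fails_qc),
                              by = c("sample", "rsid"))
  expect_true(all(failing$qual < 20 | failing$strand_bias > 0.90))
})
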