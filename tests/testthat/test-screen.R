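screen_rows <- function(conc, v_wt, v_lof) {
  tibble::tibble(line = rep(c("line_wt", "line_lof"), each = length(conc)),
                 concentration_um = rep(conc, 2),
                 viability = c(v_wt, v_lof))
}

test_that("stage 1 excludes compounds inert at 10 uM in both lines", {
  conc <- c(1, 5, 10)
  s <- stage1_hit(screen_rows(conc, c(95, 90, 85), c(96, 92, 88)))
  expect_false(s$stage1_pass)
  expect_true(s$inert)
})

test_that("stage 1 requires a viability ratio strictly above 1.2", {
  conc <- c(1, 5, 10)
  below <- stage1_hit(screen_rows(conc, c(66, 57.5, 47.6),
                                  c(60, 50, 40)))  # ratios 1.10/1.15/1.19
  expect_false(below$stage1_pass)
  expect_equal(below$max_viability_ratio, 1.19, tolerance = 1e-9)
  above <- stage1_hit(screen_rows(conc, c(90, 60, 30), c(85, 40, 10)))
  expect_true(above$stage1_pass)
  expect_equal(above$max_viability_ratio, 30 / 10)
})

test_that("ratios skip concentrations with non-positive LoF viability", {
  conc <- c(1, 5, 10)
  s <- stage1_hit(screen_rows(conc, c(80, 40, 20), c(70, 30, 0)))
  expect_equal(s$max_viability_ratio, 40 / 30)
})

test_that("stage 1 demands a measurement at the reference dose", {
  expect_error(stage1_hit(screen_rows(c(1, 5), c(80, 40), c(70, 30))),
               "reference dose")
})

test_that("hit confirmation applies the inclusive IC50 ratio threshold", {
  fit_at <- function(ic50) {
    d <- 10^seq(0, 3, length.out = 6)
    fit_dose_response(d, 100 / (1 + d / ic50), "two_param")
  }
  f52 <- fit_at(52)
  confirmed <- confirm_hit(fit_at(114), f52, TRUE)
  expect_equal(confirmed$ic50_ratio, 114 / 52, tolerance = 1e-4)
  expect_true(confirmed$confirmed)
  not <- confirm_hit(fit_at(90), f52, TRUE)
  expect_equal(not$ic50_ratio, 90 / 52, tolerance = 1e-4)
  expect_false(not$confirmed)
  # boundary is exact at ratio = 2 (inclusive): checked on exact IC50s
  boundary <- confirm_hit(104, 52, TRUE)
  expect_identical(boundary$ic50_ratio, 2)
  expect_true(boundary$confirmed)
  expect_false(confirm_hit(103.99, 52, TRUE)$confirmed)
  # stage-1 failures can never be confirmed
  expect_false(confirm_hit(fit_at(114), f52, FALSE)$confirmed)
})

test_that("unconverged fits make a compound unevaluable", {
  d <- c(0.1, 1, 10)
  good <- fit_dose_response(d, 100 / (1 + d), "two_param")
  bad <- fit_dose_response(d, c(99, 100, 98), "two_param")
  res <- confirm_hit(good, bad, TRUE)
  expect_equal(res$status, "unevaluable")
  expect_false(res$confirmed)
})

test_that("run_screen recovers exactly the planted differential hits", {
  sc <- generate_screen(screen_spec(n_compounds = 100, n_hits = 5,
                                    ic50_ratio = 4, noise_sd = 2, seed = 31))
  res <- run_screen(sc$plate)
  expect_equal(res$n_compounds, 100)
  expect_setequal(res$hits$compound[res$hits$confirmed],
                  sc$truth$compound[sc$truth$is_hit])
  expect_equal(res$hit_rate, 5.0)
})

test_that("an empty screen reports an undefined hit rate", {
  res <- run_screen(tibble::tibble())
  expect_equal(res$n_compounds, 0L)
  expect_true(is.na(res$hit_rate))
})

test_that("null screens with identical IC50s confirm almost nothing", {
  sc <- generate_screen(screen_spec(n_compounds = 1000, n_hits = 0,
                                    noise_sd = 3, seed = 53))
  res <- run_screen(sc$plate)
  expect_lt(100 * sum(res$hits$confirmed) / res$n_compounds, 1)
})

test_that("pre-normalized plates are accepted", {
  sc <- generate_screen(screen_spec(n_compounds = 4, n_hits = 1, seed = 5))
  plate <- sc$plate
  plate$viability_pct <- normalize_viability(plate$signal, plate$background,
                                             plate$dmso_signal)
  plate <- plate[, c("compound", "line", "concentration_nM", "replicate",
                     "viability_pct")]
  res_pre <- run_screen(plate, pre_normalized = TRUE)
  res_raw <- run_screen(sc$plate)
  expect_equal(res_pre$hits$confirmed, res_raw$hits$confirmed)
})
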