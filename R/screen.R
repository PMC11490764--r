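#' Stage-1 hit call for one compound across the two cell lines
#'
#' Implements the two-clause screen criterion: compounds showing less than a
#' 20% viability decrease at 10 µM in both lines (i.e. minimum viability
#' across lines > 80%) are excluded as inert; among the rest, a compound
#' passes when the per-concentration viability ratio wild-type line /
#' LoF line exceeds `ratio_min` (default 1.2, strict) at any concentration.
#' Ratios are computed only where the LoF-line viability is positive.
#'
#' @param compound_data Tibble for one compound with columns `line`
#'   (`"line_wt"` / `"line_lof"`), `concentration_um`, `viability`
#'   (replicate means).
#' @param ratio_min Viability-ratio threshold (exceeded strictly).
#' @param inert_viability Viability above which a compound is inert at the
#'   reference dose (default 80%).
#' @param reference_dose_um Dose of the inertness clause (default 10 µM).
#' @return List with `stage1_pass`, `max_viability_ratio`, `inert`.
#' @export
stage1_hit <- function(compound_data, ratio_min = 1.2,
                       inert_viability = 80, reference_dose_um = 10) {
  d <- as_tibble(compound_data) |>
    group_by(.data$line, .data$concentration_um) |>
    summarise(viability = mean(.data$viability), .groups = "drop")
  wide <- tidyr::pivot_wider(d, names_from = "line", values_from = "viability")
  if (!all(c("line_wt", "line_lof") %in% names(wide))) {
    abort("stage1_hit: both line_wt and line_lof measurements required")
  }
  at10 <- filter(wide, abs(.data$concentration_um - reference_dose_um) < 1e-9)
  if (nrow(at10) == 0) {
    abort(sprintf("stage1_hit: no measurement at the %g uM reference dose",
                  reference_dose_um))
  }
  inert <- min(at10$line_wt, at10$line_lof) > inert_viability
  ratios <- with(filter(wide, .data$line_lof > 0),
                 line_wt / line_lof)
  max_ratio <- if (length(ratios)) max(ratios) else NA_real_
  list(stage1_pass = !inert && isTRUE(max_ratio > ratio_min),
       max_viability_ratio = max_ratio,
       inert = inert)
}

#' Confirm a hit by the IC50 ratio criterion
#'
#' A compound is confirmed when it passed stage 1 and the IC50 of the
#' CYP2D6-proficient line divided by that of the LoF line is `>=
#' ic50_ratio_min` (default 2, inclusive). Unconverged fits make the
#' compound unevaluable rather than raising.
#'
#' @param fit_wt,fit_lof [fit_dose_response()] results for the two lines, or
#'   bare numeric IC50s (µM) taken as converged estimates.
#' @param stage1_pass Logical from [stage1_hit()].
#' @param ic50_ratio_min Ratio threshold (met inclusively).
#' @return One-row tibble with `stage1_pass`, `ic50_wt_um`, `ic50_lof_um`,
#'   `ic50_ratio`, `confirmed`, `status`.
#' @export
confirm_hit <- function(fit_wt, fit_lof, stage1_pass, ic50_ratio_min = 2) {
  as_fit <- function(x) {
    if (inherits(x, "dose_response_fit")) x
    else list(ic50 = as.numeric(x), converged = is.finite(x) && x > 0)
  }
  fit_wt <- as_fit(fit_wt); fit_lof <- as_fit(fit_lof)
  if (!fit_wt$converged || !fit_lof$converged) {
    return(tibble(stage1_pass = stage1_pass,
                  ic50_wt_um = NA_real_, ic50_lof_um = NA_real_,
                  ic50_ratio = NA_real_, confirmed = FALSE,
                  status = "unevaluable"))
  }
  ratio <- fit_wt$ic50 / fit_lof$ic50
  tibble(stage1_pass = stage1_pass,
         ic50_wt_um = fit_wt$ic50, ic50_lof_um = fit_lof$ic50,
         ic50_ratio = ratio,
         confirmed = stage1_pass && ratio >= ic50_ratio_min,
         status = "ok")
}

#' Run the full two-line differential-toxicity screen
#'
#' Normalizes viability (unless `pre_normalized`), averages technical
#' replicates per concentration, applies [stage1_hit()] per compound, fits
#' dose-response curves for both lines of the stage-1 selection and calls
#' confirmed hits via [confirm_hit()]. The confirmed hit rate is reported as
#' a percentage with one decimal.
#'
#' @param plate Tibble with columns `compound`, `line`, `concentration_nM`
#'   and either raw signals (`signal`, `background`, `dmso_signal`) or
#'   `viability_pct` with `pre_normalized = TRUE`.
#' @param model Dose-response model for the fits (default `"two_param"`).
#' @param pre_normalized Plate already carries `viability_pct`.
#' @param ratio_min,ic50_ratio_min,inert_viability Thresholds, see
#'   [stage1_hit()] and [confirm_hit()].
#' @return A `screen_result`: list with `hits` (per-compound table),
#'   `hit_rate` (percent, one decimal; `NA` for an empty screen),
#'   `n_compounds`, `model`.
#' @export
run_screen <- function(plate, model = "two_param", pre_normalized = FALSE,
                       ratio_min = 1.2, ic50_ratio_min = 2,
                       inert_viability = 80) {
  plate <- as_tibble(plate)
  if (nrow(plate) == 0) {
    return(structure(list(hits = tibble(), hit_rate = NA_real_,
                          n_compounds = 0L, model = model),
                     class = "screen_result"))
  }
  if (pre_normalized) {
    plate$viability <- plate$viability_pct
  } else {
    plate$viability <- normalize_viability(plate$signal, plate$background,
                                           plate$dmso_signal)
  }
  plate$concentration_um <- plate$concentration_nM / 1000
  agg <- plate |>
    group_by(.data$compound, .data$line, .data$concentration_um) |>
    summarise(viability = mean(.data$viability), .groups = "drop")

  hits <- purrr::map_dfr(split(agg, agg$compound), function(d) {
    cmp <- d$compound[1]
    res <- tryCatch({
      s1 <- stage1_hit(d, ratio_min = ratio_min,
                       inert_viability = inert_viability)
      if (!s1$stage1_pass) {
        tibble(stage1_pass = FALSE,
               max_viability_ratio = s1$max_viability_ratio,
               ic50_wt_um = NA_real_, ic50_lof_um = NA_real_,
               ic50_ratio = NA_real_, confirmed = FALSE,
               status = if (s1$inert) "inert" else "no differential viability")
      } else {
        pos <- filter(d, .data$concentration_um > 0)
        fw <- filter(pos, .data$line == "line_wt")
        fl <- filter(pos, .data$line == "line_lof")
        fit_wt <- fit_dose_response(fw$concentration_um, fw$viability, model)
        fit_lof <- fit_dose_response(fl$concentration_um, fl$viability, model)
        cc <- confirm_hit(fit_wt, fit_lof, TRUE, ic50_ratio_min)
        bind_cols(cc[, "stage1_pass"],
                  tibble(max_viability_ratio = s1$max_viability_ratio),
                  cc[, setdiff(names(cc), "stage1_pass")])
      }
    }, error = function(e) {
      tibble(stage1_pass = NA, max_viability_ratio = NA_real_,
             ic50_wt_um = NA_real_, ic50_lof_um = NA_real_,
             ic50_ratio = NA_real_, confirmed = FALSE,
             status = paste0("error: ", conditionMessage(e)))
    })
    bind_cols(tibble(compound = cmp), res)
  })
  n <- dplyr::n_distinct(agg$compound)
  structure(list(hits = hits,
                 hit_rate = round(100 * sum(hits$confirmed) / n, 1),
                 n_compounds = n, model = model),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d compound(s), %d confirmed hit(s), hit rate %s%%\n",
              x$n_compounds, if (nrow(x$hits)) sum(x$hits$confirmed) else 0L,
              format(x$hit_rate)))
  invisible(x)
}

#' @export
tidy.screen_result <- function(x, ...) x$hits

#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_compounds = x$n_compounds,
         n_stage1 = if (nrow(x$hits)) sum(x$hits$stage1_pass, na.rm = TRUE) else 0L,
         n_confirmed = if (nrow(x$hits)) sum(x$hits$confirmed) else 0L,
         hit_rate = x$hit_rate)
}

#' @export
autoplot.screen_result <- function(object, ...) {
  d <- filter(object$hits, !is.na(.data$ic50_ratio))
  ggplot(d, aes(x = .data$max_viability_ratio, y = .data$ic50_ratio,
                color = .data$confirmed)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1.2, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "max viability ratio (wt / LoF)",
                  y = "IC50 ratio (wt / LoF)",
                  title = "Two-stage hit calling") +
    ggplot2::theme_minimal()
}
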