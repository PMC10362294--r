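#' Dynamic initial iron fractions along the gradient
#'
#' The observed dawn allocation is only known at the two culture iron levels
#' (nitrogenase fraction 15% at 40 pM, 41% at 1250 pM). For other gradient
#' levels the fractions are interpolated in log(Fe') between these anchors
#' and held constant beyond them.
#'
#' @param Fe_prime iron level(s), pM.
#' @return A tibble with `Fe_prime`, `fFe0PS`, `fFe0NF`.
#' @export
gradient_initial_fractions <- function(Fe_prime) {
  lo <- template_config("low"); hi <- template_config("high")
  w <- clamp01((log(Fe_prime) - log(lo$Fe_prime)) /
                 (log(hi$Fe_prime) - log(lo$Fe_prime)))
  tibble::tibble(Fe_prime = Fe_prime,
                 fFe0PS = lo$fPS0 + w * (hi$fPS0 - lo$fPS0),
                 fFe0NF = lo$fNF0 + w * (hi$fNF0 - lo$fNF0))
}

#' Iron-gradient experiment: dynamic vs fixed allocation
#'
#' For each ambient iron level, re-optimizes the case-specific free
#' parameters (see [optimize_growth()]) in both allocation modes and
#' simulates a day, then computes the relative change of growth and
#' N2-fixation attributable to dynamic allocation,
#' `100 * (dynamic - fixed) / fixed`.
#'
#' @param levels iron levels, pM; default 10 log-spaced levels spanning
#'   20-1800 pM.
#' @param params baseline [tf_params()].
#' @param forcing a forcing object (sinusoidal by default, as in the
#'   natural-light experiment).
#' @param n_starts,seed,dt,maxit optimization controls per level and mode.
#' @param reoptimize set `FALSE` to skip per-level optimization and reuse
#'   `params` (fast, for exploration).
#' @return A `tf_gradient` object wrapping a per-(level, mode) summary
#'   tibble; `$comparison` holds the per-level relative changes and `$runs`
#'   the underlying `tf_run`s. [tidy()] returns the long summary table.
#' @export
run_fe_gradient <- function(levels = fe_gradient_levels(),
                            params = tf_params(),
                            forcing = forcing_sinusoidal(),
                            n_starts = 8, seed = 1234, dt = 10,
                            maxit = 300, reoptimize = TRUE) {
  stopifnot(all(diff(levels) > 0))
  fr <- gradient_initial_fractions(levels)
  runs <- list()
  rows <- list()
  for (i in seq_along(levels)) {
    fe <- levels[i]
    for (mode in c("dynamic", "fixed")) {
      case <- case_config(mode, fFe0PS = fr$fFe0PS[i], fFe0NF = fr$fFe0NF[i])
      run <- NULL; failed <- FALSE; note <- ""
      if (reoptimize) {
        fit <- try(optimize_growth(fe, params, forcing, case,
                                   n_starts = n_starts, seed = seed,
                                   dt = dt, maxit = maxit), silent = TRUE)
        if (inherits(fit, "try-error")) {
          failed <- TRUE; note <- as.character(fit)
        } else run <- fit$best_run
      }
      if (is.null(run) && !failed)
        run <- simulate_day(fe, params, forcing, case, dt = dt)
      key <- paste0(mode, "_", signif(fe, 6))
      runs[[key]] <- run
      rows[[key]] <- tibble::tibble(
        Fe_prime = fe, mode = mode, failed = failed, note = note,
        if (failed) tibble::tibble(G = NA_real_) else run$summary)
    }
  }
  tbl <- dplyr::bind_rows(rows)
  cmp <- tbl |>
    dplyr::select("Fe_prime", "mode", "G", "NF_daily") |>
    tidyr::pivot_wider(names_from = "mode",
                       values_from = c("G", "NF_daily")) |>
    dplyr::mutate(
      relative_change_G = 100 * (.data$G_dynamic - .data$G_fixed) /
        .data$G_fixed,
      relative_change_NF = 100 * (.data$NF_daily_dynamic -
                                    .data$NF_daily_fixed) /
        .data$NF_daily_fixed)
  structure(list(summary = tbl, comparison = cmp, runs = runs,
                 levels = levels, seed = seed),
            class = "tf_gradient")
}

#' @rdname run_fe_gradient
#' @param n number of levels.
#' @param from,to range endpoints, pM.
#' @export
fe_gradient_levels <- function(n = 10, from = 20, to = 1800)
  exp(seq(log(from), log(to), length.out = n))

#' @export
print.tf_gradient <- function(x, ...) {
  cat("<tf_gradient> ", length(x$levels), " iron levels, ",
      nrow(x$summary), " runs\n", sep = "")
  print(dplyr::select(x$comparison, "Fe_prime", "G_fixed", "G_dynamic",
                      "relative_change_G"))
  invisible(x)
}

#' Mechanism decomposition: why dynamic allocation helps
#'
#' Compares a paired dynamic and fixed run sharing forcing and iron level:
#' percent change of the daily-integrated photosynthetic O2 production and of
#' the daily-integrated respiratory-protection O2 consumption (fixed case as
#' denominator; negative = reduction), plus the per-step difference in iron
#' trapped in inactivated nitrogenase.
#'
#' @param run_dynamic,run_fixed `tf_run` objects from [simulate_day()] /
#'   [optimize_growth()].
#' @return A list of class `tf_mechanisms`: `dO2_production_pct`, `dRP_pct`,
#'   `Fe_trapped_inactive` (tibble `t`, `dynamic`, `fixed`, `difference`).
#' @export
decompose_mechanisms <- function(run_dynamic, run_fixed) {
  stopifnot(inherits(run_dynamic, "tf_run"), inherits(run_fixed, "tf_run"))
  if (run_dynamic$Fe_prime != run_fixed$Fe_prime ||
      !identical(run_dynamic$forcing, run_fixed$forcing))
    stop("paired runs must share forcing and Fe'", call. = FALSE)
  pct <- function(d, f) {
    if (f == 0) return(NA_real_)
    100 * (d - f) / f
  }
  ts_d <- run_dynamic$time_series; ts_f <- run_fixed$time_series
  n <- min(nrow(ts_d), nrow(ts_f))
  structure(list(
    dO2_production_pct = pct(run_dynamic$summary$O2prod_daily,
                             run_fixed$summary$O2prod_daily),
    dRP_pct = pct(run_dynamic$summary$RP_daily, run_fixed$summary$RP_daily),
    Fe_trapped_inactive = tibble::tibble(
      t = ts_d$t[seq_len(n)],
      dynamic = ts_d$FeNF_inact[seq_len(n)],
      fixed = ts_f$FeNF_inact[seq_len(n)],
      difference = ts_d$FeNF_inact[seq_len(n)] -
        ts_f$FeNF_inact[seq_len(n)])),
    class = "tf_mechanisms")
}

#' @export
print.tf_mechanisms <- function(x, ...) {
  cat("<tf_mechanisms> O2 production change ",
      sprintf("%.1f%%", x$dO2_production_pct),
      ", respiratory-protection change ", sprintf("%.1f%%", x$dRP_pct),
      " (dynamic vs fixed)\n", sep = "")
  invisible(x)
}

#' Derived daily metrics
#'
#' Recomputes the reporting metrics from a run's summary: gross fixed C:N
#' (`grossCF / NF_daily`), the percentage of gross fixed carbon consumed by
#' respiratory protection, and the carbon use efficiency (percentage of
#' gross carbon production assimilated into biomass).
#'
#' @param run a `tf_run` or its one-row summary tibble.
#' @return A one-row tibble: `CN_ratio`, `RP_fraction`, `CUE`.
#' @export
derived_metrics <- function(run) {
  s <- if (inherits(run, "tf_run")) run$summary else run
  if (is.na(s$grossCF) || s$grossCF <= 0)
    stop("grossCF must be > 0", call. = FALSE)
  tibble::tibble(
    CN_ratio = ifelse(s$NF_daily > 0, s$grossCF / s$NF_daily, NA_real_),
    RP_fraction = 100 * s$RP_daily / s$grossCF,
    CUE = 100 * s$dB / s$grossCF)
}

#' Follow-up experiments
#'
#' Three variants of the dynamic case at one iron level, each optimized and
#' reported against the standard optimized dynamic and fixed cases:
#' (i) the initial iron fractions are optimized instead of set from
#' observations; (ii) inactivated nitrogenase decomposes instantly, its iron
#' returning to the buffer; (iii) as (ii) with all allocatable iron started
#' in photosystems (the 90%-of-metabolic-iron experiment; the remaining 10%
#' of metabolic iron is maintenance).
#'
#' @param Fe_prime iron level, pM.
#' @param params baseline [tf_params()].
#' @param forcing a forcing object.
#' @param n_starts,seed,dt,maxit optimization controls.
#' @return A `tf_followup` object wrapping a tibble with one row per case
#'   (standard dynamic, standard fixed, variants i-iii): `G`,
#'   `gain_vs_dynamic_pct`, `gain_vs_fixed_pct`; `$runs` holds the
#'   underlying runs.
#' @export
run_followup_experiments <- function(Fe_prime, params = tf_params(),
                                     forcing = forcing_sinusoidal(),
                                     n_starts = 8, seed = 1234, dt = 10,
                                     maxit = 300) {
  fr <- gradient_initial_fractions(Fe_prime)
  base_dyn <- case_config("dynamic", fFe0PS = fr$fFe0PS, fFe0NF = fr$fFe0NF)
  cases <- list(
    dynamic = base_dyn,
    fixed = case_config("fixed", fFe0PS = fr$fFe0PS, fFe0NF = fr$fFe0NF),
    optimized_initial_pools = case_config("dynamic", fFe0PS = fr$fFe0PS,
                                          fFe0NF = fr$fFe0NF,
                                          optimize_initial_pools = TRUE),
    instant_decomposition = case_config("dynamic", fFe0PS = fr$fFe0PS,
                                        fFe0NF = fr$fFe0NF,
                                        decompose_inactivated = TRUE),
    decomposition_ps90 = case_config("dynamic", fFe0PS = 1, fFe0NF = 0,
                                     decompose_inactivated = TRUE))
  fits <- purrr::map(cases, function(cs)
    optimize_growth(Fe_prime, params, forcing, cs, n_starts = n_starts,
                    seed = seed, dt = dt, maxit = maxit))
  G <- vapply(fits, `[[`, numeric(1), "best_G")
  gain_dyn <- 100 * (unname(G) - G[["dynamic"]]) / G[["dynamic"]]
  gain_fix <- 100 * (unname(G) - G[["fixed"]]) / G[["fixed"]]
  tbl <- tibble::tibble(case = names(cases), G = unname(G),
                        gain_vs_dynamic_pct = gain_dyn,
                        gain_vs_fixed_pct = gain_fix)
  structure(list(summary = tbl, runs = purrr::map(fits, "best_run"),
                 fits = fits, Fe_prime = Fe_prime),
            class = "tf_followup")
}

#' @export
print.tf_followup <- function(x, ...) {
  cat("<tf_followup> Fe' = ", x$Fe_prime, " pM\n", sep = "")
  print(x$summary)
  invisible(x)
}
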