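#' Tidiers and plots for model results
#'
#' `tidy()` returns the long-form content of a result (time series, start
#' table, comparison table); `glance()` a one-row summary. `autoplot()`
#' draws the standard diagnostic figure for each result type.
#'
#' @param x a `tf_run`, `tf_fit`, `tf_gradient` or `tf_followup`.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.tf_run <- function(x, ...) x$time_series

#' @rdname tidiers
#' @export
glance.tf_run <- function(x, ...)
  dplyr::bind_cols(tibble::tibble(Fe_prime = x$Fe_prime,
                                  mode = x$case$mode,
                                  forcing = x$forcing$mode), x$summary)

#' @rdname tidiers
#' @export
tidy.tf_fit <- function(x, ...) x$starts

#' @rdname tidiers
#' @export
glance.tf_fit <- function(x, ...)
  tibble::tibble(Fe_prime = x$Fe_prime, mode = x$best_case$mode,
                 best_G = x$best_G, n_starts = nrow(x$starts),
                 n_converged = sum(x$starts$converged))

#' @rdname tidiers
#' @export
tidy.tf_gradient <- function(x, ...) x$summary

#' @rdname tidiers
#' @export
glance.tf_gradient <- function(x, ...)
  tibble::tibble(n_levels = length(x$levels),
                 benefit_lowest_pct = x$comparison$relative_change_G[1],
                 benefit_highest_pct =
                   x$comparison$relative_change_G[nrow(x$comparison)])

#' @rdname tidiers
#' @export
tidy.tf_followup <- function(x, ...) x$summary

#' @rdname tidiers
#' @export
tidy.tf_calibration <- function(x, ...) x$fit_report

#' @rdname tidiers
#' @param object a `tf_run` or `tf_gradient` (autoplot methods).
#' @export
autoplot.tf_run <- function(object, ...) {
  ts <- object$time_series |>
    dplyr::select("t", "V_CF", "V_NF", "V_RP", "O2") |>
    tidyr::pivot_longer(-"t", names_to = "variable")
  ggplot2::ggplot(ts, ggplot2::aes(.data$t / 3600, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time since dawn (h)", y = NULL,
                  title = sprintf("%s-Fe, Fe' = %g pM", object$case$mode,
                                  object$Fe_prime)) +
    ggplot2::theme_minimal()
}

#' Diurnal iron-pool figure
#'
#' Photosystem, buffer, active and inactivated nitrogenase iron over the
#' light period, one panel per pool, optionally overlaying several runs.
#'
#' @param ... named `tf_run` objects (names become the legend).
#' @return A ggplot object.
#' @export
plot_fe_pools <- function(...) {
  runs <- list(...)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run", seq_along(runs))
  df <- purrr::imap_dfr(runs, function(r, nm)
    dplyr::mutate(dplyr::select(r$time_series, "t", "FePS", "FeBF",
                                "FeNF_act", "FeNF_inact"), run = nm))
  df <- tidyr::pivot_longer(df, c("FePS", "FeBF", "FeNF_act", "FeNF_inact"),
                            names_to = "pool")
  ggplot2::ggplot(df, ggplot2::aes(.data$t / 3600, .data$value,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~pool, scales = "free_y") +
    ggplot2::labs(x = "time since dawn (h)",
                  y = "Fe quota (umol Fe (mol C)-1)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
autoplot.tf_gradient <- function(object, ...) {
  cmp <- object$comparison
  ggplot2::ggplot(cmp, ggplot2::aes(.data$Fe_prime,
                                    .data$relative_change_G)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ambient inorganic Fe (pM)",
                  y = "growth benefit of dynamic allocation (%)") +
    ggplot2::theme_minimal()
}

#' Write run outputs as delimited text
#'
#' Writes `timeseries.tsv` (one row per saved step) and `summary.tsv` (one
#' row of daily metrics) into a directory.
#'
#' @param run a `tf_run`.
#' @param dir output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "tf_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$time_series, file.path(dir, "timeseries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(glance(run), file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
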