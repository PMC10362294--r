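#' Light forcing
#'
#' Two forcing modes are supported: `constant` (culture incubator, as in the
#' constant-light calibration at 90 umol m-2 s-1) and `sinusoidal`
#' (I_max * sin(pi * t / day_length) over a 12-h light period, emulating a
#' natural day).
#'
#' @param I_const photon flux for constant mode, umol m-2 s-1.
#' @param I_max peak photon flux for sinusoidal mode, umol m-2 s-1
#'   (default 200, placing the sinusoidal day's growth close to the
#'   constant-light calibration; see the methods vignette).
#' @param day_length light period, s (default 43200 = 12 h).
#' @param O2_ambient dissolved O2 of the medium, mol m-3 (air-equilibrated
#'   seawater default, 0.21).
#' @return A `tf_forcing` object.
#' @export
#' @examples
#' light_at(forcing_sinusoidal(800), 21600)  # midday peak
forcing_constant <- function(I_const = 90, day_length = 43200,
                             O2_ambient = 0.21) {
  stopifnot(I_const >= 0, day_length > 0, O2_ambient >= 0)
  structure(list(mode = "constant", I_const = I_const, I_max = NA_real_,
                 day_length = day_length, O2_ambient = O2_ambient),
            class = "tf_forcing")
}

#' @rdname forcing_constant
#' @export
forcing_sinusoidal <- function(I_max = 200, day_length = 43200,
                               O2_ambient = 0.21) {
  stopifnot(I_max >= 0, day_length > 0, O2_ambient >= 0)
  structure(list(mode = "sinusoidal", I_const = NA_real_, I_max = I_max,
                 day_length = day_length, O2_ambient = O2_ambient),
            class = "tf_forcing")
}

#' @rdname forcing_constant
#' @param forcing a `tf_forcing` object.
#' @param t time since dawn, s; vectorized. Must lie in `[0, day_length]`.
#' @export
light_at <- function(forcing, t) {
  stopifnot(inherits(forcing, "tf_forcing"))
  if (any(t < 0 | t > forcing$day_length))
    stop("t outside the light period [0, ", forcing$day_length, "] s",
         call. = FALSE)
  switch(forcing$mode,
    constant   = rep_len(forcing$I_const, length(t)),
    sinusoidal = forcing$I_max * sin(pi * t / forcing$day_length)
  )
}

#' @export
print.tf_forcing <- function(x, ...) {
  amp <- if (x$mode == "constant") paste0("I = ", x$I_const)
         else paste0("I_max = ", x$I_max)
  cat("<tf_forcing> ", x$mode, " light, ", amp, " umol m-2 s-1, ",
      x$day_length / 3600, " h light period, O2_ambient = ", x$O2_ambient,
      " mol m-3\n", sep = "")
  invisible(x)
}

#' Partition ambient inorganic iron into cellular iron pools
#'
#' Total cellular iron follows a saturating quota curve of the ambient
#' dissolved inorganic iron Fe' (pM); an Fe'-dependent fraction is diverted to
#' storage (luxury uptake, larger under high iron); of the remaining
#' metabolic iron a fixed 10% sits in maintenance, and the rest is the pool
#' dynamically allocatable among photosystems, nitrogenase and buffer.
#'
#' @param Fe_prime ambient dissolved inorganic iron, pM; vectorized, >= 0.
#' @param params a [tf_params()] set.
#' @return A tibble with one row per `Fe_prime`: columns `Fe_prime`,
#'   `Fe_total`, `Fe_storage`, `Fe_maintenance`, `Fe_metabolic_allocatable`
#'   (all iron quotas in umol Fe (mol C)-1).
#' @export
#' @examples
#' partition_iron(c(40, 1250), tf_params())
partition_iron <- function(Fe_prime, params = tf_params()) {
  stopifnot(inherits(params, "tf_params"))
  if (any(!is.finite(Fe_prime)) || any(Fe_prime < 0))
    stop("Fe_prime must be finite and >= 0", call. = FALSE)
  Fe_total <- params$Q_max * Fe_prime / (Fe_prime + params$K_Fe)
  Fe_total[Fe_prime == 0] <- 0
  f_sto <- params$f_sto_max * Fe_prime / (Fe_prime + params$K_sto)
  f_sto[Fe_prime == 0] <- 0
  Fe_storage <- Fe_total * f_sto
  metabolic  <- Fe_total - Fe_storage
  tibble::tibble(
    Fe_prime = Fe_prime,
    Fe_total = Fe_total,
    Fe_storage = Fe_storage,
    Fe_maintenance = params$f_maint * metabolic,
    Fe_metabolic_allocatable = (1 - params$f_maint) * metabolic
  )
}
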