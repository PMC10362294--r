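#' Template diurnal iron trajectories
#'
#' Smooth stand-ins for the laboratory diurnal iron-quota measurements the
#' model is calibrated against (raw culture data are not redistributable, so
#' these synthetic curves encode their published features): photosystem iron
#' declines monotonically with a decline that slows over the day,
#' nitrogenase iron rises monotonically and saturates, and the dawn
#' nitrogenase fractions of allocatable metabolic iron are 15% (low iron,
#' Fe' = 40 pM) and 41% (high iron, Fe' = 1250 pM). End-of-day fractions and
#' e-folding times are co-calibrated with the model (see the methods
#' vignette).
#'
#' @param level `"low"` or `"high"`.
#' @param day_length light period, s.
#' @param params a [tf_params()] (sets the iron partition).
#' @param n number of points in the returned series.
#' @return A tibble: `time_s`, `FePS`, `FeNF` (umol Fe (mol C)-1), plus the
#'   level's `Fe_prime` and initial fractions as attributes.
#' @export
template_fe_trajectories <- function(level = c("low", "high"),
                                     day_length = 43200,
                                     params = tf_params(), n = 97) {
  level <- match.arg(level)
  cfg <- template_config(level)
  alloc <- partition_iron(cfg$Fe_prime, params)$Fe_metabolic_allocatable
  t <- seq(0, day_length, length.out = n)
  fPS <- cfg$fPS_end + (cfg$fPS0 - cfg$fPS_end) * exp(-t / cfg$tau)
  fNF <- cfg$fNF_end + (cfg$fNF0 - cfg$fNF_end) * exp(-t / cfg$tau)
  out <- tibble::tibble(time_s = t, FePS = alloc * fPS, FeNF = alloc * fNF)
  attr(out, "Fe_prime") <- cfg$Fe_prime
  attr(out, "fFe0PS") <- cfg$fPS0
  attr(out, "fFe0NF") <- cfg$fNF0
  attr(out, "level") <- level
  out
}

template_config <- function(level) {
  if (level == "low")
    list(Fe_prime = 40, fPS0 = 0.75, fPS_end = 0.05,
         fNF0 = 0.15, fNF_end = 0.93, tau = 18000,
         growth = 0.26, growth_sd = 0.02)
  else
    list(Fe_prime = 1250, fPS0 = 0.50, fPS_end = 0.02,
         fNF0 = 0.41, fNF_end = 0.68, tau = 22000,
         growth = 0.46, growth_sd = 0.01)
}

#' Generate pseudo-observations for calibration
#'
#' Samples a truth source (a [template_fe_trajectories()] table, any tibble
#' with `time_s`/`FePS`/`FeNF`, or a `tf_run`) at evenly spaced times, adds
#' independent lognormal noise with a given coefficient of variation, and
#' attaches the published daily growth-rate target for the level
#' (0.26 +/- 0.02 d-1 low iron, 0.46 +/- 0.01 d-1 high iron).
#'
#' @param truth_source see above; default is the level's template.
#' @param level `"low"` or `"high"`.
#' @param noise_cv lognormal coefficient of variation (>= 0; 0 returns the
#'   truth exactly).
#' @param n_timepoints number of sampling times across the light period.
#' @param seed integer; same seed reproduces the set exactly.
#' @param params a [tf_params()].
#' @return A `tf_obs` object: list with `Fe_prime`, `time_s`, `FePS`,
#'   `FePS_sd`, `FeNF`, `FeNF_sd`, `growth_obs`, `growth_sd`, `fFe0PS`,
#'   `fFe0NF`, `seed`. `as_tibble()`/[tidy()] give the tabular form.
#' @export
generate_pseudo_obs <- function(level = c("low", "high"),
                                truth_source = NULL, noise_cv = 0.15,
                                n_timepoints = 5, seed = 1,
                                params = tf_params()) {
  level <- match.arg(level)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  stopifnot(n_timepoints >= 2)
  cfg <- template_config(level)
  if (is.null(truth_source))
    truth_source <- template_fe_trajectories(level, params = params)
  if (inherits(truth_source, "tf_run")) {
    ts <- truth_source$time_series
    truth_source <- tibble::tibble(time_s = ts$t, FePS = ts$FePS,
                                   FeNF = ts$FeNF_act + ts$FeNF_inact)
  }
  day_length <- max(truth_source$time_s)
  times <- seq(0, day_length, length.out = n_timepoints)
  tru_ps <- stats::approx(truth_source$time_s, truth_source$FePS,
                          xout = times, rule = 2)$y
  tru_nf <- stats::approx(truth_source$time_s, truth_source$FeNF,
                          xout = times, rule = 2)$y
  # lognormal with E[X] = truth and CV = noise_cv
  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(x) {
    if (noise_cv == 0) return(x)
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  ob <- withr_seed(seed, list(FePS = noisy(tru_ps), FeNF = noisy(tru_nf)))
  structure(list(
    Fe_prime = cfg$Fe_prime, level = level, time_s = times,
    FePS = ob$FePS, FePS_sd = noise_cv * tru_ps,
    FeNF = ob$FeNF, FeNF_sd = noise_cv * tru_nf,
    growth_obs = cfg$growth, growth_sd = cfg$growth_sd,
    fFe0PS = cfg$fPS0, fFe0NF = cfg$fNF0, seed = seed),
    class = "tf_obs")
}

#' @export
print.tf_obs <- function(x, ...) {
  cat("<tf_obs> ", x$level, " iron (Fe' = ", x$Fe_prime, " pM), ",
      length(x$time_s), " timepoints, growth target ", x$growth_obs,
      " +/- ", x$growth_sd, " d-1\n", sep = "")
  invisible(x)
}

#' @export
tidy.tf_obs <- function(x, ...) {
  tibble::tibble(time_s = x$time_s, FePS = x$FePS, FePS_sd = x$FePS_sd,
                 FeNF = x$FeNF, FeNF_sd = x$FeNF_sd)
}

#' Write / read an observation set as delimited text
#'
#' Tab-separated columns `time_s`, `FePS`, `FePS_sd`, `FeNF`, `FeNF_sd`;
#' header comment lines carry the level, Fe', growth target and initial
#' fractions.
#'
#' @param obs a `tf_obs`.
#' @param path file path.
#' @export
write_obs <- function(obs, path) {
  hdr <- sprintf("# level=%s Fe_prime=%g growth=%g growth_sd=%g fFe0PS=%g fFe0NF=%g seed=%d",
                 obs$level, obs$Fe_prime, obs$growth_obs, obs$growth_sd,
                 obs$fFe0PS, obs$fFe0NF, obs$seed)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tidy(obs), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_obs
#' @export
read_obs <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(
    Fe_prime = as.numeric(meta$Fe_prime), level = meta$level,
    time_s = df$time_s, FePS = df$FePS, FePS_sd = df$FePS_sd,
    FeNF = df$FeNF, FeNF_sd = df$FeNF_sd,
    growth_obs = as.numeric(meta$growth),
    growth_sd = as.numeric(meta$growth_sd),
    fFe0PS = as.numeric(meta$fFe0PS), fFe0NF = as.numeric(meta$fFe0NF),
    seed = as.integer(meta$seed)), class = "tf_obs")
}
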