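#' Initial cell state at dawn
#'
#' Carbohydrate and carbon-skeleton pools start at a small post-night level,
#' the fixed-N store is empty, intracellular O2 equals the ambient value, and
#' the allocatable metabolic iron is split among photosystems, nitrogenase
#' and buffer according to the case's initial fractions (inactivated
#' nitrogenase starts empty: the day begins after nighttime resynthesis).
#'
#' @param partition one row of [partition_iron()] (or a Fe' scalar, which is
#'   partitioned with `params`).
#' @param case a [case_config()].
#' @param params a [tf_params()].
#' @param CH2O0,CS0 dawn carbohydrate / carbon-skeleton pools,
#'   mol C (mol C)-1.
#' @param O2_ambient medium O2, mol m-3.
#' @return A named numeric vector: `CH2O`, `CS`, `N`, `O2`, `FePS`, `FeBF`,
#'   `FeNF_act`, `FeNF_inact`.
#' @export
initial_state <- function(partition, case = case_config("dynamic"),
                          params = tf_params(), CH2O0 = 0.01, CS0 = 0.01,
                          O2_ambient = 0.21) {
  if (is.numeric(partition) && is.null(dim(partition)))
    partition <- partition_iron(partition, params)
  alloc <- partition$Fe_metabolic_allocatable[1]
  stopifnot(alloc >= 0)
  c(CH2O = CH2O0, CS = CS0, N = 0, O2 = O2_ambient,
    FePS = case$fFe0PS * alloc,
    FeBF = (1 - case$fFe0PS - case$fFe0NF) * alloc,
    FeNF_act = case$fFe0NF * alloc,
    FeNF_inact = 0)
}

trace_cols <- c(
  "t", "CH2O", "CS", "N", "O2", "FePS", "FeBF", "FeNF_act", "FeNF_inact",
  "int_CF", "int_NF", "int_RP", "int_RESP", "int_O2prod", "int_O2exch",
  "V_PET", "x_LPET", "V_NFmax", "V_NF", "V_CF", "V_RP", "V_RESP", "V_CS",
  "Phi", "T_PS_syn", "T_PS_dec", "T_NF_syn", "T_NF_inact",
  "O2_production", "O2_exchange", "I")

#' Simulate one 12-hour light period
#'
#' Integrates the coupled carbon / nitrogen / O2 / iron state with a
#' fixed-step fourth-order Runge-Kutta scheme (default dt = 10 s), then
#' converts end-of-day pools into a daily growth rate and summary metrics.
#'
#' @param Fe_prime ambient dissolved inorganic iron, pM.
#' @param params a [tf_params()].
#' @param forcing a [forcing_constant()] / [forcing_sinusoidal()].
#' @param case a [case_config()].
#' @param dt integration step, s; must divide the day length.
#' @param save_every store every k-th step in the time series (default:
#'   every minute at dt = 10).
#' @param state0 optional dawn state overriding [initial_state()].
#' @return A `tf_run` object: list with `summary` (one-row tibble: `G`,
#'   `grossCF`, `NF_daily`, `RP_daily`, `RESP_daily`, `CN_ratio`,
#'   `RP_fraction`, `CUE`, `O2prod_daily`, `O2exch_daily`, `dB`, terminal
#'   pools) and `time_series` (tibble, one row per saved step with all state
#'   and flux columns). [tidy()] returns the time series, [glance()] the
#'   summary row.
#' @export
#' @examples
#' run <- simulate_day(40, forcing = forcing_constant(90))
#' glance(run)
simulate_day <- function(Fe_prime, params = tf_params(),
                         forcing = forcing_sinusoidal(),
                         case = case_config("dynamic"), dt = 10,
                         save_every = 6, state0 = NULL) {
  stopifnot(inherits(params, "tf_params"), inherits(forcing, "tf_forcing"),
            inherits(case, "tf_case"))
  if (is.null(state0))
    state0 <- initial_state(Fe_prime, case, params,
                            O2_ambient = forcing$O2_ambient)
  I_amp <- if (forcing$mode == "constant") forcing$I_const else forcing$I_max
  res <- .simulate_day_cpp(
    as.numeric(state0[c("CH2O", "CS", "N", "O2", "FePS", "FeBF",
                        "FeNF_act", "FeNF_inact")]),
    unlist(params), forcing$mode == "sinusoidal", I_amp,
    forcing$day_length, forcing$O2_ambient,
    case$mode == "dynamic", case$decompose_inactivated, dt,
    as.integer(save_every))
  ts <- tibble::as_tibble(as.data.frame(res$trace))
  names(ts) <- trace_cols
  fin <- res$final
  summary <- daily_summary(fin, params, forcing)
  structure(list(summary = summary, time_series = ts,
                 final_state = stats::setNames(fin[1:8], trace_cols[2:9]),
                 Fe_prime = Fe_prime, params = params, forcing = forcing,
                 case = case, dt = dt),
            class = "tf_run")
}

# End-of-day integrals -> daily summary tibble
daily_summary <- function(fin, params, forcing) {
  grossCF <- fin[9]; NF_daily <- fin[10]; RP_daily <- fin[11]
  RESP_daily <- fin[12]; O2prod <- fin[13]; O2exch <- fin[14]
  g <- end_of_day_growth(stats::setNames(fin[1:8], trace_cols[2:9]), params)
  tibble::tibble(
    G = g[["G"]], dB = g[["dB"]],
    grossCF = grossCF, NF_daily = NF_daily,
    RP_daily = RP_daily, RESP_daily = RESP_daily,
    CN_ratio = ifelse(NF_daily > 0, grossCF / NF_daily, NA_real_),
    RP_fraction = ifelse(grossCF > 0, 100 * RP_daily / grossCF, NA_real_),
    CUE = ifelse(grossCF > 0, 100 * g[["dB"]] / grossCF, NA_real_),
    O2prod_daily = O2prod, O2exch_daily = O2exch,
    CH2O_T = fin[1], CS_T = fin[2], N_T = fin[3], O2_T = fin[4],
    FePS_T = fin[5], FeBF_T = fin[6], FeNF_act_T = fin[7],
    FeNF_inact_T = fin[8]
  )
}

#' Daily growth rate from the end-of-day state
#'
#' Biosynthesis is not resolved in time: the biomass increment is the
#' most limiting of fixed nitrogen (at biomass N:C `q_N`), carbon skeletons,
#' and carbohydrate discounted by the biosynthetic energy overhead `c_bio`
#' (C respired per C assembled): `dB = min(N/q_N, CS, CH2O/(1 + c_bio))`,
#' and `G = ln(1 + dB)` per day (culture-dilution convention).
#'
#' @param state named vector with at least `CH2O`, `CS`, `N`
#'   (see [initial_state()] for units).
#' @param params a [tf_params()].
#' @return Named vector `c(G = ..., dB = ...)`, growth in d-1.
#' @export
end_of_day_growth <- function(state, params = tf_params()) {
  dB <- min(state[["N"]] / params$q_N, state[["CS"]],
            state[["CH2O"]] / (1 + params$c_bio))
  dB <- max(dB, 0)
  c(G = log(1 + dB), dB = dB)
}

#' @export
print.tf_run <- function(x, ...) {
  s <- x$summary
  cat("<tf_run> ", x$case$mode, "-Fe, Fe' = ", x$Fe_prime, " pM, ",
      x$forcing$mode, " light\n", sep = "")
  cat(sprintf("  G = %.3f d-1 | gross CF = %.2f | NF = %.4f | C:N = %.1f | RP = %.0f%% | CUE = %.1f%%\n",
              s$G, s$grossCF, s$NF_daily, s$CN_ratio, s$RP_fraction, s$CUE))
  invisible(x)
}

# Pure-R reference integrator built from the exported rate-law functions.
# Used by the tests as the independent cross-check of the C++ path; too slow
# for production runs.
simulate_day_r <- function(Fe_prime, params = tf_params(),
                           forcing = forcing_sinusoidal(),
                           case = case_config("dynamic"), dt = 60,
                           state0 = NULL, t_end = NULL) {
  if (is.null(state0))
    state0 <- initial_state(Fe_prime, case, params,
                            O2_ambient = forcing$O2_ambient)
  if (is.null(t_end)) t_end <- forcing$day_length
  nstep <- round(t_end / dt)
  y <- state0
  deriv <- function(t, y) {
    y <- pmax(y, 0)
    I <- light_at(forcing, min(t, forcing$day_length))
    Phi <- nf_requirement(I, y[["CS"]], min(y[["N"]], params$N_max), params)
    V_RP <- rp_rate(Phi, y[["O2"]], params, CH2O = y[["CH2O"]])
    V_PET <- pet_rate(y[["FePS"]], I, V_RP, params)
    bud <- close_energy_budget(V_PET, y[["FeNF_act"]], y[["O2"]],
                               y[["N"]], params, CH2O = y[["CH2O"]])
    V_CS <- cs_production_rate(y[["CH2O"]], y[["CS"]], params)
    fe <- fe_pool_tendencies(
      list(FePS = y[["FePS"]], FeBF = y[["FeBF"]],
           FeNF_act = y[["FeNF_act"]], FeNF_inact = y[["FeNF_inact"]]),
      I, Phi, y[["O2"]], V_RP, params, case)
    dO2 <- o2_tendency(bud$x_LPET, V_PET, V_RP, bud$V_RESP, y[["O2"]],
                       forcing$O2_ambient, params)
    c(CH2O = bud$V_CF - V_CS - V_RP - bud$V_RESP,
      CS = V_CS, N = bud$V_NF, O2 = dO2,
      FePS = fe$dFePS, FeBF = fe$dFeBF, FeNF_act = fe$dFeNF_act,
      FeNF_inact = fe$dFeNF_inact)
  }
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt
    k1 <- deriv(t, y)
    k2 <- deriv(t + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y <- pmax(y, 0)
  }
  y
}
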