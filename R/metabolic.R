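#' Photosynthetic electron transport rate
#'
#' Total PET rate: a Michaelis term in photosystem iron, a saturating light
#' response, and an exponential inhibition by respiratory protection,
#' `vPETmax * FePS/(FePS+kFePS) * (1 - exp(-alpha_I*I)) * exp(-beta*V_RP)`.
#'
#' @param FePS photosystem iron quota, umol Fe (mol C)-1.
#' @param I photon flux, umol m-2 s-1.
#' @param V_RP respiratory-protection rate, mol C (mol C)-1 s-1.
#' @param params a [tf_params()] set.
#' @return PET rate, mol e- (mol C)-1 s-1. Vectorized over the inputs.
#' @export
pet_rate <- function(FePS, I, V_RP = 0, params = tf_params()) {
  check_nonneg(FePS = FePS, I = I, V_RP = V_RP)
  params$vPETmax * FePS / (FePS + params$kFePS) *
    (1 - exp(-params$alpha_I * I)) * exp(-params$beta * V_RP)
}

#' Intracellular requirement for N2 fixation
#'
#' The dimensionless drive `Phi` in `[0, 1]`: rises with light and with
#' carbon-skeleton availability, falls as the fixed-N store fills,
#' `(1 - exp(-alpha_I*I)) * CS/(CS+kCS) * (N_max - N)/N_max`.
#'
#' @param I photon flux, umol m-2 s-1.
#' @param CS carbon-skeleton pool, mol C (mol C)-1.
#' @param N fixed-nitrogen store, mol N (mol C)-1; must not exceed `N_max`.
#' @inheritParams pet_rate
#' @return Phi, dimensionless. Vectorized.
#' @export
nf_requirement <- function(I, CS, N, params = tf_params()) {
  check_nonneg(I = I, CS = CS, N = N)
  if (any(N > params$N_max * (1 + 1e-12)))
    stop("N exceeds N_max", call. = FALSE)
  (1 - exp(-params$alpha_I * I)) * CS / (CS + params$kCS) *
    (params$N_max - pmin(N, params$N_max)) / params$N_max
}

#' Respiratory-protection rate
#'
#' Wasteful respiration of carbohydrate that draws down intracellular O2 to
#' protect nitrogenase. It increases with the N2-fixation requirement `Phi`
#' and decreases as intracellular O2 rises:
#' `vRPmax * Phi * kO2RP/(O2 + kO2RP)`, additionally scaled to zero as the
#' carbohydrate substrate (and the O2 it consumes) run out.
#'
#' @param Phi N2-fixation requirement in `[0, 1]` (see [nf_requirement()]).
#' @param O2 intracellular O2, mol m-3.
#' @param CH2O carbohydrate pool, mol C (mol C)-1 (source limitation;
#'   `Inf` disables the limiter).
#' @inheritParams pet_rate
#' @return RP rate, mol C (mol C)-1 s-1. Vectorized.
#' @export
rp_rate <- function(Phi, O2, params = tf_params(), CH2O = Inf) {
  check_nonneg(Phi = Phi, O2 = O2)
  if (any(Phi > 1 + 1e-12)) stop("Phi must be in [0, 1]", call. = FALSE)
  params$vRPmax * Phi * params$kO2RP / (O2 + params$kO2RP) *
    src_lim(CH2O, params$lim_CH2O) * src_lim(O2, params$lim_O2)
}

#' N2-fixation rate
#'
#' Realized N2 fixation: the energetic ceiling `V_NFmax` (from
#' [close_energy_budget()]) limited by nitrogenase iron and inhibited by
#' intracellular O2, `V_NFmax * FeNF/(FeNF+kFeNF) * (1 - O2/(O2+kO2NF))`.
#'
#' @param V_NFmax energetic ceiling, mol N (mol C)-1 s-1.
#' @param FeNF active-nitrogenase iron quota, umol Fe (mol C)-1.
#' @inheritParams rp_rate
#' @return N2-fixation rate, mol N (mol C)-1 s-1. Vectorized.
#' @export
nf_rate <- function(V_NFmax, FeNF, O2, params = tf_params()) {
  check_nonneg(V_NFmax = V_NFmax, FeNF = FeNF, O2 = O2)
  V_NFmax * FeNF / (FeNF + params$kFeNF) *
    (1 - O2 / (O2 + params$kO2NF))
}

#' Carbon-skeleton production rate
#'
#' Carbohydrate is converted into carbon skeletons (biosynthetic precursors);
#' production is stimulated by carbohydrate and down-regulated by
#' carbon-skeleton accumulation:
#' `vCSmax * CH2O/(CH2O+kCH2O) * kCSi/(CS+kCSi)`. Consumes carbohydrate
#' one-to-one in carbon.
#'
#' @inheritParams rp_rate
#' @param CS carbon-skeleton pool, mol C (mol C)-1.
#' @return CS production rate, mol C (mol C)-1 s-1. Vectorized.
#' @export
cs_production_rate <- function(CH2O, CS, params = tf_params()) {
  check_nonneg(CH2O = CH2O, CS = CS)
  params$vCSmax * CH2O / (CH2O + params$kCH2O) *
    params$kCSi / (CS + params$kCSi)
}

#' Close the instantaneous ATP/NADPH budget
#'
#' The electron flux from PET is split between the linear pathway (LPET:
#' ATP + NADPH + O2) and the alternative pathway (AET: ATP only) so that the
#' immediate ATP and NADPH demands are met exactly, with nothing wasted:
#'
#' 1. `V_NFmax` is the N2-fixation rate at which post-maintenance ATP and
#'    NADPH would be entirely consumed by N2 fixation alone, at the electron
#'    split that matches its ATP:NADPH demand ratio.
#' 2. Realized `V_NF` is `V_NFmax` reduced by nitrogenase iron and O2
#'    (see [nf_rate()]); a smooth cap keeps the N store below `N_max`.
#' 3. The split `x_LPET` and the carbon-fixation rate `V_CF` then solve the
#'    two-equation linear system in which remaining ATP and NADPH are
#'    exhausted by carbon fixation at its own demand ratio.
#' 4. If PET cannot cover the maintenance ATP drain even at full AET, the
#'    deficit is met by ordinary respiration (`V_RESP` > 0) and
#'    `V_CF = V_NF = 0`.
#'
#' RP consumes carbohydrate but its ATP is wasted as heat and enters no
#' budget.
#'
#' @param V_PET total PET electron flux, mol e- (mol C)-1 s-1.
#' @param FeNF active-nitrogenase iron, umol Fe (mol C)-1.
#' @param O2 intracellular O2, mol m-3.
#' @param N current fixed-N store, mol N (mol C)-1 (for the `N_max` cap).
#' @param CH2O carbohydrate pool (source for deficit respiration).
#' @inheritParams pet_rate
#' @return A tibble with one row per input: `x_LPET`, `V_NFmax`, `V_NF`,
#'   `V_CF`, `V_RESP`.
#' @export
close_energy_budget <- function(V_PET, FeNF, O2, N = 0, params = tf_params(),
                                CH2O = Inf) {
  check_nonneg(V_PET = V_PET, FeNF = FeNF, O2 = O2, N = N)
  aL <- params$atp_per_e_LPET; aA <- params$atp_per_e_AET
  nL <- params$nadph_per_e_LPET
  aN <- params$atp_per_N_NF;  nN <- params$nadph_per_N_NF
  aC <- params$atp_per_C_CF;  nC <- params$nadph_per_C_CF
  m  <- params$atp_maintenance
  if (nL <= 0) stop("nadph_per_e_LPET must be > 0", call. = FALSE)
  dNF <- aA - aL + nL * aN / nN   # ATP shortfall of LPET vs the NF demand
  dCF <- aA - aL + nL * aC / nC
  if (dNF <= 0 || dCF <= 0)
    stop("infeasible stoichiometry: LPET alone over-supplies ATP relative ",
         "to every demand; no interior electron split exists", call. = FALSE)

  n <- max(lengths(list(V_PET, FeNF, O2, N, CH2O)))
  V_PET <- rep_len(V_PET, n); FeNF <- rep_len(FeNF, n)
  O2 <- rep_len(O2, n); N <- rep_len(N, n); CH2O <- rep_len(CH2O, n)

  atp_max <- V_PET * aA                       # all-AET ATP supply
  deficit <- atp_max <= m | V_PET <= 0

  x1 <- ifelse(deficit, 0, pmin(1, (V_PET * aA - m) / (V_PET * dNF)))
  V_NFmax <- ifelse(deficit, 0, V_PET * x1 * nL / nN)
  capN <- clamp01((params$N_max - N) / (0.02 * params$N_max))
  V_NF <- nf_rate(V_NFmax, FeNF, O2, params) * capN
  x <- ifelse(deficit, 0,
              (V_PET * aA - m - V_NF * (aN - nN * aC / nC)) / (V_PET * dCF))
  x <- clamp01(x)
  V_CF <- ifelse(deficit, 0, pmax(0, (V_PET * x * nL - V_NF * nN) / nC))
  V_RESP <- ifelse(deficit,
                   (m - pmax(atp_max, 0)) / params$atp_per_C_RESP *
                     src_lim(CH2O, params$lim_CH2O) * src_lim(O2, params$lim_O2),
                   0)
  tibble::tibble(x_LPET = x, V_NFmax = V_NFmax, V_NF = V_NF, V_CF = V_CF,
                 V_RESP = V_RESP)
}

#' Intracellular O2 tendency
#'
#' `rho_C * (x_LPET*V_PET/e_per_O2 - V_RP - V_RESP) +
#'  kappa_O2 * (O2_ambient - O2)`: LPET produces O2, respiratory protection
#' and ordinary respiration consume it (one O2 per carbohydrate C), and a
#' lumped first-order term exchanges O2 with the medium (positive = influx).
#'
#' @param x_LPET fraction of PET electrons in the linear pathway.
#' @param V_PET PET electron flux, mol e- (mol C)-1 s-1.
#' @param V_RP,V_RESP respiration rates, mol C (mol C)-1 s-1.
#' @param O2 intracellular O2, mol m-3.
#' @param O2_ambient medium O2, mol m-3.
#' @inheritParams pet_rate
#' @param decompose if `TRUE`, return the four additive terms (production,
#'   RP, RESP, exchange) as a tibble instead of their sum.
#' @return dO2/dt in mol O2 m-3 s-1, or a tibble of terms.
#' @export
o2_tendency <- function(x_LPET, V_PET, V_RP, V_RESP, O2, O2_ambient = 0.21,
                        params = tf_params(), decompose = FALSE) {
  check_nonneg(V_PET = V_PET, V_RP = V_RP, V_RESP = V_RESP, O2 = O2)
  production <- params$rho_C * x_LPET * V_PET / params$e_per_O2
  rp   <- -params$rho_C * V_RP
  resp <- -params$rho_C * V_RESP
  exchange <- params$kappa_O2 * (O2_ambient - O2)
  if (decompose)
    tibble::tibble(production = production, rp = rp, resp = resp,
                   exchange = exchange)
  else production + rp + resp + exchange
}

# --- internal helpers -----------------------------------------------------

# smooth source-availability limiter: -> 1 for pool >> k, -> 0 as pool -> 0
src_lim <- function(pool, k) ifelse(is.infinite(pool), 1, pool / (pool + k))

clamp01 <- function(x) pmin(1, pmax(0, x))

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (any(is.na(x)) || any(x < 0))
      stop(nm, " must be >= 0", call. = FALSE)
  }
  invisible(NULL)
}
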