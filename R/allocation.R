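#' Case configuration: dynamic vs fixed iron allocation
#'
#' `dynamic` mode lets iron translocate among photosystems, buffer and
#' nitrogenase during the light period; `fixed` mode freezes photosystem and
#' buffer iron and disables nitrogenase synthesis, but O2-driven nitrogenase
#' inactivation still occurs in both modes. `decompose_inactivated = TRUE`
#' runs the follow-up experiment in which inactivated nitrogenase is
#' decomposed instantly and its iron returned to the buffer pool.
#'
#' @param mode `"dynamic"` or `"fixed"`.
#' @param fFe0PS,fFe0NF initial fractions of allocatable metabolic iron in
#'   photosystems and nitrogenase; their sum must be <= 1, the remainder
#'   starts in the buffer.
#' @param decompose_inactivated logical, see above.
#' @param optimize_initial_pools logical; marks the case whose optimization
#'   also frees `fFe0PS`/`fFe0NF` (used by [optimize_growth()]).
#' @return A `tf_case` object.
#' @export
case_config <- function(mode = c("dynamic", "fixed"),
                        fFe0PS = 0.75, fFe0NF = 0.15,
                        decompose_inactivated = FALSE,
                        optimize_initial_pools = FALSE) {
  mode <- match.arg(mode)
  stopifnot(fFe0PS >= 0, fFe0PS <= 1, fFe0NF >= 0, fFe0NF <= 1)
  if (fFe0PS + fFe0NF > 1 + 1e-12)
    stop("fFe0PS + fFe0NF must be <= 1", call. = FALSE)
  structure(list(mode = mode, fFe0PS = fFe0PS, fFe0NF = fFe0NF,
                 decompose_inactivated = isTRUE(decompose_inactivated),
                 optimize_initial_pools = isTRUE(optimize_initial_pools)),
            class = "tf_case")
}

#' @export
print.tf_case <- function(x, ...) {
  cat("<tf_case> ", x$mode, "-Fe; initial PS/NF/BF fractions ",
      sprintf("%.2f/%.2f/%.2f", x$fFe0PS, x$fFe0NF,
              1 - x$fFe0PS - x$fFe0NF),
      if (x$decompose_inactivated) "; inactivated nitrogenase recycled",
      "\n", sep = "")
  invisible(x)
}

#' Iron translocation rate laws
#'
#' The four iron fluxes among the allocatable metabolic pools:
#' photosystem synthesis from buffer (light-stimulated, saturating in FePS,
#' shut off as the buffer empties), photosystem decomposition back to buffer
#' (stimulated by FePS, inhibited by respiratory protection), nitrogenase
#' synthesis from buffer (driven by the N2-fixation requirement `Phi`), and
#' O2-driven inactivation of active nitrogenase.
#'
#' @param I photon flux, umol m-2 s-1.
#' @param FePS,FeBF,FeNF_act iron quotas, umol Fe (mol C)-1.
#' @param V_RP respiratory-protection rate, mol C (mol C)-1 s-1.
#' @param Phi N2-fixation requirement in `[0, 1]`.
#' @param O2 intracellular O2, mol m-3.
#' @param params a [tf_params()] set.
#' @return Rate in umol Fe (mol C)-1 s-1. Vectorized.
#' @export
ps_synthesis_rate <- function(I, FePS, FeBF = Inf, params = tf_params()) {
  check_nonneg(I = I, FePS = FePS)
  params$TPSmaxBF * (1 - exp(-params$alpha_I * I)) *
    (1 - FePS / (FePS + params$kFePS_syn)) * src_lim(FeBF, params$lim_FeBF)
}

#' @rdname ps_synthesis_rate
#' @export
ps_decomposition_rate <- function(FePS, V_RP = 0, params = tf_params()) {
  check_nonneg(FePS = FePS, V_RP = V_RP)
  params$TBFmaxPS * FePS / (FePS + params$kFePS_dec) *
    exp(-params$beta * V_RP)
}

#' @rdname ps_synthesis_rate
#' @export
nf_synthesis_rate <- function(Phi, FeBF, params = tf_params()) {
  check_nonneg(Phi = Phi, FeBF = FeBF)
  params$TNFmaxBF * Phi * FeBF / (FeBF + params$kFeBF_syn)
}

#' @rdname ps_synthesis_rate
#' @export
nf_inactivation_rate <- function(FeNF_act, O2, params = tf_params()) {
  check_nonneg(FeNF_act = FeNF_act, O2 = O2)
  params$TNFmaxNA * FeNF_act / (FeNF_act + params$kFeNF) *
    O2 / (O2 + params$kO2NF)
}

#' Tendencies of the four allocatable iron pools
#'
#' Assembles d/dt of (FePS, FeBF, FeNF_act, FeNF_inact) from the
#' translocation rate laws under a given case. In `fixed` mode photosystem
#' synthesis/decomposition and nitrogenase synthesis are all zero; only
#' inactivation moves iron (active nitrogenase decays into the inactivated
#' pool). When `decompose_inactivated` is set, the inactivation flux is
#' routed back to the buffer and the inactivated pool stays empty. The four
#' tendencies always sum to zero (allocatable iron is conserved within the
#' day).
#'
#' @param pools named list or vector with `FePS`, `FeBF`, `FeNF_act`,
#'   `FeNF_inact` (umol Fe (mol C)-1).
#' @param I photon flux; `Phi` N2-fixation requirement; `O2` intracellular
#'   O2; `V_RP` respiratory-protection rate.
#' @inheritParams ps_synthesis_rate
#' @param case a [case_config()] object.
#' @return A tibble with one row: the four tendencies `dFePS`, `dFeBF`,
#'   `dFeNF_act`, `dFeNF_inact` plus the individual fluxes `T_PS_syn`,
#'   `T_PS_dec`, `T_NF_syn`, `T_NF_inact`.
#' @export
fe_pool_tendencies <- function(pools, I, Phi, O2, V_RP = 0,
                               params = tf_params(),
                               case = case_config("dynamic")) {
  pools <- as.list(pools)
  dynamic <- case$mode == "dynamic"
  syn_ps <- if (dynamic)
    ps_synthesis_rate(I, pools$FePS, pools$FeBF, params) else 0
  dec_ps <- if (dynamic)
    ps_decomposition_rate(pools$FePS, V_RP, params) else 0
  syn_nf <- if (dynamic)
    nf_synthesis_rate(Phi, pools$FeBF, params) else 0
  inact <- nf_inactivation_rate(pools$FeNF_act, O2, params)
  recycle <- case$decompose_inactivated
  tibble::tibble(
    dFePS = syn_ps - dec_ps,
    dFeBF = dec_ps - syn_ps - syn_nf + if (recycle) inact else 0,
    dFeNF_act = syn_nf - inact,
    dFeNF_inact = if (recycle) 0 else inact,
    T_PS_syn = syn_ps, T_PS_dec = dec_ps, T_NF_syn = syn_nf,
    T_NF_inact = inact
  )
}
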