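#' Model parameter set
#'
#' Builds the full parameter set of the trichome model: iron uptake and
#' partitioning constants, photosynthetic electron transport (PET) kinetics,
#' N2-fixation kinetics, energy stoichiometries, respiratory-protection (RP)
#' control, O2 exchange, iron translocation kinetics, and the growth
#' conversion. Defaults are the shipped calibration: the numberless constants
#' were tuned so that the growth-maximized dynamic-allocation model under
#' constant light (90 umol m-2 s-1) reproduces the observed growth rates
#' (0.26 and 0.46 d-1 at 40 and 1250 pM inorganic iron) and the observed
#' diurnal decline of photosystem iron / rise of nitrogenase iron.
#'
#' Units follow the field convention: rates are per mol cellular carbon per
#' second, iron quotas are umol Fe (mol C)-1, O2 is mol m-3, light is
#' umol photons m-2 s-1.
#'
#' @param ... named overrides of any default, e.g. `tf_params(vPETmax = 2e-3)`.
#' @return An object of class `tf_params`: a named list of scalars.
#' @export
#' @examples
#' p <- tf_params()
#' p$kFeNF
#' tf_params(vRPmax = 2e-4)$vRPmax
tf_params <- function(...) {
  p <- tf_default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  validate_params(p)
  structure(p, class = "tf_params")
}

# Shipped defaults (calibrated; see the methods vignette for provenance of
# every value). Kept as a plain function so tf_params() copies are cheap.
tf_default_params <- function() {
  list(
    ## iron uptake & partition (environment module)
    Q_max      = 500,     # max total Fe quota, umol Fe (mol C)-1
    K_Fe       = 320,     # half-sat of total quota vs Fe', pM
    f_sto_max  = 0.65,    # asymptotic luxury-storage fraction
    K_sto      = 300,     # half-sat of storage fraction vs Fe', pM
    f_maint    = 0.10,    # maintenance share of metabolic Fe (fixed, 10%)
    ## photosynthetic electron transport
    vPETmax    = 2.0e-3,  # mol e- (mol C)-1 s-1
    kFePS      = 30,      # umol Fe (mol C)-1
    alpha_I    = 0.022,   # umol-1 m2 s
    beta       = 12000,   # mol C (mol C)-1 s, RP inhibition of PET
    ## N2 fixation and its requirement signal
    kFeNF      = 100,     # umol Fe (mol C)-1
    kO2NF      = 0.05,    # mol O2 m-3
    N_max      = 0.105,   # mol N (mol C)-1
    kCS        = 0.10,    # mol C (mol C)-1
    ## energy stoichiometry
    e_per_O2        = 4,     # electrons per O2 evolved by LPET
    nadph_per_e_LPET = 0.5,
    atp_per_e_LPET  = 0.75,
    atp_per_e_AET   = 1.0,
    atp_per_C_CF    = 4.0,   # 3 (Calvin) + 1 (CCM surcharge)
    nadph_per_C_CF  = 2.0,
    atp_per_N_NF    = 8.0,   # 16 ATP per N2
    nadph_per_N_NF  = 2.0,
    atp_maintenance = 1.0e-5, # mol ATP (mol C)-1 s-1
    atp_per_C_RESP  = 4.5,
    ## respiratory protection
    vRPmax     = 1.1e-4,  # mol C (mol C)-1 s-1 (optimized per case)
    kO2RP      = 2.0,     # mol O2 m-3
    ## carbon-skeleton production
    vCSmax     = 9.0e-5,  # mol C (mol C)-1 s-1
    kCH2O      = 0.80,    # mol C (mol C)-1
    kCSi       = 0.25,    # mol C (mol C)-1, self-inhibition constant
    ## O2 exchange
    kappa_O2   = 4.0e-4,  # s-1, lumped cell/medium exchange
    rho_C      = 10,      # mol C m-3, effective carbon density
    ## iron translocation
    TPSmaxBF   = 1.0e-5,  # umol Fe (mol C)-1 s-1 (optimized, dynamic case)
    kFePS_syn  = 30,
    TBFmaxPS   = 3.7e-3,  # (optimized, dynamic case)
    kFePS_dec  = 30,
    TNFmaxBF   = 6.0e-3,  # (optimized, dynamic case)
    kFeBF_syn  = 6,
    TNFmaxNA   = 2.5e-3,  # max nitrogenase inactivation, umol Fe (mol C)-1 s-1
    ## growth conversion
    q_N        = 1 / 6.3, # biomass N:C, mol N (mol C)-1
    c_bio      = 0.4,     # C respired per C assembled into biomass
    ## numerics: source-availability limiters (pool units; keep small)
    lim_CH2O   = 1e-3,    # mol C (mol C)-1
    lim_O2     = 0.02,    # mol O2 m-3
    lim_FeBF   = 0.5      # umol Fe (mol C)-1
  )
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  pos <- c("Q_max", "K_Fe", "K_sto", "vPETmax", "kFePS", "alpha_I", "kFeNF",
           "kO2NF", "N_max", "kCS", "e_per_O2", "atp_per_C_RESP", "vRPmax",
           "kO2RP", "vCSmax", "kCH2O", "kCSi", "kappa_O2", "rho_C",
           "TPSmaxBF", "kFePS_syn", "TBFmaxPS", "kFePS_dec", "TNFmaxBF",
           "kFeBF_syn", "TNFmaxNA", "q_N")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p$f_sto_max < 0 || p$f_sto_max >= 1)
    stop("f_sto_max must be in [0, 1)", call. = FALSE)
  if (p$f_maint < 0 || p$f_maint >= 1)
    stop("f_maint must be in [0, 1)", call. = FALSE)
  if (p$nadph_per_C_CF <= 0 || p$nadph_per_N_NF <= 0)
    stop("NADPH demand stoichiometries must be > 0 (budget closure needs a ",
         "finite demand ratio)", call. = FALSE)
  invisible(p)
}

#' @export
print.tf_params <- function(x, ...) {
  cat("<tf_params> ", length(x), " constants\n", sep = "")
  df <- tibble::tibble(parameter = names(x),
                       value = unlist(x, use.names = FALSE))
  print(df, n = length(x))
  invisible(x)
}

#' Read / write a key-value text configuration
#'
#' The on-disk configuration is plain text, one `key = value` per line, with
#' `#` comments. Keys may carry a namespace prefix (`photo.vPETmax`); only the
#' final component is matched against [tf_params()] names. Keys
#' `forcing.*` / `environment.*` / `case.*` are returned separately so a whole
#' run can be described by one file.
#'
#' @param path file path.
#' @return `read_config()`: a list with elements `params` (a `tf_params`),
#'   `forcing`, `environment` and `case` (named lists of the remaining keys).
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line(s): ", paste(ln[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  ns   <- ifelse(grepl(".", keys, fixed = TRUE),
                 sub("\\..*$", "", keys), "")
  leaf <- sub("^.*\\.", "", keys)
  out <- list(forcing = list(), environment = list(), case = list())
  par_over <- list()
  for (i in seq_along(keys)) {
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) v <- vals[i]   # e.g. mode = dynamic
    if (ns[i] %in% c("forcing", "environment", "case")) {
      out[[ns[i]]][[leaf[i]]] <- v
    } else {
      par_over[[leaf[i]]] <- v
    }
  }
  out$params <- do.call(tf_params, par_over)
  out
}

#' @rdname read_config
#' @param params a `tf_params` object.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "tf_params"))
  writeLines(sprintf("%s = %.17g", names(params),
                     unlist(params, use.names = FALSE)), path)
  invisible(path)
}
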