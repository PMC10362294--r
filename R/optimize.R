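#' Growth-maximizing multistart optimization
#'
#' Optimizes the case-specific free parameters to maximize the daily growth
#' rate, mirroring the model's design premise that the organism tunes its
#' physiology for maximal growth. The fixed-allocation case frees the maximal
#' respiratory-protection rate and the two initial iron fractions
#' (`vRPmax`, `fFe0PS`, `fFe0NF`); the dynamic case frees `vRPmax` and the
#' three translocation maxima (`TPSmaxBF`, `TBFmaxPS`, `TNFmaxBF`) while
#' keeping the initial fractions at their observed values; adding
#' `optimize_initial_pools = TRUE` to the case extends the dynamic set with
#' the initial fractions.
#'
#' Starts are Latin-hypercube samples of the box (reproducible under `seed`);
#' each start runs a Nelder-Mead search on a logit-transformed scale so
#' iterates stay inside the bounds.
#'
#' @param Fe_prime ambient inorganic iron, pM.
#' @param params baseline [tf_params()]; non-free entries are held fixed.
#' @param forcing a forcing object.
#' @param case a [case_config()].
#' @param free named list of `c(lower, upper)` bounds; `NULL` uses the
#'   case-appropriate default set from [default_free_params()].
#' @param n_starts number of multistart points.
#' @param seed integer seed making the starts reproducible.
#' @param dt integration step passed to [simulate_day()].
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `tf_fit` object: `best_params` (full `tf_params`), `best_case`
#'   (case with optimized initial fractions when freed), `best_G`,
#'   `best_run` (a `tf_run` at the optimum), and `starts` (tibble of all
#'   start outcomes). [tidy()] returns the per-start table, [glance()] a
#'   one-row summary.
#' @export
optimize_growth <- function(Fe_prime, params = tf_params(),
                            forcing = forcing_sinusoidal(),
                            case = case_config("dynamic"),
                            free = NULL, n_starts = 8, seed = 1234,
                            dt = 10, maxit = 300) {
  stopifnot(n_starts >= 1)
  if (is.null(free)) free <- default_free_params(case)
  nm <- names(free)
  lo <- vapply(free, `[`, numeric(1), 1)
  hi <- vapply(free, `[`, numeric(1), 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("free-parameter bounds must be finite with lower < upper",
         call. = FALSE)

  objective <- function(theta) {  # theta on [0,1]^k
    v <- lo + theta * (hi - lo)
    pc <- apply_free(params, case, nm, v)
    if (is.null(pc)) return(1e6)  # infeasible initial fractions
    run <- try(simulate_day(Fe_prime, pc$params, forcing, pc$case, dt = dt),
               silent = TRUE)
    if (inherits(run, "try-error")) return(1e6)
    -run$summary$G
  }

  # the baseline configuration (current params / case fractions) is always
  # included as a start: the optimizer can never do worse than a feasible
  # nested point it is given
  base_v <- vapply(seq_along(nm), function(k) {
    if (nm[k] %in% c("fFe0PS", "fFe0NF")) case[[nm[k]]] else params[[nm[k]]]
  }, numeric(1))
  base_th <- pmin(pmax((base_v - lo) / (hi - lo), 1e-3), 1 - 1e-3)
  starts <- rbind(base_th, lhs_unit(n_starts, length(nm), seed))
  res <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    th0 <- starts[i, ]
    fn <- function(z) objective(inv_logit(z))
    o <- try(if (length(nm) == 1L) {
      stats::optim(logit(th0), fn, method = "Brent", lower = -13.8,
                   upper = 13.8, control = list(maxit = maxit))
    } else {
      stats::optim(logit(th0), fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-8))
    }, silent = TRUE)
    if (inherits(o, "try-error")) {
      res[[i]] <- list(ok = FALSE, G = NA_real_, theta = th0,
                       msg = as.character(o))
    } else {
      res[[i]] <- list(ok = TRUE, G = -o$value, theta = inv_logit(o$par),
                       msg = "")
    }
  }
  ok <- vapply(res, `[[`, logical(1), "ok")
  if (!any(ok)) {
    diag <- paste(sprintf("start %d: %s", which(!ok),
                          vapply(res[!ok], `[[`, "", "msg")),
                  collapse = "\n")
    stop("all optimization starts failed:\n", diag, call. = FALSE)
  }
  Gs <- vapply(res, `[[`, numeric(1), "G")
  best <- which.max(ifelse(ok, Gs, -Inf))
  vbest <- lo + res[[best]]$theta * (hi - lo)
  pcb <- apply_free(params, case, nm, vbest)
  best_run <- simulate_day(Fe_prime, pcb$params, forcing, pcb$case, dt = dt)

  start_tbl <- tibble::tibble(
    start = seq_along(res), converged = ok, G = Gs,
    purrr::map_dfr(res, function(r)
      stats::setNames(as.list(lo + r$theta * (hi - lo)), nm))
  )
  structure(list(best_params = pcb$params, best_case = pcb$case,
                 best_G = best_run$summary$G, best_run = best_run,
                 free = free, starts = start_tbl, Fe_prime = Fe_prime,
                 forcing = forcing, seed = seed),
            class = "tf_fit")
}

#' Default free-parameter boxes per case
#'
#' @param case a [case_config()].
#' @return Named list of `c(lower, upper)` bounds.
#' @export
default_free_params <- function(case) {
  if (case$mode == "fixed") {
    list(vRPmax = c(2e-5, 6e-4), fFe0PS = c(0.02, 0.98),
         fFe0NF = c(0.02, 0.98))
  } else if (case$optimize_initial_pools) {
    list(vRPmax = c(2e-5, 6e-4), TPSmaxBF = c(1e-5, 1e-3),
         TBFmaxPS = c(1e-5, 8e-3), TNFmaxBF = c(1e-5, 6e-3),
         fFe0PS = c(0.02, 0.98), fFe0NF = c(0.02, 0.98))
  } else {
    list(vRPmax = c(2e-5, 6e-4), TPSmaxBF = c(1e-5, 1e-3),
         TBFmaxPS = c(1e-5, 8e-3), TNFmaxBF = c(1e-5, 6e-3))
  }
}

# Split free values into parameter overrides and case fields; returns NULL
# when the proposed initial fractions are infeasible (sum > 1).
apply_free <- function(params, case, nm, v) {
  v <- unname(v)
  is_case <- nm %in% c("fFe0PS", "fFe0NF")
  p <- params
  if (any(!is_case)) p[nm[!is_case]] <- v[!is_case]
  cs <- case
  if (any(is_case)) {
    for (k in which(is_case)) cs[[nm[k]]] <- v[k]
    if (cs$fFe0PS + cs$fFe0NF > 1) return(NULL)
  }
  class(p) <- "tf_params"
  class(cs) <- "tf_case"
  list(params = p, case = cs)
}

# Latin hypercube on the unit box, reproducible, independent of the global
# RNG stream.
lhs_unit <- function(n, k, seed) {
  withr_seed(seed, {
    m <- matrix(NA_real_, n, k)
    for (j in seq_len(k))
      m[, j] <- (sample.int(n) - stats::runif(n)) / n
    m
  })
}

# minimal local-seed evaluation (avoids a withr dependency)
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

logit <- function(p) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  log(p / (1 - p))
}
inv_logit <- function(z) 1 / (1 + exp(-z))

#' @export
print.tf_fit <- function(x, ...) {
  cat("<tf_fit> best G = ", sprintf("%.4f", x$best_G), " d-1 over ",
      nrow(x$starts), " starts (", sum(x$starts$converged), " converged)\n",
      sep = "")
  invisible(x)
}
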