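# Composite-likelihood fitting of parametric demographic models to
# per-timepoint folded site frequency spectra, with AIC model selection.
#
# Four model families are fitted: constant size (M1), a recent exponential
# size change (M2), an instantaneous ancient size change (M3), and both
# (M4).  Each observed folded SFS (one per sampling time) contributes an
# independent Poisson likelihood over its bins plus the monomorphic class;
# this marginal composite likelihood corresponds to sampling each SFS as a
# leaf at its own time on a single-population size history.

MODEL_IDS <- c("M1_constant", "M2_recent", "M3_ancient", "M4_both")

model_k <- c(M1_constant = 1L, M2_recent = 3L, M3_ancient = 3L,
             M4_both = 5L)

default_model_bounds <- function() {
  list(N = c(10, 5e5),       # all population size parameters
       T_rc = c(10, 120),    # recent-change onset, ybp
       T_ac = c(1e3, 1e5))   # ancient-change time, ybp
}

#' Construct a demographic inference model
#'
#' @param id One of `"M1_constant"`, `"M2_recent"`, `"M3_ancient"`,
#'   `"M4_both"`.
#' @param params Named list of parameters.  M1: `N_constant`.  M2:
#'   `N_contemp`, `N_historic`, `T_rc` (recent change is exponential
#'   between `T_rc` ybp and the present; its rate is fully determined by
#'   the three parameters).  M3: `N_base`, `N_ancient`, `T_ac`
#'   (instantaneous change at `T_ac` ybp).  M4: all five.
#' @param bounds Parameter bounds (see `default_model_bounds`).
#' @return A `demographymodel`.
#' @export
demography_model <- function(id, params, bounds = default_model_bounds()) {
  id <- match.arg(id, MODEL_IDS)
  structure(list(id = id, params = params, bounds = bounds),
            class = "demographymodel")
}

#' Population size of a model at a time before present
#'
#' @param model A `demographymodel`.
#' @param y Years before present (vectorised).
#' @return Numeric vector of diploid sizes.
#' @export
model_size_ybp <- function(model, y) {
  p <- model$params
  recent <- function(y, n_c, n_h, t_rc) {
    ifelse(y >= t_rc, n_h, n_c * (n_h / n_c)^(y / t_rc))
  }
  switch(model$id,
    M1_constant = rep(p$N_constant, length(y)),
    M2_recent = recent(y, p$N_contemp, p$N_historic, p$T_rc),
    M3_ancient = ifelse(y >= p$T_ac, p$N_ancient, p$N_base),
    M4_both = ifelse(y >= p$T_ac, p$N_ancient,
                     recent(y, p$N_contemp, p$N_historic, p$T_rc)))
}

# Discretise the model's size history (shifted so time 0 = sample_time)
# onto a piecewise-constant epoch grid in generations.
model_epochs <- function(model, sample_time, gen_time, grid_points = 512) {
  grid_gen <- c(0, 10^seq(log10(1e-2), log10(1e6),
                          length.out = grid_points))
  y <- sample_time + grid_gen * gen_time
  mid_y <- sample_time +
    sqrt(pmax(grid_gen[-length(grid_gen)], 1e-3) *
           grid_gen[-1]) * gen_time
  N <- model_size_ybp(model, c(mid_y, y[length(y)]))
  list(t_bounds = grid_gen, N = N)
}

#' Composite log-likelihood of a model given per-timepoint folded SFS
#'
#' Sum over timepoints of the Poisson log-likelihood of each folded bin
#' against the model's expected folded SFS truncated at that sampling
#' time, plus a Poisson term for the monomorphic class (`L` minus the
#' expected segregating total).  Empty timepoints (n = 0) contribute
#' nothing.
#'
#' @param model A `demographymodel`.
#' @param observed A `foldedsfs` or list of them (one per timepoint).
#' @param mu Mutation rate per bp per generation.
#' @param gen_time Generation time in years.
#' @param grid_points Expected-SFS discretisation (see
#'   [expected_folded_sfs()]).
#' @return Log-likelihood (scalar; `-Inf` if a positive observation meets
#'   a non-positive expectation).
#' @export
composite_loglik <- function(model, observed, mu, gen_time = 1,
                             grid_points = 512) {
  if (inherits(observed, "foldedsfs")) observed <- list(observed)
  ll <- 0
  for (obs in observed) {
    if (obs$n < 2) next
    ex <- expected_folded_sfs(model, obs$n, obs$L, mu, obs$timepoint,
                              gen_time, grid_points)
    e <- ex$counts
    o <- obs$counts
    bad <- e <= 0 & o > 0
    if (any(bad)) return(structure(-Inf, bad_bins = which(bad)))
    nz <- e > 0
    ll <- ll + sum(o[nz] * log(e[nz]) - e[nz] - lgamma(o[nz] + 1))
    # monomorphic class
    e0 <- obs$L - sum(e)
    o0 <- obs$L - sum(o)
    if (e0 <= 0) return(structure(-Inf, bad_bins = 0L))
    ll <- ll + o0 * log(e0) - e0 - lgamma(o0 + 1)
  }
  ll
}

model_param_spec <- function(id, bounds) {
  N <- bounds$N
  switch(id,
    M1_constant = list(names = "N_constant", lower = N[1], upper = N[2]),
    M2_recent = list(names = c("N_contemp", "N_historic", "T_rc"),
                     lower = c(N[1], N[1], bounds$T_rc[1]),
                     upper = c(N[2], N[2], bounds$T_rc[2])),
    M3_ancient = list(names = c("N_base", "N_ancient", "T_ac"),
                      lower = c(N[1], N[1], bounds$T_ac[1]),
                      upper = c(N[2], N[2], bounds$T_ac[2])),
    M4_both = list(names = c("N_contemp", "N_historic", "T_rc",
                             "N_ancient", "T_ac"),
                   lower = c(N[1], N[1], bounds$T_rc[1], N[1],
                             bounds$T_ac[1]),
                   upper = c(N[2], N[2], bounds$T_rc[2], N[2],
                             bounds$T_ac[2])))
}

#' Optimiser configuration for [fit_model()]
#'
#' @param n_starts Random multi-starts (log-uniform within bounds).
#' @param maxit Iteration cap per start (L-BFGS-B).
#' @param factr Relative convergence tolerance passed to `optim`.
#' @param grid_points Expected-SFS discretisation.
#' @export
optimizer_config <- function(n_starts = 5L, maxit = 80L, factr = 1e9,
                             grid_points = 512L) {
  list(n_starts = n_starts, maxit = maxit, factr = factr,
       grid_points = grid_points)
}

#' Fit one demographic model to observed folded SFS
#'
#' Maximises the composite likelihood with bounded quasi-Newton
#' (`optim(method = "L-BFGS-B")`) on log10-transformed parameters, from
#' `n_starts` log-uniform random starting points; the best converged
#' objective is retained.  Deterministic given `seed`.
#'
#' @param id Model id (see [demography_model()]).
#' @param observed `foldedsfs` or list of them.
#' @param mu Mutation rate.
#' @param gen_time Generation time in years.
#' @param config An [optimizer_config()].
#' @param seed Seed for the multi-start draws.
#' @param bounds Parameter bounds.
#' @return A `fitresult`: model id, fitted parameters, log-likelihood,
#'   AIC, derived `Ne_C_hat` (size at 0 ybp) and `Ne_H_hat` (size at 120
#'   ybp), `converged`, `bound_hit` flags.
#' @export
fit_model <- function(id, observed, mu, gen_time = 1,
                      config = optimizer_config(), seed = 1L,
                      bounds = default_model_bounds()) {
  id <- match.arg(id, MODEL_IDS)
  spec <- model_param_spec(id, bounds)
  lo <- log10(spec$lower); hi <- log10(spec$upper)
  obj <- function(lp) {
    p <- as.list(10^lp)
    names(p) <- spec$names
    m <- demography_model(id, p, bounds)
    ll <- composite_loglik(m, observed, mu, gen_time, config$grid_points)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  set.seed(seed)
  starts <- lapply(seq_len(config$n_starts), function(i) {
    stats::runif(length(lo), lo, hi)
  })
  # include the bounds-centre as a deterministic start
  starts <- c(list((lo + hi) / 2), starts)
  best <- NULL
  any_ok <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = config$maxit,
                                  factr = config$factr)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$convergence %in% c(0L, 1L) && fit$value < 1e11
    if (ok) any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e11) {
    return(structure(list(model = id, params = NULL, loglik = -Inf,
                          aic = Inf, k = model_k[[id]], Ne_C_hat = NA,
                          Ne_H_hat = NA, converged = FALSE,
                          bound_hit = NA), class = "fitresult"))
  }
  p <- as.list(10^best$par)
  names(p) <- spec$names
  m <- demography_model(id, p, bounds)
  ll <- -best$value
  k <- model_k[[id]]
  structure(list(
    model = id, params = p, loglik = ll, aic = 2 * k - 2 * ll, k = k,
    Ne_C_hat = model_size_ybp(m, 0), Ne_H_hat = model_size_ybp(m, 120),
    converged = any_ok,
    bound_hit = any(abs(best$par - lo) < 1e-6 | abs(best$par - hi) < 1e-6)
  ), class = "fitresult")
}

#' @export
print.fitresult <- function(x, ...) {
  cat(x$model, ": loglik =", format(x$loglik), ", AIC =", format(x$aic),
      ", Ne_C =", round(x$Ne_C_hat, 1), ", Ne_H =", round(x$Ne_H_hat, 1),
      if (!isTRUE(x$converged)) "(non-converged)", "\n")
  invisible(x)
}

#' Select the best model by AIC
#'
#' Minimum AIC wins; ties are broken toward fewer parameters;
#' non-converged fits are excluded.
#'
#' @param fits List of `fitresult` objects (>= 2).
#' @param use_aicc Use the small-sample corrected AICc (with the number of
#'   folded bins as the sample size) instead of AIC.
#' @return The winning `fitresult`.
#' @export
select_model <- function(fits, use_aicc = FALSE) {
  if (length(fits) < 2L) stop("need at least two fits")
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged fits to select from")
  fits <- fits[ok]
  crit <- vapply(fits, function(f) {
    if (use_aicc) {
      nb <- attr(f, "n_bins")
      if (is.null(nb)) nb <- Inf
      f$aic + 2 * f$k * (f$k + 1) / max(nb - f$k - 1, 1)
    } else f$aic
  }, numeric(1))
  kk <- vapply(fits, `[[`, numeric(1), "k")
  fits[[order(crit, kk)[1L]]]
}

#' Classify the inferred recent trend
#'
#' `stable` if the winning model has no recent-change component (M1/M3),
#' `declining` if a recent change is present and the contemporary estimate
#' is below the historic one, `expanding` otherwise.
#'
#' @param best A `fitresult`.
#' @return One of `"stable"`, `"declining"`, `"expanding"`.
#' @export
classify_trend <- function(best) {
  if (best$model %in% c("M1_constant", "M3_ancient")) return("stable")
  if (best$Ne_C_hat < best$Ne_H_hat) "declining" else "expanding"
}

#' Fit all four models and classify
#'
#' @inheritParams fit_model
#' @param models Model ids to fit.
#' @return List with `fits`, `best`, `trend`, and a `report` data.frame.
#' @export
fit_sfs_models <- function(observed, mu, gen_time = 1,
                           config = optimizer_config(), seed = 1L,
                           models = MODEL_IDS,
                           bounds = default_model_bounds()) {
  fits <- lapply(seq_along(models), function(i) {
    fit_model(models[i], observed, mu, gen_time, config,
              seed = derive_seed(seed, "fit", models[i]), bounds)
  })
  names(fits) <- models
  best <- select_model(fits)
  report <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model, loglik = f$loglik, aic = f$aic,
               Ne_C_hat = f$Ne_C_hat, Ne_H_hat = f$Ne_H_hat,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  list(fits = fits, best = best, trend = classify_trend(best),
       report = report)
}
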