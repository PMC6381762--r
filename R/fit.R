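## Composite-likelihood fitting of demography models and AIC comparison.

#' Optimizer configuration
#'
#' Nelder-Mead simplex on transformed parameters (log for positive
#' parameters, logit for the admixture fraction and for the admixture time
#' expressed as a fraction of the split time), with a fixed, seeded set of
#' multi-start points drawn log-uniform from documented bounds.
#'
#' @param n_starts number of starts (the first is a moment-based guess, the
#'   rest are random; default 10).
#' @param max_eval maximum function evaluations per start (default 2000).
#' @param tol convergence tolerance on lnCL (default 1e-6).
#' @param seed seed for the start draws.
#' @param linkage_mode `"factor"` divides lnCL by `linkage_factor`
#'   (the 1/1000 correction); `"thin"` assumes the tally was already thinned
#'   to unlinked blocks and applies no factor.
#' @param linkage_factor divisor for the factor mode (default 1000).
#' @param bounds named list of length-2 numeric ranges for
#'   `theta_block`, `T_split`, `c_x`, `m`, `f`, `adm_frac`
#'   (`T_adm = adm_frac * T_split`).
#' @return list of settings.
#' @export
optimizer_config <- function(n_starts = 10L, max_eval = 2000L, tol = 1e-6,
                             seed = 1L, linkage_mode = c("factor", "thin"),
                             linkage_factor = 1000,
                             bounds = list(theta_block = c(1e-3, 10),
                                           T_split = c(0.01, 20),
                                           c_x = c(0.05, 20),
                                           m = c(1e-4, 10),
                                           f = c(0.01, 0.99),
                                           adm_frac = c(0.01, 0.99))) {
  list(n_starts = as.integer(n_starts), max_eval = as.integer(max_eval),
       tol = tol, seed = as.integer(seed),
       linkage_mode = match.arg(linkage_mode),
       linkage_factor = linkage_factor, bounds = bounds)
}

## transform layer: all free parameters mapped to the real line
.par_spec <- function(model) {
  nm <- c("theta_block", "T_split")
  tf <- c("log", "log")
  if (model$deviating != "none") { nm <- c(nm, "c_x"); tf <- c(tf, "log") }
  if (model$type == "IM") { nm <- c(nm, "m"); tf <- c(tf, "log") }
  if (model$type == "ADM") { nm <- c(nm, "f", "adm_frac"); tf <- c(tf, "logit", "logit") }
  list(names = nm, transform = tf)
}

.to_real <- function(p, tf) ifelse(tf == "log", log(p), stats::qlogis(p))
.from_real <- function(z, tf) ifelse(tf == "log", exp(z), stats::plogis(z))

## natural-scale vector -> the `params` expected by composite_loglik
.expand_params <- function(p, model) {
  out <- c(theta_block = unname(p[["theta_block"]]),
           T_split = unname(p[["T_split"]]))
  if (model$deviating != "none") out["c_x"] <- p[["c_x"]]
  if (model$type == "IM") out["m"] <- p[["m"]]
  if (model$type == "ADM") {
    out["f"] <- p[["f"]]
    out["T_adm"] <- p[["adm_frac"]] * p[["T_split"]]
  }
  out
}

.moment_start <- function(tally, model, bounds) {
  cfg <- tally$configs
  N <- sum(cfg$n_blocks)
  mm <- colSums(cfg[, CLASS_NAMES] * cfg$n_blocks) / N
  clamp <- function(x, b) min(max(x, b[1] * 1.5), b[2] / 1.5)
  theta0 <- clamp((mm[["het_v"]] + mm[["het_b"]]) / 4, bounds$theta_block)
  T0 <- clamp(mm[["fixed_diff"]] / (2 * theta0) - 1, bounds$T_split)
  p <- c(theta_block = theta0, T_split = T0)
  if (model$deviating != "none") {
    r <- (mm[["het_b"]] + 1e-6) / (mm[["het_v"]] + 1e-6)
    p["c_x"] <- clamp(if (model$deviating == "B") r else 1 / r, bounds$c_x)
  }
  if (model$type == "IM") p["m"] <- clamp(0.2, bounds$m)
  if (model$type == "ADM") { p["f"] <- 0.2; p["adm_frac"] <- 0.5 }
  p
}

#' Fit one demography model to a bSFS tally
#'
#' Maximizes the composite log-likelihood over the model's free parameters
#' by seeded multi-start Nelder-Mead on transformed parameters, then
#' applies the linkage correction (`lnCL / linkage_factor` by default) and
#' computes `AIC = 2 * n_free_params - 2 * lnCL_corrected`.
#'
#' @param tally a [bsfs_tally]. For the thinning linkage mode, pass the
#'   tally of thinned blocks and set `linkage_mode = "thin"` in the
#'   optimizer configuration.
#' @param model a [demography_model] (structure only; parameter fields act
#'   as placeholders).
#' @param k_max table truncation used for the likelihood (default 3).
#' @param optimizer_cfg see [optimizer_config].
#' @return object of class `fit_result`: `model_id`, `model_type`, `mle`
#'   (named natural-scale vector), `lnCL_raw`, `lnCL_corrected`, `aic`,
#'   `delta_aic` (filled by [compare_models]), `n_free_params`,
#'   `converged`, `boundary_degenerate`, `n_starts_used`, `k_max`.
#' @export
fit_model <- function(tally, model, k_max = 3L,
                      optimizer_cfg = optimizer_config()) {
  stopifnot(inherits(tally, "bsfs_tally"))
  if (nrow(tally$configs) == 0L) stop("tally is empty")
  spec <- .par_spec(model)
  bounds <- optimizer_cfg$bounds
  lo <- vapply(spec$names, function(nm) bounds[[nm]][1], numeric(1))
  hi <- vapply(spec$names, function(nm) bounds[[nm]][2], numeric(1))

  negll <- function(z) {
    p <- stats::setNames(.from_real(z, spec$transform), spec$names)
    if (any(p < lo) || any(p > hi))
      return(1e12 + sum(pmax(lo / p, p / hi, 1) - 1))
    ll <- suppressWarnings(
      composite_loglik(tally, model, .expand_params(p, model), k_max))
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  set.seed(optimizer_cfg$seed)
  starts <- list(.moment_start(tally, model, bounds))
  n_extra <- optimizer_cfg$n_starts - 1L
  if (n_extra > 0) for (s in seq_len(n_extra)) {
    starts[[s + 1L]] <- stats::setNames(
      exp(stats::runif(length(lo), log(lo * 1.2), log(hi / 1.2))), spec$names)
  }

  best <- NULL
  start_vals <- numeric(0)
  for (st in starts) {
    z0 <- .to_real(st[spec$names], spec$transform)
    start_vals <- c(start_vals, -negll(z0))
    opt <- tryCatch(
      stats::optim(z0, negll, method = "Nelder-Mead",
                   control = list(maxit = optimizer_cfg$max_eval,
                                  reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed for model ", model$model_id)

  p_hat <- stats::setNames(.from_real(best$par, spec$transform), spec$names)
  params <- .expand_params(p_hat, model)
  lnCL_raw <- -best$value
  lf <- if (optimizer_cfg$linkage_mode == "factor") optimizer_cfg$linkage_factor else 1
  lnCL_corrected <- lnCL_raw / lf
  k <- model$n_free_params
  boundary <- model$type == "ADM" &&
    (p_hat[["adm_frac"]] > 0.985 || p_hat[["adm_frac"]] < 0.015)

  structure(list(
    model_id = model$model_id,
    model_type = model_type_label(model),
    model = model,
    mle = params,
    lnCL_raw = lnCL_raw,
    lnCL_corrected = lnCL_corrected,
    aic = 2 * k - 2 * lnCL_corrected,
    delta_aic = NA_real_,
    n_free_params = k,
    converged = best$convergence == 0,
    boundary_degenerate = isTRUE(boundary),
    n_starts_used = length(starts),
    start_lnCL = start_vals,
    k_max = as.integer(k_max),
    linkage_mode = optimizer_cfg$linkage_mode,
    linkage_factor = lf
  ), class = "fit_result")
}

#' @exportS3Method base::print
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s (%s): lnCL_raw = %.3f, corrected = %.4f, AIC = %.4f%s>\n",
              x$model_id, x$model_type, x$lnCL_raw, x$lnCL_corrected, x$aic,
              if (!x$converged) ", NOT converged" else ""))
  print(signif(x$mle, 5))
  invisible(x)
}

#' Fit and rank a set of demography models by composite-likelihood AIC
#'
#' Fits every model in the grid and reports the comparison table. The
#' `delta_aic` column follows the sign convention of the published table:
#' `AIC_best - AIC_model`, so the best model is exactly 0 and all others
#' are negative. The textbook non-negative differences are emitted as
#' `delta_aic_std`.
#'
#' @param tally a [bsfs_tally].
#' @param grid list of [demography_model]s (default [model_grid]).
#' @param k_max table truncation.
#' @param optimizer_cfg see [optimizer_config].
#' @return list of class `model_comparison`: `table` (data.frame sorted by
#'   AIC) and `fits` (list of `fit_result` / error messages per model).
#' @export
compare_models <- function(tally, grid = model_grid(), k_max = 3L,
                           optimizer_cfg = optimizer_config()) {
  if (length(grid) < 2L) stop("need at least 2 models to compare")
  fits <- lapply(grid, function(m)
    tryCatch(fit_model(tally, m, k_max, optimizer_cfg),
             error = function(e) structure(list(model_id = m$model_id,
                                                error = conditionMessage(e)),
                                           class = "fit_error")))
  ok <- !vapply(fits, inherits, logical(1), "fit_error")
  tab <- data.frame(
    model_id = vapply(fits, `[[`, character(1), "model_id"),
    model_type = vapply(fits, function(f)
      if (inherits(f, "fit_error")) NA_character_ else f$model_type, character(1)),
    n_free_params = vapply(fits, function(f)
      if (inherits(f, "fit_error")) NA_integer_ else f$n_free_params, integer(1)),
    lnCL_raw = vapply(fits, function(f)
      if (inherits(f, "fit_error")) NA_real_ else f$lnCL_raw, numeric(1)),
    lnCL_corrected = vapply(fits, function(f)
      if (inherits(f, "fit_error")) NA_real_ else f$lnCL_corrected, numeric(1)),
    aic = vapply(fits, function(f)
      if (inherits(f, "fit_error")) NA_real_ else f$aic, numeric(1)),
    converged = vapply(fits, function(f)
      if (inherits(f, "fit_error")) NA else f$converged, logical(1)))
  best <- min(tab$aic, na.rm = TRUE)
  tab$delta_aic <- best - tab$aic
  tab$delta_aic_std <- tab$aic - best
  tab <- tab[order(tab$aic), , drop = FALSE]
  rownames(tab) <- NULL
  for (i in which(ok)) fits[[i]]$delta_aic <- best - fits[[i]]$aic
  structure(list(table = tab, fits = fits), class = "model_comparison")
}

#' @exportS3Method base::print
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$table, digits = 6)
  invisible(x)
}
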