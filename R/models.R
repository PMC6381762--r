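## Demographic scenarios: two demes V and B that merge into a single
## ancestral deme at T_split (time in units of 2*Ne_ref generations,
## backwards from the present). Deme sizes are relative to the reference:
## c_d = Ne_d / Ne_ref, with the ancestor fixed at c_anc = 1. Gene flow is
## either continuous unidirectional migration (IM) or a single admixture
## pulse (ADM). Directions are forwards in time; backwards in time a
## forwards flow B->V means lineages currently in V jump to B.

#' Construct a demography model
#'
#' @param type one of `"DIV"` (strict divergence), `"IM"`
#'   (isolation-with-migration), `"ADM"` (isolation with an admixture pulse).
#' @param direction forwards-in-time direction of gene flow, `"VB"` (V to B)
#'   or `"BV"` (B to V); `NULL` for DIV.
#' @param deviating which species carries a free effective size differing
#'   from the reference: `"none"`, `"V"` or `"B"`. All other demes (and the
#'   ancestor) have relative size 1.
#' @param T_split split time, units of 2*Ne_ref generations (> 0, or 0 for
#'   the degenerate panmictic limit used in tests).
#' @param c_x relative size of the deviating species (ignored when
#'   `deviating = "none"`).
#' @param m backwards migration rate per lineage per 2*Ne_ref generations
#'   (IM only).
#' @param f admixed fraction in `[0, 1]` (ADM only).
#' @param T_adm admixture time, `0 < T_adm < T_split` (ADM only).
#' @param model_id optional label, e.g. `"M3.3"`.
#' @return an object of class `demography_model`.
#' @export
demography_model <- function(type = c("DIV", "IM", "ADM"),
                             direction = NULL,
                             deviating = c("none", "V", "B"),
                             T_split = 1,
                             c_x = 1,
                             m = 0,
                             f = 0,
                             T_adm = NA_real_,
                             model_id = NULL) {
  type <- match.arg(type)
  deviating <- match.arg(deviating)
  if (type == "DIV") {
    direction <- NULL
  } else {
    if (is.null(direction) || !direction %in% c("VB", "BV"))
      stop("direction must be \"VB\" or \"BV\" for ", type, " models")
  }
  if (!is.finite(T_split) || T_split < 0) stop("T_split must be finite and >= 0")
  if (!is.finite(c_x) || c_x <= 0) stop("c_x must be finite and > 0")
  if (type == "IM") {
    if (!is.finite(m) || m < 0) stop("m must be finite and >= 0")
  } else m <- 0
  if (type == "ADM") {
    if (!is.finite(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
    if (!is.finite(T_adm) || T_adm <= 0 || T_adm >= T_split)
      stop("T_adm must satisfy 0 < T_adm < T_split")
  } else { f <- 0; T_adm <- NA_real_ }

  c_V <- if (deviating == "V") c_x else 1
  c_B <- if (deviating == "B") c_x else 1
  n_free <- switch(type, DIV = 2L, IM = 3L, ADM = 4L) +
    (deviating != "none")
  ## free params: theta_block, T_split, (c_x), and m or (f, T_adm)

  structure(list(
    model_id  = model_id %||% paste0(type, if (!is.null(direction)) paste0("_", direction),
                                     if (deviating != "none") paste0("_", deviating, "x")),
    type      = type,
    direction = direction,
    deviating = deviating,
    T_split   = T_split,
    c_V       = c_V,
    c_B       = c_B,
    c_anc     = 1,
    m         = m,
    f         = f,
    T_adm     = T_adm,
    n_free_params = n_free
  ), class = "demography_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.demography_model <- function(x, ...) {
  dir <- if (is.null(x$direction)) "" else
    sprintf(" %s->%s", substr(x$direction, 1, 1), substr(x$direction, 2, 2))
  cat(sprintf("<demography_model %s: %s%s, deviating=%s>\n",
              x$model_id, x$type, dir, x$deviating))
  cat(sprintf("  T_split=%g  c_V=%g c_B=%g c_anc=%g", x$T_split, x$c_V, x$c_B, x$c_anc))
  if (x$type == "IM") cat(sprintf("  m=%g", x$m))
  if (x$type == "ADM") cat(sprintf("  f=%g T_adm=%g", x$f, x$T_adm))
  cat(sprintf("  (%d free params)\n", x$n_free_params))
  invisible(x)
}

## names of free parameters (besides theta_block, which is always free)
.free_param_names <- function(model) {
  p <- c("theta_block", "T_split")
  if (model$deviating != "none") p <- c(p, "c_x")
  if (model$type == "IM") p <- c(p, "m")
  if (model$type == "ADM") p <- c(p, "f", "T_adm")
  p
}

## rebuild a model with free parameter values substituted in
.model_with_params <- function(model, par) {
  demography_model(
    type = model$type, direction = model$direction, deviating = model$deviating,
    T_split = unname(par[["T_split"]]),
    c_x = if (model$deviating != "none") unname(par[["c_x"]]) else 1,
    m = if (model$type == "IM") unname(par[["m"]]) else 0,
    f = if (model$type == "ADM") unname(par[["f"]]) else 0,
    T_adm = if (model$type == "ADM") unname(par[["T_adm"]]) else NA_real_,
    model_id = model$model_id)
}

#' The 13-model scenario grid
#'
#' The model grid compared in the analysis: single-size divergence and
#' isolation-with-migration models (M1.1-M1.3), their two-size counterparts
#' with either species carrying a free effective size (M2.* with V
#' deviating, M3.* with B deviating), and two-size admixture-pulse models
#' (M4.* V deviating, M5.* B deviating). Within each class, `.1` is strict
#' divergence, `.2` has gene flow from V to B, and `.3` from B to V. The
#' model `M3.3` (IM, two sizes with B deviating, flow B to V) is the grid's
#' analogue of the best-supported scenario for the green lizard species pair.
#'
#' Parameter values in the returned models are placeholders; fitting
#' replaces all free parameters.
#'
#' @return list of 13 [demography_model] objects, named by model id.
#' @export
model_grid <- function() {
  g <- list()
  add <- function(id, ...) g[[id]] <<- demography_model(..., model_id = id)
  t0 <- 1; ta <- 0.5
  add("M1.1", type = "DIV", deviating = "none", T_split = t0)
  add("M1.2", type = "IM", direction = "VB", deviating = "none", T_split = t0, m = 0.1)
  add("M1.3", type = "IM", direction = "BV", deviating = "none", T_split = t0, m = 0.1)
  add("M2.1", type = "DIV", deviating = "V", T_split = t0, c_x = 1)
  add("M2.2", type = "IM", direction = "VB", deviating = "V", T_split = t0, c_x = 1, m = 0.1)
  add("M2.3", type = "IM", direction = "BV", deviating = "V", T_split = t0, c_x = 1, m = 0.1)
  add("M3.1", type = "DIV", deviating = "B", T_split = t0, c_x = 1)
  add("M3.2", type = "IM", direction = "VB", deviating = "B", T_split = t0, c_x = 1, m = 0.1)
  add("M3.3", type = "IM", direction = "BV", deviating = "B", T_split = t0, c_x = 1, m = 0.1)
  add("M4.2", type = "ADM", direction = "VB", deviating = "V", T_split = t0, c_x = 1, f = 0.1, T_adm = ta)
  add("M4.3", type = "ADM", direction = "BV", deviating = "V", T_split = t0, c_x = 1, f = 0.1, T_adm = ta)
  add("M5.2", type = "ADM", direction = "VB", deviating = "B", T_split = t0, c_x = 1, f = 0.1, T_adm = ta)
  add("M5.3", type = "ADM", direction = "BV", deviating = "B", T_split = t0, c_x = 1, f = 0.1, T_adm = ta)
  g
}

#' Human-readable model type label in the style of the comparison table
#' @param model a [demography_model]
#' @return character label such as `"IM 2 B(x)->V"`.
#' @export
model_type_label <- function(model) {
  nsz <- if (model$deviating == "none") "1" else "2"
  mark <- function(sp) if (model$deviating == sp) paste0(sp, "(x)") else sp
  if (model$type == "DIV") return(paste0("DIV ", nsz,
    if (model$deviating != "none") paste0(" ", mark(model$deviating)) else ""))
  from <- substr(model$direction, 1, 1); to <- substr(model$direction, 2, 2)
  paste0(model$type, " ", nsz, " ", mark(from), "->", mark(to))
}
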