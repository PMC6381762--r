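## Genome-wide summary statistics and conversion of dimensionless MLEs into
## demographic units.

#' Mutation-rate / generation-time calibration
#'
#' @param mu mutations per site per generation (e.g. 1e-9 from four-fold
#'   degenerate sites, or 1.77e-8 from mitochondrial divergence).
#' @param g generation time in years (default 3.5).
#' @param block_len block length in bases (default 200).
#' @return object of class `calibration`.
#' @export
calibration <- function(mu, g = 3.5, block_len = 200L) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
  if (!is.finite(g) || g <= 0) stop("g must be > 0")
  structure(list(mu = mu, g = g, block_len = as.integer(block_len)),
            class = "calibration")
}

#' Convert dimensionless estimates to demographic units
#'
#' Internal units: time in multiples of 2*Ne_ref generations; deme sizes
#' relative to Ne_ref; `theta_block` is the expected number of mutations per
#' block on a branch of one time unit, i.e.
#' `theta_block = 2 * Ne_ref * mu * block_len` (so that per-site
#' heterozygosity equals the textbook `4 * Ne * mu`). Given a calibration
#' this inverts to individuals, generations and years.
#' Migration is reported under both common conventions, `Ne_recipient * m`
#' and `4 * Ne_recipient * m` migrants per generation, because the scaler
#' behind a printed "migrants per generation" is often left implicit.
#'
#' @param fit a `fit_result` from [fit_model] (must have converged), or a
#'   named parameter vector like its `mle` together with `model`.
#' @param cal a [calibration].
#' @param model the [demography_model]; defaults to `fit$model`.
#' @return list of class `scaled_estimates`.
#' @export
scale_estimates <- function(fit, cal, model = NULL) {
  stopifnot(inherits(cal, "calibration"))
  if (inherits(fit, "fit_result")) {
    if (!fit$converged) stop("fit did not converge; refusing to scale")
    params <- fit$mle
    model <- model %||% fit$model
  } else {
    params <- fit
    if (is.null(model)) stop("model required when scaling a bare parameter vector")
  }
  model <- .model_with_params(model, params)
  theta <- params[["theta_block"]]
  Ne_ref <- theta / (2 * cal$mu * cal$block_len)
  T_gen <- model$T_split * 2 * Ne_ref
  recip <- if (model$type %in% c("IM", "ADM"))
    substr(model$direction, 2, 2) else NA_character_
  c_recip <- if (identical(recip, "V")) model$c_V
             else if (identical(recip, "B")) model$c_B else NA_real_
  m_per_gen <- if (model$type == "IM") model$m / (2 * Ne_ref) else NA_real_

  structure(list(
    Ne_ref = Ne_ref,
    Ne_V = model$c_V * Ne_ref,
    Ne_B = model$c_B * Ne_ref,
    Ne_anc = model$c_anc * Ne_ref,
    T_split_generations = T_gen,
    T_split_years = T_gen * cal$g,
    gene_flow_direction = if (is.na(recip)) NA_character_
                          else paste0(substr(model$direction, 1, 1), "->", recip),
    m_per_generation = m_per_gen,
    migrants_per_generation_Nm = if (model$type == "IM")
      c_recip * Ne_ref * m_per_gen else NA_real_,
    migrants_per_generation_4Nm = if (model$type == "IM")
      4 * c_recip * Ne_ref * m_per_gen else NA_real_,
    f = if (model$type == "ADM") model$f else NA_real_,
    T_adm_years = if (model$type == "ADM")
      model$T_adm * 2 * Ne_ref * cal$g else NA_real_,
    calibration = unclass(cal)
  ), class = "scaled_estimates")
}

#' @exportS3Method base::print
print.scaled_estimates <- function(x, ...) {
  cat(sprintf("<scaled_estimates: mu = %g, g = %g y>\n",
              x$calibration$mu, x$calibration$g))
  cat(sprintf("  Ne_ref = %.0f  Ne_V = %.0f  Ne_B = %.0f  Ne_anc = %.0f\n",
              x$Ne_ref, x$Ne_V, x$Ne_B, x$Ne_anc))
  cat(sprintf("  T_split = %.0f generations = %.3g years\n",
              x$T_split_generations, x$T_split_years))
  if (!is.na(x$m_per_generation))
    cat(sprintf("  gene flow %s: Nm = %.4g (4Nm = %.4g) migrants/generation\n",
                x$gene_flow_direction, x$migrants_per_generation_Nm,
                x$migrants_per_generation_4Nm))
  if (!is.na(x$f))
    cat(sprintf("  admixture %s: f = %.3g at %.3g years\n",
                x$gene_flow_direction, x$f, x$T_adm_years))
  invisible(x)
}

#' Per-generation mutation rate implied by a pairwise distance
#'
#' `mu = pairwise_distance / T_total_generations`, where the total
#' separation is twice the split time in generations (both branches
#' accumulate substitutions). The convention is returned alongside the
#' value.
#'
#' @param pairwise_distance substitutions per site between the two taxa.
#' @param T_total_generations total separation in generations
#'   (2 x split time).
#' @return list with `mu` and `convention`.
#' @export
mutation_rate_from_divergence <- function(pairwise_distance, T_total_generations) {
  if (pairwise_distance < 0) stop("pairwise_distance must be >= 0")
  if (!is.finite(T_total_generations) || T_total_generations <= 0)
    stop("T_total_generations must be > 0")
  list(mu = pairwise_distance / T_total_generations,
       convention = "mu = d / T_total; T_total = 2 * split time in generations")
}

#' Genome-wide diversity and differentiation from a two-sample VCF
#'
#' `pi` per species is the number of heterozygous sites divided by the
#' number of callable sites; `dxy` is the mean over sites of the fraction
#' of the four between-species allele pairs that differ (sites absent from
#' the VCF count 0); `FST` defaults to the Hudson form
#' `1 - mean(pi_V, pi_B) / dxy`, with a `(dxy - pi_w) / (dxy + pi_w)`
#' alternative. Excluded sites (missing genotypes, >2 alleles) are skipped.
#'
#' @param vcf path to a VCF or a `VariantAnnotation::VCF` object.
#' @param callable_sites number of callable sites; commonly the summed BED
#'   length (an approximation: it assumes all BED bases are callable).
#' @param sample_v,sample_b VCF sample names (defaults: column order).
#' @param fst_estimator `"hudson"` (default) or `"dxy_ratio"`.
#' @return list with `pi_V`, `pi_B`, `dxy`, `fst`, `fst_estimator`,
#'   `n_sites_used`, `callable_sites`.
#' @export
diversity_stats <- function(vcf, callable_sites, sample_v = NULL, sample_b = NULL,
                            fst_estimator = c("hudson", "dxy_ratio")) {
  fst_estimator <- match.arg(fst_estimator)
  if (!is.finite(callable_sites) || callable_sites <= 0)
    stop("callable_sites must be > 0")
  v <- .read_vcf_gt(vcf, sample_v, sample_b)
  cls <- .classify_sites(v$gt_v, v$gt_b)
  use <- cls != "excluded"
  av <- .parse_gt(v$gt_v[use])
  ab <- .parse_gt(v$gt_b[use])
  ## fraction of the 2x2 between-species allele pairs that differ, per site
  dxy_site <- (outer_ne <- function(a, b) (a[1, ] != b[1, ]) + (a[1, ] != b[2, ]) +
                 (a[2, ] != b[1, ]) + (a[2, ] != b[2, ]))(av, ab) / 4
  pi_V <- sum(cls %in% c("het_v", "shared_het")) / callable_sites
  pi_B <- sum(cls %in% c("het_b", "shared_het")) / callable_sites
  dxy <- sum(dxy_site) / callable_sites
  pi_w <- mean(c(pi_V, pi_B))
  fst <- if (dxy == 0) NA_real_
         else if (fst_estimator == "hudson") 1 - pi_w / dxy
         else (dxy - pi_w) / (dxy + pi_w)
  list(pi_V = pi_V, pi_B = pi_B, dxy = dxy, fst = fst,
       fst_estimator = fst_estimator,
       n_sites_used = sum(use), callable_sites = callable_sites)
}

#' Generation length as the mean age of the mothers of all offspring
#'
#' `G = sum(a * n_a * m_a) / sum(n_a * m_a)` over age classes, with
#' `n_a` breeding females and `m_a` fecundity per class.
#'
#' @param age_classes data.frame (or matrix) with columns `age` (years),
#'   `n_females`, `fecundity`.
#' @return generation length in years.
#' @export
generation_length <- function(age_classes) {
  ac <- as.data.frame(age_classes)
  stopifnot(all(c("age", "n_females", "fecundity") %in% names(ac)))
  w <- ac$n_females * ac$fecundity
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with positive sum")
  sum(ac$age * w) / sum(w)
}
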