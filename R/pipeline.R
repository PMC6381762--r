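## Command-line orchestration: configuration, logging, manifests, and the
## simulate / tabulate / fit / summarize subcommands.

#' Pipeline configuration
#'
#' Houses the analysis constants (200-base blocks, the 1/1000 linkage
#' correction, the 3.5-year generation time, and the two mutation-rate
#' calibrations) plus paths and switches. All defaults are the constants
#' used in the published analysis.
#'
#' @param vcf,bed,outdir input VCF, input BED of intergenic regions, output
#'   directory.
#' @param block_len block length in bases (default 200).
#' @param four_gamete apply the four-gamete filter (default TRUE).
#' @param linkage_mode `"factor"` (divide lnCL by `linkage_param`) or
#'   `"thin"` (fit every `linkage_param`-th block).
#' @param linkage_param linkage correction parameter (default 1000).
#' @param k_max bSFS truncation (default 3).
#' @param models character vector of model ids from [model_grid] (default
#'   all 13).
#' @param calibrations list of [calibration]s (default: mu = 1.77e-8 and
#'   mu = 1e-9, both with g = 3.5 years).
#' @param sample_v,sample_b VCF sample names (defaults: column order).
#' @param excluded_ceiling per-block excluded-site ceiling (default 0.1).
#' @param n_starts,max_eval optimizer settings (see [optimizer_config]).
#' @param sim_model,sim_theta_block,sim_n_blocks,sim_missing_frac settings
#'   for the `simulate` subcommand; the default model emulates the inferred
#'   history of the green lizard pair (two sizes, gene flow B to V).
#' @param seed integer seed.
#' @param log_file optional path appended to by [pipeline_log].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, bed = NULL, outdir = ".",
                            block_len = 200L, four_gamete = TRUE,
                            linkage_mode = c("factor", "thin"),
                            linkage_param = 1000L, k_max = 3L,
                            models = names(model_grid()),
                            calibrations = list(calibration(1.77e-8, 3.5, block_len),
                                                calibration(1e-9, 3.5, block_len)),
                            sample_v = NULL, sample_b = NULL,
                            excluded_ceiling = 0.1,
                            n_starts = 10L, max_eval = 2000L,
                            sim_model = NULL, sim_theta_block = 0.3,
                            sim_n_blocks = 1000L, sim_missing_frac = 0,
                            seed = 1L, log_file = NULL) {
  linkage_mode <- match.arg(linkage_mode)
  if (block_len < 1) stop("block_len must be >= 1")
  if (linkage_param < 1) stop("linkage parameter must be >= 1")
  if (length(models) < 1) stop("at least one model required")
  if (length(calibrations) < 1) stop("at least one calibration required")
  bad <- setdiff(models, names(model_grid()))
  if (length(bad)) stop("unknown model id(s): ", paste(bad, collapse = ", "))
  if (is.null(sim_model)) sim_model <- default_truth_model()
  structure(list(vcf = vcf, bed = bed, outdir = outdir,
                 block_len = as.integer(block_len), four_gamete = four_gamete,
                 linkage_mode = linkage_mode,
                 linkage_param = as.integer(linkage_param),
                 k_max = as.integer(k_max), models = models,
                 calibrations = calibrations,
                 sample_v = sample_v, sample_b = sample_b,
                 excluded_ceiling = excluded_ceiling,
                 n_starts = as.integer(n_starts),
                 max_eval = as.integer(max_eval),
                 sim_model = sim_model,
                 sim_theta_block = sim_theta_block,
                 sim_n_blocks = as.integer(sim_n_blocks),
                 sim_missing_frac = sim_missing_frac,
                 seed = as.integer(seed), log_file = log_file),
            class = "pipeline_config")
}

#' Default generating model of the synthetic data
#'
#' Two effective sizes with species B reduced, continuous gene flow from B
#' into V: the scenario class best supported for the green lizard pair,
#' with parameter values chosen to echo its reported diversity
#' (theta_block = 0.3 per 200-bp block, giving per-site heterozygosity near
#' the reported values), size ratio (c_B = 0.4), a split around 2
#' coalescent time units and about 0.29 migrants per generation into V
#' (m = 0.576).
#'
#' @return a [demography_model].
#' @export
default_truth_model <- function() {
  demography_model(type = "IM", direction = "BV", deviating = "B",
                   T_split = 2, c_x = 0.4, m = 0.576, model_id = "M3.3")
}

#' Log a pipeline message to stderr (and to the configured log file)
#' @param config a [pipeline_config].
#' @param ... message parts, passed to `paste0`.
#' @export
pipeline_log <- function(config, ...) {
  msg <- paste0("[bsfsdem] ", ...)
  message(msg)
  if (!is.null(config$log_file)) cat(msg, "\n", file = config$log_file,
                                     append = TRUE, sep = "")
  invisible(msg)
}

## manifest: everything needed to reproduce the run bit-identically
.write_manifest <- function(config, outdir, command) {
  ser <- tempfile()
  on.exit(unlink(ser))
  saveRDS(config[setdiff(names(config), "log_file")], ser)
  manifest <- list(command = command,
                   config_hash = unname(tools::md5sum(ser)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("bsfsdem")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(outdir, paste0(command, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a genotype fixture (subcommand `simulate`)
#'
#' @param config a [pipeline_config]; uses its `sim_*` fields and writes
#'   `sim.vcf`, `sim.bed`, `sim.fasta` plus the truth sidecar and manifest
#'   into `outdir`.
#' @return list of written paths (invisibly the full fixture summary).
#' @export
cmd_simulate <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(config$sim_model, config$sim_theta_block,
                    config$sim_n_blocks, config$block_len, config$seed,
                    config$sim_missing_frac)
  paths <- list(vcf = file.path(config$outdir, "sim.vcf"),
                bed = file.path(config$outdir, "sim.bed"),
                fasta = file.path(config$outdir, "sim.fasta"))
  res <- simulate_genotype_fixture(cfg, paths$vcf, paths$bed, paths$fasta,
                                   sample_v = config$sample_v %||% "viridis",
                                   sample_b = config$sample_b %||% "bilineata")
  .write_manifest(config, config$outdir, "simulate")
  pipeline_log(config, "simulate: wrote ", res$n_blocks, " blocks, ",
               res$n_sites, " sites (seed ", config$seed, ")")
  invisible(res)
}

#' Tabulate the bSFS from VCF + BED (subcommand `tabulate`)
#'
#' Runs partition -> classify -> four-gamete filter -> tally and writes
#' `tally.tsv` (and `tally_thinned.tsv` in thinning mode) plus
#' `tabulate_summary.json`.
#'
#' @param config a [pipeline_config] with `vcf` and `bed` set.
#' @return invisibly, a list with the tally and summary.
#' @export
cmd_tabulate <- function(config) {
  if (is.null(config$vcf) || is.null(config$bed))
    stop("tabulate requires vcf and bed inputs")
  if (!file.exists(config$vcf)) stop("missing VCF: ", config$vcf)
  if (!file.exists(config$bed)) stop("missing BED: ", config$bed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  blocks <- partition_blocks(config$bed, config$block_len)
  spectra <- tabulate_blocks(blocks, config$vcf, config$sample_v,
                             config$sample_b, config$excluded_ceiling)
  n_dropped <- attr(spectra, "n_dropped_excluded")
  if (config$four_gamete) {
    flt <- four_gamete_filter(spectra)
    kept <- flt$kept; n_removed <- flt$n_removed
  } else {
    kept <- spectra; n_removed <- 0L
  }
  tally <- bsfs_tally(kept, n_filtered_blocks = n_removed)
  write_tally(tally, file.path(config$outdir, "tally.tsv"),
              file.path(config$outdir, "tabulate_summary.json"))
  thinned <- NULL
  if (config$linkage_mode == "thin") {
    thinned <- bsfs_tally(thin_blocks(kept, config$linkage_param))
    write_tally(thinned, file.path(config$outdir, "tally_thinned.tsv"))
  }
  .write_manifest(config, config$outdir, "tabulate")
  pipeline_log(config, "tabulate: ", tally$n_total_blocks, " blocks, ",
               n_removed, " removed by four-gamete filter (",
               filter_percentage(n_removed, tally$n_total_blocks), "%), ",
               n_dropped, " dropped for excluded sites; ",
               tally$n_distinct, " distinct configurations (k_max applies at fit time)")
  invisible(list(tally = tally, thinned = thinned, spectra = spectra,
                 n_dropped_excluded = n_dropped))
}

#' Fit the model grid and report the AIC comparison (subcommand `fit`)
#'
#' @param config a [pipeline_config].
#' @param tally a [bsfs_tally]; defaults to reading `tally.tsv` (or the
#'   thinned tally in thinning mode) from `outdir`.
#' @return invisibly, the `model_comparison` plus scaled estimates of the
#'   best model under each calibration.
#' @export
cmd_fit <- function(config, tally = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(tally)) {
    path <- file.path(config$outdir,
                      if (config$linkage_mode == "thin") "tally_thinned.tsv"
                      else "tally.tsv")
    if (!file.exists(path)) stop("missing tally file: ", path)
    tally <- read_tally(path)
  }
  grid <- model_grid()[config$models]
  ocfg <- optimizer_config(n_starts = config$n_starts,
                           max_eval = config$max_eval,
                           seed = config$seed,
                           linkage_mode = config$linkage_mode,
                           linkage_factor = config$linkage_param)
  pipeline_log(config, "fit: k_max = ", config$k_max, ", linkage = ",
               config$linkage_mode, "(", config$linkage_param, "), ",
               length(grid), " models, ", config$n_starts, " starts")
  cmp <- compare_models(tally, grid, config$k_max, ocfg)
  utils::write.table(cmp$table, file.path(config$outdir, "model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  best_id <- cmp$table$model_id[1]
  best_fit <- cmp$fits[[which(vapply(cmp$fits, `[[`, character(1), "model_id")
                              == best_id)]]
  scaled <- lapply(config$calibrations, function(cal)
    unclass(scale_estimates(best_fit, cal)))
  jsonlite::write_json(list(table = cmp$table, best_model = best_id,
                            scaled_estimates = scaled),
                       file.path(config$outdir, "model_comparison.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  .write_manifest(config, config$outdir, "fit")
  pipeline_log(config, "fit: best model ", best_id, " (",
               cmp$table$model_type[1], "), AIC = ",
               format(cmp$table$aic[1], digits = 8))
  invisible(list(comparison = cmp, best_fit = best_fit, scaled = scaled))
}

#' Genome-wide diversity summaries (subcommand `summarize`)
#'
#' @param config a [pipeline_config] with `vcf` and `bed` set; callable
#'   sites default to the summed BED length.
#' @return invisibly, the [diversity_stats] list.
#' @export
cmd_summarize <- function(config) {
  if (is.null(config$vcf) || is.null(config$bed))
    stop("summarize requires vcf and bed inputs")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  regions <- rtracklayer::import(config$bed, format = "BED")
  callable <- sum(BiocGenerics::width(GenomicRanges::reduce(regions)))
  stats <- diversity_stats(config$vcf, callable, config$sample_v, config$sample_b)
  jsonlite::write_json(stats, file.path(config$outdir, "diversity.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(config, config$outdir, "summarize")
  pipeline_log(config, "summarize: pi_V = ", signif(stats$pi_V, 4),
               ", pi_B = ", signif(stats$pi_B, 4),
               ", dxy = ", signif(stats$dxy, 4),
               ", FST(", stats$fst_estimator, ") = ", signif(stats$fst, 4))
  invisible(stats)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `tabulate`, `fit`, `summarize`. Options can
#' come from a JSON config file (`--config`) with flag overrides. Exit
#' codes: 0 success, 2 input/validation error, 3 numerical failure.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return integer exit code, invisibly.
#' @export
bsfs_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: bsfsdem <simulate|tabulate|fit|summarize> [options]"
  if (length(args) < 1L || !args[1] %in%
      c("simulate", "tabulate", "fit", "summarize")) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON config file"),
    optparse::make_option("--vcf", type = "character", default = NULL),
    optparse::make_option("--bed", type = "character", default = NULL),
    optparse::make_option("--outdir", type = "character", default = "."),
    optparse::make_option("--block-len", type = "integer", default = NULL),
    optparse::make_option("--k-max", type = "integer", default = NULL),
    optparse::make_option("--linkage-mode", type = "character", default = NULL),
    optparse::make_option("--linkage-param", type = "integer", default = NULL),
    optparse::make_option("--models", type = "character", default = NULL,
                          help = "comma-separated model ids"),
    optparse::make_option("--n-starts", type = "integer", default = NULL),
    optparse::make_option("--n-blocks", type = "integer", default = NULL,
                          help = "simulate: number of blocks"),
    optparse::make_option("--theta-block", type = "double", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--no-four-gamete", action = "store_true",
                          default = FALSE)))
  opt <- tryCatch(optparse::parse_args(parser, args = args[-1]),
                  error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(opt)) return(invisible(2L))

  status <- tryCatch({
    base <- if (!is.null(opt$config))
      jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()
    override <- list(vcf = opt$vcf, bed = opt$bed, outdir = opt$outdir,
                     block_len = opt$`block-len`, k_max = opt$`k-max`,
                     linkage_mode = opt$`linkage-mode`,
                     linkage_param = opt$`linkage-param`,
                     models = if (!is.null(opt$models))
                       strsplit(opt$models, ",")[[1]] else NULL,
                     n_starts = opt$`n-starts`,
                     sim_n_blocks = opt$`n-blocks`,
                     sim_theta_block = opt$`theta-block`,
                     seed = opt$seed)
    override <- override[!vapply(override, is.null, logical(1))]
    base[names(override)] <- override
    if (opt$`no-four-gamete`) base$four_gamete <- FALSE
    config <- do.call(pipeline_config, base)
    switch(sub,
           simulate = cmd_simulate(config),
           tabulate = cmd_tabulate(config),
           fit = cmd_fit(config),
           summarize = cmd_summarize(config))
    0L
  }, error = function(e) {
    message("[bsfsdem] error: ", conditionMessage(e))
    if (grepl("uniformization|negative configuration|non-convergent|failed",
              conditionMessage(e))) 3L else 2L
  })
  invisible(status)
}
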