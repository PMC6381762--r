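## Structured-coalescent simulator for the (2,2) sample configuration.
## Doubles as the synthetic stand-in for the study's genotype data and as
## the Monte-Carlo oracle for the analytic likelihood.

.model_sim_args <- function(model) {
  mig_from <- -1L; adm_from <- -1L
  if (model$type == "IM" && model$m > 0) {
    ## forwards flow X->Y is, backwards in time, lineages in Y jumping to X
    mig_from <- if (model$direction == "BV") 0L else 1L
  }
  if (model$type == "ADM" && model$f > 0) {
    adm_from <- if (model$direction == "BV") 0L else 1L
  }
  list(T_split = model$T_split, c_V = model$c_V, c_B = model$c_B,
       c_anc = model$c_anc, m = model$m, mig_from = mig_from,
       T_adm = if (is.na(model$T_adm)) Inf else model$T_adm,
       f = model$f, adm_from = adm_from)
}

#' Simulate class-resolved branch lengths of random genealogies
#'
#' Draws independent genealogies of the four sampled alleles (two per
#' species) under a demography model and returns, per genealogy, the total
#' branch length falling in each of the four folded mutation classes, in
#' units of 2*Ne_ref generations.
#'
#' @param model a [demography_model].
#' @param n number of replicate genealogies.
#' @return numeric matrix `n x 4`, columns
#'   `c("het_b","het_v","shared_het","fixed_diff")`. Uses R's RNG stream;
#'   call `set.seed()` for reproducibility.
#' @export
simulate_branch_lengths <- function(model, n) {
  stopifnot(inherits(model, "demography_model"), n >= 1)
  a <- .model_sim_args(model)
  tau <- .sim_class_lengths_cpp(as.integer(n), a$T_split, a$c_V, a$c_B, a$c_anc,
                                a$m, a$mig_from, a$T_adm, a$f, a$adm_from)
  colnames(tau) <- CLASS_NAMES
  tau
}

#' Simulate one genealogy
#'
#' @param model a [demography_model].
#' @param seed integer seed.
#' @return named numeric vector of the four class-resolved branch lengths
#'   (`tau_hetB` reported as `het_b`, etc.), units of 2*Ne_ref generations.
#' @export
simulate_genealogy <- function(model, seed) {
  set.seed(seed)
  drop(simulate_branch_lengths(model, 1L))
}

#' Simulation configuration
#'
#' @param model a [demography_model] with concrete parameter values.
#' @param theta_block expected mutations per block on a branch of length 1
#'   (one unit = 2*Ne_ref generations; equals `2 * Ne_ref * mu * block_len`).
#' @param n_blocks number of independent blocks.
#' @param block_len block length in bases (default 200, the block size used
#'   throughout the analysis).
#' @param seed integer seed.
#' @param missing_frac fraction of emitted genotype calls replaced by `./.`
#'   in [simulate_genotype_fixture] (default 0).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(model, theta_block, n_blocks, block_len = 200L,
                       seed = 1L, missing_frac = 0) {
  stopifnot(inherits(model, "demography_model"))
  if (!is.finite(theta_block) || theta_block <= 0) stop("theta_block must be > 0")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (block_len < 1) stop("block_len must be >= 1")
  if (missing_frac < 0 || missing_frac >= 1) stop("missing_frac must be in [0, 1)")
  structure(list(model = model, theta_block = theta_block,
                 n_blocks = as.integer(n_blocks),
                 block_len = as.integer(block_len),
                 seed = as.integer(seed), missing_frac = missing_frac),
            class = "sim_config")
}

#' Simulate block spectra
#'
#' One independent genealogy per block (blocks unlinked); within a block all
#' sites share the genealogy (no recombination within blocks). Mutation
#' counts per class are Poisson with mean `theta_block * tau_class`.
#'
#' @param cfg a [sim_config].
#' @return integer matrix `n_blocks x 4` of per-block mutation-type counts,
#'   columns in the fixed `(het_b, het_v, shared_het, fixed_diff)` order.
#' @export
simulate_block_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tau <- simulate_branch_lengths(cfg$model, cfg$n_blocks)
  counts <- matrix(stats::rpois(length(tau), cfg$theta_block * tau),
                   nrow = nrow(tau), dimnames = list(NULL, CLASS_NAMES))
  storage.mode(counts) <- "integer"
  counts
}

## genotype strings realizing one mutation of each class; the choice of
## which species carries the alternate allele in a fixed difference is a
## folding-equivalent convention.
.CLASS_GT <- list(
  het_b      = c(v = "0/0", b = "0/1"),
  het_v      = c(v = "0/1", b = "0/0"),
  shared_het = c(v = "0/1", b = "0/1"),
  fixed_diff = c(v = "1/1", b = "0/0")
)

#' Write a synthetic VCF/BED/FASTA fixture realizing simulated spectra
#'
#' Emits a minimal reference FASTA (one contig of concatenated blocks), a
#' BED of "intergenic" intervals laid out as consecutive blocks, and a
#' biallelic two-sample VCF whose per-block site patterns realize the
#' simulated block spectra exactly under the infinite-sites model
#' (positions sampled without replacement within each block). A JSON
#' sidecar records the generating parameters and seed.
#'
#' @param cfg a [sim_config].
#' @param out_vcf,out_bed,out_fasta output paths (plain text, uncompressed).
#' @param contig contig name used in all three files.
#' @param sample_v,sample_b sample column names (species V first).
#' @return invisibly, a list with the simulated spectra matrix and counts of
#'   written records; the truth sidecar is written next to `out_vcf` as
#'   `<out_vcf>.truth.json`.
#' @export
simulate_genotype_fixture <- function(cfg, out_vcf, out_bed, out_fasta,
                                      contig = "chr_sim",
                                      sample_v = "viridis", sample_b = "bilineata") {
  spectra <- simulate_block_spectra(cfg)  # seeds the RNG
  L <- cfg$block_len
  if (any(rowSums(spectra) > L))
    stop("block too short to place the drawn mutation count under infinite sites")
  n_blocks <- nrow(spectra)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_blocks * L, replace = TRUE)

  starts0 <- (seq_len(n_blocks) - 1L) * L  # 0-based block starts
  rows <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    k <- sum(spectra[i, ])
    if (k == 0L) next
    pos <- sort(sample.int(L, k)) + starts0[i]  # 1-based positions
    cls <- rep(CLASS_NAMES, times = spectra[i, ])[sample.int(k)]
    gt_v <- vapply(cls, function(cl) .CLASS_GT[[cl]][["v"]], character(1))
    gt_b <- vapply(cls, function(cl) .CLASS_GT[[cl]][["b"]], character(1))
    refb <- ref[pos]
    altb <- vapply(refb, function(r) sample(setdiff(bases, r), 1L), character(1))
    rows[[i]] <- data.frame(pos = pos, ref = refb, alt = altb,
                            gt_v = gt_v, gt_b = gt_b)
  }
  vtab <- do.call(rbind, rows)
  n_sites <- if (is.null(vtab)) 0L else nrow(vtab)

  if (n_sites > 0L && cfg$missing_frac > 0) {
    for (col in c("gt_v", "gt_b")) {
      hit <- stats::runif(n_sites) < cfg$missing_frac
      vtab[[col]][hit] <- "./."
    }
  }

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(paste(ref, collapse = ""), contig)),
    out_fasta)

  bed <- GenomicRanges::GRanges(contig,
           IRanges::IRanges(start = starts0 + 1L, width = L))
  rtracklayer::export(bed, out_bed, format = "BED")

  con <- file(out_vcf, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsfsdem_simulate_genotype_fixture",
    sprintf("##contig=<ID=%s,length=%d>", contig, n_blocks * L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_v, sample_b), collapse = "\t")), con)
  if (n_sites > 0L) {
    writeLines(paste(contig, vtab$pos, ".", vtab$ref, vtab$alt, ".", "PASS",
                     ".", "GT", vtab$gt_v, vtab$gt_b, sep = "\t"), con)
  }

  truth <- list(
    model_id = cfg$model$model_id, type = cfg$model$type,
    direction = cfg$model$direction, deviating = cfg$model$deviating,
    T_split = cfg$model$T_split, c_V = cfg$model$c_V, c_B = cfg$model$c_B,
    c_anc = cfg$model$c_anc, m = cfg$model$m, f = cfg$model$f,
    T_adm = cfg$model$T_adm,
    theta_block = cfg$theta_block, n_blocks = cfg$n_blocks,
    block_len = cfg$block_len, seed = cfg$seed,
    missing_frac = cfg$missing_frac,
    sample_v = sample_v, sample_b = sample_b, contig = contig)
  jsonlite::write_json(truth, paste0(out_vcf, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(spectra = spectra, n_sites = n_sites, n_blocks = n_blocks,
                 vcf = out_vcf, bed = out_bed, fasta = out_fasta,
                 truth_json = paste0(out_vcf, ".truth.json")))
}

#' Reconstruct a demography model (and simulation config) from a truth sidecar
#' @param path path to a `*.truth.json` written by [simulate_genotype_fixture].
#' @return a [sim_config].
#' @export
read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- demography_model(type = tr$type,
                            direction = tr$direction,
                            deviating = tr$deviating,
                            T_split = tr$T_split,
                            c_x = if (tr$deviating == "V") tr$c_V
                                  else if (tr$deviating == "B") tr$c_B else 1,
                            m = tr$m, f = tr$f,
                            T_adm = if (is.null(tr$T_adm)) NA_real_ else tr$T_adm,
                            model_id = tr$model_id)
  sim_config(model, tr$theta_block, tr$n_blocks, tr$block_len, tr$seed,
             tr$missing_frac)
}
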