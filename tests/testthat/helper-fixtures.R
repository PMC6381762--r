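# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

panmictic_model <- function() {
  demography_model(type = "DIV", deviating = "none", T_split = 0,
                   model_id = "PANMICTIC")
}

# the stated synthetic world: two-Ne IM B->V echoing the lizard pair
truth_model <- function() default_truth_model()
TRUTH_THETA <- 0.3

# a small on-disk VCF/BED/FASTA fixture and its generating spectra
small_fixture <- function() memo("small_fixture", {
  dir <- file.path(tempdir(), "bsfsdem_fixture")
  dir.create(dir, showWarnings = FALSE)
  cfg <- sim_config(truth_model(), TRUTH_THETA, n_blocks = 300, block_len = 200,
                    seed = 71)
  fx <- simulate_genotype_fixture(cfg,
                                  file.path(dir, "f.vcf"),
                                  file.path(dir, "f.bed"),
                                  file.path(dir, "f.fa"))
  fx$cfg <- cfg
  fx
})

# write a minimal two-sample VCF from a data.frame(chrom, pos, ref, alt, gt_v, gt_b)
write_test_vcf <- function(df, path, contig_len = 1e6L,
                           samples = c("viridis", "bilineata")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", unique(df$chrom), contig_len),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(df) > 0)
    writeLines(paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", ".",
                     "GT", df$gt_v, df$gt_b, sep = "\t"), con)
  invisible(path)
}

# closed-form panmictic probability of observing zero mutations (n = 4)
pan_p_zero <- function(theta) prod(sapply(4:2, function(k)
  choose(k, 2) / (choose(k, 2) + k * theta)))
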