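# Block partitioning, site classification, filtering and tallying.

library(GenomicRanges)

test_that("partition_blocks chops intervals as documented", {
  gr1 <- GRanges("chr1", IRanges::IRanges(start = 1, width = 1000))
  expect_length(partition_blocks(gr1, 200), 5)
  gr2 <- GRanges("chr1", IRanges::IRanges(start = 1, width = 199))
  expect_length(partition_blocks(gr2, 200), 0)
  # intervals of length 450 and 300 -> 2 + 1 blocks from each left end
  gr3 <- GRanges("chr1", IRanges::IRanges(start = c(101, 1001),
                                          width = c(450, 300)))
  b <- partition_blocks(gr3, 200)
  expect_length(b, 3)
  expect_identical(BiocGenerics::start(b), c(101L, 301L, 1001L))
  expect_identical(BiocGenerics::width(b), rep(200L, 3))
  # overlapping input is merged first
  gr4 <- GRanges("chr1", IRanges::IRanges(start = c(1, 151), width = c(200, 250)))
  expect_length(partition_blocks(gr4, 200), 2)
})

test_that("classify_site matches an exhaustive independent enumeration", {
  alleles <- c("0", "1", "2", ".")
  gts <- apply(expand.grid(alleles, alleles), 1, paste, collapse = "/")
  oracle <- function(gv, gb) {
    a <- strsplit(c(gv, gb), "/")
    all4 <- unlist(a)
    if (any(all4 == ".")) return("excluded")
    if (length(unique(all4)) > 2) return("excluded")
    hv <- a[[1]][1] != a[[1]][2]
    hb <- a[[2]][1] != a[[2]][2]
    if (hv && hb) return("shared_het")
    if (hv) return("het_v")
    if (hb) return("het_b")
    if (a[[1]][1] == a[[2]][1]) "invariant" else "fixed_diff"
  }
  for (gv in gts) for (gb in gts)
    expect_identical(classify_site(gv, gb), oracle(gv, gb))
  # phased separators and ploidy errors
  expect_identical(classify_site("0|1", "0/0"), "het_v")
  expect_error(classify_site("0/1/1", "0/0"), "ploidy")
})

test_that("tabulate_blocks counts sites per block and reproduces simulated spectra", {
  fx <- small_fixture()
  blocks <- partition_blocks(fx$bed, 200)
  sp <- tabulate_blocks(blocks, fx$vcf)
  m <- as.matrix(sp[, c("het_b", "het_v", "shared_het", "fixed_diff")])
  expect_identical(unname(m), unname(fx$spectra))
  expect_identical(sum(sp$n_excluded_sites), 0L)
  expect_identical(attr(sp, "n_dropped_excluded"), 0L)
})

test_that("tabulate_blocks handles hand-crafted sites, empty blocks and boundaries", {
  dir <- withr::local_tempdir()
  # block 1 spans [0, 200): sites classified het_v, het_v, fixed_diff
  # block 2 spans [200, 400): empty; 1-based position 200 falls in block 1,
  # position 201 in block 2
  df <- data.frame(chrom = "c1", pos = c(10, 150, 200, 401),
                   ref = "A", alt = "G",
                   gt_v = c("0/1", "0/1", "1/1", "0/1"),
                   gt_b = c("0/0", "0/0", "0/0", "0/1"))
  vcf <- write_test_vcf(df, file.path(dir, "t.vcf"))
  blocks <- GRanges("c1", IRanges::IRanges(start = c(1, 201, 401), width = 200))
  sp <- tabulate_blocks(blocks, vcf)
  expect_identical(unname(as.matrix(sp[, c("het_b", "het_v", "shared_het",
                                           "fixed_diff")])),
                   matrix(c(0L, 2L, 0L, 1L,
                            0L, 0L, 0L, 0L,
                            0L, 0L, 1L, 0L), 3, byrow = TRUE))
})

test_that("excluded sites are tracked and over-ceiling blocks dropped", {
  dir <- withr::local_tempdir()
  df <- data.frame(chrom = "c1",
                   pos = c(1:30, 201),
                   ref = "A", alt = "G",
                   gt_v = c(rep("./.", 30), "0/1"),
                   gt_b = "0/0")
  vcf <- write_test_vcf(df, file.path(dir, "e.vcf"))
  blocks <- GRanges("c1", IRanges::IRanges(start = c(1, 201), width = 200))
  sp <- tabulate_blocks(blocks, vcf)         # ceiling 0.1 * 200 = 20 < 30
  expect_identical(nrow(sp), 1L)
  expect_identical(attr(sp, "n_dropped_excluded"), 1L)
  sp2 <- tabulate_blocks(blocks, vcf, excluded_ceiling = 0.2)
  expect_identical(nrow(sp2), 2L)
  expect_identical(sp2$n_excluded_sites, c(30L, 0L))
})

test_that("tabulate_blocks rejects unknown samples and unsorted VCFs", {
  fx <- small_fixture()
  blocks <- partition_blocks(fx$bed, 200)
  expect_error(tabulate_blocks(blocks, fx$vcf, sample_v = "nope"),
               "sample names")
  dir <- withr::local_tempdir()
  df <- data.frame(chrom = "c1", pos = c(100, 50), ref = "A", alt = "G",
                   gt_v = "0/1", gt_b = "0/0")
  vcf <- write_test_vcf(df, file.path(dir, "u.vcf"))
  expect_error(tabulate_blocks(GRanges("c1", IRanges::IRanges(1, 200)), vcf),
               "not sorted")
})

test_that("four_gamete_filter removes exactly the violating blocks and is idempotent", {
  m <- rbind(c(0L, 1L, 1L, 1L),   # both types present -> removed
             c(0L, 0L, 3L, 0L),   # kept
             c(2L, 2L, 0L, 5L),   # kept
             c(0L, 0L, 0L, 0L))   # kept
  colnames(m) <- c("het_b", "het_v", "shared_het", "fixed_diff")
  flt <- four_gamete_filter(m)
  expect_identical(flt$n_removed, 1L)
  expect_identical(flt$n_kept, 3L)
  expect_identical(flt$percent_removed, 25)
  flt2 <- four_gamete_filter(flt$kept)
  expect_identical(flt2$n_removed, 0L)
  expect_identical(flt2$kept, flt$kept)
})

test_that("thin_blocks keeps indices 0, step, 2*step, ...", {
  m <- matrix(0L, 5000, 4, dimnames = list(NULL, c("het_b", "het_v",
                                                   "shared_het", "fixed_diff")))
  expect_identical(nrow(thin_blocks(m, 1000)), 5L)
  expect_identical(thin_blocks(m, 1), m)
  expect_identical(nrow(thin_blocks(m[1:999, ], 1000)), 1L)
})

test_that("bsfs_tally counts configurations exactly", {
  m <- rbind(c(0L, 1L, 0L, 0L), c(0L, 1L, 0L, 0L), c(2L, 0L, 0L, 1L))
  colnames(m) <- c("het_b", "het_v", "shared_het", "fixed_diff")
  tl <- bsfs_tally(m)
  expect_identical(tl$n_distinct, 2L)
  expect_identical(tl$n_recurrent, 1L)
  expect_identical(tl$n_total_blocks, 3L)
  expect_identical(tl$configs$n_blocks[1], 2L)
  empty <- bsfs_tally(m[0, , drop = FALSE])
  expect_identical(empty$n_distinct, 0L)
  expect_identical(empty$n_total_blocks, 0L)
})

test_that("tally matches a brute-force recount and is order-invariant", {
  sp <- simulate_block_spectra(sim_config(truth_model(), TRUTH_THETA, 1e4,
                                          seed = 120))
  tl <- bsfs_tally(sp)
  key <- apply(sp, 1, paste, collapse = ",")
  expect_identical(tl$n_distinct, length(unique(key)))
  expect_identical(tl$n_recurrent, sum(table(key) > 1))
  expect_identical(sum(tl$configs$n_blocks), nrow(sp))
  set.seed(1)
  tl2 <- bsfs_tally(sp[sample(nrow(sp)), ])
  expect_identical(tl$configs, tl2$configs)
})

test_that("write_tally / read_tally round-trip with the JSON summary", {
  dir <- withr::local_tempdir()
  sp <- simulate_block_spectra(sim_config(truth_model(), TRUTH_THETA, 500,
                                          seed = 121))
  tl <- bsfs_tally(sp, n_filtered_blocks = 7L)
  write_tally(tl, file.path(dir, "t.tsv"), file.path(dir, "t.json"))
  tl2 <- read_tally(file.path(dir, "t.tsv"), n_filtered_blocks = 7L)
  expect_identical(tl$configs[order(do.call(order, tl$configs)), ],
                   tl2$configs[order(do.call(order, tl2$configs)), ])
  js <- jsonlite::read_json(file.path(dir, "t.json"), simplifyVector = TRUE)
  expect_identical(js$n_total_blocks, tl$n_total_blocks)
  expect_identical(js$percent_filtered,
                   round(100 * 7 / tl$n_total_blocks, 2))
  expect_identical(js$n_distinct, tl$n_distinct)
})
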