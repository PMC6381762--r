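## From VCF + BED to the blockwise SFS tally: partition intergenic regions
## into fixed-length blocks, classify each biallelic site into the four
## folded mutation types, apply the four-gamete filter, and tally the bSFS.

#' Partition intervals into fixed-length blocks
#'
#' Chops each (merged) interval into consecutive non-overlapping windows of
#' exactly `block_len` bases from its left end; a trailing remainder shorter
#' than `block_len` is dropped. Order is contig order, then coordinate.
#'
#' @param regions a `GRanges` of regions, or a path to a BED file
#'   (0-based half-open; read with `rtracklayer`).
#' @param block_len block length in bases (default 200).
#' @return `GRanges` of blocks.
#' @export
partition_blocks <- function(regions, block_len = 200L) {
  if (is.character(regions)) regions <- rtracklayer::import(regions, format = "BED")
  stopifnot(methods::is(regions, "GRanges"), block_len >= 1)
  if (any(BiocGenerics::start(regions) < 1))
    stop("negative or zero coordinates in regions")
  regions <- GenomicRanges::reduce(GenomicRanges::sort(regions))
  win <- GenomicRanges::slidingWindows(regions, width = as.integer(block_len),
                                       step = as.integer(block_len))
  win <- unlist(win)
  win[BiocGenerics::width(win) == block_len]
}

.parse_gt <- function(gt) {
  ## returns 2-row character matrix of alleles; NA for missing
  if (length(gt) == 0L) return(matrix(character(0), nrow = 2L))
  parts <- strsplit(gt, "[/|]")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("ploidy != 2 in genotype(s): ",
                     paste(utils::head(gt[bad], 3), collapse = ", "))
  m <- matrix(unlist(parts), nrow = 2L)
  m[m == "."] <- NA_character_
  m
}

## vectorized classifier over genotype strings
.classify_sites <- function(gt_v, gt_b) {
  av <- .parse_gt(gt_v)
  ab <- .parse_gt(gt_b)
  n <- length(gt_v)
  out <- character(n)
  miss <- is.na(av[1, ]) | is.na(av[2, ]) | is.na(ab[1, ]) | is.na(ab[2, ])
  nalleles <- vapply(seq_len(n), function(i)
    length(unique(c(av[, i], ab[, i]))), integer(1))
  het_v <- av[1, ] != av[2, ]
  het_b <- ab[1, ] != ab[2, ]
  out[miss | (!miss & nalleles > 2L)] <- "excluded"
  todo <- out == ""
  out[todo & het_v & het_b] <- "shared_het"
  out[todo & het_v & !het_b] <- "het_v"
  out[todo & !het_v & het_b] <- "het_b"
  hom <- todo & !het_v & !het_b
  out[hom & av[1, ] == ab[1, ]] <- "invariant"
  out[hom & av[1, ] != ab[1, ]] <- "fixed_diff"
  out
}

#' Classify one biallelic site into a folded mutation type
#'
#' Classification uses only the four sampled alleles; the reference and
#' ancestral alleles are irrelevant (folded spectrum). Sites with any
#' missing allele, or with more than two distinct alleles among the four
#' sampled, are `excluded`.
#'
#' @param genotype_v,genotype_b diploid genotype strings (e.g. `"0/1"`,
#'   `"1|1"`, `"./."`) for the species-V and species-B sample.
#' @return one of `"het_v"`, `"het_b"`, `"shared_het"`, `"fixed_diff"`,
#'   `"invariant"`, `"excluded"`.
#' @examples
#' classify_site("0/1", "0/0")  # "het_v"
#' classify_site("1/1", "1/1")  # "invariant" (folding)
#' classify_site("1/1", "0/0")  # "fixed_diff"
#' @export
classify_site <- function(genotype_v, genotype_b) {
  .classify_sites(genotype_v, genotype_b)
}

.read_vcf_gt <- function(vcf, sample_v, sample_b) {
  if (is.character(vcf))
    vcf <- VariantAnnotation::readVcf(vcf)
  smp <- colnames(vcf)
  if (is.null(sample_v)) sample_v <- smp[1]
  if (is.null(sample_b)) sample_b <- smp[2]
  if (!all(c(sample_v, sample_b) %in% smp))
    stop("sample names not found in VCF header: ",
         paste(setdiff(c(sample_v, sample_b), smp), collapse = ", "))
  gr <- SummarizedExperiment::rowRanges(vcf)
  pos <- BiocGenerics::start(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (is.unsorted(order(match(chr, unique(chr)), pos)) ||
      any(stats::ave(pos, chr, FUN = function(p) c(0, diff(p))) < 0))
    stop("VCF positions are not sorted")
  gt <- VariantAnnotation::geno(vcf)$GT
  list(gr = gr, gt_v = gt[, sample_v], gt_b = gt[, sample_b])
}

#' Tabulate per-block mutation-type counts from a VCF
#'
#' Counts the four folded mutation types over the sites falling in each
#' block. VCF positions are 1-based; blocks are 0-based half-open at the
#' BED boundary, converted here. Sites absent from the VCF are treated as
#' invariant (variant-only caller output). Sites classified `excluded`
#' (missing genotypes or more than two alleles) are tallied per block;
#' blocks whose excluded-site count exceeds `excluded_ceiling * block
#' width` are dropped and reported separately.
#'
#' @param blocks `GRanges` of blocks from [partition_blocks].
#' @param vcf path to a VCF file, or a `VariantAnnotation::VCF` object with
#'   exactly the two expected samples.
#' @param sample_v,sample_b VCF sample names for species V and B; defaults:
#'   first and second sample column.
#' @param excluded_ceiling maximum tolerated fraction of excluded sites per
#'   block (default 0.1).
#' @return data.frame of class `bsfs_spectra`: one row per kept block with
#'   columns `chrom`, `start` (0-based), `end`, the four counts, and
#'   `n_excluded_sites`; attribute `n_dropped_excluded` counts dropped
#'   blocks.
#' @export
tabulate_blocks <- function(blocks, vcf, sample_v = NULL, sample_b = NULL,
                            excluded_ceiling = 0.1) {
  stopifnot(methods::is(blocks, "GRanges"))
  v <- .read_vcf_gt(vcf, sample_v, sample_b)
  cls <- .classify_sites(v$gt_v, v$gt_b)

  hits <- GenomicRanges::findOverlaps(v$gr, blocks)
  blk <- factor(S4Vectors::subjectHits(hits), levels = seq_along(blocks))
  site_cls <- cls[S4Vectors::queryHits(hits)]

  counts <- sapply(c(CLASS_NAMES, "excluded"), function(cn)
    as.integer(table(blk[site_cls == cn])))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(blocks)),
    start = BiocGenerics::start(blocks) - 1L,
    end = BiocGenerics::end(blocks),
    counts, check.names = FALSE)
  names(df)[names(df) == "excluded"] <- "n_excluded_sites"

  over <- df$n_excluded_sites > excluded_ceiling * BiocGenerics::width(blocks)
  kept <- df[!over, , drop = FALSE]
  rownames(kept) <- NULL
  structure(kept, class = c("bsfs_spectra", "data.frame"),
            n_dropped_excluded = sum(over))
}

.spectra_counts <- function(spectra) {
  if (is.matrix(spectra)) {
    stopifnot(ncol(spectra) >= 4)
    m <- spectra[, CLASS_NAMES, drop = FALSE]
  } else {
    m <- as.matrix(spectra[, CLASS_NAMES, drop = FALSE])
  }
  storage.mode(m) <- "integer"
  m
}

#' Four-gamete filter
#'
#' Under infinite sites and no recombination within a block, a block cannot
#' contain both a fixed difference and a shared heterozygous site: such a
#' block would require more than one genealogy. Blocks with
#' `fixed_diff > 0` and `shared_het > 0` are removed.
#'
#' @param spectra a `bsfs_spectra` data.frame or a 4-column count matrix.
#' @return list with `kept`, `removed` (same type as input), `n_kept`,
#'   `n_removed` and `percent_removed` (rounded to 2 decimals).
#' @export
four_gamete_filter <- function(spectra) {
  m <- .spectra_counts(spectra)
  bad <- m[, "fixed_diff"] > 0L & m[, "shared_het"] > 0L
  kept <- if (is.matrix(spectra)) spectra[!bad, , drop = FALSE]
          else spectra[!bad, , drop = FALSE]
  removed <- spectra[bad, , drop = FALSE]
  list(kept = kept, removed = removed,
       n_kept = sum(!bad), n_removed = sum(bad),
       percent_removed = filter_percentage(sum(bad), length(bad)))
}

#' Percentage of blocks removed by a filter
#' @param n_removed,n_total block counts.
#' @return `100 * n_removed / n_total`, rounded to 2 decimals.
#' @export
filter_percentage <- function(n_removed, n_total) {
  round(100 * n_removed / n_total, 2)
}

#' Thin blocks to approximately unlinked subsets
#'
#' Retains blocks at indices 1, 1 + step, 1 + 2*step, ... in genomic order;
#' used by the thinning variant of the linkage correction (every 1,000th
#' block treated as effectively unlinked). Unlike the tally, thinning is
#' sensitive to block order.
#'
#' @param spectra a `bsfs_spectra` data.frame or count matrix.
#' @param step keep every `step`-th block (default 1000).
#' @return subset of `spectra`.
#' @export
thin_blocks <- function(spectra, step = 1000L) {
  stopifnot(step >= 1)
  n <- if (is.matrix(spectra)) nrow(spectra) else nrow(spectra)
  spectra[seq.int(1L, n, by = as.integer(step)), , drop = FALSE]
}

#' Tally the blockwise SFS
#'
#' Exact multiset count of configurations
#' `(het_b, het_v, shared_het, fixed_diff)` across blocks.
#'
#' @param spectra a `bsfs_spectra` data.frame or 4-column count matrix.
#' @param n_filtered_blocks number of blocks removed upstream (recorded for
#'   reporting; default 0).
#' @return object of class `bsfs_tally`: list with `configs` (data.frame of
#'   distinct configurations and their `n_blocks`, most frequent first),
#'   `n_total_blocks` (= kept + filtered), `n_filtered_blocks`,
#'   `n_distinct`, `n_recurrent` (configurations appearing more than once).
#' @export
bsfs_tally <- function(spectra, n_filtered_blocks = 0L) {
  m <- .spectra_counts(spectra)
  if (nrow(m) == 0L) {
    configs <- stats::setNames(
      data.frame(integer(0), integer(0), integer(0), integer(0), integer(0)),
      c(CLASS_NAMES, "n_blocks"))
  } else {
    key <- paste(m[, 1], m[, 2], m[, 3], m[, 4])
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    cfgm <- matrix(as.integer(parts), nrow = nrow(parts))
    configs <- data.frame(cfgm, n_blocks = as.integer(tab))
    names(configs) <- c(CLASS_NAMES, "n_blocks")
    configs <- configs[order(-configs$n_blocks), , drop = FALSE]
    rownames(configs) <- NULL
  }
  structure(list(
    configs = configs,
    n_total_blocks = nrow(m) + as.integer(n_filtered_blocks),
    n_filtered_blocks = as.integer(n_filtered_blocks),
    n_distinct = nrow(configs),
    n_recurrent = sum(configs$n_blocks > 1L)
  ), class = "bsfs_tally")
}

#' @exportS3Method base::print
print.bsfs_tally <- function(x, ...) {
  cat(sprintf(paste0("<bsfs_tally: %d blocks (%d filtered), %d distinct ",
                     "configurations, %d recurrent>\n"),
              x$n_total_blocks, x$n_filtered_blocks, x$n_distinct, x$n_recurrent))
  print(utils::head(x$configs, 5))
  if (nrow(x$configs) > 5) cat("  ...\n")
  invisible(x)
}

#' Write a tally as TSV (configurations) plus a JSON summary
#' @param tally a [bsfs_tally].
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_tally <- function(tally, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(tally$configs, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    n_rm <- tally$n_filtered_blocks
    jsonlite::write_json(list(
      n_total_blocks = tally$n_total_blocks,
      n_filtered_blocks = n_rm,
      percent_filtered = filter_percentage(n_rm, tally$n_total_blocks),
      n_distinct = tally$n_distinct,
      n_recurrent = tally$n_recurrent
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tally)
}

#' Read a tally back from its TSV representation
#' @param tsv_path path written by [write_tally].
#' @param n_filtered_blocks optional filtered-block count for the metadata.
#' @return a [bsfs_tally].
#' @export
read_tally <- function(tsv_path, n_filtered_blocks = 0L) {
  configs <- utils::read.table(tsv_path, header = TRUE, sep = "\t")
  stopifnot(all(c(CLASS_NAMES, "n_blocks") %in% names(configs)))
  m <- as.matrix(configs[rep(seq_len(nrow(configs)), configs$n_blocks),
                         CLASS_NAMES, drop = FALSE])
  bsfs_tally(m, n_filtered_blocks)
}
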