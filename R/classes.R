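## Folded mutation classes for the (2,2) sample: one diploid from species V
## (alleles v1, v2) and one from species B (alleles b1, b2).
##
## Internally a branch is identified by the subset of sampled alleles it
## subtends, encoded as a 4-bit mask: bit 1 = v1, bit 2 = v2, bit 3 = b1,
## bit 4 = b2. The spectrum is folded, so a subset and its complement map to
## the same class.

LEAF_NAMES <- c("v1", "v2", "b1", "b2")

## Fixed configuration ordering used everywhere in the package.
CLASS_NAMES <- c("het_b", "het_v", "shared_het", "fixed_diff")

.mask_of <- function(leaves) {
  idx <- match(leaves, LEAF_NAMES)
  if (anyNA(idx)) stop("unknown leaf label(s): ", paste(leaves[is.na(idx)], collapse = ", "))
  sum(bitwShiftL(1L, idx - 1L))
}

.popcount4 <- function(mask) {
  sum(bitwAnd(bitwShiftR(mask, 0:3), 1L))
}

## class index (1..4 in CLASS_NAMES order) of a branch mask, 0 < mask < 15
.class_of_mask <- function(mask) {
  stopifnot(mask > 0L, mask < 15L)
  n <- .popcount4(mask)
  if (n == 3L) {
    mask <- bitwAnd(bitwNot(mask), 15L)  # fold to the singleton complement
    n <- 1L
  }
  nv <- sum(bitwAnd(bitwShiftR(mask, 0:1), 1L))
  nb <- sum(bitwAnd(bitwShiftR(mask, 2:3), 1L))
  if (n == 1L) {
    if (nv == 1L) 2L else 1L            # het_v / het_b
  } else {                               # n == 2
    if (nv == 2L || nb == 2L) 4L else 3L # fixed_diff / shared_het
  }
}

#' Folded mutation class of a genealogical branch
#'
#' Maps the set of sampled alleles subtended by a branch to one of the four
#' folded mutation types of the blockwise joint site frequency spectrum.
#' Because the spectrum is folded, a subset and its complement are
#' equivalent: a mutation on the branch above `{v1}` and one on the branch
#' above `{v2, b1, b2}` both appear as a site heterozygous only in species V.
#'
#' @param subset character vector of leaf labels, a subset of
#'   `c("v1","v2","b1","b2")`; must be proper and non-empty.
#' @return one of `"het_b"`, `"het_v"`, `"shared_het"`, `"fixed_diff"`.
#' @examples
#' branch_class_of(c("v1"))             # "het_v"
#' branch_class_of(c("v1", "v2"))       # "fixed_diff"
#' branch_class_of(c("v1", "b1"))       # "shared_het"
#' branch_class_of(c("v1", "v2", "b1")) # "het_b" (folds to {b2})
#' @export
branch_class_of <- function(subset) {
  subset <- unique(subset)
  if (length(subset) == 0L || length(subset) >= 4L)
    stop("subset must be a proper non-empty subset of the four sampled alleles")
  CLASS_NAMES[.class_of_mask(.mask_of(subset))]
}

## All 15 set partitions of {1,2,3,4} via restricted growth strings.
## Each partition is a list of bit masks (one per block), masks sorted.
.enumerate_partitions <- function() {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > 4L) {
      masks <- vapply(seq_len(k), function(b)
        sum(bitwShiftL(1L, which(assign == b) - 1L)), integer(1))
      out[[length(out) + 1L]] <<- sort(masks)
      return(invisible(NULL))
    }
    for (b in seq_len(min(k + 1L, i))) rec(c(assign, b), max(k, b))
  }
  rec(integer(0), 0L)
  out
}

PARTITIONS <- .enumerate_partitions()  # 15 = Bell(4)

.partition_key <- function(masks) paste(sort(masks), collapse = ".")

PARTITION_INDEX <- stats::setNames(seq_along(PARTITIONS),
                                   vapply(PARTITIONS, .partition_key, character(1)))

## per-partition class-accumulation counts: n_i = number of blocks whose mask
## maps to folded class i (the fully coalesced partition accrues nothing).
.partition_class_counts <- function(masks) {
  n <- c(0, 0, 0, 0)
  for (m in masks) {
    if (m == 15L) next
    k <- .class_of_mask(m)
    n[k] <- n[k] + 1
  }
  n
}

PARTITION_CLASS_COUNTS <- t(vapply(PARTITIONS, .partition_class_counts, numeric(4)))
colnames(PARTITION_CLASS_COUNTS) <- CLASS_NAMES

## coalescence map: for partition p, all unordered block pairs and the index
## of the partition obtained by merging that pair.
.partition_coal_targets <- function(masks) {
  nb <- length(masks)
  if (nb < 2L) return(matrix(integer(0), ncol = 3))
  res <- list()
  for (a in seq_len(nb - 1L)) for (b in (a + 1L):nb) {
    merged <- c(masks[-c(a, b)], bitwOr(masks[a], masks[b]))
    res[[length(res) + 1L]] <- c(a, b, PARTITION_INDEX[[.partition_key(merged)]])
  }
  do.call(rbind, res)
}

PARTITION_COAL <- lapply(PARTITIONS, .partition_coal_targets)
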