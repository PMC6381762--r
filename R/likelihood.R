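## Analytic probabilities of bSFS mutational configurations.
##
## The computation augments the pre-split lineage process with the running
## vector of mutation counts per folded class, truncated at k_max with a
## per-class lumped overflow cell. Mutations of class i occur at rate
## theta_block * n_i(state); the augmented chain is propagated over the
## pre-split epoch by uniformization (an exact series method for matrix
## exponentials of Markov generators), the admixture pulse is applied as an
## instantaneous relabeling, and the absorbing ancestral epoch is solved
## exactly by a first-passage recursion over the (partition, counts) lattice
## (counts only grow and lineages only merge, so one ordered sweep
## suffices). Probability is conserved throughout, so the full table sums
## to 1 up to the uniformization series tail (< 1e-13).

.lik_cache <- new.env(parent = emptyenv())

## assemble the coefficient decomposition of the transposed product-space
## generator: Gt@x = W %*% c(1/c_V, 1/c_B, m, theta). Cached per model
## structure and k_max (pattern and coefficients are parameter-free).
.product_space <- function(model, k_max) {
  key <- paste(model$type, model$direction %||% "-", model$deviating, k_max, sep = "|")
  hit <- .lik_cache[[key]]
  if (!is.null(hit)) return(hit)

  ss <- build_state_space(model)
  M <- ss$n_states
  K <- k_max + 2L            # counts 0..k_max plus overflow
  nc <- K^4L
  N <- M * nc

  ## count-cell bookkeeping: cnt[cell, class] in 0..K-1 (K-1 = overflow)
  grid <- as.matrix(expand.grid(c1 = 0:(K - 1), c2 = 0:(K - 1),
                                c3 = 0:(K - 1), c4 = 0:(K - 1)))
  stride <- K^(0:3)

  rate <- c(coal_V = 1, coal_B = 2, mig = 3)  # parameter slot per kind
  tr <- ss$transitions

  ii <- list(); jj <- list(); pp <- list(); xx <- list()
  add <- function(i, j, p, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; pp[[k]] <<- rep(p, length(i)); xx[[k]] <<- x
  }

  cells <- seq_len(nc)
  base <- (cells - 1L) * M
  if (nrow(tr) > 0L) {
    ## lineage moves, replicated over count cells (transposed: row=to, col=from)
    for (r in seq_len(nrow(tr))) {
      add(base + tr$to[r], base + tr$from[r], rate[[tr$kind[r]]], rep(1, nc))
      add(base + tr$from[r], base + tr$from[r], rate[[tr$kind[r]]], rep(-1, nc))
    }
  }
  ## mutations: class i in state l at rate theta * n_i(l); counts saturate,
  ## and events in a saturated class are dropped from in- and out-flow alike
  for (cl in 1:4) {
    ls <- which(ss$class_counts[, cl] > 0)
    if (length(ls) == 0L) next
    unsat <- which(grid[, cl] < K - 1L)
    dest <- unsat + stride[cl]
    for (l in ls) {
      nl <- ss$class_counts[l, cl]
      add((dest - 1L) * M + l, (unsat - 1L) * M + l, 4L, rep(nl, length(unsat)))
      add((unsat - 1L) * M + l, (unsat - 1L) * M + l, 4L, rep(-nl, length(unsat)))
    }
  }

  ii <- unlist(ii); jj <- unlist(jj); pp <- unlist(pp); xx <- unlist(xx)
  ## one sparse coefficient matrix per parameter slot, then align all four
  ## onto the union pattern so that per-evaluation assembly is one matvec
  Ws <- lapply(1:4, function(p) {
    sel <- pp == p
    Matrix::sparseMatrix(i = ii[sel], j = jj[sel], x = xx[sel], dims = c(N, N))
  })
  pat <- abs(Ws[[1]])
  for (p in 2:4) pat <- pat + abs(Ws[[p]])
  pat <- methods::as(pat, "CsparseMatrix")
  spat <- Matrix::summary(pat)
  slot_key <- spat$i + N * (spat$j - 1)   # doubles: N^2 can exceed .Machine int
  coef <- matrix(0, nrow = length(slot_key), ncol = 4)
  for (p in 1:4) {
    sw <- Matrix::summary(Ws[[p]])
    if (nrow(sw) == 0L) next
    idx <- match(sw$i + N * (sw$j - 1), slot_key)
    coef[idx, p] <- sw$x
  }
  diag_slots <- which(spat$i == spat$j)

  out <- list(ss = ss, M = M, K = K, nc = nc, N = N, grid = grid,
              stride = stride, pattern = pat, coef = coef,
              diag_slots = diag_slots,
              part_ind = outer(ss$partition_of, seq_along(PARTITIONS), "=="))
  .lik_cache[[key]] <- out
  out
}

## propagate the augmented distribution vector over a time span by
## uniformization; exact up to a series tail below 1e-14 of total mass
.propagate <- function(ps, Gt, Lambda, v, t) {
  if (t <= 0 || Lambda <= 0) return(v)
  lt <- Lambda * t
  if (lt > 2e5) stop("uniformization budget exceeded (Lambda*t = ", signif(lt, 3),
                     "); parameters are outside the supported range")
  n_max <- ceiling(lt + 10 * sqrt(lt + 1) + 20)
  w <- stats::dpois(0, lt)
  res <- w * v
  cumw <- w
  vk <- v
  for (k in seq_len(n_max)) {
    vk <- vk + as.vector(Gt %*% vk) / Lambda
    w <- stats::dpois(k, lt)
    res <- res + w * vk
    cumw <- cumw + w
    if (cumw > 1 - 1e-14 && k > lt) break
  }
  res
}

## exact absorbing-epoch sweep: p0 is the (count cell x partition) joint
## mass at the start of the ancestral epoch; returns the final count-cell
## distribution after all lineages have coalesced (counts saturate at the
## overflow cell)
.ancestral_absorb <- function(p0, theta, c_anc, K) {
  dims <- c(K, K, K, K)
  kmax <- K - 2L
  nparts <- length(PARTITIONS)
  nblocks <- vapply(PARTITIONS, length, integer(1))
  base <- lapply(seq_len(nparts), function(p) array(p0[, p], dims))

  unsat <- lapply(1:4, function(cl) {
    u <- array(0, dims)
    idx <- slice.index(u, cl) <= kmax + 1L  # count values 0..kmax unsaturated
    u[idx] <- 1
    u
  })
  shift1 <- function(x, cl) {
    y <- array(0, dims)
    switch(cl,
           `1` = { y[-1, , , ] <- x[-K, , , ] },
           `2` = { y[, -1, , ] <- x[, -K, , ] },
           `3` = { y[, , -1, ] <- x[, , -K, ] },
           `4` = { y[, , , -1] <- x[, , , -K] })
    y
  }

  final <- array(0, dims)
  for (p in order(nblocks, decreasing = TRUE)) {
    n <- nblocks[p]
    if (n == 1L) { final <- final + base[[p]]; next }
    ni <- PARTITION_CLASS_COUNTS[p, ]
    npairs <- n * (n - 1) / 2
    R <- array(npairs / c_anc, dims)
    for (cl in 1:4) if (ni[cl] > 0) R <- R + theta * ni[cl] * unsat[[cl]]
    w <- lapply(1:4, function(cl)
      if (ni[cl] > 0) theta * ni[cl] * unsat[[cl]] / R else NULL)

    m <- base[[p]]
    tot <- m
    for (iter in seq_len(4L * (K - 1L))) {    # nilpotent: counts only grow
      nxt <- array(0, dims)
      for (cl in 1:4) if (!is.null(w[[cl]]))
        nxt <- nxt + shift1(w[[cl]] * m, cl)
      if (sum(nxt) == 0) break
      tot <- tot + nxt
      m <- nxt
    }

    flow <- (1 / c_anc) / R * tot
    for (r in seq_len(nrow(PARTITION_COAL[[p]]))) {
      tgt <- PARTITION_COAL[[p]][r, 3]
      base[[tgt]] <- base[[tgt]] + flow
    }
  }
  final
}

#' Analytic distribution of bSFS configurations under a demography model
#'
#' Computes the probability of every mutational configuration
#' `(het_b, het_v, shared_het, fixed_diff)` with per-class counts in
#' `0..k_max`, plus a lumped overflow cell per class (counts exceeding
#' `k_max`), for 200-bp-style blocks with mutation scaler `theta_block`.
#'
#' @param model a [demography_model] with concrete parameters.
#' @param theta_block expected mutations per block per unit branch length.
#' @param k_max per-class truncation (default 3).
#' @return object of class `bsfs_table`: a 4-d probability array with
#'   dimnames `0..k_max, ">k_max"` per class, plus attributes.
#' @export
config_distribution <- function(model, theta_block, k_max = 3L) {
  stopifnot(inherits(model, "demography_model"), k_max >= 0L)
  if (!is.finite(theta_block) || theta_block < 0) stop("theta_block must be >= 0")
  ps <- .product_space(model, k_max)
  K <- ps$K

  if (model$T_split > 0) {
    x <- as.vector(ps$coef %*% c(1 / model$c_V, 1 / model$c_B, model$m, theta_block))
    Gt <- ps$pattern
    Gt@x <- x
    Lambda <- max(-x[ps$diag_slots], 0)
    v <- numeric(ps$N)
    v[ps$ss$init] <- 1     # count cell 0 is the first block of the vector
    if (model$type == "ADM") {
      v <- .propagate(ps, Gt, Lambda, v, model$T_adm)
      P <- .pulse_matrix(ps$ss, model$f)
      v <- as.vector(crossprod(P, matrix(v, ps$M, ps$nc)))
      v <- .propagate(ps, Gt, Lambda, v, model$T_split - model$T_adm)
    } else {
      v <- .propagate(ps, Gt, Lambda, v, model$T_split)
    }
    p0 <- crossprod(matrix(v, ps$M, ps$nc), ps$part_ind)  # nc x 15
  } else {
    p0 <- matrix(0, ps$nc, length(PARTITIONS))
    p0[1, PARTITION_INDEX[[.partition_key(c(1L, 2L, 4L, 8L))]]] <- 1
  }

  tab <- .ancestral_absorb(p0, theta_block, model$c_anc, K)
  if (min(tab) < -1e-10)
    stop("negative configuration probability beyond tolerance: ", min(tab))
  tab[tab < 0] <- 0
  lab <- c(as.character(0:k_max), paste0(">", k_max))
  dimnames(tab) <- stats::setNames(rep(list(lab), 4), CLASS_NAMES)
  structure(tab, class = "bsfs_table", theta_block = theta_block,
            k_max = as.integer(k_max), model_id = model$model_id)
}

#' @exportS3Method base::print
print.bsfs_table <- function(x, ...) {
  cat(sprintf("<bsfs_table: model %s, theta_block = %g, k_max = %d, total = %.10f>\n",
              attr(x, "model_id"), attr(x, "theta_block"), attr(x, "k_max"),
              sum(x)))
  invisible(x)
}

#' Write a configuration probability table as TSV
#' @param table a `bsfs_table`.
#' @param path output path.
#' @export
write_bsfs_table <- function(table, path) {
  K <- attr(table, "k_max") + 2L
  grid <- expand.grid(dimnames(table), stringsAsFactors = FALSE)
  df <- cbind(grid, probability = as.vector(table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probability of one bSFS configuration
#'
#' @param model a [demography_model].
#' @param theta_block mutation scaler per block.
#' @param config integer vector of 4 counts in the fixed
#'   `(het_b, het_v, shared_het, fixed_diff)` order; counts greater than
#'   `k_max` address the per-class lumped overflow cell.
#' @param k_max truncation (default 3).
#' @return probability (scalar).
#' @export
config_probability <- function(model, theta_block, config, k_max = 3L) {
  stopifnot(length(config) == 4L, all(config >= 0))
  tab <- config_distribution(model, theta_block, k_max)
  idx <- pmin(as.integer(config), k_max + 1L) + 1L
  tab[idx[1], idx[2], idx[3], idx[4]]
}

#' Monte-Carlo estimate of a configuration probability
#'
#' Rao-Blackwellized oracle: simulates genealogies and averages the product
#' of Poisson probability masses of the observed per-class counts given the
#' simulated class-resolved branch lengths. Serves as the independent check
#' of [config_probability].
#'
#' @inheritParams config_probability
#' @param n_sims number of simulated genealogies.
#' @param seed integer seed.
#' @param lumped logical(4); `TRUE` entries evaluate the upper Poisson tail
#'   `P(count > config)` for that class (the lumped overflow cell).
#' @return list with `estimate` and `se`.
#' @export
mc_config_probability <- function(model, theta_block, config, n_sims, seed,
                                  lumped = rep(FALSE, 4)) {
  stopifnot(n_sims >= 1, length(config) == 4L)
  set.seed(seed)
  tau <- simulate_branch_lengths(model, n_sims)
  w <- rep(1, n_sims)
  for (cl in 1:4) {
    mu <- theta_block * tau[, cl]
    w <- w * if (lumped[cl]) stats::ppois(config[cl], mu, lower.tail = FALSE)
             else stats::dpois(config[cl], mu)
  }
  list(estimate = mean(w), se = stats::sd(w) / sqrt(n_sims))
}

#' Monte-Carlo estimate of the full configuration table
#'
#' Vectorized version of [mc_config_probability] over every cell of the
#' truncated table (including lumped overflow cells), sharing one set of
#' simulated genealogies across cells.
#'
#' @inheritParams mc_config_probability
#' @param k_max truncation.
#' @return list of two 4-d arrays, `estimate` and `se`, matching the layout
#'   of [config_distribution].
#' @export
mc_config_table <- function(model, theta_block, k_max, n_sims, seed) {
  set.seed(seed)
  tau <- simulate_branch_lengths(model, n_sims)
  K <- k_max + 2L
  W <- lapply(1:4, function(cl) {
    mu <- theta_block * tau[, cl]
    cbind(vapply(0:k_max, function(k) stats::dpois(k, mu), numeric(n_sims)),
          stats::ppois(k_max, mu, lower.tail = FALSE))
  })
  A <- W[[1]][, rep(1:K, times = K)] * W[[2]][, rep(1:K, each = K)]
  B <- W[[3]][, rep(1:K, times = K)] * W[[4]][, rep(1:K, each = K)]
  est <- crossprod(A, B) / n_sims
  m2 <- crossprod(A * A, B * B) / n_sims
  vr <- pmax(m2 - est^2, 0) * n_sims / (n_sims - 1)
  lab <- c(as.character(0:k_max), paste0(">", k_max))
  dn <- stats::setNames(rep(list(lab), 4), CLASS_NAMES)
  list(estimate = array(est, c(K, K, K, K), dimnames = dn),
       se = array(sqrt(vr / n_sims), c(K, K, K, K), dimnames = dn))
}

## map tally configurations onto cells of a truncated table
.tally_cell_index <- function(tally, k_max) {
  K <- k_max + 2L
  cfg <- as.matrix(tally$configs[, CLASS_NAMES])
  idx <- pmin(cfg, k_max + 1L)
  1L + idx %*% K^(0:3)
}

#' Composite log-likelihood of a bSFS tally under a model
#'
#' `lnCL = sum_config n_config * ln P(config)` treating blocks as
#' independent. Probabilities are floored at 1e-300 (with a warning) so
#' that configurations that are impossible under extreme parameters do not
#' produce `-Inf`.
#'
#' @param tally a [bsfs_tally].
#' @param model a [demography_model] (structure; free parameters are taken
#'   from `params`).
#' @param params named vector with `theta_block` and the model's free
#'   parameters (`T_split`, and `c_x`, `m`, `f`, `T_adm` as applicable).
#' @param k_max truncation used for the probability table.
#' @return scalar lnCL.
#' @export
composite_loglik <- function(tally, model, params, k_max = 3L) {
  stopifnot(inherits(tally, "bsfs_tally"))
  if (nrow(tally$configs) == 0L) stop("tally is empty")
  m2 <- .model_with_params(model, params)
  tab <- config_distribution(m2, params[["theta_block"]], k_max)
  loglik_from_table(tally, tab)
}

#' Composite log-likelihood given a precomputed probability table
#' @param tally a [bsfs_tally].
#' @param table a `bsfs_table` from [config_distribution].
#' @return scalar lnCL.
#' @export
loglik_from_table <- function(tally, table) {
  k_max <- attr(table, "k_max")
  p <- as.vector(table)[.tally_cell_index(tally, k_max)]
  if (any(p < 1e-300)) {
    warning("configuration probabilities floored at 1e-300")
    p <- pmax(p, 1e-300)
  }
  sum(tally$configs$n_blocks * log(p))
}
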