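## Pre-split state space of the structured coalescent for the (2,2) sample.
##
## A lineage configuration is a set partition of the four sampled alleles
## (each block = one ancestral lineage, encoded as a bit mask) together with
## a deme label per lineage. Events in the pre-split epoch are pairwise
## coalescence within a deme (rate 1/c_deme per pair) and, for IM models,
## backwards migration of single lineages (rate m per eligible lineage).
## Admixture pulses are instantaneous stochastic relabelings handled by a
## separate pulse matrix, not by the generator.

.state_key <- function(masks, demes) {
  o <- order(masks)
  paste(masks[o], demes[o], sep = ":", collapse = ",")
}

#' Enumerate the pre-split state space and transition structure of a model
#'
#' Breadth-first enumeration of all lineage configurations reachable from
#' the sample (v1, v2 in deme V; b1, b2 in deme B) under the model's event
#' set. Each state is annotated with the rate at which it accrues branch
#' length into each folded mutation class (the number of its lineages whose
#' leaf subset maps to that class).
#'
#' @param model a [demography_model].
#' @return list with elements `states` (list of `masks`/`demes`),
#'   `class_counts` (matrix n_states x 4), `transitions` (data.frame
#'   `from`, `to`, `kind` in `coal_V`/`coal_B`/`mig`), `partition_of`
#'   (index into the 15 leaf partitions per state), `init` (index of the
#'   sampling state) and `pulse_moves` (for ADM models, per-state single
#'   lineage relabeling targets used to assemble the pulse matrix).
#' @export
build_state_space <- function(model) {
  stopifnot(inherits(model, "demography_model"))
  mig_from <- if (model$type == "IM") {
    if (model$direction == "BV") 0L else 1L
  } else -1L
  pulse_from <- if (model$type == "ADM") {
    if (model$direction == "BV") 0L else 1L
  } else -1L

  states <- list()
  index <- new.env(parent = emptyenv())
  get_id <- function(masks, demes) {
    o <- order(masks); masks <- masks[o]; demes <- demes[o]
    key <- .state_key(masks, demes)
    id <- index[[key]]
    if (is.null(id)) {
      id <- length(states) + 1L
      states[[id]] <<- list(masks = masks, demes = demes)
      index[[key]] <- id
    }
    id
  }

  init <- get_id(c(1L, 2L, 4L, 8L), c(0L, 0L, 1L, 1L))
  trans <- list()
  pulse_moves <- list()
  q <- init
  while (length(q) > 0L) {
    id <- q[[1L]]; q <- q[-1L]
    st <- states[[id]]
    n <- length(st$masks)
    nbefore <- length(states)
    if (n >= 2L) {
      for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
        if (st$demes[a] != st$demes[b]) next
        masks2 <- c(st$masks[-c(a, b)], bitwOr(st$masks[a], st$masks[b]))
        demes2 <- c(st$demes[-c(a, b)], st$demes[a])
        to <- get_id(masks2, demes2)
        trans[[length(trans) + 1L]] <-
          c(id, to, if (st$demes[a] == 0L) 1L else 2L)  # coal_V / coal_B
      }
    }
    switch_from <- if (mig_from >= 0L) mig_from else pulse_from
    if (switch_from >= 0L) {
      for (a in seq_len(n)) {
        if (st$demes[a] != switch_from) next
        demes2 <- st$demes; demes2[a] <- 1L - switch_from
        to <- get_id(st$masks, demes2)
        if (mig_from >= 0L) {
          trans[[length(trans) + 1L]] <- c(id, to, 3L)  # mig
        }
      }
    }
    if (length(states) > nbefore) q <- c(q, seq.int(nbefore + 1L, length(states)))
  }

  M <- length(states)
  tr <- if (length(trans) > 0L) do.call(rbind, trans) else matrix(integer(0), ncol = 3)
  transitions <- data.frame(from = tr[, 1], to = tr[, 2],
                            kind = c("coal_V", "coal_B", "mig")[tr[, 3]])
  class_counts <- t(vapply(states, function(st) {
    n <- c(0, 0, 0, 0)
    for (mk in st$masks) if (mk != 15L) {
      k <- .class_of_mask(mk); n[k] <- n[k] + 1
    }
    n
  }, numeric(4)))
  colnames(class_counts) <- CLASS_NAMES
  partition_of <- vapply(states, function(st)
    PARTITION_INDEX[[.partition_key(st$masks)]], integer(1))

  if (pulse_from >= 0L) {
    ## per state: indices of lineages eligible to switch and, per subset of
    ## them, the target state (used to fill the pulse matrix for a given f)
    pulse_moves <- lapply(seq_len(M), function(id) {
      st <- states[[id]]
      elig <- which(st$demes == pulse_from)
      k <- length(elig)
      subs <- lapply(0:(2^k - 1), function(bits) {
        take <- elig[bitwAnd(bitwShiftR(bits, seq_len(k) - 1L), 1L) == 1L]
        demes2 <- st$demes; demes2[take] <- 1L - pulse_from
        o <- order(st$masks)
        c(n_moved = length(take),
          to = index[[.state_key(st$masks, demes2)]])
      })
      list(k = k, moves = do.call(rbind, subs))
    })
  }

  structure(list(states = states, class_counts = class_counts,
                 transitions = transitions, partition_of = partition_of,
                 init = init, n_states = M, mig_from = mig_from,
                 pulse_from = pulse_from, pulse_moves = pulse_moves),
            class = "bsfs_state_space")
}

#' Generator matrix of the pre-split lineage process
#'
#' @param ss a state space from [build_state_space].
#' @param model a [demography_model] supplying the rates.
#' @return sparse `dgCMatrix` generator (rows = origin states, row sums 0).
#' @export
state_generator <- function(ss, model) {
  rate <- c(coal_V = 1 / model$c_V, coal_B = 1 / model$c_B, mig = model$m)
  tr <- ss$transitions
  M <- ss$n_states
  if (nrow(tr) == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                  x = numeric(0), dims = c(M, M)))
  x <- rate[tr$kind]
  Q <- Matrix::sparseMatrix(i = tr$from, j = tr$to, x = x, dims = c(M, M))
  Matrix::Diagonal(M, x = -Matrix::rowSums(Q)) + Q
}

## pulse matrix P[s, s'] = P(state s -> s') when each lineage in the
## recipient deme independently switches deme with probability f
.pulse_matrix <- function(ss, f) {
  M <- ss$n_states
  P <- matrix(0, M, M)
  for (id in seq_len(M)) {
    pm <- ss$pulse_moves[[id]]
    k <- pm$k
    if (k == 0L) { P[id, id] <- 1; next }
    pr <- f^pm$moves[, "n_moved"] * (1 - f)^(k - pm$moves[, "n_moved"])
    for (r in seq_len(nrow(pm$moves)))
      P[id, pm$moves[r, "to"]] <- P[id, pm$moves[r, "to"]] + pr[r]
  }
  P
}
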