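# Shared helpers: random instances and independent brute-force oracles.
# The oracles deliberately avoid the package's own code paths (explicit
# loops, no hashing, no matrix products) so that agreement is evidence.

rand_adjacency <- function(n, p = 0.5) {
  m <- matrix(0L, n, n)
  up <- which(upper.tri(m))
  m[up] <- as.integer(runif(length(up)) < p)
  m <- m + t(m)
  binary_adjacency(m)
}

rand_binary_series <- function(t, n) {
  matrix(as.integer(runif(t * n) < 0.5), t, n)
}

# Successor of a state by explicit per-node neighbour loop.
oracle_step <- function(state, adjm, a, b, inclusive) {
  n <- length(state)
  nxt <- integer(n)
  for (i in seq_len(n)) {
    sig <- 0L
    for (j in seq_len(n)) if (adjm[i, j] == 1L) sig <- sig + state[j]
    nxt[i] <- if (inclusive) as.integer(sig >= a && sig <= b)
              else as.integer(sig > a && sig < b)
  }
  nxt
}

# Transient/period by storing every visited state and linear search for the
# first recurrence (exhaustive state-graph traversal from one start).
oracle_period <- function(state, adjm, a, b, inclusive, max_steps = NULL) {
  n <- length(state)
  if (is.null(max_steps)) max_steps <- 2L^n + 2L
  visited <- list(state)
  for (t in seq_len(max_steps)) {
    state <- oracle_step(state, adjm, a, b, inclusive)
    for (k in seq_along(visited)) {
      if (all(visited[[k]] == state))
        return(list(transient = k - 1L, period = t - (k - 1L)))
    }
    visited[[t + 1L]] <- state
  }
  list(transient = NA_integer_, period = NA_integer_)
}

# All labeled connected graphs on n nodes, as a list of adjacency matrices.
connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  npair <- nrow(pairs)
  out <- list()
  for (mask in 0:(2L^npair - 1L)) {
    m <- matrix(0L, n, n)
    for (k in seq_len(npair)) {
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0L) {
        m[pairs[k, 1], pairs[k, 2]] <- 1L
        m[pairs[k, 2], pairs[k, 1]] <- 1L
      }
    }
    # BFS connectivity
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(m[v, ] == 1L & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen)) out[[length(out) + 1L]] <- m
  }
  out
}

# Pearson correlation of two vectors by the textbook covariance/(sd*sd)
# formula, written long-hand.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

int_states <- function(n) {
  # all 2^n binary vectors of length n
  lapply(0:(2L^n - 1L), function(k)
    as.integer(bitwAnd(bitwShiftR(k, 0:(n - 1L)), 1L)))
}
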