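# Windowed-threshold Boolean dynamics on a binary adjacency.
#
# Each node carries a 0/1 state. Writing sigma_i for the number of active
# neighbours of node i, the update is: s_i(t+1) = 1 iff sigma_i(t) lies in
# the activation window [a, b] (inclusive by default; a strict-inequality
# mode is available). Update order is governed by the scheme: CRBN
# (synchronous), ARBN (one random node/step), DARBN (per-node phase (p, q),
# sequential), GARBN (g random nodes/step, simultaneous), DGARBN (DARBN
# eligibility, simultaneous).

#' Activation-window threshold rule
#'
#' A node switches on at the next step exactly when its local sum (number of
#' active neighbours) falls inside the window. In `"inclusive"` mode
#' (default) the node fires for `a <= sigma <= b`; in `"strict"` mode for
#' `a < sigma < b`. Inclusive is the default because a strict window makes
#' narrow rules such as a = b = 1 unable to fire at all, contradicting the
#' non-trivial dynamics those rules exhibit.
#'
#' @param a,b Integer window bounds, `0 <= a <= b`.
#' @param boundary `"inclusive"` or `"strict"`.
#' @return A `threshold_rule` object.
#' @examples
#' apply_rule(2, threshold_rule(1, 4)) # 1
#' @export
threshold_rule <- function(a, b, boundary = c("inclusive", "strict")) {
  boundary <- match.arg(boundary)
  a <- as.integer(a); b <- as.integer(b)
  if (is.na(a) || is.na(b) || a < 0L) stop("need integer bounds with a >= 0")
  if (b < a) stop("need b >= a")
  structure(list(a = a, b = b, boundary = boundary), class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> window [%d, %d], %s\n", x$a, x$b, x$boundary))
  invisible(x)
}

#' Update-scheme specification
#'
#' Chooses how node updates are ordered in time:
#' * `"CRBN"` — classic synchronous: all nodes simultaneously (deterministic);
#' * `"ARBN"` — one uniformly chosen node per step (stochastic);
#' * `"DARBN"` — node i is eligible at step t iff `q[i] == t %% p[i]`;
#'   eligible nodes update one by one in ascending index, each seeing the
#'   changes already made during the step (deterministic);
#' * `"GARBN"` — `g` nodes drawn uniformly without replacement each step,
#'   updated simultaneously (stochastic; per-node update probability g/N);
#' * `"DGARBN"` — DARBN eligibility, but eligible nodes update
#'   simultaneously (deterministic).
#'
#' @param kind One of `"CRBN"`, `"ARBN"`, `"DARBN"`, `"GARBN"`, `"DGARBN"`.
#' @param p,q Per-node integer phase vectors (recycled to length N at
#'   simulation time) with `0 <= q < p`; DARBN/DGARBN only.
#' @param g Nodes updated per step; GARBN only.
#' @param seed Integer seed for the stochastic kinds (mandatory there).
#' @return A `scheme_spec` object.
#' @export
update_scheme <- function(kind = c("CRBN", "ARBN", "DARBN", "GARBN", "DGARBN"),
                          p = NULL, q = NULL, g = NULL, seed = NULL) {
  kind <- match.arg(toupper(kind), c("CRBN", "ARBN", "DARBN", "GARBN", "DGARBN"))
  if (kind %in% c("DARBN", "DGARBN")) {
    if (is.null(p) || is.null(q)) stop(kind, " needs per-node p and q")
    p <- as.integer(p); q <- as.integer(q)
    if (any(p < 1L)) stop("p must be positive")
    if (any(q < 0L) || any(q >= rep_len(p, length(q))))
      stop("need 0 <= q < p for every node")
  }
  if (kind == "GARBN") {
    if (is.null(g) || g < 1L) stop("GARBN needs g >= 1")
    g <- as.integer(g)
  }
  if (kind %in% c("ARBN", "GARBN") && is.null(seed))
    stop(kind, " is stochastic: a seed is required")
  structure(list(kind = kind, p = p, q = q, g = g, seed = seed),
            class = "scheme_spec")
}

is_deterministic_scheme <- function(scheme) {
  scheme$kind %in% c("CRBN", "DARBN", "DGARBN")
}

#' Local sum of active neighbours
#'
#' `sigma_i = sum_j adj[i, j] * state[j]`; the node's own state never
#' contributes (the diagonal is zero).
#'
#' @param state Binary state vector of length N.
#' @param adj A `binary_adjacency`.
#' @param i Node index (1-based).
#' @return Integer neighbour-activation count.
#' @export
local_sum <- function(state, adj, i) {
  stopifnot(inherits(adj, "binary_adjacency"))
  if (length(state) != adj$n_nodes)
    stop("state length does not match adjacency")
  if (i < 1L || i > adj$n_nodes) stop("node index out of range")
  as.integer(sum(adj$matrix[i, ] * state))
}

#' Apply the threshold rule to a local sum
#'
#' @param sigma Non-negative integer local sum (vectorised).
#' @param rule A [threshold_rule].
#' @return 0/1 integer, same length as `sigma`.
#' @export
apply_rule <- function(sigma, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (rule$boundary == "inclusive")
    as.integer(sigma >= rule$a & sigma <= rule$b)
  else
    as.integer(sigma > rule$a & sigma < rule$b)
}

#' Flip the state of selected nodes
#'
#' Returns a copy of `state` with the listed bits inverted (an involution:
#' flipping twice restores the original). Used to seed damage-spreading
#' experiments.
#'
#' @param state Binary state vector.
#' @param flips Integer node indices to flip (may be empty).
#' @return Perturbed copy of `state`.
#' @export
perturb <- function(state, flips) {
  flips <- as.integer(flips)
  if (length(flips) && (min(flips) < 1L || max(flips) > length(state)))
    stop("flip index out of range")
  state[flips] <- 1L - state[flips]
  state
}

check_state <- function(initial, adj) {
  if (length(initial) != adj$n_nodes)
    stop("initial state length does not match adjacency")
  initial <- as.integer(initial)
  if (any(is.na(initial)) || any(initial < 0L | initial > 1L))
    stop("initial state must be 0/1")
  initial
}

scheme_phases <- function(scheme, n) {
  list(p = rep_len(scheme$p, n), q = rep_len(scheme$q, n))
}

# One update step; `t` is the 0-based index of the step being taken.
step_state <- function(state, adjm, rule, scheme, t, phases = NULL) {
  switch(scheme$kind,
    CRBN = apply_rule(as.vector(adjm %*% state), rule),
    ARBN = {
      i <- sample.int(length(state), 1L)
      state[i] <- apply_rule(sum(adjm[i, ] * state), rule)
      state
    },
    GARBN = {
      idx <- sample.int(length(state), min(scheme$g, length(state)))
      sig <- as.vector(adjm[idx, , drop = FALSE] %*% state)
      state[idx] <- apply_rule(sig, rule)
      state
    },
    DARBN = {
      elig <- which(phases$q == t %% phases$p)
      for (i in elig)
        state[i] <- apply_rule(sum(adjm[i, ] * state), rule)
      state
    },
    DGARBN = {
      elig <- which(phases$q == t %% phases$p)
      if (length(elig)) {
        sig <- as.vector(adjm[elig, , drop = FALSE] %*% state)
        state[elig] <- apply_rule(sig, rule)
      }
      state
    })
}

#' Simulate Boolean dynamics on a binary adjacency
#'
#' Iterates the windowed-threshold update for `steps` steps from the given
#' initial configuration, under the chosen update scheme. Stochastic schemes
#' (ARBN, GARBN) are reproducible from the scheme's seed; the global RNG
#' state is left untouched.
#'
#' @param initial Binary state vector of length N (time 0).
#' @param adj A `binary_adjacency`.
#' @param rule A [threshold_rule].
#' @param steps Number of update steps (>= 1).
#' @param scheme An [update_scheme()]; default classic synchronous.
#' @return A `bn_trajectory`: list with `states` ((steps+1) x N integer
#'   matrix, row t+1 = configuration at time t), `rule`, `scheme`, `n_nodes`.
#' @examples
#' adj <- binarize(synthetic_connectome(10, seed = 1), 0.5)
#' tr <- simulate_bn(rep(c(1L, 0L), 5), adj, threshold_rule(1, 4), steps = 50)
#' dim(tr$states) # 51 x 10
#' @export
simulate_bn <- function(initial, adj, rule, steps,
                        scheme = update_scheme("CRBN")) {
  stopifnot(inherits(adj, "binary_adjacency"),
            inherits(rule, "threshold_rule"),
            inherits(scheme, "scheme_spec"))
  if (steps < 1L) stop("steps must be >= 1")
  state <- check_state(initial, adj)
  n <- adj$n_nodes
  phases <- if (scheme$kind %in% c("DARBN", "DGARBN")) scheme_phases(scheme, n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  states <- matrix(0L, nrow = steps + 1L, ncol = n)
  states[1L, ] <- state
  for (t in seq_len(steps)) {
    state <- step_state(state, adj$matrix, rule, scheme, t - 1L, phases)
    states[t + 1L, ] <- state
  }
  structure(list(states = states, rule = rule, scheme = scheme,
                 n_nodes = n), class = "bn_trajectory")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf("<bn_trajectory> %d nodes x %d steps (%s, window [%d, %d])\n",
              x$n_nodes, nrow(x$states) - 1L, x$scheme$kind,
              x$rule$a, x$rule$b))
  invisible(x)
}

lcm_int <- function(v) {
  gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)
  Reduce(function(a, b) a %/% gcd2(a, b) * b, as.integer(v), 1L)
}

#' Detect the transient and period of a deterministic trajectory
#'
#' Runs the dynamics forward, hashing each visited configuration; the first
#' revisit of a configuration seen at time `t1` and met again at `t2` gives
#' `transient = t1` and `period = t2 - t1`. For the phase-dependent schemes
#' (DARBN, DGARBN) the pair (configuration, `t mod lcm(p)`) is hashed, since
#' the configuration alone does not determine the successor. Returns an
#' `NA` period if no revisit occurs within the horizon.
#'
#' @param initial Binary initial state.
#' @param adj A `binary_adjacency`.
#' @param rule A [threshold_rule].
#' @param scheme Deterministic [update_scheme()] (CRBN, DARBN or DGARBN);
#'   stochastic schemes are rejected.
#' @param horizon Steps examined for a recurrence (default 500, the standard
#'   run length).
#' @param warm_start Steps simulated before recurrence tracking begins
#'   (default 0); reported transients are absolute times including the
#'   warm-up.
#' @return A `period_result`: list with `transient`, `period` (`NA` if
#'   none found), `horizon`.
#' @examples
#' adj <- binary_adjacency(matrix(c(0, 1, 1, 0), 2))
#' detect_period(c(1L, 0L), adj, threshold_rule(1, 1))$period # 2
#' @export
detect_period <- function(initial, adj, rule, scheme = update_scheme("CRBN"),
                          horizon = 500L, warm_start = 0L) {
  stopifnot(inherits(adj, "binary_adjacency"),
            inherits(rule, "threshold_rule"))
  if (!is_deterministic_scheme(scheme))
    stop("detect_period requires a deterministic scheme (CRBN/DARBN/DGARBN)")
  if (horizon < 2L) stop("horizon must be >= 2")
  state <- check_state(initial, adj)
  n <- adj$n_nodes
  phases <- if (scheme$kind %in% c("DARBN", "DGARBN")) scheme_phases(scheme, n)
  modulus <- if (is.null(phases)) 1L else lcm_int(phases$p)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  t <- 0L
  while (t < warm_start) {
    state <- step_state(state, adj$matrix, rule, scheme, t, phases)
    t <- t + 1L
  }
  tmax <- warm_start + horizon
  repeat {
    key <- paste0(paste(state, collapse = ""), "@", t %% modulus)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      return(structure(list(transient = prev, period = t - prev,
                            horizon = horizon), class = "period_result"))
    }
    seen[[key]] <- t
    if (t >= tmax) break
    state <- step_state(state, adj$matrix, rule, scheme, t, phases)
    t <- t + 1L
  }
  structure(list(transient = NA_integer_, period = NA_integer_,
                 horizon = horizon), class = "period_result")
}

#' @export
print.period_result <- function(x, ...) {
  if (is.na(x$period))
    cat(sprintf("<period_result> no period within %d steps\n", x$horizon))
  else
    cat(sprintf("<period_result> transient %d, period %d (horizon %d)\n",
                x$transient, x$period, x$horizon))
  invisible(x)
}

#' Classify the dynamical regime of a period result
#'
#' No recurrence within the horizon is labelled `"chaotic"`; a long cycle
#' (period above `complex_cutoff`) is `"complex"` (high or medium
#' periodicity); a short cycle is `"ordered"`.
#'
#' @param p A `period_result` (or a bare period, `NA` meaning none found).
#' @param complex_cutoff Period above which a cycle counts as complex
#'   (default 8).
#' @return `"chaotic"`, `"complex"` or `"ordered"`.
#' @export
classify_regime <- function(p, complex_cutoff = 8L) {
  period <- if (inherits(p, "period_result")) p$period else p
  if (is.na(period)) "chaotic"
  else if (period > complex_cutoff) "complex"
  else "ordered"
}
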