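# Parameter-grid sweeps over the activation window (a, b) and thresholds
# (x, z), plus stability scoring of a circuit configuration against the
# ten-circuit reference, and damage-spreading experiments.

#' Sweep the activation window over a period map
#'
#' Runs [detect_period()] for every cell of the `a_range` x `b_range` grid
#' on the binarized connectome and attaches the regime classification,
#' producing a period table (e.g. a 1..7 x b 1..13 gives 91 cells). Cells
#' are computed independently and emitted in lexicographic (a, b) order.
#'
#' @param conn A [connectome] (binarized at `x`) or a `binary_adjacency`
#'   (then `x` is ignored).
#' @param initial Binary initial state.
#' @param a_range,b_range Integer vectors of window bounds. Cells with
#'   `b < a` denote an empty activation window: no local sum can fire the
#'   node, so every state maps to all-zero in one step (transient 0 or 1,
#'   period 1, ordered).
#' @param x Connection threshold used to binarize a weighted connectome.
#' @param steps Recurrence horizon per cell (default 500).
#' @param boundary Window boundary mode, see [threshold_rule()].
#' @param warm_start Steps before recurrence tracking, see [detect_period()].
#' @param complex_cutoff Passed to [classify_regime()].
#' @return A `sweep_grid`: data frame with columns `a`, `b`, `transient`,
#'   `period`, `regime`, with the run parameters in attributes.
#' @export
period_sweep <- function(conn, initial, a_range, b_range, x = 0.9,
                         steps = 500L, boundary = "inclusive",
                         warm_start = 0L, complex_cutoff = 8L) {
  if (!length(a_range) || !length(b_range)) stop("empty parameter range")
  adj <- if (inherits(conn, "binary_adjacency")) conn else binarize(conn, x)
  rows <- list()
  for (a in sort(unique(as.integer(a_range))))
    for (b in sort(unique(as.integer(b_range)))) {
      pr <- if (b < a) {
        # empty window: all states map to all-zero at the next step
        structure(list(transient = if (all(initial == 0L)) 0L else 1L,
                       period = 1L, horizon = steps),
                  class = "period_result")
      } else {
        detect_period(initial, adj, threshold_rule(a, b, boundary),
                      horizon = steps, warm_start = warm_start)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(a = a, b = b, transient = pr$transient,
                   period = pr$period,
                   regime = classify_regime(pr, complex_cutoff))
    }
  out <- do.call(rbind, rows)
  attr(out, "x") <- if (inherits(conn, "binary_adjacency")) NA_real_ else x
  attr(out, "steps") <- steps
  attr(out, "boundary") <- boundary
  class(out) <- c("sweep_grid", "data.frame")
  out
}

#' Lay a period sweep out as an a x b table
#'
#' @param grid A `sweep_grid`.
#' @param no_period Cell text for chaotic cells (default `"NP"`).
#' @return Character matrix, rows named by `a`, columns by `b`.
#' @export
sweep_table <- function(grid, no_period = "NP") {
  a_vals <- sort(unique(grid$a)); b_vals <- sort(unique(grid$b))
  tab <- matrix("", length(a_vals), length(b_vals),
                dimnames = list(paste0("a=", a_vals), paste0("b=", b_vals)))
  for (i in seq_len(nrow(grid))) {
    v <- grid$period[i]
    tab[match(grid$a[i], a_vals), match(grid$b[i], b_vals)] <-
      if (is.na(v)) no_period else as.character(v)
  }
  tab
}

#' Score a circuit configuration against a reference
#'
#' Compares a candidate circuit set to a reference configuration (typically
#' [reference_circuits()]): exact member-set matches, reference circuits
#' that survive only as proper sub-circuits of a larger candidate circuit,
#' per-reference-circuit counts of candidates sharing at least one area,
#' and a Jaccard score = exact matches / distinct member sets across both
#' families. Containment is deliberately reported apart from matching — a
#' circuit absorbed into a larger one is partial survival, not identity.
#'
#' @param candidate,reference `circuit_set`s; `reference` must be non-empty.
#' @return A `stability_report` list: `exact_matches` (data frame ref/cand
#'   indices), `containments` (data frame ref/cand indices with ref proper
#'   subset of cand), `shared_area_counts` (integer per reference circuit),
#'   `jaccard`, `n_candidate`, `n_reference`.
#' @examples
#' ref <- reference_circuits()
#' compare_to_reference(ref, ref)$jaccard # 1
#' @export
compare_to_reference <- function(candidate, reference) {
  stopifnot(inherits(candidate, "circuit_set"),
            inherits(reference, "circuit_set"))
  if (!length(reference$circuits)) stop("reference must be non-empty")
  mr <- circuit_members(reference)
  mc <- circuit_members(candidate)
  key <- function(v) paste(v, collapse = ",")
  kr <- vapply(mr, key, character(1)); kc <- vapply(mc, key, character(1))
  exact <- do.call(rbind, lapply(seq_along(kr), function(r) {
    hit <- which(kc == kr[r])
    if (length(hit)) data.frame(reference = r, candidate = hit) else NULL
  }))
  contain <- do.call(rbind, lapply(seq_along(mr), function(r) {
    hit <- which(vapply(mc, function(s)
      length(mr[[r]]) < length(s) && all(mr[[r]] %in% s), logical(1)))
    if (length(hit)) data.frame(reference = r, candidate = hit) else NULL
  }))
  empty <- data.frame(reference = integer(0), candidate = integer(0))
  shared <- vapply(mr, function(r)
    sum(vapply(mc, function(s) length(intersect(r, s)) > 0L, logical(1))),
    integer(1))
  n_exact <- if (is.null(exact)) 0L else nrow(exact)
  union_sets <- length(unique(c(kr, kc)))
  structure(list(exact_matches = exact %||% empty,
                 containments = contain %||% empty,
                 shared_area_counts = shared,
                 jaccard = n_exact / union_sets,
                 n_candidate = length(mc), n_reference = length(mr)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %d candidate vs %d reference circuits\n",
    x$n_candidate, x$n_reference))
  cat(sprintf("  exact matches: %d; containments: %d; jaccard: %.3f\n",
              nrow(x$exact_matches), nrow(x$containments), x$jaccard))
  invisible(x)
}

#' Damage spreading between a trajectory and its perturbed twin
#'
#' Runs two trajectories from `initial` and `perturb(initial, flips)` under
#' the same (deterministic) rule and scheme, and returns the Hamming
#' distance between them at each time step — the standard probe of
#' sensitivity to perturbations: does the damage die out, persist, or
#' spread?
#'
#' @param initial Binary initial state.
#' @param flips Node indices flipped in the twin (may be empty).
#' @param adj A `binary_adjacency`.
#' @param rule A [threshold_rule].
#' @param steps Number of steps to follow.
#' @param scheme Deterministic [update_scheme()].
#' @return Integer vector of length `steps + 1`: Hamming distance at times
#'   0..steps.
#' @export
damage_spread <- function(initial, flips, adj, rule, steps,
                          scheme = update_scheme("CRBN")) {
  if (!is_deterministic_scheme(scheme))
    stop("damage_spread requires a deterministic scheme")
  t1 <- simulate_bn(initial, adj, rule, steps, scheme)
  t2 <- simulate_bn(perturb(check_state(initial, adj), flips),
                    adj, rule, steps, scheme)
  as.integer(rowSums(t1$states != t2$states))
}
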