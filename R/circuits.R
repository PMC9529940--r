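# Emergent circuit extraction. Node time series from a Boolean trajectory
# are correlated pairwise (after removing nodes that never change); a
# circuit seeded at area r is r together with every area whose correlation
# with r exceeds the threshold z. Circuits are deduplicated — two members of
# one circuit need not be correlated above z with each other (hub
# structure): two strongly correlated pairs sharing a hub can merge into a
# three-area circuit whose third pair is weak.

resolve_window <- function(window, tmax) {
  # windows are in time units 0..steps (row t+1 of the state matrix)
  if (is.null(window)) window <- c(0L, tmax)
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be c(t_start, t_end) with t_start <= t_end")
  if (window[1] < 0L || window[2] > tmax)
    stop(sprintf("window [%d, %d] outside trajectory times 0..%d",
                 window[1], window[2], tmax))
  as.integer(window)
}

traj_states <- function(traj) {
  if (inherits(traj, "bn_trajectory")) traj$states else as.matrix(traj)
}

#' Remove constant nodes from a trajectory window
#'
#' Nodes whose state never changes over the window (always on or always
#' off) carry no dynamical signal and would make correlations undefined;
#' they are reported and removed before circuit extraction. The partition
#' kept / always-on / always-off is exhaustive and disjoint.
#'
#' @param traj A `bn_trajectory` or a T x N 0/1 matrix (row t+1 = time t).
#' @param window `c(t_start, t_end)` in time steps (0-based, inclusive);
#'   default the whole trajectory.
#' @return List with `series` (window rows x kept nodes, column names =
#'   node ids), `kept`, `always_on`, `always_off` (integer node ids).
#' @export
drop_constant_nodes <- function(traj, window = NULL) {
  states <- traj_states(traj)
  window <- resolve_window(window, nrow(states) - 1L)
  rows <- (window[1] + 1L):(window[2] + 1L)
  sub <- states[rows, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty window")
  mins <- apply(sub, 2L, min)
  maxs <- apply(sub, 2L, max)
  always_on <- which(mins == 1L)
  always_off <- which(maxs == 0L)
  kept <- which(mins != maxs)
  series <- sub[, kept, drop = FALSE]
  colnames(series) <- as.character(kept)
  list(series = series, kept = kept,
       always_on = always_on, always_off = always_off, window = window)
}

#' Pearson correlation matrix of node time series
#'
#' Computes the pairwise Pearson correlation of the 0/1 node signals over
#' the window. Every column must vary on the window (run
#' [drop_constant_nodes()] first); a zero-variance column is an error, not
#' an NA.
#'
#' @param series T x M 0/1 matrix (columns named with node ids), or the
#'   list returned by [drop_constant_nodes()].
#' @param window Optional `c(t_start, t_end)` restriction (0-based rows
#'   relative to the series start).
#' @return A `correlation_matrix`: list with `matrix` (M x M, unit
#'   diagonal), `kept_nodes` (integer ids), `window`.
#' @export
correlation_matrix <- function(series, window = NULL) {
  win0 <- NULL
  if (is.list(series) && !is.null(series$series)) {
    win0 <- series$window
    series <- series$series
  }
  series <- as.matrix(series)
  window <- resolve_window(window, nrow(series) - 1L)
  series <- series[(window[1] + 1L):(window[2] + 1L), , drop = FALSE]
  if (nrow(series) < 2L) stop("window too short to correlate")
  if (any(apply(series, 2L, function(col) min(col) == max(col))))
    stop("zero-variance column: remove constant nodes first")
  m <- stats::cor(series)
  kept <- if (!is.null(colnames(series))) as.integer(colnames(series))
          else seq_len(ncol(series))
  structure(list(matrix = m, kept_nodes = kept,
                 window = win0 %||% window), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d nodes, window [%d, %d]\n",
              length(x$kept_nodes), x$window[1], x$window[2]))
  invisible(x)
}

new_circuit_set <- function(circuits, z) {
  structure(list(circuits = circuits, z = z), class = "circuit_set")
}

#' Build a circuit set from explicit member lists
#'
#' @param members List of integer node-id vectors (each of size >= 2).
#' @param labels Optional character vector mapping node id to area label;
#'   defaults to the ids themselves.
#' @param z Correlation threshold to record.
#' @return A `circuit_set` (deduplicated, sorted by size then member ids).
#' @export
circuit_set <- function(members, labels = NULL, z = NA_real_) {
  circuits <- lapply(members, function(m) {
    m <- sort(unique(as.integer(m)))
    if (length(m) < 2L) stop("a circuit needs at least 2 members")
    lab <- if (is.null(labels)) as.character(m) else labels[m]
    structure(list(members = m, labels = lab), class = "circuit")
  })
  canonicalize_circuits(circuits, z)
}

canonicalize_circuits <- function(circuits, z) {
  if (length(circuits)) {
    keys <- vapply(circuits, function(cc) paste(cc$members, collapse = ","),
                   character(1))
    circuits <- circuits[!duplicated(keys)]
    sizes <- vapply(circuits, function(cc) length(cc$members), integer(1))
    lex <- vapply(circuits, function(cc)
      paste(sprintf("%05d", cc$members), collapse = ","), character(1))
    circuits <- circuits[order(sizes, lex)]
  }
  new_circuit_set(circuits, z)
}

#' @export
print.circuit_set <- function(x, ...) {
  cat(sprintf("<circuit_set> %d circuits (z = %s)\n", length(x$circuits),
              format(x$z)))
  for (i in seq_along(x$circuits)) {
    cc <- x$circuits[[i]]
    cat(sprintf("  %2d: {%s}  {%s}\n", i,
                paste(cc$members, collapse = ", "),
                paste(cc$labels, collapse = ", ")))
  }
  invisible(x)
}

#' @export
format.circuit <- function(x, ...) {
  sprintf("{%s}", paste(x$labels, collapse = ", "))
}

#' Extract emergent circuits by correlation thresholding
#'
#' For each seed node r, the candidate circuit is r together with every node
#' whose correlation with r is strictly greater than `z` (signed Pearson by
#' default; `mode = "absolute"` thresholds `|corr|`). Candidates with at
#' least two members are kept and identical member sets are counted once.
#' Note the hub property: nodes of one circuit need not be pairwise
#' correlated above `z`.
#'
#' @param corr A `correlation_matrix`.
#' @param z Correlation threshold in \[0, 1).
#' @param labels Optional node-id -> label vector (e.g.
#'   `brodmann_nodes()$label`).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return A `circuit_set`, ordered by circuit size then member ids.
#' @examples
#' # two strong pairs sharing a hub merge into a 3-member circuit
#' m <- diag(3); m[1, 2] <- m[2, 1] <- 0.9
#' m[2, 3] <- m[3, 2] <- 0.9; m[1, 3] <- m[3, 1] <- 0.5
#' cm <- structure(list(matrix = m, kept_nodes = 1:3, window = c(0, 49)),
#'                 class = "correlation_matrix")
#' extract_circuits(cm, 0.87)
#' @export
extract_circuits <- function(corr, z, labels = NULL,
                             mode = c("signed", "absolute")) {
  stopifnot(inherits(corr, "correlation_matrix"))
  mode <- match.arg(mode)
  if (!is.numeric(z) || length(z) != 1L || z < 0 || z >= 1)
    stop("z must lie in [0, 1)")
  cand <- unname(seed_candidates(corr, z, mode))
  cand <- cand[vapply(cand, length, integer(1)) >= 2L]
  circuits <- lapply(cand, function(mem) {
    lab <- if (is.null(labels)) as.character(mem) else labels[mem]
    structure(list(members = mem, labels = lab), class = "circuit")
  })
  canonicalize_circuits(circuits, z)
}

# Per-seed candidate sets: for seed node r (by kept-node id), the sorted ids
# {r} + {s : corr(r, s) > z}. Monotone in z: lowering z can only grow each
# candidate. Singletons (no mate above z) are kept here and filtered by
# extract_circuits.
seed_candidates <- function(corr, z, mode = "signed") {
  m <- corr$matrix
  if (mode == "absolute") m <- abs(m)
  ids <- corr$kept_nodes
  out <- lapply(seq_along(ids), function(r) {
    mates <- setdiff(which(m[r, ] > z), r)
    sort(ids[c(r, mates)])
  })
  names(out) <- as.character(ids)
  out
}

#' Extract circuits straight from a trajectory
#'
#' Convenience wrapper: removes constant nodes on the window, correlates the
#' remaining signals and thresholds at `z`.
#'
#' @inheritParams drop_constant_nodes
#' @inheritParams extract_circuits
#' @return A `circuit_set`.
#' @export
trajectory_circuits <- function(traj, z, window = NULL, labels = NULL,
                                mode = c("signed", "absolute")) {
  red <- drop_constant_nodes(traj, window)
  if (ncol(red$series) == 0L) return(new_circuit_set(list(), z))
  extract_circuits(correlation_matrix(red), z, labels = labels,
                   mode = match.arg(mode))
}

circuit_members <- function(cs) lapply(cs$circuits, `[[`, "members")

#' Pairwise intersection ratios between two circuit sets
#'
#' Entry (r, s) is `|members(r) intersect members(s)| / |members(r)|`, rows
#' indexed by `A`, columns by `B`. The ratio is 1 exactly when circuit r is
#' contained in circuit s; over a single set the diagonal is all 1.
#'
#' @param A,B Non-empty `circuit_set`s (`B` defaults to `A`).
#' @return An `intersection_matrix`: list with `ratios` and the two member
#'   lists.
#' @examples
#' ref <- reference_circuits()
#' intersection_matrix(ref)$ratios[2, 9] # circuit 2 inside circuit 9: 1
#' @export
intersection_matrix <- function(A, B = A) {
  stopifnot(inherits(A, "circuit_set"), inherits(B, "circuit_set"))
  ma <- circuit_members(A); mb <- circuit_members(B)
  if (!length(ma) || !length(mb)) stop("both circuit sets must be non-empty")
  ratios <- matrix(0, length(ma), length(mb))
  for (r in seq_along(ma))
    for (s in seq_along(mb))
      ratios[r, s] <- length(intersect(ma[[r]], mb[[s]])) / length(ma[[r]])
  structure(list(ratios = ratios, row_members = ma, col_members = mb),
            class = "intersection_matrix")
}

#' @export
print.intersection_matrix <- function(x, digits = 3, ...) {
  print(round(x$ratios, digits))
  invisible(x)
}

#' Circuit membership count per area label
#'
#' For each area label occurring in the set, the number of circuits whose
#' label set contains it (e.g. an area "in common with 3 circuits").
#'
#' @param A A `circuit_set`.
#' @return Named integer vector, names sorted.
#' @examples
#' membership_counts(reference_circuits())[["43L"]] # 3
#' @export
membership_counts <- function(A) {
  stopifnot(inherits(A, "circuit_set"))
  labs <- unlist(lapply(A$circuits, `[[`, "labels"))
  if (!length(labs)) return(integer(0))
  counts <- table(labs)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[order(names(out))]
}

#' Proper-subset relations among circuits
#'
#' All ordered pairs (r, s) of circuit indices with members(r) a proper
#' subset of members(s).
#'
#' @param A A `circuit_set`.
#' @return Data frame with integer columns `r`, `s` (zero rows if none).
#' @examples
#' subset_relations(reference_circuits()) # (2,9) (7,9) (5,10) (6,10)
#' @export
subset_relations <- function(A) {
  stopifnot(inherits(A, "circuit_set"))
  mem <- circuit_members(A)
  out <- list()
  for (r in seq_along(mem))
    for (s in seq_along(mem)) {
      if (r == s) next
      if (length(mem[[r]]) < length(mem[[s]]) &&
          all(mem[[r]] %in% mem[[s]]))
        out[[length(out) + 1L]] <- c(r, s)
    }
  if (!length(out)) return(data.frame(r = integer(0), s = integer(0)))
  m <- do.call(rbind, out)
  data.frame(r = m[, 1], s = m[, 2])
}
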