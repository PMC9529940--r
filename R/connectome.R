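# Connectome container: weighted, symmetric, zero-diagonal adjacency over
# labelled brain regions, plus thresholding to binary graphs and synthesis
# of weight matrices with prescribed first two moments.

default_nodes <- function(n) {
  data.frame(index = seq_len(n), label = as.character(seq_len(n)),
             x = NA_real_, y = NA_real_, z = NA_real_,
             stringsAsFactors = FALSE)
}

#' Construct a connectome from a weight matrix
#'
#' Validates and wraps an N x N weight matrix as a `connectome` object.
#' Weights must lie in \[0, 1\] with a zero diagonal. Numerically
#' near-symmetric input (maximum asymmetry at most `1e-9`) is symmetrised by
#' averaging; larger asymmetry is an error — nothing is clamped silently.
#'
#' @param weights Square numeric matrix, entries in \[0, 1\], zero diagonal.
#' @param nodes Optional node metadata data frame with columns `index` and
#'   `label` (and optionally `x`, `y`, `z`); defaults to integer labels.
#' @return An object of class `connectome`: a list with `n_nodes`, `weights`
#'   and `nodes`.
#' @seealso [load_weights()], [synthetic_connectome()], [binarize()]
#' @export
connectome <- function(weights, nodes = NULL) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square numeric matrix")
  n <- nrow(weights)
  if (n < 2L) stop("a connectome needs at least 2 nodes")
  if (anyNA(weights)) stop("weights contain missing values")
  if (any(weights < 0) || any(weights > 1))
    stop("weights must lie in [0, 1]")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9)
    stop(sprintf("weight matrix is asymmetric (max |w - t(w)| = %g)", asym))
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0))
    stop("diagonal must be all zero (no self-connections)")
  if (is.null(nodes)) nodes <- default_nodes(n)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) != n)
    stop(sprintf("node table has %d rows but matrix has %d nodes",
                 nrow(nodes), n))
  if (!all(c("index", "label") %in% names(nodes)))
    stop("node table needs 'index' and 'label' columns")
  if (anyDuplicated(nodes$label))
    stop("node labels must be unique")
  if (!identical(as.integer(nodes$index), seq_len(n)))
    stop("node indices must be contiguous 1..N")
  dimnames(weights) <- NULL
  structure(list(n_nodes = n, weights = weights, nodes = nodes),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<connectome> %d nodes, mean weight %.3f (sd %.3f)\n",
              x$n_nodes, mean(w), stats::sd(w)))
  invisible(x)
}

#' Load a connectome weight matrix from delimited text
#'
#' Reads an N x N weight matrix (TSV/CSV, optional header, `#` comments
#' ignored) and optionally a node table, and returns a validated
#' [connectome]. The node table may be a BrainNet-Viewer style `.node` file
#' (whitespace-delimited columns `x y z color size label`) or any delimited
#' table with `index` and `label` columns.
#'
#' @param path Path to the weight-matrix file.
#' @param nodes Optional path to a node table.
#' @param sep Field separator for the matrix file; guessed from the file
#'   extension when `NULL` (`.csv` means comma, otherwise whitespace).
#' @return A `connectome` object.
#' @export
load_weights <- function(path, nodes = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else ""
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)][1]
  header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                       if (sep == "") "\\s+" else sep)[[1]][1])))
  m <- utils::read.table(path, sep = sep, header = header,
                         comment.char = "#", row.names = NULL)
  if (header || !is.numeric(as.matrix(m)[, 1])) {
    # tolerate a leading row-name column
    if (!is.numeric(m[[1]])) m[[1]] <- NULL
  }
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in '%s' is not square (%d x %d)", path,
                 nrow(m), ncol(m)))
  node_df <- if (!is.null(nodes)) read_node_table(nodes) else NULL
  connectome(m, nodes = node_df)
}

#' Read a node metadata table
#'
#' Accepts either a BrainNet-Viewer `.node` layout (six whitespace-delimited
#' columns `x y z color size label`, no header) or a delimited table with at
#' least `index` and `label` columns.
#'
#' @param path Path to the node file.
#' @return Data frame with columns `index`, `label`, `x`, `y`, `z`.
#' @export
read_node_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (is.character(tab[[1]]) && any(tab[[1]] %in% c("index", "label"))) {
    tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE)
  }
  if (all(c("index", "label") %in% names(tab))) {
    for (cc in c("x", "y", "z")) if (is.null(tab[[cc]])) tab[[cc]] <- NA_real_
    return(tab[, c("index", "label", "x", "y", "z")])
  }
  if (ncol(tab) == 6L) {
    return(data.frame(index = seq_len(nrow(tab)), label = as.character(tab[[6]]),
                      x = tab[[1]], y = tab[[2]], z = tab[[3]],
                      stringsAsFactors = FALSE))
  }
  stop("unrecognized node table layout: need .node columns or index/label")
}

#' Write a node table in BrainNet-Viewer .node layout
#'
#' @param nodes Node data frame (as from [brodmann_nodes()]).
#' @param path Output path.
#' @param color,size Constant color/size columns (BrainNet conventions).
#' @return `path`, invisibly.
#' @export
write_node_table <- function(nodes, path, color = 1, size = 1) {
  out <- data.frame(x = ifelse(is.na(nodes$x), 0, nodes$x),
                    y = ifelse(is.na(nodes$y), 0, nodes$y),
                    z = ifelse(is.na(nodes$z), 0, nodes$z),
                    color = color, size = size, label = nodes$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a weight or adjacency matrix as delimited text
#'
#' @param x A `connectome`, `binary_adjacency`, or plain matrix.
#' @param path Output path (tab-separated, no header).
#' @param comment Optional character vector written as `#`-prefixed header
#'   lines (used by the CLI to record parameters).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, comment = NULL) {
  m <- if (is.list(x)) x[["weights"]] %||% x[["matrix"]] else x
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap a 0/1 matrix as a binary adjacency
#'
#' Validates a hand-built binary matrix (symmetric, zero diagonal, entries
#' in \{0, 1\}) for direct use with the dynamics functions, bypassing the
#' weighted-connectome thresholding step.
#'
#' @param m Square 0/1 matrix.
#' @param provenance Optional record of how the matrix was obtained.
#' @return A `binary_adjacency` object.
#' @export
binary_adjacency <- function(m, provenance = list(kind = "manual")) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("adjacency must be square")
  if (!all(m %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (any(m != t(m))) stop("adjacency must be symmetric")
  if (any(diag(m) != 0)) stop("adjacency diagonal must be zero")
  new_binary_adjacency(m, provenance)
}

new_binary_adjacency <- function(m, provenance) {
  storage.mode(m) <- "integer"
  structure(list(n_nodes = nrow(m), matrix = m, provenance = provenance),
            class = "binary_adjacency")
}

#' @export
print.binary_adjacency <- function(x, ...) {
  cat(sprintf("<binary_adjacency> %d nodes, %d edges (%s)\n", x$n_nodes,
              sum(x$matrix[upper.tri(x$matrix)]),
              paste(names(x$provenance), unlist(x$provenance),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Binarize a connectome at a global weight threshold
#'
#' Converts the weighted matrix to a 0/1 adjacency: an edge is kept exactly
#' when its weight is strictly greater than the threshold `x` ("above the
#' threshold"); `w == x` yields no edge. Output is symmetric with zero
#' diagonal.
#'
#' @param c A [connectome].
#' @param x Threshold in \[0, 1\].
#' @return A `binary_adjacency` object recording the thresholding used.
#' @examples
#' cn <- synthetic_connectome(10, seed = 1)
#' adj <- binarize(cn, 0.9)
#' @export
binarize <- function(c, x) {
  stopifnot(inherits(c, "connectome"))
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 1)
    stop("threshold x must be a single value in [0, 1]")
  m <- (c$weights > x) * 1L
  diag(m) <- 0L
  new_binary_adjacency(m, list(kind = "global", x = x))
}

#' Binarize with a per-row threshold ramp
#'
#' Row `i` uses threshold `t_i = start + step * (i - 1)`, so thresholds
#' fluctuate across nodes (rows beyond `t_i > 1` keep no edges). The per-row
#' rule is asymmetric on an undirected graph, so edges are symmetrised:
#' under `combine = "and"` (default, conservative) edge (i, j) is kept iff
#' `w_ij` clears both row thresholds; under `"or"` it suffices to clear one.
#'
#' @param c A [connectome].
#' @param start Ramp starting threshold (default 0.8).
#' @param step Per-row increment (default 0.01); must be non-negative.
#' @param combine `"and"` or `"or"` symmetrisation of the row rule.
#' @return A `binary_adjacency`.
#' @export
ramp_binarize <- function(c, start = 0.8, step = 0.01,
                          combine = c("and", "or")) {
  stopifnot(inherits(c, "connectome"))
  combine <- match.arg(combine)
  if (start < 0 || start > 1) stop("ramp start must be in [0, 1]")
  if (step < 0) stop("ramp step must be non-negative")
  n <- c$n_nodes
  thr <- start + step * (seq_len(n) - 1)
  row_pass <- c$weights > matrix(thr, n, n) # entry ij: w_ij > t_i
  m <- if (combine == "and") (row_pass & t(row_pass)) * 1L
       else (row_pass | t(row_pass)) * 1L
  diag(m) <- 0L
  new_binary_adjacency(m, list(kind = "ramp", start = start, step = step,
                               combine = combine))
}

#' Synthesize a connectome with prescribed weight moments
#'
#' Samples a symmetric, zero-diagonal weight matrix whose off-diagonal
#' entries follow a moment-matched distribution on \[0, 1\]. The default is
#' a Beta(alpha, beta) law with alpha, beta solved from the target mean and
#' standard deviation (the human-connectome reference statistics: mean 0.51,
#' sd 0.288); a rejection-sampled truncated normal is available as an
#' alternative (its realised moments are slightly shrunk by truncation).
#'
#' @param n Number of nodes (at least 2).
#' @param mean,sd Target off-diagonal mean and standard deviation; must be
#'   admissible for a \[0, 1\]-supported law (`sd^2 < mean * (1 - mean)`).
#' @param seed Integer seed; same seed gives an identical matrix.
#' @param nodes Optional node metadata (see [connectome()]).
#' @param method `"beta"` (moment-matched, default) or `"truncnorm"`.
#' @return A [connectome].
#' @examples
#' cn <- synthetic_connectome(82, seed = 0)
#' mean(cn$weights[upper.tri(cn$weights)]) # close to 0.51
#' @export
synthetic_connectome <- function(n, mean = 0.51, sd = 0.288, seed = 0L,
                                 nodes = NULL, method = c("beta", "truncnorm")) {
  method <- match.arg(method)
  if (n < 2L) stop("n must be at least 2")
  if (mean <= 0 || mean >= 1) stop("mean must lie strictly inside (0, 1)")
  if (sd <= 0 || sd^2 >= mean * (1 - mean))
    stop("inadmissible (mean, sd): need sd^2 < mean * (1 - mean)")
  npair <- n * (n - 1L) / 2L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- switch(method,
    beta = {
      nu <- mean * (1 - mean) / sd^2 - 1
      stats::rbeta(npair, shape1 = mean * nu, shape2 = (1 - mean) * nu)
    },
    truncnorm = {
      out <- numeric(0)
      while (length(out) < npair) {
        cand <- stats::rnorm(2L * npair, mean, sd)
        out <- c(out, cand[cand >= 0 & cand <= 1])
      }
      out[seq_len(npair)]
    })
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- w
  m <- m + t(m)
  connectome(m, nodes = nodes)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
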