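# Reference fixtures: the 82-region Brodmann parcellation used throughout,
# the Action-Execution initial activation vector, and the ten-circuit
# reference configuration (a = 1, b = 4, x = 0.9, z = 0.87).

# 41 Brodmann areas present in the 82-node parcellation (no 12-16, 31, 33).
.brodmann_areas <- c(1:11, 17:30, 32, 34:48)

# Talairach coordinates (mm) for nodes 1-21; the remaining nodes carry NA.
.brodmann_coords21 <- matrix(c(
  -43.347, -33.267, 61.135,
   36.017,  34.877, 63.832,
  -46.592, -34.283, 48.439,
   43.042, -34.882, 49.442,
  -41.124, -26.628, 51.922,
   38.726, -26.779, 51.931,
  -27.911, -22.877, 60.537,
   26.884, -22.774, 60.284,
  -11.711, -50.335, 66.925,
   10.565, -50.376, 65.651,
  -28.722,  -3.387, 55.569,
   26.821,  -3.144, 55.585,
  -21.962, -64.890, 53.277,
   20.152, -64.938, 52.170,
  -18.278,  22.911, 55.919,
   16.811,  23.184, 56.088,
  -24.594,  37.320, 42.974,
   22.509,  37.266, 43.076,
  -16.038,  59.012,  9.959,
   13.505,  59.285, 10.292,
  -15.868,  41.999, -12.318
), ncol = 3, byrow = TRUE)

#' Brodmann 82-node parcellation table
#'
#' Node metadata for the 82-region connectome parcellation built on the
#' Brodmann atlas: 41 cortical areas, each split into left (`L`) and right
#' (`R`) hemisphere nodes. Odd node indices are left-hemisphere, even are
#' right; e.g. node 9 is `"5L"`, node 71 is `"43L"`. Talairach coordinates
#' (mm) are carried where published (nodes 1-21) and `NA` elsewhere.
#'
#' @return A data frame with columns `index` (1-82), `label` (e.g. `"42R"`),
#'   and `x`, `y`, `z` Talairach coordinates.
#' @examples
#' nodes <- brodmann_nodes()
#' nodes$label[c(4, 46, 71)] # "2R" "28R" "43L"
#' @export
brodmann_nodes <- function() {
  labels <- as.vector(rbind(paste0(.brodmann_areas, "L"),
                            paste0(.brodmann_areas, "R")))
  coords <- matrix(NA_real_, nrow = 82, ncol = 3)
  coords[seq_len(nrow(.brodmann_coords21)), ] <- .brodmann_coords21
  data.frame(index = 1:82, label = labels,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

#' Action-Execution initial activation state
#'
#' The published initial condition for the Action-Execution behavioural
#' domain: a binary vector over the 82 connectome nodes with exactly the 16
#' regions of the Action-Execution activation map switched on (primary
#' somatosensory and motor cortex, parietal and frontal areas, Broca's area,
#' among others).
#'
#' @return Integer 0/1 vector of length 82 (sums to 16).
#' @examples
#' s0 <- action_execution_state()
#' sum(s0) # 16
#' brodmann_nodes()$label[s0 == 1]
#' @export
action_execution_state <- function() {
  on <- c(2L, 4L, 8L, 9L, 10L, 15L, 19L, 21L, 28L, 35L, 39L, 41L,
          63L, 64L, 75L, 79L)
  s <- integer(82)
  s[on] <- 1L
  s
}

#' Ten-circuit reference configuration
#'
#' The reference circuit set extracted from the model run with activation
#' window a = 1, b = 4, connection threshold x = 0.9 and correlation
#' threshold z = 0.87: eight two-area circuits and two three-area circuits,
#' against which parameter-varied configurations are compared (see
#' [compare_to_reference()]).
#'
#' @return A [circuit_set] of 10 circuits with node members and Brodmann
#'   labels, ordered by size then member ids.
#' @examples
#' ref <- reference_circuits()
#' length(ref$circuits)       # 10
#' ref$circuits[[9]]$labels   # "5L" "32L" "43L"
#' @export
reference_circuits <- function() {
  members <- list(
    c(4L, 46L), c(9L, 71L), c(23L, 30L), c(33L, 45L), c(37L, 42L),
    c(37L, 55L), c(51L, 71L), c(70L, 76L), c(9L, 51L, 71L), c(37L, 42L, 55L)
  )
  labels <- brodmann_nodes()$label
  circuits <- lapply(members, function(m) {
    structure(list(members = m, labels = labels[m]), class = "circuit")
  })
  new_circuit_set(circuits, z = 0.87)
}

#' Bundle of reference fixtures
#'
#' Convenience accessor returning the three package fixtures at once: the
#' 82-node label table, the Action-Execution initial state and the
#' ten-circuit reference configuration. Repeated calls return identical
#' values.
#'
#' @return A list with elements `nodes`, `init`, `reference`.
#' @export
fixtures <- function() {
  list(nodes = brodmann_nodes(),
       init = action_execution_state(),
       reference = reference_circuits())
}
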