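#' Build a circular flower array
#'
#' Constructs the geometry of an open-field radial-arm maze: `n` artificial
#' flowers equally spaced on a circle in a vertical plane (x horizontal,
#' y vertical, centre at the origin). Flower 1 sits at the top of the circle
#' and ids increase clockwise, matching a labelled apparatus.
#'
#' @param n Number of flowers (default 8). Must be at least 3.
#' @param radius Circle radius in arbitrary length units. Must be positive.
#' @return An object of class `flower_array`: a list with `n_flowers`,
#'   `radius` and `positions` (an `n x 2` matrix of x/y coordinates, row `k`
#'   for flower `k`).
#' @examples
#' arr <- build_flower_array(8, 1)
#' arr$positions[1, ] # flower 1 at the top: (0, 1)
#' @export
build_flower_array <- function(n = 8, radius = 1) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 3)
    stop("invalid geometry: need at least 3 flowers", call. = FALSE)
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("invalid geometry: radius must be positive", call. = FALSE)
  n <- as.integer(n)
  # flower k at angle 90 deg - (k-1) * 360/n deg, CCW from +x axis
  theta <- (90 - (seq_len(n) - 1) * 360 / n) * pi / 180
  pos <- cbind(x = radius * cos(theta), y = radius * sin(theta))
  # snap values that are exact zeros in exact arithmetic
  pos[abs(pos) < 1e-12] <- 0
  rownames(pos) <- seq_len(n)
  structure(list(n_flowers = n, radius = radius, positions = pos),
            class = "flower_array")
}

#' @export
print.flower_array <- function(x, ...) {
  cat("Flower array:", x$n_flowers, "flowers on a circle of radius",
      x$radius, "(flower 1 at top, ids clockwise)\n")
  invisible(x)
}

#' Angle of a travel vector from the vertical
#'
#' Angle in degrees between the directed travel vector `to - from` and the
#' upward unit vector: 0 is straight up, 90 horizontal, 180 straight down.
#' With `directed = FALSE` the angle is folded into \[0, 90\], ignoring
#' whether the move was upward or downward.
#'
#' @param from,to Length-2 numeric xy coordinates.
#' @param directed Keep the up/down distinction (default `TRUE`)?
#' @return Angle in degrees.
#' @export
travel_angle_from_vertical <- function(from, to, directed = TRUE) {
  v <- as.numeric(to) - as.numeric(from)
  len <- sqrt(sum(v^2))
  if (len == 0)
    stop("undefined direction: identical points", call. = FALSE)
  ang <- acos(pmin(1, pmax(-1, v[2] / len))) * 180 / pi
  if (!directed && ang > 90) ang <- 180 - ang
  ang
}

#' Directed neighbour pairs of a flower array
#'
#' All `2n` directed pairs of angularly adjacent flowers (each flower to its
#' clockwise and counter-clockwise neighbour).
#'
#' @param array A [build_flower_array()] object.
#' @return A two-column integer matrix with columns `from` and `to`.
#' @export
neighbor_pairs <- function(array) {
  stopifnot(inherits(array, "flower_array"))
  n <- array$n_flowers
  i <- seq_len(n)
  nxt <- i %% n + 1L
  prv <- (i - 2L) %% n + 1L
  cbind(from = c(i, i), to = c(nxt, prv))
}

#' Construct a visit-sequence record
#'
#' The atomic behavioural record: one bee's ordered flower choices in one
#' foraging bout. A bout is "complete" when every flower of the array was
#' visited at least once.
#'
#' @param choices Integer vector of 1-based flower ids in visit order.
#' @param bee_id,colony_id Identifiers.
#' @param bout_index 1-based bout number.
#' @param phase `"training"` or `"test"`.
#' @param duration_s Bout duration in seconds (optional).
#' @param n_flowers Number of flowers in the array (default 8).
#' @return An object of class `visit_sequence`.
#' @export
visit_sequence <- function(choices, bee_id = NA, colony_id = NA,
                           bout_index = 1L, phase = c("training", "test"),
                           duration_s = NA_real_, n_flowers = 8L) {
  phase <- match.arg(phase)
  choices <- as.integer(choices)
  if (length(choices) == 0)
    stop("malformed record: empty choice sequence", call. = FALSE)
  bad <- which(is.na(choices) | choices < 1L | choices > n_flowers)
  if (length(bad))
    stop(sprintf("malformed record: invalid flower id at visit %d", bad[1]),
         call. = FALSE)
  if (!is.na(duration_s) && duration_s < 0)
    stop("malformed record: negative duration", call. = FALSE)
  structure(list(bee_id = bee_id, colony_id = colony_id,
                 bout_index = as.integer(bout_index), phase = phase,
                 choices = choices, duration_s = as.numeric(duration_s),
                 n_flowers = as.integer(n_flowers),
                 complete = length(unique(choices)) == n_flowers),
            class = "visit_sequence")
}

#' @export
print.visit_sequence <- function(x, ...) {
  cat(sprintf("Visit sequence: bee %s, bout %d (%s), %d visits%s\n",
              x$bee_id, x$bout_index, x$phase, length(x$choices),
              if (x$complete) ", complete" else ""))
  cat(" choices:", paste(x$choices, collapse = " "), "\n")
  invisible(x)
}

#' Validate a visit sequence against an array
#'
#' Checks that every choice is a valid flower id for the array and refreshes
#' the completeness flag.
#'
#' @param seq A [visit_sequence()].
#' @param array A [build_flower_array()] object.
#' @return The validated `visit_sequence` (invisibly identical content).
#' @export
validate_sequence <- function(seq, array) {
  stopifnot(inherits(seq, "visit_sequence"), inherits(array, "flower_array"))
  bad <- which(seq$choices < 1L | seq$choices > array$n_flowers)
  if (length(bad))
    stop(sprintf("malformed record: invalid flower id at visit %d", bad[1]),
         call. = FALSE)
  seq$n_flowers <- array$n_flowers
  seq$complete <- length(unique(seq$choices)) == array$n_flowers
  seq
}

# internal: accept a visit_sequence or a bare integer vector of choices
as_choices <- function(seq) {
  if (inherits(seq, "visit_sequence")) seq$choices else as.integer(seq)
}
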