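#' Spearman rank correlation (mid-ranks)
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Errors on
#' constant input, where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  cor(rx, ry)
}

#' Contiguity preference
#'
#' Proportion of all observed transitions that land on an angularly adjacent
#' flower ("contiguity preference" — the tendency to travel to the nearest
#' neighbouring flower), together with its expectation under the chance
#' model: 2/n when self-transitions are allowed, 2/(n-1) when excluded.
#'
#' @param counts `n x n` matrix of directed transition counts (from row to
#'   column), e.g. `attr(estimate_transition_matrix(...), "counts")`.
#' @param array A [build_flower_array()] object.
#' @param exclude_self Chance expectation without self-transitions.
#' @return A list: `observed_proportion`, `expected_chance`, `n_transitions`.
#' @export
contiguity_preference <- function(counts, array, exclude_self = FALSE) {
  stopifnot(inherits(array, "flower_array"))
  counts <- as.matrix(counts)
  total <- sum(counts)
  if (total == 0) stop("no data: empty transition counts", call. = FALSE)
  np <- neighbor_pairs(array)
  adj <- sum(counts[np])
  n <- array$n_flowers
  list(observed_proportion = adj / total,
       expected_chance = if (exclude_self) 2 / (n - 1) else 2 / n,
       n_transitions = total)
}

#' Vertical bias in neighbour-to-neighbour transitions
#'
#' Tests whether movement between adjacent flowers is biased towards flying
#' upwards: for each directed neighbour pair, the observed transition
#' frequency is paired with the travel angle from vertical of that move, and
#' the two are rank-correlated. A strongly negative rho means near-vertical
#' upward moves are over-represented.
#'
#' @param counts `n x n` directed transition count matrix.
#' @param array A [build_flower_array()] object.
#' @param directed Use the 2n directed pairs with angles in \[0, 180\]
#'   (default); otherwise the n undirected pairs, summing both directions
#'   and folding angles into \[0, 90\].
#' @param conditional Normalise each pair's count by its source flower's
#'   outgoing total instead of by all transitions.
#' @return An object of class `vertical_bias`: list with `pairs` (data frame
#'   `from`, `to`, `count`, `frequency`, `angle_deg`), `rho` (`NA` with a
#'   warning when frequencies are constant) and `n_pairs`.
#' @export
vertical_bias <- function(counts, array, directed = TRUE,
                          conditional = FALSE) {
  stopifnot(inherits(array, "flower_array"))
  counts <- as.matrix(counts)
  np <- neighbor_pairs(array)
  pos <- array$positions
  ang <- vapply(seq_len(nrow(np)), function(k)
    travel_angle_from_vertical(pos[np[k, 1], ], pos[np[k, 2], ],
                               directed = directed),
    numeric(1))
  # snap to 1e-9 degrees so geometrically equal chords tie exactly in ranks
  ang <- round(ang, 9)
  cnt <- counts[np]
  tab <- data.frame(from = np[, 1], to = np[, 2], count = cnt,
                    angle_deg = ang)
  if (!directed) {
    key <- paste(pmin(tab$from, tab$to), pmax(tab$from, tab$to))
    tab <- do.call(rbind, lapply(split(tab, key), function(d)
      data.frame(from = min(d$from[1], d$to[1]),
                 to = max(d$from[1], d$to[1]),
                 count = sum(d$count), angle_deg = d$angle_deg[1])))
    rownames(tab) <- NULL
  }
  denom <- if (conditional) rowSums(counts)[tab$from]
           else rep(sum(counts), nrow(tab))
  tab$frequency <- ifelse(denom > 0, tab$count / denom, 0)
  tab <- tab[, c("from", "to", "count", "frequency", "angle_deg")]
  rho <- if (sd(tab$frequency) == 0) {
    warning("transition frequencies are constant; rho undefined")
    NA_real_
  } else spearman_rho(tab$frequency, tab$angle_deg)
  structure(list(pairs = tab, rho = rho, n_pairs = nrow(tab)),
            class = "vertical_bias")
}

#' @export
print.vertical_bias <- function(x, ...) {
  cat(sprintf("Vertical bias over %d neighbour pairs: Spearman rho = %s\n",
              x$n_pairs,
              if (is.na(x$rho)) "NA" else format(round(x$rho, 3))))
  invisible(x)
}
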