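#' Total revisits in a bout
#'
#' Number of visits to flowers already visited earlier in the same bout —
#' the count of spatial working-memory errors.
#'
#' @param seq A [visit_sequence()] or an integer vector of flower choices.
#' @return Non-negative integer.
#' @examples
#' total_revisits(c(1, 2, 3, 2, 4, 5, 6, 1, 7, 8)) # 2
#' @export
total_revisits <- function(seq) {
  ch <- as_choices(seq)
  length(ch) - length(unique(ch))
}

#' Correct choices before the first revisit
#'
#' Length of the initial run of novel-flower visits; equals the number of
#' visits when the bout contains no revisit (at most 8 in a complete
#' error-free bout).
#'
#' @inheritParams total_revisits
#' @return Integer at least 1.
#' @export
correct_before_first_revisit <- function(seq) {
  ch <- as_choices(seq)
  dup <- duplicated(ch)
  if (!any(dup)) length(ch) else which(dup)[1] - 1L
}

#' Correct choices in the first eight visits
#'
#' Number of the first eight visits that landed on a flower not previously
#' visited within the bout. Undefined (returned as `NA`) for bouts shorter
#' than eight visits; downstream models treat such records as missing.
#'
#' @inheritParams total_revisits
#' @return Integer in 0..8, or `NA_integer_`.
#' @export
correct_in_first_eight <- function(seq) {
  ch <- as_choices(seq)
  if (length(ch) < 8L) return(NA_integer_)
  sum(!duplicated(ch)[1:8])
}

#' Per-choice success indicators for the first eight visits
#'
#' Expands a bout into eight binary outcomes (1 = novel flower, 0 = revisit),
#' the response used by the binomial mixed model. `NA` (length 8) when the
#' bout has fewer than eight visits.
#'
#' @inheritParams total_revisits
#' @return Integer vector of length 8 (or all-`NA`).
#' @export
binary_choice_expansion <- function(seq) {
  ch <- as_choices(seq)
  if (length(ch) < 8L) return(rep(NA_integer_, 8L))
  as.integer(!duplicated(ch)[1:8])
}

#' Time per visit
#'
#' Bout duration divided by the number of visits; the statistical stage
#' models its natural log. Returns `NA` when the duration is missing or
#' non-positive (undefined metric, recorded as missing). A
#' `per_revisit = TRUE` switch divides by total revisits instead (undefined,
#' `NA`, at zero revisits).
#'
#' @param seq A [visit_sequence()] with `duration_s` set, or a bare choice
#'   vector together with `duration_s`.
#' @param duration_s Duration in seconds; taken from `seq` when omitted.
#' @param per_revisit Divide by total revisits instead of total visits.
#' @return Seconds per visit, or `NA_real_`.
#' @export
time_per_visit <- function(seq, duration_s = NULL, per_revisit = FALSE) {
  ch <- as_choices(seq)
  if (is.null(duration_s))
    duration_s <- if (inherits(seq, "visit_sequence")) seq$duration_s else NA_real_
  if (is.na(duration_s) || duration_s <= 0) return(NA_real_)
  denom <- if (per_revisit) total_revisits(ch) else length(ch)
  if (denom == 0) return(NA_real_)
  duration_s / denom
}

#' First-revisit survival record
#'
#' Encodes a bout for the survival analysis of the choice at which the first
#' revisit occurred. The event time is the index of the first erroneous
#' choice (so `time = correct_before_first_revisit + 1`); bouts with no
#' revisit are right-censored at choice 8.
#'
#' @inheritParams total_revisits
#' @return A list with `time` (integer in 2..8) and `event` (logical).
#' @export
first_revisit_survival <- function(seq) {
  ch <- as_choices(seq)
  dup <- duplicated(ch)
  if (any(dup)) {
    list(time = as.integer(which(dup)[1]), event = TRUE)
  } else {
    list(time = 8L, event = FALSE)
  }
}

#' All RAM performance statistics for one bout
#'
#' @inheritParams time_per_visit
#' @return A one-row data frame with `n_visits`, `complete`,
#'   `total_revisits`, `correct_before_first_revisit`,
#'   `correct_in_first_eight`, `time_per_visit_s`, `survival_time`,
#'   `survival_event`.
#' @export
bout_metrics <- function(seq, duration_s = NULL) {
  ch <- as_choices(seq)
  nfl <- if (inherits(seq, "visit_sequence")) seq$n_flowers else 8L
  surv <- first_revisit_survival(ch)
  data.frame(
    n_visits = length(ch),
    complete = length(unique(ch)) == nfl,
    total_revisits = total_revisits(ch),
    correct_before_first_revisit = correct_before_first_revisit(ch),
    correct_in_first_eight = correct_in_first_eight(ch),
    time_per_visit_s = time_per_visit(seq, duration_s),
    survival_time = surv$time,
    survival_event = surv$event
  )
}

#' Per-bout metrics table from long-format visit and bout tables
#'
#' Collapses a long visit table (one row per visit) into one row of RAM
#' statistics per bee and bout, joining bout durations where available.
#'
#' @param visits Data frame with columns `bee_id`, `colony_id`, `bout_index`,
#'   `phase`, `visit_index`, `flower_id`.
#' @param bouts Optional data frame with `bee_id`, `bout_index`, `phase`,
#'   `duration_s`.
#' @param n_flowers Flowers in the array (default 8).
#' @return Data frame, one row per (bee, bout), with identifiers, phase and
#'   all [bout_metrics()] columns.
#' @export
metrics_table <- function(visits, bouts = NULL, n_flowers = 8L) {
  stopifnot(all(c("bee_id", "bout_index", "flower_id", "visit_index")
                %in% names(visits)))
  visits <- visits[order(visits$bee_id, visits$bout_index, visits$visit_index), ]
  key <- interaction(visits$bee_id, visits$bout_index, drop = TRUE)
  rows <- lapply(split(visits, key), function(d) {
    m <- bout_metrics(visit_sequence(
      d$flower_id, bee_id = d$bee_id[1],
      colony_id = if ("colony_id" %in% names(d)) d$colony_id[1] else NA,
      bout_index = d$bout_index[1],
      phase = if ("phase" %in% names(d)) as.character(d$phase[1]) else "training",
      n_flowers = n_flowers))
    cbind(data.frame(bee_id = d$bee_id[1],
                     colony_id = if ("colony_id" %in% names(d)) d$colony_id[1] else NA,
                     bout_index = d$bout_index[1],
                     phase = if ("phase" %in% names(d)) as.character(d$phase[1]) else "training"),
          m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(bouts) && "duration_s" %in% names(bouts)) {
    idx <- match(paste(out$bee_id, out$bout_index),
                 paste(bouts$bee_id, bouts$bout_index))
    dur <- bouts$duration_s[idx]
    out$time_per_visit_s <- ifelse(!is.na(dur) & dur > 0,
                                   dur / out$n_visits, NA_real_)
  }
  out[order(out$bee_id, out$bout_index), , drop = FALSE]
}
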