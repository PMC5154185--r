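#' Transition matrix for flower-to-flower movement
#'
#' A row-stochastic matrix `P` (row i = distribution of the next flower given
#' the bee is on flower i) together with a first-choice distribution over
#' flowers; the parameterisation of the stereotyped-movement null model.
#'
#' @param P `n x n` matrix of probabilities with rows summing to 1.
#' @param first Probability vector of length `n` for the first choice of a
#'   bout; defaults to uniform.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(P, first = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (ncol(P) != n) stop("transition matrix must be square", call. = FALSE)
  if (is.null(first)) first <- rep(1 / n, n)
  if (length(first) != n)
    stop("first-choice vector length must match matrix", call. = FALSE)
  if (any(P < 0) || any(first < 0))
    stop("probabilities must be non-negative", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  if (abs(sum(first) - 1) > 1e-12)
    stop("first-choice probabilities must sum to 1", call. = FALSE)
  structure(list(P = unname(P), first = unname(as.numeric(first)),
                 n_flowers = n),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix over", x$n_flowers, "flowers\n")
  cat(" first-choice:", signif(x$first, 3), "\n")
  print(signif(x$P, 3))
  invisible(x)
}

#' Agent policies for simulated maze bouts
#'
#' Three movement policies for a simulated bee on the maze:
#'
#' * **chance** — every choice (including the first) is uniform over all
#'   flowers; with `exclude_current = TRUE` the current flower is excluded
#'   (uniform over the other `n - 1`).
#' * **stereotyped** — the first choice follows the matrix's first-choice
#'   distribution, every later choice the transition-matrix row of the
#'   current flower; visited status never influences the choice.
#' * **memory** — with probability `m` the choice is drawn from the base
#'   policy's distribution renormalised over *unvisited* flowers (perfect
#'   working-memory avoidance), otherwise from the unmodified base
#'   distribution. `m = 0` is the base policy; `m = 1` never revisits.
#'
#' @param n_flowers Number of flowers (default 8).
#' @param exclude_current For the chance policy, forbid self-transitions.
#' @param matrix A [transition_matrix()].
#' @param m Working-memory strength in \[0, 1\].
#' @param base Base policy for the memory mixture (default chance).
#' @return An object of class `agent_policy`.
#' @name agent_policy
NULL

#' @rdname agent_policy
#' @export
chance_policy <- function(n_flowers = 8L, exclude_current = FALSE) {
  n <- as.integer(n_flowers)
  P <- if (exclude_current) {
    M <- matrix(1 / (n - 1), n, n); diag(M) <- 0; M
  } else matrix(1 / n, n, n)
  structure(list(kind = "chance", first = rep(1 / n, n), P = P,
                 m = 0, n_flowers = n),
            class = "agent_policy")
}

#' @rdname agent_policy
#' @export
stereotyped_policy <- function(matrix) {
  if (!inherits(matrix, "transition_matrix"))
    stop("misconfiguration: stereotyped policy requires a transition_matrix",
         call. = FALSE)
  structure(list(kind = "stereotyped", first = matrix$first, P = matrix$P,
                 m = 0, n_flowers = matrix$n_flowers),
            class = "agent_policy")
}

#' @rdname agent_policy
#' @export
memory_policy <- function(m, base = chance_policy()) {
  if (!is.numeric(m) || length(m) != 1 || m < 0 || m > 1)
    stop("memory strength m must be in [0, 1]", call. = FALSE)
  stopifnot(inherits(base, "agent_policy"))
  structure(list(kind = "memory", first = base$first, P = base$P,
                 m = m, n_flowers = base$n_flowers),
            class = "agent_policy")
}

#' @export
print.agent_policy <- function(x, ...) {
  cat("Agent policy:", x$kind,
      if (x$kind == "memory") sprintf("(m = %g)", x$m) else "", "\n")
  invisible(x)
}

#' Draw the next flower choice under a policy
#'
#' Single-step reference implementation of the policy semantics (the bulk
#' simulation engine uses a compiled equivalent).
#'
#' @param policy An [agent_policy].
#' @param current Current flower id, or `NULL` before the first choice.
#' @param visited Integer vector of already-visited flower ids.
#' @return A flower id.
#' @export
next_choice <- function(policy, current = NULL, visited = integer()) {
  stopifnot(inherits(policy, "agent_policy"))
  n <- policy$n_flowers
  base <- if (is.null(current)) policy$first else policy$P[current, ]
  if (policy$m > 0 && runif(1) < policy$m) {
    w <- base
    w[visited] <- 0
    if (sum(w) <= 0) { w <- rep(1, n); w[visited] <- 0 }
    sample.int(n, 1L, prob = w)
  } else {
    sample.int(n, 1L, prob = base)
  }
}

#' Simulate one foraging bout
#'
#' Generates choices until every flower has been visited or a hard cap is
#' reached (cap-hit bouts are flagged incomplete, with a warning).
#'
#' @param policy An [agent_policy].
#' @param max_visits Hard cap on visits (default 10000), guaranteeing
#'   termination for pathological transition matrices.
#' @param ... Passed to [visit_sequence()] (identifiers, phase).
#' @return A [visit_sequence()].
#' @export
simulate_bout <- function(policy, max_visits = 10000L, ...) {
  stopifnot(inherits(policy, "agent_policy"))
  seqs <- sim_bouts_seq_cpp(1L, policy$first, policy$P, policy$m,
                            as.integer(max_visits), 0)
  out <- visit_sequence(seqs[[1]], n_flowers = policy$n_flowers, ...)
  if (!out$complete)
    warning("bout hit the visit cap before covering all flowers")
  out
}

#' Monte Carlo null distribution of RAM metrics under a policy
#'
#' Simulates `n_iterations` independent bouts under `policy` and summarises
#' the per-bout RAM statistics: mean, standard deviation and Monte Carlo
#' standard error (sd / sqrt(n)) for each requested metric.
#'
#' @param policy An [agent_policy].
#' @param metrics Character vector among `"total_revisits"`,
#'   `"correct_before_first_revisit"`, `"correct_in_first_eight"`,
#'   `"n_visits"`.
#' @param n_iterations Number of simulated bouts.
#' @param seed Optional integer seed (recorded in the result).
#' @param max_visits Per-bout visit cap.
#' @param keep_values Keep the per-iteration values (memory permitting)?
#' @return An object of class `null_distribution`: list with `summary`
#'   (one row per metric: `metric`, `mean`, `sd`, `mc_se`, `n_iterations`),
#'   `policy_kind`, `seed`, and optionally `values`.
#' @export
monte_carlo_null <- function(policy,
                             metrics = c("total_revisits",
                                         "correct_before_first_revisit",
                                         "correct_in_first_eight"),
                             n_iterations = 1e6, seed = NULL,
                             max_visits = 10000L, keep_values = FALSE) {
  stopifnot(inherits(policy, "agent_policy"), n_iterations >= 1)
  metrics <- match.arg(metrics, several.ok = TRUE,
                       choices = c("total_revisits",
                                   "correct_before_first_revisit",
                                   "correct_in_first_eight", "n_visits"))
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_bouts_metrics_cpp(as.integer(n_iterations), policy$first,
                               policy$P, policy$m, as.integer(max_visits))
  colnames(sim) <- c("n_visits", "total_revisits",
                     "correct_before_first_revisit",
                     "correct_in_first_eight", "complete")
  summ <- do.call(rbind, lapply(metrics, function(mt) {
    v <- sim[, mt]
    v <- v[!is.na(v)]
    data.frame(metric = mt, mean = mean(v), sd = sd(v),
               mc_se = sd(v) / sqrt(length(v)),
               n_iterations = length(v))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, policy_kind = policy$kind, seed = seed,
                 values = if (keep_values) sim[, metrics, drop = FALSE]),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Monte Carlo null (%s policy, %s iterations)\n",
              x$policy_kind, format(max(x$summary$n_iterations),
                                    big.mark = ",")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# internal: pooled directed transition and first-choice counts
count_transitions <- function(bouts, n_flowers = 8L) {
  chs <- lapply(bouts, as_choices)
  firsts <- vapply(chs, `[`, 0L, 1L)
  from <- unlist(lapply(chs, function(ch) ch[-length(ch)]), use.names = FALSE)
  to <- unlist(lapply(chs, function(ch) ch[-1]), use.names = FALSE)
  lv <- seq_len(n_flowers)
  counts <- unname(unclass(table(factor(from, lv), factor(to, lv))))
  first <- as.numeric(unname(unclass(table(factor(firsts, lv)))))
  list(counts = counts, first = first)
}

#' Estimate an empirical transition matrix from observed bouts
#'
#' Pools directed flower-to-flower transition counts over consecutive visit
#' pairs across all supplied bouts (plus pooled first-choice counts) and
#' normalises each row after adding `pseudocount` to every cell. Rows with
#' no observations and zero pseudocount fall back to uniform with a warning.
#'
#' @param bouts A list of [visit_sequence()] objects (or bare choice
#'   vectors), or a long visit data frame as in [metrics_table()].
#' @param pseudocount Non-negative smoothing constant added to every cell.
#' @param n_flowers Number of flowers.
#' @return A [transition_matrix()] with attribute `"counts"` (raw counts)
#'   and `"first_counts"`.
#' @export
estimate_transition_matrix <- function(bouts, pseudocount = 0,
                                       n_flowers = 8L) {
  if (is.data.frame(bouts)) {
    bouts <- bouts[order(bouts$bee_id, bouts$bout_index, bouts$visit_index), ]
    key <- interaction(bouts$bee_id, bouts$bout_index, drop = TRUE)
    bouts <- lapply(split(bouts$flower_id, key), as.integer)
  }
  if (length(bouts) == 0)
    stop("no data: at least one bout is required", call. = FALSE)
  cc <- count_transitions(bouts, n_flowers)
  if (sum(cc$counts) == 0 && pseudocount == 0)
    stop("no data: no transitions observed", call. = FALSE)
  P <- cc$counts + pseudocount
  zero <- rowSums(P) == 0
  if (any(zero)) {
    warning(sprintf("%d transition row(s) unobserved; falling back to uniform",
                    sum(zero)))
    P[zero, ] <- 1
  }
  P <- P / rowSums(P)
  fw <- cc$first + pseudocount
  if (sum(fw) == 0) fw <- rep(1, n_flowers)
  tm <- transition_matrix(P, fw / sum(fw))
  attr(tm, "counts") <- cc$counts
  attr(tm, "first_counts") <- cc$first
  tm
}

#' Compare observed metric values to a Monte Carlo null
#'
#' Computes the observed mean with a two-sided confidence interval
#' (Student-t on `n - 1` df by default, or a percentile bootstrap) and
#' reports whether the simulated null mean falls inside it, and in which
#' direction the observed bees deviate. Metric polarity is respected: fewer
#' revisits is better, more correct choices is better.
#'
#' @param observed Numeric vector of per-bee observed metric values
#'   (length at least 2).
#' @param null A [monte_carlo_null()] result (or its summary row).
#' @param metric Metric name; needed when `null` covers several metrics.
#' @param level Confidence level (default 0.95).
#' @param type `"t"` (default) or `"bootstrap"` percentile interval.
#' @param n_boot Bootstrap resamples when `type = "bootstrap"`.
#' @return One-row data frame: `metric`, `n_obs`, `observed_mean`,
#'   `ci_lower`, `ci_upper`, `null_mean`, `null_inside`, `direction`
#'   (`"better"`, `"worse"` or `"indistinguishable"`).
#' @export
compare_to_null <- function(observed, null, metric = NULL, level = 0.95,
                            type = c("t", "bootstrap"), n_boot = 10000L) {
  type <- match.arg(type)
  observed <- observed[!is.na(observed)]
  if (length(observed) < 2)
    stop("insufficient data: need at least 2 observed values", call. = FALSE)
  if (inherits(null, "null_distribution")) {
    summ <- null$summary
    if (is.null(metric)) {
      if (nrow(summ) > 1)
        stop("specify `metric`: null covers several metrics", call. = FALSE)
      metric <- summ$metric[1]
    }
    row <- summ[summ$metric == metric, ]
    if (nrow(row) != 1) stop("metric not found in null", call. = FALSE)
    null_mean <- row$mean
  } else {
    null_mean <- as.numeric(null)
    if (is.null(metric)) metric <- NA_character_
  }
  n <- length(observed)
  mu <- mean(observed)
  if (type == "t") {
    se <- sd(observed) / sqrt(n)
    tq <- qt(1 - (1 - level) / 2, df = n - 1)
    ci <- c(mu - tq * se, mu + tq * se)
  } else {
    bm <- replicate(n_boot, mean(sample(observed, n, replace = TRUE)))
    ci <- unname(quantile(bm, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  inside <- null_mean >= ci[1] && null_mean <= ci[2]
  lower_is_better <- identical(metric, "total_revisits")
  direction <- if (inside) "indistinguishable"
    else if ((mu < null_mean) == lower_is_better) "better" else "worse"
  data.frame(metric = metric, n_obs = n, observed_mean = mu,
             ci_lower = ci[1], ci_upper = ci[2], null_mean = null_mean,
             null_inside = inside, direction = direction)
}
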