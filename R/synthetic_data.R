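#' Configuration of a synthetic RAM dose-response experiment
#'
#' Defaults mirror the design of the motivating assay: 7 colonies, 61 bees
#' in four acute thiamethoxam dose groups (0 / 0.091 / 0.377 / 2.5 ng per
#' bee, n = 16/14/16/15), thorax widths from a truncated normal spanning
#' roughly 4.5-6.1 mm, ten training bouts approaching asymptotic
#' performance, and one post-exposure test bout whose working-memory
#' strength is degraded as a function of dose and body size.
#'
#' The training trajectory is exponential-saturating,
#' `m(bout) = m_max * (1 - exp(-bout / tau))`, with a colony random
#' intercept added on the logit scale. Exposure lowers the logit of memory
#' strength by `gamma * log1p(dose) * (1 + delta * (size - thorax_mean))`
#' (see [post_exposure_memory()]). The defaults `gamma = 1.4`,
#' `delta = 0.5` calibrate the high-dose group to roughly 3-5 times the
#' control group's expected revisits, with larger bees hit harder.
#' Per-visit times are log-normal with a negative body-size slope
#' (`beta_size = -0.335`: bigger bees move faster).
#'
#' @param n_colonies Number of source colonies.
#' @param group_sizes Named integer vector of bees per treatment, in order
#'   control, ld091, ld377, high.
#' @param doses_ng Doses (ng/bee) matching `group_sizes`.
#' @param thorax_mean,thorax_sd,thorax_bounds Truncated-normal thorax-width
#'   distribution (mm).
#' @param n_training Training bouts before exposure.
#' @param m_max,tau Asymptote and time constant of the training trajectory.
#' @param colony_sd SD of the colony intercept on the logit-memory scale.
#' @param gamma Per-unit log-dose impairment of logit memory strength.
#' @param delta Size interaction slope (per mm above `thorax_mean`).
#' @param time_mu0 Mean log seconds per visit at the mean thorax width.
#' @param time_beta_size Log-time slope per mm of thorax width.
#' @param time_sd Residual SD of log per-visit time.
#' @param quit_hazard Per-visit probability of abandoning the bout early
#'   (default 0; > 0 produces incomplete bouts).
#' @param n_flowers Flowers on the maze.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_colonies = 7L,
                              group_sizes = c(control = 16L, ld091 = 14L,
                                              ld377 = 16L, high = 15L),
                              doses_ng = c(control = 0, ld091 = 0.091,
                                           ld377 = 0.377, high = 2.5),
                              thorax_mean = 5.45, thorax_sd = 0.35,
                              thorax_bounds = c(4.4, 6.2),
                              n_training = 10L,
                              m_max = 0.85, tau = 3,
                              colony_sd = 0.3,
                              gamma = 1.4, delta = 0.5,
                              time_mu0 = log(25), time_beta_size = -0.335,
                              time_sd = 0.3,
                              quit_hazard = 0,
                              n_flowers = 8L) {
  if (!setequal(names(group_sizes), names(doses_ng)))
    stop("config error: group_sizes and doses_ng must share names",
         call. = FALSE)
  if (any(group_sizes < 0) || sum(group_sizes) < 1)
    stop("config error: invalid group sizes", call. = FALSE)
  if (thorax_sd < 0 || colony_sd < 0 || time_sd < 0)
    stop("config error: standard deviations must be >= 0", call. = FALSE)
  if (m_max <= 0 || m_max > 1)
    stop("config error: m_max must be in (0, 1]", call. = FALSE)
  if (quit_hazard < 0 || quit_hazard >= 1)
    stop("config error: quit_hazard must be in [0, 1)", call. = FALSE)
  structure(list(n_colonies = as.integer(n_colonies),
                 group_sizes = group_sizes, doses_ng = doses_ng,
                 thorax_mean = thorax_mean, thorax_sd = thorax_sd,
                 thorax_bounds = thorax_bounds,
                 n_training = as.integer(n_training),
                 m_max = m_max, tau = tau, colony_sd = colony_sd,
                 gamma = gamma, delta = delta,
                 time_mu0 = time_mu0, time_beta_size = time_beta_size,
                 time_sd = time_sd, quit_hazard = quit_hazard,
                 n_flowers = as.integer(n_flowers)),
            class = "experiment_config")
}

# internal: truncated-normal draws by rejection
rtruncnorm <- function(n, mean, sd, bounds) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  out[seq_len(n)]
}

# internal: polynomial rolling hash of a config, for provenance records
config_hash <- function(config) {
  s <- paste(names(unlist(config)), unlist(config), collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Generate the bee table of a synthetic experiment
#'
#' Bees are assigned to colonies round-robin, treatments are allocated at
#' random respecting the exact group sizes, and thorax widths are drawn
#' from the configured truncated normal.
#'
#' @param config An [experiment_config()].
#' @return Data frame: `bee_id`, `colony_id`, `thorax_width_mm`,
#'   `treatment`, `dose_ng`.
#' @export
generate_bees <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  n <- sum(config$group_sizes)
  treatments <- sample(rep(names(config$group_sizes), config$group_sizes))
  data.frame(
    bee_id = sprintf("bee%03d", seq_len(n)),
    colony_id = sprintf("colony%d", (seq_len(n) - 1L) %% config$n_colonies + 1L),
    thorax_width_mm = rtruncnorm(n, config$thorax_mean, config$thorax_sd,
                                 config$thorax_bounds),
    treatment = factor(treatments, levels = names(config$group_sizes)),
    dose_ng = unname(config$doses_ng[treatments])
  )
}

#' Post-exposure working-memory strength
#'
#' Dose-response model of acute pesticide impairment on the logit scale:
#' `logit(m_test) = logit(m_train) - gamma * log1p(dose) *
#' (1 + delta * (size - thorax_mean))`. A zero dose returns `m_train`
#' exactly; with `delta > 0` larger bees are more strongly impaired at any
#' positive dose.
#'
#' @param m_train Pre-exposure memory strength in (0, 1).
#' @param dose_ng Acute dose in ng per bee.
#' @param size_mm Thorax width in mm.
#' @param config An [experiment_config()] supplying `gamma`, `delta` and
#'   `thorax_mean`.
#' @return Memory strength in (0, 1).
#' @export
post_exposure_memory <- function(m_train, dose_ng, size_mm,
                                 config = experiment_config()) {
  stopifnot(all(m_train > 0), all(m_train < 1))
  if (all(dose_ng == 0)) return(m_train)
  drop <- config$gamma * log1p(dose_ng) *
    (1 + config$delta * (size_mm - config$thorax_mean))
  ifelse(dose_ng == 0, m_train, plogis(qlogis(m_train) - drop))
}

#' Generate a complete synthetic RAM experiment
#'
#' For each bee: ten training bouts simulated under the memory policy at
#' strength `m(bout) = m_max * (1 - exp(-bout/tau))` (colony intercept on
#' the logit scale), then one post-exposure test bout at
#' [post_exposure_memory()] applied to the bee's asymptotic strength.
#' Bout durations are `n_visits * exp(draw)` with per-visit log-time
#' normal in thorax width.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return An object of class `ram_experiment`: list with data frames
#'   `bees`, `visits`, `bouts`, and `log` (seed, config hash, config).
#' @export
generate_experiment <- function(config = experiment_config(), seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  bees <- generate_bees(config)
  u <- rnorm(config$n_colonies, 0, config$colony_sd)
  names(u) <- sprintf("colony%d", seq_len(config$n_colonies))
  nfl <- config$n_flowers
  first <- rep(1 / nfl, nfl)
  P <- matrix(1 / nfl, nfl, nfl)

  visits <- vector("list", nrow(bees) * (config$n_training + 1L))
  bouts <- vector("list", length(visits))
  k <- 0L
  for (i in seq_len(nrow(bees))) {
    uc <- u[[bees$colony_id[i]]]
    m_base <- config$m_max * (1 - exp(-seq_len(config$n_training) / config$tau))
    m_tr <- plogis(qlogis(m_base) + uc)
    m_asym <- m_tr[config$n_training]
    m_test <- post_exposure_memory(min(m_asym, 1 - 1e-12), bees$dose_ng[i],
                                   bees$thorax_width_mm[i], config)
    m_all <- c(m_tr, m_test)
    mu_t <- config$time_mu0 +
      config$time_beta_size * (bees$thorax_width_mm[i] - config$thorax_mean)
    for (b in seq_along(m_all)) {
      ch <- sim_bouts_seq_cpp(1L, first, P, min(m_all[b], 1), 10000L,
                              config$quit_hazard)[[1]]
      phase <- if (b > config$n_training) "test" else "training"
      tpv <- exp(rnorm(1, mu_t, config$time_sd))
      k <- k + 1L
      visits[[k]] <- data.frame(bee_id = bees$bee_id[i],
                                colony_id = bees$colony_id[i],
                                bout_index = b, phase = phase,
                                visit_index = seq_along(ch), flower_id = ch)
      bouts[[k]] <- data.frame(bee_id = bees$bee_id[i], bout_index = b,
                               phase = phase,
                               duration_s = length(ch) * tpv)
    }
  }
  structure(list(bees = bees,
                 visits = do.call(rbind, visits),
                 bouts = do.call(rbind, bouts),
                 log = list(seed = seed, config_hash = config_hash(config),
                            config = config)),
            class = "ram_experiment")
}

#' @export
print.ram_experiment <- function(x, ...) {
  cat(sprintf("Synthetic RAM experiment: %d bees, %d bouts, %d visits (seed %s)\n",
              nrow(x$bees), nrow(x$bouts), nrow(x$visits), x$log$seed))
  print(table(x$bees$treatment))
  invisible(x)
}
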