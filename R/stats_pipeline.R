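#' Candidate model set for the all-subsets comparison
#'
#' The five hierarchical candidate models fitted to every response: the
#' basic model (constant only), size, treatment, treatment + size, and
#' treatment * size (interaction models always contain both main effects).
#' Every candidate carries the family's random-effect structure: a colony
#' intercept, plus a bee-in-colony intercept for the per-choice binomial
#' family.
#'
#' @param response One of `"revisits"`, `"first8"`, `"time"`, `"survival"`.
#' @return A list of five `model_spec` objects (label, fixed-effect terms,
#'   response, family).
#' @export
build_candidate_set <- function(response = c("revisits", "first8", "time",
                                             "survival")) {
  response <- match.arg(response)
  family <- switch(response, revisits = "nbinom2", first8 = "binomial",
                   time = "gaussian", survival = "coxph")
  fixed <- list(basic = character(0),
                size = "size",
                treatment = "treatment",
                `treatment + size` = c("treatment", "size"),
                `treatment * size` = c("treatment", "size",
                                       "treatment:size"))
  lapply(names(fixed), function(lb)
    structure(list(label = lb, fixed = fixed[[lb]], response = response,
                   family = family),
              class = "model_spec"))
}

# internal: fixed-effect right-hand side of a spec
spec_rhs <- function(spec) {
  if (length(spec$fixed) == 0) "1" else paste(spec$fixed, collapse = " + ")
}

# internal: uniform fit container
fit_result <- function(label, family, loglik, k, coefficients, converged,
                       fit = NULL, notes = character()) {
  structure(list(label = label, family = family, loglik = loglik, k = k,
                 aic = -2 * loglik + 2 * k, coefficients = coefficients,
                 converged = converged, fit = fit, notes = notes),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit [%s]: logLik %.3f, k = %d, AIC %.2f%s\n", x$family,
              x$label, x$loglik, x$k, x$aic,
              if (!x$converged) " (NOT converged)" else ""))
  if (nrow(x$coefficients)) print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# internal: tidy glmmTMB conditional coefficients
tmb_coefs <- function(fit) {
  cc <- summary(fit)$coefficients$cond
  data.frame(term = rownames(cc), estimate = cc[, 1], se = cc[, 2],
             row.names = NULL)
}

# internal: glmmTMB convergence flag
tmb_converged <- function(fit) {
  isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
}

#' Negative-binomial GLMM for total revisits
#'
#' NB2 mixed model with log link and a colony random intercept, fitted by
#' maximum likelihood (Laplace approximation). The AIC parameter count is
#' fixed effects + 1 dispersion + 1 random-intercept variance.
#'
#' @param data Test-bout analysis frame with columns `total_revisits`,
#'   `treatment`, `size`, `colony_id` (see [test_bout_data()]).
#' @param spec A `model_spec` from [build_candidate_set()].
#' @return A `fit_result`.
#' @export
fit_nb_glmm <- function(data, spec) {
  f <- as.formula(paste("total_revisits ~", spec_rhs(spec),
                        "+ (1 | colony_id)"))
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(f, data = data, family = glmmTMB::nbinom2()))
  ll <- logLik(fit)
  fit_result(spec$label, "nbinom2", as.numeric(ll), attr(ll, "df"),
             tmb_coefs(fit), tmb_converged(fit), fit)
}

#' Binomial GLMM for per-choice success in the first eight visits
#'
#' Logit-link mixed model on the binary success of each of the first eight
#' choices, with bee nested within colony as random intercepts. Complete
#' separation (all successes or all failures) is flagged rather than
#' fitted: the intercept is reported at `clamp` on the logit scale.
#'
#' @param data Long per-choice frame with columns `success` (0/1),
#'   `treatment`, `size`, `colony_id`, `bee_id` (see [choice_binary_data()]).
#' @param spec A `model_spec`.
#' @param clamp Logit value reported for a separated intercept.
#' @return A `fit_result`.
#' @export
fit_binomial_glmm <- function(data, spec, clamp = 15) {
  y <- data$success
  if (all(y == y[1])) {
    co <- data.frame(term = "(Intercept)",
                     estimate = if (y[1] == 1) clamp else -clamp,
                     se = NA_real_)
    return(fit_result(spec$label, "binomial", NA_real_, NA_integer_, co,
                      converged = FALSE, notes = "complete separation"))
  }
  f <- as.formula(paste("success ~", spec_rhs(spec),
                        "+ (1 | colony_id / bee_id)"))
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(f, data = data, family = stats::binomial()))
  ll <- logLik(fit)
  fit_result(spec$label, "binomial", as.numeric(ll), attr(ll, "df"),
             tmb_coefs(fit), tmb_converged(fit), fit)
}

#' Linear mixed model for log time per visit
#'
#' Gaussian mixed model on the natural log of time per visit with a colony
#' random intercept, fitted by ML (not REML) so that AICs are comparable
#' across fixed-effect structures.
#'
#' @param data Test-bout frame with positive `time_per_visit_s`.
#' @param spec A `model_spec`.
#' @return A `fit_result`.
#' @export
fit_lmm_log_time <- function(data, spec) {
  tpv <- data$time_per_visit_s
  if (any(is.na(tpv)) || any(tpv <= 0))
    stop("data error: time per visit must be present and positive",
         call. = FALSE)
  data$log_tpv <- log(tpv)
  f <- as.formula(paste("log_tpv ~", spec_rhs(spec), "+ (1 | colony_id)"))
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(f, data = data, family = stats::gaussian(), REML = FALSE))
  ll <- logLik(fit)
  fit_result(spec$label, "gaussian", as.numeric(ll), attr(ll, "df"),
             tmb_coefs(fit), tmb_converged(fit), fit)
}

#' Cox proportional-hazards model for the choice at first revisit
#'
#' Partial-likelihood fit with Efron tie handling (event times are small
#' integer choice indices, heavily tied). Bouts with no revisit are
#' right-censored at choice 8. Colony enters as a gamma shared frailty by
#' default, with stratification or omission as alternatives; because every
#' candidate model shares the same colony handling, the choice cancels in
#' AIC differences. The AIC parameter count is the number of fixed
#' regression coefficients.
#'
#' @param data Frame with `survival_time`, `survival_event`, `treatment`,
#'   `size`, `colony_id`.
#' @param spec A `model_spec`.
#' @param colony `"frailty"` (default), `"strata"` or `"none"`.
#' @return A `fit_result`; `coefficients` gains `hr` (hazard-ratio) column.
#' @export
fit_coxph <- function(data, spec, colony = c("frailty", "strata", "none")) {
  colony <- match.arg(colony)
  if (sum(data$survival_event) == 0)
    stop("no information: no first-revisit events observed", call. = FALSE)
  terms <- c(spec$fixed,
             switch(colony,
                    frailty = "survival::frailty(colony_id, distribution = \"gamma\")",
                    strata = "survival::strata(colony_id)",
                    none = NULL))
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  f <- as.formula(paste("survival::Surv(survival_time, survival_event) ~",
                        rhs))
  fit <- suppressWarnings(
    survival::coxph(f, data = data, ties = "efron"))
  cf <- coef(fit)
  cf <- cf[!is.na(cf)]
  se <- if (length(cf)) sqrt(diag(as.matrix(fit$var))[seq_along(cf)]) else numeric(0)
  co <- data.frame(term = names(cf), estimate = unname(cf),
                   se = unname(se), row.names = NULL)
  if (nrow(co)) co$hr <- exp(co$estimate)
  ll <- unname(fit$loglik[length(fit$loglik)])
  monotone <- nrow(co) > 0 && any(abs(co$estimate) > 15)
  fit_result(spec$label, "coxph", ll, nrow(co), co,
             converged = !monotone, fit = fit,
             notes = if (monotone) "possible monotone likelihood" else character())
}

#' Fit the whole candidate set for one response
#'
#' @param data The analysis frame appropriate to the response:
#'   [test_bout_data()] output for `"revisits"`, `"time"` and `"survival"`;
#'   [choice_binary_data()] output for `"first8"`.
#' @param response As in [build_candidate_set()].
#' @param ... Passed to the family's fitter (e.g. `colony` for the Cox
#'   family).
#' @return Named list of `fit_result`s (one per candidate).
#' @export
fit_candidate_set <- function(data, response, ...) {
  specs <- build_candidate_set(response)
  fitter <- switch(specs[[1]]$family,
                   nbinom2 = fit_nb_glmm, binomial = fit_binomial_glmm,
                   gaussian = fit_lmm_log_time, coxph = fit_coxph)
  fits <- lapply(specs, function(sp) fitter(data, sp, ...))
  names(fits) <- vapply(specs, `[[`, "", "label")
  fits
}

#' Akaike weights and best-set membership
#'
#' `delta_i = AIC_i - min(AIC)`; `w_i = exp(-delta_i/2) / sum_j
#' exp(-delta_j/2)`. The best set comprises models with `delta < 2`
#' (strict).
#'
#' @param aics Numeric vector of AICs (or, equivalently, delta-AICs).
#' @param labels Optional model labels.
#' @return A `selection_table` data frame sorted by delta: `model`, `aic`,
#'   `delta_aic`, `weight`, `best_set`.
#' @export
akaike_weights <- function(aics, labels = NULL) {
  if (is.null(labels))
    labels <- if (!is.null(names(aics))) names(aics)
              else paste0("model", seq_along(aics))
  ok <- is.finite(aics)
  if (!any(ok)) stop("no finite AIC values", call. = FALSE)
  if (!all(ok)) {
    warning(sprintf("dropping %d model(s) with non-finite AIC", sum(!ok)))
    aics <- aics[ok]; labels <- labels[ok]
  }
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = labels, aic = aics, delta_aic = delta,
                    weight = w, best_set = delta < 2)
  out <- out[order(out$delta_aic), ]
  rownames(out) <- NULL
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Wald confidence interval
#'
#' `b +/- z * se` with `z` the standard-normal quantile for the level.
#'
#' @param b Estimate(s).
#' @param se Standard error(s), non-negative.
#' @param level Confidence level (default 0.95).
#' @return Two-column matrix `lower`, `upper`.
#' @export
wald_ci <- function(b, se, level = 0.95) {
  stopifnot(all(se >= 0 | is.na(se)))
  z <- qnorm(1 - (1 - level) / 2)
  cbind(lower = b - z * se, upper = b + z * se)
}

#' Hazard ratio with Wald interval
#'
#' `exp(b)` with the exponentiated Wald interval of `b`.
#'
#' @inheritParams wald_ci
#' @return Data frame with `hr`, `lower`, `upper`.
#' @export
hazard_ratio <- function(b, se, level = 0.95) {
  ci <- exp(wald_ci(b, se, level))
  data.frame(hr = exp(b), lower = ci[, "lower"], upper = ci[, "upper"])
}

#' AIC selection and model averaging over a fitted candidate set
#'
#' Builds the selection table over the converged fits and, when two or more
#' models fall within two AIC units of the best, averages coefficients over
#' that best set with Akaike weights renormalised inside it. The default is
#' conditional averaging (each coefficient averaged only over best-set
#' models that contain it); `method = "full"` treats a coefficient absent
#' from a model as 0. The unconditional standard error is
#' `sum_i w_i * sqrt(se_i^2 + (b_i - b_bar)^2)`. A single-model best set
#' passes the best model's estimates through.
#'
#' @param fits Named list of `fit_result`s (e.g. [fit_candidate_set()]).
#' @param method `"conditional"` (default) or `"full"`.
#' @param level Confidence level for Wald intervals.
#' @return A `model_selection` object: list with `selection`
#'   (the [akaike_weights()] table), `averaged` (per-term estimate, SE, CI;
#'   hazard-ratio columns for Cox fits), `method`, `best_models`.
#' @export
select_and_average <- function(fits, method = c("conditional", "full"),
                               level = 0.95) {
  method <- match.arg(method)
  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (!any(conv)) stop("no converged fits to select from", call. = FALSE)
  if (!all(conv))
    warning(sprintf("excluding %d non-converged fit(s): %s", sum(!conv),
                    paste(names(fits)[!conv], collapse = ", ")))
  fits <- fits[conv]
  sel <- akaike_weights(vapply(fits, `[[`, 0, "aic"), names(fits))
  best <- sel$model[sel$best_set]
  is_cox <- fits[[1]]$family == "coxph"

  if (length(best) == 1L) {
    co <- fits[[best]]$coefficients
    avg <- data.frame(term = co$term, estimate = co$estimate, se = co$se,
                      wald_ci(co$estimate, co$se, level))
  } else {
    w <- sel$weight[sel$best_set]
    w <- setNames(w / sum(w), best)
    terms <- unique(unlist(lapply(fits[best],
                                  function(f) f$coefficients$term)))
    avg <- do.call(rbind, lapply(terms, function(tm) {
      has <- vapply(best, function(ml)
        tm %in% fits[[ml]]$coefficients$term, TRUE)
      if (method == "conditional") {
        ml <- best[has]
        wi <- w[ml] / sum(w[ml])
        b <- vapply(ml, function(m) {
          cf <- fits[[m]]$coefficients
          cf$estimate[cf$term == tm]
        }, 0)
        s <- vapply(ml, function(m) {
          cf <- fits[[m]]$coefficients
          cf$se[cf$term == tm]
        }, 0)
      } else {
        wi <- w
        b <- vapply(best, function(m) {
          cf <- fits[[m]]$coefficients
          if (tm %in% cf$term) cf$estimate[cf$term == tm] else 0
        }, 0)
        s <- vapply(best, function(m) {
          cf <- fits[[m]]$coefficients
          if (tm %in% cf$term) cf$se[cf$term == tm] else 0
        }, 0)
      }
      bbar <- sum(wi * b)
      se <- sum(wi * sqrt(s^2 + (b - bbar)^2))
      data.frame(term = tm, estimate = bbar, se = se,
                 wald_ci(bbar, se, level))
    }))
  }
  rownames(avg) <- NULL
  if (is_cox) {
    hr <- hazard_ratio(avg$estimate, avg$se, level)
    avg$hr <- hr$hr; avg$hr_lower <- hr$lower; avg$hr_upper <- hr$upper
  }
  structure(list(selection = sel, averaged = avg, method = method,
                 best_models = best, family = fits[[1]]$family),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection (", x$family, " family)\n", sep = "")
  print(as.data.frame(x$selection), row.names = FALSE, digits = 4)
  cat(sprintf("Averaging (%s) over: %s\n", x$method,
              paste(x$best_models, collapse = ", ")))
  print(x$averaged, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Body-size split re-analysis of total revisits
#'
#' Splits bees at a thorax-width threshold into "smaller" (<= threshold)
#' and "large" (> threshold) strata and, within each, compares the
#' treatment-only negative-binomial GLMM to the basic model:
#' `delta_aic = AIC(basic) - AIC(treatment)` (positive favours treatment),
#' with treatment coefficients and Wald intervals.
#'
#' @param data Test-bout analysis frame (see [test_bout_data()]).
#' @param threshold_mm Split point in mm (default 5.46).
#' @param level Confidence level.
#' @return List with one entry per non-empty stratum: `n`, `delta_aic`,
#'   `coefficients` (treatment terms with CIs), `fits`.
#' @export
size_split_analysis <- function(data, threshold_mm = 5.46, level = 0.95) {
  strata <- list(smaller = data[data$size <= threshold_mm, ],
                 large = data[data$size > threshold_mm, ])
  out <- list()
  for (nm in names(strata)) {
    d <- droplevels(strata[[nm]])
    if (nrow(d) == 0) {
      warning(sprintf("empty '%s' stratum skipped", nm))
      next
    }
    specs <- build_candidate_set("revisits")
    basic <- fit_nb_glmm(d, specs[[1]])
    treat <- fit_nb_glmm(d, specs[[3]])
    co <- treat$coefficients
    co <- co[grepl("^treatment", co$term), , drop = FALSE]
    co <- cbind(co, wald_ci(co$estimate, co$se, level))
    rownames(co) <- NULL
    out[[nm]] <- list(n = nrow(d), delta_aic = basic$aic - treat$aic,
                      coefficients = co,
                      fits = list(basic = basic, treatment = treat))
  }
  structure(out, class = "size_split", threshold_mm = threshold_mm)
}

#' @export
print.size_split <- function(x, ...) {
  cat("Size-split re-analysis at", attr(x, "threshold_mm"), "mm\n")
  for (nm in names(x)) {
    cat(sprintf(" %s bees (n = %d): dAIC(basic - treatment) = %.2f\n",
                nm, x[[nm]]$n, x[[nm]]$delta_aic))
    print(x[[nm]]$coefficients, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Kaplan-Meier curves of the choice at first revisit
#'
#' Product-limit estimator per group with Greenwood standard errors,
#' serialised as a step-function table.
#'
#' @param data Frame with `survival_time`, `survival_event` and the
#'   grouping column.
#' @param by Grouping column name (default `"treatment"`).
#' @return Data frame: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `std_err`, `lower`, `upper`.
#' @export
kaplan_meier <- function(data, by = "treatment") {
  stopifnot(by %in% names(data))
  grp <- factor(data[[by]])
  if (any(table(grp) == 0))
    stop("every group needs at least one record", call. = FALSE)
  sf <- survival::survfit(
    survival::Surv(data$survival_time, data$survival_event) ~ grp)
  sm <- summary(sf, censored = TRUE)
  groups <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time))
            else sub("^grp=", "", as.character(sm$strata))
  data.frame(group = groups, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, n_censor = sm$n.censor, surv = sm$surv,
             std_err = sm$std.err, lower = sm$lower, upper = sm$upper)
}

#' Assemble the test-bout analysis frame
#'
#' One row per bee: the post-exposure test bout's RAM statistics joined to
#' the bee covariates (`treatment` with control as reference level, `size`
#' = thorax width in mm, `colony_id`).
#'
#' @param experiment A [generate_experiment()] object, or a list with
#'   `bees`, `visits`, `bouts` data frames.
#' @return Analysis data frame used by the fitting functions.
#' @export
test_bout_data <- function(experiment) {
  mt <- metrics_table(experiment$visits[experiment$visits$phase == "test", ],
                      experiment$bouts)
  bees <- experiment$bees
  idx <- match(mt$bee_id, bees$bee_id)
  lev <- if (is.factor(bees$treatment)) levels(bees$treatment)
         else unique(as.character(bees$treatment))
  mt$treatment <- factor(as.character(bees$treatment[idx]), levels = lev)
  if ("control" %in% lev)
    mt$treatment <- stats::relevel(mt$treatment, ref = "control")
  mt$size <- bees$thorax_width_mm[idx]
  mt$dose_ng <- bees$dose_ng[idx]
  mt
}

#' Assemble the long per-choice frame for the binomial family
#'
#' Expands each bee's test bout into eight binary success rows
#' ([binary_choice_expansion()]); bouts with fewer than eight visits are
#' dropped with a message reporting the count.
#'
#' @inheritParams test_bout_data
#' @return Long data frame: `bee_id`, `colony_id`, `treatment`, `size`,
#'   `choice_index`, `success`.
#' @export
choice_binary_data <- function(experiment) {
  vis <- experiment$visits[experiment$visits$phase == "test", ]
  bees <- experiment$bees
  key <- split(vis, vis$bee_id)
  dropped <- 0L
  rows <- lapply(key, function(d) {
    d <- d[order(d$visit_index), ]
    bin <- binary_choice_expansion(d$flower_id)
    if (anyNA(bin)) { dropped <<- dropped + 1L; return(NULL) }
    i <- match(d$bee_id[1], bees$bee_id)
    data.frame(bee_id = d$bee_id[1], colony_id = bees$colony_id[i],
               treatment = as.character(bees$treatment[i]),
               size = bees$thorax_width_mm[i],
               choice_index = 1:8, success = bin)
  })
  if (dropped > 0)
    message(sprintf("dropped %d test bout(s) shorter than 8 visits", dropped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  lev <- if (is.factor(bees$treatment)) levels(bees$treatment)
         else unique(as.character(bees$treatment))
  out$treatment <- factor(out$treatment, levels = lev)
  if ("control" %in% lev)
    out$treatment <- stats::relevel(out$treatment, ref = "control")
  out
}
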