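# Three-parameter reinforcement-learning model of T-maze choice.
#
# Value learning follows the delta rule on the chosen option only,
#   V <- V + alpha * (R - V),
# and the choice rule is a softmax on the value difference plus a
# perseveration term on the previous side,
#   P_R(t) = 1 / (1 + exp(-[beta (V_R - V_L) + chi (C_R(t-1) - C_L(t-1))])),
# with C coded 0/1 so the perseveration input is +1 after a right choice,
# -1 after a left choice and 0 on the first trial. Rewards are
# deterministic at the chosen side's current solution value (water 1,
# sucrose 3, saccharin 1, nicotine 0.3) and learned values persist across
# bottle swaps - the swap changes which side pays which value, not the
# animal's estimates.
#
# Parameters are bounded: alpha in ]0, 1], beta in ]0, 20], chi in
# [-2, 2]; the open ends are realized with a numerical floor of 1e-6.
# Fitting maximizes the sequence likelihood (values initialized at 0);
# generative simulation initializes values at 1.

.rl_bounds <- function() {
  list(lower = c(alpha = 1e-6, beta = 1e-6, chi = -2),
       upper = c(alpha = 1, beta = 20, chi = 2))
}

#' Validate an (alpha, beta, chi) latent triplet
#'
#' @param alpha learning rate in `]0, 1]`.
#' @param beta inverse temperature in `]0, 20]`.
#' @param chi perseveration in `[-2, 2]` (positive = repeat, negative =
#'   alternate).
#' @return named numeric vector of class `latent_triplet`.
#' @export
latent_triplet <- function(alpha, beta, chi = 0) {
  b <- .rl_bounds()
  v <- c(alpha = alpha, beta = beta, chi = chi)
  if (any(v < b$lower - 1e-12) || any(v > b$upper + 1e-12))
    stop2("triplet outside model bounds: alpha ]0,1], beta ]0,20], chi [-2,2]")
  structure(v, class = "latent_triplet")
}

#' Delta-rule value update
#'
#' @param v current expected value of the chosen option.
#' @param reward delivered reward.
#' @param alpha learning rate in `[0, 1]`.
#' @return updated value `v + alpha * (reward - v)`.
#' @export
update_value <- function(v, reward, alpha) {
  if (any(alpha < 0) || any(alpha > 1)) stop2("alpha must lie in [0, 1]")
  v + alpha * (reward - v)
}

#' Softmax probability of choosing the right side
#'
#' @param v_left,v_right current expected values.
#' @param beta inverse temperature.
#' @param chi perseveration weight.
#' @param prev_choice `"L"`, `"R"` or `"none"` (first trial; the
#'   perseveration term is then 0).
#' @return probability in `(0, 1)` of a right choice.
#' @export
choice_probability <- function(v_left, v_right, beta, chi = 0,
                               prev_choice = c("none", "L", "R")) {
  prev_choice <- match.arg(prev_choice)
  persev <- switch(prev_choice, none = 0, L = -1, R = 1)
  x <- beta * (v_right - v_left) + chi * persev
  stats::plogis(x)
}

.record_trial_vectors <- function(record) {
  tr <- record$trials
  se <- record$sessions
  i <- match(tr$session_id, se$session_id)
  list(choice = as.integer(tr$chosen_side == "R"),
       high_side = as.integer(tr$high_side == "R"),
       value_low = se$value_low[i],
       value_high = se$value_high[i])
}

#' Negative log-likelihood of a choice sequence
#'
#' Chains the delta rule and the softmax over the record's trials, reward
#' values taken from its session table; per-trial probabilities are floored
#' at 1e-12 before the log so pathological parameter values remain finite
#' during optimization.
#'
#' @param record a [mouse_record()] whose sessions carry `value_low` /
#'   `value_high`.
#' @param triplet a [latent_triplet()] (or plain numeric `c(alpha, beta,
#'   chi)`).
#' @param v0 initial expected value of both options (0 for fitting).
#' @return negative log-likelihood in nats.
#' @export
sequence_nll <- function(record, triplet, v0 = 0) {
  if (!nrow(record$trials)) stop2("empty record")
  tv <- .record_trial_vectors(record)
  rl_nll_core(tv$choice, tv$high_side, tv$value_low, tv$value_high,
              triplet[["alpha"]], triplet[["beta"]], triplet[["chi"]],
              v0, 1e-12)
}

#' Fitting configuration
#'
#' @param n_starts random multi-start count for the bounded optimizer.
#' @param seed integer seed for the start draws.
#' @param v0 initial option value used in the likelihood (0: values unknown
#'   at the start of the experiment).
#' @param factr L-BFGS-B convergence factor (passed to [stats::optim()]).
#' @param min_trials records with fewer trials are refused.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, seed = 1, v0 = 0, factr = 1e7,
                       min_trials = 10) {
  structure(list(n_starts = n_starts, seed = seed, v0 = v0, factr = factr,
                 min_trials = min_trials), class = "fit_config")
}

.fit_record <- function(record, config, fix_chi = FALSE) {
  n <- nrow(record$trials)
  if (n < config$min_trials)
    stop2("too few trials (", n, " < ", config$min_trials, ") for '",
          record$mouse_id, "'")
  tv <- .record_trial_vectors(record)
  b <- .rl_bounds()
  free <- if (fix_chi) 1:2 else 1:3
  obj <- function(par) {
    chi <- if (fix_chi) 0 else par[3]
    rl_nll_core(tv$choice, tv$high_side, tv$value_low, tv$value_high,
                par[1], par[2], chi, config$v0, 1e-12)
  }
  set.seed(derive_seed(config$seed, 1e6 + n))
  starts <- matrix(stats::runif(config$n_starts * length(free),
                                min = rep(b$lower[free], each = config$n_starts),
                                max = rep(b$upper[free], each = config$n_starts)),
                   nrow = config$n_starts)
  # deterministic grid start points: the likelihood is flat in alpha as
  # beta -> 0, so uniform draws alone can miss low-beta / high-alpha basins
  grid <- as.matrix(expand.grid(alpha = c(0.1, 0.5, 0.9),
                                beta = c(0.25, 1, 4)))
  if (!fix_chi) grid <- cbind(grid, chi = 0)
  starts <- rbind(starts, unname(grid))
  best <- NULL; best_start <- NA_integer_; any_ok <- FALSE; msgs <- character()
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = b$lower[free], upper = b$upper[free],
                   control = list(factr = config$factr, maxit = 500)),
      error = function(e) e)
    if (inherits(res, "error")) { msgs <- c(msgs, conditionMessage(res)); next }
    any_ok <- TRUE
    if (is.null(best) || res$value < best$value - 1e-9) {
      best <- res; best_start <- s
    }
  }
  if (!any_ok) stop2("optimizer failed on all starts for '", record$mouse_id,
                     "': ", paste(unique(msgs), collapse = "; "))
  # derivative-free polish: L-BFGS-B can stall on the nearly flat surfaces
  # of weakly structured (Explorer-like) records
  clamp <- function(par) pmin(pmax(par, b$lower[free]), b$upper[free])
  pol <- tryCatch(stats::optim(best$par, function(par) obj(clamp(par)),
                               method = "Nelder-Mead",
                               control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) {
    best$par <- clamp(pol$par)
    best$value <- pol$value
  }
  p <- length(free)
  par <- best$par
  triplet <- latent_triplet(par[1], par[2], if (fix_chi) 0 else par[3])
  structure(list(mouse_id = record$mouse_id, triplet = triplet,
                 nll = best$value, n_trials = n,
                 bic = 2 * best$value + p * log(n), p = p,
                 converged = best$convergence == 0,
                 n_starts_used = nrow(starts), best_start = best_start),
            class = "rl_fit")
}

#' Fit the full 3-parameter model to one animal
#'
#' Bounded maximum likelihood (L-BFGS-B) from `n_starts` uniform draws
#' within the parameter box; the lowest negative log-likelihood wins, ties
#' (within 1e-9) going to the earlier start. BIC uses 3 free parameters.
#'
#' @param record a [mouse_record()] (at least `min_trials` trials).
#' @param config a [fit_config()].
#' @return an `rl_fit`: `triplet`, `nll`, `n_trials`, `bic`, `converged`,
#'   `n_starts_used`, `best_start`.
#' @export
fit_mouse <- function(record, config = fit_config()) {
  .fit_record(record, config, fix_chi = FALSE)
}

#' Fit the nested 2-parameter model (perseveration pinned at 0)
#'
#' @inheritParams fit_mouse
#' @return an `rl_fit` with `chi = 0` and BIC on 2 free parameters.
#' @export
fit_reduced <- function(record, config = fit_config()) {
  .fit_record(record, config, fix_chi = TRUE)
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit>", x$mouse_id, " alpha =", signif(x$triplet[["alpha"]], 4),
      " beta =", signif(x$triplet[["beta"]], 4),
      " chi =", signif(x$triplet[["chi"]], 4),
      " nll =", signif(x$nll, 6), " bic =", signif(x$bic, 6), "\n")
  invisible(x)
}

#' Compare the full and reduced model fits of one animal
#'
#' Likelihood-ratio test (chi-square, 1 df) and BIC difference for the
#' nested pair; a slightly negative raw statistic (optimizer noise) is
#' clipped to 0 with a warning.
#'
#' @param fit_full,fit_reduced `rl_fit` objects on the same record.
#' @return list `delta_bic` (reduced - full; positive favors the full
#'   model), `lrt_statistic`, `lrt_p`.
#' @export
compare_models <- function(fit_full, fit_reduced) {
  if (fit_full$n_trials != fit_reduced$n_trials)
    stop2("fits are on records of different length")
  stat <- 2 * (fit_reduced$nll - fit_full$nll)
  if (stat < 0) {
    warning("negative likelihood-ratio statistic clipped to 0")
    stat <- 0
  }
  df <- fit_full$p - fit_reduced$p
  list(delta_bic = fit_reduced$bic - fit_full$bic,
       lrt_statistic = stat,
       lrt_p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Fit every animal of a cohort, full and reduced models
#'
#' @param x a [cohort()].
#' @param config a [fit_config()]; each animal gets an independent child
#'   seed derived from `config$seed`.
#' @return data.frame with per-animal full-model parameters, `nll`, `bic`,
#'   `converged`, reduced-model columns and the nested comparison
#'   (`delta_bic`, `lrt_statistic`, `lrt_p`).
#' @export
fit_cohort <- function(x, config = fit_config()) {
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(seq_along(x$records), function(i) {
    r <- x$records[[i]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    ff <- fit_mouse(r, cfg)
    fr <- fit_reduced(r, cfg)
    cmp <- withCallingHandlers(
      compare_models(ff, fr),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(mouse_id = r$mouse_id,
               alpha = ff$triplet[["alpha"]], beta = ff$triplet[["beta"]],
               chi = ff$triplet[["chi"]], nll = ff$nll, bic = ff$bic,
               n_trials = ff$n_trials, converged = ff$converged,
               alpha_red = fr$triplet[["alpha"]], beta_red = fr$triplet[["beta"]],
               nll_red = fr$nll, bic_red = fr$bic,
               delta_bic = cmp$delta_bic, lrt_statistic = cmp$lrt_statistic,
               lrt_p = cmp$lrt_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
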