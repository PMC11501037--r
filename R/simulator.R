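# Generative simulation of choice sequences from latent triplets, and the
# three model-based prediction experiments built on it: the
# reward-difference (delta-V) sweep, the latent-variable attribution
# study, and the cross-context prediction of nicotine choice.

#' Build a session schedule
#'
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session (scalar or vector).
#' @param value_low,value_high reward values of the reference and the
#'   varying/high side (scalars or per-session vectors).
#' @param first_high side holding `value_high` in session 1; sides
#'   alternate every session.
#' @param v0 initial option value used when simulating from this schedule
#'   (1: naive animals expect the water value).
#' @return data.frame(`session_id`, `n_trials`, `high_side`, `value_low`,
#'   `value_high`) with attribute `v0`.
#' @export
session_schedule <- function(n_sessions = 6, trials_per_session = 50,
                             value_low = 1, value_high = 3,
                             first_high = "L", v0 = 1) {
  stopifnot(first_high %in% .sides, n_sessions >= 1,
            all(trials_per_session >= 1))
  sides <- rep(c(first_high, setdiff(.sides, first_high)),
               length.out = n_sessions)
  out <- data.frame(session_id = seq_len(n_sessions),
                    n_trials = rep(as.integer(trials_per_session),
                                   length.out = n_sessions),
                    high_side = sides,
                    value_low = rep(value_low, length.out = n_sessions),
                    value_high = rep(value_high, length.out = n_sessions),
                    stringsAsFactors = FALSE)
  attr(out, "v0") <- v0
  out
}

.schedule_trial_vectors <- function(schedule) {
  idx <- rep(seq_len(nrow(schedule)), times = schedule$n_trials)
  list(session_id = schedule$session_id[idx],
       high_side = as.integer(schedule$high_side[idx] == "R"),
       high_side_chr = schedule$high_side[idx],
       value_low = schedule$value_low[idx],
       value_high = schedule$value_high[idx])
}

#' Simulate one animal's choice sequence
#'
#' Per trial: the softmax choice probability is computed from the current
#' values and the previous side, a choice is drawn, the chosen side's
#' solution value is delivered as reward, and the chosen value is updated
#' by the delta rule. Values persist across sessions.
#'
#' @param triplet a [latent_triplet()] or numeric `c(alpha, beta, chi)`.
#' @param schedule a [session_schedule()].
#' @param seed integer seed; the same seed reproduces the record exactly.
#' @param mouse_id id given to the simulated record.
#' @param days_observed metadata carried on the record (`NA` by default).
#' @return a [mouse_record()].
#' @export
simulate_mouse <- function(triplet, schedule, seed, mouse_id = "sim",
                           days_observed = NA_real_) {
  tv <- .schedule_trial_vectors(schedule)
  v0 <- attr(schedule, "v0") %||% 1
  set.seed(seed)
  ch <- rl_simulate_core(tv$high_side, tv$value_low, tv$value_high,
                         triplet[["alpha"]], triplet[["beta"]],
                         triplet[["chi"]], v0)
  trials <- data.frame(index = seq_along(ch), session_id = tv$session_id,
                       chosen_side = ifelse(ch == 1L, "R", "L"),
                       high_side = tv$high_side_chr, stringsAsFactors = FALSE)
  sess <- schedule[, c("session_id", "high_side", "value_low", "value_high",
                       "n_trials")]
  mouse_record(mouse_id, trials, sessions = sess, days_observed = days_observed)
}

#' Simulate a cohort from a table of latent triplets
#'
#' Each animal receives a child seed derived from the master seed, so the
#' whole cohort is reproducible and per-animal records do not depend on
#' cohort order beyond their own index.
#'
#' @param triplets data.frame with columns `mouse_id`, `alpha`, `beta`,
#'   `chi`; optional `days_observed`.
#' @param schedule a [session_schedule()], or a list of schedules (one per
#'   animal).
#' @param seed master seed.
#' @return a [cohort()].
#' @export
simulate_cohort <- function(triplets, schedule, seed) {
  triplets <- as.data.frame(triplets)
  if (!nrow(triplets)) stop2("empty triplet table")
  per_animal <- is.list(schedule) && !is.data.frame(schedule)
  recs <- lapply(seq_len(nrow(triplets)), function(i) {
    sch <- if (per_animal) schedule[[i]] else schedule
    simulate_mouse(c(alpha = triplets$alpha[i], beta = triplets$beta[i],
                     chi = triplets$chi[i]),
                   sch, seed = derive_seed(seed, i),
                   mouse_id = as.character(triplets$mouse_id[i]),
                   days_observed = if ("days_observed" %in% names(triplets))
                     triplets$days_observed[i] else NA_real_)
  })
  cohort(recs)
}

.cohort_descriptors <- function(x) {
  t(vapply(x$records, descriptor_vector, numeric(5)))
}

#' Reward-difference (delta-V) sweep
#'
#' One side keeps the reference value 1 while the other side's value is
#' 1 + delta-V; for each delta-V and each group of triplets, cohorts are
#' simulated and the five descriptors summarized. `Pref` is computed with
#' respect to the varying-value side. Seeds depend on (group, replicate,
#' animal) but not on delta-V, so the delta-V = 2 column reproduces a plain
#' water/sucrose simulation under the same seeds.
#'
#' @param triplets_by_group named list of triplet data.frames (see
#'   [simulate_cohort()]).
#' @param dv_grid delta-V values; `1 + dv` must be non-negative.
#' @param n_sessions,trials_per_session schedule template (sides
#'   alternate).
#' @param n_replicates simulated cohorts per (group, delta-V).
#' @param seed master seed.
#' @return object of class `sweep_result`: `summary` (long data.frame
#'   `group`, `dv`, `descriptor`, `mean`, `sd`), `per_animal`, `dv_grid`,
#'   `n_replicates`, `seed`.
#' @export
delta_v_sweep <- function(triplets_by_group, dv_grid = c(-1, 0, 1, 2, 3),
                          n_sessions = 6, trials_per_session = 50,
                          n_replicates = 20, seed = 1) {
  if (any(1 + dv_grid < 0)) stop2("negative reward value: 1 + dv must be >= 0")
  stopifnot(is.list(triplets_by_group), length(names(triplets_by_group)) > 0)
  per_animal <- list()
  gi <- 0
  for (g in names(triplets_by_group)) {
    gi <- gi + 1
    tr <- as.data.frame(triplets_by_group[[g]])
    for (dv in dv_grid) {
      sch <- session_schedule(n_sessions, trials_per_session,
                              value_low = 1, value_high = 1 + dv)
      for (rep_i in seq_len(n_replicates)) {
        co <- simulate_cohort(tr, sch,
                              seed = derive_seed(seed, gi * 1000L + rep_i))
        D <- .cohort_descriptors(co)
        per_animal[[length(per_animal) + 1L]] <-
          data.frame(group = g, dv = dv, replicate = rep_i,
                     mouse_id = rownames(D), D, row.names = NULL,
                     stringsAsFactors = FALSE)
      }
    }
  }
  pa <- do.call(rbind, per_animal)
  long <- do.call(rbind, lapply(.descriptor_cols, function(d) {
    agg_m <- stats::aggregate(pa[[d]], by = list(group = pa$group, dv = pa$dv),
                              FUN = mean, na.rm = TRUE)
    agg_s <- stats::aggregate(pa[[d]], by = list(group = pa$group, dv = pa$dv),
                              FUN = stats::sd, na.rm = TRUE)
    data.frame(group = agg_m$group, dv = agg_m$dv, descriptor = d,
               mean = agg_m$x, sd = agg_s$x, stringsAsFactors = FALSE)
  }))
  structure(list(summary = long, per_animal = pa, dv_grid = dv_grid,
                 n_replicates = n_replicates, seed = seed),
            class = "sweep_result")
}

#' Latent-variable attribution study
#'
#' Simulates each animal under recombinations of the cohort's fitted
#' latent variables to ask which parameter carries the between-archetype
#' descriptor differences: `own` uses each animal's own triplet;
#' `random_triplet` permutes whole triplets across animals;
#' `shuffle_alpha` / `shuffle_beta` / `shuffle_chi` permute one parameter
#' and keep the other two; `random_triplet_empirical_trials` additionally
#' sizes each animal's sessions from its empirical trials/day (3-day
#' sessions). Permutations are without replacement so parameter marginals
#' are preserved. Simulation seeds do not depend on the mode, so `own`
#' reproduces [simulate_cohort()] exactly.
#'
#' @param cohort_fits data.frame with `mouse_id`, `alpha`, `beta`, `chi`,
#'   `label` (the animal's archetype) and, for the empirical-trials mode,
#'   `trials_per_day`.
#' @param mode one of the modes above.
#' @param n_sessions,trials_per_session schedule template.
#' @param seed master seed (also seeds the permutation).
#' @return list with `per_animal` descriptors (original `label` kept),
#'   `summary` (mean/sd by label x descriptor), `mode`, `seed`.
#' @export
attribution_study <- function(cohort_fits,
                              mode = c("own", "random_triplet",
                                       "shuffle_alpha", "shuffle_beta",
                                       "shuffle_chi",
                                       "random_triplet_empirical_trials"),
                              n_sessions = 6, trials_per_session = 50,
                              seed = 1) {
  mode <- match.arg(mode)
  cf <- as.data.frame(cohort_fits)
  stopifnot(all(c("mouse_id", "alpha", "beta", "chi", "label") %in% names(cf)))
  n <- nrow(cf)
  set.seed(derive_seed(seed, 777L))
  perm <- sample.int(n)
  tr <- cf[, c("mouse_id", "alpha", "beta", "chi")]
  if (mode %in% c("random_triplet", "random_triplet_empirical_trials")) {
    tr[, c("alpha", "beta", "chi")] <- cf[perm, c("alpha", "beta", "chi")]
  } else if (mode == "shuffle_alpha") {
    tr$alpha <- cf$alpha[perm]
  } else if (mode == "shuffle_beta") {
    tr$beta <- cf$beta[perm]
  } else if (mode == "shuffle_chi") {
    tr$chi <- cf$chi[perm]
  }
  if (mode == "random_triplet_empirical_trials") {
    stopifnot("trials_per_day" %in% names(cf))
    schedules <- lapply(pmax(1L, as.integer(round(cf$trials_per_day * 3))),
                        function(nt) session_schedule(n_sessions, nt))
    co <- simulate_cohort(tr, schedules, seed = seed)
  } else {
    co <- simulate_cohort(tr, session_schedule(n_sessions, trials_per_session),
                          seed = seed)
  }
  D <- .cohort_descriptors(co)
  pa <- data.frame(mouse_id = cf$mouse_id, label = cf$label, D,
                   row.names = NULL, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(.descriptor_cols, function(d) {
    m <- tapply(pa[[d]], pa$label, mean, na.rm = TRUE)
    s <- tapply(pa[[d]], pa$label, stats::sd, na.rm = TRUE)
    data.frame(label = names(m), descriptor = d, mean = as.numeric(m),
               sd = as.numeric(s), stringsAsFactors = FALSE)
  }))
  list(per_animal = pa, summary = long, mode = mode, seed = seed)
}

#' Mean absolute between-group descriptor separation
#'
#' For each descriptor, the mean over group pairs of the absolute
#' difference of group means, averaged over descriptors with defined
#' values. Used to quantify how much of the between-archetype structure an
#' attribution mode preserves.
#'
#' @param per_animal data.frame with `label` and the five descriptor
#'   columns (as returned by [attribution_study()]).
#' @return a single non-negative number.
#' @export
descriptor_separation <- function(per_animal) {
  gaps <- vapply(.descriptor_cols, function(d) {
    m <- tapply(per_animal[[d]], per_animal$label, mean, na.rm = TRUE)
    m <- m[is.finite(m)]
    if (length(m) < 2) return(NA_real_)
    pairs <- utils::combn(length(m), 2)
    mean(abs(m[pairs[1, ]] - m[pairs[2, ]]))
  }, numeric(1))
  mean(gaps, na.rm = TRUE)
}

#' Cross-context prediction: sucrose block then nicotine block
#'
#' One continuous simulation of 2 x `n_sessions_per_block` sessions with a
#' value change at the block boundary: values (1, 3) in the first block
#' (water vs sucrose) and (1, 0.3) in the second (saccharin vs
#' nicotine+saccharin). Learned values carry over the boundary; the five
#' descriptors are computed separately per block, `Pref` with respect to
#' the varying-value side (sucrose, then nicotine).
#'
#' @param triplets triplet data.frame (see [simulate_cohort()]), typically
#'   fitted on water/sucrose data.
#' @param n_sessions_per_block,trials_per_session schedule template.
#' @param seed master seed.
#' @param reset_values if `TRUE`, option values are reset to the schedule
#'   `v0` at the block boundary (sensitivity analysis; default carries
#'   values over).
#' @return data.frame: one row per animal x block (`"WS"`, `"SaN"`) with
#'   the five descriptors.
#' @export
cross_context_prediction <- function(triplets, n_sessions_per_block = 6,
                                     trials_per_session = 50, seed = 1,
                                     reset_values = FALSE) {
  nb <- n_sessions_per_block
  sides <- rep(c("L", "R"), length.out = 2 * nb)
  full <- data.frame(session_id = seq_len(2 * nb),
                     n_trials = trials_per_session,
                     high_side = sides,
                     value_low = 1,
                     value_high = rep(c(3, 0.3), each = nb),
                     stringsAsFactors = FALSE)
  attr(full, "v0") <- 1
  triplets <- as.data.frame(triplets)
  rows <- lapply(seq_len(nrow(triplets)), function(i) {
    tri <- c(alpha = triplets$alpha[i], beta = triplets$beta[i],
             chi = triplets$chi[i])
    sd_i <- derive_seed(seed, i)
    if (reset_values) {
      sch1 <- full[seq_len(nb), ]; attr(sch1, "v0") <- 1
      sch2 <- full[nb + seq_len(nb), ]; attr(sch2, "v0") <- 1
      rec1 <- simulate_mouse(tri, sch1, seed = sd_i)
      rec2 <- simulate_mouse(tri, sch2, seed = derive_seed(sd_i, 2L))
    } else {
      rec <- simulate_mouse(tri, full, seed = sd_i,
                            mouse_id = as.character(triplets$mouse_id[i]))
      rec1 <- .subset_record(rec, rec$trials$session_id <= nb)
      rec2 <- .subset_record(rec, rec$trials$session_id > nb)
    }
    rbind(data.frame(mouse_id = as.character(triplets$mouse_id[i]),
                     block = "WS", t(descriptor_vector(rec1)),
                     stringsAsFactors = FALSE),
          data.frame(mouse_id = as.character(triplets$mouse_id[i]),
                     block = "SaN", t(descriptor_vector(rec2)),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

.subset_record <- function(record, keep) {
  tr <- record$trials[keep, , drop = FALSE]
  sess <- record$sessions[record$sessions$session_id %in% unique(tr$session_id), ,
                          drop = FALSE]
  nt <- table(factor(tr$session_id, levels = sess$session_id))
  sess$n_trials <- as.integer(nt)
  structure(list(mouse_id = record$mouse_id, trials = tr, sessions = sess,
                 days_observed = record$days_observed),
            class = "mouse_record")
}
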