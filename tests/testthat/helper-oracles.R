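# Independent oracles and fixture builders. None of these share code with
# the package implementation paths they check.

# Brute-force forward-chaining negative log-likelihood: plain R loop,
# probabilities written out directly from the model definition.
oracle_nll <- function(record, alpha, beta, chi, v0 = 0, p_floor = 1e-12) {
  tr <- record$trials
  se <- record$sessions
  vL <- v0; vR <- v0
  prev <- NA_character_
  nll <- 0
  for (t in seq_len(nrow(tr))) {
    persev <- if (is.na(prev)) 0 else if (prev == "R") 1 else -1
    x <- beta * (vR - vL) + chi * persev
    pR <- 1 / (1 + exp(-x))
    p <- if (tr$chosen_side[t] == "R") pR else 1 - pR
    nll <- nll - log(max(p, p_floor))
    s <- se[se$session_id == tr$session_id[t], ]
    reward <- if (tr$chosen_side[t] == s$high_side) s$value_high else s$value_low
    if (tr$chosen_side[t] == "R") vR <- vR + alpha * (reward - vR)
    else vL <- vL + alpha * (reward - vL)
    prev <- tr$chosen_side[t]
  }
  nll
}

# Random but structurally valid choice record.
random_record <- function(n_trials, seed, n_sessions = 2,
                          value_low = 1, value_high = 3) {
  set.seed(seed)
  per <- diff(round(seq(0, n_trials, length.out = n_sessions + 1)))
  per <- per[per > 0]
  hs <- rep(rep(c("L", "R"), length.out = length(per)), times = per)
  trials <- data.frame(index = seq_len(n_trials),
                       session_id = rep(seq_along(per), times = per),
                       chosen_side = sample(c("L", "R"), n_trials, replace = TRUE),
                       high_side = hs, stringsAsFactors = FALSE)
  mouse_record(paste0("r", seed), trials, value_low = value_low,
               value_high = value_high)
}

random_triplet_draw <- function(seed) {
  set.seed(seed)
  c(alpha = runif(1, 0.05, 1), beta = runif(1, 0.1, 8), chi = runif(1, -1.5, 1.5))
}

# Record built directly from side vectors (one session unless stated).
record_from_sides <- function(chosen, high, session = rep(1L, length(chosen)),
                              id = "m", days = 10,
                              value_low = 1, value_high = 3) {
  trials <- data.frame(index = seq_along(chosen), session_id = session,
                       chosen_side = chosen, high_side = high,
                       stringsAsFactors = FALSE)
  mouse_record(id, trials, days_observed = days,
               value_low = value_low, value_high = value_high)
}

# Swap all L/R labels of a record (choices, high sides).
mirror_record <- function(record) {
  flip <- function(x) ifelse(x == "L", "R", "L")
  tr <- record$trials
  tr$chosen_side <- flip(tr$chosen_side)
  tr$high_side <- flip(tr$high_side)
  se <- record$sessions
  se$high_side <- flip(se$high_side)
  mouse_record(record$mouse_id, tr[, c("index", "session_id", "chosen_side",
                                       "high_side")],
               sessions = se[, c("session_id", "high_side", "value_low",
                                 "value_high")],
               days_observed = record$days_observed)
}

# Exhaustive grid over the 2-simplex with the given step.
simplex_grid <- function(step = 0.01) {
  a1 <- seq(0, 1, step)
  g <- expand.grid(a1 = a1, a2 = a1)
  g <- g[g$a1 + g$a2 <= 1 + 1e-12, ]
  cbind(g$a1, g$a2, pmax(0, 1 - g$a1 - g$a2))
}

# Align fitted archetypes to planted vertices by greedy nearest matching;
# returns max row-wise L2 error.
vertex_alignment_error <- function(Z, V) {
  d <- as.matrix(stats::dist(rbind(Z, V)))[seq_len(nrow(Z)),
                                           nrow(Z) + seq_len(nrow(V))]
  perm <- apply(d, 1, which.min)
  max(sqrt(rowSums((Z - V[perm, , drop = FALSE])^2)))
}

# Planted-vertex data set: sparse Dirichlet mixtures plus the pure
# vertices themselves (noiseless convex combinations).
planted_vertex_data <- function(n = 300, seed = 7) {
  V <- matrix(c(0, 0, 1, 0, 0.5, 1), 3, 2, byrow = TRUE)
  set.seed(seed)
  W <- matrix(rgamma((n - 6) * 3, 0.2), n - 6, 3)
  W <- W / rowSums(W)
  W <- rbind(W, diag(3), diag(3))
  list(X = W %*% V, V = V)
}

prior_triplets <- function(profile, n, seed) {
  p <- default_profile_priors()[[profile]]
  set.seed(seed)
  data.frame(mouse_id = paste0(profile, "_", seq_len(n)),
             alpha = runif(n, p$alpha_range[1], p$alpha_range[2]),
             beta = runif(n, p$beta_range[1], p$beta_range[2]),
             chi = runif(n, p$chi_range[1], p$chi_range[2]),
             stringsAsFactors = FALSE)
}
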