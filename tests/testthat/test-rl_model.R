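test_that("delta-rule update satisfies its analytic identities", {
  expect_equal(update_value(0.7, 3, 1), 3)       # full update
  expect_equal(update_value(0.7, 3, 0), 0.7)     # no update
  expect_equal(update_value(0, 3, 0.5), 1.5)     # direct substitution
  expect_error(update_value(0, 3, 1.2), "alpha")
  # contraction: |v' - R| = (1 - a) |v - R|
  for (seed in 1:5) {
    set.seed(seed)
    v <- runif(1, -2, 4); r <- runif(1, 0, 3); a <- runif(1)
    expect_equal(abs(update_value(v, r, a) - r), (1 - a) * abs(v - r))
  }
})

test_that("softmax choice rule hits limits and mirror symmetry", {
  expect_equal(choice_probability(1, 1, beta = 3, chi = 0), 0.5)
  expect_equal(choice_probability(0.2, 2.7, beta = 0, chi = 0), 0.5)
  expect_equal(choice_probability(0, 1, beta = 2, chi = 0),
               1 / (1 + exp(-2)))
  expect_equal(choice_probability(0, 1, beta = 2, chi = 0), 0.88080,
               tolerance = 1e-5)
  # perseveration pushes toward repeating the previous side
  expect_gt(choice_probability(1, 1, beta = 1, chi = 0.8, prev_choice = "R"), 0.5)
  expect_lt(choice_probability(1, 1, beta = 1, chi = 0.8, prev_choice = "L"), 0.5)
  # mirror: swapping the options (and the previous side) flips P exactly
  for (seed in 1:10) {
    set.seed(seed)
    vl <- runif(1, 0, 3); vr <- runif(1, 0, 3)
    b <- runif(1, 0, 10); ch <- runif(1, -2, 2)
    p <- choice_probability(vl, vr, b, ch, "R")
    pm <- choice_probability(vr, vl, b, ch, "L")
    expect_equal(p + pm, 1, tolerance = 1e-12)
  }
  # extreme logits stay inside (0, 1) without overflow
  expect_gt(choice_probability(0, 1000, beta = 20, chi = 0), 0)
  expect_lt(choice_probability(1000, 0, beta = 20, chi = 0), 1)
})

test_that("sequence likelihood matches analytic limits", {
  r1 <- record_from_sides("L", "L")
  expect_equal(sequence_nll(r1, c(alpha = 0.5, beta = 2, chi = 1), v0 = 0),
               log(2))
  rn <- random_record(57, 2)
  expect_equal(sequence_nll(rn, c(alpha = 0.5, beta = 0, chi = 0)),
               57 * log(2))
})

test_that("sequence likelihood equals the hand-chained 3-trial computation", {
  # choices R,R,L; sucrose (3) on R, water (1) on L; a=0.5 b=1 chi=0.5 v0=0
  r <- record_from_sides(c("R", "R", "L"), rep("R", 3))
  a <- 0.5; b <- 1; ch <- 0.5
  vL <- 0; vR <- 0
  p1 <- 1 / (1 + exp(-(b * (vR - vL))))          # no previous choice
  vR <- vR + a * (3 - vR)                        # chose R, got sucrose
  p2 <- 1 / (1 + exp(-(b * (vR - vL) + ch * 1)))
  vR <- vR + a * (3 - vR)
  p3 <- 1 - 1 / (1 + exp(-(b * (vR - vL) + ch * 1)))
  hand <- -(log(p1) + log(p2) + log(p3))
  expect_equal(sequence_nll(r, c(alpha = a, beta = b, chi = ch), v0 = 0),
               hand, tolerance = 1e-12)
})

test_that("likelihood agrees with the brute-force oracle on random records", {
  for (seed in 1:25) {
    r <- random_record(10 + seed %% 20, seed, n_sessions = 1 + seed %% 3)
    tri <- random_triplet_draw(1000 + seed)
    expect_equal(sequence_nll(r, tri, v0 = 0),
                 oracle_nll(r, tri[["alpha"]], tri[["beta"]], tri[["chi"]],
                            v0 = 0),
                 tolerance = 1e-12)
    expect_equal(sequence_nll(r, tri, v0 = 1),
                 oracle_nll(r, tri[["alpha"]], tri[["beta"]], tri[["chi"]],
                            v0 = 1),
                 tolerance = 1e-12)
  }
})

test_that("values persist across bottle swaps in the likelihood", {
  # two sessions, swap after trial 2; all R choices
  r <- record_from_sides(rep("R", 4), c("R", "R", "L", "L"),
                         session = c(1L, 1L, 2L, 2L))
  tri <- c(alpha = 0.5, beta = 1, chi = 0)
  got <- sequence_nll(r, tri, v0 = 0)
  # oracle carries vR over the swap; session 2 pays water on R
  expect_equal(got, oracle_nll(r, 0.5, 1, 0, v0 = 0), tolerance = 1e-12)
  # resetting values at the swap would give a different answer
  r1 <- record_from_sides(rep("R", 2), rep("R", 2))
  r2 <- record_from_sides(rep("R", 2), rep("L", 2))
  reset_sum <- sequence_nll(r1, tri, v0 = 0) + sequence_nll(r2, tri, v0 = 0)
  expect_false(isTRUE(all.equal(got, reset_sum)))
})

test_that("maximum-likelihood fit dominates the truth and respects bounds", {
  sch <- session_schedule()
  tri <- c(alpha = 0.8, beta = 5, chi = 0)
  rec <- simulate_mouse(tri, sch, seed = 21)
  cfg <- fit_config(n_starts = 10, seed = 2, v0 = 1)
  f <- fit_mouse(rec, cfg)
  expect_lte(f$nll, sequence_nll(rec, tri, v0 = 1) + 1e-6)
  b <- f$triplet
  expect_true(b[["alpha"]] > 0 && b[["alpha"]] <= 1)
  expect_true(b[["beta"]] > 0 && b[["beta"]] <= 20)
  expect_true(b[["chi"]] >= -2 && b[["chi"]] <= 2)
  expect_equal(f$bic, 2 * f$nll + 3 * log(f$n_trials))
  # reproducible given the same config
  f2 <- fit_mouse(rec, cfg)
  expect_identical(unclass(f$triplet), unclass(f2$triplet))
  expect_identical(f$nll, f2$nll)
})

test_that("fits beat chance on constant-side records and refuse tiny ones", {
  alll <- record_from_sides(rep("L", 40), rep(c("L", "R"), each = 20),
                            session = rep(1:2, each = 20))
  f <- fit_mouse(alll, fit_config(n_starts = 5, seed = 3))
  expect_lte(f$nll, 40 * log(2))
  tiny <- record_from_sides(rep("L", 5), rep("L", 5))
  expect_error(fit_mouse(tiny), "too few trials")
})

test_that("the nested 2-parameter model never beats the full model", {
  for (seed in c(31, 32)) {
    rec <- simulate_mouse(c(alpha = 0.5, beta = 2, chi = 0),
                          session_schedule(), seed = seed)
    cfg <- fit_config(n_starts = 8, seed = 5, v0 = 1)
    ff <- fit_mouse(rec, cfg)
    fr <- fit_reduced(rec, cfg)
    expect_gte(fr$nll, ff$nll - 1e-6)
    expect_equal(fr$triplet[["chi"]], 0)
    expect_equal(fr$bic, 2 * fr$nll + 2 * log(fr$n_trials))
    cmp <- compare_models(ff, fr)
    expect_gte(cmp$lrt_statistic, 0)
    expect_true(cmp$lrt_p >= 0 && cmp$lrt_p <= 1)
  }
})

test_that("model comparison computes the chi-square LRT correctly", {
  f1 <- structure(list(nll = 100, bic = 2 * 100 + 3 * log(300), n_trials = 300,
                       p = 3), class = "rl_fit")
  f0 <- structure(list(nll = 103, bic = 2 * 103 + 2 * log(300), n_trials = 300,
                       p = 2), class = "rl_fit")
  cmp <- compare_models(f1, f0)
  expect_equal(cmp$lrt_statistic, 6)
  expect_equal(cmp$lrt_p, 0.0143059, tolerance = 1e-4)
  same <- compare_models(f1, structure(list(nll = 100, bic = 0, n_trials = 300,
                                            p = 2), class = "rl_fit"))
  expect_equal(same$lrt_statistic, 0)
  expect_equal(same$lrt_p, 1)
  # optimizer noise: slightly better reduced fit clips to 0 with warning
  f0b <- structure(list(nll = 99.9999, bic = 0, n_trials = 300, p = 2),
                   class = "rl_fit")
  expect_warning(cmp2 <- compare_models(f1, f0b), "clipped")
  expect_equal(cmp2$lrt_statistic, 0)
  f_other <- structure(list(nll = 1, bic = 1, n_trials = 10, p = 2),
                       class = "rl_fit")
  expect_error(compare_models(f1, f_other), "different length")
})

test_that("triplet validation enforces the parameter box", {
  expect_error(latent_triplet(0, 1, 0), "bounds")
  expect_error(latent_triplet(0.5, 21, 0), "bounds")
  expect_error(latent_triplet(0.5, 1, 2.5), "bounds")
  t <- latent_triplet(1, 20, -2)
  expect_equal(unclass(t), c(alpha = 1, beta = 20, chi = -2))
})
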