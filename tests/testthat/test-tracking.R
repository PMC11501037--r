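events_df <- function(times, locs, id = "m1") {
  data.frame(mouse_id = id, time_s = times, location = locs,
             stringsAsFactors = FALSE)
}

test_that("residency episodes collapse runs and flag the open tail", {
  ev <- events_df(c(0, 100, 200), c("N", "N", "F"))
  ep <- residency_episodes(ev)
  expect_equal(ep$location, c("N", "F"))
  expect_equal(ep$start, c(0, 200))
  expect_equal(ep$duration, c(200, 0))
  expect_equal(ep$open, c(FALSE, TRUE))
  single <- residency_episodes(events_df(5, "C"))
  expect_equal(single$duration, 0)
  expect_true(single$open)
  expect_error(residency_episodes(events_df(c(10, 5), c("N", "F"))),
               "decreasing|unsorted")
  expect_error(residency_episodes(events_df(0, "Z")), "location")
})

test_that("first-order transition probabilities are direct counts", {
  ev <- events_df(seq(0, 500, 100), c("C", "N", "C", "F", "C", "F"))
  tp <- transition_probabilities(ev, 1)
  expect_equal(tp$p[tp$from == "C" & tp$to == "F"], 2 / 3)
  expect_equal(tp$p[tp$from == "C" & tp$to == "N"], 1 / 3)
  # outgoing rows always sum to 1
  sums <- tapply(tp$p, tp$from, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("second-order transitions skip the hub", {
  ev <- events_df(seq(0, 700, 100),
                  c("N", "C", "F", "C", "N", "C", "F", "C"))
  t2 <- transition_probabilities(ev, 2)
  expect_equal(t2$p[t2$from == "N" & t2$to == "F"], 1)
  expect_equal(t2$p[t2$from == "F" & t2$to == "N"], 1)
  # an animal never visiting S has no S rows (undefined, not zero)
  expect_false("S" %in% t2$from)
})

test_that("occupancy fractions and entropy behave analytically", {
  # equal dwell in all five zones -> uniform occupancy, maximal entropy
  ev <- events_df(seq(0, 500, 100), c("N", "F", "C", "S", "T", "N"))
  occ <- occupancy_fractions(ev)
  expect_equal(as.numeric(occ[1, -1]), rep(0.2, 5))
  expect_equal(sum(occ[1, -1]), 1, tolerance = 1e-9)
  act <- suppressWarnings(activity_summary(ev))
  expect_equal(act$per_animal$ena, log(5), tolerance = 1e-12)
  # single-compartment animal: zero entropy
  ev1 <- events_df(c(0, 1000, 2000), rep("N", 3))
  act1 <- suppressWarnings(activity_summary(ev1))
  expect_equal(act1$per_animal$ena, 0)
  expect_equal(act1$per_animal$nbd, 0)
})

test_that("metrics are robust to detection-rate splitting and permutation", {
  set.seed(4)
  n <- 60
  locs <- sample(c("N", "F", "C", "S"), n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
  locs <- locs[c(TRUE, diff(as.integer(factor(locs))) != 0)]
  times <- cumsum(c(0, rexp(length(locs) - 1, 1 / 300)))
  ev <- events_df(times, locs)
  # split every closed episode into repeated same-location detections
  split_ev <- do.call(rbind, lapply(seq_along(times), function(i) {
    nxt <- c(times[-1], times[length(times)])[i]
    tt <- times[i] + c(0, 30, 60)
    tt <- tt[tt == times[i] | tt < nxt]
    events_df(tt, rep(locs[i], length(tt)))
  }))
  expect_equal(occupancy_fractions(split_ev), occupancy_fractions(ev))
  expect_equal(transition_probabilities(split_ev, 1),
               transition_probabilities(ev, 1))
  # entropy depends only on dwell totals, not their order
  ep <- residency_episodes(ev)
  ep_closed <- ep[!ep$open, ]
  perm <- sample(nrow(ep_closed))
  t2 <- cumsum(c(0, ep_closed$duration[perm]))
  ev_perm <- events_df(t2, c(ep_closed$location[perm],
                             ep$location[ep$open]))
  a1 <- suppressWarnings(activity_summary(ev))$per_animal$ena
  a2 <- suppressWarnings(activity_summary(ev_perm))$per_animal$ena
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("consumption estimator subtracts the non-chosen side", {
  d <- data.frame(mouse_id = "m1", day = 1:3,
                  chosen_delta = c(4.5, 2.0, NA),
                  nonchosen_delta = c(0.6, 2.0, 0.5))
  out <- estimate_consumption(d)
  expect_equal(out$consumption_ml_day, mean(c(3.9, 0)))
  expect_equal(out$n_days, 2L)
  expect_equal(out$n_flagged, 0L)
  neg <- data.frame(mouse_id = "m2", day = 1,
                    chosen_delta = -0.4, nonchosen_delta = 0.1)
  expect_equal(estimate_consumption(neg)$n_flagged, 1L)
})

test_that("correlation module recovers exact linear relations", {
  comp <- data.frame(mouse_id = paste0("m", 1:10),
                     alpha_Tr = seq(0, 1, length.out = 10),
                     alpha_Ex = seq(1, 0, length.out = 10),
                     alpha_NS = 0.5)
  met <- data.frame(mouse_id = comp$mouse_id,
                    same = comp$alpha_Tr,
                    scaled = -2 * comp$alpha_Tr + 0.3)
  # exact linear inputs make summary.lm warn about a perfect fit; expected
  res <- suppressWarnings(correlate_with_composition(met, comp))
  expect_equal(res$r["same", "alpha_Tr"], 1)
  reg <- res$regression
  expect_equal(reg$slope[reg$metric == "same" & reg$composition == "alpha_Tr"], 1)
  expect_equal(reg$adj_r2[reg$metric == "same" & reg$composition == "alpha_Tr"], 1)
  expect_equal(res$r["scaled", "alpha_Tr"], -1)
  expect_equal(reg$slope[reg$metric == "scaled" & reg$composition == "alpha_Tr"],
               -2)
  # constant composition column -> undefined cell, not an error
  expect_true(is.na(res$r["same", "alpha_NS"]))
  # fewer than 3 pairs -> undefined
  res2 <- correlate_with_composition(met[1:2, ], comp[1:2, ])
  expect_true(all(is.na(res2$r)))
})

test_that("group statistics helper reports pairwise rank tests with Holm", {
  set.seed(8)
  v <- c(rnorm(10, 0), rnorm(10, 3), rnorm(10, 0.2))
  g <- rep(c("a", "b", "c"), each = 10)
  out <- report_group_stats(v, g)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$p_adj >= out$p))
  expect_true(out$p_adj[out$group1 == "a" & out$group2 == "b"] < 0.01)
  # identical groups: p near 1, never significant
  same <- report_group_stats(rep(1:5, 2), rep(c("x", "y"), each = 5))
  expect_gt(same$p, 0.9)
  # single group -> undefined row
  one <- report_group_stats(1:5, rep("x", 5))
  expect_true(is.na(one$p))
  kw <- report_group_stats(v, g, method = "kruskal")
  expect_equal(kw$test, "kruskal")
  expect_lt(kw$p, 0.01)
})
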