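test_that("switch index hits its anchor cases and is mirror symmetric", {
  all_l <- record_from_sides(rep("L", 20), rep("L", 20))
  expect_equal(switch_index(all_l), 0)
  even <- record_from_sides(rep(c("L", "R"), 10), rep("L", 20))
  expect_equal(switch_index(even), 1)
  skew <- record_from_sides(c(rep("L", 15), rep("R", 5)), rep("L", 20))
  expect_equal(switch_index(skew), 0.5)  # 1 - |0.75 - 0.25|
  for (seed in 1:10) {
    r <- random_record(30, seed)
    expect_equal(switch_index(r), switch_index(mirror_record(r)))
  }
})

test_that("conditional switch counts within-session pairs correctly", {
  # choices L,L,R,R,L,L with sucrose on R: low-outcome t are 1,2,5;
  # of pairs (1,2),(2,3),(5,6) only (2,3) switches
  r <- record_from_sides(c("L", "L", "R", "R", "L", "L"), rep("R", 6))
  expect_equal(conditional_switch(r, "low"), 1 / 3)
  # high-outcome t are 3,4: pairs (3,4),(4,5); (4,5) switches
  expect_equal(conditional_switch(r, "high"), 1 / 2)
  # every low-outcome trial followed by a change
  r2 <- record_from_sides(c("L", "R", "L", "R"), rep("R", 4))
  expect_equal(conditional_switch(r2, "low"), 1)
  # single-trial sessions leave no within-session pair
  r3 <- record_from_sides(c("L", "R", "L"), c("L", "R", "L"),
                          session = 1:3)
  expect_true(is.na(conditional_switch(r3, "low")))
  # session boundaries are excluded by default, included on request
  r4 <- record_from_sides(c("L", "L", "R", "R"), c("R", "R", "L", "L"),
                          session = c(1L, 1L, 2L, 2L))
  expect_equal(conditional_switch(r4, "low"), (0 + 0) / 2)
  expect_equal(conditional_switch(r4, "low", within_session_only = FALSE),
               1 / 3)
})

test_that("preference averages per-session high-side fractions", {
  # session fractions 0.8 and 0.6 -> 0.7
  ch <- c(rep("L", 8), rep("R", 2), rep("R", 6), rep("L", 4))
  hs <- rep(c("L", "R"), each = 10)
  r <- record_from_sides(ch, hs, session = rep(1:2, each = 10))
  expect_equal(preference(r), 0.7)
  perfect <- record_from_sides(rep(c("L", "R"), each = 5),
                               rep(c("L", "R"), each = 5),
                               session = rep(1:2, each = 5))
  expect_equal(preference(perfect), 1)
  half <- record_from_sides(rep(c("L", "R"), 25), rep("L", 50))
  expect_equal(preference(half), 0.5)
})

test_that("side bias folds the mean left fraction and ignores tracking", {
  always_l <- record_from_sides(rep("L", 10), rep(c("L", "R"), each = 5),
                                session = rep(1:2, each = 5))
  expect_equal(side_bias(always_l), 1)
  # per-session p_L = 0.9 and 0.7 -> |2*0.8 - 1| = 0.6
  ch <- c(rep("L", 9), "R", rep("L", 7), rep("R", 3))
  r <- record_from_sides(ch, rep(c("L", "R"), each = 10),
                         session = rep(1:2, each = 10))
  expect_equal(side_bias(r), 0.6)
  # perfect tracker across alternating sessions has no side bias
  tracker <- record_from_sides(rep(c("L", "R"), each = 10),
                               rep(c("L", "R"), each = 10),
                               session = rep(1:2, each = 10))
  expect_equal(side_bias(tracker), 0)
})

test_that("preference and side bias are invariant to session order", {
  r <- random_record(60, 3, n_sessions = 4)
  tr <- r$trials
  reord <- do.call(rbind, lapply(c(3, 1, 4, 2), function(s)
    tr[tr$session_id == s, ]))
  reord$index <- seq_len(nrow(reord))
  r2 <- mouse_record("m", reord[, c("index", "session_id", "chosen_side",
                                    "high_side")])
  expect_equal(preference(r2), preference(r))
  expect_equal(side_bias(r2), side_bias(r))
})

test_that("descriptor matrix assembles, scales and rejects properly", {
  recs <- lapply(1:6, function(i) {
    r <- random_record(40, i, n_sessions = 2)
    r$mouse_id <- paste0("m", i)
    r
  })
  co <- cohort(recs)
  M <- descriptor_matrix(co, scaling = "minmax")
  expect_equal(colnames(M), c("switch", "sw_low", "sw_high", "pref", "side_bias"))
  for (j in seq_len(5)) {
    if (attr(M, "col_maxs")[j] > attr(M, "col_mins")[j]) {
      expect_equal(min(M[, j]), 0)
      expect_equal(max(M[, j]), 1)
    }
  }
  raw <- descriptor_matrix(co, scaling = "raw")
  expect_equal(raw[3, "pref"], preference(recs[[3]]))
  # constant column -> zeros with a warning
  same <- cohort(lapply(1:4, function(i)
    record_from_sides(rep(c("L", "R"), 10), rep("L", 20), id = paste0("c", i))))
  expect_warning(Ms <- descriptor_matrix(same), "constant")
  expect_true(all(Ms[, "switch"] == 0))
  # undefined descriptors name the offending animal
  recs2 <- c(recs, list(record_from_sides("L", "L", id = "tiny")))
  expect_error(descriptor_matrix(cohort(recs2)), "tiny")
  M2 <- descriptor_matrix(cohort(recs2), na_action = "omit")
  expect_equal(nrow(M2), 6L)
})

test_that("non-switcher origin classification covers the 2x2 categories", {
  ws_l <- record_from_sides(c("R", rep("L", 9)), rep("L", 10))  # first high at t1? R vs L high: t1 low; first high trial chooses L on L
  # preferred L; first sucrose encountered on L (trial 2); categories vs WW side
  ww_l <- record_from_sides(rep("L", 8), rep("L", 8), value_high = 1)
  ww_r <- record_from_sides(rep("R", 8), rep("R", 8), value_high = 1)
  expect_equal(classify_nonswitcher_origin(ws_l, ww_l), "first-sucrose & same-WW")
  expect_equal(classify_nonswitcher_origin(ws_l, ww_r),
               "first-sucrose & opposite-WW")
  # preferred L but sucrose first found on R
  ws_r <- record_from_sides(c("R", rep("L", 9)), rep("R", 10))
  expect_equal(classify_nonswitcher_origin(ws_r, ww_r),
               "opposite-first-sucrose & opposite-WW")
  expect_equal(classify_nonswitcher_origin(ws_r, ww_l),
               "opposite-first-sucrose & same-WW")
  # degenerate cases: no sucrose found, or an exact 50/50 split
  no_hit <- record_from_sides(rep("L", 10), rep("R", 10))
  expect_true(is.na(classify_nonswitcher_origin(no_hit, ww_l)))
  split <- record_from_sides(rep(c("L", "R"), 5), rep("L", 10))
  expect_true(is.na(classify_nonswitcher_origin(split, ww_l)))
})
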