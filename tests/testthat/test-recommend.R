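cfg <- tscs_protocol()

muscles <- c("LQ", "LTS", "RQ", "RTS")

# rating with given green pattern: greens[[k]] = (n, I) pairs green for
# muscle k; everything else no_response
rating_with_greens <- function(grid, greens_by_cell) {
  df <- expand.grid(muscle = muscles, electrode_position = grid$n,
                    amplitude_mA = grid$I, stringsAsFactors = FALSE)
  df <- unique(df)
  df$label <- "no_response"
  for (g in greens_by_cell) {
    sel <- df$electrode_position == g[1] & df$amplitude_mA == g[2] &
      df$muscle %in% muscles[seq_len(g[3])]
    df$label[sel] <- "reflex"
  }
  rating_from_spec(df)
}

test_that("amplitude threshold is the first green at each electrode", {
  r <- rating_with_greens(list(n = 1:4, I = seq(5, 75, 5)),
                          list(c(2, 40, 2), c(2, 45, 4), c(3, 25, 2),
                               c(3, 30, 2)))
  thr <- tscs_amplitude_thresholds(r)
  expect_equal(thr$threshold_mA[thr$electrode_position == 2], 40)
  expect_equal(thr$threshold_mA[thr$electrode_position == 3], 25)
  expect_true(is.na(thr$threshold_mA[thr$electrode_position == 4]))
})

test_that("ranking priorities: green count, then distance to threshold, then amplitude", {
  # A: 4 greens at I - I' = 5; B: 3 greens at I - I' = 0 -> A above B
  r <- rating_with_greens(list(n = 1:2, I = seq(35, 45, 5)),
                          list(c(1, 40, 2), c(1, 45, 4), c(2, 40, 3)))
  rk <- tscs_rank_pairs(r, cfg = cfg)
  expect_equal(rk$electrode_position[1], 1)
  expect_equal(rk$amplitude_mA[1], 45)
  expect_equal(rk$green_count[1], 4)

  # equal green counts: smaller I - I' wins
  r2 <- rating_with_greens(list(n = 1:2, I = seq(30, 45, 5)),
                           list(c(1, 30, 3), c(1, 40, 3), c(2, 35, 3)))
  rk2 <- tscs_rank_pairs(r2, cfg = cfg)
  expect_equal(rk2$delta_threshold_mA, c(0, 0, 10))
  # residual tie at delta = 0 and equal I is impossible here; equal delta
  # resolves by lower amplitude
  expect_equal(rk2$amplitude_mA[1:2], c(30, 35))
})

test_that("pairs below the minimal requirement are never ranked", {
  r <- rating_with_greens(list(n = 1:2, I = c(40, 45)), list(c(1, 40, 1)))
  expect_equal(nrow(tscs_rank_pairs(r, cfg = cfg)), 0)
})

test_that("ranking equals the brute-force lexicographic oracle", {
  set.seed(101)
  for (i in 1:200) {
    r <- random_rating(n_pos = sample(2:4, 1), n_amp = sample(3:8, 1))
    thr <- tscs_amplitude_thresholds(r)
    rk <- tscs_rank_pairs(r, thr, cfg)
    cells <- data.frame(n = r$electrode_position, I = r$amplitude_mA,
                        green = as.integer(r$label == "reflex"))
    oracle <- rank_oracle(cells, thr, cfg$min_green_muscles)
    expect_equal(nrow(rk), nrow(oracle))
    if (nrow(rk) > 0) {
      expect_equal(rk$electrode_position, oracle$n)
      expect_equal(rk$amplitude_mA, oracle$I)
      expect_equal(rk$green_count, oracle$green)
      expect_equal(rk$rank, oracle$rank)
    }
  }
})

test_that("cost function normalizes per muscle and averages over muscles", {
  # all four muscles at their own maxima with complete suppression: J = 1
  df <- expand.grid(muscle = muscles, electrode_position = 1L,
                    amplitude_mA = c(40, 45), stringsAsFactors = FALSE)
  df$label <- "reflex"
  df$amp1_uV <- ifelse(df$amplitude_mA == 45, c(100, 200, 300, 400), 10)
  df$suppression <- 1
  r <- rating_from_spec(df)
  J <- tscs_cost_scores(r, cfg)
  expect_equal(J$J[J$amplitude_mA == 45], 1)
  expect_equal(J$J[J$amplitude_mA == 40],
               mean(10 / c(100, 200, 300, 400)))

  # hand-built 2x2 grid, frozen against a spreadsheet-style recomputation
  df2 <- expand.grid(muscle = muscles, electrode_position = 1:2,
                     amplitude_mA = 40, stringsAsFactors = FALSE)
  df2$label <- "reflex"
  df2$amp1_uV <- c(100, 50, 200, 80,   # n = 1
                   300, 150, 100, 20)  # n = 2
  df2$suppression <- c(0.9, 0.8, 0.7, 1.0,
                       0.5, 0.6, 0.9, 0.2)
  r2 <- rating_from_spec(df2)
  J2 <- tscs_cost_scores(r2, cfg)
  # per-muscle maxima: LQ 300, LTS 150, RQ 200, RTS 80
  j_n1 <- (100/300*0.9 + 50/150*0.8 + 200/200*0.7 + 80/80*1.0) / 4
  j_n2 <- (300/300*0.5 + 150/150*0.6 + 100/200*0.9 + 20/80*0.2) / 4
  expect_equal(J2$J[J2$electrode_position == 1], j_n1)
  expect_equal(J2$J[J2$electrode_position == 2], j_n2)

  # invalid cells and all-zero muscles contribute nothing
  df3 <- df2
  df3$label[df3$electrode_position == 2] <- "invalid"
  df3$amp1_uV[df3$electrode_position == 2] <- NA
  df3$suppression[df3$electrode_position == 2] <- NA
  J3 <- tscs_cost_scores(rating_from_spec(df3), cfg)
  expect_equal(J3$J[J3$electrode_position == 2], 0)
})

test_that("J is invariant to rescaling one muscle's amplitudes", {
  set.seed(55)
  r <- random_rating(n_pos = 3, n_amp = 6)
  J1 <- tscs_cost_scores(r, cfg)
  r2 <- r
  sel <- r2$muscle == "LTS"
  r2$amp1_uV[sel] <- r2$amp1_uV[sel] * 7.3
  r2$amp2_uV[sel] <- r2$amp2_uV[sel] * 7.3  # suppression unchanged
  J2 <- tscs_cost_scores(r2, cfg)
  expect_equal(J1$J, J2$J, tolerance = 1e-12)
})

test_that("recommendation applies the 90% rule with grid flooring", {
  r <- rating_with_greens(list(n = 1:4, I = seq(5, 75, 5)),
                          list(c(2, 40, 2), c(2, 45, 4)))
  rec <- tscs_recommend(r, cfg)
  expect_equal(rec$status, "ok")
  expect_equal(rec$ranking$electrode_position, 2)
  expect_equal(rec$ranking$threshold_mA, 40)
  expect_equal(rec$ranking$therapy_mA, 35)  # 0.9 * 40 = 36 -> grid floor 35
  expect_equal(rec$cost$electrode_position, 2)
  expect_true(rec$agreement)

  cfg_none <- tscs_protocol(rounding = "none")
  r20 <- rating_with_greens(list(n = 1:2, I = seq(5, 75, 5)),
                            list(c(1, 20, 2)))
  rec20 <- tscs_recommend(r20, cfg_none)
  expect_equal(rec20$ranking$therapy_mA, 18)  # exact 0.9 * 20
})

test_that("no candidate pair yields an absent recommendation with a reason", {
  df <- expand.grid(muscle = muscles, electrode_position = 1:4,
                    amplitude_mA = seq(5, 75, 5), stringsAsFactors = FALSE)
  df$label <- "no_response"
  rec <- tscs_recommend(rating_from_spec(df), cfg)
  expect_equal(rec$status, "none")
  expect_match(rec$reason, "at least 2 muscles")
  expect_equal(nrow(rec$rank_table), 0)
  td <- tidy(rec)
  expect_true(all(is.na(td$therapy_mA)))
})

test_that("therapy amplitude is always sub-threshold", {
  for (thr in seq(10, 75, 5)) {
    r <- rating_with_greens(list(n = 1L, I = seq(5, 75, 5)),
                            list(c(1, thr, 2)))
    rec <- tscs_recommend(r, cfg)
    expect_lt(rec$ranking$therapy_mA, thr)
  }
})

test_that("removing an electrode preserves the relative order of the rest", {
  set.seed(77)
  for (i in 1:50) {
    r <- random_rating(n_pos = 4, n_amp = 6)
    rk_full <- tscs_rank_pairs(r, cfg = cfg)
    drop_n <- sample(1:4, 1)
    r_sub <- dplyr::filter(r, electrode_position != drop_n)
    rk_sub <- tscs_rank_pairs(r_sub, cfg = cfg)
    kept <- dplyr::filter(rk_full, electrode_position != drop_n)
    expect_equal(rk_sub$electrode_position, kept$electrode_position)
    expect_equal(rk_sub$amplitude_mA, kept$amplitude_mA)
  }
})

test_that("tidy and glance summarize a recommendation", {
  r <- rating_with_greens(list(n = 1:2, I = seq(5, 75, 5)),
                          list(c(2, 40, 2), c(2, 45, 4)))
  rec <- tscs_recommend(r, cfg)
  td <- tidy(rec)
  expect_equal(td$method, c("ranking", "cost"))
  expect_equal(td$therapy_mA, c(35, 35))
  gl <- glance(rec)
  expect_equal(gl$status, "ok")
  expect_true(gl$agreement)
})
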