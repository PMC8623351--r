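cfg <- tscs_protocol()

aligned_tibble <- function(series_by_muscle, status = "aligned",
                           n = 1, I = 5, j = 1) {
  tibble::tibble(
    electrode_position = n, amplitude_mA = I, repetition = j,
    muscle = names(series_by_muscle), status = status,
    onset = ifelse(status == "aligned", 40L, NA_integer_),
    samples = unname(series_by_muscle))
}

test_that("prefiltering removes offsets and keeps blanks exactly zero", {
  const <- rep(12.5, 331)
  synced <- aligned_tibble(list(LQ = const, LTS = const, RQ = const,
                                RTS = const))
  filt <- tscs_prefilter(synced, cfg)
  expect_true(all(purrr::map_lgl(filt$samples,
                                 ~ isTRUE(all.equal(.x, rep(0, 331))))))

  set.seed(2)
  x <- rnorm(331, 0, 20)
  filt2 <- tscs_prefilter(aligned_tibble(list(LQ = x, LTS = x, RQ = x,
                                              RTS = x)), cfg)
  y <- filt2$samples[[1]]
  # blank windows -2..2 ms and 48..52 ms -> indices 29:33 and 79:83
  expect_equal(y[29:33], rep(0, 5))
  expect_equal(y[79:83], rep(0, 5))
})

test_that("the band-stop suppresses 45 Hz interference", {
  # a narrow 4 Hz-wide notch settles over ~250 ms, so attenuation is
  # assessed on a long window away from the edges (baseline sweeps are
  # filtered without blanking and may have any length)
  t <- (0:999) / 1000
  x <- sin(2 * pi * 45 * t)
  filt <- tscs_prefilter(aligned_tibble(list(LQ = x, LTS = x, RQ = x,
                                             RTS = x), status = "baseline"),
                         cfg)
  y <- filt$samples[[1]]
  expect_lt(max(abs(y[200:800])), 0.05)
})

test_that("filtering is zero-phase: symmetric pulses keep their peak", {
  x <- exp(-((1:331 - 166) / 12)^2)
  y <- tscscalib:::prefilter_series(x, cfg, blank = FALSE)
  expect_lte(abs(which.max(y) - 166), 1)
  # and the pulse stays symmetric about its peak
  expect_lt(max(abs(y[166 - (1:30)] - y[166 + (1:30)])), 1e-3)
})

test_that("noise profile pools the late window and estimates the SD", {
  flat <- rep(7, 331)
  tib <- dplyr::bind_rows(lapply(1:3, function(j) aligned_tibble(
    list(LQ = flat, LTS = flat, RQ = flat, RTS = flat), j = j)))
  prof <- tscs_noise_profile(tib, cfg)
  expect_equal(prof$noise_uV, rep(0, 4))

  set.seed(31)
  reps <- lapply(1:60, function(j) {
    x <- rnorm(331, 0, 5)
    aligned_tibble(list(LQ = x, LTS = -x, RQ = x, RTS = x), j = j)
  })
  tib2 <- dplyr::bind_rows(reps)
  prof2 <- tscs_noise_profile(tib2, cfg)  # 60 x 201 > 1e4 pooled samples
  expect_true(all(abs(prof2$noise_uV - 5) / 5 < 0.05))
  # SD is symmetric under sign flip: LTS got -x and matches LQ exactly
  expect_equal(prof2$noise_uV[prof2$muscle == "LTS"],
               prof2$noise_uV[prof2$muscle == "LQ"])

  expect_error(
    tscs_noise_profile(dplyr::filter(tib2, muscle != "RTS"), cfg), "RTS")
})

test_that("similarity gate keeps replicating sweeps and drops outliers", {
  set.seed(4)
  base <- rnorm(331, 0, 3)
  noise_uV <- 3
  # identical repetitions: RMSE 0, all kept
  g <- tscs_similarity_gate(list(base, base, base), noise_uV, cfg)
  expect_true(g$valid)
  expect_equal(g$keep, 1:3)

  # constant offset of 20x the noise level: RMSE equals the offset, which
  # exceeds the 16x gate, so the outlier is dropped
  g2 <- tscs_similarity_gate(list(base, base, base + 20 * noise_uV),
                             noise_uV, cfg)
  expect_true(g2$valid)
  expect_equal(g2$keep, 1:2)

  # three mutually dissimilar repetitions: invalid
  g3 <- tscs_similarity_gate(list(base, base + 60, base - 60), noise_uV, cfg)
  expect_false(g3$valid)

  # fewer than two repetitions: invalid with explicit reason
  g4 <- tscs_similarity_gate(list(base), noise_uV, cfg)
  expect_false(g4$valid)
  expect_match(g4$reason, "insufficient")
})

test_that("the kept subset is maximal and the relation symmetric", {
  set.seed(9)
  for (i in 1:50) {
    reps <- lapply(1:3, function(j) rnorm(331, 0, runif(1, 1, 40)))
    noise_uV <- 2
    idx <- c(36:76, 86:126)
    sim <- function(a, b)
      sqrt(mean((reps[[a]][idx] - reps[[b]][idx])^2)) < 16 * noise_uV
    pairs_ok <- c(sim(1, 2), sim(1, 3), sim(2, 3))
    subsets <- list(1:3, c(1, 2), c(1, 3), c(2, 3))
    ok <- c(all(pairs_ok), pairs_ok[1], pairs_ok[2], pairs_ok[3])
    expected <- if (any(ok)) subsets[[which(ok)[1]]] else integer(0)
    g <- tscs_similarity_gate(reps, noise_uV, cfg)
    expect_equal(g$keep, expected)
    expect_equal(g$valid, length(expected) >= 2)
  }
})

test_that("averaging is the pointwise mean over the response window", {
  # small amplitude so every pair passes the 16x-noise similarity gate
  x <- sin((1:331) / 10) * 5
  make <- function(series, j) aligned_tibble(
    list(LQ = series, LTS = series, RQ = series, RTS = series), j = j)
  noise <- tibble::tibble(muscle = c("LQ", "LTS", "RQ", "RTS"), noise_uV = 3)

  # mean of identical sweeps is that sweep, cropped to -1..200 ms (202 samples)
  tib <- dplyr::bind_rows(make(x, 1), make(x, 2), make(x, 3))
  avg <- tscs_average_responses(tib, noise, cfg)
  expect_true(all(avg$status == "averaged"))
  expect_true(all(avg$n_averaged == 3))
  expect_equal(avg$mean_series[[1]], x[30:231])

  # mean of x and -x vanishes
  tib2 <- dplyr::bind_rows(make(x, 1), make(-x, 2))
  avg2 <- tscs_average_responses(tib2, noise, cfg)
  expect_equal(avg2$mean_series[[1]], rep(0, 202))

  # sweeps differing by a constant average to the midpoint
  tib3 <- dplyr::bind_rows(make(x, 1), make(x + 10, 2))
  avg3 <- tscs_average_responses(tib3, noise, cfg)
  expect_equal(avg3$mean_series[[1]], x[30:231] + 5)
})

test_that("baseline-only cells are kept, unusable cells are invalid", {
  x <- rep(1, 331)
  noise <- tibble::tibble(muscle = c("LQ", "LTS", "RQ", "RTS"), noise_uV = 3)
  mk <- function(status, j) aligned_tibble(
    list(LQ = x, LTS = x, RQ = x, RTS = x), status = status, j = j)
  bl <- dplyr::bind_rows(mk("baseline", 1), mk("baseline", 2),
                         mk("discarded", 3))
  avg <- tscs_average_responses(bl, noise, cfg)
  expect_true(all(avg$status == "baseline"))

  bad <- dplyr::bind_rows(mk("aligned", 1), mk("discarded", 2),
                          mk("discarded", 3))
  avg2 <- tscs_average_responses(bad, noise, cfg)
  expect_true(all(avg2$status == "invalid"))
  expect_true(all(avg2$reason == "insufficient repetitions"))
})
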