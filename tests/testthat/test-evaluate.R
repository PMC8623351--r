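cfg <- tscs_protocol()

test_that("peak-to-peak measures max minus min in the response windows", {
  s <- numeric(202)
  # first-response window is 10..45 ms after the stimulus (indices 12:47)
  s[20] <- 300; s[26] <- -100
  expect_equal(tscs_peak_to_peak(s, "first", cfg), 400)
  expect_equal(tscs_peak_to_peak(numeric(202), "first", cfg), 0)
  # second window is shifted by the 50 ms inter-pulse interval (60..95 ms)
  s2 <- numeric(202); s2[70] <- 120; s2[75] <- -30
  expect_equal(tscs_peak_to_peak(s2, "second", cfg), 150)
  expect_error(tscs_peak_to_peak(numeric(50), "second", cfg), "beyond")
})

test_that("peak-to-peak agrees with a brute-force scan over the samples", {
  set.seed(21)
  t_axis <- -1 + (0:201)  # ms at 1 kHz
  for (i in 1:25) {
    s <- rnorm(202, 0, 50)
    for (w in list(c(10, 45), c(60, 95))) {
      inside <- which(t_axis >= w[1] & t_axis <= w[2])
      oracle <- max(s[inside]) - min(s[inside])
      got <- tscs_peak_to_peak(s, if (w[1] == 10) "first" else "second", cfg)
      expect_equal(got, oracle)
    }
  }
})

test_that("suppression ratio is 1 - amp2/amp1 clipped to [0, 1]", {
  expect_equal(tscs_suppression(400, 0), 1)    # complete suppression
  expect_equal(tscs_suppression(400, 400), 0)  # equal responses: M-wave-like
  expect_equal(tscs_suppression(100, 150), 0)  # facilitation clips to 0
  expect_equal(tscs_suppression(100, 40), 0.6)
  expect_equal(tscs_suppression(0, 50), 0)     # no first response: defined 0
  # scale invariance
  expect_equal(tscs_suppression(37 * 5, 11 * 5), tscs_suppression(37, 11))
})

test_that("classification follows the four-color rules", {
  expect_equal(tscs_classify(100, 0.8, 5), "reflex")
  expect_equal(tscs_classify(100, 0.5, 5), "m_wave")
  expect_equal(tscs_classify(40, 0.9, 2), "no_response")   # 50 uV gate
  expect_equal(tscs_classify(100, 0.9, 20), "no_response") # 6 SD gate
  expect_equal(tscs_classify(100, 0.8, 5, valid = FALSE), "invalid")
})

test_that("rules are exhaustive, mutually exclusive, and strict at bounds", {
  noise_uV <- 8  # 6x noise = 48 < 50, so the absolute gate binds
  for (amp1 in seq(0, 200, by = 2)) {
    for (sup in seq(0, 1, by = 0.05)) {
      for (valid in c(TRUE, FALSE)) {
        lab <- tscs_classify(amp1, sup, noise_uV, valid, cfg)
        expected <- if (!valid) "invalid"
        else if (amp1 <= 50 || amp1 <= 48) "no_response"
        else if (sup > 0.6) "reflex"
        else "m_wave"
        expect_equal(lab, expected)
      }
    }
  }
  # boundary strictness: both gates use strict >, and so does suppression
  expect_equal(tscs_classify(50, 0.9, 1), "no_response")
  expect_equal(tscs_classify(60, 0.9, 10), "no_response")
  expect_equal(tscs_classify(100, 0.6, 5), "m_wave")
  expect_equal(tscs_classify(100, 0.6 + 1e-9, 5), "reflex")
})

test_that("the rating matrix labels every cell and carries features", {
  cfg2 <- small_cfg(positions = 1:2, amps = c(35, 40, 45))
  sess <- tscs_simulate_session(tscs_sim_truth(cfg2), cfg2, seed = 17)
  synced <- tscs_synchronize(sess, cfg2)
  filt <- tscs_prefilter(synced, cfg2)
  noise <- tscs_noise_profile(filt, cfg2)
  resp <- tscs_average_responses(filt, noise, cfg2)
  rating <- tscs_rate(resp, noise, cfg2)
  expect_equal(nrow(rating), 4 * 2 * 3)
  expect_true(all(rating$label %in% c("no_response", "reflex", "m_wave",
                                      "invalid")))
  expect_true(all(is.na(rating$amp1_uV[rating$label == "invalid"])))
  expect_true(all(!is.na(rating$amp1_uV[rating$label != "invalid"])))
  expect_equal(unname(c(no_response = "gray", reflex = "green",
                        m_wave = "yellow", invalid = "red")[rating$label]),
               rating$color)
  # electrode 2 recruits triceps surae reflexes from 40 mA in this truth
  r <- dplyr::filter(rating, electrode_position == 2, muscle == "LTS")
  expect_equal(r$label[r$amplitude_mA == 35], "no_response")
  expect_equal(r$label[r$amplitude_mA == 40], "reflex")
})

test_that("an invalid cell produces invalid labels in all muscles there", {
  cfg2 <- small_cfg(positions = 1L, amps = c(40, 45))
  truth <- tscs_sim_truth(cfg2, recruitment = tibble::tibble(
    muscle = rep(c("LQ", "LTS", "RQ", "RTS"), 1),
    electrode_position = 1L,
    type = "reflex", threshold_mA = 40, suppression = 0.85,
    latency_ms = c(12, 20, 12, 20), max_amp_uV = 400),
    corrupt_rate = 0)
  sess <- tscs_simulate_session(truth, cfg2, seed = 2)
  # corrupt all three repetitions of (n=1, I=45) with mutually dissimilar
  # early movement bursts (samples 40..130, i.e. inside the similarity
  # windows of every jittered onset but clear of the noise window)
  idx <- which(sess$electrode_position == 1 & sess$amplitude_mA == 45)
  tau <- 0:90
  for (k in seq_along(idx)) {
    rep_id <- sess$repetition[idx[k]]
    burst <- 800 * rep_id * sin(pi * tau / 90) *
      sin(2 * pi * 11 * tau / 1000 + rep_id)
    x <- sess$samples[[idx[k]]]
    x[40 + tau] <- x[40 + tau] + burst
    sess$samples[[idx[k]]] <- x
  }
  cal <- tscs_calibrate(sess, cfg2)
  bad <- dplyr::filter(cal$rating, amplitude_mA == 45)
  expect_true(all(bad$label == "invalid"))
  good <- dplyr::filter(cal$rating, amplitude_mA == 40)
  expect_true(all(good$label != "invalid"))
})
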