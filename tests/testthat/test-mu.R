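test_that("multitaper power concentrates at the sinusoid frequency", {
  fs <- 200
  x <- sin(2 * pi * 10 * seq(0, 0.995, by = 1 / fs))
  in_band <- multitaper_band_power(x, fs, 9, 12)
  out_band <- multitaper_band_power(x, fs, 15, 18)
  expect_gte(in_band / out_band, 100)
  expect_equal(multitaper_band_power(numeric(200), fs, 9, 12), 0)
  expect_error(multitaper_band_power(x, fs, 90, 110), "Nyquist")
})

test_that("multitaper PSD integrates to the variance (Parseval, 200 seeds)", {
  fs <- 200
  set.seed(7)
  totals <- replicate(200, {
    x <- stats::rnorm(fs, sd = 2)
    sp <- multitaper_psd(x, fs)
    sum(sp$psd) * (fs / length(x)) # df = 1 Hz
  })
  expect_equal(mean(totals), 4, tolerance = 0.1)
})

test_that("DPSS tapers are orthonormal with near-unity concentrations", {
  dp <- dpss_tapers(200, nw = 2, k = 3)
  gram <- crossprod(dp$tapers)
  expect_equal(gram, diag(3), tolerance = 1e-8)
  expect_true(all(dp$eigen > 0.9))
  expect_true(all(diff(dp$eigen) < 0)) # ordered by concentration
})

test_that("suppression score matches its closed form and sign convention", {
  expect_equal(mu_suppression_score(1.0, 1.0), 0, tolerance = 1e-12)
  expect_equal(mu_suppression_score(0.5, 1.0), 50, tolerance = 1e-12)
  expect_equal(mu_suppression_score(1.2, 1.0), -20, tolerance = 1e-12)
  expect_error(mu_suppression_score(1, 0), "positive")
  expect_error(mu_suppression_score(1, -2), "positive")

  # sign property and scale invariance, exactly
  set.seed(11)
  task <- stats::runif(50, 0.01, 3)
  rest <- stats::runif(50, 0.01, 3)
  s <- mu_suppression_score(task, rest)
  expect_identical(s > 0, task < rest)
  for (c_scale in c(1e-6, 0.5, 7, 1e6)) {
    expect_equal(mu_suppression_score(task * c_scale, rest * c_scale), s,
                 tolerance = 1e-12)
  }
})

test_that("sliding search grid covers 13 windows of 3 Hz at 1 Hz steps", {
  w <- miconn:::mu_band_windows(c(5, 20), 3, 1)
  expect_equal(nrow(w), 13)
  expect_equal(w$lo[1], 5)
  expect_equal(w$hi[1], 8)
  expect_equal(w$lo[13], 17)
  expect_equal(w$hi[13], 20)
})

test_that("band selection recovers a planted 9-12 Hz suppression (seed 3)", {
  sim <- simulate_recording(sim_config(n_sessions = 1,
                                       trials_per_session = 120,
                                       erd_depth = 0.5, seed = 3))
  sel <- select_mu_band(sim$recording)
  expect_lte(abs(sel$lo - 9), 1)
  expect_lte(abs(sel$hi - 12), 1)
  # the chosen window's tabulated score dominates the table
  expect_true(all(sel$score >= sel$table$score - 1e-12))
  expect_equal(sel$score,
               sel$table$score[sel$table$lo == sel$lo & sel$table$hi == sel$hi])
})

test_that("exact ties break toward the lowest-frequency window", {
  # task window identical to rest window -> every per-trial score is exactly
  # 0 for every candidate band -> full tie
  fs <- 200
  n <- 401
  arr <- array(0, c(4, 19, n))
  set.seed(5)
  for (i in 1:4) {
    for (c in 1:19) {
      seg <- stats::rnorm(200)
      arr[i, c, ] <- c(seg, seg, 0)
    }
  }
  rec <- epoched_recording(
    arr, fs, seq(-200, 200) / fs,
    tibble::tibble(trial = 1:4, task = c("left", "right", "left", "right"),
                   session = 1L, day = 1L)
  )
  sel <- select_mu_band(rec)
  expect_equal(c(sel$lo, sel$hi), c(5, 8))
  expect_equal(sel$score, 0, tolerance = 1e-9)
})

test_that("musc_series blocks pool tasks and respect chronology", {
  sim <- small_sim()
  rec <- select_trials(sim$recording, tasks = c("left", "right"))
  ms <- musc_series(rec, c(9, 12), block_size = 20)
  expect_s3_class(ms, "musc_series")
  # 60 non-hold trials -> 3 blocks per role
  expect_equal(sum(ms$channel_role == "contra"), 3)
  expect_equal(sum(ms$channel_role == "ipsi"), 3)
  expect_true(all(ms$n_trials == 20))
  expect_true(all(is.finite(ms$musc)))
})

test_that("musc_series can synchronize days", {
  sims <- lapply(1:2, function(d) {
    simulate_recording(sim_config(n_sessions = 1, trials_per_session = 60,
                                  day = d, seed = d))$recording
  })
  sims[[2]]$meta$trial <- sims[[2]]$meta$trial + 60L
  rec <- bind_recordings(sims)
  ms <- musc_series(select_trials(rec, tasks = c("left", "right")),
                    c(9, 12), synchronize_days = TRUE)
  expect_false("day" %in% names(ms))
  expect_equal(sum(ms$channel_role == "contra"), 2) # 40 non-hold per day
})
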