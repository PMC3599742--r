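test_that("all generators are seed-deterministic and emit positive intervals", {
  gens <- list(
    function(s) generate_wnu(300, seed = s),
    function(s) generate_af(300, seed = s),
    function(s) generate_chf(300, seed = s),
    function(s) generate_healthy(300, seed = s),
    function(s) generate_apnea(300, seed = s)
  )
  for (g in gens) {
    a <- g(11)
    b <- g(11)
    c_ <- g(12)
    expect_identical(a$intervals, b$intervals)
    expect_false(identical(a$intervals, c_$intervals))
    expect_true(all(a$intervals > 0))
  }
})

test_that("white-noise generator matches its uniform model", {
  r <- generate_wnu(15000, low = 600, high = 1400, seed = 2)
  # CLT bound: mean 1000, sd of the mean = (800/sqrt(12))/sqrt(n)
  se <- (800 / sqrt(12)) / sqrt(15000)
  expect_lt(abs(mean(r$intervals) - 1000), 3 * se)
  expect_identical(r$label, "WNU")

  near_const <- generate_wnu(100, low = 800, high = 800.001, seed = 1)
  expect_lt(diff(range(near_const$intervals)), 0.01)

  expect_error(generate_wnu(100, low = 0, high = 10), "positive")
  expect_error(generate_wnu(100, low = 900, high = 800), "exceed")
})

test_that("healthy generator limits behave as specified", {
  flat <- generate_healthy(50, osc_amplitude = 0, noise_sd = 0, seed = 1)
  expect_equal(diff(range(flat$intervals)), 0)

  # ar_coeff = 0: lag-1 autocorrelation of the noise is near zero
  r <- generate_healthy(5000, osc_amplitude = 0, ar_coeff = 0, noise_sd = 20,
                        seed = 3)
  ac <- stats::acf(r$intervals, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(ac), 3 / sqrt(5000))

  # pure sinusoid: the difference sequence is periodic with the oscillation period
  s <- generate_healthy(200, osc_amplitude = 50, osc_period_beats = 5,
                        noise_sd = 0, seed = 1)
  d <- compute_rrid(s)$diffs
  expect_equal(d[1:20], d[6:25], tolerance = 1e-9)
})

test_that("AF generator yields uncorrelated heavy-variance intervals", {
  r <- generate_af(8000, seed = 5)
  ac <- stats::acf(r$intervals, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(ac), 3 / sqrt(8000))

  # RRID sd of an i.i.d. series is sd * sqrt(2); use unclipped parameters
  r2 <- generate_af(8000, mean_rr = 1000, sd = 100, seed = 6)
  d <- compute_rrid(r2)$diffs
  expect_equal(stats::sd(d), 100 * sqrt(2), tolerance = 0.05)

  expect_equal(diff(range(generate_af(100, sd = 0, seed = 1)$intervals)), 0)
})

test_that("CHF generator has rare jumps and suppressed variability", {
  r <- generate_chf(5000, jump_prob = 0.02, jump_scale = 200, base_sd = 2,
                    ar_coeff = 0, seed = 7)
  jumps <- sum(abs(compute_rrid(r)$diffs) > 100)
  # each jump shows up in ~2 differences; binomial 3-sigma band on 5000*0.02
  expect_gt(jumps, 2 * (100 - 3 * sqrt(100 * 0.98)))
  expect_lt(jumps, 2 * (100 + 3 * sqrt(100 * 0.98)) + 10)

  near_const <- generate_chf(200, jump_prob = 0, base_sd = 0.001, seed = 1)
  expect_lt(diff(range(near_const$intervals)), 1)

  # preset SDNN ordering: CHF below healthy-young variability
  chf <- generate_chf(2000, seed = 8)
  hy <- generate_healthy(2000, seed = 9)
  expect_lt(stats::sd(chf$intervals), stats::sd(hy$intervals))
})

test_that("apnea generator produces the cyclic oscillation", {
  # noise-free: dominant DFT peak at frequency 1/cycle_period
  r <- generate_apnea(1200, cycle_amplitude = 100, cycle_period_beats = 40,
                      noise_sd = 0, seed = 1)
  x <- r$intervals - mean(r$intervals)
  spec <- Mod(stats::fft(x))[2:(length(x) / 2)]
  peak_freq <- which.max(spec) / length(x)
  expect_equal(peak_freq, 1 / 40, tolerance = 1e-3)

  # zero cycle amplitude reduces to the healthy generator without oscillation
  a <- generate_apnea(300, mean_rr = 900, cycle_amplitude = 0, ar_coeff = 0.7,
                      noise_sd = 8, seed = 4)
  h <- generate_healthy(300, mean_rr = 900, osc_amplitude = 0, ar_coeff = 0.7,
                        noise_sd = 8, seed = 4)
  expect_identical(a$intervals, h$intervals)
})

test_that("study presets produce the documented class structure", {
  s1 <- generate_study("study1", seed = 1, length = 120)
  expect_length(s1, 142L)
  expect_equal(as.vector(table(corpus_labels(s1))[c("AF", "CHF", "HE", "HY", "WNU")]),
               c(9, 43, 20, 20, 50))

  s2 <- generate_study("study2", seed = 1, length = 120)
  expect_length(s2, 80L)
  expect_equal(as.vector(table(corpus_labels(s2))), rep(20, 4))

  # identical master seed: byte-identical corpus
  expect_identical(generate_study("study1", seed = 5, length = 100),
                   generate_study("study1", seed = 5, length = 100))
  expect_false(identical(generate_study("study1", seed = 5, length = 100),
                         generate_study("study1", seed = 6, length = 100)))
})

test_that("per-record seeds follow the master-seed-plus-index rule", {
  s2 <- generate_study("study2", seed = 100, length = 50)
  direct <- generate_apnea(50, seed = 101L, record_id = "APNEA_001")
  expect_identical(s2[[1]]$intervals, direct$intervals)
})
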