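# Evaluation statistics: grand averages, window amplitudes, split-half
# SNR, score-cycle regression, distribution tests.

test_that("grand averages are per-condition means over kept trials", {
  ep <- make_test_epochs(n_s = 4, n_n = 4, n_ch = 2, n_t = 20, seed = 1)
  ep$data[1:4, , ] <- rep(ep$data[1, , ], each = 4)   # identical epochs
  erp <- grand_average(ep)
  expect_equal(erp$waveforms$smoking, ep$data[1, , ])
  expect_equal(erp$n_trials[["smoking"]], 4)
  # rejected trials are excluded
  ep2 <- make_test_epochs(n_s = 4, n_n = 4, n_ch = 2, n_t = 20, seed = 2)
  ep2$data[1, , ] <- 1e4
  ep2$kept[1] <- FALSE
  erp2 <- grand_average(ep2)
  manual <- apply(ep2$data[2:4, , , drop = FALSE], c(2, 3), mean)
  expect_equal(erp2$waveforms$smoking, manual)
  ep2$kept[ep2$labels == "neutral"] <- FALSE
  expect_error(grand_average(ep2), "no kept trials")
})

test_that("grand averaging is linear in the epoch data", {
  a <- make_test_epochs(n_s = 3, n_n = 3, n_ch = 2, n_t = 10, seed = 3)
  b <- make_test_epochs(n_s = 3, n_n = 3, n_ch = 2, n_t = 10, seed = 4)
  ab <- a; ab$data <- a$data + b$data
  expect_equal(grand_average(ab)$waveforms$smoking,
               grand_average(a)$waveforms$smoking +
               grand_average(b)$waveforms$smoking)
})

test_that("window amplitude summarizes boxcars exactly", {
  fs <- 250; n_t <- 300
  times <- seq(-200, by = 4, length.out = n_t)
  wave <- matrix(0, 1, n_t)
  erp0 <- structure(list(waveforms = list(smoking = wave),
                         n_trials = c(smoking = 10), times_ms = times,
                         channel_labels = "Pz"), class = "erp_result")
  expect_equal(p300_amplitude(erp0)[["smoking"]], 0)
  # boxcar exactly on the window
  on <- times >= 300 & times < 550
  wave1 <- wave; wave1[1, on] <- 5
  erp1 <- erp0; erp1$waveforms$smoking <- wave1
  expect_equal(p300_amplitude(erp1)[["smoking"]], 5)
  # boxcar on the first half of the window -> half the amplitude
  half <- times >= 300 & times < 424
  wave2 <- wave; wave2[1, half] <- 5
  erp2 <- erp0; erp2$waveforms$smoking <- wave2
  expect_equal(p300_amplitude(erp2)[["smoking"]],
               5 * sum(half) / sum(on))
  expect_error(p300_amplitude(erp0, channels = "Qz"), "Qz")
})

test_that("split-half SNR matches its averaging-gain oracle", {
  fs <- 250; n_t <- 300
  times <- seq(-200, by = 4, length.out = n_t)
  post <- times >= 0
  sig <- sin(2 * pi * 3 * times / 1000) * 2
  mk <- function(n, noise_sd, seed) {
    withr::with_seed(seed, {
      arr <- array(0, c(n, 1, n_t))
      for (i in 1:n) arr[i, 1, ] <- sig + rnorm(n_t, sd = noise_sd)
    })
    structure(list(data = arr, times_ms = times,
                   labels = rep("smoking", n), kept = rep(TRUE, n),
                   channel_labels = "Pz", sampling_rate = fs),
              class = "epoch_set")
  }
  # identical trials -> infinite SNR sentinel
  ep0 <- mk(4, 0, 1)
  expect_warning(v <- snr_pz(ep0), "Inf")
  expect_identical(v, Inf)
  # pure noise -> SNR near 1 in the median
  meds <- vapply(1:100, function(i) {
    ep <- mk(16, 1, 100 + i); ep$data <- ep$data -
      array(rep(sig, each = 16), c(16, 1, n_t))
    snr_pz(ep)
  }, 1)
  expect_lt(abs(median(meds) - 1), 0.3)
  # planted signal: SNR ~ R * N (signal power over window / noise power,
  # times the trial count)
  R <- mean(sig[post] ^ 2) / 4           # noise_sd = 2
  snrs <- vapply(1:60, function(i) snr_pz(mk(24, 2, 200 + i)), 1)
  expected <- R * 24 + 1                 # +1: signal estimate carries noise
  expect_lt(abs(mean(snrs) - expected) / expected, 0.2)
  expect_error(snr_pz(mk(3, 1, 1)), "at least 4")
})

test_that("score-cycle regression matches the direct Pearson formula", {
  mk_trace <- function(scores) {
    structure(data.frame(cycle = rep(seq_along(scores), each = 2),
                         trial = rep(1:2, length(scores)),
                         t_s = seq_len(2 * length(scores)),
                         raw_score = rep(scores, each = 2),
                         displayed_score = rep(scores, each = 2),
                         picture_level = 1L),
              class = c("feedback_trace", "data.frame"))
  }
  lin <- mk_trace(seq(0.9, 0.2, length.out = 8))
  reg <- score_cycle_regression(lin)
  expect_equal(reg$pearson_r, -1)
  expect_lt(reg$p, 1e-10)
  # hand-computed toy table
  y <- c(0.81, 0.74, 0.69, 0.71, 0.62, 0.60, 0.55, 0.49)
  reg2 <- score_cycle_regression(mk_trace(y))
  x <- 1:8
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x)) ^ 2) * sum((y - mean(y)) ^ 2))
  expect_equal(reg2$pearson_r, r_direct, tolerance = 1e-12)
  slope_direct <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x)) ^ 2)
  expect_equal(reg2$slope, slope_direct, tolerance = 1e-12)
  expect_true(reg2$ci[1] < reg2$slope && reg2$slope < reg2$ci[2])
  # constant scores -> undefined flag
  const <- score_cycle_regression(mk_trace(rep(0.5, 8)))
  expect_true(const$undefined)
  expect_true(is.na(const$pearson_r))
})

test_that("null score-cycle p-values are uniform", {
  mk_trace <- function(scores) {
    structure(data.frame(cycle = seq_along(scores), trial = 1L,
                         t_s = seq_along(scores), raw_score = scores,
                         displayed_score = scores, picture_level = 1L),
              class = c("feedback_trace", "data.frame"))
  }
  ps <- vapply(1:200, function(i) {
    withr::with_seed(3000 + i, s <- runif(8))
    score_cycle_regression(mk_trace(s))$p
  }, 1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("distribution tests match closed forms and calibrate", {
  # textbook one-sample t: accuracies vs chance 0.5
  v <- c(0.62, 0.55, 0.71, 0.58, 0.64)
  out <- distribution_tests(v)
  t_direct <- (mean(v) - 0.5) / (sd(v) / sqrt(5))
  expect_equal(out$one_sample_t$t, t_direct, tolerance = 1e-12)
  expect_equal(out$one_sample_t$df, 4)
  expect_equal(out$one_sample_t$p,
               2 * pt(-abs(t_direct), 4), tolerance = 1e-12)
  # all exactly at chance
  out2 <- distribution_tests(rep(0.5, 6))
  expect_equal(out2$one_sample_t$t, 0)
  expect_equal(out2$one_sample_t$p, 1)
  # KS against a fitted normal keeps normal samples most of the time
  keep <- vapply(1:20, function(i) {
    withr::with_seed(500 + i, x <- rnorm(1000))
    distribution_tests(x)$ks_normality_p > 0.01
  }, TRUE)
  expect_gte(mean(keep), 0.9)
  expect_error(distribution_tests(c(1, 2)), "at least 3")
})

test_that("topography export samples the waveform every 200 ms", {
  ep <- make_test_epochs(n_s = 4, n_n = 4, n_ch = 3, n_t = 300, seed = 9)
  erp <- grand_average(ep)
  tab <- topography_table(erp, "smoking")
  expect_equal(nrow(tab), 3)
  expect_identical(names(tab)[-1],
                   paste0("t", seq(0, 1000, by = 200), "ms"))
})
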