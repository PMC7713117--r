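sine_epoch <- function(freq, sfreq = 256, t_start = -0.5, t_end = 0.8,
                       n_channels = 3) {
  t <- seq(t_start, t_end, by = 1 / sfreq)
  mat <- matrix(rep(sin(2 * pi * freq * t), each = n_channels), n_channels)
  epochs_from_trials(list(mat), sfreq = sfreq, t_start = t_start)
}

test_that("the zero-phase band-pass preserves passband sinusoids", {
  ep <- sine_epoch(10)
  out <- bandpass_filter(ep, preproc_config(band_low = 1, band_high = 40))
  t <- erpcluster:::epoch_times(out)
  core <- t > -0.3 & t < 0.6 # away from epoch edges
  x <- ep$data[1, 1, ]
  y <- out$data[1, 1, ]
  amp <- sqrt(2 * mean(y[core]^2)) # RMS amplitude of the sinusoid
  expect_lt(abs(amp - 1), 0.02)
  # zero net phase: peak latency moves by less than one sample
  p_in <- which.max(x * (t > 0 & t < 0.11))
  p_out <- which.max(y * (t > 0 & t < 0.11))
  expect_lte(abs(p_in - p_out), 1L)
})

test_that("slow drift far below the passband is strongly attenuated", {
  sfreq <- 256
  t <- seq(-2, 6, by = 1 / sfreq) # long epoch so 0.1 Hz is resolvable
  mat <- matrix(sin(2 * pi * 0.1 * t), 1)
  ep <- eeg_epochs(
    array(rbind(mat, mat), c(1, 2, length(t))),
    tibble::tibble(subject = "s1", trial = 1), sfreq, -2,
    make_montage(2, "grid")
  )
  out <- bandpass_filter(ep, preproc_config())
  core <- t > -1 & t < 5
  expect_lt(max(abs(out$data[1, 1, core])), 0.1) # >= 90% attenuation
})

test_that("an even (symmetric) input stays symmetric about its centre", {
  sfreq <- 128
  t <- seq(-2, 2, by = 1 / sfreq) # long enough for edge transients to die
  sym <- exp(-t^2 / 0.01) # Gaussian bump centred at 0
  ep <- eeg_epochs(
    array(rep(sym, each = 2), c(1, 2, length(t))),
    tibble::tibble(subject = "s1", trial = 1), sfreq, -2,
    make_montage(2, "grid")
  )
  out <- bandpass_filter(ep, preproc_config(band_low = 1, band_high = 30))
  y <- out$data[1, 1, ]
  expect_lt(max(abs(y - rev(y))), 1e-4 * max(abs(y)))
})

test_that("band edges violating the Nyquist limit are rejected", {
  ep <- sine_epoch(10, sfreq = 64)
  expect_invalid(bandpass_filter(ep, preproc_config(band_high = 40)))
})

test_that("average reference zeroes the channel mean and is idempotent", {
  mat <- matrix(c(1, 2, 3), 3, 5)
  ep <- epochs_from_trials(list(mat))
  out <- rereference_average(ep)
  expect_equal(out$data[1, , 1], c(-1, 0, 1))
  expect_equal(max(abs(colMeans(out$data[1, , ]))), 0)
  twice <- rereference_average(out)
  expect_equal(twice$data, out$data, tolerance = 1e-12)
})

test_that("average reference refuses a single channel", {
  ep <- eeg_epochs(
    array(1, c(1, 1, 4)), tibble::tibble(subject = "s1", trial = 1),
    256, 0, NULL
  )
  expect_invalid(rereference_average(ep))
})

test_that("baseline correction zeroes the baseline mean", {
  ep <- epochs_from_trials(list(matrix(5, 3, 256)), t_start = -0.3)
  out <- baseline_correct(ep, c(-200, 0))
  expect_equal(max(abs(out$data)), 0)

  set.seed(1)
  ep2 <- epochs_from_trials(list(matrix(rnorm(3 * 256), 3)), t_start = -0.3)
  out2 <- baseline_correct(ep2, c(-200, 0))
  idx <- erpcluster:::window_to_idx(c(-200, 0), 256, -0.3, 256)
  expect_lt(max(abs(rowMeans(out2$data[1, , idx]))), 1e-9)
})

test_that("baseline windows outside the epoch are rejected", {
  ep <- epochs_from_trials(list(matrix(0, 2, 100)), t_start = -0.2)
  expect_invalid(baseline_correct(ep, c(-300, -250)))
})

test_that("artifact rejection applies the max-absolute rule exactly", {
  good <- matrix(rnorm(2 * 50, sd = 5), 2)
  bad <- good
  bad[1, 10] <- 150
  ep <- epochs_from_trials(list(good, bad, good),
    info = tibble::tibble(
      subject = "s1", group = "A", timepoint = "T1",
      stim_class = "cue", trial = 1:3
    )
  )
  res <- reject_artifact_trials(ep, 100)
  expect_identical(dim(res$epochs$data)[1], 2L)
  expect_equal(res$report$n_rejected, 1L)
  expect_equal(res$report$fraction, 1 / 3)

  res2 <- reject_artifact_trials(ep, 1000)
  expect_identical(res2$report$n_rejected, 0L)
  expect_identical(res2$report$fraction, 0)
  expect_invalid(reject_artifact_trials(ep, -5))
})

test_that("crop-and-average follows the closed-interval convention", {
  trials <- replicate(10, matrix(seq_len(4 * 300), 4), simplify = FALSE)
  ep <- epochs_from_trials(trials, sfreq = 256, t_start = -0.3,
    info = tibble::tibble(
      subject = "s1", group = "A", timepoint = "T1",
      stim_class = "cue", trial = 1:10
    )
  )
  erp <- crop_and_average(ep, c(-200, 600))
  expect_identical(dim(erp$data)[3], 206L) # round(0.8 * 256) + 1
  expect_identical(erp$info$n_trials, 10L)
  # mean of identical trials is the trial itself (over the cropped window)
  idx <- erpcluster:::window_to_idx(c(-200, 600), 256, -0.3, 300)
  expect_equal(erp$data[1, , ], trials[[1]][, idx])
})

test_that("averaging refuses an empty trial set", {
  ep <- epochs_from_trials(list(matrix(0, 2, 100)), t_start = -0.2)
  ep$data <- ep$data[0, , , drop = FALSE]
  ep$info <- ep$info[0, ]
  expect_invalid(crop_and_average(ep, c(-100, 100)))
})

test_that("linear preprocessing stages are additive and scale-equivariant", {
  set.seed(2)
  a <- matrix(rnorm(3 * 256), 3)
  b <- matrix(rnorm(3 * 256), 3)
  mk <- function(m) epochs_from_trials(list(m), t_start = -0.3)
  cfg <- preproc_config(band_low = 1, band_high = 30)
  chain <- function(ep) {
    baseline_correct(
      rereference_average(bandpass_filter(ep, cfg)),
      c(-200, 0)
    )$data
  }
  expect_equal(chain(mk(a + b)), chain(mk(a)) + chain(mk(b)),
    tolerance = 1e-8
  )
  expect_equal(chain(mk(3 * a)), 3 * chain(mk(a)), tolerance = 1e-8)
})

test_that("the full chain records its order and drops incorrect trials", {
  set.seed(3)
  trials <- replicate(6, matrix(rnorm(4 * 300, sd = 3), 4), simplify = FALSE)
  ep <- epochs_from_trials(trials,
    sfreq = 256, t_start = -0.3,
    info = tibble::tibble(
      subject = "s1", group = "A", timepoint = "T1", stim_class = "cue",
      trial = 1:6, rt_ms = rnorm(6, 430, 40),
      correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
    )
  )
  res <- preprocess_epochs(ep, preproc_config(crop_window = c(-200, 500)))
  expect_identical(
    res$order,
    c("filter", "average-reference", "reject", "baseline", "average")
  )
  expect_identical(res$erps$info$n_trials, 5L) # incorrect trial dropped
})
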