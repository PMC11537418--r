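test_that("band splitting passes theta, rejects distant tones, and removes DC", {
  fs <- 2000
  tt <- seq(0, 10, by = 1 / fs)[-1]
  theta8 <- sin(2 * pi * 8 * tt)
  sb <- split_bands(theta8 + 2, fs = fs)          # +2 V DC offset
  mid <- function(x) x[round(length(x) * 0.25):round(length(x) * 0.75)]
  expect_gte(max(mid(sb$theta)), 0.95)
  expect_lt(abs(mean(sb$ds)), 0.05)               # detrend removed the DC
  tone50 <- sin(2 * pi * 50 * tt)
  sb50 <- split_bands(tone50, fs = fs)
  expect_lte(max(abs(mid(sb50$theta))), 0.01)
  expect_gte(max(mid(sb50$gamma)), 0.9)
  expect_error(split_bands(rnorm(20), fs = fs), "warm-up")
})

test_that("zero-phase filtering leaves a symmetric impulse response", {
  fs <- 400
  x <- numeric(2001); x[1001] <- 1
  y <- ca1forge:::butter_filtfilt(x, fs, c(4, 12), "pass")
  expect_lt(max(abs(y[1001 + 1:300] - y[1001 - 1:300])), 1e-9)
})

test_that("multitaper PSD finds peaks at the stated resolution and obeys Parseval", {
  fs <- 400
  tt <- seq(0, 20, by = 1 / fs)[-1]
  set.seed(5)
  x <- sin(2 * pi * 8 * tt) + rnorm(length(tt), 0, 0.2)
  ps <- multitaper_psd(x, fs, resolution = 1.5)
  expect_lt(abs(ps$peak_frequency - 8), 0.75)
  df <- diff(ps$freq)[1]
  expect_lt(abs(sum(ps$psd) * df - stats::var(x)) / stats::var(x), 0.05)
  # white noise: flat spectrum, negligible log-log slope
  wn <- rnorm(8000)
  pw <- multitaper_psd(wn, fs, resolution = 1.5)
  keep <- pw$freq > 5 & pw$freq < 180
  slope <- stats::coef(stats::lm(log(pw$psd[keep]) ~ log(pw$freq[keep])))[2]
  expect_lt(abs(slope), 0.1)
  expect_error(multitaper_psd(rnorm(50), fs, resolution = 1.5), "too short")
})

test_that("the Morlet spectrogram tracks tones and chirps", {
  fs <- 400
  tt <- seq(0, 10, by = 1 / fs)[-1]
  tone <- sin(2 * pi * 40 * tt)
  sp <- wavelet_spectrogram(tone, fs, freqs = seq(5, 80, 0.5))
  mid <- round(length(tt) / 2)
  expect_equal(sp$freqs[which.max(sp$power_db[, mid])], 40, tolerance = 1)
  # linear chirp 5 -> 20 Hz: ridge increases monotonically
  f_inst <- 5 + (20 - 5) * tt / max(tt)
  chirp <- sin(2 * pi * cumsum(f_inst) / fs)
  spc <- wavelet_spectrogram(chirp, fs, freqs = seq(2, 30, 0.25))
  probe <- round(seq(0.15, 0.85, length.out = 12) * length(tt))
  ridge <- spc$freqs[apply(spc$power_db[, probe], 2, which.max)]
  expect_true(all(diff(ridge) > -0.26))   # monotone up to grid step
  expect_gt(stats::cor(ridge, seq_along(ridge)), 0.98)
  # zero signal: floored, finite dB
  sp0 <- wavelet_spectrogram(numeric(800), fs)
  expect_true(all(is.finite(sp0$power_db)))
})

test_that("CSD of polynomial depth profiles follows the second derivative", {
  nt <- 50; nch <- 9
  depths <- seq(0, 400, length.out = nch)
  quad <- outer(rep(1, nt), depths^2)
  cq <- csd_1d(quad, depths)
  expect_lt(stats::sd(as.vector(cq$csd)), 1e-9)    # spatially constant
  lin <- outer(rep(1, nt), depths)
  cl_ <- csd_1d(lin, depths)
  expect_lt(max(abs(cl_$csd)), 1e-9)               # zero for linear profiles
  expect_error(csd_1d(quad[, 1:2], depths[1:2]), "3 channels")
  # synthetic dipole: source and sink localized at the generating depths
  prof <- exp(-(depths - 100)^2 / (2 * 30^2)) - exp(-(depths - 300)^2 / (2 * 30^2))
  v <- outer(sin(2 * pi * 8 * seq_len(nt) / nt), prof)
  cd <- csd_1d(v, depths, smooth_sd = 0.5)
  mean_abs <- colMeans(abs(cd$csd))
  pk <- cd$depths[order(mean_abs, decreasing = TRUE)[1:2]]
  expect_true(min(abs(pk - 100)) <= 50)
  expect_true(min(abs(pk - 300)) <= 50)
})

test_that("Rayleigh statistics are calibrated and phases recovered", {
  # all spikes at 90 degrees
  r <- rayleigh_test(rep(pi / 2, 25))
  expect_equal(r$mean_angle_deg, 90)
  expect_equal(r$resultant, 1)
  expect_lt(r$p, 1e-6)
  # type-I error under uniform phases ~ alpha
  set.seed(31)
  rej <- vapply(1:1000, function(i) {
    rayleigh_test(stats::runif(40, 0, 2 * pi))$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  # von Mises kappa = 2 sample: mean recovered within 5 degrees
  set.seed(7)
  n <- 500
  # acceptance-rejection sampler for von Mises(mu = 2 rad, kappa = 2)
  vm <- numeric(0)
  while (length(vm) < n) {
    cand <- stats::runif(1000, 0, 2 * pi)
    keep <- stats::runif(1000) < exp(2 * (cos(cand - 2) - 1))
    vm <- c(vm, cand[keep])
  }
  vm <- vm[1:n]
  rv <- rayleigh_test(vm)
  expect_lt(abs(rv$mean_angle_deg - 2 * 180 / pi), 5)
})

test_that("the phase-locking pipeline recovers a known locking phase", {
  fs <- 400
  tt <- seq(0, 20, by = 1 / fs)[-1]
  theta <- sin(2 * pi * 8 * tt)
  # spikes at the theta peak: a quarter period after the trough -> 180 deg
  # (phase convention: trough = 0, peak = 180)
  peak_times_ms <- 1000 * (which(diff(sign(diff(theta))) < 0) + 1) / fs
  set.seed(3)
  spikes <- data.frame(
    gid = rep(1:20, each = 40),
    time = rep(sample(peak_times_ms, 40), 20) + rnorm(800, 0, 2))
  pl <- phase_locking(spikes, theta, fs)
  expect_equal(nrow(pl), 20)
  expect_true(all(pl$locked))
  err <- abs(pl$mean_phase_deg - 180)
  expect_true(all(pmin(err, 360 - err) < 10))
  # cells with too few spikes are excluded and counted
  few <- data.frame(gid = 99, time = c(100, 200))
  pl2 <- phase_locking(rbind(spikes, few), theta, fs)
  expect_equal(attr(pl2, "n_excluded"), 1)
})

test_that("waveform asymmetry is zero for sines and log(1/3) for a 1:3 sawtooth", {
  fs <- 400
  tt <- seq(0, 20, by = 1 / fs)[-1]
  sine <- sin(2 * pi * 8 * tt)
  ai <- asymmetry_index(sine, fs)
  expect_false(ai$flagged)
  expect_lt(abs(ai$mean), 0.05)
  # sawtooth with rise:decay = 1:3 at 8 Hz
  period <- 1 / 8
  ph <- (tt %% period) / period
  saw <- ifelse(ph < 0.25, ph / 0.25, 1 - (ph - 0.25) / 0.75)
  ais <- asymmetry_index(saw, fs)
  expect_lt(abs(ais$mean - log(1 / 3)), 0.1)
  # inverted sawtooth flips the sign
  aii <- asymmetry_index(-saw, fs)
  expect_lt(abs(aii$mean + ais$mean), 0.1)
  expect_true(asymmetry_index(sine[1:30], fs)$flagged)
})

test_that("STTC matches brute-force tiling and its invariances", {
  T_ <- c(0, 10000)
  a <- sort(runif(20, 0, 10000))
  expect_equal(sttc(a, a, 10, T_), 1)
  # brute-force check on small trains
  brute_sttc <- function(a, b, dt, T_range) {
    T_len <- diff(T_range)
    grid <- seq(T_range[1], T_range[2], by = 0.5)
    ta <- mean(vapply(grid, function(g) any(abs(g - a) <= dt), TRUE))
    tb <- mean(vapply(grid, function(g) any(abs(g - b) <= dt), TRUE))
    pa <- mean(vapply(a, function(s) any(abs(s - b) <= dt), TRUE))
    pb <- mean(vapply(b, function(s) any(abs(s - a) <= dt), TRUE))
    0.5 * ((pa - tb) / (1 - pa * tb) + (pb - ta) / (1 - pb * ta))
  }
  set.seed(17)
  for (k in 1:5) {
    x <- sort(runif(20, 0, 2000)); y <- sort(runif(15, 0, 2000))
    expect_equal(sttc(x, y, 10, c(0, 2000)),
                 brute_sttc(x, y, 10, c(0, 2000)), tolerance = 0.02)
  }
  # symmetry and global-shift invariance
  expect_equal(sttc(x, y, 10, c(0, 2000)), sttc(y, x, 10, c(0, 2000)))
  expect_equal(sttc(x + 500, y + 500, 10, c(500, 2500)),
               sttc(x, y, 10, c(0, 2000)), tolerance = 1e-9)
  # independent Poisson trains decorrelate
  set.seed(23)
  vals <- vapply(1:20, function(i) {
    p1 <- sort(runif(500, 0, 100e3)); p2 <- sort(runif(500, 0, 100e3))
    sttc(p1, p2, 10, c(0, 100e3))
  }, 0)
  expect_gte(mean(abs(vals) < 0.05), 0.95)
  expect_warning(sttc(numeric(0), 1:3, 10, c(0, 10)), "empty")
})

test_that("correlograms peak at zero lag for identical trains and gains scale", {
  tr <- list(sort(runif(200, 0, 5000)))
  cg <- spike_correlogram(list(tr[[1]], tr[[1]]), pairs = cbind(1, 2))
  expect_equal(cg$lag[which.max(cg$density)], 0, tolerance = 5)
  sc <- data.frame(gid = 1, time = 1:100)
  ca1 <- data.frame(gid = 2, time = 1:100)
  expect_equal(unname(io_gain(sc, ca1)), 1)
  expect_equal(unname(io_gain(sc, rbind(ca1, ca1))), 2)
  gg <- io_gain(sc, ca1, groups = list(PC = 2, INT = 3))
  expect_equal(unname(gg["PC"]), 1)
  expect_equal(unname(gg["INT"]), 0)
  expect_warning(io_gain(sc[0, ], ca1), "undefined")
})

test_that("the ADF check separates noise from random walks", {
  set.seed(41)
  expect_true(adf_check(rnorm(500))$stationary)
  walks <- vapply(1:100, function(i) {
    adf_check(cumsum(rnorm(400)))$stationary
  }, TRUE)
  expect_gte(mean(!walks), 0.9)
  # a pure linear trend is detrended before testing
  expect_true(adf_check(seq_len(300) * 0.01 + rnorm(300, 0, 0.1))$stationary)
  expect_error(adf_check(rnorm(50)), "too short")
})
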