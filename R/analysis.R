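#' Analytic signal via the Hilbert transform (FFT method)
#'
#' @param x real signal.
#' @return complex analytic signal.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

butter_filtfilt <- function(x, fs, cutoff, type, order = 6) {
  wn <- cutoff / (fs / 2)
  if (type == "pass") {
    flt <- signal::butter(order / 2, wn, type = "pass")
  } else {
    flt <- signal::butter(order, wn, type = type)
  }
  as.numeric(signal::filtfilt(flt, x))
}

#' Split a raw extracellular trace into canonical bands
#'
#' Detrends, separates the raw signal (sampled at \code{fs}, nominally
#' 2 kHz) into LFP (< 400 Hz) and high-frequency (> 400 Hz) components with
#' zero-phase 6th-order Butterworth filters, downsamples the LFP to 400 Hz,
#' and band-filters into delta (1-3 Hz), theta (4-12 Hz) and gamma
#' (30-120 Hz).
#'
#' @param x raw signal vector.
#' @param fs sampling rate, Hz (>= 2000 for the raw split).
#' @param fs_ds downsampled rate (default 400 Hz).
#' @return list: lfp, hf (at fs), ds (downsampled LFP), delta, theta, gamma
#'   (at fs_ds), fs, fs_ds.
#' @export
split_bands <- function(x, fs = 2000, fs_ds = 400) {
  if (length(x) < 6 * fs / 100) stop("trace shorter than filter warm-up")
  x <- stats::residuals(stats::lm(x ~ seq_along(x)))   # detrend
  lfp <- butter_filtfilt(x, fs, 400, "low")
  hf <- butter_filtfilt(x, fs, 400, "high")
  dec <- max(1L, round(fs / fs_ds))
  ds <- as.numeric(signal::decimate(lfp, dec, ftype = "fir"))
  band <- function(lo, hi) butter_filtfilt(ds, fs_ds, c(lo, hi), "pass")
  list(lfp = lfp, hf = hf, ds = ds,
       delta = band(1, 3), theta = band(4, 12), gamma = band(30, 120),
       fs = fs, fs_ds = fs_ds)
}

#' Multitaper power spectral density
#'
#' Sine-taper multitaper estimate with a requested frequency resolution
#' (half-bandwidth = resolution / 2); the taper count follows from the
#' time-bandwidth product. One-sided density scaled so that
#' sum(psd) * df equals the signal variance (Parseval).
#'
#' @param x signal. @param fs sampling rate, Hz.
#' @param resolution frequency resolution, Hz (default 1.5).
#' @return list: freq, psd, peak_frequency, n_tapers.
#' @export
multitaper_psd <- function(x, fs, resolution = 1.5) {
  n <- length(x)
  W <- resolution / 2
  K <- max(1L, floor(2 * n * W / fs) - 1L)
  if (n * W / fs < 1) stop("signal too short for the requested resolution")
  x <- x - mean(x)
  nf <- floor(n / 2) + 1
  acc <- numeric(nf)
  tgrid <- seq_len(n)
  for (k in seq_len(K)) {
    tap <- sqrt(2 / (n + 1)) * sin(pi * k * tgrid / (n + 1))
    X <- stats::fft(x * tap)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / K / fs
  # fold two-sided power into the one-sided density
  if (n %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  else psd[2:nf] <- 2 * psd[2:nf]
  freq <- (seq_len(nf) - 1) * fs / n
  list(freq = freq, psd = psd,
       peak_frequency = freq[which.max(psd[freq > 0.5])] ,
       n_tapers = K)
}

#' Complex Morlet wavelet spectrogram
#'
#' FFT-based continuous wavelet transform with a fixed number of cycles per
#' frequency; magnitude returned in dB (floored for zero signal).
#'
#' @param x signal (typically the 400 Hz LFP).
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz (default 1-150 in 0.25 steps).
#' @param n_cycles wavelet width in cycles (default 7).
#' @param db_floor dB floor (default -200).
#' @return list: time, freqs, power_db (freqs x time matrix).
#' @export
wavelet_spectrogram <- function(x, fs, freqs = seq(1, 150, 0.25),
                                n_cycles = 7, db_floor = -200) {
  n <- length(x)
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1) * fs / n
  fgrid[fgrid > fs / 2] <- fgrid[fgrid > fs / 2] - fs
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigma_f <- f0 / n_cycles
    H <- exp(-(fgrid - f0)^2 / (2 * sigma_f^2)) * (fgrid > 0)
    w <- stats::fft(X * H, inverse = TRUE) / n
    out[i, ] <- Mod(w)^2
  }
  power_db <- 10 * log10(pmax(out, 10^(db_floor / 10)))
  list(time = (seq_len(n) - 1) / fs, freqs = freqs, power_db = power_db)
}

#' One-dimensional current source density
#'
#' Regularised second spatial derivative of the (theta-filtered)
#' multichannel signal across depth, with optional Gaussian smoothing over
#' channels. Sign convention: sinks negative.
#'
#' @param v time x channels matrix.
#' @param depths monotone channel depths, um (>= 3 channels).
#' @param smooth_sd Gaussian smoothing SD in channel units (0 disables).
#' @return list: csd (time x (channels - 2)), depths (interior channels).
#' @export
csd_1d <- function(v, depths, smooth_sd = 0) {
  nch <- ncol(v)
  if (nch < 3) stop("CSD needs at least 3 channels")
  if (is.unsorted(depths) && is.unsorted(rev(depths))) {
    stop("channel depths must be monotone")
  }
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd)
    k <- stats::dnorm(-half:half, 0, smooth_sd); k <- k / sum(k)
    vs <- v
    for (c_ in seq_len(nch)) {
      idx <- clamp(c_ + (-half:half), 1, nch)
      vs[, c_] <- as.vector(v[, idx] %*% k)
    }
    v <- vs
  }
  h <- mean(diff(depths))
  csd <- -(v[, 1:(nch - 2)] - 2 * v[, 2:(nch - 1)] + v[, 3:nch]) / h^2
  list(csd = csd, depths = depths[2:(nch - 1)])
}

#' Rayleigh test of circular uniformity
#'
#' @param angles_rad angles in radians.
#' @return list: mean_angle_deg, resultant (R in [0,1]), z, p, n.
#' @export
rayleigh_test <- function(angles_rad) {
  n <- length(angles_rad)
  C <- mean(cos(angles_rad)); S <- mean(sin(angles_rad))
  R <- sqrt(C^2 + S^2)
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (R * n)^2)) - (1 + 2 * n))
  list(mean_angle_deg = (atan2(S, C) * 180 / pi) %% 360,
       resultant = R, z = z, p = min(1, p), n = n)
}

#' Spike-phase locking against a theta-band signal
#'
#' Assigns each spike the instantaneous phase of the analytic (Hilbert)
#' transform of the theta signal, with the oscillation trough at 0 degrees,
#' then summarises each cell by its circular resultant and a Rayleigh test.
#' Cells with fewer than \code{min_spikes} are excluded and counted.
#'
#' @param spikes data.frame (gid, time ms).
#' @param theta theta-band signal vector.
#' @param fs sampling rate of \code{theta}, Hz.
#' @param t0_ms time of the first theta sample.
#' @param min_spikes minimum spikes per cell (default 10).
#' @param alpha Rayleigh significance level.
#' @return data.frame per cell: gid, n, mean_phase_deg, resultant, p, locked;
#'   attribute \code{n_excluded}.
#' @export
phase_locking <- function(spikes, theta, fs, t0_ms = 0, min_spikes = 10,
                          alpha = 0.05) {
  ph <- (Arg(hilbert_analytic(theta)) + pi) %% (2 * pi)   # trough = 0
  idx <- round((spikes$time - t0_ms) / 1000 * fs) + 1
  ok <- idx >= 1 & idx <= length(theta)
  spikes <- spikes[ok, , drop = FALSE]; idx <- idx[ok]
  spikes$phase <- ph[idx]
  cells <- split(spikes$phase, spikes$gid)
  excluded <- sum(vapply(cells, length, 0L) < min_spikes)
  cells <- cells[vapply(cells, length, 0L) >= min_spikes]
  res <- lapply(names(cells), function(g) {
    rt <- rayleigh_test(cells[[g]])
    data.frame(gid = as.integer(g), n = rt$n,
               mean_phase_deg = rt$mean_angle_deg, resultant = rt$resultant,
               p = rt$p, locked = rt$p < alpha)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gid = integer(0), n = integer(0), mean_phase_deg = numeric(0),
               resultant = numeric(0), p = numeric(0), locked = logical(0))
  attr(out, "n_excluded") <- excluded
  out
}

# local extrema of a z-scored signal beyond a threshold
find_extrema <- function(z, thresh) {
  n <- length(z)
  pk <- which(z > thresh & c(-Inf, z[-n]) < z & z > c(z[-1], -Inf))
  tr <- which(z < -thresh & c(Inf, z[-n]) > z & z < c(z[-1], Inf))
  list(peaks = pk, troughs = tr)
}

#' Theta waveform asymmetry index
#'
#' For a 1-80 Hz low-passed LFP, peaks and troughs are located by z-score
#' thresholding; each oscillation contributes log(t_rise / t_decay), where
#' t_rise is the trough-to-peak and t_decay the peak-to-next-trough
#' duration. Negative values indicate a fast rise and slow decay.
#'
#' @param x filtered LFP vector.
#' @param fs sampling rate, Hz.
#' @param z_thresh detection threshold in SD units (default 1).
#' @return list: indices (per cycle), mean, n_cycles; flagged = TRUE when
#'   fewer than 3 cycles are found.
#' @export
asymmetry_index <- function(x, fs, z_thresh = 1) {
  z <- (x - mean(x)) / stats::sd(x)
  ex <- find_extrema(z, z_thresh)
  tr <- ex$troughs; pk <- ex$peaks
  idxs <- numeric(0)
  for (i in seq_along(tr)) {
    nxt_pk <- pk[pk > tr[i]][1]
    if (is.na(nxt_pk)) next
    nxt_tr <- tr[tr > nxt_pk][1]
    if (is.na(nxt_tr)) next
    t_rise <- (nxt_pk - tr[i]) / fs
    t_decay <- (nxt_tr - nxt_pk) / fs
    if (t_rise > 0 && t_decay > 0) idxs <- c(idxs, log(t_rise / t_decay))
  }
  list(indices = idxs, mean = if (length(idxs)) mean(idxs) else NA_real_,
       n_cycles = length(idxs), flagged = length(idxs) < 3)
}

# total length of the union of +/-dt tiles around spikes, clipped to [0, T]
tiled_time <- function(train, dt, T_) {
  if (length(train) == 0) return(0)
  lo <- pmax(train - dt, 0); hi <- pmin(train + dt, T_)
  o <- order(lo); lo <- lo[o]; hi <- hi[o]
  tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
    else { tot <- tot + cur_hi - cur_lo; cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  (tot + cur_hi - cur_lo) / T_
}

# proportion of spikes in `a` lying within +/-dt of any spike in `b`
prop_tiled <- function(a, b, dt) {
  if (length(a) == 0 || length(b) == 0) return(0)
  idx <- findInterval(a, b)
  d_lo <- ifelse(idx >= 1, a - b[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(b), b[pmin(idx + 1, length(b))] - a, Inf)
  mean(pmin(d_lo, d_hi) <= dt)
}

#' Spike time tiling coefficient (STTC)
#'
#' Firing-rate-robust correlation between two spike trains within a
#' recording window, using +/- dt tiles (default 10 ms).
#'
#' @param a,b sorted spike time vectors, ms.
#' @param dt tiling half-width, ms.
#' @param T_range recording window c(start, end), ms.
#' @return coefficient in [-1, 1]; NA (with warning) for an empty train.
#' @export
sttc <- function(a, b, dt = 10, T_range) {
  if (length(a) == 0 || length(b) == 0) {
    warning("STTC undefined for an empty spike train")
    return(NA_real_)
  }
  T_ <- diff(T_range)
  a <- sort(a) - T_range[1]; b <- sort(b) - T_range[1]
  TA <- tiled_time(a, dt, T_); TB <- tiled_time(b, dt, T_)
  PA <- prop_tiled(a, b, dt); PB <- prop_tiled(b, a, dt)
  t1 <- if (1 - PA * TB != 0) (PA - TB) / (1 - PA * TB) else 0
  t2 <- if (1 - PB * TA != 0) (PB - TA) / (1 - PB * TA) else 0
  0.5 * (t1 + t2)
}

#' Spike-spike correlogram over cell pairs
#'
#' Histogram of pairwise spike-time differences, averaged over pairs and
#' normalised to unit area.
#'
#' @param trains list of spike-time vectors (ms).
#' @param pairs 2-column matrix of train indices; default all ordered pairs.
#' @param bin_ms bin width (default 10). @param max_lag_ms histogram range.
#' @return list: lag (bin centers), density.
#' @export
spike_correlogram <- function(trains, pairs = NULL, bin_ms = 10,
                              max_lag_ms = 100) {
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, length(trains), length(trains))),
                 arr.ind = TRUE)
    pairs <- idx
  }
  # bins centered on zero lag
  breaks <- seq(-max_lag_ms - bin_ms / 2, max_lag_ms + bin_ms / 2, by = bin_ms)
  acc <- numeric(length(breaks) - 1)
  for (p in seq_len(nrow(pairs))) {
    a <- trains[[pairs[p, 1]]]; b <- trains[[pairs[p, 2]]]
    if (length(a) == 0 || length(b) == 0) next
    d <- as.vector(outer(b, a, `-`))
    d <- d[abs(d) <= max_lag_ms]
    acc <- acc + graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  }
  dens <- if (sum(acc) > 0) acc / sum(acc) / bin_ms else acc
  list(lag = (breaks[-1] + breaks[-length(breaks)]) / 2, density = dens)
}

#' Input-output spike gain between afferent and target populations
#'
#' Ratio of CA1 to CA3 (afferent) spike counts, overall or per group.
#'
#' @param sc_spikes afferent spike table (gid, time).
#' @param ca1_spikes CA1 spike table (gid, time).
#' @param groups optional named list of CA1 gid vectors (e.g. PC, INT).
#' @return named numeric gains; NA (with warning) if no afferent spikes.
#' @export
io_gain <- function(sc_spikes, ca1_spikes, groups = NULL) {
  n_sc <- nrow(sc_spikes)
  if (n_sc == 0) {
    warning("gain undefined: no afferent spikes")
    return(NA_real_)
  }
  if (is.null(groups)) return(c(all = nrow(ca1_spikes) / n_sc))
  vapply(groups, function(g) sum(ca1_spikes$gid %in% g) / n_sc, 0)
}

#' Augmented Dickey-Fuller stationarity check
#'
#' Linear-detrends the signal, then fits the standard augmented regression
#' (constant included) and compares the unit-root t-statistic with the
#' large-sample 5\% critical value. Because of the prior detrending the
#' trend-case critical value (-3.41) applies. Rejection means stationary.
#'
#' @param x signal (length >= 100).
#' @param n_lags augmentation lags; default floor((n - 1)^(1/3)).
#' @param critical critical value at the chosen level.
#' @return list: statistic, critical, stationary (logical).
#' @export
adf_check <- function(x, n_lags = NULL, critical = -3.41) {
  n <- length(x)
  if (n < 100) stop("signal too short for the ADF check")
  if (stats::sd(x) == 0) {
    return(list(statistic = -Inf, critical = critical, stationary = TRUE))
  }
  x <- stats::residuals(stats::lm(x ~ seq_len(n)))
  if (is.null(n_lags)) n_lags <- floor((n - 1)^(1 / 3))
  dx <- diff(x)
  y <- dx[(n_lags + 1):length(dx)]
  xlag <- x[(n_lags + 1):(n - 1)]
  lags <- sapply(seq_len(n_lags), function(k) {
    dx[(n_lags + 1 - k):(length(dx) - k)]
  })
  fit <- if (n_lags > 0) stats::lm(y ~ xlag + lags) else stats::lm(y ~ xlag)
  sm <- summary(fit)$coefficients
  stat <- sm["xlag", "t value"]
  list(statistic = unname(stat), critical = critical,
       stationary = stat < critical)
}
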