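#' Rate function constructors
#'
#' A rate function is a list with \code{fn(t_ms) -> Hz}, a \code{max_rate}
#' bound (for thinning) and a \code{mean_rate}.
#'
#' @name rate-functions
NULL

#' Constant firing-rate function
#' @param rate_hz mean rate, Hz.
#' @return rate function object.
#' @export
constant_rate <- function(rate_hz) {
  stopifnot(rate_hz >= 0)
  structure(list(fn = function(t) rep(rate_hz, length(t)),
                 max_rate = rate_hz, mean_rate = rate_hz,
                 kind = "constant"), class = "ca1_rate")
}

#' Sinusoidally modulated firing rate
#'
#' rate(t) = m (1 + sin(2 pi f t)): the per-cell mean rate m defines both
#' offset and amplitude, so the rate touches zero at the trough and peaks at
#' 2m. An independent-amplitude variant is available via \code{amplitude}.
#'
#' @param cell_frequency_hz per-cell mean rate m, Hz.
#' @param signal_frequency_hz modulation (signal) frequency f, Hz.
#' @param amplitude optional amplitude overriding the default (= m), Hz.
#' @return rate function object.
#' @export
sinusoidal_rate <- function(cell_frequency_hz, signal_frequency_hz,
                            amplitude = NULL) {
  stopifnot(cell_frequency_hz > 0, signal_frequency_hz > 0)
  a <- if (is.null(amplitude)) cell_frequency_hz else amplitude
  f <- signal_frequency_hz
  m <- cell_frequency_hz
  structure(list(
    fn = function(t) pmax(0, m + a * sin(2 * pi * f * t / 1000)),
    max_rate = m + a, mean_rate = m, kind = "sinusoidal",
    signal_frequency_hz = f), class = "ca1_rate")
}

#' Periodic rate from a phase histogram of discharge probability
#'
#' Maps a (possibly smoothed) discharge-probability histogram over phase
#' (radians, trough = 0) to a periodic temporal rate at the given frequency,
#' normalised so the time-averaged rate equals \code{mean_rate_hz}.
#'
#' @param phase_probs non-negative discharge probabilities over a uniform
#'   phase grid covering [0, 2 pi).
#' @param frequency_hz oscillation frequency.
#' @param mean_rate_hz requested time-averaged rate.
#' @param smoothing width (bins) of a moving-average smoother; 0 disables.
#' @return rate function object.
#' @export
phase_histogram_rate <- function(phase_probs, frequency_hz, mean_rate_hz = 1,
                                 smoothing = 0) {
  stopifnot(all(phase_probs >= 0))
  if (sum(phase_probs) == 0) stop("all-zero phase histogram")
  p <- phase_probs
  if (smoothing > 0) {
    k <- rep(1 / (2 * smoothing + 1), 2 * smoothing + 1)
    n <- length(p)
    ext <- c(p[(n - smoothing + 1):n], p, p[1:smoothing])
    p <- stats::filter(ext, k, sides = 2)[(smoothing + 1):(smoothing + n)]
  }
  p <- p / mean(p) * mean_rate_hz
  nb <- length(p)
  period_ms <- 1000 / frequency_hz
  fn <- function(t) {
    ph <- (t %% period_ms) / period_ms      # [0,1) cycle position
    idx <- pmin(floor(ph * nb) + 1, nb)
    p[idx]
  }
  structure(list(fn = fn, max_rate = max(p), mean_rate = mean_rate_hz,
                 kind = "phase_histogram", frequency_hz = frequency_hz),
            class = "ca1_rate")
}

#' Poisson spike trains from a rate function
#'
#' Homogeneous rates are sampled directly; inhomogeneous rates through
#' Lewis-Shedler thinning of a dominating homogeneous process (exact for
#' bounded rates).
#'
#' @param rate a rate function object (see \code{\link{constant_rate}}).
#' @param n_sources number of independent trains.
#' @param duration_ms duration, ms.
#' @param seed RNG seed.
#' @return data.frame (gid, time) of sorted spike times per source.
#' @export
poisson_trains <- function(rate, n_sources, duration_ms, seed = 1) {
  stopifnot(duration_ms > 0, n_sources >= 1)
  if (rate$max_rate < 0) stop("negative rate")
  with_seed(seed, {
    out <- vector("list", n_sources)
    lam <- rate$max_rate / 1000            # spikes per ms
    for (g in seq_len(n_sources)) {
      n <- stats::rpois(1, lam * duration_ms)
      ts <- sort(stats::runif(n, 0, duration_ms))
      if (rate$kind != "constant" && n > 0) {
        keep <- stats::runif(n) < rate$fn(ts) / rate$max_rate
        ts <- ts[keep]
      }
      out[[g]] <- if (length(ts)) data.frame(gid = g, time = ts) else NULL
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- data.frame(gid = integer(0), time = numeric(0))
    res
  })
}

#' Sinusoidal hyperpolarizing current for medial-septum disinhibition
#'
#' I(t) = -A + A sin(2 pi f t): mean fixed at minus the amplitude so the
#' waveform stays in [-2A, 0] and never depolarizes.
#'
#' @param frequency_hz oscillation frequency (theta; default 8 Hz).
#' @param amplitude_nA amplitude A > 0, nA.
#' @param duration_ms,dt_ms sampling.
#' @return list(time, current, description).
#' @export
ms_disinhibition_current <- function(frequency_hz = 8, amplitude_nA = 0.2,
                                     duration_ms = 1000, dt_ms = 0.5) {
  stopifnot(amplitude_nA > 0)
  t <- seq(0, duration_ms, by = dt_ms)
  i <- -amplitude_nA + amplitude_nA * sin(2 * pi * frequency_hz * t / 1000)
  list(time = t, current = i, description = "sinusoidal-hyperpolarizing")
}

#' Tonic depolarization relative to rheobase
#'
#' @param rheobase_nA the neuron's rheobase current, nA.
#' @param percent stimulation level, percent of rheobase (e.g. 115-140).
#' @return constant current, nA.
#' @export
tonic_depolarization <- function(rheobase_nA, percent) {
  percent / 100 * rheobase_nA
}
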