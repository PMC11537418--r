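#' Tsodyks-Markram synapse parameter set
#'
#' @param u_se utilization of synaptic efficacy (per-vesicle release
#'   probability), in [0, 1].
#' @param tau_rec recovery (depression) time constant, ms.
#' @param tau_facil facilitation time constant, ms (0 = none).
#' @param g_max peak conductance per released vesicle, nS.
#' @param n_rrp release-ready vesicle pool size (>= 1).
#' @param tau_rise,tau_decay receptor kinetics, ms.
#' @param e_rev reversal potential, mV.
#' @param nmda_ratio NMDA/AMPA peak conductance ratio.
#' @return list of class \code{tm_params}.
#' @export
tm_params <- function(u_se = 0.5, tau_rec = 500, tau_facil = 0, g_max = 1,
                      n_rrp = 1, tau_rise = 0.2, tau_decay = 3, e_rev = 0,
                      nmda_ratio = 0) {
  stopifnot(u_se >= 0, u_se <= 1, tau_rec > 0, tau_facil >= 0, n_rrp >= 1)
  structure(list(u_se = u_se, tau_rec = tau_rec, tau_facil = tau_facil,
                 g_max = g_max, n_rrp = as.integer(n_rrp),
                 tau_rise = tau_rise, tau_decay = tau_decay, e_rev = e_rev,
                 nmda_ratio = nmda_ratio),
            class = "tm_params")
}

#' ACh dose-response of depolarizing current
#'
#' Hill function with maximum 0.567 nA, half-concentration 100 uM and
#' exponent 0.436; zero current at zero concentration (control).
#'
#' @param concentration ACh (or agonist-equivalent) concentration, uM.
#' @return depolarizing current, nA.
#' @export
ach_current <- function(concentration) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  0.567 * concentration^0.436 / (100^0.436 + concentration^0.436)
}

#' ACh scaling factor of release probability
#'
#' Decreasing Hill factor applied multiplicatively to U_SE for all pathways
#' (including Schaffer collaterals): 1 at zero concentration, 0.5 at
#' 4.541 uM.
#'
#' @param concentration ACh concentration, uM.
#' @return factor in (0, 1].
#' @export
ach_release_scaling <- function(concentration) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  # C^-0.576 / (4.541^-0.576 + C^-0.576), written to be stable at C = 0
  1 / (1 + (concentration / 4.541)^0.576)
}

#' Calcium dependence of release probability
#'
#' Hill scaling of U_SE with extracellular calcium, normalised to 1 at the
#' reference 2 mM. Three steepness profiles are offered; their exponents
#' (steep 4, intermediate 3, shallow 2; half-concentration 2.3 mM) are
#' package defaults standing in for unpublished calibration values.
#'
#' @param calcium extracellular calcium, mM (> 0).
#' @param profile "steep", "intermediate" or "shallow".
#' @param half_mM Hill half-concentration.
#' @param reference_mM concentration at which the factor is 1.
#' @return positive scaling factor.
#' @export
calcium_scaling <- function(calcium, profile = c("intermediate", "steep",
                                                 "shallow"),
                            half_mM = 2.3, reference_mM = 2) {
  profile <- match.arg(profile)
  stopifnot(all(calcium > 0))
  n <- switch(profile, steep = 4, intermediate = 3, shallow = 2)
  hill <- function(ca) ca^n / (half_mM^n + ca^n)
  hill(calcium) / hill(reference_mM)
}

#' Stochastic Tsodyks-Markram release with multivesicular release
#'
#' Facilitation variable u decays with tau_facil and jumps by
#' U_eff (1 - u) at each spike, where U_eff is U_SE scaled by the calcium
#' and ACh factors. Each unrecovered vesicle recovers independently with
#' rate 1/tau_rec; at a spike every recovered vesicle releases independently
#' with probability u. Vesicle count is conserved.
#'
#' @param spike_times sorted presynaptic spike times, ms.
#' @param params a \code{tm_params}.
#' @param calcium extracellular calcium, mM.
#' @param ach ACh concentration, uM.
#' @param ca_profile calcium profile (see \code{\link{calcium_scaling}}).
#' @param seed RNG seed; NULL uses the current stream.
#' @return data.frame per spike: time, released (vesicles), g_peak (nS,
#'   released x g_max), u (pre-release facilitation state), recovered
#'   (vesicles available just before the spike).
#' @export
tm_release <- function(spike_times, params, calcium = 2, ach = 0,
                       ca_profile = "intermediate", seed = NULL) {
  if (is.unsorted(spike_times, strictly = FALSE)) {
    stop("spike times must be sorted")
  }
  u_eff <- clamp(params$u_se * calcium_scaling(calcium, ca_profile) *
                   ach_release_scaling(ach), 0, 1)
  n <- params$n_rrp
  run <- function() {
    recovered <- rep(TRUE, n)
    u <- 0
    last_t <- -Inf
    out_rel <- integer(length(spike_times))
    out_u <- numeric(length(spike_times))
    out_rec <- integer(length(spike_times))
    for (k in seq_along(spike_times)) {
      t_ <- spike_times[k]
      dt <- t_ - last_t
      # recovery of unrecovered vesicles
      if (any(!recovered) && is.finite(dt)) {
        p_rec <- 1 - exp(-dt / params$tau_rec)
        idx <- which(!recovered)
        recovered[idx] <- stats::runif(length(idx)) < p_rec
      }
      # facilitation decay + jump
      u <- if (params$tau_facil > 0 && is.finite(dt)) {
        u * exp(-dt / params$tau_facil)
      } else 0
      u <- u + u_eff * (1 - u)
      avail <- which(recovered)
      rel <- avail[stats::runif(length(avail)) < u]
      recovered[rel] <- FALSE
      out_rel[k] <- length(rel)
      out_u[k] <- u
      out_rec[k] <- length(avail)
      last_t <- t_
    }
    data.frame(time = spike_times, released = out_rel,
               g_peak = out_rel * params$g_max, u = out_u,
               recovered = out_rec)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Deterministic Tsodyks-Markram mean-field recursion
#'
#' Classic u/x recursion giving the expected released fraction per spike;
#' the expectation of the stochastic model.
#'
#' @inheritParams tm_release
#' @return data.frame: time, u, x (recovered fraction before spike),
#'   release_fraction (u * x).
#' @export
tm_deterministic <- function(spike_times, params, calcium = 2, ach = 0,
                             ca_profile = "intermediate") {
  u_eff <- clamp(params$u_se * calcium_scaling(calcium, ca_profile) *
                   ach_release_scaling(ach), 0, 1)
  u <- 0; x <- 1; last_t <- -Inf
  out <- matrix(0, length(spike_times), 3)
  for (k in seq_along(spike_times)) {
    dt <- spike_times[k] - last_t
    if (is.finite(dt)) {
      x <- 1 - (1 - x) * exp(-dt / params$tau_rec)
      u <- if (params$tau_facil > 0) u * exp(-dt / params$tau_facil) else 0
    }
    u <- u + u_eff * (1 - u)
    out[k, ] <- c(u, x, u * x)
    x <- x - u * x
    last_t <- spike_times[k]
  }
  data.frame(time = spike_times, u = out[, 1], x = out[, 2],
             release_fraction = out[, 3])
}

#' Render a conductance trace from release events
#'
#' Linear superposition of peak-normalised double-exponential kernels, one
#' per release event (g_peak x [exp(-t/tau_decay) - exp(-t/tau_rise)] /
#' peak factor).
#'
#' @param events data.frame with time (ms) and g_peak (nS).
#' @param params a \code{tm_params} (kinetics).
#' @param times evaluation time grid, ms.
#' @return conductance vector, nS.
#' @export
conductance_trace <- function(events, params, times) {
  tr <- params$tau_rise; td <- params$tau_decay
  tp <- tr * td / (td - tr) * log(td / tr)
  pk <- exp(-tp / td) - exp(-tp / tr)
  g <- numeric(length(times))
  for (i in seq_len(nrow(events))) {
    dt <- times - events$time[i]
    on <- dt >= 0
    g[on] <- g[on] + events$g_peak[i] *
      (exp(-dt[on] / td) - exp(-dt[on] / tr)) / pk
  }
  g
}

#' Miniature (spontaneous) release event train for one synapse
#'
#' Spontaneous vesicle release modelled as a Poisson process of virtual
#' presynaptic events driven through the same stochastic release machinery.
#'
#' @param rate presynaptic mini rate, Hz.
#' @param duration ms.
#' @param params a \code{tm_params}.
#' @param seed RNG seed.
#' @return release event data.frame as from \code{\link{tm_release}}.
#' @export
minis_train <- function(rate, duration, params, seed = 1) {
  ts <- with_seed(seed, sort(stats::runif(stats::rpois(1, rate * duration / 1000),
                                          0, duration)))
  tm_release(ts, params, seed = substream_seed(seed, "minirel"))
}

#' Relative-error cost over fit targets
#'
#' Sum over targets of |x_mod - x_exp| / |x_exp|.
#'
#' @param x_mod,x_exp numeric vectors of model and experimental values
#'   (matched positions or shared names).
#' @return non-negative scalar.
#' @export
fit_cost <- function(x_mod, x_exp) {
  if (!is.null(names(x_exp)) && !is.null(names(x_mod))) {
    x_mod <- x_mod[names(x_exp)]
  }
  if (any(x_exp == 0)) stop("experimental target of 0 not allowed")
  sum(abs(x_mod - x_exp) / abs(x_exp))
}

#' Two-step alternating grid search for Schaffer-collateral parameters
#'
#' Step 1 scans (g_max, n_rrp) against amplitude/variability targets; step 2
#' scans AMPA (tau_rise, tau_decay) against kinetics targets. The steps
#' alternate, each re-run with the other's current optimum, until both are
#' stable or \code{max_iter} is reached (then the best-so-far is returned
#' with \code{converged = FALSE}).
#'
#' @param grid list with numeric vectors g_max, n_rrp, tau_rise, tau_decay.
#' @param simulator function(params) -> named numeric feature vector.
#' @param targets list with named numeric vectors \code{step1} and
#'   \code{step2} of experimental values.
#' @param base a \code{tm_params} supplying the non-fitted parameters.
#' @param max_iter maximum alternation cycles.
#' @return list(params, cost, converged, iterations).
#' @export
fit_sc_parameters <- function(grid, simulator, targets, base = tm_params(),
                              max_iter = 10) {
  stopifnot(length(grid$g_max) > 0, length(grid$n_rrp) > 0,
            length(grid$tau_rise) > 0, length(grid$tau_decay) > 0)
  cur <- base
  cur$g_max <- grid$g_max[1]; cur$n_rrp <- as.integer(grid$n_rrp[1])
  cur$tau_rise <- grid$tau_rise[1]; cur$tau_decay <- grid$tau_decay[1]
  eval_cost <- function(p, tg) fit_cost(simulator(p), tg)
  it <- 0; converged <- FALSE
  repeat {
    it <- it + 1
    prev <- cur
    # step 1: conductance and vesicle pool
    best <- Inf
    for (gm in grid$g_max) for (nr in grid$n_rrp) {
      p <- cur; p$g_max <- gm; p$n_rrp <- as.integer(nr)
      cost <- eval_cost(p, targets$step1)
      if (cost < best) { best <- cost; cur <- p }
    }
    # step 2: AMPA kinetics
    best2 <- Inf
    for (trs in grid$tau_rise) for (tds in grid$tau_decay) {
      p <- cur; p$tau_rise <- trs; p$tau_decay <- tds
      cost <- eval_cost(p, targets$step2)
      if (cost < best2) { best2 <- cost; cur <- p }
    }
    stable <- identical(
      c(prev$g_max, prev$n_rrp, prev$tau_rise, prev$tau_decay),
      c(cur$g_max, cur$n_rrp, cur$tau_rise, cur$tau_decay))
    if (stable) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  total <- eval_cost(cur, c(targets$step1, targets$step2))
  list(params = cur, cost = total, converged = converged, iterations = it)
}

#' Postsynaptic-potential features of a trace
#'
#' Amplitude, 10-90\% rise time, half-width and exponential decay time
#' constant of the dominant deflection.
#'
#' @param times time grid, ms.
#' @param v membrane potential (or current) samples.
#' @param baseline_window length-2 time window used for the baseline, ms.
#' @param min_snr minimum amplitude-to-baseline-SD ratio (default 5); below it the trace
#'   is flagged (\code{flagged = TRUE}, features NA).
#' @return list(amplitude, rise_time, half_width, decay_tau, flagged).
#' @export
psp_features <- function(times, v, baseline_window = c(0, 10), min_snr = 5) {
  bl <- v[times >= baseline_window[1] & times <= baseline_window[2]]
  base <- mean(bl); noise <- stats::sd(bl)
  dv <- v - base
  sgn <- if (max(dv) >= -min(dv)) 1 else -1
  dv <- dv * sgn
  pk <- which.max(dv)
  amp <- dv[pk]
  if (!is.finite(amp) || (noise > 0 && amp < min_snr * noise) || amp <= 0) {
    return(list(amplitude = NA_real_, rise_time = NA_real_,
                half_width = NA_real_, decay_tau = NA_real_, flagged = TRUE))
  }
  cross_time <- function(frac, rising) {
    thr <- frac * amp
    if (rising) {
      idx <- which(dv[seq_len(pk)] >= thr)[1]
      if (is.na(idx) || idx == 1) return(times[1])
      stats::approx(dv[(idx - 1):idx], times[(idx - 1):idx], xout = thr)$y
    } else {
      post <- dv[pk:length(dv)]
      idx <- which(post <= thr)[1]
      if (is.na(idx) || idx == 1) return(times[length(times)])
      j <- pk + idx - 1
      stats::approx(dv[(j - 1):j], times[(j - 1):j], xout = thr)$y
    }
  }
  rise <- cross_time(0.9, TRUE) - cross_time(0.1, TRUE)
  half <- cross_time(0.5, FALSE) - cross_time(0.5, TRUE)
  # decay tau from log-linear fit between 90% and 10% of the falling phase
  fall <- which(times > times[pk] & dv > 0.05 * amp & dv < 0.9 * amp)
  fall <- fall[times[fall] < cross_time(0.05, FALSE)]
  decay_tau <- NA_real_
  if (length(fall) >= 3) {
    fit <- stats::lm(log(dv[fall]) ~ times[fall])
    decay_tau <- -1 / stats::coef(fit)[2]
  }
  list(amplitude = amp * sgn, rise_time = rise, half_width = half,
       decay_tau = unname(decay_tau), flagged = FALSE)
}
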