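#' Surrogate point-neuron model (adaptive exponential integrate-and-fire)
#'
#' A deliberately simple stand-in for detailed multicompartment models, so
#' network-level claims are property-level, not value-level. With
#' \code{delta_T = 0} the model reduces to leaky integrate-and-fire with
#' closed-form rheobase g_L (V_T - E_L).
#'
#' @param etype label (e.g. "cADpyr", "cAC").
#' @param C_pF capacitance. @param g_L_nS leak conductance.
#' @param E_L_mV leak reversal. @param V_T_mV threshold.
#' @param delta_T_mV spike sharpness (0 = LIF). @param V_reset_mV reset.
#' @param t_ref_ms refractory period. @param a_nS,b_nA,tau_w_ms adaptation.
#' @param V_cut_mV numerical spike cut.
#' @return list of class \code{point_neuron}.
#' @export
point_neuron <- function(etype = "cADpyr", C_pF = 150, g_L_nS = 10,
                         E_L_mV = -70, V_T_mV = -50, delta_T_mV = 2,
                         V_reset_mV = -60, t_ref_ms = 2, a_nS = 0,
                         b_nA = 0.02, tau_w_ms = 120, V_cut_mV = 0) {
  stopifnot(V_T_mV > V_reset_mV, t_ref_ms >= 0)
  structure(list(etype = etype, C = C_pF, g_L = g_L_nS, E_L = E_L_mV,
                 V_T = V_T_mV, delta_T = delta_T_mV, V_reset = V_reset_mV,
                 t_ref = t_ref_ms, a = a_nS, b = b_nA, tau_w = tau_w_ms,
                 V_cut = V_cut_mV), class = "point_neuron")
}

# single-neuron fixed-step integration under constant current; returns
# number of spikes
simulate_constant_current <- function(neuron, I_nA, duration_ms = 500,
                                      dt = 0.1) {
  v <- neuron$E_L; w <- 0; refr <- 0; nspk <- 0L
  nstep <- ceiling(duration_ms / dt)
  for (k in seq_len(nstep)) {
    if (refr > 0) { refr <- refr - dt; next }
    expterm <- if (neuron$delta_T > 0) {
      neuron$g_L * neuron$delta_T * exp(clamp((v - neuron$V_T) / neuron$delta_T,
                                              -50, 20))
    } else 0
    i_pA <- -neuron$g_L * (v - neuron$E_L) + expterm - w * 1000 + I_nA * 1000
    v <- v + dt * i_pA / neuron$C
    w <- w + dt * (neuron$a * (v - neuron$E_L) / 1000 - w) / neuron$tau_w
    thr <- if (neuron$delta_T > 0) neuron$V_cut else neuron$V_T
    if (v >= thr) {
      nspk <- nspk + 1L
      v <- neuron$V_reset
      w <- w + neuron$b
      refr <- neuron$t_ref
    }
  }
  nspk
}

#' Estimate rheobase by bisection
#'
#' Halves a current bracket until its width is below \code{accuracy} and
#' returns the upper bound of the final step, ensuring the returned current
#' elicits a spike.
#'
#' @param neuron a \code{point_neuron}.
#' @param accuracy bracket width target, nA (default 1e-3).
#' @param bracket initial (low, high) search interval, nA.
#' @param duration_ms test-pulse duration.
#' @return rheobase estimate, nA (upper bound); attribute \code{iterations}.
#' @export
estimate_rheobase <- function(neuron, accuracy = 1e-3, bracket = c(0, 2),
                              duration_ms = 500) {
  lo <- bracket[1]; hi <- bracket[2]
  if (simulate_constant_current(neuron, hi, duration_ms) == 0) {
    stop("neuron does not spike at bracket maximum")
  }
  it <- 0L
  while (hi - lo > accuracy) {
    mid <- (lo + hi) / 2
    if (simulate_constant_current(neuron, mid, duration_ms) > 0) hi <- mid
    else lo <- mid
    it <- it + 1L
  }
  structure(hi, iterations = it)
}

default_etypes <- function() {
  list(
    cADpyr = point_neuron("cADpyr", C_pF = 180, g_L_nS = 9, E_L_mV = -70,
                          V_T_mV = -50, b_nA = 0.04),
    cAC = point_neuron("cAC", C_pF = 100, g_L_nS = 8, E_L_mV = -65,
                       V_T_mV = -52, b_nA = 0.01, t_ref_ms = 1.5))
}

#' Run the surrogate network
#'
#' Fixed-step (forward Euler) integration of adaptive exponential
#' integrate-and-fire neurons coupled by stochastic Tsodyks-Markram
#' synapses. Bath conditions apply globally: extracellular calcium scales
#' U_SE, ACh scales U_SE and injects the dose-dependent depolarizing
#' current into every cell; Mg is a condition tag entering only the NMDA
#' block (not modelled by default).
#'
#' @param cells data.frame with gid, etype (and optionally mtype).
#' @param synapses data.frame with pre (cell gid, or negative external fiber
#'   id), post, g_max (nS), e_rev (mV), u_se, tau_rec, tau_facil, n_rrp,
#'   delay (ms; default 1). Negative \code{pre} rows are driven by
#'   \code{ext_spikes}.
#' @param ext_spikes data.frame (gid = negative fiber ids, time ms) of
#'   afferent spikes; NULL for none.
#' @param i_ext constant current per cell (nA), scalar or vector.
#' @param conditions list(calcium_mM = 2, ach_uM = 0, ca_profile,
#'   temperature, mg_mM) applied globally.
#' @param duration_ms,dt_ms integration window and step.
#' @param seed RNG seed.
#' @param etypes named list of \code{point_neuron} models.
#' @param record_v gids whose membrane potential is recorded.
#' @param i_wave optional function(t_ms) -> nA added to every cell (e.g.
#'   the MS disinhibition waveform restricted via \code{i_wave_gids}).
#' @param i_wave_gids gids receiving \code{i_wave} (default all).
#' @return list: spikes (gid, time), v (matrix, recorded cells), syn_current
#'   (time x cells matrix, nA, net synaptic + injected), times.
#' @export
run_network <- function(cells, synapses, ext_spikes = NULL, i_ext = 0,
                        conditions = list(), duration_ms = 1000, dt_ms = 0.5,
                        seed = 1, etypes = default_etypes(),
                        record_v = integer(0), i_wave = NULL,
                        i_wave_gids = NULL) {
  ca <- conditions$calcium_mM %||% 2
  ach <- conditions$ach_uM %||% 0
  prof <- conditions$ca_profile %||% "intermediate"
  ncell <- nrow(cells)
  gids <- cells$gid
  gidx <- stats::setNames(seq_len(ncell), gids)
  nstep <- ceiling(duration_ms / dt_ms)
  times <- (seq_len(nstep) - 1) * dt_ms

  nm <- lapply(cells$etype, function(e) etypes[[e]])
  Cv <- vapply(nm, `[[`, 0, "C"); gL <- vapply(nm, `[[`, 0, "g_L")
  EL <- vapply(nm, `[[`, 0, "E_L"); VT <- vapply(nm, `[[`, 0, "V_T")
  dT <- vapply(nm, `[[`, 0, "delta_T"); Vr <- vapply(nm, `[[`, 0, "V_reset")
  tref <- vapply(nm, `[[`, 0, "t_ref"); aa <- vapply(nm, `[[`, 0, "a")
  bb <- vapply(nm, `[[`, 0, "b"); tw <- vapply(nm, `[[`, 0, "tau_w")
  Vcut <- vapply(nm, `[[`, 0, "V_cut")

  ns <- nrow(synapses)
  if (ns > 0) {
    if (is.null(synapses$delay)) synapses$delay <- 1
    if (is.null(synapses$tau_facil)) synapses$tau_facil <- 0
    syn_post <- gidx[as.character(synapses$post)]
    u_eff <- clamp(synapses$u_se * calcium_scaling(ca, prof) *
                     ach_release_scaling(ach), 0, 1)
    syn_u <- numeric(ns); syn_rec <- as.integer(synapses$n_rrp)
    syn_last <- rep(-Inf, ns)
    pre_map <- split(seq_len(ns), synapses$pre)
    delay_steps <- pmax(1L, as.integer(round(synapses$delay / dt_ms)))
    inh <- synapses$e_rev < -40
  } else {
    pre_map <- list(); inh <- logical(0)
  }
  # exc/inh conductance channels, single-exponential decay per class
  tau_e <- conditions$tau_e %||% 3; tau_i <- conditions$tau_i %||% 8
  gE <- numeric(ncell); gI <- numeric(ncell)
  max_delay <- if (ns > 0) max(delay_steps) else 1L
  bufE <- matrix(0, max_delay, ncell); bufI <- matrix(0, max_delay, ncell)

  ext_by_step <- NULL
  if (!is.null(ext_spikes) && nrow(ext_spikes) > 0) {
    stp <- pmin(nstep, floor(ext_spikes$time / dt_ms) + 1L)
    ext_by_step <- split(ext_spikes$gid, stp)
  }

  i_base <- rep(i_ext, length.out = ncell) + ach_current(ach)
  wave_mask <- if (is.null(i_wave_gids)) rep(TRUE, ncell) else
    gids %in% i_wave_gids

  v <- EL; w <- numeric(ncell); refr <- numeric(ncell)
  spk_g <- integer(0); spk_t <- numeric(0)
  vrec_idx <- match(record_v, gids); vrec_idx <- vrec_idx[!is.na(vrec_idx)]
  vrec <- if (length(vrec_idx)) matrix(NA_real_, nstep, length(vrec_idx)) else NULL
  isyn_rec <- matrix(0, nstep, ncell)
  prev_spiking <- integer(0)

  with_seed(seed, for (k in seq_len(nstep)) {
    t_now <- times[k]
    # presynaptic events: cells that spiked last step + external fibers now
    firing <- as.character(gids[prev_spiking])
    if (!is.null(ext_by_step)) {
      e <- ext_by_step[[as.character(k)]]
      if (!is.null(e)) firing <- c(firing, as.character(unique(e)))
    }
    if (length(firing) > 0 && ns > 0) {
      sidx <- unlist(pre_map[firing], use.names = FALSE)
      if (length(sidx) > 0) {
        dtv <- t_now - syn_last[sidx]
        n_unrec <- synapses$n_rrp[sidx] - syn_rec[sidx]
        p_rec <- 1 - exp(-dtv / synapses$tau_rec[sidx])
        p_rec[!is.finite(dtv)] <- 1
        syn_rec[sidx] <- syn_rec[sidx] +
          stats::rbinom(length(sidx), n_unrec, p_rec)
        uu <- ifelse(synapses$tau_facil[sidx] > 0 & is.finite(dtv),
                     syn_u[sidx] * exp(-dtv / synapses$tau_facil[sidx]), 0)
        uu <- uu + u_eff[sidx] * (1 - uu)
        rel <- stats::rbinom(length(sidx), syn_rec[sidx], uu)
        syn_rec[sidx] <- syn_rec[sidx] - rel
        syn_u[sidx] <- uu
        syn_last[sidx] <- t_now
        dg <- rel * synapses$g_max[sidx]
        hit <- dg > 0
        if (any(hit)) {
          slot <- ((k - 1 + delay_steps[sidx][hit]) %% max_delay) + 1L
          tgt <- syn_post[sidx][hit]
          for (q in seq_along(slot)) {
            if (inh[sidx][hit][q]) {
              bufI[slot[q], tgt[q]] <- bufI[slot[q], tgt[q]] + dg[q]
            } else {
              bufE[slot[q], tgt[q]] <- bufE[slot[q], tgt[q]] + dg[q]
            }
          }
        }
      }
    }
    slot_now <- ((k - 1) %% max_delay) + 1L
    gE <- gE * exp(-dt_ms / tau_e) + bufE[slot_now, ]
    gI <- gI * exp(-dt_ms / tau_i) + bufI[slot_now, ]
    bufE[slot_now, ] <- 0; bufI[slot_now, ] <- 0

    i_syn_pA <- -gE * (v - 0) - gI * (v - (-80))
    i_inj <- i_base
    if (!is.null(i_wave)) i_inj <- i_inj + ifelse(wave_mask, i_wave(t_now), 0)
    isyn_rec[k, ] <- i_syn_pA / 1000 + i_inj

    active <- refr <= 0
    expterm <- ifelse(dT > 0,
                      gL * dT * exp(clamp((v - VT) / dT, -50, 20)), 0)
    dv <- (-gL * (v - EL) + expterm - w * 1000 + i_syn_pA + i_inj * 1000) / Cv
    v <- ifelse(active, clamp(v + dt_ms * dv, -120, 60), v)
    w <- w + dt_ms * (aa * (v - EL) / 1000 - w) / tw
    refr <- pmax(0, refr - dt_ms)
    thr <- ifelse(dT > 0, Vcut, VT)
    spiking <- which(active & v >= thr)
    if (length(spiking) > 0) {
      v[spiking] <- Vr[spiking]
      w[spiking] <- w[spiking] + bb[spiking]
      refr[spiking] <- tref[spiking]
      spk_g <- c(spk_g, gids[spiking]); spk_t <- c(spk_t, rep(t_now, length(spiking)))
    }
    prev_spiking <- spiking
    if (!is.null(vrec)) vrec[k, ] <- v[vrec_idx]
    if (any(!is.finite(v))) stop("NaN/Inf membrane state at t = ", t_now)
  })
  list(spikes = data.frame(gid = spk_g, time = spk_t),
       v = vrec, v_gids = gids[vrec_idx], syn_current = isyn_rec,
       times = times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Point-source extracellular potential proxy
#'
#' V(channel) = sum_i I_i / (4 pi sigma d_i) with the source-channel
#' distance floored at \code{floor_um}. A proxy for forward modelling from
#' membrane currents; amplitudes are in arbitrary microvolt-like units.
#'
#' @param currents time x cells matrix (nA).
#' @param positions cells x 3 matrix of source positions (um).
#' @param channels channels x 3 matrix of electrode positions (um).
#' @param sigma_S_m extracellular conductivity (default 0.3 S/m).
#' @param floor_um distance floor (default 10 um).
#' @return list of class \code{field_trace}: samples (time x channels),
#'   depths (channel positions), n_floored.
#' @export
lfp_proxy <- function(currents, positions, channels, sigma_S_m = 0.3,
                      floor_um = 10) {
  positions <- matrix(positions, ncol = 3)
  channels <- matrix(channels, ncol = 3)
  nch <- nrow(channels)
  out <- matrix(0, nrow(currents), nch)
  n_floored <- 0L
  for (c_ in seq_len(nch)) {
    d <- sqrt(colSums((t(positions) - channels[c_, ])^2))
    n_floored <- n_floored + sum(d < floor_um)
    d <- pmax(d, floor_um)
    out[, c_] <- currents %*% (1 / (4 * pi * sigma_S_m * d))
  }
  structure(list(samples = out, depths = channels[, 2], n_floored = n_floored),
            class = "field_trace")
}

#' Input-output curve of Schaffer-collateral volleys
#'
#' Activates growing fractions of the SC fiber pool with a synchronous
#' volley and reports the fraction of sampled neurons that spike within the
#' response window, with and without GABAergic (inhibitory) synapses,
#' across seeds.
#'
#' @param cells,synapses circuit tables as for \code{\link{run_network}}.
#' @param n_fibers size of the SC fiber pool (negative pre ids 1..n_fibers).
#' @param fractions input levels (0-1).
#' @param sample_gids neurons scored (e.g. 101 SP cells).
#' @param seeds integer vector of seeds (one run per seed per condition).
#' @param t_volley_ms volley time. @param window_ms response window length.
#' @param i_ext,conditions,dt_ms passed to \code{\link{run_network}}.
#' @return data.frame: fraction, condition ("control"/"no_gaba"), seed,
#'   responding (fraction of sampled neurons spiking).
#' @export
io_curve <- function(cells, synapses, n_fibers, fractions = seq(0.05, 1, 0.05),
                     sample_gids = NULL, seeds = 1:5, t_volley_ms = 50,
                     window_ms = 50, i_ext = 0, conditions = list(),
                     dt_ms = 0.5) {
  if (is.null(sample_gids)) sample_gids <- cells$gid
  res <- list()
  for (sd_ in seeds) {
    fiber_order <- with_seed(substream_seed(sd_, "iofibers"),
                             sample.int(n_fibers))
    for (cond in c("control", "no_gaba")) {
      syn <- if (cond == "no_gaba") {
        synapses[synapses$e_rev > -40 | synapses$pre < 0, , drop = FALSE]
      } else synapses
      for (f in fractions) {
        nact <- max(1L, round(f * n_fibers))
        act <- fiber_order[seq_len(nact)]
        exts <- data.frame(gid = -act, time = t_volley_ms)
        sim <- run_network(cells, syn, ext_spikes = exts, i_ext = i_ext,
                           conditions = conditions,
                           duration_ms = t_volley_ms + window_ms + 10,
                           dt_ms = dt_ms, seed = substream_seed(sd_, "iorun"))
        spk <- sim$spikes
        hit <- unique(spk$gid[spk$time >= t_volley_ms &
                                spk$time <= t_volley_ms + window_ms])
        res[[length(res) + 1L]] <- data.frame(
          fraction = f, condition = cond, seed = sd_,
          responding = mean(sample_gids %in% hit))
      }
    }
  }
  do.call(rbind, res)
}
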