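#' Default pathway physiology for the surrogate network
#'
#' Per-class stochastic Tsodyks-Markram parameters used when wiring toy
#' circuits. Excitatory synapses reverse at 0 mV, inhibitory at -80 mV;
#' Schaffer-collateral inputs onto interneurons are strong and fast, giving
#' effective feedforward inhibition.
#'
#' @return named list of parameter lists.
#' @export
default_pathway_params <- function() {
  list(
    SC_PC  = list(g_max = 0.3, e_rev = 0, u_se = 0.5, tau_rec = 500,
                  tau_facil = 0, n_rrp = 12, delay = 1),
    SC_INT = list(g_max = 4.0, e_rev = 0, u_se = 0.5, tau_rec = 500,
                  tau_facil = 0, n_rrp = 2, delay = 1),
    E_E    = list(g_max = 0.3, e_rev = 0, u_se = 0.5, tau_rec = 670,
                  tau_facil = 17, n_rrp = 4, delay = 1),
    E_I    = list(g_max = 0.6, e_rev = 0, u_se = 0.5, tau_rec = 670,
                  tau_facil = 17, n_rrp = 2, delay = 1),
    I_E    = list(g_max = 1.2, e_rev = -80, u_se = 0.25, tau_rec = 420,
                  tau_facil = 20, n_rrp = 4, delay = 1),
    I_I    = list(g_max = 0.8, e_rev = -80, u_se = 0.25, tau_rec = 420,
                  tau_facil = 20, n_rrp = 2, delay = 1))
}

pathway_row <- function(pre, post, par) {
  data.frame(pre = pre, post = post, g_max = par$g_max, e_rev = par$e_rev,
             u_se = par$u_se, tau_rec = par$tau_rec,
             tau_facil = par$tau_facil, n_rrp = par$n_rrp, delay = par$delay)
}

#' Build a deterministic miniature CA1 circuit
#'
#' End-to-end fixture: a slab atlas with coordinates and layers, placed and
#' oriented cells, and a synapse table ready for \code{\link{run_network}}.
#' Wiring is either anatomical touch detection plus pruning ("touch",
#' suitable for a few tens of cells) or statistical ("random": fixed
#' in-degrees with the same admissibility structure, fast at a few hundred
#' cells). Schaffer-collateral afferents are always wired statistically:
#' each cell draws its convergence of synapses from a uniform fiber pool.
#'
#' @param n_pc,n_int cell counts.
#' @param n_fibers SC fiber pool size.
#' @param sc_per_pc,sc_per_int afferent synapses per cell.
#' @param wiring "random" or "touch".
#' @param k_ie,k_ei,k_ee in-degrees for random wiring (I->E per PC, E->I per
#'   INT, E->E per PC).
#' @param seed RNG seed.
#' @param pathway_params see \code{\link{default_pathway_params}}.
#' @return list: cells, synapses (internal), sc_synapses, n_fibers, field,
#'   layers, geoms (touch wiring only).
#' @export
make_toy_circuit <- function(n_pc = 40, n_int = 10, n_fibers = 100,
                             sc_per_pc = 40, sc_per_int = 20,
                             wiring = c("random", "touch"),
                             k_ie = 8, k_ei = 10, k_ee = 5,
                             seed = 1,
                             pathway_params = default_pathway_params()) {
  wiring <- match.arg(wiring)
  if (n_pc + n_int == 0) {
    empty <- data.frame()
    return(list(cells = empty, synapses = empty, sc_synapses = empty,
                n_fibers = n_fibers))
  }
  ax <- make_atlas("slab", dims = c(30, 10, 12), voxel_size = 20)
  cl <- compute_centerline(ax$mask, ax$endpoints)
  field <- build_coordinates(ax$mask, cl, ax$upper_shell, ax$lower_shell)
  props <- layer_proportions(c(SO = 168, SP = 59, SR = 279, SLM = 146))
  layers <- assign_layers(field, props)
  recipe <- data.frame(mtype = c("SP_PC", "SP_PVBC"),
                       layer = c("SP", "SP"),
                       count = c(n_pc, n_int))
  cells <- place_somata(field, layers, recipe,
                        seed = substream_seed(seed, "place"))
  pp <- pathway_params
  syn <- list()
  with_seed(substream_seed(seed, "wire"), {
    pcs <- cells$gid[is_pc(cells$mtype)]
    ints <- cells$gid[!is_pc(cells$mtype)]
    if (wiring == "random") {
      for (g in pcs) {
        if (length(ints) > 0 && k_ie > 0) {
          pre <- sample(ints, min(k_ie, length(ints)))
          syn[[length(syn) + 1L]] <- pathway_row(pre, g, pp$I_E)
        }
        if (k_ee > 0 && length(pcs) > 1) {
          pre <- sample(setdiff(pcs, g), min(k_ee, length(pcs) - 1))
          syn[[length(syn) + 1L]] <- pathway_row(pre, g, pp$E_E)
        }
      }
      for (g in ints) {
        if (k_ei > 0 && length(pcs) > 0) {
          pre <- sample(pcs, min(k_ei, length(pcs)))
          syn[[length(syn) + 1L]] <- pathway_row(pre, g, pp$E_I)
        }
      }
      geoms <- NULL
    } else {
      morphs_pc <- make_morphologies(4, "pc", depth = 2, seg_len = 30,
                                     axon_reach = 250,
                                     seed = substream_seed(seed, "mpc"))
      morphs_in <- make_morphologies(4, "interneuron", depth = 2,
                                     seg_len = 35,
                                     seed = substream_seed(seed, "mint"))
      sel <- lapply(seq_len(nrow(cells)), function(i) {
        if (is_pc(cells$mtype[i])) morphs_pc[[1 + (i %% 4)]]
        else morphs_in[[1 + (i %% 4)]]
      })
      rots <- lapply(seq_len(nrow(cells)), function(i) {
        orient_cell(field, cells[i, ], cells$mtype[i], sel[[i]],
                    seed = substream_seed(seed, paste0("rot", i)))
      })
      geoms <- realize_cells(cells, sel, rots)
      ap <- find_appositions(geoms)
      if (nrow(ap) > 0) {
        axlen <- stats::setNames(
          vapply(geoms, function(g) g$axon_length, 0),
          vapply(geoms, function(g) as.character(g$gid), ""))
        conn <- paste(ap$pre_gid, ap$post_gid)
        mu <- nrow(ap) / length(unique(conn))
        ap <- prune(ap, list(syn_per_conn = predict_synapses_per_connection(mu)),
                    axon_length = axlen,
                    seed = substream_seed(seed, "prune"))
        mt <- stats::setNames(cells$mtype, cells$gid)
        cls <- function(pre, post) {
          pe <- is_pc(mt[as.character(pre)]); po <- is_pc(mt[as.character(post)])
          ifelse(pe & po, "E_E", ifelse(pe, "E_I", ifelse(po, "I_E", "I_I")))
        }
        ap$class <- cls(ap$pre_gid, ap$post_gid)
        for (cc in unique(ap$class)) {
          sub <- ap[ap$class == cc, ]
          syn[[length(syn) + 1L]] <- pathway_row(sub$pre_gid, sub$post_gid,
                                                 pp[[cc]])
        }
      }
    }
    # SC afferents: statistical convergence from a uniform fiber pool
    sc <- list()
    for (g in pcs) {
      sc[[length(sc) + 1L]] <- pathway_row(-sample.int(n_fibers, sc_per_pc,
                                                       replace = TRUE),
                                           g, pp$SC_PC)
    }
    for (g in ints) {
      sc[[length(sc) + 1L]] <- pathway_row(-sample.int(n_fibers, sc_per_int,
                                                       replace = TRUE),
                                           g, pp$SC_INT)
    }
  })
  internal <- if (length(syn)) do.call(rbind, syn) else
    data.frame(pre = integer(0), post = integer(0))
  sc_tab <- if (length(sc)) do.call(rbind, sc) else
    data.frame(pre = integer(0), post = integer(0))
  rownames(internal) <- NULL; rownames(sc_tab) <- NULL
  list(cells = cells, synapses = internal, sc_synapses = sc_tab,
       n_fibers = n_fibers, field = field, layers = layers,
       geoms = if (wiring == "touch") geoms else NULL)
}
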