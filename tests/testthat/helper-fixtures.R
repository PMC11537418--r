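# shared fixtures, built once per test run and memoised

get_fx_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ax <- make_atlas("slab", dims = c(40, 12, 12), voxel_size = 10)
      cl <- compute_centerline(ax$mask, ax$endpoints)
      fld <- build_coordinates(ax$mask, cl, ax$upper_shell, ax$lower_shell)
      cache <<- list(ax = ax, cl = cl, field = fld)
    }
    cache
  }
})

get_fx_annulus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ax <- make_atlas("quarter_annulus", inner_radius = 40, outer_radius = 60,
                       thickness = 24, voxel_size = 10)
      cl <- compute_centerline(ax$mask, ax$endpoints)
      fld <- build_coordinates(ax$mask, cl, ax$upper_shell, ax$lower_shell)
      cache <<- list(ax = ax, cl = cl, field = fld)
    }
    cache
  }
})

# independent segment-segment distance oracle: dense parameter grid with one
# local refinement; error << 1e-3 um for segments up to ~100 um
oracle_seg_dist <- function(p0, p1, q0, q1, n = 41) {
  eval_grid <- function(ss, tt) {
    A <- outer(ss, p1 - p0) + matrix(p0, length(ss), 3, byrow = TRUE)
    B <- outer(tt, q1 - q0) + matrix(q0, length(tt), 3, byrow = TRUE)
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) - 2 * A %*% t(B) +
      outer(rep(1, nrow(A)), rowSums(B^2))
    idx <- arrayInd(which.min(d2), dim(d2))
    list(d = sqrt(max(0, d2[idx])), arg = c(ss[idx[1]], tt[idx[2]]))
  }
  g1 <- eval_grid(seq(0, 1, length.out = n), seq(0, 1, length.out = n))
  h <- 1 / (n - 1)
  s0 <- g1$arg[1]; t0 <- g1$arg[2]
  g2 <- eval_grid(seq(max(0, s0 - h), min(1, s0 + h), length.out = n),
                  seq(max(0, t0 - h), min(1, t0 + h), length.out = n))
  min(g1$d, g2$d)
}

# brute-force apposition oracle over realized cell geometries (no prefilter,
# independent distance routine)
oracle_appositions <- function(geoms, thresholds = c(onto_PC = 1, onto_INT = 6),
                               margin = 0) {
  out <- list()
  for (i in seq_along(geoms)) for (j in seq_along(geoms)) {
    if (i == j) next
    pre <- geoms[[i]]; post <- geoms[[j]]
    comps <- ca1forge:::admissible_compartments(pre$mtype, post$mtype)
    if (is.null(comps)) next
    thr <- if (grepl("PC$", post$mtype)) thresholds[["onto_PC"]] else
      thresholds[["onto_INT"]]
    axon <- pre$segments[pre$segments$compartment %in% c("axon", "AIS"), ]
    tcomp <- if ("AIS" %in% comps) "AIS" else setdiff(comps, "soma")
    tgt <- post$segments[post$segments$compartment %in% tcomp, ]
    for (k in seq_len(nrow(axon))) {
      q0 <- as.numeric(axon[k, c("x0", "y0", "z0")])
      q1 <- as.numeric(axon[k, c("x1", "y1", "z1")])
      for (h in seq_len(nrow(tgt))) {
        d <- oracle_seg_dist(q0, q1,
                             as.numeric(tgt[h, c("x0", "y0", "z0")]),
                             as.numeric(tgt[h, c("x1", "y1", "z1")]))
        if (d <= thr - margin) {
          out[[length(out) + 1L]] <- data.frame(
            pre_gid = pre$gid, post_gid = post$gid,
            pre_node = axon$node_id[k], post_node = tgt$node_id[h])
        }
      }
      if ("soma" %in% comps) {
        d <- oracle_seg_dist(q0, q1, post$soma$center, post$soma$center) -
          post$soma$radius
        if (d <= thr - margin) {
          out[[length(out) + 1L]] <- data.frame(
            pre_gid = pre$gid, post_gid = post$gid,
            pre_node = axon$node_id[k], post_node = 0L)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(pre_gid = integer(0), post_gid = integer(0),
                      pre_node = integer(0), post_node = integer(0)))
  }
  do.call(rbind, out)
}

# hand-built morphology: simple straight axon/dendrite cells for controlled
# apposition geometry
straight_cell_geom <- function(gid, mtype, soma, axon_to = NULL,
                               dend_to = NULL) {
  segs <- list()
  if (!is.null(axon_to)) {
    segs[[length(segs) + 1L]] <- data.frame(
      x0 = soma[1], y0 = soma[2], z0 = soma[3],
      x1 = axon_to[1], y1 = axon_to[2], z1 = axon_to[3],
      compartment = "axon", node_id = 2L)
  }
  if (!is.null(dend_to)) {
    segs[[length(segs) + 1L]] <- data.frame(
      x0 = soma[1], y0 = soma[2], z0 = soma[3],
      x1 = dend_to[1], y1 = dend_to[2], z1 = dend_to[3],
      compartment = "dend", node_id = 3L)
  }
  list(gid = gid, mtype = mtype,
       soma = list(center = soma, radius = 5),
       segments = do.call(rbind, segs),
       axon_length = if (is.null(axon_to)) 0 else
         sqrt(sum((axon_to - soma)^2)))
}

# simple morphology data.frame builders
chain_morph <- function(pts, types, radii = 1) {
  n <- nrow(pts)
  morphology(data.frame(
    id = seq_len(n), type = types, x = pts[, 1], y = pts[, 2], z = pts[, 3],
    radius = rep(radii, length.out = n),
    parent = c(-1L, seq_len(n - 1))), name = "chain")
}
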