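#' Afferent convergence targets as range midpoints
#'
#' Experimental reports bound the number of afferent Schaffer-collateral
#' synapses per CA1 pyramidal cell and per interneuron; the model targets
#' the midpoint of each range (e.g. 13,059-28,697 -> 20,878 for PCs and
#' 7,952-17,476 -> 12,714 for interneurons).
#'
#' @param range_pc,range_int length-2 numeric (low, high).
#' @return list(pc_target, int_target).
#' @export
convergence_targets <- function(range_pc, range_int) {
  stopifnot(range_pc[1] <= range_pc[2], range_int[1] <= range_int[2])
  list(pc_target = mean(range_pc), int_target = mean(range_int))
}

#' Allocate synapse counts to layers
#'
#' Largest-remainder integer allocation of a total over per-layer fractions
#' (e.g. SLM 0.3%, SR 67.9%, SP 7.1%, SO 24.7% for Schaffer collaterals).
#'
#' @param total synapse count.
#' @param fractions named fractions summing to 1 (within 1e-6).
#' @return named integer counts summing exactly to total.
#' @export
allocate_layer_counts <- function(total, fractions) {
  if (abs(sum(fractions) - 1) > 1e-6) stop("layer fractions must sum to 1")
  stats::setNames(largest_remainder(total, fractions), names(fractions))
}

#' Length-weighted segment sampling of synapse placements
#'
#' Draws \code{n} postsynaptic segments with replacement, weighted by segment
#' length so short segments are not oversampled, then places each synapse at
#' a uniform random offset along its segment. Somata are excluded upstream
#' (they are not viable targets for this pathway).
#'
#' @param segments data.frame with x0..z1 coordinates plus any id columns
#'   (e.g. post_gid, node_id).
#' @param n number of placements.
#' @param seed RNG seed.
#' @return data.frame: the sampled segment rows plus \code{offset} (0-1) and
#'   synapse coordinates x, y, z.
#' @export
sample_segments <- function(segments, n, seed = 1) {
  if (n == 0) return(cbind(segments[0, , drop = FALSE],
                           offset = numeric(0), x = numeric(0),
                           y = numeric(0), z = numeric(0)))
  if (nrow(segments) == 0) stop("empty segment pool with positive count")
  len <- sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2 +
                (segments$z1 - segments$z0)^2)
  with_seed(seed, {
    idx <- sample.int(nrow(segments), n, replace = TRUE, prob = len)
    off <- stats::runif(n)
    out <- segments[idx, , drop = FALSE]
    out$offset <- off
    out$x <- out$x0 + off * (out$x1 - out$x0)
    out$y <- out$y0 + off * (out$y1 - out$y0)
    out$z <- out$z0 + off * (out$z1 - out$z0)
    rownames(out) <- NULL
    out
  })
}

#' Assign presynaptic fibers to synapse placements
#'
#' Each synapse is attached to a uniformly random fiber id in 1..n_fibers,
#' so per-fiber divergence is multinomial around total/n_fibers.
#'
#' @param placements data.frame of synapse placements.
#' @param n_fibers number of afferent fibers (>= 1).
#' @param seed RNG seed.
#' @return placements with a \code{fiber} column.
#' @export
assign_fibers <- function(placements, n_fibers, seed = 1) {
  stopifnot(n_fibers >= 1)
  with_seed(seed, {
    placements$fiber <- sample.int(n_fibers, nrow(placements), replace = TRUE)
  })
  placements
}

#' Build a Schaffer-collateral projection onto a toy circuit
#'
#' Runs the afferent workflow separately for pyramidal cells and
#' interneurons: per-class totals from convergence targets, layer allocation
#' from the recipe fractions, length-weighted segment sampling within each
#' layer, and uniform fiber assignment.
#'
#' @param geoms list from \code{\link{realize_cells}}.
#' @param cells the placed-cell table (for m-types and layers).
#' @param field coordinate field (for the synapse layer label).
#' @param layers layer label array.
#' @param recipe list: n_fibers, pc_target, int_target, layer_fractions
#'   (named over layers present).
#' @param seed RNG seed.
#' @return synapse table with pathway label "SC": fiber, post_gid, node_id,
#'   offset, x, y, z, layer.
#' @export
build_sc_projection <- function(geoms, cells, field, layers, recipe, seed = 1) {
  seg_all <- do.call(rbind, lapply(geoms, function(g) {
    s <- g$segments[g$segments$compartment == "dend", , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    s$post_gid <- g$gid
    s$post_is_pc <- is_pc(g$mtype)
    s
  }))
  d <- dim(field$r); vs <- field$mask$voxel_size
  seg_layer <- function(s) {
    mid <- cbind((s$x0 + s$x1) / 2, (s$y0 + s$y1) / 2, (s$z0 + s$z1) / 2)
    ijk <- pmin(pmax(ceiling(sweep(mid, 2, field$mask$origin) / vs), 1),
                matrix(d, nrow(s), 3, byrow = TRUE))
    layers[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
  }
  seg_all$layer <- seg_layer(seg_all)
  out <- list()
  for (cls in c(TRUE, FALSE)) {
    segs <- seg_all[seg_all$post_is_pc == cls & !is.na(seg_all$layer), ,
                    drop = FALSE]
    n_post <- sum(is_pc(cells$mtype) == cls)
    if (n_post == 0 || nrow(segs) == 0) next
    tgt <- if (cls) recipe$pc_target else recipe$int_target
    total <- round(tgt * n_post)
    fr <- recipe$layer_fractions[recipe$layer_fractions > 0]
    present <- intersect(names(fr), unique(segs$layer))
    fr <- fr[present] / sum(fr[present])
    counts <- allocate_layer_counts(total, fr)
    for (ly in names(counts)) {
      pool <- segs[segs$layer == ly, , drop = FALSE]
      if (counts[[ly]] == 0) next
      if (nrow(pool) == 0) stop("no segments in layer ", ly)
      pl <- sample_segments(pool, counts[[ly]],
                            seed = substream_seed(seed, paste0("sc", ly, cls)))
      out[[length(out) + 1L]] <- pl
    }
  }
  syn <- do.call(rbind, out)
  syn <- assign_fibers(syn, recipe$n_fibers,
                       seed = substream_seed(seed, "fiber"))
  syn$pathway <- "SC"
  rownames(syn) <- NULL
  syn
}
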