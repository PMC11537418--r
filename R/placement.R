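#' Derive a cell composition from pyramidal-cell density and E/I balance
#'
#' The pyramidal count is density x SP volume. Interneuron pools are given as
#' relative proportions and rescaled so that the inhibitory fraction of the
#' total equals \code{ei_ratio} (CA1 E:I is 89:11).
#'
#' @param pc_density pyramidal cells per mm^3 (e.g. 264e3).
#' @param sp_volume stratum pyramidale volume in mm^3.
#' @param interneuron_pools named non-negative vector of relative interneuron
#'   pool sizes (any scale).
#' @param ei_ratio inhibitory fraction of all neurons, in (0, 1).
#' @return data.frame with mtype, count, excitatory.
#' @export
derive_composition <- function(pc_density, sp_volume, interneuron_pools,
                               ei_ratio = 0.11) {
  stopifnot(pc_density > 0, ei_ratio > 0, ei_ratio < 1,
            all(interneuron_pools >= 0), sum(interneuron_pools) > 0)
  if (sp_volume <= 0) stop("SP volume must be positive")
  pc <- round(pc_density * sp_volume)
  int_total <- round(pc * ei_ratio / (1 - ei_ratio))
  ints <- largest_remainder(int_total, interneuron_pools)
  data.frame(
    mtype = c("SP_PC", names(interneuron_pools)),
    count = c(pc, ints),
    excitatory = c(TRUE, rep(FALSE, length(ints))),
    stringsAsFactors = FALSE)
}

# relative position of r within its layer's r-interval
layer_relative_position <- function(r, breaks, layer_names, layer) {
  k <- match(layer, layer_names)
  (r - breaks[k]) / (breaks[k + 1] - breaks[k])
}

#' Place somata by density-weighted multinomial voxel allocation
#'
#' Each m-type's requested count is split over its admissible voxels by a
#' multinomial draw with weights proportional to density x voxel volume, so
#' the total is conserved exactly; cells land uniformly within their voxel.
#' SR_SCA somata are restricted to the mid-SR band (0.5 +/- 0.05 of the layer)
#' and SLM_PPA to the lower SLM band (0.02-0.10 of the layer).
#'
#' @param field a \code{ca1_coordinate_field}.
#' @param layers layer-label array from \code{\link{assign_layers}}.
#' @param recipe data.frame with columns mtype, layer (label, or several
#'   separated by "+"), count; optional column etype with e-type label.
#' @param seed RNG seed.
#' @return data.frame of cells: gid, mtype, etype, x, y, z, l, t, r, layer.
#' @export
place_somata <- function(field, layers, recipe, seed = 1) {
  breaks <- attr(layers, "breaks"); lnames <- attr(layers, "layers")
  occ <- field$mask$occupancy
  vs <- field$mask$voxel_size
  vox <- which(occ)
  ai <- arrayInd(vox, dim(occ))
  vlayer <- layers[vox]
  vr <- field$r[vox]
  out <- list()
  gid0 <- 0L
  with_seed(seed, {
    for (i in seq_len(nrow(recipe))) {
      mt <- recipe$mtype[i]
      lys <- strsplit(recipe$layer[i], "\\+")[[1]]
      adm <- vlayer %in% lys
      if (grepl("SCA$", mt)) {
        rel <- layer_relative_position(vr, breaks, lnames, "SR")
        adm <- adm & rel >= 0.45 & rel <= 0.55
      } else if (grepl("PPA$", mt)) {
        rel <- layer_relative_position(vr, breaks, lnames, "SLM")
        adm <- adm & rel >= 0.02 & rel <= 0.10
      }
      if (!any(adm)) stop("no admissible voxels for m-type ", mt)
      cnt <- recipe$count[i]
      if (cnt == 0) next
      sel <- which(adm)
      w <- rep(1, length(sel))          # equal voxel volumes, uniform density
      alloc <- as.vector(stats::rmultinom(1, cnt, w))
      rep_idx <- rep(sel, alloc)
      jit <- matrix(stats::runif(3 * cnt, -0.5, 0.5), ncol = 3)
      pos <- sweep((ai[rep_idx, , drop = FALSE] - 0.5 + jit) * vs, 2,
                   field$mask$origin, `+`)
      et <- if ("etype" %in% names(recipe)) recipe$etype[i] else
        if (isTRUE(recipe$excitatory[i]) || grepl("PC$", mt)) "cADpyr" else "cAC"
      out[[length(out) + 1L]] <- data.frame(
        gid = gid0 + seq_len(cnt), mtype = mt, etype = et,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        l = field$l[vox[rep_idx]], t = field$t[vox[rep_idx]],
        r = field$r[vox[rep_idx]], layer = vlayer[rep_idx],
        stringsAsFactors = FALSE)
      gid0 <- gid0 + cnt
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# numerical gradient direction of a coordinate array at a voxel
field_axis <- function(field, which_coord, ijk) {
  a <- field[[which_coord]]
  d <- dim(a)
  g <- numeric(3)
  for (ax in 1:3) {
    lo <- ijk; hi <- ijk
    lo[ax] <- max(1, ijk[ax] - 1); hi[ax] <- min(d[ax], ijk[ax] + 1)
    v1 <- a[lo[1], lo[2], lo[3]]; v2 <- a[hi[1], hi[2], hi[3]]
    if (is.na(v1) || is.na(v2)) { g[ax] <- 0; next }
    g[ax] <- (v2 - v1) / max(1, hi[ax] - lo[ax])
  }
  if (sum(g^2) < 1e-18) return(NULL)
  g / sqrt(sum(g^2))
}

#' Orientation (rotation matrix) for a cell at a position
#'
#' The morphology's local y-axis is aligned with the radial direction vector.
#' Interneurons receive a seeded uniform rotation about it; pyramidal cells
#' are rotated so the (pre-aligned, x-axis) axon lies along the local
#' transverse direction, with the branch-rich side facing decreasing t
#' (the subiculum end).
#'
#' @param field a \code{ca1_coordinate_field}.
#' @param cell one-row data.frame from \code{\link{place_somata}}.
#' @param mtype m-type label; "*PC" types get the transverse axon rule.
#' @param morph optional \code{ca1_morphology} used to find the branch-rich
#'   axon side (its x sign); defaults to -x.
#' @param seed RNG seed for the interneuron azimuth.
#' @return 3 x 3 rotation matrix (columns = images of local x, y, z).
#' @export
orient_cell <- function(field, cell, mtype, morph = NULL, seed = 1) {
  d <- dim(field$r)
  vs <- field$mask$voxel_size
  ijk <- pmin(pmax(ceiling((c(cell$x, cell$y, cell$z) - field$mask$origin) / vs),
                   1), d)
  yloc <- field$direction[, ijk[1], ijk[2], ijk[3]]
  yloc <- yloc / sqrt(sum(yloc^2))
  tdir <- field_axis(field, "t", ijk)
  if (is.null(tdir)) tdir <- field_axis(field, "l", ijk)
  if (is.null(tdir)) tdir <- if (abs(yloc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  xloc <- tdir - sum(tdir * yloc) * yloc
  xloc <- xloc / sqrt(sum(xloc^2))
  zloc <- c(xloc[2] * yloc[3] - xloc[3] * yloc[2],
            xloc[3] * yloc[1] - xloc[1] * yloc[3],
            xloc[1] * yloc[2] - xloc[2] * yloc[1])
  R <- cbind(xloc, yloc, zloc)
  if (grepl("PC$", mtype)) {
    # point the branch-rich axon side toward decreasing t
    rich_sign <- -1
    if (!is.null(morph)) {
      ax <- morph$nodes[morph$nodes$type == SWC_AXON, , drop = FALSE]
      kid_count <- table(ax$parent)
      bps <- ax[ax$id %in% as.integer(names(kid_count)[kid_count > 1]), ,
                drop = FALSE]
      if (nrow(bps) > 0) rich_sign <- sign(sum(sign(bps$x)) + 0.5)
    }
    # local x currently maps morph +x to increasing t; flip if the rich side
    # would face increasing t
    if (rich_sign > 0) R <- R %*% diag(c(-1, 1, -1))
  } else {
    th <- with_seed(seed, stats::runif(1, 0, 2 * pi))
    Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
    R <- R %*% Ry
  }
  R
}

#' Interval overlap score between a morphology interval and a target interval
#'
#' overlap(a, r) / max(width(a), width(r)), floored at 0: only a perfect
#' overlap scores 1.
#'
#' @param a,r numeric length-2 intervals (lo, hi), micrometres.
#' @return score in [0, 1].
#' @export
interval_score <- function(a, r) {
  wa <- a[2] - a[1]; wr <- r[2] - r[1]
  den <- max(wa, wr)
  if (den <= 0) return(as.numeric(a[1] == r[1] && a[2] == r[2]))
  max((min(a[2], r[2]) - max(a[1], r[1])) / den, 0)
}

#' Aggregate placement score for a morphology at a soma position
#'
#' Optional rule scores are combined by a harmonic mean (zero if any optional
#' score falls below 0.001); strict rules by a minimum; the total is their
#' product. Morphology intervals are shifted by the soma position y0 before
#' scoring.
#'
#' @param rules list of rules, each a list with \code{kind}
#'   ("optional"/"strict"), \code{interval} (annotation interval, micrometres
#'   relative to the soma) and \code{target} (target interval along the local
#'   radial axis, micrometres, absolute).
#' @param y0 soma position along the radial axis, micrometres.
#' @return total score in [0, 1]; components in attributes
#'   \code{optional_score}, \code{strict_score}.
#' @export
score_placement <- function(rules, y0 = 0) {
  stopifnot(length(rules) > 0)
  opt <- numeric(0); str_ <- numeric(0)
  for (rl in rules) {
    s <- interval_score(rl$interval + y0, rl$target)
    if (identical(rl$kind, "strict")) str_ <- c(str_, s) else opt <- c(opt, s)
  }
  i_hat <- if (length(opt) == 0) 1
           else if (any(opt < 0.001)) 0
           else length(opt) / sum(1 / opt)
  l_hat <- if (length(str_) == 0) 1 else min(str_)
  out <- i_hat * l_hat
  attr(out, "optional_score") <- i_hat
  attr(out, "strict_score") <- l_hat
  out
}

#' Select a morphology for a position from scored candidates
#'
#' Samples among candidates with probability proportional to score
#' ("proportional", the default, resolves ties and near-ties by seeded
#' sampling) or picks the argmax ("argmax"). All-zero scores drop the
#' position (a counted outcome, not an error).
#'
#' @param scores numeric candidate scores in [0, 1].
#' @param method "proportional" or "argmax".
#' @param seed RNG seed.
#' @return index into scores, or NA_integer_ if the position is dropped.
#' @export
select_morphology <- function(scores, method = c("proportional", "argmax"),
                              seed = 1) {
  method <- match.arg(method)
  if (length(scores) == 0 || all(scores <= 0)) return(NA_integer_)
  if (method == "argmax") return(which.max(scores))
  with_seed(seed, sample.int(length(scores), 1, prob = scores))
}
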