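#' @section SWC type codes:
#' 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite.
#' @name morph-module
#' @keywords internal
NULL

SWC_SOMA <- 1L; SWC_AXON <- 2L; SWC_BASAL <- 3L; SWC_APICAL <- 4L

soma_center <- function(m) {
  s <- m$nodes[m$nodes$type == SWC_SOMA, , drop = FALSE]
  if (nrow(s) == 0) s <- m$nodes[m$nodes$parent == -1, , drop = FALSE]
  c(mean(s$x), mean(s$y), mean(s$z))
}

soma_radius <- function(m) {
  s <- m$nodes[m$nodes$type == SWC_SOMA, , drop = FALSE]
  if (nrow(s) == 0) return(0)
  max(s$radius)
}

#' Curate a raw morphology
#'
#' Centers the soma at the origin, removes zero-length segments, flags
#' missing axons, and compensates tissue shrinkage by anisotropic rescaling:
#' coordinates are multiplied by (1 + shrink_xy) in x/y and (1 + shrink_z)
#' in z (slice preparations typically shrink ~25% in z and ~10% in x/y).
#'
#' @param m a \code{ca1_morphology}.
#' @param shrink_z,shrink_xy shrinkage fractions to compensate (>= 0).
#' @return curated \code{ca1_morphology} (provenance "repaired"); attribute
#'   \code{no_axon} is TRUE for cells without any axon node.
#' @export
curate <- function(m, shrink_z = 0, shrink_xy = 0) {
  n <- m$nodes
  ctr <- soma_center(m)
  n$x <- n$x - ctr[1]; n$y <- n$y - ctr[2]; n$z <- n$z - ctr[3]
  # drop zero-length segments (child duplicating its parent position)
  repeat {
    p <- match(n$parent, n$id)
    zl <- which(!is.na(p) &
                  (n$x - n$x[p])^2 + (n$y - n$y[p])^2 + (n$z - n$z[p])^2 < 1e-18 &
                  n$type == n$type[p] & n$type != SWC_SOMA)
    if (length(zl) == 0) break
    drop_id <- n$id[zl[1]]; parent_id <- n$parent[zl[1]]
    n$parent[n$parent == drop_id] <- parent_id
    n <- n[n$id != drop_id, ]
  }
  n$x <- n$x * (1 + shrink_xy); n$y <- n$y * (1 + shrink_xy)
  n$z <- n$z * (1 + shrink_z)
  out <- morphology(n, name = m$name, provenance = "repaired")
  attr(out, "no_axon") <- !any(n$type == SWC_AXON)
  out
}

# children list keyed by row index, rows in parent-before-child order
child_index <- function(nodes) {
  p <- match(nodes$parent, nodes$id)
  split(seq_len(nrow(nodes))[!is.na(p)], p[!is.na(p)])
}

#' Scale-and-jitter clone of a morphology
#'
#' Isotropic scaling by (1 + scale) with |scale| <= 0.15, plus seeded
#' per-branch diversification: each branch gets a rotation about its parent
#' direction drawn from N(0, jitter_rot_sd) and a length factor from
#' N(1, jitter_len_sd), applied to the whole branch.
#'
#' @param m a \code{ca1_morphology}.
#' @param scale fraction in [-0.15, 0.15].
#' @param jitter_rot_sd rotation jitter SD, radians (0 disables).
#' @param jitter_len_sd branch length factor SD (0 disables).
#' @param seed RNG seed for the jitter.
#' @return cloned \code{ca1_morphology} (provenance "clone").
#' @export
scale_clone <- function(m, scale = 0, jitter_rot_sd = 0, jitter_len_sd = 0,
                        seed = 1) {
  if (abs(scale) > 0.15 + 1e-12) stop("|scale| must be <= 0.15")
  n <- m$nodes
  f <- 1 + scale
  n$x <- n$x * f; n$y <- n$y * f; n$z <- n$z * f
  n$radius <- n$radius * f
  if (jitter_rot_sd > 0 || jitter_len_sd > 0) {
    n <- with_seed(seed, jitter_branches(n, jitter_rot_sd, jitter_len_sd))
  }
  morphology(n, name = paste0(m$name, "_clone"), provenance = "clone")
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  matrix(c(
    a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
    a[2] * a[1] * C + a[3] * s_, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s_,
    a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, a[3]^2 * C + c_),
    3, 3, byrow = TRUE)
}

# per-branch rotation/length jitter; nodes must be parent-before-child
jitter_branches <- function(nodes, rot_sd, len_sd) {
  kids <- child_index(nodes)
  nkids <- vapply(seq_len(nrow(nodes)), function(i) {
    k <- kids[[as.character(i)]]; if (is.null(k)) 0L else length(k)
  }, 0L)
  pos <- cbind(nodes$x, nodes$y, nodes$z)
  newpos <- pos
  pidx <- match(nodes$parent, nodes$id)
  # accumulated transform per node: rotation matrix and length factor
  Rs <- vector("list", nrow(nodes)); lens <- rep(1, nrow(nodes))
  root <- which(nodes$parent == -1)
  Rs[[root]] <- diag(3)
  for (i in seq_len(nrow(nodes))) {
    if (i == root) next
    p <- pidx[i]
    R <- Rs[[p]]; lf <- lens[p]
    branch_start <- nkids[p] != 1L  # child of a branch point (or of root)
    if (branch_start) {
      seg <- pos[i, ] - pos[p, ]
      axis <- if (sum(seg^2) > 1e-18) seg else c(0, 1, 0)
      if (rot_sd > 0) R <- R %*% rotation_about(axis, stats::rnorm(1, 0, rot_sd))
      if (len_sd > 0) lf <- lf * max(0.2, stats::rnorm(1, 1, len_sd))
    }
    Rs[[i]] <- R; lens[i] <- lf
    seg <- pos[i, ] - pos[p, ]
    newpos[i, ] <- newpos[p, ] + as.vector(R %*% seg) * lf
  }
  nodes$x <- newpos[, 1]; nodes$y <- newpos[, 2]; nodes$z <- newpos[, 3]
  nodes
}

#' Align the axon principal axis with the transverse (x) axis
#'
#' Rotates the whole morphology so the first principal component of the
#' axonal point cloud lies along x, with the axon centroid on the +x side so
#' the caudal portion is oriented consistently. Collinear or tiny axons fall
#' back to the first-to-last-point direction. When \code{original} is given
#' (clone validation), the aligned clone is rejected if its z-range exceeds
#' \code{reject_ratio} times the aligned original's z-range.
#'
#' @param m a \code{ca1_morphology} with an axon.
#' @param original optional reference \code{ca1_morphology}.
#' @param reject_ratio rejection threshold on the z-range ratio.
#' @return aligned \code{ca1_morphology}, or \code{NULL} if rejected.
#' @export
pca_align_axon <- function(m, original = NULL, reject_ratio = 3.3) {
  ax <- m$nodes[m$nodes$type == SWC_AXON, , drop = FALSE]
  if (nrow(ax) < 3) stop("axon must have at least 3 points")
  pts <- cbind(ax$x, ax$y, ax$z)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  v1 <- sv$v[, 1]
  if (sv$d[1] < 1e-9) v1 <- pts[nrow(pts), ] - pts[1, ]
  if (sqrt(sum(v1^2)) < 1e-12) v1 <- c(1, 0, 0)
  v1 <- v1 / sqrt(sum(v1^2))
  if (sum(v1 * ctr) < 0) v1 <- -v1   # axon bulk toward +x
  R <- rotation_to_x(v1)
  n <- m$nodes
  rot <- cbind(n$x, n$y, n$z) %*% t(R)
  n$x <- rot[, 1]; n$y <- rot[, 2]; n$z <- rot[, 3]
  out <- morphology(n, name = m$name, provenance = m$provenance)
  if (!is.null(original)) {
    zr <- diff(range(out$nodes$z))
    zr0 <- diff(range(original$nodes$z))
    if (zr0 > 0 && zr / zr0 > reject_ratio) return(NULL)
  }
  out
}

# rotation taking unit vector v to +x
rotation_to_x <- function(v) {
  x <- c(1, 0, 0)
  c_ <- sum(v * x)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  axis <- c(v[2] * x[3] - v[3] * x[2], v[3] * x[1] - v[1] * x[3],
            v[1] * x[2] - v[2] * x[1])
  rotation_about(axis, acos(c_))
}

#' Default "overall visible spread" of two samples
#'
#' Width of the union of the boxplot whisker intervals
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR] of the two populations.
#'
#' @param a,b numeric vectors.
#' @return non-negative scalar.
#' @export
ovs_whisker_union <- function(a, b) {
  wi <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  }
  ia <- wi(a); ib <- wi(b)
  max(ia[2], ib[2]) - min(ia[1], ib[1])
}

#' Median-over-visible-spread (MVS) score between two feature populations
#'
#' |median(a) - median(b)| / OVS(a, b). Scores below 0.3 indicate good
#' agreement between the populations. The spread function is pluggable; the
#' default is the whisker-union rule of \code{\link{ovs_whisker_union}}.
#'
#' @param a,b numeric vectors (non-empty, finite).
#' @param ovs function(a, b) -> positive scalar spread.
#' @return non-negative scalar; +Inf (with a warning) when the spread is zero
#'   but the medians differ.
#' @export
mvs_score <- function(a, b, ovs = ovs_whisker_union) {
  stopifnot(length(a) > 0, length(b) > 0, all(is.finite(a)), all(is.finite(b)))
  dm <- abs(stats::median(a) - stats::median(b))
  s <- ovs(a, b)
  if (s <= 0) {
    if (dm == 0) return(0)
    warning("zero spread with unequal medians; score is infinite")
    return(Inf)
  }
  dm / s
}

#' Topological persistence diagram of a neurite
#'
#' Radial-distance filtration of the neurite tree with the elder rule: the
#' filtration value of a node is its Euclidean distance from the soma surface
#' (soma radius subtracted, floored at 0). At each branch point the component
#' whose tip reaches farthest survives; every other component dies and
#' contributes one bar (start = its farthest tip distance, end = the merge
#' distance). One bar per leaf.
#'
#' @param m a \code{ca1_morphology}.
#' @param neurite_type SWC type code(s): 2 axon, 3 basal, 4 apical.
#' @return data.frame with columns start, end (micrometres); zero rows for an
#'   absent neurite.
#' @export
persistence_diagram <- function(m, neurite_type = SWC_APICAL) {
  n <- m$nodes
  ctr <- soma_center(m); sr <- soma_radius(m)
  keep <- n$type %in% neurite_type
  if (!any(keep)) return(data.frame(start = numeric(0), end = numeric(0)))
  f_all <- pmax(0, sqrt((n$x - ctr[1])^2 + (n$y - ctr[2])^2 +
                          (n$z - ctr[3])^2) - sr)
  # treat the neurite as rooted at the soma (filtration 0)
  sub <- which(keep)
  in_sub <- logical(nrow(n)); in_sub[sub] <- TRUE
  pidx <- match(n$parent, n$id)
  parent_sub <- ifelse(!is.na(pidx) & in_sub[pidx], pidx, NA)
  kids <- split(sub[!is.na(parent_sub[sub])],
                parent_sub[sub][!is.na(parent_sub[sub])])
  bars_s <- numeric(0); bars_e <- numeric(0)
  # reverse topological order: children come after parents in `n`
  vmax <- f_all
  for (i in rev(sub)) {
    ch <- kids[[as.character(i)]]
    if (is.null(ch) || length(ch) == 0) next            # leaf: vmax = f
    vv <- vmax[ch]
    surv <- which.max(vv)
    vmax[i] <- vv[surv]   # carries the farthest *tip* of the component
    if (length(ch) > 1) {
      dead <- vv[-surv]
      bars_s <- c(bars_s, dead)
      bars_e <- c(bars_e, rep(f_all[i], length(dead)))
    }
  }
  # stems (subtree roots whose parent is outside the neurite) die at the soma
  stems <- sub[is.na(parent_sub[sub])]
  for (s_ in stems) {
    bars_s <- c(bars_s, vmax[s_]); bars_e <- c(bars_e, 0)
  }
  out <- data.frame(start = bars_s, end = bars_e)
  out[order(-out$start), , drop = FALSE]
}

#' Persistence image of a diagram
#'
#' Gaussian-kernel density of the (start, end) bar points on a regular grid,
#' normalised to integrate to 1.
#'
#' @param d persistence diagram (data.frame start/end) or a list of diagrams
#'   (population; bars pooled).
#' @param grid_n grid resolution per axis.
#' @param bandwidth Gaussian sigma in micrometres.
#' @param xlim,ylim axis limits; default spans the data plus 3 bandwidths.
#' @return matrix grid_n x grid_n with attributes \code{x}, \code{y}.
#' @export
persistence_image <- function(d, grid_n = 50, bandwidth = 10,
                              xlim = NULL, ylim = NULL) {
  if (is.list(d) && !is.data.frame(d)) d <- do.call(rbind, d)
  stopifnot(nrow(d) > 0)
  if (is.null(xlim)) xlim <- range(d$start) + c(-3, 3) * bandwidth
  if (is.null(ylim)) ylim <- range(d$end) + c(-3, 3) * bandwidth
  gx <- seq(xlim[1], xlim[2], length.out = grid_n)
  gy <- seq(ylim[1], ylim[2], length.out = grid_n)
  img <- matrix(0, grid_n, grid_n)
  for (k in seq_len(nrow(d))) {
    img <- img + outer(stats::dnorm(gx, d$start[k], bandwidth),
                       stats::dnorm(gy, d$end[k], bandwidth))
  }
  cell <- diff(gx)[1] * diff(gy)[1]
  tot <- sum(img) * cell
  if (tot > 0) img <- img / tot
  attr(img, "x") <- gx; attr(img, "y") <- gy
  img
}

#' Difference of persistence images of two populations
#'
#' Both populations are rendered on a common grid before subtraction.
#' @param pop_a,pop_b lists of persistence diagrams.
#' @inheritParams persistence_image
#' @return matrix (image A minus image B).
#' @export
persistence_image_diff <- function(pop_a, pop_b, grid_n = 50, bandwidth = 10) {
  all_ <- rbind(do.call(rbind, pop_a), do.call(rbind, pop_b))
  xlim <- range(all_$start) + c(-3, 3) * bandwidth
  ylim <- range(all_$end) + c(-3, 3) * bandwidth
  ia <- persistence_image(pop_a, grid_n, bandwidth, xlim, ylim)
  ib <- persistence_image(pop_b, grid_n, bandwidth, xlim, ylim)
  ia - ib
}
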