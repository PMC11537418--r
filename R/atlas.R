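#' Voxelized region mask
#'
#' A dense boolean occupancy grid with world metadata. Voxel centers sit at
#' \code{origin + (index - 0.5) * voxel_size} (micrometres).
#'
#' @param occupancy 3-D logical array.
#' @param voxel_size micrometres per voxel edge.
#' @param origin world offset of the grid corner, micrometres.
#' @return object of class \code{ca1_mask}.
#' @export
region_mask <- function(occupancy, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(length(dim(occupancy)) == 3, voxel_size > 0)
  occ <- array(as.logical(occupancy), dim = dim(occupancy))
  if (!any(occ)) stop("empty region mask")
  structure(list(occupancy = occ, voxel_size = voxel_size, origin = origin),
            class = "ca1_mask")
}

#' @export
print.ca1_mask <- function(x, ...) {
  cat(sprintf("<ca1_mask> %s voxels (%d occupied), voxel %g um\n",
              paste(dim(x$occupancy), collapse = "x"), sum(x$occupancy),
              x$voxel_size))
  invisible(x)
}

#' World coordinates of occupied voxel centers
#' @param mask a \code{ca1_mask}.
#' @return matrix n x 3 (micrometres).
#' @export
voxel_centers <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  sweep((idx - 0.5) * mask$voxel_size, 2, mask$origin, `+`)
}

# shift a 3-D array by (di,dj,dk), padding with `fill`
shift3 <- function(a, di, dj, dk, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  si <- seq_len(d[1]); sj <- seq_len(d[2]); sk <- seq_len(d[3])
  fi <- si - di; fj <- sj - dj; fk <- sk - dk
  oki <- fi >= 1 & fi <= d[1]; okj <- fj >= 1 & fj <= d[2]; okk <- fk >= 1 & fk <= d[3]
  out[si[oki], sj[okj], sk[okk]] <- a[fi[oki], fj[okj], fk[okk]]
  out
}

neighbor_offsets <- function(connectivity = 26) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  if (connectivity == 6) g <- g[abs(g$di) + abs(g$dj) + abs(g$dk) == 1, ]
  g
}

dilate3 <- function(a, connectivity = 26) {
  out <- a
  offs <- neighbor_offsets(connectivity)
  for (i in seq_len(nrow(offs)))
    out <- out | shift3(a, offs$di[i], offs$dj[i], offs$dk[i], fill = FALSE)
  out
}

erode3 <- function(a, connectivity = 26, pad = TRUE) {
  # pad = TRUE treats out-of-array as occupied (border-neutral closing)
  out <- a
  offs <- neighbor_offsets(connectivity)
  for (i in seq_len(nrow(offs)))
    out <- out & shift3(a, offs$di[i], offs$dj[i], offs$dk[i], fill = pad)
  out
}

# connected components by iterative frontier expansion; returns labels array
label_components <- function(occ, connectivity = 26) {
  lab <- array(0L, dim(occ))
  nextlab <- 0L
  remaining <- occ
  while (any(remaining)) {
    nextlab <- nextlab + 1L
    seed <- array(FALSE, dim(occ))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate3(seed, connectivity) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    lab[seed] <- nextlab
    remaining <- remaining & !seed
    if (nextlab > 4096L) stop("too many connected components")
  }
  lab
}

# separable Gaussian smoothing of a numeric 3-D array (sigma in voxels)
gauss3 <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2)); k <- k / sum(k)
  for (axis in 1:3) {
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      sh <- switch(axis,
                   shift3(a, off, 0, 0, 0),
                   shift3(a, 0, off, 0, 0),
                   shift3(a, 0, 0, off, 0))
      acc <- acc + k[j] * sh
    }
    a <- acc
  }
  a
}

#' Smooth a region mask
#'
#' Gaussian smoothing of the occupancy (threshold 0.5) followed by a
#' morphological closing, then retention of the largest connected component,
#' which removes isolated voxels.
#'
#' @param mask a \code{ca1_mask}.
#' @param sigma Gaussian sigma in micrometres (0 disables).
#' @param closing_radius closing radius in voxels (0 disables).
#' @return smoothed \code{ca1_mask}; attribute \code{voxel_change} reports the
#'   relative voxel-count change.
#' @export
smooth_mask <- function(mask, sigma = 0, closing_radius = 1) {
  occ <- mask$occupancy
  n0 <- sum(occ)
  num <- array(as.numeric(occ), dim(occ))
  if (sigma > 0) {
    # normalized convolution: renormalise by the in-array kernel mass so
    # array edges are not eroded
    sm <- gauss3(num, sigma / mask$voxel_size)
    norm <- gauss3(array(1, dim(occ)), sigma / mask$voxel_size)
    occ <- sm / norm >= 0.5
  }
  if (closing_radius > 0) {
    a <- occ
    for (i in seq_len(closing_radius)) a <- dilate3(a)
    for (i in seq_len(closing_radius)) a <- erode3(a)
    occ <- a
  }
  if (!any(occ)) stop("smoothing produced an empty mask (over-aggressive parameters)")
  lab <- label_components(occ)
  tab <- tabulate(lab[lab > 0])
  occ <- lab == which.max(tab)
  out <- region_mask(occ, mask$voxel_size, mask$origin)
  attr(out, "voxel_change") <- (sum(occ) - n0) / n0
  out
}

# distance transform (to outside of mask), voxel units, by iterated chamfer
# relaxation over the 26-neighborhood with Euclidean step weights
distance_transform <- function(occ) {
  big <- sum(dim(occ))
  dt <- array(ifelse(occ, big, 0), dim(occ))
  offs <- neighbor_offsets(26)
  w <- sqrt(offs$di^2 + offs$dj^2 + offs$dk^2)
  repeat {
    prev <- dt
    for (i in seq_len(nrow(offs))) {
      cand <- shift3(dt, offs$di[i], offs$dj[i], offs$dk[i], fill = 0) + w[i]
      dt <- pmin(dt, cand)
    }
    if (max(abs(dt - prev)) < 1e-9) break
  }
  dt
}

#' Compute a smooth centerline through a region mask
#'
#' Follows the ridge of the interior distance transform: a weighted Dijkstra
#' shortest path between the two endpoints (edge cost inversely weighted by
#' the distance transform) is extracted on the voxel graph and approximated by
#' a cubic spline parameterised by normalised arc length.
#'
#' @param mask a \code{ca1_mask}.
#' @param endpoints 2 x 3 matrix of world coordinates (micrometres) inside the
#'   mask.
#' @param n_control number of spline control points.
#' @return object of class \code{ca1_centerline}.
#' @export
compute_centerline <- function(mask, endpoints, n_control = 15) {
  occ <- mask$occupancy
  d <- dim(occ)
  endpoints <- matrix(endpoints, ncol = 3)
  idx_of <- function(p) {
    ijk <- pmin(pmax(ceiling((p - mask$origin) / mask$voxel_size), 1), d)
    if (!occ[ijk[1], ijk[2], ijk[3]]) stop("endpoint outside mask")
    ijk
  }
  e1 <- idx_of(endpoints[1, ]); e2 <- idx_of(endpoints[2, ])

  dt <- distance_transform(occ)
  vox <- which(occ)                       # linear indices of in-mask voxels
  id <- array(0L, d); id[vox] <- seq_along(vox)
  offs <- neighbor_offsets(26)
  stepw <- sqrt(offs$di^2 + offs$dj^2 + offs$dk^2)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  inv_dt <- 1 / pmax(dt, 0.5)
  for (i in seq_len(nrow(offs))) {
    nb_id <- shift3(id, offs$di[i], offs$dj[i], offs$dk[i], fill = 0L)
    nb_inv <- shift3(inv_dt, offs$di[i], offs$dj[i], offs$dk[i], fill = 0)
    sel <- vox[nb_id[vox] > 0L]
    if (length(sel) == 0) next
    from <- c(from, id[sel]); to <- c(to, nb_id[sel])
    wt <- c(wt, stepw[i] * 0.5 * (inv_dt[sel] + nb_inv[sel]))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- wt
  v1 <- id[e1[1], e1[2], e1[3]]; v2 <- id[e2[1], e2[2], e2[3]]
  sp <- suppressWarnings(igraph::shortest_paths(g, from = v1, to = v2))
  path <- as.integer(sp$vpath[[1]])
  if (length(path) < 2) stop("no path between endpoints: mask disconnected")
  ai <- arrayInd(vox[path], d)
  pts <- sweep((ai - 0.5) * mask$voxel_size, 2, mask$origin, `+`)

  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen)); s <- s / max(s)
  keep <- round(seq(1, nrow(pts), length.out = min(n_control, nrow(pts))))
  cp <- pts[keep, , drop = FALSE]; sc <- s[keep]
  sc[duplicated(sc)] <- sc[duplicated(sc)] + 1e-9
  fx <- stats::splinefun(sc, cp[, 1], method = "natural")
  fy <- stats::splinefun(sc, cp[, 2], method = "natural")
  fz <- stats::splinefun(sc, cp[, 3], method = "natural")
  ss <- seq(0, 1, length.out = 200)
  arc <- sum(sqrt(rowSums(cbind(diff(fx(ss)), diff(fy(ss)), diff(fz(ss)))^2)))
  structure(list(control_points = cp, fx = fx, fy = fy, fz = fz,
                 arc_length = arc),
            class = "ca1_centerline")
}

#' Evaluate a centerline at parameter values
#' @param cl a \code{ca1_centerline}.
#' @param s parameters in [0, 1].
#' @return matrix of 3-D points (micrometres).
#' @export
centerline_point <- function(cl, s) cbind(cl$fx(s), cl$fy(s), cl$fz(s))

#' Unit tangent of a centerline at parameter values
#' @inheritParams centerline_point
#' @export
centerline_tangent <- function(cl, s) {
  unit_rows(cbind(cl$fx(s, deriv = 1), cl$fy(s, deriv = 1), cl$fz(s, deriv = 1)))
}

# normalize shells to point matrices (surface sample points, world um)
shell_points <- function(shell, mask) {
  if (is.matrix(shell)) return(shell)
  if (is.data.frame(shell)) return(as.matrix(shell[, c("x", "y", "z")]))
  if (is.array(shell)) {
    idx <- which(as.logical(shell), arr.ind = TRUE)
    return(sweep((idx - 0.5) * mask$voxel_size, 2, mask$origin, `+`))
  }
  stop("shell must be a point matrix/data.frame or a voxel array")
}

#' Build the parametric (l, t, r) coordinate field
#'
#' Assigns each in-mask voxel a longitudinal coordinate from the nearest
#' centerline cross-section, a transverse coordinate from the spline parameter
#' of its nearest upper-lower connecting segment, and a radial coordinate as
#' the relative position along that segment (0 at the lower shell, 1 at the
#' upper shell). Direction vectors point along increasing r.
#'
#' @param mask a \code{ca1_mask}.
#' @param centerline a \code{ca1_centerline}.
#' @param upper_shell,lower_shell boundary surfaces: point matrices (n x 3,
#'   world micrometres) or voxel arrays. Lower maps to r = 0 (SO/alveus side),
#'   upper to r = 1 (SLM/pial side).
#' @param max_unassigned_frac error threshold on the fraction of voxels that
#'   cannot be assigned before nearest-neighbour filling (default 0.01).
#' @return object of class \code{ca1_coordinate_field} with arrays l, t, r
#'   (NaN outside the mask) and a 4-D direction array (3 x dims).
#' @export
build_coordinates <- function(mask, centerline, upper_shell, lower_shell,
                              max_unassigned_frac = 0.01) {
  occ <- mask$occupancy; d <- dim(occ); vs <- mask$voxel_size
  up <- shell_points(upper_shell, mask)
  lo <- shell_points(lower_shell, mask)

  n_planes <- max(2L, round(centerline$arc_length / vs))
  s_grid <- seq(0, 1, length.out = n_planes)
  P <- centerline_point(centerline, s_grid)
  Tn <- centerline_tangent(centerline, s_grid)

  vox <- which(occ)
  ai <- arrayInd(vox, d)
  V <- sweep((ai - 0.5) * vs, 2, mask$origin, `+`)

  nearest_plane <- function(X) {
    # argmin_i ||x - P_i||, ties toward lower index (lower l)
    d2 <- outer(rowSums(X^2), rep(1, nrow(P))) - 2 * X %*% t(P) +
      outer(rep(1, nrow(X)), rowSums(P^2))
    max.col(-d2, ties.method = "first")
  }
  pv <- nearest_plane(V)
  pu <- nearest_plane(up)
  pl <- nearest_plane(lo)

  l_arr <- array(NaN, d); t_arr <- array(NaN, d); r_arr <- array(NaN, d)
  dir_arr <- array(NaN, c(3, d))
  assigned <- array(FALSE, d)

  # planes without shell hits borrow from the nearest plane that has them
  borrow <- function(assign_vec, i) {
    if (any(assign_vec == i)) return(which(assign_vec == i))
    hit <- sort(unique(assign_vec))
    which(assign_vec == hit[which.min(abs(hit - i))])
  }

  for (i in seq_len(n_planes)) {
    vsel <- which(pv == i)
    if (length(vsel) == 0) next
    usel <- borrow(pu, i); lsel <- borrow(pl, i)
    if (length(usel) < 1 || length(lsel) < 1) next
    Upts <- up[usel, , drop = FALSE]; Lpts <- lo[lsel, , drop = FALSE]
    tang <- Tn[i, ]
    w <- colMeans(Upts) - colMeans(Lpts)       # rough radial direction
    w <- w - sum(w * tang) * tang
    if (sqrt(sum(w^2)) < 1e-9) next
    e2 <- w / sqrt(sum(w^2))                   # in-plane radial
    # in-plane transverse; e2 x tangent so (e1, e2, tangent) is right-handed
    e1 <- c(e2[2] * tang[3] - e2[3] * tang[2],
            e2[3] * tang[1] - e2[1] * tang[3],
            e2[1] * tang[2] - e2[2] * tang[1])
    order_line <- function(pts) {
      a <- as.vector((pts - matrix(P[i, ], nrow(pts), 3, byrow = TRUE)) %*% e1)
      o <- order(a)
      pts <- pts[o, , drop = FALSE]
      if (nrow(pts) == 1) return(list(pts = pts, u = 0.5))
      cl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      if (max(cl) == 0) cl <- seq(0, 1, length.out = nrow(pts))
      list(pts = pts, u = cl / max(cl))
    }
    U <- order_line(Upts); L <- order_line(Lpts)
    N <- max(length(U$u), length(L$u), 2L)
    ug <- seq(0, 1, length.out = N)
    resample <- function(line) {
      if (length(line$u) == 1) return(matrix(line$pts, N, 3, byrow = TRUE))
      apply(line$pts, 2, function(col) stats::approx(line$u, col, xout = ug,
                                                     rule = 2)$y)
    }
    B <- resample(U)   # upper endpoints, r = 1
    A <- resample(L)   # lower endpoints, r = 0
    AB <- B - A
    ab2 <- pmax(rowSums(AB^2), 1e-12)

    Vp <- V[vsel, , drop = FALSE]
    best_d2 <- rep(Inf, nrow(Vp)); best_j <- rep(1L, nrow(Vp))
    best_r <- rep(0, nrow(Vp))
    for (j in seq_len(N)) {
      dv <- Vp - matrix(A[j, ], nrow(Vp), 3, byrow = TRUE)
      tt <- clamp(as.vector(dv %*% AB[j, ]) / ab2[j], 0, 1)
      d2j <- rowSums((dv - outer(tt, AB[j, ]))^2)
      better <- d2j < best_d2
      best_d2[better] <- d2j[better]
      best_j[better] <- j
      best_r[better] <- tt[better]
    }
    lin <- vox[vsel]
    l_arr[lin] <- s_grid[i]
    t_arr[lin] <- ug[best_j]
    r_arr[lin] <- best_r
    dirs <- unit_rows(AB[best_j, , drop = FALSE])
    ijk <- ai[vsel, , drop = FALSE]
    for (axc in 1:3) dir_arr[cbind(axc, ijk)] <- dirs[, axc]
    assigned[lin] <- TRUE
  }

  n_un <- sum(occ & !assigned)
  if (n_un / sum(occ) > max_unassigned_frac) {
    stop(sprintf("%d voxels (%.1f%%) could not be assigned coordinates",
                 n_un, 100 * n_un / sum(occ)))
  }
  if (n_un > 0) {
    filled <- fill_nearest(list(l_arr, t_arr, r_arr, dir_arr), occ, assigned)
    l_arr <- filled[[1]]; t_arr <- filled[[2]]; r_arr <- filled[[3]]
    dir_arr <- filled[[4]]
  }
  out <- structure(list(l = l_arr, t = t_arr, r = r_arr, direction = dir_arr,
                        mask = mask, n_unassigned = n_un),
                   class = "ca1_coordinate_field")
  # recompute orientation from the r gradient so the vector field corresponds
  # exactly to the coordinate space
  direction_vectors(out)
}

# fill unassigned in-mask voxels from the nearest assigned neighbor
fill_nearest <- function(arrs, occ, assigned) {
  d <- dim(occ)
  todo <- occ & !assigned
  offs <- neighbor_offsets(26)
  guard <- 0
  while (any(todo) && guard < 200) {
    guard <- guard + 1
    for (v in which(todo)) {
      ijk <- arrayInd(v, d)
      for (i in sample(nrow(offs))) {
        ni <- ijk + c(offs$di[i], offs$dj[i], offs$dk[i])
        if (any(ni < 1) || any(ni > d)) next
        if (assigned[ni[1], ni[2], ni[3]]) {
          arrs[[1]][v] <- arrs[[1]][ni[1], ni[2], ni[3]]
          arrs[[2]][v] <- arrs[[2]][ni[1], ni[2], ni[3]]
          arrs[[3]][v] <- arrs[[3]][ni[1], ni[2], ni[3]]
          arrs[[4]][, ijk[1], ijk[2], ijk[3]] <- arrs[[4]][, ni[1], ni[2], ni[3]]
          assigned[v] <- TRUE
          todo[v] <- FALSE
          break
        }
      }
    }
  }
  arrs
}

#' @export
print.ca1_coordinate_field <- function(x, ...) {
  cat(sprintf("<ca1_coordinate_field> %s voxels, %d in mask (%d filled)\n",
              paste(dim(x$l), collapse = "x"), sum(x$mask$occupancy),
              x$n_unassigned))
  invisible(x)
}

#' Recompute direction vectors from the radial-coordinate gradient
#'
#' Returns the field with \code{direction} replaced by the normalised
#' numerical gradient of r (direction of increasing r), which by construction
#' flips sign if the upper and lower shells are exchanged. Zero-gradient
#' voxels are filled from the nearest assigned neighbour; their count is kept
#' in \code{n_zero_gradient}.
#'
#' @param field a \code{ca1_coordinate_field}.
#' @return updated field.
#' @export
direction_vectors <- function(field) {
  r <- field$r; occ <- field$mask$occupancy; d <- dim(r)
  vsz <- field$mask$voxel_size
  grad_axis <- function(axis) {
    shp <- function(o) switch(axis, shift3(r, o, 0, 0, NaN),
                              shift3(r, 0, o, 0, NaN), shift3(r, 0, 0, o, NaN))
    fwd <- shp(-1); bwd <- shp(1)
    g <- (fwd - bwd) / (2 * vsz)
    one_sided <- is.na(fwd) & !is.na(bwd)
    g[one_sided] <- (r[one_sided] - bwd[one_sided]) / vsz
    one_sided <- !is.na(fwd) & is.na(bwd)
    g[one_sided] <- (fwd[one_sided] - r[one_sided]) / vsz
    g[is.na(g)] <- 0
    g
  }
  gx <- grad_axis(1); gy <- grad_axis(2); gz <- grad_axis(3)
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  zero <- occ & nrm < 1e-12
  nrm[nrm < 1e-12] <- 1
  dir_arr <- array(NaN, c(3, d))
  vox <- which(occ); ijk <- arrayInd(vox, d)
  dir_arr[cbind(1, ijk)] <- (gx / nrm)[vox]
  dir_arr[cbind(2, ijk)] <- (gy / nrm)[vox]
  dir_arr[cbind(3, ijk)] <- (gz / nrm)[vox]
  if (any(zero)) {
    assigned <- occ & !zero
    dummy <- array(0, d)
    filled <- fill_nearest(list(dummy, dummy, dummy, dir_arr), occ, assigned)
    dir_arr <- filled[[4]]
  }
  field$direction <- dir_arr
  field$n_zero_gradient <- sum(zero)
  field
}

#' Layer proportions from mean layer thicknesses
#'
#' Normalises mean per-layer thicknesses (micrometres) into the uniform
#' voxel-fraction proportions used to cut the radial coordinate into layers.
#'
#' @param thickness named numeric vector of thicknesses, e.g.
#'   \code{c(SO = 168, SP = 59, SR = 279, SLM = 146)}.
#' @return named proportions summing to 1.
#' @export
layer_proportions <- function(thickness) {
  stopifnot(all(thickness > 0))
  thickness / sum(thickness)
}

#' Assign layer labels from the radial coordinate
#'
#' Layers occupy consecutive r-intervals with the given proportions, ordered
#' from r = 0: SO, SP, SR, SLM (SO/alveus side to SLM/pial side).
#'
#' @param field a \code{ca1_coordinate_field}.
#' @param proportions positive fractions per layer, ordered from r = 0;
#'   must sum to 1 within 1e-6. Names default to SO/SP/SR/SLM for length 4.
#' @return character array of layer labels (NA outside mask); attribute
#'   \code{breaks} carries the cumulative r-interval boundaries.
#' @export
assign_layers <- function(field, proportions) {
  if (abs(sum(proportions) - 1) > 1e-6) stop("layer proportions must sum to 1")
  if (any(proportions <= 0)) stop("layer proportions must be positive")
  nm <- names(proportions)
  if (is.null(nm)) {
    nm <- if (length(proportions) == 4) c("SO", "SP", "SR", "SLM")
          else paste0("L", seq_along(proportions))
  }
  breaks <- c(0, cumsum(proportions))
  breaks[length(breaks)] <- 1 + 1e-12
  lab <- array(NA_character_, dim(field$r))
  inm <- which(field$mask$occupancy)
  bin <- findInterval(field$r[inm], breaks, rightmost.closed = TRUE)
  bin <- clamp(bin, 1, length(nm))
  lab[inm] <- nm[bin]
  attr(lab, "breaks") <- stats::setNames(breaks, NULL)
  attr(lab, "layers") <- nm
  lab
}

#' Persist a coordinate field as NRRD grids
#'
#' Writes l, t, r as scalar grids and the direction field as one 4-D grid.
#' @param field a \code{ca1_coordinate_field}.
#' @param dir output directory.
#' @export
write_coordinate_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- field$mask$voxel_size; org <- field$mask$origin
  write_nrrd(field$l, file.path(dir, "l.nrrd"), vs, org)
  write_nrrd(field$t, file.path(dir, "t.nrrd"), vs, org)
  write_nrrd(field$r, file.path(dir, "r.nrrd"), vs, org)
  write_nrrd(field$direction, file.path(dir, "direction.nrrd"), vs, org)
  write_nrrd(array(as.numeric(field$mask$occupancy), dim(field$l)),
             file.path(dir, "mask.nrrd"), vs, org)
  invisible(dir)
}
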