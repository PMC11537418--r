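#' Generate a synthetic atlas volume with analytic ground-truth coordinates
#'
#' Three desk-scale geometries emulating a bent CA1-like slab:
#' \describe{
#'   \item{slab}{axis-aligned box; longitudinal = x, transverse = y,
#'     radial = z.}
#'   \item{quarter_annulus}{quarter of an annular slab around the z axis;
#'     longitudinal along the arc, radial along the cylindrical radius,
#'     transverse = z.}
#'   \item{bent_slab}{half-annulus variant of the same geometry.}
#' }
#' Each fixture carries the occupancy mask, analytic (l, t, r) grids and
#' direction vectors, boundary shells as exact surface point sets, and
#' centerline endpoints, so atlas operations can be checked against closed
#' geometry.
#'
#' @param kind "slab", "quarter_annulus" or "bent_slab".
#' @param dims for slab: voxel counts (nx, ny, nz). For annuli: ignored.
#' @param inner_radius,outer_radius annulus radii in voxels.
#' @param thickness annulus z-thickness in voxels.
#' @param voxel_size micrometres per voxel.
#' @return list with mask, l, t, r, direction, upper_shell, lower_shell,
#'   endpoints.
#' @export
make_atlas <- function(kind = c("slab", "quarter_annulus", "bent_slab"),
                       dims = c(100, 20, 20),
                       inner_radius = 40, outer_radius = 60, thickness = 24,
                       voxel_size = 10) {
  kind <- match.arg(kind)
  vs <- voxel_size
  if (kind == "slab") {
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    occ <- array(TRUE, c(nx, ny, nz))
    mask <- region_mask(occ, vs)
    ci <- function(n) (seq_len(n) - 0.5)
    l <- array(rep(ci(nx) / nx, times = ny * nz), c(nx, ny, nz))
    t_ <- array(rep(rep(ci(ny) / ny, each = nx), times = nz), c(nx, ny, nz))
    r <- array(rep(ci(nz) / nz, each = nx * ny), c(nx, ny, nz))
    dir_arr <- array(0, c(3, nx, ny, nz)); dir_arr[3, , , ] <- 1
    grid2 <- expand.grid(x = ci(nx) * vs, y = ci(ny) * vs)
    upper <- cbind(grid2$x, grid2$y, nz * vs)   # r = 1 face
    lower <- cbind(grid2$x, grid2$y, 0)         # r = 0 face
    endpoints <- rbind(c(0.5 * vs, ny / 2 * vs, nz / 2 * vs),
                       c((nx - 0.5) * vs, ny / 2 * vs, nz / 2 * vs))
  } else {
    ang <- if (kind == "quarter_annulus") pi / 2 else pi
    ri <- inner_radius; ro <- outer_radius; nz <- thickness
    n <- ceiling(ro) + 1
    occ <- array(FALSE, c(n, n, nz))
    if (kind == "bent_slab") occ <- array(FALSE, c(2 * n, n, nz))
    d <- dim(occ)
    cx <- if (kind == "bent_slab") n else 0   # annulus center (voxel units)
    ii <- (seq_len(d[1]) - 0.5) - cx
    jj <- (seq_len(d[2]) - 0.5)
    rho <- sqrt(outer(ii^2, jj^2, `+`))
    theta <- atan2(matrix(jj, d[1], d[2], byrow = TRUE),
                   matrix(ii, d[1], d[2]))
    in2d <- rho >= ri & rho <= ro & theta >= 0 & theta <= ang
    occ[] <- rep(as.vector(in2d), times = nz)
    mask <- region_mask(occ, vs)
    l <- array(NaN, d); t_ <- array(NaN, d); r <- array(NaN, d)
    dir_arr <- array(NaN, c(3, d))
    vox <- which(occ); ai <- arrayInd(vox, d)
    vrho <- rho[cbind(ai[, 1], ai[, 2])]
    vth <- theta[cbind(ai[, 1], ai[, 2])]
    l[vox] <- vth / ang
    r[vox] <- (vrho - ri) / (ro - ri)
    t_[vox] <- (ai[, 3] - 0.5) / nz
    dir_arr[cbind(1, ai)] <- cos(vth)   # radial direction = increasing rho
    dir_arr[cbind(2, ai)] <- sin(vth)
    dir_arr[cbind(3, ai)] <- 0
    nth <- ceiling(ang * ro * 3)
    th_g <- (seq_len(nth) - 0.5) / nth * ang
    zg <- (seq_len(nz) - 0.5) * vs
    g <- expand.grid(th = th_g, z = zg)
    upper <- cbind((cx + ro * cos(g$th)) * vs, ro * sin(g$th) * vs, g$z)
    lower <- cbind((cx + ri * cos(g$th)) * vs, ri * sin(g$th) * vs, g$z)
    rm <- (ri + ro) / 2
    endpoints <- rbind(
      c((cx + rm * cos(0.01)) * vs, rm * sin(0.01) * vs, nz / 2 * vs),
      c((cx + rm * cos(ang - 0.01)) * vs, rm * sin(ang - 0.01) * vs,
        nz / 2 * vs))
  }
  list(mask = mask, l = l, t = t_, r = r, direction = dir_arr,
       upper_shell = upper, lower_shell = lower, endpoints = endpoints,
       kind = kind)
}
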