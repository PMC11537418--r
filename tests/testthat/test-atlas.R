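test_that("smoothing leaves a solid cube essentially unchanged and fills holes", {
  cube <- region_mask(array(TRUE, c(20, 20, 20)), voxel_size = 1)
  sm <- smooth_mask(cube, sigma = 1, closing_radius = 1)
  expect_lt(abs(sum(sm$occupancy) - sum(cube$occupancy)) / sum(cube$occupancy),
            0.02)

  holed <- array(TRUE, c(10, 10, 10))
  holed[5, 5, 5] <- FALSE
  sm2 <- smooth_mask(region_mask(holed), sigma = 0, closing_radius = 1)
  expect_true(sm2$occupancy[5, 5, 5])
})

test_that("salt-and-pepper noise is cleaned to within 5% of the clean slab", {
  clean <- array(FALSE, c(30, 12, 12))
  clean[, 3:10, 3:10] <- TRUE
  noisy <- clean
  set.seed(42)
  flip <- sample(length(noisy), round(0.05 * length(noisy)))
  noisy[flip] <- !noisy[flip]
  sm <- smooth_mask(region_mask(noisy), sigma = 2, closing_radius = 1)
  expect_lt(abs(sum(sm$occupancy) - sum(clean)) / sum(clean), 0.05)
  # output is a single connected component
  lab <- ca1forge:::label_components(sm$occupancy)
  expect_equal(max(lab), 1L)
})

test_that("centerline of a straight slab runs along its axis", {
  fx <- get_fx_slab()
  ss <- seq(0.1, 0.9, length.out = 20)
  pts <- centerline_point(fx$cl, ss)
  # slab is 40x12x12 at 10 um: axis at y = z = 60 um
  expect_lt(max(abs(pts[, 2] - 60)), 10)
  expect_lt(max(abs(pts[, 3] - 60)), 10)
  # monotone along x from endpoint A to B
  expect_true(all(diff(pts[, 1]) > 0))
})

test_that("centerline of a quarter annulus follows the mid-radius arc", {
  fx <- get_fx_annulus()
  ss <- seq(0.05, 0.95, length.out = 40)
  pts <- centerline_point(fx$cl, ss)
  rad <- sqrt(pts[, 1]^2 + pts[, 2]^2) / 10   # voxel units
  expect_true(all(abs(rad - 50) <= 1.5))
})

test_that("disconnected masks are rejected by the centerline search", {
  occ <- array(FALSE, c(20, 5, 5))
  occ[1:5, , ] <- TRUE; occ[15:20, , ] <- TRUE
  m <- region_mask(occ)
  expect_error(compute_centerline(m, rbind(c(2.5, 2.5, 2.5), c(17.5, 2.5, 2.5))),
               "disconnected|no path")
})

test_that("slab radial coordinate equals fractional depth", {
  fx <- get_fx_slab()
  occ <- fx$ax$mask$occupancy
  expect_lt(max(abs(fx$field$r[occ] - fx$ax$r[occ])), 0.02)
  # in-mask coordinates in [0,1], NaN outside (slab is all in-mask)
  expect_true(all(fx$field$r[occ] >= 0 & fx$field$r[occ] <= 1))
  expect_true(all(fx$field$l[occ] >= 0 & fx$field$l[occ] <= 1))
  expect_true(all(fx$field$t[occ] >= 0 & fx$field$t[occ] <= 1))
})

test_that("annulus radial coordinate matches the analytic cylindrical ratio", {
  fx <- get_fx_annulus()
  occ <- fx$ax$mask$occupancy
  expect_lt(max(abs(fx$field$r[occ] - fx$ax$r[occ])), 0.05)
})

test_that("r histogram is approximately uniform on a constant-thickness slab", {
  fx <- get_fx_slab()
  r <- fx$field$r[fx$ax$mask$occupancy]
  ks <- max(abs(stats::ecdf(r)(seq(0, 1, 0.01)) - seq(0, 1, 0.01)))
  expect_lt(ks, 0.1)
})

test_that("out-of-mask voxels carry NaN coordinates", {
  fx <- get_fx_annulus()
  outside <- !fx$ax$mask$occupancy
  expect_true(all(is.nan(fx$field$r[outside])))
  expect_true(all(is.nan(fx$field$l[outside])))
})

test_that("direction vectors are unit norm and match the analytic field", {
  fx_s <- get_fx_slab()
  occ <- fx_s$ax$mask$occupancy
  d <- fx_s$field$direction
  nrm <- sqrt(d[1, , , ]^2 + d[2, , , ]^2 + d[3, , , ]^2)
  expect_lt(max(abs(nrm[occ] - 1)), 1e-6)
  ang <- acos(pmin(1, abs(d[3, , , ][occ]))) * 180 / pi
  expect_lt(max(ang), 2)

  fx_a <- get_fx_annulus()
  occ_a <- fx_a$ax$mask$occupancy
  da <- fx_a$field$direction; dt <- fx_a$ax$direction
  dots <- da[1, , , ][occ_a] * dt[1, , , ][occ_a] +
    da[2, , , ][occ_a] * dt[2, , , ][occ_a] +
    da[3, , , ][occ_a] * dt[3, , , ][occ_a]
  ang_a <- acos(pmin(1, abs(dots))) * 180 / pi
  expect_lt(stats::quantile(ang_a, 0.99), 5)
})

test_that("swapping the shells flips r and negates the direction field", {
  fx <- get_fx_slab()
  flipped <- build_coordinates(fx$ax$mask, fx$cl,
                               upper_shell = fx$ax$lower_shell,
                               lower_shell = fx$ax$upper_shell)
  occ <- fx$ax$mask$occupancy
  expect_lt(max(abs((1 - flipped$r[occ]) - fx$field$r[occ])), 0.02)
  dots <- flipped$direction[3, , , ][occ] * fx$field$direction[3, , , ][occ]
  expect_true(all(dots < 0))
})

test_that("r is monotone along each radial column of the slab", {
  fx <- get_fx_slab()
  r <- fx$field$r
  for (i in c(5, 20, 35)) for (j in c(3, 9)) {
    expect_true(all(diff(r[i, j, ]) > 0))
  }
})

test_that("coordinates are invariant to a 90-degree rotation of the mask", {
  ax <- make_atlas("slab", dims = c(30, 10, 10), voxel_size = 10)
  cl <- compute_centerline(ax$mask, ax$endpoints)
  f1 <- build_coordinates(ax$mask, cl, ax$upper_shell, ax$lower_shell)
  # rotate 90 degrees about z: (x, y) -> (y, -x); regenerate via aperm
  occ2 <- aperm(ax$mask$occupancy, c(2, 1, 3))
  m2 <- region_mask(occ2, 10)
  rot_pts <- function(p) cbind(p[, 2], p[, 1], p[, 3])   # mirror-swap x/y
  cl2 <- compute_centerline(m2, rot_pts(ax$endpoints))
  f2 <- build_coordinates(m2, cl2, rot_pts(ax$upper_shell),
                          rot_pts(ax$lower_shell))
  r1 <- f1$r[ax$mask$occupancy]
  r2 <- aperm(f2$r, c(2, 1, 3))[ax$mask$occupancy]
  expect_lt(max(abs(r1 - r2)), 0.02)
})

test_that("layer proportions from printed thicknesses match the printed fractions", {
  lp <- layer_proportions(c(SO = 168, SP = 59, SR = 279, SLM = 146))
  expect_equal(round(unname(lp["SR"]), 5), 0.42791)
  expect_equal(round(unname(lp["SLM"]), 3), 0.224)
  expect_equal(round(unname(lp["SP"]), 3), 0.090)
  expect_equal(round(unname(lp["SO"]), 3), 0.258)
})

test_that("layer assignment follows the cumulative r-intervals from r = 0", {
  fx <- get_fx_slab()
  props <- c(SO = 0.258, SP = 0.090, SR = 0.42791, SLM = 0.22409)
  lab <- assign_layers(fx$field, props)
  occ <- fx$ax$mask$occupancy
  # an r = 0.5 voxel sits in SR (cumulative SO 0.258, SP 0.348, SR 0.77591)
  mid <- which(occ & abs(fx$field$r - 0.5) < 0.02)
  expect_true(all(lab[mid] == "SR"))
  # per-layer voxel fractions match proportions within slab quantization
  frac <- table(lab[occ]) / sum(occ)
  expect_true(all(abs(frac[names(props)] - props) < 1 / 12 + 0.02))
  expect_error(assign_layers(fx$field, c(0.5, 0.4)), "sum to 1")
})

test_that("layer fractions converge to the requested proportions with resolution", {
  props <- c(SO = 0.258, SP = 0.090, SR = 0.42791, SLM = 0.22409)
  err_at <- function(nz) {
    ax <- make_atlas("slab", dims = c(20, 6, nz), voxel_size = 10)
    cl <- compute_centerline(ax$mask, ax$endpoints)
    fld <- build_coordinates(ax$mask, cl, ax$upper_shell, ax$lower_shell)
    lab <- assign_layers(fld, props)
    occ <- ax$mask$occupancy
    frac <- table(factor(lab[occ], levels = names(props))) / sum(occ)
    max(abs(frac - props))
  }
  expect_lt(err_at(40), err_at(8))
})

test_that("NRRD round-trips coordinate fields", {
  fx <- get_fx_slab()
  dir <- withr::local_tempdir()
  write_coordinate_field(fx$field, dir)
  rr <- read_nrrd(file.path(dir, "r.nrrd"))
  expect_equal(rr$data, fx$field$r, tolerance = 1e-6)
  expect_equal(rr$voxel_size, 10)
})
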