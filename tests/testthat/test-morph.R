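test_that("curation centers the soma, scales shrinkage, and drops zero-length segments", {
  m <- make_morphologies(1, "pc", seed = 5)[[1]]
  # shift the whole cell away from the origin
  m$nodes$x <- m$nodes$x + 100
  cur <- curate(m)
  expect_equal(ca1forge:::soma_center(cur), c(0, 0, 0))
  expect_equal(total_length(cur), total_length(m), tolerance = 1e-9)

  z0 <- diff(range(cur$nodes$z))
  cur_z <- curate(m, shrink_z = 0.25)
  expect_equal(diff(range(cur_z$nodes$z)), z0 * 1.25, tolerance = 1e-9)

  # duplicate point makes a zero-length segment; removal keeps total length
  n <- m$nodes
  dup <- n[nrow(n), ]
  dup$id <- max(n$id) + 1L; dup$parent <- n$id[nrow(n)]
  m2 <- morphology(rbind(n, dup), name = "dup")
  cur2 <- curate(m2)
  expect_equal(nrow(cur2$nodes), nrow(n))
  expect_equal(total_length(cur2), total_length(m), tolerance = 1e-9)

  # a cell without an axon is flagged
  no_ax <- morphology(n[n$type != 2, ], name = "noax")
  expect_true(attr(curate(no_ax), "no_axon"))
})

test_that("scale/clone respects the 15% bound and is exactly linear and deterministic", {
  m <- make_morphologies(1, "interneuron", seed = 3)[[1]]
  expect_equal(scale_clone(m, 0)$nodes[, c("x", "y", "z")],
               m$nodes[, c("x", "y", "z")])
  expect_equal(total_length(scale_clone(m, 0.10)), total_length(m) * 1.10,
               tolerance = 1e-9)
  expect_error(scale_clone(m, 0.2), "0.15")

  c1 <- scale_clone(m, 0.05, jitter_rot_sd = 0.2, jitter_len_sd = 0.1, seed = 9)
  c2 <- scale_clone(m, 0.05, jitter_rot_sd = 0.2, jitter_len_sd = 0.1, seed = 9)
  expect_identical(c1$nodes, c2$nodes)
  expect_equal(c1$provenance, "clone")
})

test_that("PCA axon realignment recovers the transverse axis after rotation", {
  m <- make_morphologies(1, "pc", seed = 11)[[1]]
  a0 <- pca_align_axon(m)
  # rotate 37 degrees in the xz-plane and re-align
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  mr <- m
  rot <- as.matrix(m$nodes[, c("x", "y", "z")]) %*% t(R)
  mr$nodes$x <- rot[, 1]; mr$nodes$y <- rot[, 2]; mr$nodes$z <- rot[, 3]
  a1 <- pca_align_axon(mr)
  axis_of <- function(mm) {
    ax <- mm$nodes[mm$nodes$type == 2, ]
    svd(scale(cbind(ax$x, ax$y, ax$z), scale = FALSE))$v[, 1]
  }
  v <- axis_of(a1)
  expect_lt(acos(min(1, abs(v[1]))) * 180 / pi, 1)
  # already-aligned morphology unchanged up to sign of the principal axis
  v0 <- axis_of(a0)
  expect_lt(acos(min(1, abs(v0[1]))) * 180 / pi, 1)
})

test_that("clones stretched beyond 3.3x the original z-range are rejected", {
  m <- make_morphologies(1, "pc", seed = 13)[[1]]
  orig <- pca_align_axon(m)
  stretched <- orig
  stretched$nodes$z <- stretched$nodes$z * 3.4
  expect_null(pca_align_axon(stretched, original = orig, reject_ratio = 3.3))
  ok <- orig
  ok$nodes$z <- ok$nodes$z * 1.5
  expect_false(is.null(pca_align_axon(ok, original = orig, reject_ratio = 3.3)))
})

test_that("MVS score follows |dmedian| / OVS and its invariances", {
  a <- c(0, 1, 2)
  expect_equal(mvs_score(a, a), 0)
  # worked example with an injected spread of 4: shift of +1 scores 0.25
  expect_equal(mvs_score(a, a + 1, ovs = function(a, b) 4), 0.25)
  b <- c(0.5, 1.5, 3, 4)
  expect_equal(mvs_score(a, b), mvs_score(b, a))
  expect_equal(mvs_score(a + 10, b + 10), mvs_score(a, b))
  # good-agreement threshold: identical populations are well below 0.3
  expect_lt(mvs_score(a, a + 0.1), 0.3)
  expect_warning(s <- mvs_score(c(1, 1, 1), c(2, 2, 2),
                                ovs = function(a, b) 0), "infinite")
  expect_identical(s, Inf)
})

test_that("persistence diagrams implement the elder rule on radial distance", {
  # single unbranched neurite reaching 100 um: one bar (100, 0)
  pts <- cbind(seq(0, 100, by = 20), 0, 0)
  m <- chain_morph(pts, c(1L, rep(4L, 5)), radii = c(1e-9, rep(1, 5)))
  d <- persistence_diagram(m, 4)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 100)
  expect_equal(d$end, 0)

  # Y-tree: branch at 50, tips at 100 and 80 -> {(100, 0), (80, 50)}
  nodes <- data.frame(
    id = 1:6, type = c(1L, rep(4L, 5)),
    x = c(0, 25, 50, 75, 100, 80),
    y = 0, z = 0, radius = c(1e-9, rep(1, 5)),
    parent = c(-1L, 1L, 2L, 3L, 4L, 3L))
  # make the second tip branch into y so its radial distance is 80
  nodes$x[6] <- 50; nodes$y[6] <- sqrt(80^2 - 50^2)
  y <- morphology(nodes, "ytree")
  dy <- persistence_diagram(y, 4)
  expect_equal(nrow(dy), 2)
  expect_equal(sort(dy$start), c(80, 100))
  expect_equal(dy$end[which.max(dy$start)], 0, tolerance = 1e-6)
  expect_equal(dy$end[which.min(dy$start)], 50, tolerance = 1e-6)
})

test_that("bar count equals leaf count on random trees", {
  for (s in 1:25) {
    m <- make_morphologies(1, "pc", depth = 3, seed = s)[[1]]
    for (ty in c(2L, 3L, 4L)) {
      d <- persistence_diagram(m, ty)
      nd <- m$nodes
      sub <- nd[nd$type == ty, ]
      if (nrow(sub) == 0) next
      leaves <- sum(!(sub$id %in% nd$parent[nd$type == ty]))
      expect_equal(nrow(d), leaves)
    }
  }
})

test_that("persistence is rotation invariant and scales linearly with cloning", {
  m <- make_morphologies(1, "interneuron", seed = 21)[[1]]
  d0 <- persistence_diagram(m, 3)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mr <- m
  rot <- as.matrix(m$nodes[, c("x", "y", "z")]) %*% t(R)
  mr$nodes$x <- rot[, 1]; mr$nodes$y <- rot[, 2]; mr$nodes$z <- rot[, 3]
  d1 <- persistence_diagram(mr, 3)
  expect_equal(d1$start, d0$start, tolerance = 1e-9)
  expect_equal(d1$end, d0$end, tolerance = 1e-9)

  dc <- persistence_diagram(scale_clone(m, 0.1), 3)
  expect_equal(dc$start, d0$start * 1.1, tolerance = 1e-9)
  expect_equal(dc$end, d0$end * 1.1, tolerance = 1e-9)
})

test_that("persistence images normalise and vanish for identical populations", {
  m <- make_morphologies(3, "interneuron", seed = 2)
  pop <- lapply(m, persistence_diagram, neurite_type = 3L)
  img <- persistence_image(pop[[1]], grid_n = 40, bandwidth = 8)
  cell <- diff(attr(img, "x"))[1] * diff(attr(img, "y"))[1]
  expect_equal(sum(img) * cell, 1, tolerance = 1e-6)
  # single bar gives a single bump centered at the bar
  one <- data.frame(start = 50, end = 10)
  im1 <- persistence_image(one, grid_n = 41, bandwidth = 5)
  pk <- which(im1 == max(im1), arr.ind = TRUE)
  expect_equal(attr(im1, "x")[pk[1]], 50, tolerance = 1)
  expect_equal(attr(im1, "y")[pk[2]], 10, tolerance = 1)
  diff_img <- persistence_image_diff(pop, pop)
  expect_lt(max(abs(diff_img)), 1e-12)
})

test_that("SWC files round-trip exactly", {
  m <- make_morphologies(1, "pc", seed = 8)[[1]]
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path, name = m$name)
  expect_equal(m2$nodes$x, m$nodes$x, tolerance = 1e-8)
  expect_equal(m2$nodes$parent, m$nodes$parent)
  expect_equal(m2$nodes$type, m$nodes$type)
})
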