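test_that("composition from density and E/I ratio reproduces printed-scale counts", {
  comp <- derive_composition(264e3, 1.5789,
                             c(SP_PVBC = 2, SO_OLM = 2, SP_AA = 1),
                             ei_ratio = 0.11)
  pc <- comp$count[comp$mtype == "SP_PC"]
  expect_equal(pc, 416830)
  ints <- sum(comp$count[!comp$excitatory])
  expect_equal(ints / (ints + pc), 0.11, tolerance = 1e-4)
  # pool proportions are preserved
  expect_equal(comp$count[comp$mtype == "SP_PVBC"],
               comp$count[comp$mtype == "SO_OLM"], tolerance = 1)
  # already-consistent counts stay fixed: I pool of 11 against E = 89
  comp2 <- derive_composition(89, 1, c(A = 11), ei_ratio = 0.11)
  expect_equal(comp2$count, c(89, 11))
  expect_error(derive_composition(264e3, 0, c(A = 1)), "positive")
})

test_that("soma placement conserves counts and respects layers and bands", {
  fx <- get_fx_slab()
  props <- c(SO = 0.258, SP = 0.090, SR = 0.42791, SLM = 0.22409)
  lab <- assign_layers(fx$field, props)
  recipe <- data.frame(
    mtype = c("SP_PC", "SP_PVBC", "SR_SCA", "SLM_PPA"),
    layer = c("SP", "SP", "SR", "SLM"),
    count = c(300, 60, 50, 40))
  cells <- place_somata(fx$field, lab, recipe, seed = 4)
  expect_equal(nrow(cells), 450)
  expect_equal(as.integer(table(cells$mtype)[recipe$mtype]),
               as.integer(recipe$count))
  expect_true(all(cells$layer[cells$mtype == "SP_PC"] == "SP"))
  # SCA restricted to mid-SR band, PPA to lower SLM band
  breaks <- attr(lab, "breaks")
  rel <- function(r, layer) {
    k <- match(layer, attr(lab, "layers"))
    (r - breaks[k]) / (breaks[k + 1] - breaks[k])
  }
  sca_rel <- rel(cells$r[cells$mtype == "SR_SCA"], "SR")
  expect_true(all(sca_rel >= 0.45 - 0.05 & sca_rel <= 0.55 + 0.05))
  ppa_rel <- rel(cells$r[cells$mtype == "SLM_PPA"], "SLM")
  expect_true(all(ppa_rel >= 0.02 - 0.05 & ppa_rel <= 0.10 + 0.05))
  # no admissible voxels is an error
  bad <- data.frame(mtype = "X", layer = "NOPE", count = 5)
  expect_error(place_somata(fx$field, lab, bad, seed = 1), "admissible")
  # determinism
  cells2 <- place_somata(fx$field, lab, recipe, seed = 4)
  expect_identical(cells, cells2)
})

test_that("multinomial allocation splits evenly over equal-weight voxels", {
  # two admissible voxels, uniform weights: expect a binomial 50/50 split
  set.seed(1)
  alloc <- stats::rmultinom(1, 1000, c(1, 1))
  expect_lt(abs(alloc[1] - 500), 3 * sqrt(1000 * 0.25))
  # the same property realized through place_somata on a 2-voxel layer band
  fx <- get_fx_slab()
  lab <- assign_layers(fx$field, c(SO = 0.5, SP = 0.5))
  recipe <- data.frame(mtype = "SO_X", layer = "SO", count = 500)
  cells <- place_somata(fx$field, lab, recipe, seed = 2)
  expect_equal(nrow(cells), 500)
  expect_true(all(cells$r <= 0.5 + 1e-9))
})

test_that("cell orientation aligns local y with the radial axis", {
  fx <- get_fx_slab()
  props <- c(SO = 0.258, SP = 0.090, SR = 0.42791, SLM = 0.22409)
  lab <- assign_layers(fx$field, props)
  cells <- place_somata(fx$field, lab,
                        data.frame(mtype = "SP_PVBC", layer = "SP",
                                   count = 20), seed = 6)
  for (i in seq_len(5)) {
    R <- orient_cell(fx$field, cells[i, ], "SP_PVBC", seed = i)
    # local y (2nd column) maps to the slab radial direction (+z)
    ang <- acos(min(1, abs(R[3, 2]))) * 180 / pi
    expect_lt(ang, 2)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    # same seed, same azimuth
    expect_identical(R, orient_cell(fx$field, cells[i, ], "SP_PVBC", seed = i))
  }
})

test_that("PC orientation puts the axon principal axis along the transverse axis", {
  fx <- get_fx_slab()
  props <- c(SO = 0.258, SP = 0.090, SR = 0.42791, SLM = 0.22409)
  lab <- assign_layers(fx$field, props)
  cells <- place_somata(fx$field, lab,
                        data.frame(mtype = "SP_PC", layer = "SP", count = 5),
                        seed = 7)
  m <- pca_align_axon(make_morphologies(1, "pc", seed = 2)[[1]])
  for (i in seq_len(3)) {
    R <- orient_cell(fx$field, cells[i, ], "SP_PC", morph = m, seed = i)
    ax <- m$nodes[m$nodes$type == 2, ]
    pts <- as.matrix(ax[, c("x", "y", "z")]) %*% t(R)
    v1 <- svd(scale(pts, scale = FALSE))$v[, 1]
    radial <- fx$field$direction[, 1, 1, 6]   # slab radial = +z
    # perpendicular to radial within 5 degrees
    expect_lt(abs(90 - acos(abs(sum(v1 * c(0, 0, 1)))) * 180 / pi), 5)
  }
})

test_that("placement rule scores follow the overlap/harmonic-mean/min algebra", {
  perfect <- list(list(kind = "optional", interval = c(0, 10),
                       target = c(0, 10)),
                  list(kind = "strict", interval = c(-5, 5),
                       target = c(-5, 5)))
  expect_equal(as.numeric(score_placement(perfect, y0 = 0)), 1)

  # Eq 5 arithmetic: a=[0,10], r=[5,15] -> 0.5; symmetric under swap
  expect_equal(interval_score(c(0, 10), c(5, 15)), 0.5)
  expect_equal(interval_score(c(5, 15), c(0, 10)), 0.5)

  # Eq 4 arithmetic: {0.5, 1} -> 2/3
  s <- score_placement(list(
    list(kind = "optional", interval = c(0, 10), target = c(5, 15)),
    list(kind = "optional", interval = c(0, 10), target = c(0, 10))), y0 = 0)
  expect_equal(attr(s, "optional_score"), 2 / 3)

  # a near-zero optional score zeroes the aggregate
  tiny <- list(
    list(kind = "optional", interval = c(0, 10), target = c(9.995, 10 + 9990)),
    list(kind = "optional", interval = c(0, 10), target = c(0, 10)))
  s0 <- score_placement(tiny, y0 = 0)
  expect_lt(interval_score(c(0, 10), c(9.995, 10 + 9990)), 0.001)
  expect_equal(as.numeric(s0), 0)

  # strict rules aggregate by min, total is the product, always in [0,1]
  mix <- list(
    list(kind = "strict", interval = c(0, 10), target = c(5, 15)),
    list(kind = "strict", interval = c(0, 10), target = c(0, 10)),
    list(kind = "optional", interval = c(0, 10), target = c(0, 20)))
  sm <- score_placement(mix, y0 = 0)
  expect_equal(attr(sm, "strict_score"), 0.5)
  expect_equal(as.numeric(sm), 0.5 * 0.5)
  # soma offset shifts the morphology interval (Eq 6)
  sh <- score_placement(list(list(kind = "strict", interval = c(0, 10),
                                  target = c(5, 15))), y0 = 5)
  expect_equal(as.numeric(sh), 1)
  # empty interval scores zero against a non-empty target
  expect_equal(interval_score(c(3, 3), c(0, 10)), 0)
})

test_that("random score sweeps keep the total inside [0, 1]", {
  set.seed(99)
  for (k in 1:200) {
    rules <- lapply(seq_len(sample(1:4, 1)), function(i) {
      a <- sort(stats::runif(2, -50, 50)); r <- sort(stats::runif(2, -50, 50))
      list(kind = sample(c("optional", "strict"), 1), interval = a, target = r)
    })
    s <- as.numeric(score_placement(rules, y0 = stats::runif(1, -20, 20)))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("morphology selection is score-proportional with dropped all-zero positions", {
  expect_equal(select_morphology(1), 1L)
  expect_true(is.na(select_morphology(c(0, 0))))
  set.seed(3)
  picks <- vapply(1:10000, function(i) {
    select_morphology(c(0.2, 0.8), seed = i)
  }, 0L)
  p1 <- mean(picks == 1)
  expect_lt(abs(p1 - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  expect_equal(select_morphology(c(0.1, 0.9, 0.5), method = "argmax"), 2L)
})
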