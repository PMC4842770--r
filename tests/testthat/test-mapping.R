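test_that("gaussian map is a normalized convex combination", {
  m <- make_brain_mesh(2)
  set <- make_case_study_montage(m)

  # constant input -> constant field
  f <- gaussian_map(m, set, rep(3.5, 64), 10)
  expect_equal(f$values, rep(3.5, nrow(m$vertices)), tolerance = 1e-12)
  expect_true(all(f$covered))

  # single electrode -> constant at its value for any sigma
  one <- electrode_set(matrix(c(-70, 0, 0), 1))
  for (sg in c(0.5, 10, 1000)) {
    f1 <- gaussian_map(m, one, 7, sg)
    expect_equal(f1$values, rep(7, nrow(m$vertices)), tolerance = 1e-12)
  }

  # equidistant vertex between values 0 and 1 -> 0.5
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5, 0), c(5, -5, 0),
             c(5, 0, 50))
  mm <- tri_mesh(v, unit_tetrahedron()$faces)
  two <- electrode_set(rbind(c(0, 0, 0), c(10, 0, 0)))
  ff <- gaussian_map(mm, two, c(0, 1), 8)
  expect_equal(ff$values[3], 0.5, tolerance = 1e-9)
  expect_equal(ff$values[4], 0.5, tolerance = 1e-9)

  expect_error(gaussian_map(m, electrode_set(), numeric(0)),
               "empty-montage")
  expect_error(gaussian_map(m, set, rep(1, 64), 0), "domain error")
})

test_that("linear map marks out-of-radius vertices uncovered", {
  v <- rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0), c(0, 0, 30))
  m <- tri_mesh(v, unit_tetrahedron()$faces)
  set <- electrode_set(rbind(c(0, 0, 0), c(12, 0, 0)))
  f <- linear_map(m, set, c(2, 8), radius_mm = 10)
  expect_false(f$covered[3])
  expect_true(is.na(f$values[3]))
  # vertex coincident with electrode 1, electrode 2 out of range
  expect_equal(f$values[1], 2, tolerance = 1e-12)
  ok <- f$covered
  expect_true(all(f$values[ok] >= 2 - 1e-12 & f$values[ok] <= 8 + 1e-12))
})

test_that("interpolants match direct weight summation on random configs", {
  set.seed(5)
  m <- make_brain_mesh(1)
  for (rep in 1:3) {
    k <- sample(3:8, 1)
    pos <- matrix(rnorm(3 * k, sd = 50), k)
    vals <- rnorm(k)
    set <- electrode_set(pos)
    fg <- gaussian_map(m, set, vals, 20)
    expect_lt(max(abs(fg$values -
                      brute_force_field(m, pos, vals, "gauss", 20))), 1e-9)
    fl <- linear_map(m, set, vals, 60)
    bf <- brute_force_field(m, pos, vals, "linear", 60)
    expect_equal(is.na(fl$values), is.na(bf))
    ok <- !is.na(bf)
    expect_lt(max(abs(fl$values[ok] - bf[ok])), 1e-9)
  }
})

test_that("gaussian map limits: Voronoi at tiny sigma, mean at huge sigma", {
  set.seed(8)
  m <- make_brain_mesh(1)
  pos <- electrode_positions(make_case_study_montage(make_brain_mesh(1)))[
    seq(1, 64, by = 8), ]
  vals <- rnorm(8)
  set <- electrode_set(pos)
  f0 <- gaussian_map(m, set, vals, 0.01)
  d2 <- as.matrix(dist(rbind(m$vertices, pos)))
  nearest <- apply(d2[seq_len(nrow(m$vertices)),
                      nrow(m$vertices) + 1:8], 1, which.min)
  expect_equal(f0$values, vals[nearest], tolerance = 1e-6)
  finf <- gaussian_map(m, set, vals, 1e5)
  expect_equal(finf$values, rep(mean(vals), nrow(m$vertices)),
               tolerance = 1e-4)
})

test_that("field is invariant to electrode order", {
  set.seed(21)
  m <- make_brain_mesh(1)
  pos <- matrix(rnorm(18, sd = 40), 6)
  vals <- rnorm(6)
  perm <- sample(6)
  f1 <- gaussian_map(m, electrode_set(pos), vals, 12)
  f2 <- gaussian_map(m, electrode_set(pos[perm, ]), vals[perm], 12)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
})

test_that("display ranges: auto, manual, degenerate", {
  expect_equal(scale_range(c(-2, 0, 5)), c(-2, 5))
  expect_equal(scale_range(c(-2, 0, 5), "manual", 0, 1), c(0, 1))
  expect_error(scale_range(1:3, "manual", 2, 2), "domain error")
  r <- scale_range(rep(4, 10))
  expect_equal(r, c(4 - 1e-9, 4 + 1e-9))
  # clamping: a value below the manual range maps to the low color
  cols <- map_colors(c(-2, 0, 1), c(0, 1), "bluered")
  expect_equal(cols[1, ], c(0, 0, 1))
})

test_that("node replotting maps values through the colormap", {
  set <- electrode_set(matrix(rnorm(12), 4, 3))
  same <- replot_nodes(set, rep(2, 4))
  expect_equal(nrow(unique(same[, c("r", "g", "b")])), 1L)

  vals <- c(0, 1, 2, 3)
  rp <- replot_nodes(set, vals, colormap = "gray")
  expect_equal(unname(unlist(rp[1, c("r", "g", "b")])), c(0, 0, 0))
  expect_equal(unname(unlist(rp[4, c("r", "g", "b")])), c(1, 1, 1))
  # monotone values give monotone gray levels
  expect_true(all(diff(rp$r) > 0))
  # positions unchanged
  expect_equal(electrode_positions(rp), electrode_positions(set))
  expect_error(replot_nodes(set, 1:3), "shape error")
})
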