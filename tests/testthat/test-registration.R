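test_that("center pixel casts along the view axis, deterministically", {
  cam <- camera(c(0, 0, 400), c(0, 0, 0), c(0, 1, 0), view_angle = 30)
  r <- cast_ray(cam, c(800, 800), c(400, 400))
  expect_equal(r$origin, c(0, 0, 400))
  expect_equal(r$direction, c(0, 0, -1), tolerance = 1e-12)
  r2 <- cast_ray(cam, c(800, 800), c(400, 400))
  expect_identical(r, r2)
})

test_that("top-center pixel is elevated by half the view angle", {
  cam <- camera(c(0, 0, 400), c(0, 0, 0), c(0, 1, 0), view_angle = 30)
  r <- cast_ray(cam, c(800, 800), c(400, 0))
  elev <- asin(sum(r$direction * c(0, 1, 0)))
  expect_equal(elev * 180 / pi, 15, tolerance = 1e-9)
})

test_that("ray casting is viewport-resolution covariant", {
  cam <- camera(c(50, -30, 350), c(0, 10, 5), c(0, 1, 0), view_angle = 40)
  r1 <- cast_ray(cam, c(640, 480), c(123, 456))
  r2 <- cast_ray(cam, c(1280, 960), c(246, 912))
  expect_equal(r1$direction, r2$direction, tolerance = 1e-12)
  expect_error(cast_ray(cam, c(640, 480), c(700, 10)), "outside")
})

test_that("nearest intersection is returned, not the far side", {
  m <- make_brain_mesh(3, scale_mm = c(200, 200, 200))  # sphere r = 100
  ray <- list(origin = c(0, 0, 400), direction = c(0, 0, -1))
  hit <- intersect_ray(ray, m)
  expect_false(is.null(hit))
  expect_gt(hit$point[3], 0)  # front hemisphere, not z ~ -100
  expect_equal(hit$point[1:2], c(0, 0), tolerance = 1e-6)

  miss <- intersect_ray(list(origin = c(0, 0, 400),
                             direction = c(1, 0, 0)), m)
  expect_null(miss)
})

test_that("intersection matches the brute-force all-triangle oracle", {
  set.seed(31)
  m <- make_brain_mesh(2)
  for (i in 1:40) {
    origin <- c(0, 0, 0) + 400 * normalize_dir(rnorm(3))
    target <- rnorm(3, sd = 40)
    dir <- normalize_dir(target - origin)
    ray <- list(origin = origin, direction = dir)
    a <- intersect_ray(ray, m)
    b <- brute_force_hit(ray, m)
    expect_identical(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_equal(a$point, b$point, tolerance = 1e-6)
      expect_equal(a$face, b$face)
    }
  }
})

test_that("ray-cast placements lie on the mesh surface", {
  m <- make_brain_mesh(2)
  cam <- camera_preset(m, "left")
  set <- register_clicks(m, cam, c(400, 300),
                         rbind(c(200, 150), c(220, 140), c(180, 170)))
  expect_equal(nrow(set), 3L)
  pos <- electrode_positions(set)
  for (i in 1:3) {
    ray <- list(origin = cam$position,
                direction = normalize_dir(pos[i, ] - cam$position))
    hit <- brute_force_hit(ray, m)
    expect_lt(abs(hit$t - sqrt(sum((pos[i, ] - cam$position)^2))), 1e-6)
  }
})

test_that("insert-after shifts subsequent indices", {
  s <- electrode_set(matrix(rnorm(12), 4, 3))
  s2 <- place_electrode(s, c(9, 9, 9), insert_after = 2)
  expect_equal(nrow(s2), 5L)
  expect_equal(electrode_positions(s2)[3, ], c(9, 9, 9))
  expect_equal(electrode_positions(s2)[4:5, ], electrode_positions(s)[3:4, ])
  expect_equal(s2$label, as.character(1:5))
  expect_error(place_electrode(s, c(0, 0, 0), insert_after = 7),
               "index error")

  # place then remove restores the original
  s3 <- remove_electrode(s2, 3)
  expect_equal(electrode_positions(s3), electrode_positions(s))

  # append to empty
  e <- place_electrode(electrode_set(), c(1, 2, 3))
  expect_equal(nrow(e), 1L)
  expect_equal(e$label, "1")
  expect_equal(nrow(remove_electrode(e, 1)), 0L)
})

test_that("random edit sequences keep indices contiguous", {
  set.seed(99)
  s <- electrode_set()
  for (i in 1:60) {
    k <- nrow(s)
    if (k == 0 || runif(1) < 0.6) {
      s <- place_electrode(s, rnorm(3), insert_after = sample(0:k, 1))
    } else {
      s <- remove_electrode(s, sample(k, 1))
    }
    expect_equal(s$label, as.character(seq_len(nrow(s))))
  }
})

test_that("tuning quantizes to the step and accumulates exactly", {
  s <- electrode_set(matrix(0, 1, 3))
  s2 <- tune_electrode(s, 1, c(0.1, 0, 0), step = 0.1)
  expect_equal(s2$x, 0.1)
  expect_identical(tune_electrode(s, 1, c(0, 0, 0))$x, 0)
  expect_error(tune_electrode(s, 1, c(1, 0, 0), step = 0), "domain error")

  s10 <- s
  for (i in 1:10) s10 <- tune_electrode(s10, 1, c(0.1, 0, 0), step = 0.1)
  s1 <- tune_electrode(s, 1, c(1, 0, 0), step = 0.1)
  expect_equal(s10$x, s1$x, tolerance = 1e-9)
})
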