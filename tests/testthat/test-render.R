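small_scene <- function(...) {
  m <- make_brain_mesh(1)
  mont <- electrode_set(electrode_positions(
    make_case_study_montage(m))[seq(1, 64, by = 4), ])
  scene_spec(mesh = m, electrodes = mont, ...)
}

test_that("rendering is deterministic and respects toggles", {
  sc <- small_scene()
  a <- render_scene(sc, 160, 120)
  b <- render_scene(sc, 160, 120)
  expect_identical(a, b)
  expect_equal(dim(a), c(120L, 160L, 3L))
  expect_true(all(a >= 0 & a <= 1))

  sc_off <- sc
  sc_off$show_electrodes <- FALSE
  expect_false(identical(render_scene(sc_off, 160, 120), a))

  sc_black <- sc
  sc_black$background <- "black"
  img_b <- render_scene(sc_black, 160, 120)
  expect_equal(img_b[1, 1, ], c(0, 0, 0))
  expect_equal(a[1, 1, ], c(1, 1, 1))
})

test_that("opacity reveals interior electrodes", {
  m <- make_brain_mesh(2)
  deep <- electrode_set(matrix(c(0, 0, 0), 1), radius = 6)
  solid <- scene_spec(mesh = m, electrodes = deep, opacity = 1,
                      show_colorbar = FALSE)
  translucent <- scene_spec(mesh = m, electrodes = deep, opacity = 0.3,
                            show_colorbar = FALSE)
  img1 <- render_scene(solid, 160, 120)
  img2 <- render_scene(translucent, 160, 120)
  redness <- function(img) max(img[, , 1] - img[, , 2])
  expect_lt(redness(img1), 0.05)  # hidden behind the opaque surface
  expect_gt(redness(img2), 0.1)   # blended through the translucent surface
})

test_that("rendering does not mutate the scene", {
  sc <- small_scene()
  snap <- unserialize(serialize(sc, NULL))
  invisible(render_scene(sc, 80, 60))
  expect_identical(sc, snap)
})

test_that("one image is exported per parameter row, reproducibly", {
  sc <- small_scene()
  k <- nrow(sc$electrodes)
  params <- matrix(rnorm(5 * k), 5)
  dir <- withr::local_tempdir()
  files <- export_images(sc, params, file.path(dir, "frame"),
                         format = "png", width = 120, height = 90)
  expect_length(files, 5L)
  expect_true(all(file.exists(files)))
  expect_equal(basename(files[1]), "frame_001.png")
  expect_equal(basename(files[5]), "frame_005.png")

  files1 <- export_images(sc, params[1, , drop = FALSE],
                          file.path(dir, "single"), width = 120,
                          height = 90)
  expect_length(files1, 1L)

  # identical inputs -> identical bytes
  dir2 <- withr::local_tempdir()
  files2 <- export_images(sc, params, file.path(dir2, "frame"),
                          format = "png", width = 120, height = 90)
  for (i in seq_along(files)) expect_file_bytes_equal(files[i], files2[i])

  expect_error(export_images(sc, matrix(1, 1, k + 2),
                             file.path(dir, "bad")), "electrodes")
})

test_that("BMP export writes a well-formed 24-bit bitmap", {
  sc <- small_scene()
  dir <- withr::local_tempdir()
  f <- export_images(sc, matrix(rnorm(nrow(sc$electrodes)), 1),
                     file.path(dir, "img"), format = "bmp",
                     width = 100, height = 80)
  expect_match(f, "img_001\\.bmp$")
  hdr <- readBin(f, "raw", 54)
  expect_identical(rawToChar(hdr[1:2]), "BM")
  w <- readBin(hdr[19:22], "integer", 1, size = 4, endian = "little")
  h <- readBin(hdr[23:26], "integer", 1, size = 4, endian = "little")
  bpp <- readBin(hdr[29:30], "integer", 1, size = 2, endian = "little")
  expect_equal(c(w, h, bpp), c(100L, 80L, 24L))
  expect_equal(file.size(f), 54 + 80 * 100 * 3)  # row stride already 4-aligned
})

test_that("camera presets satisfy the camera invariants", {
  m <- make_brain_mesh(1)
  for (v in c("left", "right", "anterior", "posterior", "superior",
              "inferior")) {
    cam <- camera_preset(m, v)
    expect_equal(sqrt(sum(cam$view_up^2)), 1, tolerance = 1e-6)
    expect_equal(cam$distance,
                 sqrt(sum((cam$position - cam$focal_point)^2)),
                 tolerance = 1e-6)
    expect_gt(cam$view_angle, 0)
    expect_lt(cam$view_angle, 180)
  }
})

test_that("scene JSON resolves paths and settings", {
  dir <- withr::local_tempdir()
  m <- make_brain_mesh(1)
  mont <- electrode_set(matrix(rnorm(9, sd = 30), 3, 3))
  write_mof(m, file.path(dir, "brain.mof"))
  write_epf(mont, file.path(dir, "montage.epf"))
  write_cpf(camera_preset(m, "left"), file.path(dir, "view.cpf"))
  js <- file.path(dir, "scene.json")
  writeLines(jsonlite::toJSON(list(
    mesh = "brain.mof", electrodes = "montage.epf", camera = "view.cpf",
    opacity = 0.5, background = "black", colormap = "hot",
    mapping = list(method = "linear", radius = 20)), auto_unbox = TRUE),
    js)
  sc <- read_scene_json(js)
  expect_s3_class(sc, "scene_spec")
  expect_equal(nrow(sc$mesh$vertices), nrow(m$vertices))
  expect_equal(nrow(sc$electrodes), 3L)
  expect_equal(sc$opacity, 0.5)
  expect_equal(sc$background, "black")
  expect_equal(sc$mapping$method, "linear")
  expect_equal(sc$mapping$radius, 20)
})
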