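test_that("mof write/read roundtrips vertices to float32 and faces exactly", {
  td <- unit_tetrahedron()
  m <- tri_mesh(td$vertices, td$faces)
  p <- withr::local_tempfile(fileext = ".mof")
  write_mof(m, p)
  m2 <- read_mof(p)
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)

  ico <- make_brain_mesh(3)  # 642 vertices = 10 * 4^3 + 2
  write_mof(ico, p)
  expect_equal(nrow(read_mof(p)$vertices), 642L)
})

test_that("mof rejects bad magic and dangling face indices", {
  p <- withr::local_tempfile(fileext = ".mof")
  writeBin(charToRaw("NOTAMESH"), p)
  expect_error(read_mof(p), "byte offset 0")

  # hand-craft a file whose face references vertex index V (out of range)
  con <- file(p, "wb")
  writeBin(charToRaw("CORTIMOF"), con)
  writeBin(c(4L, 1L), con, size = 4L, endian = "little")
  writeBin(as.numeric(1:12), con, size = 4L, endian = "little")
  writeBin(c(0L, 1L, 4L), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_mof(p), "dangling face index")
})

test_that("epf roundtrips, honors hand edits, and flags bad input", {
  set <- electrode_set(rbind(c(1, 2, 3), c(-4.5, 0, 2.25), c(10, -10, 0)),
                       labels = c("A1", "A2", "A3"), space = "MNI")
  p <- withr::local_tempfile(fileext = ".epf")
  write_epf(set, p)
  set2 <- read_epf(p)
  expect_equal(electrode_positions(set2), electrode_positions(set),
               tolerance = 1e-9)
  expect_equal(set2$label, set$label)
  expect_identical(attr(set2, "space"), "MNI")

  # write(read(write)) is byte-stable
  p2 <- withr::local_tempfile(fileext = ".epf")
  write_epf(set2, p2)
  expect_file_bytes_equal(p, p2)

  # the file is the source of truth: move electrode 2 by +5 mm in x
  lines <- readLines(p)
  f <- strsplit(lines[3], "\t")[[1]]
  f[3] <- as.character(as.numeric(f[3]) + 5)
  lines[3] <- paste(f, collapse = "\t")
  writeLines(lines, p)
  set3 <- read_epf(p)
  expect_equal(set3$x[2], set$x[2] + 5)

  # empty file -> empty set
  writeLines(character(0), p)
  expect_equal(nrow(read_epf(p)), 0L)

  writeLines(c("1\tA\t1\t2\tnot_a_number"), p)
  expect_error(read_epf(p), "line 1.*non-numeric")
  writeLines(c("1\tA\t1\t2\t3", "1\tB\t4\t5\t6"), p)
  expect_error(read_epf(p), "duplicate")
})

test_that("cpf roundtrips the full camera and validates invariants", {
  cam <- camera(c(10, -20, 380), c(0, 5, 0), c(0, 1, 0.2),
                view_angle = 25, rotation = 30)
  p <- withr::local_tempfile(fileext = ".cpf")
  write_cpf(cam, p)
  cam2 <- read_cpf(p)
  for (fld in c("position", "focal_point", "view_up", "view_angle",
                "distance", "rotation"))
    expect_equal(cam2[[fld]], cam[[fld]], tolerance = 1e-9)

  # rotation 360 normalizes to 0
  cam3 <- camera(rotation = 360)
  expect_equal(cam3$rotation, 0)
  write_cpf(camera(rotation = 359.5), p)
  expect_equal(read_cpf(p)$rotation, 359.5)

  # stored distance inconsistent with the position -> validation error
  lines <- readLines(p)
  lines[grepl("^distance", lines)] <- "distance\t123.456"
  writeLines(lines, p)
  expect_error(read_cpf(p), "inconsistent")

  writeLines(lines[!grepl("^view_angle", lines)], p)
  expect_error(read_cpf(p), "view_angle")
})

test_that("parameter/matrix tables parse, validate shape, and roundtrip", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\t2\t3\t4", "5\t6\t7\t8"), p)
  v <- read_table_file(p, "params")
  expect_equal(dim(v), c(2L, 4L))
  expect_error(read_table_file(p, "matrix"), "square")

  writeLines(c("1\t2\t3", "4\t5"), p)
  expect_error(read_table_file(p, "params"), "row 2")

  # 64 x 64 roundtrip at full precision
  set.seed(11)
  M <- matrix(runif(64 * 64), 64)
  M <- (M + t(M)) / 2
  write_table_file(M, p, "matrix")
  M2 <- read_table_file(p, "matrix")
  expect_lt(max(abs(M2 - M)), 1e-9)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_table_file(M2, p2, "matrix")
  expect_file_bytes_equal(p, p2)

  # symmetrization warns on gross asymmetry and is idempotent
  A <- M; A[1, 2] <- A[1, 2] + 0.5
  write_table_file(A, p, "params")
  expect_warning(S <- read_table_file(p, "matrix"), "symmetrized")
  expect_equal(S, (A + t(A)) / 2, tolerance = 1e-12)
  expect_identical(S, (S + t(S)) / 2)
})

test_that("OFF and PLY interchange preserves geometry", {
  m <- make_brain_mesh(1)
  for (ext in c(".off", ".ply")) {
    p <- withr::local_tempfile(fileext = ext)
    write_mesh(m, p)
    m2 <- read_mesh(p)
    expect_identical(m2$faces, m$faces)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  }
})

test_that("coordinate import applies affine transforms correctly", {
  pts <- matrix(rnorm(15), 5, 3)
  s <- import_coordinates(pts)
  expect_equal(electrode_positions(s), pts, tolerance = 1e-12)
  expect_equal(s$label, as.character(1:5))

  tr <- diag(4); tr[1, 4] <- 10
  s2 <- import_coordinates(pts, transform = tr)
  expect_equal(electrode_positions(s2)[, 1], pts[, 1] + 10)

  # 90 degree rotation about z maps (1,0,0) to (0,1,0)
  th <- pi / 2
  rot <- diag(4)
  rot[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  s3 <- import_coordinates(matrix(c(1, 0, 0), 1), transform = rot)
  expect_equal(electrode_positions(s3)[1, ], c(0, 1, 0), tolerance = 1e-9)

  expect_error(import_coordinates(pts, transform = matrix(0, 4, 4)),
               "singular")
})
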