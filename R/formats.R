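MOF_MAGIC <- charToRaw("CORTIMOF")

fmt_num <- function(x) {
  # canonical, locale-independent, full-precision ASCII for doubles
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

#' Write a brain model file (.mof)
#'
#' The model file is the only binary format: a little-endian container with
#' an 8-byte magic string, uint32 vertex and face counts, a float32 vertex
#' block (row-major x y z) and a uint32 face block (row-major, 0-based
#' indices on disk). Vertices therefore roundtrip at float32 precision and
#' faces exactly.
#'
#' @param mesh a \code{tri_mesh}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mof <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(MOF_MAGIC, con)
  writeBin(as.integer(c(nrow(mesh$vertices), nrow(mesh$faces))), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "little")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a brain model file (.mof)
#'
#' @param path path to a file written by \code{\link{write_mof}}.
#' @return a validated \code{tri_mesh}.
#' @export
read_mof <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (length(magic) < 8L || !identical(magic, MOF_MAGIC))
    stop("format error: bad magic at byte offset 0 (not a .mof file): ", path)
  counts <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (length(counts) < 2L || any(counts < 0))
    stop("format error: truncated header at byte offset 8")
  nv <- counts[1]; nf <- counts[2]
  verts <- readBin(con, "numeric", nv * 3L, size = 4L, endian = "little")
  if (length(verts) < nv * 3L)
    stop("format error: truncated vertex block at byte offset ",
         16 + length(verts) * 4)
  faces <- readBin(con, "integer", nf * 3L, size = 4L, endian = "little")
  if (length(faces) < nf * 3L)
    stop("format error: truncated face block at byte offset ",
         16 + nv * 12 + length(faces) * 4)
  faces <- matrix(faces, ncol = 3L, byrow = TRUE) + 1L
  bad <- which(faces < 1L | faces > nv, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("validation error: dangling face index in face(s) ",
         paste(unique(bad[, 1L])[1:min(5, length(unique(bad[, 1L])))],
               collapse = ", "))
  tri_mesh(matrix(verts, ncol = 3L, byrow = TRUE), faces)
}

#' Write an electrode position file (.epf)
#'
#' Tab-separated ASCII with one comment header line, then one line per
#' contact: \code{index label x y z r g b radius}. Coordinates are mm,
#' colors RGB in [0, 1], radius mm. The file is the source of truth: users
#' can edit coordinates directly in it and the edit is honored on re-read.
#'
#' @param set an \code{electrode_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_epf <- function(set, path) {
  df <- as.data.frame(set)
  lines <- c(sprintf("# cortimap electrode position file v1\tspace=%s",
                     attr(set, "space")))
  if (nrow(df) > 0) {
    body <- vapply(seq_len(nrow(df)), function(i) {
      paste(c(i, df$label[i],
              fmt_num(c(df$x[i], df$y[i], df$z[i],
                        df$r[i], df$g[i], df$b[i], df$radius[i]))),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an electrode position file (.epf)
#'
#' @param path path to a file written by \code{\link{write_epf}} (possibly
#'   hand-edited). Missing style columns take the default ball style.
#' @return an \code{electrode_set}.
#' @export
read_epf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  space <- "native"
  hdr <- grepl("^#", lines)
  if (any(hdr)) {
    m <- regmatches(lines[hdr][1],
                    regexpr("space=(native|MNI|Talairach)", lines[hdr][1]))
    if (length(m) == 1) space <- sub("space=", "", m)
  }
  lines <- lines[!hdr & nzchar(trimws(lines))]
  if (length(lines) == 0) return(electrode_set(space = space))
  sty <- default_electrode_style()
  idx <- integer(length(lines)); labs <- character(length(lines))
  pos <- matrix(NA_real_, length(lines), 3)
  col <- matrix(sty$color, length(lines), 3, byrow = TRUE)
  rad <- rep(sty$radius, length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      stop("parse error at line ", i, ": expected at least 5 tab-separated ",
           "fields (index label x y z)")
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (any(is.na(xyz)))
      stop("parse error at line ", i, ": non-numeric coordinate")
    idx[i] <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx[i])) stop("parse error at line ", i, ": bad index field")
    labs[i] <- f[2]
    pos[i, ] <- xyz
    if (length(f) >= 8) {
      rgb <- suppressWarnings(as.numeric(f[6:8]))
      if (any(is.na(rgb)))
        stop("parse error at line ", i, ": non-numeric color")
      col[i, ] <- rgb
    }
    if (length(f) >= 9) {
      r <- suppressWarnings(as.numeric(f[9]))
      if (is.na(r)) stop("parse error at line ", i, ": non-numeric radius")
      rad[i] <- r
    }
  }
  if (anyDuplicated(idx))
    stop("validation error: duplicate electrode index ",
         idx[duplicated(idx)][1])
  o <- order(idx)
  electrode_set(pos[o, , drop = FALSE], labels = labs[o],
                colors = col[o, , drop = FALSE], radius = rad[o],
                space = space)
}

#' Write a camera position file (.cpf)
#'
#' Tab-separated ASCII key/value lines storing the full camera state:
#' position, focal point, view-up, view angle, distance and roll, so a saved
#' view can be restored exactly.
#'
#' @param cam a \code{bfm_camera}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cpf <- function(cam, path) {
  lines <- c("# cortimap camera position file v1",
             paste(c("position", fmt_num(cam$position)), collapse = "\t"),
             paste(c("focal_point", fmt_num(cam$focal_point)),
                   collapse = "\t"),
             paste(c("view_up", fmt_num(cam$view_up)), collapse = "\t"),
             paste(c("view_angle", fmt_num(cam$view_angle)), collapse = "\t"),
             paste(c("distance", fmt_num(cam$distance)), collapse = "\t"),
             paste(c("rotation", fmt_num(cam$rotation)), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a camera position file (.cpf)
#'
#' Validates that the stored distance matches the position/focal-point
#' distance (within 1e-3 mm) and that view-up is a unit vector; the rotation
#' angle is normalized to [0, 360) on read.
#'
#' @param path path to a file written by \code{\link{write_cpf}}.
#' @return a \code{bfm_camera}.
#' @export
read_cpf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(vals))) stop("parse error: non-numeric value for key ", f[1])
    kv[[f[1]]] <- vals
  }
  for (key in c("position", "focal_point", "view_up", "view_angle"))
    if (is.null(kv[[key]]))
      stop("parse error: missing required key '", key, "'")
  vu <- kv$view_up
  if (abs(sqrt(sum(vu^2)) - 1) > 1e-6)
    stop("validation error: view_up is not unit length")
  cam <- camera(kv$position, kv$focal_point, vu, kv$view_angle,
                rotation = if (is.null(kv$rotation)) 0 else kv$rotation)
  if (!is.null(kv$distance) && abs(kv$distance - cam$distance) > 1e-3)
    stop("validation error: stored distance ", kv$distance,
         " inconsistent with position/focal_point distance ", cam$distance)
  cam
}

#' Read a tab-separated parameter or correlation table
#'
#' Functional-parameter files are m x n matrices (m rows of per-channel
#' values, e.g. time stages); correlation files are n x n matrices with
#' entry (i, j) the correlation measure between channels i and j. Both are
#' plain ASCII with tab-separated values and a locale-independent decimal
#' point.
#'
#' For \code{kind = "matrix"} the table must be square; asymmetry up to
#' \code{1e-6} is accepted silently, larger asymmetry is symmetrized as
#' \code{(C + t(C)) / 2} with a warning.
#'
#' @param path input file path.
#' @param kind "params" for an m x n parameter table, "matrix" for an n x n
#'   correlation matrix.
#' @return numeric matrix; for "matrix", exactly symmetric.
#' @export
read_table_file <- function(path, kind = c("params", "matrix")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("parse error: empty table file")
  rows <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(rows[[1]])
  vals <- matrix(NA_real_, length(rows), n)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n)
      stop("parse error at row ", i, ": expected ", n, " values, got ",
           length(rows[[i]]))
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(v))) stop("parse error at row ", i, ": non-numeric value")
    vals[i, ] <- v
  }
  if (!all(is.finite(vals))) stop("table contains non-finite values")
  if (kind == "matrix") {
    if (nrow(vals) != ncol(vals))
      stop("shape error: correlation matrix must be square, got ",
           nrow(vals), " x ", ncol(vals))
    asym <- max(abs(vals - t(vals)))
    if (asym > 1e-6) {
      warning("matrix asymmetry ", signif(asym, 3),
              " exceeds 1e-6; symmetrized as (C + t(C))/2")
      vals <- (vals + t(vals)) / 2
    } else if (asym > 0) {
      vals <- (vals + t(vals)) / 2
    }
  }
  vals
}

#' Write a tab-separated parameter or correlation table
#'
#' @param values numeric matrix (m x n parameters, or n x n correlations).
#' @param path output file path.
#' @param kind "params" or "matrix"; "matrix" enforces squareness.
#' @return \code{path}, invisibly.
#' @export
write_table_file <- function(values, path, kind = c("params", "matrix")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (kind == "matrix" && nrow(values) != ncol(values))
    stop("shape error: correlation matrix must be square")
  if (!all(is.finite(values))) stop("table contains non-finite values")
  lines <- apply(values, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Import electrode coordinates from a generic table
#'
#' Entry point for coordinates produced by other localization routes
#' (stereotactic planning, CT/X-ray identification, ...): any table whose
#' first three numeric columns are x, y, z can be imported, optionally
#' through a 4 x 4 affine transform into the model space.
#'
#' @param table matrix or data frame with at least 3 numeric columns
#'   (x, y, z in mm); an optional "label" column is honored.
#' @param space coordinate space tag of the result.
#' @param transform 4 x 4 affine applied to each point (identity default);
#'   must be invertible.
#' @return an \code{electrode_set}, input order preserved; labels
#'   auto-generated "1".."n" when absent.
#' @export
import_coordinates <- function(table, space = "native",
                               transform = diag(4)) {
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L)))
    stop("transform must be a 4 x 4 affine matrix")
  if (abs(det(transform)) < 1e-12)
    stop("validation error: singular transform")
  labels <- NULL
  if (is.data.frame(table)) {
    if ("label" %in% names(table)) labels <- as.character(table$label)
    num <- vapply(table, is.numeric, logical(1))
    if (sum(num) < 3) stop("table needs at least 3 numeric columns")
    xyz <- as.matrix(table[, which(num)[1:3], drop = FALSE])
  } else {
    xyz <- as.matrix(table)
    if (ncol(xyz) < 3) stop("table needs at least 3 numeric columns")
    xyz <- xyz[, 1:3, drop = FALSE]
  }
  storage.mode(xyz) <- "double"
  hom <- cbind(xyz, 1) %*% t(transform)
  pts <- hom[, 1:3, drop = FALSE] / hom[, 4]
  electrode_set(pts, labels = labels, space = space)
}

#' Read a mesh from OFF, ASCII PLY or .mof
#'
#' Interchange importer for triangle meshes: dispatches on the file
#' extension (.off, .ply, .mof). OFF/PLY faces are 0-based on disk and
#' converted to R's 1-based indexing.
#'
#' @param path input mesh file.
#' @return a \code{tri_mesh}.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mof = read_mof(path),
         off = read_off(path),
         ply = read_ply(path),
         stop("unsupported mesh format: .", ext,
              " (supported: .mof, .off, .ply)"))
}

#' Write a mesh to OFF, ASCII PLY or .mof, by extension
#' @param mesh a \code{tri_mesh}.
#' @param path output path ending in .mof, .off or .ply.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mof = write_mof(mesh, path),
         off = write_off(mesh, path),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (toupper(trimws(lines[1])) != "OFF")
    stop("format error: missing OFF header")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vl <- lines[3:(2 + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  fl <- lines[(3 + nv):(2 + nv + nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("only triangle faces are supported")
    x[2:4] + 1L
  }))
  tri_mesh(verts, faces)
}

write_off <- function(mesh, path) {
  lines <- c("OFF",
             paste(nrow(mesh$vertices), nrow(mesh$faces), 0),
             apply(mesh$vertices, 1, function(v)
               paste(fmt_num(v), collapse = " ")),
             apply(mesh$faces, 1, function(f)
               paste(c(3L, f - 1L), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply" ||
      !grepl("ascii", lines[grepl("^format", lines)][1]))
    stop("format error: only ASCII PLY is supported")
  nv <- as.integer(sub(".*vertex\\s+", "",
                       lines[grepl("^element vertex", lines)][1]))
  nf <- as.integer(sub(".*face\\s+", "",
                       lines[grepl("^element face", lines)][1]))
  hdr_end <- which(trimws(lines) == "end_header")[1]
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("only triangle faces are supported")
    x[2:4] + 1L
  }))
  tri_mesh(verts, faces)
}

write_ply <- function(mesh, path) {
  lines <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(mesh$vertices)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(mesh$faces)),
             "property list uchar int vertex_indices", "end_header",
             apply(mesh$vertices, 1, function(v)
               paste(fmt_num(v), collapse = " ")),
             apply(mesh$faces, 1, function(f)
               paste(c(3L, f - 1L), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a cortimap file
#'
#' Reads the file with the reader matching its extension (.mof/.off/.ply
#' mesh, .epf electrodes, .cpf camera, .txt table) and reports what it
#' contains; errors surface as parse/validation errors.
#'
#' @param path file to validate.
#' @param kind for .txt files, "params" or "matrix"; others auto-detect.
#' @return a one-line description string, invisibly; prints it.
#' @export
validate_file <- function(path, kind = "params") {
  ext <- tolower(tools::file_ext(path))
  desc <- switch(ext,
    mof = , off = , ply = {
      m <- read_mesh(path)
      sprintf("%s mesh: %d vertices, %d faces, %s", ext,
              nrow(m$vertices), nrow(m$faces),
              if (is_closed(m)) "closed" else "open")
    },
    epf = {
      s <- read_epf(path)
      sprintf("electrode set: %d contact(s), space %s", nrow(s),
              attr(s, "space"))
    },
    cpf = {
      cm <- read_cpf(path)
      sprintf("camera: distance %.2f mm, view angle %.1f deg",
              cm$distance, cm$view_angle)
    },
    txt = {
      v <- read_table_file(path, kind)
      sprintf("%s table: %d x %d", kind, nrow(v), ncol(v))
    },
    stop("unknown file type: .", ext))
  cat(desc, "\n")
  invisible(desc)
}
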