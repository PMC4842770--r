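# ---- deterministic software rasterizer -------------------------------------
# All rendering is pure R arithmetic on pixel matrices: identical scenes give
# byte-identical buffers on any platform, with no display or GPU required.

#' Scene description for headless rendering
#'
#' Collects everything one view shows: the brain mesh (with opacity), the
#' electrode balls, stick edges, an optional surface scalar field, camera,
#' and display toggles. Rendering never mutates the scene.
#'
#' @param mesh a \code{tri_mesh}, or NULL.
#' @param electrodes an \code{electrode_set}, or NULL.
#' @param edges a styled \code{edge_set} (see \code{\link{edge_styles}}), or
#'   NULL; stick endpoints are electrode centers.
#' @param field a \code{scalar_field} draped over the mesh, or NULL.
#' @param camera a \code{bfm_camera}; default left-lateral preset framing
#'   the mesh.
#' @param opacity mesh opacity in [0, 1]; below 1 the mesh is alpha-blended
#'   so interior electrodes and sticks show through.
#' @param background "white" or "black".
#' @param show_axes,show_colorbar,show_electrodes,show_labels display
#'   toggles.
#' @param colormap colormap name for the surface field and colorbar.
#' @param mesh_color base RGB of the unmapped surface.
#' @param edge_radius_mm stick radius in mm.
#' @param mapping list of surface-mapping settings used by
#'   \code{\link{export_images}}: \code{method} ("gauss" or "linear"),
#'   \code{sigma}, \code{radius}, \code{range} (NULL = auto per row).
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(mesh = NULL, electrodes = NULL, edges = NULL,
                       field = NULL, camera = NULL, opacity = 1,
                       background = c("white", "black"), show_axes = FALSE,
                       show_colorbar = TRUE, show_electrodes = TRUE,
                       show_labels = FALSE, colormap = "bluered",
                       mesh_color = c(0.82, 0.8, 0.78),
                       edge_radius_mm = 0.8,
                       mapping = list(method = "gauss", sigma = 10,
                                      radius = 15, range = NULL)) {
  background <- match.arg(background)
  if (!is.numeric(opacity) || opacity < 0 || opacity > 1)
    stop("opacity must be in [0, 1]")
  if (is.null(camera)) {
    if (is.null(mesh)) stop("a camera is required when there is no mesh")
    camera <- camera_preset(mesh, "left")
  }
  structure(list(mesh = mesh, electrodes = electrodes, edges = edges,
                 field = field, camera = camera, opacity = opacity,
                 background = background, show_axes = show_axes,
                 show_colorbar = show_colorbar,
                 show_electrodes = show_electrodes,
                 show_labels = show_labels, colormap = colormap,
                 mesh_color = mesh_color, edge_radius_mm = edge_radius_mm,
                 mapping = mapping),
            class = "scene_spec")
}

new_canvas <- function(w, h, bg) {
  e <- new.env(parent = emptyenv())
  e$R <- matrix(bg[1], h, w); e$G <- matrix(bg[2], h, w)
  e$B <- matrix(bg[3], h, w); e$Z <- matrix(Inf, h, w)
  e$w <- w; e$h <- h
  e
}

# project an n x 3 world matrix into camera space (columns x, y, z-depth)
to_camera <- function(P, cam, basis) {
  Q <- sweep(P, 2L, cam$position)
  cbind(Q %*% basis$right, Q %*% basis$up, Q %*% basis$forward)
}

# rasterize triangle soup given as corner matrices (world mm) + corner colors
raster_tris <- function(cv, cam, basis, P1, P2, P3, C1, C2, C3,
                        alpha = 1, sort_bf = FALSE, shade = TRUE) {
  if (nrow(P1) == 0L) return(invisible())
  tanv <- tan(cam$view_angle / 2 * pi / 180)
  A1 <- to_camera(P1, cam, basis)
  A2 <- to_camera(P2, cam, basis)
  A3 <- to_camera(P3, cam, basis)
  near <- 1e-3 * cam$distance
  ok <- A1[, 3] > near & A2[, 3] > near & A3[, 3] > near
  if (!any(ok)) return(invisible())
  if (shade) {
    n <- vec_cross(P2 - P1, P3 - P1)
    nn <- row_norms(n)
    ctr <- (P1 + P2 + P3) / 3
    vd <- sweep(ctr, 2L, cam$position)
    vdn <- row_norms(vd)
    lam <- abs(rowSums(n * vd)) / (nn * vdn)
    lam[!is.finite(lam)] <- 0
    inten <- 0.35 + 0.65 * lam
    C1 <- C1 * inten; C2 <- C2 * inten; C3 <- C3 * inten
  }
  w <- cv$w; h <- cv$h
  sx <- function(A) w / 2 + (A[, 1] / A[, 3]) / tanv * (h / 2)
  sy <- function(A) h / 2 - (A[, 2] / A[, 3]) / tanv * (h / 2)
  X1 <- sx(A1); Y1 <- sy(A1); X2 <- sx(A2); Y2 <- sy(A2)
  X3 <- sx(A3); Y3 <- sy(A3)
  idx <- which(ok)
  if (sort_bf) {
    zc <- (A1[idx, 3] + A2[idx, 3] + A3[idx, 3]) / 3
    idx <- idx[order(-zc, idx)]
  }
  for (t in idx) {
    x1 <- X1[t]; y1 <- Y1[t]; x2 <- X2[t]; y2 <- Y2[t]
    x3 <- X3[t]; y3 <- Y3[t]
    ix0 <- max(1L, floor(min(x1, x2, x3) + 0.5))
    ix1 <- min(w, ceiling(max(x1, x2, x3) + 0.5))
    iy0 <- max(1L, floor(min(y1, y2, y3) + 0.5))
    iy1 <- min(h, ceiling(max(y1, y2, y3) + 0.5))
    if (ix0 > ix1 || iy0 > iy1) next
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    if (abs(det) < 1e-12) next
    px <- seq.int(ix0, ix1) - 0.5
    py <- seq.int(iy0, iy1) - 0.5
    nx <- length(px); ny <- length(py)
    PX <- rep(px, each = ny); PY <- rep(py, times = nx)
    l2 <- ((PX - x1) * (y3 - y1) - (x3 - x1) * (PY - y1)) / det
    l3 <- ((x2 - x1) * (PY - y1) - (PX - x1) * (y2 - y1)) / det
    l1 <- 1 - l2 - l3
    ins <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(ins)) next
    zi <- l1 * A1[t, 3] + l2 * A2[t, 3] + l3 * A3[t, 3]
    rows <- rep(seq.int(iy0, iy1), times = nx)
    cols <- rep(seq.int(ix0, ix1), each = ny)
    sel <- which(ins)
    pix <- cbind(rows[sel], cols[sel])
    zold <- cv$Z[pix]
    vis <- zi[sel] < zold
    if (!any(vis)) next
    sel <- sel[vis]; pix <- pix[vis, , drop = FALSE]
    cr <- l1[sel] * C1[t, 1] + l2[sel] * C2[t, 1] + l3[sel] * C3[t, 1]
    cg <- l1[sel] * C1[t, 2] + l2[sel] * C2[t, 2] + l3[sel] * C3[t, 2]
    cb <- l1[sel] * C1[t, 3] + l2[sel] * C2[t, 3] + l3[sel] * C3[t, 3]
    if (alpha >= 1) {
      cv$R[pix] <- cr; cv$G[pix] <- cg; cv$B[pix] <- cb
      cv$Z[pix] <- zi[sel]
    } else {
      cv$R[pix] <- alpha * cr + (1 - alpha) * cv$R[pix]
      cv$G[pix] <- alpha * cg + (1 - alpha) * cv$G[pix]
      cv$B[pix] <- alpha * cb + (1 - alpha) * cv$B[pix]
      # no depth write: transparency does not occlude
    }
  }
  invisible()
}

# unit UV-sphere triangle soup, fixed tessellation for determinism
unit_sphere_tris <- function(nseg = 16L) {
  nth <- nseg; nph <- max(3L, nseg %/% 2L)
  th <- seq(0, 2 * pi, length.out = nth + 1L)
  ph <- seq(0, pi, length.out = nph + 1L)
  vtx <- function(i, j)
    c(sin(ph[j]) * cos(th[i]), sin(ph[j]) * sin(th[i]), cos(ph[j]))
  P1 <- NULL; P2 <- NULL; P3 <- NULL
  a <- list(); b <- list(); c3 <- list()
  k <- 1L
  for (j in seq_len(nph)) for (i in seq_len(nth)) {
    v00 <- vtx(i, j); v10 <- vtx(i + 1L, j)
    v01 <- vtx(i, j + 1L); v11 <- vtx(i + 1L, j + 1L)
    if (j > 1L) { a[[k]] <- v00; b[[k]] <- v10; c3[[k]] <- v11; k <- k + 1L }
    if (j < nph) { a[[k]] <- v00; b[[k]] <- v11; c3[[k]] <- v01; k <- k + 1L }
  }
  list(p1 = do.call(rbind, a), p2 = do.call(rbind, b),
       p3 = do.call(rbind, c3))
}

# cylinder side between two points, 16-gon cross-section
cylinder_tris <- function(p, q, radius, nseg = 16L) {
  axis <- q - p
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) return(NULL)
  az <- axis / len
  ref <- if (abs(az[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ax <- normalize3(cross3(az, ref))
  ay <- cross3(az, ax)
  th <- seq(0, 2 * pi, length.out = nseg + 1L)
  ring <- t(vapply(th, function(a) ax * cos(a) + ay * sin(a),
                   numeric(3))) * radius
  b0 <- sweep(ring, 2L, p, "+")
  b1 <- sweep(ring, 2L, q, "+")
  i <- seq_len(nseg)
  list(p1 = rbind(b0[i, ], b1[i + 1L, ]),
       p2 = rbind(b0[i + 1L, ], b0[i + 1L, ]),
       p3 = rbind(b1[i, ], b1[i, ]))
}

draw_line3d <- function(cv, cam, basis, p, q, color, px_width = 1) {
  tanv <- tan(cam$view_angle / 2 * pi / 180)
  A <- to_camera(rbind(p, q), cam, basis)
  near <- 1e-3 * cam$distance
  if (A[1, 3] <= near || A[2, 3] <= near) return(invisible())
  w <- cv$w; h <- cv$h
  s <- cbind(w / 2 + (A[, 1] / A[, 3]) / tanv * (h / 2),
             h / 2 - (A[, 2] / A[, 3]) / tanv * (h / 2))
  npts <- max(2L, ceiling(2 * sqrt(sum((s[2, ] - s[1, ])^2))))
  tt <- seq(0, 1, length.out = npts)
  xs <- s[1, 1] + tt * (s[2, 1] - s[1, 1])
  ys <- s[1, 2] + tt * (s[2, 2] - s[1, 2])
  zs <- A[1, 3] + tt * (A[2, 3] - A[1, 3])
  for (off in seq_len(px_width) - 1L) {
    ix <- round(xs + 0.5) + off %% 2L
    iy <- round(ys + 0.5) + off %/% 2L
    okp <- ix >= 1 & ix <= w & iy >= 1 & iy <= h
    pix <- cbind(iy[okp], ix[okp])
    vis <- zs[okp] < cv$Z[pix]
    pix <- pix[vis, , drop = FALSE]
    cv$R[pix] <- color[1]; cv$G[pix] <- color[2]; cv$B[pix] <- color[3]
    cv$Z[pix] <- zs[okp][vis]
  }
  invisible()
}

#' Render a scene to a raster image
#'
#' Deterministic z-buffered rasterization of the scene: the brain surface
#' (optionally colored by a draped scalar field, optionally transparent),
#' electrode balls as spheres, connection sticks as cylinders, plus 2D
#' overlays (colorbar, labels, axes). Identical scenes render to identical
#' pixel buffers.
#'
#' @param scene a \code{scene_spec}.
#' @param width,height image size in pixels.
#' @return height x width x 3 numeric array in [0, 1].
#' @export
render_scene <- function(scene, width = 640, height = 480) {
  bg <- if (scene$background == "white") c(1, 1, 1) else c(0, 0, 0)
  cv <- new_canvas(width, height, bg)
  cam <- scene$camera
  basis <- camera_basis(cam)

  # opaque pass: electrodes and sticks first
  pos <- NULL
  if (!is.null(scene$electrodes) && nrow(scene$electrodes) > 0)
    pos <- electrode_positions(scene$electrodes)
  if (!is.null(scene$edges) && nrow(scene$edges) > 0 && !is.null(pos)) {
    ed <- as.data.frame(scene$edges)
    if (is.null(ed$r)) { ed$r <- 0.3; ed$g <- 0.3; ed$b <- 0.3 }
    for (e in seq_len(nrow(ed))) {
      cy <- cylinder_tris(pos[ed$i[e], ], pos[ed$j[e], ],
                          scene$edge_radius_mm)
      if (is.null(cy)) next
      col <- matrix(c(ed$r[e], ed$g[e], ed$b[e]), nrow(cy$p1), 3,
                    byrow = TRUE)
      raster_tris(cv, cam, basis, cy$p1, cy$p2, cy$p3, col, col, col)
    }
  }
  if (scene$show_electrodes && !is.null(pos)) {
    us <- unit_sphere_tris(16L)
    df <- as.data.frame(scene$electrodes)
    for (e in seq_len(nrow(df))) {
      r <- df$radius[e]
      ctr <- pos[e, ]
      col <- matrix(c(df$r[e], df$g[e], df$b[e]), nrow(us$p1), 3,
                    byrow = TRUE)
      raster_tris(cv, cam, basis,
                  sweep(us$p1 * r, 2L, ctr, "+"),
                  sweep(us$p2 * r, 2L, ctr, "+"),
                  sweep(us$p3 * r, 2L, ctr, "+"), col, col, col)
    }
  }
  if (scene$show_axes) {
    org <- if (is.null(scene$mesh)) c(0, 0, 0) else
      apply(scene$mesh$vertices, 2L, min) - 10
    len <- if (is.null(scene$mesh)) 50 else
      0.4 * max(apply(scene$mesh$vertices, 2L, max) -
                apply(scene$mesh$vertices, 2L, min))
    draw_line3d(cv, cam, basis, org, org + c(len, 0, 0), c(1, 0, 0), 2)
    draw_line3d(cv, cam, basis, org, org + c(0, len, 0), c(0, 0.7, 0), 2)
    draw_line3d(cv, cam, basis, org, org + c(0, 0, len), c(0, 0, 1), 2)
  }

  # mesh pass (opaque -> z-buffered; transparent -> back-to-front blend)
  if (!is.null(scene$mesh) && scene$opacity > 0) {
    m <- scene$mesh
    vcol <- matrix(scene$mesh_color, nrow(m$vertices), 3, byrow = TRUE)
    if (!is.null(scene$field)) {
      f <- scene$field
      cols <- map_colors(ifelse(is.na(f$values), f$range[1], f$values),
                         f$range, scene$colormap)
      vcol[f$covered, ] <- cols[f$covered, , drop = FALSE]
    }
    f1 <- m$faces[, 1L]; f2 <- m$faces[, 2L]; f3 <- m$faces[, 3L]
    raster_tris(cv, cam, basis,
                m$vertices[f1, , drop = FALSE],
                m$vertices[f2, , drop = FALSE],
                m$vertices[f3, , drop = FALSE],
                vcol[f1, , drop = FALSE], vcol[f2, , drop = FALSE],
                vcol[f3, , drop = FALSE],
                alpha = scene$opacity, sort_bf = scene$opacity < 1)
  }

  # 2D overlays
  fg <- if (scene$background == "white") c(0, 0, 0) else c(1, 1, 1)
  if (scene$show_colorbar) {
    rng <- if (!is.null(scene$field)) scene$field$range
      else if (!is.null(scene$edges) && !is.null(attr(scene$edges, "scale")))
        attr(scene$edges, "scale")
      else c(0, 1)
    draw_colorbar(cv, scene$colormap, rng, fg)
  }
  if (scene$show_labels && !is.null(pos)) {
    tanv <- tan(cam$view_angle / 2 * pi / 180)
    df <- as.data.frame(scene$electrodes)
    A <- to_camera(pos, cam, basis)
    up_off <- pos + outer(df$radius * 1.2, basis$up)
    A2 <- to_camera(up_off, cam, basis)
    for (e in seq_len(nrow(df))) {
      if (A[e, 3] <= 0) next
      zhere <- cv$Z[max(1, min(cv$h, round(cv$h / 2 -
            (A[e, 2] / A[e, 3]) / tanv * (cv$h / 2)))),
            max(1, min(cv$w, round(cv$w / 2 +
            (A[e, 1] / A[e, 3]) / tanv * (cv$h / 2))))]
      # hide the label when something other than the ball itself occludes it
      if (A[e, 3] > zhere + 3 * df$radius[e] + 1) next
      sx <- cv$w / 2 + (A2[e, 1] / A2[e, 3]) / tanv * (cv$h / 2)
      sy <- cv$h / 2 - (A2[e, 2] / A2[e, 3]) / tanv * (cv$h / 2)
      draw_text(cv, round(sx), round(sy) - 8, df$label[e], fg)
    }
  }
  array(c(cv$R, cv$G, cv$B), c(height, width, 3L))
}

draw_colorbar <- function(cv, colormap, rng, fg) {
  w <- cv$w; h <- cv$h
  bw <- max(8L, round(w * 0.025))
  x0 <- w - bw - 8L; x1 <- w - 9L
  y0 <- round(h * 0.15); y1 <- round(h * 0.85)
  if (x0 < 1 || y1 <= y0) return(invisible())
  f <- cortimap_colormap(colormap)
  u <- (y1 - seq.int(y0, y1)) / (y1 - y0)
  cols <- f(u)
  for (k in seq_along(u)) {
    cv$R[y0 + k - 1L, x0:x1] <- cols[k, 1]
    cv$G[y0 + k - 1L, x0:x1] <- cols[k, 2]
    cv$B[y0 + k - 1L, x0:x1] <- cols[k, 3]
  }
  cv$R[c(y0 - 1L, y1 + 1L), (x0 - 1L):(x1 + 1L)] <- fg[1]
  cv$G[c(y0 - 1L, y1 + 1L), (x0 - 1L):(x1 + 1L)] <- fg[2]
  cv$B[c(y0 - 1L, y1 + 1L), (x0 - 1L):(x1 + 1L)] <- fg[3]
  cv$R[(y0 - 1L):(y1 + 1L), c(x0 - 1L, x1 + 1L)] <- fg[1]
  cv$G[(y0 - 1L):(y1 + 1L), c(x0 - 1L, x1 + 1L)] <- fg[2]
  cv$B[(y0 - 1L):(y1 + 1L), c(x0 - 1L, x1 + 1L)] <- fg[3]
  draw_text(cv, x0 - 2L, y0 - 12L, sprintf("%.3g", rng[2]), fg,
            align = "right")
  draw_text(cv, x0 - 2L, y1 + 4L, sprintf("%.3g", rng[1]), fg,
            align = "right")
  invisible()
}

#' Export one image per parameter row
#'
#' Mirrors batch result export: for every row of the loaded functional
#' parameter table, the row is interpolated onto the surface with the
#' scene's mapping settings and the scene is rendered and written to
#' \code{<out_prefix>_NNN.<format>}. Re-exporting the same inputs produces
#' identical files.
#'
#' @param scene a \code{scene_spec} with a mesh and electrodes.
#' @param params m x n parameter matrix (n = number of electrodes); each row
#'   produces one image.
#' @param out_prefix output path prefix.
#' @param format "png" (default) or "bmp".
#' @param width,height image size in pixels.
#' @return character vector of the m files written.
#' @export
export_images <- function(scene, params, out_prefix,
                          format = c("png", "bmp"), width = 640,
                          height = 480) {
  format <- match.arg(format)
  params <- as.matrix(params)
  if (nrow(params) < 1) stop("params must have at least one row")
  if (is.null(scene$mesh) || is.null(scene$electrodes))
    stop("export_images needs a scene with mesh and electrodes")
  if (ncol(params) != nrow(scene$electrodes))
    stop("params has ", ncol(params), " columns but the montage has ",
         nrow(scene$electrodes), " electrodes")
  mp <- scene$mapping
  out <- character(nrow(params))
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    fld <- if (identical(mp$method, "linear"))
      linear_map(scene$mesh, scene$electrodes, row,
                 radius_mm = if (is.null(mp$radius)) 15 else mp$radius)
    else
      gaussian_map(scene$mesh, scene$electrodes, row,
                   extend_sigma_mm = if (is.null(mp$sigma)) 10 else mp$sigma)
    if (!is.null(mp$range)) fld$range <- mp$range
    sc <- scene
    sc$field <- fld
    img <- render_scene(sc, width, height)
    out[i] <- sprintf("%s_%03d.%s", out_prefix, i, format)
    write_image(img, out[i], format)
  }
  out
}

#' Write a raster image to PNG or BMP
#'
#' @param img height x width x 3 array in [0, 1].
#' @param path output file.
#' @param format "png" or "bmp" (24-bit uncompressed).
#' @return \code{path}, invisibly.
#' @export
write_image <- function(img, path, format = c("png", "bmp")) {
  format <- match.arg(format)
  if (format == "png") png::writePNG(img, path) else write_bmp(img, path)
  invisible(path)
}

write_bmp <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  row_bytes <- w * 3L
  pad <- (4L - row_bytes %% 4L) %% 4L
  data_size <- (row_bytes + pad) * h
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  writeBin(charToRaw("BM"), con)
  u32(54L + data_size); u16(0L); u16(0L); u32(54L)
  u32(40L); u32(w); u32(h); u16(1L); u16(24L); u32(0L); u32(data_size)
  u32(2835L); u32(2835L); u32(0L); u32(0L)
  q <- function(m) as.integer(pmin(255, pmax(0, round(m * 255))))
  padraw <- as.raw(rep(0L, pad))
  for (y in h:1) {
    row <- as.raw(rbind(q(img[y, , 3]), q(img[y, , 2]), q(img[y, , 1])))
    writeBin(c(row, padraw), con)
  }
  invisible(path)
}
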