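normalize3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("camera error: zero-norm vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Perspective camera for the brain view
#'
#' A pinhole perspective camera looking from \code{position} towards
#' \code{focal_point}, with vertical field of view \code{view_angle} degrees
#' and an additional roll of \code{rotation} degrees about the view axis.
#' The view-up vector is re-normalized; the camera distance is derived as
#' \code{||position - focal_point||}. Rotation angles are normalized to
#' [0, 360).
#'
#' @param position camera position, mm (length-3).
#' @param focal_point point the camera looks at, mm (length-3).
#' @param view_up approximate up direction (must not be parallel to the view
#'   axis); normalized to unit length.
#' @param view_angle vertical field of view in degrees, in (0, 180).
#' @param rotation roll about the view axis, degrees.
#' @return object of class \code{bfm_camera} with fields \code{position},
#'   \code{focal_point}, \code{view_up}, \code{view_angle}, \code{distance},
#'   \code{rotation}.
#' @export
camera <- function(position = c(0, 0, 400), focal_point = c(0, 0, 0),
                   view_up = c(0, 1, 0), view_angle = 30, rotation = 0) {
  position <- as.numeric(position)
  focal_point <- as.numeric(focal_point)
  if (length(position) != 3L || length(focal_point) != 3L)
    stop("position and focal_point must be length-3")
  if (!all(is.finite(c(position, focal_point, view_up, view_angle, rotation))))
    stop("camera error: non-finite field")
  if (view_angle <= 0 || view_angle >= 180)
    stop("camera error: view_angle must be in (0, 180) degrees")
  d <- sqrt(sum((position - focal_point)^2))
  if (d == 0) stop("camera error: zero-norm view direction")
  view_up <- normalize3(as.numeric(view_up))
  fwd <- (focal_point - position) / d
  if (abs(sum(fwd * view_up)) > 1 - 1e-9)
    stop("camera error: view_up parallel to the view axis")
  structure(list(position = position, focal_point = focal_point,
                 view_up = view_up, view_angle = as.numeric(view_angle),
                 distance = d,
                 rotation = as.numeric(rotation) %% 360),
            class = "bfm_camera")
}

#' @export
print.bfm_camera <- function(x, ...) {
  cat(sprintf(paste0("camera: position (%.2f, %.2f, %.2f) -> focal ",
                     "(%.2f, %.2f, %.2f)\n"),
              x$position[1], x$position[2], x$position[3],
              x$focal_point[1], x$focal_point[2], x$focal_point[3]))
  cat(sprintf("  view angle %.1f deg, distance %.2f mm, roll %.1f deg\n",
              x$view_angle, x$distance, x$rotation))
  invisible(x)
}

# orthonormal camera basis (right, up, forward) including roll
camera_basis <- function(cam) {
  fwd <- normalize3(cam$focal_point - cam$position)
  right <- normalize3(cross3(fwd, cam$view_up))
  up <- cross3(right, fwd)
  r <- cam$rotation * pi / 180
  if (r != 0) {
    right2 <- cos(r) * right + sin(r) * up
    up2 <- -sin(r) * right + cos(r) * up
    right <- right2; up <- up2
  }
  list(right = right, up = up, forward = fwd)
}

#' Preset camera perspectives
#'
#' Quick views of a mesh from the six anatomical directions, looking at the
#' mesh centroid from a distance scaled to the mesh extent.
#'
#' @param mesh a \code{tri_mesh} the view should frame.
#' @param view one of "left", "right", "anterior", "posterior", "superior",
#'   "inferior" (RAS convention: +x right, +y anterior, +z superior).
#' @param view_angle vertical field of view, degrees.
#' @return a \code{bfm_camera}.
#' @export
camera_preset <- function(mesh, view = c("left", "right", "anterior",
                                         "posterior", "superior", "inferior"),
                          view_angle = 30) {
  view <- match.arg(view)
  ctr <- colMeans(mesh$vertices)
  diag_len <- sqrt(sum((apply(mesh$vertices, 2, max) -
                        apply(mesh$vertices, 2, min))^2))
  d <- 1.4 * diag_len / (2 * tan(view_angle / 2 * pi / 180))
  dir <- switch(view,
                left      = c(-1, 0, 0),
                right     = c(1, 0, 0),
                anterior  = c(0, 1, 0),
                posterior = c(0, -1, 0),
                superior  = c(0, 0, 1),
                inferior  = c(0, 0, -1))
  up <- if (view %in% c("superior", "inferior")) c(0, 1, 0) else c(0, 0, 1)
  camera(position = ctr + dir * d, focal_point = ctr, view_up = up,
         view_angle = view_angle)
}

#' Cast a viewing ray through a viewport pixel
#'
#' Converts a 2D viewport coordinate to the 3D ray that a mouse click at that
#' position would project into the scene, using the pinhole model: the ray
#' starts at the camera position and passes through the pixel on the image
#' plane. Pixel coordinates are continuous with (0, 0) the top-left corner of
#' the viewport, so the viewport center maps exactly to the view axis and the
#' top-center pixel is elevated by exactly half the view angle. Scaling the
#' viewport and the pixel coordinates together leaves the ray unchanged.
#'
#' @param cam a \code{bfm_camera}.
#' @param viewport_wh viewport width and height in pixels (length-2).
#' @param pixel_xy pixel position, x right / y down from top-left (length-2).
#' @return list with \code{origin} (camera position) and unit \code{direction}.
#' @export
cast_ray <- function(cam, viewport_wh, pixel_xy) {
  w <- viewport_wh[1]; h <- viewport_wh[2]
  px <- pixel_xy[1]; py <- pixel_xy[2]
  if (w <= 0 || h <= 0) stop("viewport dimensions must be positive")
  if (px < 0 || px > w || py < 0 || py > h)
    stop("pixel outside the viewport")
  b <- camera_basis(cam)
  tanv <- tan(cam$view_angle / 2 * pi / 180)
  xs <- (px - w / 2) / (h / 2)
  ys <- (h / 2 - py) / (h / 2)
  dir <- b$forward + tanv * (xs * b$right + ys * b$up)
  list(origin = cam$position, direction = normalize3(dir))
}

#' Intersect a ray with a triangle mesh
#'
#' Vectorized Moller-Trumbore intersection over all faces, returning the
#' nearest hit along the ray (smallest positive ray parameter). When a ray
#' grazes an edge shared by two faces at the same parameter, the lowest face
#' index wins, so results are deterministic.
#'
#' @param ray list with \code{origin} and unit \code{direction} (e.g. from
#'   \code{\link{cast_ray}}).
#' @param mesh a \code{tri_mesh}.
#' @param eps tolerance for the ray-parameter and barycentric tests.
#' @return \code{NULL} on a miss, else a list with \code{point} (3D mm),
#'   \code{t} (ray parameter, mm) and \code{face} (face index).
#' @export
intersect_ray <- function(ray, mesh, eps = 1e-9) {
  o <- ray$origin; d <- ray$direction
  v1 <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  dm <- matrix(d, nrow(e2), 3, byrow = TRUE)
  pv <- vec_cross(dm, e2)
  det <- rowSums(e1 * pv)
  tv <- matrix(o, nrow(e1), 3, byrow = TRUE) - v1
  u <- rowSums(tv * pv) / det
  qv <- vec_cross(tv, e1)
  v <- rowSums(dm * qv) / det
  t <- rowSums(e2 * qv) / det
  hit <- abs(det) > 1e-14 & u >= -eps & v >= -eps & (u + v) <= 1 + eps &
    t > eps
  if (!any(hit)) return(NULL)
  idx <- which(hit)
  best <- unname(idx[order(t[idx], idx)][1L])
  list(point = unname(o + t[best] * d), t = unname(t[best]), face = best)
}
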