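default_electrode_style <- function() list(color = c(1, 0, 0), radius = 2)

#' Ordered set of registered electrode contacts
#'
#' An electrode set is an ordered list of contacts; the contact index is its
#' row position, so indices are always contiguous 1..k, also after inserts
#' and removals. Each contact carries a label, a 3D position in mm (same
#' space as the brain model, e.g. MNI or Talairach), an RGB display color in
#' [0, 1] and a ball radius in mm. The default ball style is a red sphere of
#' radius 2 mm.
#'
#' @param positions k x 3 numeric matrix of contact positions (mm); may have
#'   zero rows for an empty set.
#' @param labels character vector of contact labels; defaults to "1".."k".
#' @param colors k x 3 matrix (or single color recycled) of RGB in [0, 1].
#' @param radius numeric vector (or scalar) of ball radii in mm, > 0.
#' @param space coordinate space tag: "MNI", "Talairach" or "native".
#' @return object of class \code{electrode_set}: a data frame with columns
#'   \code{label, x, y, z, r, g, b, radius} and attribute \code{space}.
#' @export
electrode_set <- function(positions = matrix(numeric(0), 0, 3),
                          labels = NULL, colors = NULL, radius = NULL,
                          space = c("native", "MNI", "Talairach")) {
  space <- match.arg(space)
  positions <- matrix(as.numeric(positions), ncol = 3)
  k <- nrow(positions)
  if (k > 0 && !all(is.finite(positions)))
    stop("electrode positions must be finite")
  if (is.null(labels)) labels <- as.character(seq_len(k))
  if (length(labels) != k) stop("labels length must match positions")
  sty <- default_electrode_style()
  if (is.null(colors))
    colors <- matrix(rep(sty$color, each = k), k, 3)
  colors <- matrix(as.numeric(colors), ncol = 3)
  if (nrow(colors) == 1L && k > 1L)
    colors <- colors[rep(1L, k), , drop = FALSE]
  if (k > 0 && (any(colors < 0) || any(colors > 1)))
    stop("electrode colors must be RGB in [0, 1]")
  if (is.null(radius)) radius <- rep(sty$radius, k)
  radius <- rep_len(as.numeric(radius), k)
  if (any(radius <= 0)) stop("electrode radius must be > 0")
  df <- data.frame(label = as.character(labels),
                   x = positions[, 1], y = positions[, 2], z = positions[, 3],
                   r = colors[, 1], g = colors[, 2], b = colors[, 3],
                   radius = radius, stringsAsFactors = FALSE)
  structure(df, space = space, class = c("electrode_set", "data.frame"))
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("electrode_set: %d contact(s), space %s\n",
              nrow(x), attr(x, "space")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Positions of an electrode set as a matrix
#' @param set an \code{electrode_set}.
#' @return k x 3 numeric matrix (mm).
#' @export
electrode_positions <- function(set) {
  unname(as.matrix(as.data.frame(set)[, c("x", "y", "z")]))
}

n_electrodes <- function(set) nrow(set)

rebuild_set <- function(df, space) {
  rownames(df) <- NULL
  structure(df, space = space, class = c("electrode_set", "data.frame"))
}

#' Place a new electrode
#'
#' Adds a contact at \code{point}. By default the contact is appended;
#' \code{insert_after = j} inserts it after contact j (0 prepends), shifting
#' subsequent indices up by one, mirroring an "insert after electrode"
#' control.
#'
#' @param set an \code{electrode_set}.
#' @param point length-3 position in mm (typically a ray-cast surface hit).
#' @param label contact label; defaults to its ordinal after insertion.
#' @param color RGB in [0, 1]; default red.
#' @param radius ball radius in mm; default 2.
#' @param insert_after insert position in [0, k]; \code{NULL} appends.
#' @param relabel if TRUE (default) numeric-looking labels are reset to the
#'   new ordinals after the edit.
#' @return the modified \code{electrode_set}.
#' @export
place_electrode <- function(set, point, label = NULL, color = NULL,
                            radius = NULL, insert_after = NULL,
                            relabel = TRUE) {
  k <- nrow(set)
  if (is.null(insert_after)) insert_after <- k
  if (insert_after < 0 || insert_after > k)
    stop("index error: insert_after must be in [0, ", k, "]")
  sty <- default_electrode_style()
  if (is.null(color)) color <- sty$color
  if (is.null(radius)) radius <- sty$radius
  if (radius <= 0) stop("electrode radius must be > 0")
  if (is.null(label)) label <- as.character(insert_after + 1L)
  new_row <- data.frame(label = as.character(label),
                        x = point[1], y = point[2], z = point[3],
                        r = color[1], g = color[2], b = color[3],
                        radius = radius, stringsAsFactors = FALSE)
  df <- as.data.frame(set)
  df <- rbind(df[seq_len(insert_after), , drop = FALSE], new_row,
              df[seq_len(k) > insert_after, , drop = FALSE])
  if (relabel) {
    auto <- grepl("^[0-9]+$", df$label)
    df$label[auto] <- as.character(seq_len(nrow(df)))[auto]
  }
  rebuild_set(df, attr(set, "space"))
}

#' Remove an electrode
#'
#' Deletes contact \code{index}; remaining contacts close ranks so indices
#' stay contiguous (a second click on a placed electrode cancels it).
#'
#' @param set an \code{electrode_set}.
#' @param index contact ordinal to remove.
#' @param relabel renumber numeric-looking labels after the edit.
#' @return the modified \code{electrode_set}.
#' @export
remove_electrode <- function(set, index, relabel = TRUE) {
  k <- nrow(set)
  if (index < 1 || index > k) stop("index error: no electrode ", index)
  df <- as.data.frame(set)[-index, , drop = FALSE]
  if (relabel) {
    auto <- grepl("^[0-9]+$", df$label)
    df$label[auto] <- as.character(seq_len(nrow(df)))[auto]
  }
  rebuild_set(df, attr(set, "space"))
}

#' Fine-tune an electrode position
#'
#' Moves contact \code{index} by \code{delta_xyz}, quantized to integer
#' multiples of \code{step} per axis (default 0.1 mm, i.e. sub-millimetre
#' tuning). The contact is NOT re-projected onto the surface: tuning may
#' deliberately move it off the mesh, e.g. to compensate for brain
#' deformation after implantation.
#'
#' @param set an \code{electrode_set}.
#' @param index contact ordinal.
#' @param delta_xyz length-3 displacement in mm.
#' @param step tuning step in mm, > 0; each displacement component is rounded
#'   to the nearest multiple of it.
#' @return the modified \code{electrode_set}.
#' @export
tune_electrode <- function(set, index, delta_xyz, step = 0.1) {
  if (step <= 0) stop("domain error: step must be > 0")
  if (index < 1 || index > nrow(set)) stop("index error: no electrode ", index)
  delta <- round(as.numeric(delta_xyz) / step) * step
  df <- as.data.frame(set)
  df[index, c("x", "y", "z")] <- df[index, c("x", "y", "z")] + delta
  rebuild_set(df, attr(set, "space"))
}

#' Register electrodes from viewport clicks
#'
#' The scriptable equivalent of mouse placement: for each viewport pixel a
#' ray is cast through the camera and intersected with the brain surface,
#' and an electrode ball is placed at the first hit.
#'
#' @param mesh a \code{tri_mesh}.
#' @param cam a \code{bfm_camera}.
#' @param viewport_wh viewport size in pixels.
#' @param pixels n x 2 matrix of click positions (or n x 3 with an
#'   insert-after column).
#' @param set existing \code{electrode_set} to extend; empty by default.
#' @param color,radius ball style for the new contacts.
#' @param on_miss "error" (default) or "skip" for rays missing the surface.
#' @return the extended \code{electrode_set}.
#' @export
register_clicks <- function(mesh, cam, viewport_wh, pixels,
                            set = electrode_set(), color = NULL,
                            radius = NULL, on_miss = c("error", "skip")) {
  on_miss <- match.arg(on_miss)
  pixels <- matrix(as.numeric(pixels), ncol = ncol(as.matrix(pixels)))
  for (i in seq_len(nrow(pixels))) {
    ray <- cast_ray(cam, viewport_wh, pixels[i, 1:2])
    hit <- intersect_ray(ray, mesh)
    if (is.null(hit)) {
      if (on_miss == "error")
        stop("click ", i, " misses the brain surface")
      warning("click ", i, " misses the brain surface; skipped")
      next
    }
    ins <- if (ncol(pixels) >= 3 && is.finite(pixels[i, 3]))
      pixels[i, 3] else NULL
    set <- place_electrode(set, hit$point, color = color, radius = radius,
                           insert_after = ins)
  }
  set
}
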