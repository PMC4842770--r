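#' Named colormaps
#'
#' Returns a colormap function mapping values in [0, 1] to RGB in [0, 1].
#' The default map color transition is the diverging blue-to-red map, so
#' red areas mark high values (high activity) and blue areas low values.
#'
#' @param name one of "bluered", "jet", "hot", "gray".
#' @return function(u) taking a numeric vector in [0, 1] (values are
#'   clamped) and returning an n x 3 RGB matrix in [0, 1].
#' @export
cortimap_colormap <- function(name = c("bluered", "jet", "hot", "gray")) {
  name <- match.arg(name)
  anchors <- switch(name,
    bluered = rbind(c(0, 0, 1), c(1, 1, 1), c(1, 0, 0)),
    jet = rbind(c(0, 0, 0.5), c(0, 0, 1), c(0, 1, 1), c(1, 1, 0),
                c(1, 0, 0), c(0.5, 0, 0)),
    hot = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
    gray = rbind(c(0, 0, 0), c(1, 1, 1)))
  n <- nrow(anchors)
  function(u) {
    u <- pmin(1, pmax(0, as.numeric(u)))
    pos <- u * (n - 1)
    i0 <- pmin(floor(pos), n - 2)
    w <- pos - i0
    anchors[i0 + 1, , drop = FALSE] * (1 - w) +
      anchors[i0 + 2, , drop = FALSE] * w
  }
}

# squared Euclidean distances between an n x 3 and an m x 3 point set
dist2_xyz <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}

new_scalar_field <- function(values, covered, range) {
  structure(list(values = values, covered = covered, range = range),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar_field: %d vertices (%d covered), range [%g, %g]\n",
              length(x$values), sum(x$covered), x$range[1], x$range[2]))
  invisible(x)
}

#' Gaussian interpolation of electrode values onto the surface
#'
#' Each mesh vertex receives the Gaussian-weighted mean of the per-electrode
#' values, with weights \code{w_i = exp(-d_i^2 / (2 sigma^2))} and d the 3D
#' Euclidean distance from vertex to contact. The "Gauss Extend" parameter
#' is sigma in mm. Because weights are normalized, the field is a convex
#' combination of the inputs (never outside their min/max), every vertex is
#' covered, and as sigma shrinks the map tends to a nearest-electrode
#' (Voronoi) assignment while for very large sigma it tends to the global
#' mean. Weight normalization is computed relative to the nearest contact,
#' so small sigmas do not underflow.
#'
#' @param mesh a \code{tri_mesh}.
#' @param set an \code{electrode_set} with k >= 1 contacts.
#' @param row_values numeric length-k: one parameter value per contact
#'   (one row of a parameter table).
#' @param extend_sigma_mm Gaussian sigma in mm (> 0), default 10.
#' @return a \code{scalar_field} with all vertices covered and an auto
#'   display range (min/max of \code{row_values}).
#' @export
gaussian_map <- function(mesh, set, row_values, extend_sigma_mm = 10) {
  k <- nrow(set)
  if (k == 0) stop("empty-montage error: no electrodes to interpolate")
  if (length(row_values) != k)
    stop("row_values length ", length(row_values), " != ", k, " electrodes")
  if (!is.finite(extend_sigma_mm) || extend_sigma_mm <= 0)
    stop("domain error: extend_sigma_mm must be > 0")
  d2 <- dist2_xyz(mesh$vertices, electrode_positions(set))
  # subtract the per-vertex minimum distance: normalized weights are
  # invariant to this and it prevents underflow at small sigma
  w <- exp(-(d2 - apply(d2, 1, min)) / (2 * extend_sigma_mm^2))
  vals <- unname(as.vector(w %*% row_values) / rowSums(w))
  new_scalar_field(vals, rep(TRUE, nrow(mesh$vertices)),
                   scale_range(row_values))
}

#' Linear (cone-kernel) interpolation of electrode values
#'
#' Weighted mean with the linear falloff \code{w_i = max(0, 1 - d_i / R)}.
#' Vertices farther than \code{radius_mm} from every contact have zero total
#' weight: they are marked uncovered, get \code{NA} values, and are excluded
#' from the display-range computation. Covered vertices are convex
#' combinations of the contact values.
#'
#' @param mesh a \code{tri_mesh}.
#' @param set an \code{electrode_set} with k >= 1 contacts.
#' @param row_values numeric length-k parameter values.
#' @param radius_mm support radius R in mm (> 0), default 15 (about 1.5x a
#'   typical 10 mm contact spacing).
#' @return a \code{scalar_field}; uncovered vertices are \code{NA}.
#' @export
linear_map <- function(mesh, set, row_values, radius_mm = 15) {
  k <- nrow(set)
  if (k == 0) stop("empty-montage error: no electrodes to interpolate")
  if (length(row_values) != k)
    stop("row_values length ", length(row_values), " != ", k, " electrodes")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("domain error: radius_mm must be > 0")
  d <- sqrt(dist2_xyz(mesh$vertices, electrode_positions(set)))
  w <- 1 - d / radius_mm
  w[w < 0] <- 0
  tot <- unname(rowSums(w))
  covered <- tot > 0
  vals <- rep(NA_real_, nrow(mesh$vertices))
  vals[covered] <- (w[covered, , drop = FALSE] %*% row_values) / tot[covered]
  rng <- if (any(covered)) scale_range(range(vals[covered])) else c(0, 1)
  new_scalar_field(vals, covered, rng)
}

#' Display range for a mapped parameter
#'
#' Auto mode uses the min/max of the plotted electrode values; manual mode
#' uses the supplied pair and downstream color mapping clamps values outside
#' it. A degenerate auto range (constant values) is widened symmetrically by
#' 1e-9 so color mapping stays well defined.
#'
#' @param values numeric values of the plotted row (auto mode).
#' @param mode "auto" or "manual".
#' @param manual_lo,manual_hi manual display bounds, required for manual
#'   mode, with \code{manual_lo < manual_hi}.
#' @return numeric length-2 \code{c(lo, hi)}.
#' @export
scale_range <- function(values, mode = c("auto", "manual"),
                        manual_lo = NULL, manual_hi = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(manual_lo) || is.null(manual_hi))
      stop("manual mode requires manual_lo and manual_hi")
    if (manual_lo >= manual_hi)
      stop("domain error: manual_lo must be < manual_hi")
    return(c(manual_lo, manual_hi))
  }
  r <- range(values, na.rm = TRUE)
  if (r[1] == r[2]) r <- r + c(-1e-9, 1e-9)
  r
}

#' Map values to colors over a display range
#'
#' @param values numeric vector; values outside \code{range} are clamped.
#' @param range length-2 display bounds (lo < hi).
#' @param colormap colormap name (see \code{\link{cortimap_colormap}}) or a
#'   colormap function.
#' @return n x 3 RGB matrix in [0, 1].
#' @export
map_colors <- function(values, range, colormap = "bluered") {
  f <- if (is.function(colormap)) colormap else cortimap_colormap(colormap)
  u <- (values - range[1]) / (range[2] - range[1])
  f(u)
}

#' Recolor electrode balls by a per-node value
#'
#' Replots the electrodes so their ball colors encode a node value (e.g. a
#' parameter row or the summed connection strength), mapped through the
#' active colormap over the display range. Positions, radii and labels are
#' unchanged.
#'
#' @param set an \code{electrode_set}.
#' @param node_values numeric length-k values, one per contact.
#' @param range display bounds; default auto from \code{node_values}.
#' @param colormap colormap name or function.
#' @return the restyled \code{electrode_set}.
#' @export
replot_nodes <- function(set, node_values, range = NULL,
                         colormap = "bluered") {
  if (length(node_values) != nrow(set))
    stop("shape error: node_values length ", length(node_values),
         " != ", nrow(set), " electrodes")
  if (is.null(range)) range <- scale_range(node_values)
  cols <- map_colors(node_values, range, colormap)
  df <- as.data.frame(set)
  df$r <- cols[, 1]; df$g <- cols[, 2]; df$b <- cols[, 3]
  rebuild_set(df, attr(set, "space"))
}
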