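upper_values <- function(C) C[upper.tri(C)]

check_sym <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("correlation matrix must be square")
  asym <- max(abs(C - t(C)))
  if (asym > 1e-6) {
    warning("matrix asymmetry ", signif(asym, 3),
            " exceeds 1e-6; symmetrized as (C + t(C))/2")
    C <- (C + t(C)) / 2
  } else if (asym > 0) C <- (C + t(C)) / 2
  C
}

#' Automatic connection threshold at a target sparsity
#'
#' Picks the threshold tau that keeps the strongest \code{ceiling(sparsity
#' * P)} of the P = n(n-1)/2 possible connections when edges are defined by
#' the strict rule \code{C[i, j] > tau}. tau is the k-th largest
#' off-diagonal value minus a tiny relative nudge so that value itself
#' survives the strict comparison. Tied values at the cutoff are all kept
#' (the realized edge count can then exceed the target; a message reports
#' this).
#'
#' @param C symmetric correlation/synchronization matrix (diagonal ignored).
#' @param sparsity target fraction of possible connections, in (0, 1];
#'   default 0.1.
#' @param use_abs threshold on |C| instead of signed values.
#' @return the threshold tau.
#' @export
auto_threshold <- function(C, sparsity = 0.1, use_abs = FALSE) {
  C <- check_sym(C)
  n <- nrow(C)
  if (n < 2) stop("domain error: need at least 2 channels")
  if (!is.finite(sparsity) || sparsity <= 0 || sparsity > 1)
    stop("domain error: sparsity must be in (0, 1]")
  v <- upper_values(C)
  if (use_abs) v <- abs(v)
  P <- length(v)
  k <- ceiling(sparsity * P)
  vs <- sort(v, decreasing = TRUE)
  vk <- vs[k]
  tau <- vk - max(abs(vk), 1) * 1e-12
  kept <- sum(v > tau)
  if (kept > k)
    message("ties at the cutoff: keeping ", kept,
            " connections for a target of ", k)
  tau
}

#' Threshold a correlation matrix into an edge set
#'
#' Keeps every upper-triangle pair with \code{C[i, j] > tau} (strict, so a
#' display threshold of 0.6 keeps strengths above 0.6, and a threshold at or
#' above the matrix maximum hides all connections). The diagonal is ignored.
#'
#' @param C symmetric correlation/synchronization matrix.
#' @param tau threshold; use \code{\link{auto_threshold}} for sparsity-based
#'   selection or pass a manual value.
#' @param mode "weighted" keeps edge weights for styling; "binary" renders
#'   all surviving edges alike.
#' @param use_abs threshold and weight by |C| (for signed correlations).
#' @return object of class \code{edge_set}: data frame with columns
#'   \code{i, j, weight} (i < j) and attributes \code{threshold},
#'   \code{mode}, \code{n}.
#' @export
threshold_edges <- function(C, tau, mode = c("weighted", "binary"),
                            use_abs = FALSE) {
  mode <- match.arg(mode)
  C <- check_sym(C)
  n <- nrow(C)
  W <- if (use_abs) abs(C) else C
  idx <- which(upper.tri(W) & W > tau, arr.ind = TRUE)
  o <- order(idx[, 1L], idx[, 2L])
  idx <- idx[o, , drop = FALSE]
  df <- data.frame(i = idx[, 1L], j = idx[, 2L],
                   weight = W[idx])
  structure(df, threshold = tau, mode = mode, n = n,
            class = c("edge_set", "data.frame"))
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set: %d edge(s) over %d node(s), threshold %g, %s\n",
              nrow(x), attr(x, "n"), attr(x, "threshold"), attr(x, "mode")))
  invisible(x)
}

#' Summed connection strength per node
#'
#' Node strength is the sum of the weights of all surviving edges incident
#' to the node; isolated nodes score 0. Replotting electrode balls by this
#' score highlights network hubs.
#'
#' @param edge_set an \code{edge_set}.
#' @param n number of nodes; defaults to the matrix size recorded in the
#'   edge set.
#' @return numeric length-n strengths.
#' @export
node_strength <- function(edge_set, n = attr(edge_set, "n")) {
  if (nrow(edge_set) > 0 && max(edge_set$i, edge_set$j) > n)
    stop("index error: edge endpoint exceeds n = ", n)
  s <- numeric(n)
  for (col in c("i", "j")) {
    t <- rowsum(edge_set$weight, edge_set[[col]])
    s[as.integer(rownames(t))] <- s[as.integer(rownames(t))] + t[, 1L]
  }
  s
}

#' Stick colors for a thresholded network
#'
#' Single mode colors every stick alike (binary network); scaled mode maps
#' edge weights through a colormap over a scale that is either automatic
#' (min/max of the surviving edge weights) or manual, with out-of-range
#' weights clamped, so a narrow manual scale highlights the strongest
#' connections.
#'
#' @param edge_set an \code{edge_set}.
#' @param color_mode "single" or "scaled".
#' @param scale_mode "auto" or "manual" (scaled mode only).
#' @param lo,hi manual scale bounds (lo < hi).
#' @param colormap colormap for scaled mode.
#' @param single_color RGB for single mode; default mid gray.
#' @return the edge set with added columns \code{r, g, b} and attribute
#'   \code{scale} (the color scale used, or NULL for single mode).
#' @export
edge_styles <- function(edge_set, color_mode = c("single", "scaled"),
                        scale_mode = c("auto", "manual"), lo = NULL,
                        hi = NULL, colormap = "jet",
                        single_color = c(0.3, 0.3, 0.3)) {
  color_mode <- match.arg(color_mode)
  scale_mode <- match.arg(scale_mode)
  df <- as.data.frame(edge_set)
  scl <- NULL
  if (color_mode == "single" || nrow(df) == 0) {
    df$r <- rep(single_color[1], nrow(df))
    df$g <- rep(single_color[2], nrow(df))
    df$b <- rep(single_color[3], nrow(df))
  } else {
    scl <- if (scale_mode == "manual") {
      if (is.null(lo) || is.null(hi)) stop("manual scale requires lo and hi")
      if (lo >= hi) stop("domain error: lo must be < hi")
      c(lo, hi)
    } else scale_range(df$weight)
    cols <- map_colors(df$weight, scl, colormap)
    df$r <- cols[, 1]; df$g <- cols[, 2]; df$b <- cols[, 3]
  }
  structure(df, threshold = attr(edge_set, "threshold"),
            mode = attr(edge_set, "mode"), n = attr(edge_set, "n"),
            scale = scl, class = c("edge_set", "data.frame"))
}
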