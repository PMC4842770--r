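# Shared fixtures and independent brute-force oracles used across tests.

normalize_dir <- function(v) v / sqrt(sum(v * v))

unit_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  list(vertices = v, faces = f)
}

# independent ray/triangle oracle: plane intersection + barycentric test,
# looping over every face (no shared code with intersect_ray)
brute_force_hit <- function(ray, mesh) {
  best_t <- Inf; best_face <- NA; best_p <- NULL
  o <- ray$origin; d <- ray$direction
  for (f in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[f, 1], ]
    b <- mesh$vertices[mesh$faces[f, 2], ]
    c3 <- mesh$vertices[mesh$faces[f, 3], ]
    n <- c((b - a)[2] * (c3 - a)[3] - (b - a)[3] * (c3 - a)[2],
           (b - a)[3] * (c3 - a)[1] - (b - a)[1] * (c3 - a)[3],
           (b - a)[1] * (c3 - a)[2] - (b - a)[2] * (c3 - a)[1])
    denom <- sum(n * d)
    if (abs(denom) < 1e-14) next
    t <- sum(n * (a - o)) / denom
    if (t <= 1e-9 || t >= best_t) next
    p <- o + t * d
    # barycentric via areas
    area2 <- function(p1, p2, p3) {
      u <- p2 - p1; w <- p3 - p1
      cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
              u[1] * w[2] - u[2] * w[1])
      sqrt(sum(cr^2))
    }
    A <- area2(a, b, c3)
    l1 <- area2(p, b, c3) / A
    l2 <- area2(a, p, c3) / A
    l3 <- area2(a, b, p) / A
    if (abs(l1 + l2 + l3 - 1) < 1e-7) {
      best_t <- t; best_face <- f; best_p <- p
    }
  }
  if (is.infinite(best_t)) NULL else list(point = best_p, t = best_t,
                                          face = best_face)
}

# direct double-loop edge scan (independent of threshold_edges)
brute_force_edges <- function(C, tau) {
  out <- NULL
  n <- nrow(C)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (C[i, j] > tau) out <- rbind(out, c(i, j, C[i, j]))
  out
}

# direct per-vertex weight summation (independent of the matrix algebra in
# gaussian_map / linear_map)
brute_force_field <- function(mesh, pos, values, kernel, param) {
  v <- mesh$vertices
  out <- rep(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    wsum <- 0; vsum <- 0
    for (e in seq_len(nrow(pos))) {
      d <- sqrt(sum((v[i, ] - pos[e, ])^2))
      w <- if (kernel == "gauss") exp(-d^2 / (2 * param^2))
      else max(0, 1 - d / param)
      wsum <- wsum + w
      vsum <- vsum + w * values[e]
    }
    if (wsum > 0) out[i] <- vsum / wsum
  }
  out
}

# exact point-to-triangle distance (Eberly's region classification)
point_tri_dist <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c3; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c3)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c3 - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

point_to_mesh_distance <- function(p, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f)
    point_tri_dist(p, mesh$vertices[mesh$faces[f, 1], ],
                   mesh$vertices[mesh$faces[f, 2], ],
                   mesh$vertices[mesh$faces[f, 3], ]), numeric(1)))
}

expect_file_bytes_equal <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}
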