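# row-wise cross product of two n x 3 matrices
vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

#' Triangle-mesh brain surface
#'
#' Constructs a validated triangle mesh from a vertex coordinate matrix and a
#' face index matrix. Coordinates are interpreted as millimetres in the same
#' space (e.g. MNI or Talairach) that electrode positions will use; no axis
#' flips or unit conversions are applied. Faces are 1-based in R; on-disk
#' formats store them 0-based.
#'
#' Degenerate faces (area below \code{1e-12} mm^2, or faces referencing the
#' same vertex twice) are dropped with a message. Face indices outside
#' \code{[1, V]} are an error.
#'
#' @param vertices numeric matrix, V x 3, vertex coordinates in mm.
#' @param faces integer matrix, F x 3, 1-based vertex indices per triangle.
#' @param drop_degenerate drop zero-area faces instead of erroring.
#' @return an object of class \code{tri_mesh}: a list with elements
#'   \code{vertices} and \code{faces}.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' m <- tri_mesh(v, f)
#' @export
tri_mesh <- function(vertices, faces, drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  if (nrow(vertices) < 4L)
    stop("validation error: a mesh needs at least 4 vertices, got ",
         nrow(vertices))
  if (!all(is.finite(vertices))) stop("vertices contain non-finite values")
  bad <- which(faces < 1L | faces > nrow(vertices), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("validation error: face ", bad[1L, 1L],
         " references vertex index ", faces[bad[1L, , drop = FALSE]],
         " outside [1, ", nrow(vertices), "]")
  dup <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
    faces[, 2L] == faces[, 3L]
  areas <- tri_areas(vertices, faces)
  degen <- dup | areas < 1e-12
  if (any(degen)) {
    if (!drop_degenerate)
      stop("validation error: ", sum(degen), " degenerate face(s)")
    message(sum(degen), " degenerate face(s) dropped")
    faces <- faces[!degen, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

tri_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c <- vertices[faces[, 3L], , drop = FALSE]
  0.5 * row_norms(vec_cross(b - a, c - a))
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Per-face unit normals
#'
#' Right-hand-rule normals from the vertex winding order, unit length.
#'
#' @param mesh a \code{tri_mesh}.
#' @return F x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  n <- vec_cross(b - a, c - a)
  n / row_norms(n)
}

# unique undirected edges as a 2-column matrix (sorted pairs)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for a closed surface of genus 0 (a topological sphere), which is
#' what a single-hemisphere or whole-brain outer surface should be.
#'
#' @param mesh a \code{tri_mesh}.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Is the mesh a closed surface?
#'
#' A mesh is closed when every undirected edge is shared by exactly two faces.
#'
#' @param mesh a \code{tri_mesh}.
#' @return logical.
#' @export
is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

# quadric (4x4) accumulated per vertex from incident face planes
vertex_quadrics <- function(vertices, faces) {
  nv <- nrow(vertices)
  n <- face_normals(list(vertices = vertices, faces = faces))
  d <- -rowSums(n * vertices[faces[, 1L], , drop = FALSE])
  p <- cbind(n, d)                      # F x 4 plane coefficients
  Q <- array(0, c(nv, 4L, 4L))
  for (col in 1:3) {
    idx <- faces[, col]
    for (i in 1:4) for (j in i:4) {
      s <- rowsum(p[, i] * p[, j], idx)
      rows <- as.integer(rownames(s))
      Q[rows, i, j] <- Q[rows, i, j] + s[, 1L]
      if (j > i) Q[rows, j, i] <- Q[rows, i, j]
    }
  }
  Q
}

quadric_cost <- function(Q, v) {
  h <- c(v, 1)
  as.numeric(h %*% Q %*% h)
}

#' Decimate a mesh by quadric edge collapse
#'
#' Reduces the face count to approximately \code{target_fraction} of the
#' input (or to \code{target_faces}) using greedy quadric-error edge
#' collapses. The collapse sequence is deterministic given the input vertex
#' and face order, and does not depend on the target, so a smaller target
#' simply continues the same sequence (face counts are monotone in the
#' target). Designed for closed surfaces; collapses that would break local
#' manifoldness are skipped.
#'
#' @param mesh a \code{tri_mesh}.
#' @param target_fraction fraction of faces to keep, in (0, 1].
#' @param target_faces absolute face-count target (overrides the fraction).
#' @return a validated \code{tri_mesh} with reduced face count.
#' @export
decimate_mesh <- function(mesh, target_fraction = NULL, target_faces = NULL) {
  nf0 <- nrow(mesh$faces)
  if (is.null(target_faces)) {
    if (is.null(target_fraction))
      stop("supply target_fraction or target_faces")
    if (!is.finite(target_fraction) || target_fraction <= 0 ||
        target_fraction > 1)
      stop("domain error: target_fraction must be in (0, 1]")
    if (target_fraction == 1) return(mesh)
    target_faces <- round(target_fraction * nf0)
  }
  if (target_faces >= nf0) return(mesh)
  target_faces <- max(4L, as.integer(target_faces))

  V <- mesh$vertices
  Fm <- mesh$faces
  Q <- vertex_quadrics(V, Fm)
  face_alive <- rep(TRUE, nrow(Fm))
  nf <- nrow(Fm)

  # vertex -> incident faces map, maintained incrementally
  vf <- vector("list", nrow(V))
  for (col in 1:3) {
    sp <- split(seq_len(nrow(Fm)), Fm[, col])
    for (k in names(sp)) {
      ki <- as.integer(k)
      vf[[ki]] <- c(vf[[ki]], sp[[k]])
    }
  }

  edge_key <- function(a, b) pmin(a, b) * (nrow(V) + 1) + pmax(a, b)
  edges <- mesh_edges(mesh)
  cost <- numeric(nrow(edges))
  cand <- matrix(0, nrow(edges), 3L)

  eval_edge <- function(a, b) {
    Qe <- Q[a, , ] + Q[b, , ]
    va <- V[a, ]; vb <- V[b, ]
    cands <- rbind((va + vb) / 2, va, vb)
    costs <- c(quadric_cost(Qe, cands[1L, ]),
               quadric_cost(Qe, cands[2L, ]),
               quadric_cost(Qe, cands[3L, ]))
    k <- which.min(costs)
    list(cost = costs[k], pos = cands[k, ])
  }
  for (e in seq_len(nrow(edges))) {
    ev <- eval_edge(edges[e, 1L], edges[e, 2L])
    cost[e] <- ev$cost
    cand[e, ] <- ev$pos
  }
  edge_alive <- rep(TRUE, nrow(edges))

  neighbours <- function(v) {
    fs <- vf[[v]]
    fs <- fs[face_alive[fs]]
    setdiff(unique(as.vector(Fm[fs, ])), v)
  }

  while (nf > target_faces) {
    live <- which(edge_alive)
    if (length(live) == 0L) break
    o <- live[order(cost[live], edges[live, 1L], edges[live, 2L])]
    collapsed <- FALSE
    for (e in o) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      # link condition: a and b must share exactly two neighbours on a
      # closed manifold; more would pinch the surface
      common <- intersect(neighbours(a), neighbours(b))
      if (length(common) != 2L) { edge_alive[e] <- FALSE; next }
      # collapse b into a
      pos <- cand[e, ]
      fa <- unique(c(vf[[a]], vf[[b]]))
      fa <- fa[face_alive[fa]]
      sub <- Fm[fa, , drop = FALSE]
      sub[sub == b] <- a
      dead <- sub[, 1L] == sub[, 2L] | sub[, 1L] == sub[, 3L] |
        sub[, 2L] == sub[, 3L]
      # geometric guard: reject collapses flipping any surviving normal
      oldV <- V[a, ]
      V[a, ] <- pos
      keep_idx <- fa[!dead]
      ok <- TRUE
      if (length(keep_idx) > 0L) {
        subk <- sub[!dead, , drop = FALSE]
        p1 <- V[subk[, 1L], , drop = FALSE]
        p2 <- V[subk[, 2L], , drop = FALSE]
        p3 <- V[subk[, 3L], , drop = FALSE]
        nn <- vec_cross(p2 - p1, p3 - p1)
        o1 <- mesh$vertices[subk[, 1L], , drop = FALSE]
        o2 <- mesh$vertices[subk[, 2L], , drop = FALSE]
        # compare against pre-collapse geometry of the same faces
        q1 <- Fm[keep_idx, , drop = FALSE]
        r1 <- V; r1[a, ] <- oldV
        pa <- r1[q1[, 1L], , drop = FALSE]
        pb <- r1[q1[, 2L], , drop = FALSE]
        pc <- r1[q1[, 3L], , drop = FALSE]
        no <- vec_cross(pb - pa, pc - pa)
        if (any(rowSums(nn * no) <= 0)) ok <- FALSE
      }
      if (!ok) {
        V[a, ] <- oldV
        edge_alive[e] <- FALSE
        next
      }
      Fm[fa, ] <- sub
      face_alive[fa[dead]] <- FALSE
      nf <- nf - sum(dead)
      Q[a, , ] <- Q[a, , ] + Q[b, , ]
      vf[[a]] <- keep_idx
      vf[[b]] <- integer(0)
      # retire edges touching b, refresh edges touching a
      touching_b <- which(edge_alive & (edges[, 1L] == b | edges[, 2L] == b))
      edge_alive[touching_b] <- FALSE
      nb <- neighbours(a)
      exist <- which(edge_alive & (edges[, 1L] == a | edges[, 2L] == a))
      exist_other <- ifelse(edges[exist, 1L] == a,
                            edges[exist, 2L], edges[exist, 1L])
      for (v2 in nb) {
        hit <- exist[exist_other == v2]
        if (length(hit) >= 1L) {
          ev <- eval_edge(a, v2)
          cost[hit[1L]] <- ev$cost
          cand[hit[1L], ] <- ev$pos
        } else {
          ev <- eval_edge(a, v2)
          edges <- rbind(edges, c(min(a, v2), max(a, v2)))
          cost <- c(cost, ev$cost)
          cand <- rbind(cand, ev$pos)
          edge_alive <- c(edge_alive, TRUE)
        }
      }
      collapsed <- TRUE
      break
    }
    if (!collapsed) break
  }

  keep <- which(face_alive)
  used <- sort(unique(as.vector(Fm[keep, ])))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  f2 <- matrix(remap[Fm[keep, ]], ncol = 3L)
  tri_mesh(V[used, , drop = FALSE], f2)
}
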