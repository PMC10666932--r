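#' Spherical icosahedral cortical meshes
#'
#' A `surface_mesh` is a subdivided icosahedron projected onto a sphere of
#' nominal radius (default 100 mm, the scale of a template cortical sphere),
#' together with a cortex mask marking non-cortical (medial-wall) vertices.
#' Subdivision order `k` yields `10 * 4^k + 2` vertices; order 3 (642
#' vertices) and order 4 (2562) are the usual coarse connectivity-target
#' grids, and order 5 (10,242 per hemisphere, 20,484 for both) is the usual
#' full-resolution cortical model.
#'
#' Vertices follow the coarse-first index convention: the first
#' `10 * 4^(k-1) + 2` vertices of an order-`k` mesh are exactly the vertices
#' of the order-`(k-1)` mesh, so coarser grids are index prefixes of finer
#' ones. All vertex indices in this package are 1-based.
#'
#' @param order Non-negative integer subdivision order (at most 7).
#' @param nominal_radius_mm Positive sphere radius in millimetres.
#' @param hemisphere `"left"` or `"right"`.
#'
#' @return An object of class `surface_mesh` with fields `vertices`
#'   (n x 3 coordinates), `faces` (m x 3 vertex indices), `hemisphere`,
#'   `cortex_mask` (logical per vertex, `FALSE` = medial wall),
#'   `subdivision_order`, and `nominal_radius_mm`.
#' @examples
#' mesh <- build_icosphere(2)
#' n_vertices(mesh)  # 10 * 4^2 + 2 = 162
#' @export
build_icosphere <- function(order, nominal_radius_mm = 100,
                            hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  .assert(length(order) == 1L && is.finite(order) && order == round(order),
          "`order` must be a single integer")
  .assert(order >= 0, "`order` must be >= 0")
  .assert(order <= 7, "`order` must be <= 7 (guard against runaway mesh size)")
  .assert(is.finite(nominal_radius_mm) && nominal_radius_mm > 0,
          "`nominal_radius_mm` must be positive")

  phi <- (1 + sqrt(5)) / 2
  V <- matrix(c(
    -1,  phi, 0,    1,  phi, 0,   -1, -phi, 0,    1, -phi, 0,
     0, -1,  phi,   0,  1,  phi,   0, -1, -phi,   0,  1, -phi,
     phi, 0, -1,    phi, 0,  1,   -phi, 0, -1,   -phi, 0,  1
  ), ncol = 3, byrow = TRUE)
  V <- .project_to_sphere(V, nominal_radius_mm)
  F_ <- matrix(c(
    1, 12, 6,   1, 6, 2,    1, 2, 8,    1, 8, 11,   1, 11, 12,
    2, 6, 10,   6, 12, 5,   12, 11, 3,  11, 8, 7,   8, 2, 9,
    4, 10, 5,   4, 5, 3,    4, 3, 7,    4, 7, 9,    4, 9, 10,
    5, 10, 6,   3, 5, 12,   7, 3, 11,   9, 7, 8,    10, 9, 2
  ), ncol = 3, byrow = TRUE)

  k <- 0
  while (k < order) {
    sub <- .subdivide_once(V, F_, nominal_radius_mm)
    V <- sub$vertices
    F_ <- sub$faces
    k <- k + 1
  }
  storage.mode(F_) <- "integer"

  structure(
    list(
      vertices = V,
      faces = F_,
      hemisphere = hemisphere,
      cortex_mask = rep(TRUE, nrow(V)),
      subdivision_order = as.integer(order),
      nominal_radius_mm = nominal_radius_mm
    ),
    class = "surface_mesh"
  )
}

.project_to_sphere <- function(V, radius) {
  V * (radius / sqrt(rowSums(V^2)))
}

# One round of midpoint subdivision. New midpoints are appended after the
# existing vertices so the coarse-first prefix convention holds.
.subdivide_once <- function(V, F_, radius) {
  edges <- rbind(F_[, c(1, 2)], F_[, c(2, 3)], F_[, c(1, 3)])
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  mid_of <- setNames(seq_len(sum(first)) + nrow(V), key[first])
  mids <- .project_to_sphere((V[lo[first], , drop = FALSE] +
                              V[hi[first], , drop = FALSE]) / 2, radius)
  V2 <- rbind(V, mids)

  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m_ab <- mid_of[ekey(F_[, 1], F_[, 2])]
  m_bc <- mid_of[ekey(F_[, 2], F_[, 3])]
  m_ac <- mid_of[ekey(F_[, 1], F_[, 3])]
  F2 <- rbind(
    cbind(F_[, 1], m_ab, m_ac),
    cbind(F_[, 2], m_bc, m_ab),
    cbind(F_[, 3], m_ac, m_bc),
    cbind(m_ab, m_bc, m_ac)
  )
  dimnames(F2) <- NULL
  list(vertices = V2, faces = F2)
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %s hemisphere, order %d: %d vertices (%d cortical), %d faces, radius %g mm\n",
    x$hemisphere, x$subdivision_order, nrow(x$vertices), sum(x$cortex_mask),
    nrow(x$faces), x$nominal_radius_mm
  ))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh A [surface_mesh][build_icosphere].
#' @return Integer vertex count.
#' @export
n_vertices <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nrow(mesh$vertices)
}

#' Cortical (unmasked) vertex indices of a mesh
#' @inheritParams n_vertices
#' @return Integer vector of 1-based vertex indices with `cortex_mask = TRUE`.
#' @export
cortex_indices <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  which(mesh$cortex_mask)
}

#' Great-circle geodesic distance between mesh vertices
#'
#' Distances are exact great-circle arc lengths on the nominal sphere
#' (`radius * angle` between the unit position vectors), not graph shortest
#' paths: the meshes are spheres by construction, so the closed form is exact.
#'
#' @inheritParams n_vertices
#' @param i,j Vertex indices (1-based); recycled to a common length.
#' @return Numeric distances in millimetres.
#' @examples
#' mesh <- build_icosphere(1)
#' geodesic_distance(mesh, 1, 1)  # 0
#' @export
geodesic_distance <- function(mesh, i, j) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- n_vertices(mesh)
  .assert(all(is.finite(i)) && all(is.finite(j)), "vertex indices must be finite")
  .assert(all(i >= 1 & i <= n) && all(j >= 1 & j <= n),
          "vertex index out of range [1, ", n, "]")
  U <- mesh$vertices / mesh$nominal_radius_mm
  d <- rowSums(U[i, , drop = FALSE] * U[j, , drop = FALSE])
  out <- mesh$nominal_radius_mm * acos(pmin(1, pmax(-1, d)))
  out[i == j] <- 0
  out
}

# Distances (mm) from each of `centers` to every vertex: |centers| x n matrix.
.geodesic_rows <- function(mesh, centers) {
  U <- mesh$vertices / mesh$nominal_radius_mm
  D <- tcrossprod(U[centers, , drop = FALSE], U)
  mesh$nominal_radius_mm * acos(pmin(pmax(D, -1), 1))
}

#' Mask a polar cap of a spherical mesh
#'
#' Marks all vertices within `cap_angle_deg` of `cap_axis` as non-cortical,
#' a synthetic stand-in for the medial wall (real masks are read from file).
#' Idempotent; returns a modified copy.
#'
#' @inheritParams n_vertices
#' @param cap_axis Numeric length-3 direction (normalized internally).
#' @param cap_angle_deg Cap half-angle in degrees, in (0, 90).
#' @return A `surface_mesh` with an updated `cortex_mask`.
#' @export
apply_polar_cap_mask <- function(mesh, cap_axis, cap_angle_deg) {
  stopifnot(inherits(mesh, "surface_mesh"))
  .assert(length(cap_axis) == 3 && all(is.finite(cap_axis)) &&
            sum(cap_axis^2) > 0, "`cap_axis` must be a nonzero 3-vector")
  .assert(is.finite(cap_angle_deg) && cap_angle_deg > 0 && cap_angle_deg < 90,
          "`cap_angle_deg` must lie in (0, 90)")
  axis <- cap_axis / sqrt(sum(cap_axis^2))
  U <- mesh$vertices / mesh$nominal_radius_mm
  ang <- acos(pmin(1, pmax(-1, drop(U %*% axis)))) * 180 / pi
  mesh$cortex_mask <- mesh$cortex_mask & (ang > cap_angle_deg)
  mesh
}

.validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  r <- sqrt(rowSums(mesh$vertices^2))
  .assert(all(abs(r - mesh$nominal_radius_mm) <=
                1e-6 * mesh$nominal_radius_mm),
          "mesh vertices must lie on the nominal sphere")
  n <- n_vertices(mesh)
  .assert(all(mesh$faces >= 1 & mesh$faces <= n), "face indices out of range")
  .assert(all(tabulate(mesh$faces, n) > 0), "every vertex must belong to a face")
  invisible(mesh)
}
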