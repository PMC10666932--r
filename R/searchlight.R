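#' Geodesic searchlights on a spherical mesh
#'
#' A searchlight is the set of cortical vertices within a geodesic radius of
#' a center vertex (closed ball: vertices exactly at the radius are
#' included). Masked (non-cortical) vertices are excluded from membership,
#' and masked centers are dropped with a warning.
#'
#' @inheritParams n_vertices
#' @param centers Integer vertex indices to center searchlights on; defaults
#'   to every cortical vertex.
#' @param radius_mm Positive geodesic radius in millimetres (15 mm is the
#'   canonical alignment/evaluation radius).
#' @return An object of class `searchlight_set`: list with `radius_mm`,
#'   `centers` and `members` (a list of sorted cortical vertex indices, one
#'   per center).
#' @examples
#' mesh <- build_icosphere(2)
#' sl <- build_searchlight_set(mesh, radius_mm = 15)
#' lengths(sl$members)[1:3]
#' @export
build_searchlight_set <- function(mesh, centers = cortex_indices(mesh),
                                  radius_mm) {
  stopifnot(inherits(mesh, "surface_mesh"))
  .assert(is.finite(radius_mm) && radius_mm > 0, "`radius_mm` must be > 0")
  n <- n_vertices(mesh)
  .assert(all(centers >= 1 & centers <= n), "center index out of range")
  centers <- as.integer(centers)
  cortical <- mesh$cortex_mask
  drop <- !cortical[centers]
  if (any(drop)) {
    warning(sprintf("dropping %d masked searchlight center(s)", sum(drop)))
    centers <- centers[!drop]
  }
  members <- vector("list", length(centers))
  if (length(centers)) {
    # chunk the distance computation to bound memory on dense meshes
    chunk <- 512L
    for (start in seq(1L, length(centers), by = chunk)) {
      idx <- start:min(start + chunk - 1L, length(centers))
      D <- .geodesic_rows(mesh, centers[idx])
      for (k in seq_along(idx)) {
        D[k, centers[idx[k]]] <- 0  # self-distance is exactly zero
        members[[idx[k]]] <- which(cortical & D[k, ] <= radius_mm)
      }
    }
  }
  structure(
    list(radius_mm = radius_mm, centers = centers, members = members,
         n_vertices = n, hemisphere = mesh$hemisphere),
    class = "searchlight_set"
  )
}

#' @exportS3Method base::print
print.searchlight_set <- function(x, ...) {
  cat(sprintf(
    "<searchlight_set> %d searchlights, radius %g mm, median size %d\n",
    length(x$centers), x$radius_mm,
    as.integer(stats::median(lengths(x$members)))
  ))
  invisible(x)
}

#' Coarse-to-fine connectivity-target grids
#'
#' Connectivity targets are a coarse subset of the cortical vertices of both
#' hemispheres (left first). In coarse mode the targets of each hemisphere
#' are the first `10 * 4^grid_order + 2` vertices (the coarse-first prefix
#' convention), minus masked vertices; each target's time series is later
#' averaged over an `averaging_radius_mm` searchlight. In `"full"` mode
#' every cortical vertex is its own target and no averaging occurs.
#'
#' Indices in `target_indices` are global both-hemisphere indices: left
#' hemisphere vertices keep their indices, right hemisphere vertices are
#' offset by the left vertex count.
#'
#' @param left_mesh,right_mesh [surface_mesh][build_icosphere] objects for
#'   the two hemispheres.
#' @param grid_order Integer subdivision order of the coarse grid, or the
#'   string `"full"` for vertex-wise targets.
#' @param averaging_radius_mm Averaging searchlight radius in millimetres
#'   (ignored in `"full"` mode).
#' @return An object of class `target_grid`.
#' @export
build_target_grid <- function(left_mesh, right_mesh, grid_order,
                              averaging_radius_mm = NA_real_) {
  stopifnot(inherits(left_mesh, "surface_mesh"),
            inherits(right_mesh, "surface_mesh"))
  nL <- n_vertices(left_mesh)
  full <- identical(grid_order, "full") || identical(grid_order, "FULL")
  if (!full) {
    .assert(length(grid_order) == 1L && is.finite(grid_order) &&
              grid_order == round(grid_order) && grid_order >= 0,
            "`grid_order` must be a non-negative integer or \"full\"")
    .assert(grid_order <= left_mesh$subdivision_order &&
              grid_order <= right_mesh$subdivision_order,
            "`grid_order` exceeds the mesh subdivision order")
    .assert(is.finite(averaging_radius_mm) && averaging_radius_mm > 0,
            "`averaging_radius_mm` must be > 0 in coarse mode")
  }
  pick <- function(mesh, offset) {
    if (full) {
      loc <- cortex_indices(mesh)
    } else {
      n_coarse <- 10L * 4L^grid_order + 2L
      loc <- seq_len(n_coarse)
      loc <- loc[mesh$cortex_mask[loc]]
    }
    list(local = loc, global = loc + offset)
  }
  left <- pick(left_mesh, 0L)
  right <- pick(right_mesh, nL)
  structure(
    list(
      grid_order = if (full) "full" else as.integer(grid_order),
      averaging_radius_mm = if (full) NA_real_ else averaging_radius_mm,
      target_indices = c(left$global, right$global),
      local_indices = list(left = left$local, right = right$local),
      n_left_vertices = nL,
      n_right_vertices = n_vertices(right_mesh)
    ),
    class = "target_grid"
  )
}

#' @exportS3Method base::print
print.target_grid <- function(x, ...) {
  cat(sprintf(
    "<target_grid> order %s: %d targets (%d left, %d right), averaging radius %s mm\n",
    as.character(x$grid_order), length(x$target_indices),
    length(x$local_indices$left), length(x$local_indices$right),
    format(x$averaging_radius_mm)
  ))
  invisible(x)
}

#' Averaging searchlights for a coarse target grid
#'
#' Builds, for each target of a coarse grid, the set of cortical vertices
#' (in global both-hemisphere indices) within the grid's averaging radius of
#' the target center on its own hemisphere. Used by [target_timeseries()].
#'
#' @param grid A [target_grid][build_target_grid].
#' @inheritParams build_target_grid
#' @return A list of integer vectors, one per target (class
#'   `grid_searchlights`); `NULL` for full-resolution grids.
#' @export
grid_averaging_searchlights <- function(grid, left_mesh, right_mesh) {
  stopifnot(inherits(grid, "target_grid"))
  if (identical(grid$grid_order, "full")) return(NULL)
  sl_left <- build_searchlight_set(left_mesh, grid$local_indices$left,
                                   grid$averaging_radius_mm)
  sl_right <- build_searchlight_set(right_mesh, grid$local_indices$right,
                                    grid$averaging_radius_mm)
  members <- c(
    sl_left$members,
    lapply(sl_right$members, function(m) m + grid$n_left_vertices)
  )
  class(members) <- "grid_searchlights"
  members
}
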