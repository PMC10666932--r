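#' Orthogonal Procrustes rotation between two matched point sets
#'
#' Finds the orthogonal matrix `R` (reflections permitted, no scaling)
#' minimizing `||R A - B||_F`, via the singular value decomposition
#' `B t(A) = U S t(V)`, `R = U t(V)`. Rank-deficient cross products are
#' handled by the same formula (the minimum is still attained; the
#' particular solution depends on the SVD's singular-vector choice).
#'
#' @param A,B Numeric matrices of identical dimension `k x m`: rows are the
#'   vertices of one searchlight in the source (`A`) and target (`B`)
#'   subject, columns are shared connectivity targets (CHA) or shared
#'   timepoints (RHA).
#' @return A `k x k` orthogonal matrix.
#' @examples
#' A <- matrix(rnorm(6 * 40), 6)
#' R <- orthogonal_procrustes(A, A)
#' max(abs(R - diag(6))) < 1e-8
#' @export
orthogonal_procrustes <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  .assert(nrow(A) >= 1 && ncol(A) >= 1, "empty input")
  if (!all(dim(A) == dim(B))) {
    .stop_invalid("shape mismatch: A is ", nrow(A), "x", ncol(A),
                  ", B is ", nrow(B), "x", ncol(B))
  }
  .assert(all(is.finite(A)) && all(is.finite(B)), "non-finite input")
  s <- svd(tcrossprod(B, A))
  tcrossprod(s$u, s$v)
}

# Common internal representation for the thing a searchlight transform is
# fitted on: a seeds x columns matrix whose rows are the hemisphere's
# cortical vertices (in increasing vertex order).
.seed_pattern <- function(values, seed_indices, hemisphere, subject_id,
                          n_vertices) {
  structure(
    list(values = values, seed_indices = seed_indices,
         hemisphere = hemisphere, subject_id = subject_id,
         n_vertices = n_vertices),
    class = "seed_pattern"
  )
}

.as_seed_pattern <- function(x) {
  if (inherits(x, "seed_pattern")) return(x)
  if (inherits(x, "connectivity_profile")) {
    nV <- x$target_grid$n_left_vertices
    if (x$hemisphere == "right") nV <- x$target_grid$n_right_vertices
    return(.seed_pattern(x$values, x$seed_indices, x$hemisphere,
                         x$subject_id, nV))
  }
  .stop_invalid("expected a connectivity_profile or seed_pattern")
}

#' Fit and aggregate per-searchlight Procrustes transforms
#'
#' For every searchlight, fits the orthogonal Procrustes rotation taking the
#' source subject's rows (connectivity profiles, or response patterns for
#' RHA) to the target subject's rows, and aggregates the rotations by block
#' summation into one sparse hemisphere-wide transformation matrix. The
#' summed matrix is deliberately not normalized: the per-vertex scale it
#' introduces is absorbed by the z-scoring applied after
#' [apply_transform()], which makes self-alignment exactly
#' correlation-preserving.
#'
#' @param source_profile,target_profile [connectivity_profile()] objects of
#'   the same hemisphere with identical seed sets and column spaces (same
#'   targets, or same timepoints for RHA patterns).
#' @param searchlights A [searchlight_set][build_searchlight_set] at the
#'   alignment radius (canonically 15 mm), with centers at every cortical
#'   vertex.
#' @param method Label recorded on the result, `"CHA"` or `"RHA"`.
#' @param step Iterative-schedule step index recorded on the result.
#' @return An object of class `transformation_matrix`: sparse
#'   `n_vertices x n_vertices` map from the source subject's vertex space
#'   (columns) to the target subject's (rows), with fields
#'   `source_subject`, `target_subject`, `hemisphere`, `method`, `step`,
#'   `alignment_radius_mm`.
#' @export
fit_searchlight_transform <- function(source_profile, target_profile,
                                      searchlights, method = "CHA",
                                      step = 1L) {
  src <- .as_seed_pattern(source_profile)
  tgt <- .as_seed_pattern(target_profile)
  stopifnot(inherits(searchlights, "searchlight_set"))
  .assert(identical(src$seed_indices, tgt$seed_indices),
          "source and target must share the same seed index space")
  .assert(ncol(src$values) == ncol(tgt$values),
          "source and target must share the same column space")
  .assert(src$hemisphere == tgt$hemisphere, "hemisphere mismatch")
  nV <- src$n_vertices

  row_of <- integer(nV)
  row_of[src$seed_indices] <- seq_along(src$seed_indices)

  sizes <- lengths(searchlights$members)
  if (all(sizes == 0)) .stop_invalid("all searchlights are empty")
  if (any(sizes == 0)) {
    warning(sprintf("skipping %d empty searchlight(s)", sum(sizes == 0)))
  }
  keep <- which(sizes > 0)
  total <- sum(sizes[keep]^2)
  ii <- integer(total); jj <- integer(total); xx <- numeric(total)
  pos <- 0L
  for (c_ in keep) {
    S <- searchlights$members[[c_]]
    rows <- row_of[S]
    R_S <- orthogonal_procrustes(src$values[rows, , drop = FALSE],
                                 tgt$values[rows, , drop = FALSE])
    k <- length(S)
    idx <- pos + seq_len(k * k)
    ii[idx] <- rep(S, times = k)
    jj[idx] <- rep(S, each = k)
    xx[idx] <- as.vector(R_S)
    pos <- pos + k * k
  }
  values <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nV, nV))
  structure(
    list(
      source_subject = src$subject_id,
      target_subject = tgt$subject_id,
      hemisphere = src$hemisphere,
      values = values,
      method = method,
      step = as.integer(step),
      alignment_radius_mm = searchlights$radius_mm
    ),
    class = "transformation_matrix"
  )
}

#' @exportS3Method base::print
print.transformation_matrix <- function(x, ...) {
  cat(sprintf(
    "<transformation_matrix> %s -> %s (%s, %s step %d): %d x %d sparse, %d nonzeros\n",
    x$source_subject, x$target_subject, x$hemisphere, x$method, x$step,
    nrow(x$values), ncol(x$values), Matrix::nnzero(x$values)
  ))
  invisible(x)
}

#' Pair of per-hemisphere transformation matrices
#'
#' One step of a subject-pair alignment: the left- and right-hemisphere
#' sparse transforms fitted at the same schedule step.
#'
#' @param left,right [transformation_matrix][fit_searchlight_transform]
#'   objects for the two hemispheres.
#' @return An object of class `transform_step`.
#' @export
transform_step <- function(left, right) {
  stopifnot(inherits(left, "transformation_matrix"),
            inherits(right, "transformation_matrix"))
  .assert(left$hemisphere == "left" && right$hemisphere == "right",
          "transform_step needs a left and a right hemisphere matrix")
  structure(list(left = left, right = right), class = "transform_step")
}

#' Identity (anatomical-alignment) transform step
#'
#' The AA baseline: other subjects' data used on the shared template mesh
#' without any functional transformation.
#'
#' @param n_left,n_right Vertex counts of the two hemisphere meshes.
#' @param source_subject,target_subject Labels.
#' @return A `transform_step` whose matrices are sparse identities.
#' @export
identity_step <- function(n_left, n_right, source_subject = "source",
                          target_subject = "target") {
  mk <- function(n, hemi) {
    structure(
      list(source_subject = source_subject, target_subject = target_subject,
           hemisphere = hemi,
           values = Matrix::Diagonal(n),
           method = "AA", step = 1L, alignment_radius_mm = NA_real_),
      class = "transformation_matrix"
    )
  }
  transform_step(mk(n_left, "left"), mk(n_right, "right"))
}

#' Apply a transform step to a time series
#'
#' Left-multiplies every timepoint's vertex pattern by the hemisphere's
#' transformation matrix (equivalently, right-multiplies the data matrix by
#' its transpose), then re-z-scores each run. The subject id is annotated as
#' `"source->target"`.
#'
#' @param step A [transform_step()] (or single
#'   [transformation_matrix][fit_searchlight_transform] when the time series
#'   covers exactly that hemisphere).
#' @param ts A [time_series()]; z-scored first if it is not already.
#' @return The transformed, re-z-scored `time_series`.
#' @export
apply_transform <- function(step, ts) {
  stopifnot(inherits(ts, "time_series"))
  if (!ts$zscored) ts <- zscore_runs(ts)
  if (inherits(step, "transformation_matrix")) {
    .assert(ncol(ts$data) == ncol(step$values),
            "dimension mismatch: data has ", ncol(ts$data),
            " vertices, transform expects ", ncol(step$values))
    ts$data <- as.matrix(Matrix::tcrossprod(ts$data, step$values))
    tgt <- step$target_subject
  } else {
    stopifnot(inherits(step, "transform_step"))
    nL <- ncol(step$left$values)
    nR <- ncol(step$right$values)
    .assert(ncol(ts$data) == nL + nR,
            "dimension mismatch: data has ", ncol(ts$data),
            " vertices, transforms expect ", nL + nR)
    left <- seq_len(nL)
    ts$data <- cbind(
      as.matrix(Matrix::tcrossprod(ts$data[, left, drop = FALSE],
                                   step$left$values)),
      as.matrix(Matrix::tcrossprod(ts$data[, -left, drop = FALSE],
                                   step$right$values))
    )
    tgt <- step$left$target_subject
  }
  ts$subject_id <- paste0(ts$subject_id, "->", tgt)
  zscore_runs(ts)
}

#' Fit a response-hyperalignment (RHA) transform for one hemisphere
#'
#' Identical to the CHA searchlight fit except that the matrices entering
#' each Procrustes problem are the subjects' time-locked response patterns
#' (vertices in the searchlight x timepoints of the movie) rather than
#' connectivity profiles. Both subjects must therefore have watched the same
#' movie: run counts and per-run timepoint counts must match exactly.
#'
#' @param source_ts,target_ts [time_series()] objects time-locked to the
#'   same stimulus.
#' @inheritParams fit_searchlight_transform
#' @param hemisphere `"left"` or `"right"`.
#' @param mesh The hemisphere's [surface_mesh][build_icosphere].
#' @param n_left_vertices Vertex count of the left mesh (locates the right
#'   hemisphere block; defaults to the mesh's own count for `"left"`).
#' @return A [transformation_matrix][fit_searchlight_transform] with
#'   `method = "RHA"`.
#' @export
fit_rha_transform <- function(source_ts, target_ts, searchlights,
                              hemisphere = c("left", "right"), mesh,
                              n_left_vertices = NULL) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(source_ts, "time_series"),
            inherits(target_ts, "time_series"),
            inherits(mesh, "surface_mesh"))
  if (!identical(source_ts$run_table$n_timepoints,
                 target_ts$run_table$n_timepoints)) {
    .stop_invalid(
      "RHA requires responses to the same movie: run timepoint counts ",
      "differ between subjects (response patterns in a pair must be ",
      "time-locked to an identical stimulus)")
  }
  if (!source_ts$zscored) source_ts <- zscore_runs(source_ts)
  if (!target_ts$zscored) target_ts <- zscore_runs(target_ts)
  seeds <- cortex_indices(mesh)
  offset <- if (hemisphere == "left") 0L else
    (if (is.null(n_left_vertices)) n_vertices(mesh) else n_left_vertices)
  pat <- function(ts) .seed_pattern(
    t(ts$data[, seeds + offset, drop = FALSE]), seeds, hemisphere,
    ts$subject_id, n_vertices(mesh))
  fit_searchlight_transform(pat(source_ts), pat(target_ts), searchlights,
                            method = "RHA", step = 1L)
}
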