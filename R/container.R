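#' Single-file cohort container
#'
#' Persists a cohort bundle (and optionally fitted transform chains and
#' predicted maps) to a single hierarchical container file with a validated
#' schema: groups `mesh` (left/right coordinates, faces, masks),
#' `subjects/<id>` (movie and localizer runs), `design`, `transforms`
#' (sparse triplets per subject pair/hemisphere/step with method and radius
#' attributes), `maps`, and `manifest`. The container round-trips all
#' arrays bitwise.
#'
#' @param bundle A [make_cohort()] bundle.
#' @param path Output file path.
#' @param transforms Optional named list (`"<source>-><target>"`) of
#'   [transform_chain][fit_iterative_cha] objects.
#' @param maps Optional list of `contrast_map` objects.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(bundle, path, transforms = NULL, maps = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  container <- list(
    schema = "chalign-container",
    version = 1L,
    mesh = list(left = bundle$left_mesh, right = bundle$right_mesh),
    subjects = stats::setNames(lapply(bundle$subject_ids, function(id) {
      list(movie = bundle$movies[[id]],
           localizer = bundle$localizers[[id]],
           ground_truth = bundle$subjects[[id]])
    }), bundle$subject_ids),
    design = bundle$design,
    hrf = bundle$hrf,
    template = bundle$template,
    transforms = lapply(transforms, .chain_to_triplets),
    maps = maps,
    manifest = bundle$manifest
  )
  saveRDS(container, path)
  invisible(path)
}

#' @rdname write_cohort
#' @return For `read_cohort()`: a list with elements `bundle`
#'   (`cohort_bundle`), `transforms` (named list of chains or `NULL`) and
#'   `maps`.
#' @export
read_cohort <- function(path) {
  .assert(file.exists(path), "no such container: ", path)
  container <- readRDS(path)
  .validate_container(container)
  ids <- names(container$subjects)
  bundle <- structure(
    list(
      left_mesh = container$mesh$left, right_mesh = container$mesh$right,
      cortex_mask = c(container$mesh$left$cortex_mask,
                      container$mesh$right$cortex_mask),
      template = container$template,
      subjects = lapply(container$subjects, `[[`, "ground_truth"),
      movies = lapply(container$subjects, `[[`, "movie"),
      localizers = lapply(container$subjects, `[[`, "localizer"),
      design = container$design, hrf = container$hrf,
      subject_ids = ids, manifest = container$manifest
    ),
    class = "cohort_bundle"
  )
  list(bundle = bundle,
       transforms = lapply(container$transforms, .chain_from_triplets),
       maps = container$maps)
}

.validate_container <- function(container) {
  .assert(is.list(container) &&
            identical(container$schema, "chalign-container"),
          "container schema violation: not a chalign container")
  for (grp in c("mesh", "subjects", "design", "manifest")) {
    .assert(!is.null(container[[grp]]),
            "container schema violation: missing group '", grp, "'")
  }
  .assert(inherits(container$mesh$left, "surface_mesh") &&
            inherits(container$mesh$right, "surface_mesh"),
          "container schema violation: group 'mesh' must hold two meshes")
  nV <- n_vertices(container$mesh$left) + n_vertices(container$mesh$right)
  for (id in names(container$subjects)) {
    for (m in container$subjects[[id]]$movie) {
      .assert(ncol(m$data) == nV,
              "container schema violation: subjects/", id,
              " vertex count inconsistent with mesh")
    }
  }
  invisible(container)
}

# Sparse transforms are stored as (row, col, value) triplets plus metadata,
# so any schedule prefix can be replayed without refitting.
.chain_to_triplets <- function(chain) {
  stopifnot(inherits(chain, "transform_chain"))
  steps <- lapply(chain$steps, function(st) {
    lapply(st[c("left", "right")], function(M) {
      T_ <- methods::as(M$values, "TsparseMatrix")
      list(row = T_@i + 1L, col = T_@j + 1L, value = T_@x,
           dim = dim(M$values), method = M$method, step = M$step,
           alignment_radius_mm = M$alignment_radius_mm,
           hemisphere = M$hemisphere)
    })
  })
  list(source_subject = chain$source_subject,
       target_subject = chain$target_subject, method = chain$method,
       schedule = chain$schedule, steps = steps)
}

.chain_from_triplets <- function(x) {
  steps <- lapply(x$steps, function(st) {
    ms <- lapply(st, function(tr) {
      structure(
        list(source_subject = x$source_subject,
             target_subject = x$target_subject,
             hemisphere = tr$hemisphere,
             values = Matrix::sparseMatrix(i = tr$row, j = tr$col,
                                           x = tr$value, dims = tr$dim),
             method = tr$method, step = tr$step,
             alignment_radius_mm = tr$alignment_radius_mm),
        class = "transformation_matrix"
      )
    })
    transform_step(ms$left, ms$right)
  })
  structure(
    list(steps = steps, schedule = x$schedule, method = x$method,
         source_subject = x$source_subject,
         target_subject = x$target_subject),
    class = "transform_chain"
  )
}
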