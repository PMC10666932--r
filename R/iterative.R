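#' Coarse-to-fine alignment schedules
#'
#' An alignment schedule lists, for each iterative CHA step, the
#' connectivity-target grid order (or `"full"` for vertex-wise targets), the
#' averaging searchlight radius, and the alignment searchlight radius.
#'
#' @param grid_orders Vector of integer grid orders and/or `"full"`.
#' @param averaging_radii_mm Averaging radii in millimetres (`NA` for
#'   `"full"` steps).
#' @param alignment_radii_mm Alignment searchlight radii; a single value is
#'   recycled (the canonical radius is 15 mm for every step).
#' @return An object of class `alignment_schedule`: a list of per-step specs.
#' @examples
#' default_cha_schedule()  # the canonical six-step schedule
#' @export
cha_schedule <- function(grid_orders, averaging_radii_mm,
                         alignment_radii_mm = 15) {
  .assert(length(grid_orders) >= 1, "a schedule needs at least one step")
  .assert(length(averaging_radii_mm) == length(grid_orders),
          "one averaging radius per step required")
  alignment_radii_mm <- rep_len(alignment_radii_mm, length(grid_orders))
  steps <- lapply(seq_along(grid_orders), function(s) {
    g <- grid_orders[[s]]
    full <- identical(g, "full") || identical(g, "FULL")
    list(
      step = s,
      grid_order = if (full) "full" else as.integer(g),
      averaging_radius_mm = if (full) NA_real_ else
        as.numeric(averaging_radii_mm[[s]]),
      alignment_radius_mm = as.numeric(alignment_radii_mm[[s]])
    )
  })
  structure(steps, class = "alignment_schedule")
}

#' @rdname cha_schedule
#' @details `default_cha_schedule()` is the canonical six-step
#'   coarse-to-fine schedule for full-resolution (order-5) meshes: steps 1-3
#'   use order-3 target grids (642 per hemisphere before masking) with 13 mm
#'   averaging searchlights, steps 4-5 use order-4 grids (2562 per
#'   hemisphere) with 7 mm searchlights, and step 6 uses every cortical
#'   vertex as its own target. Alignment searchlights are 15 mm throughout.
#' @export
default_cha_schedule <- function() {
  cha_schedule(list(3, 3, 3, 4, 4, "full"), c(13, 13, 13, 7, 7, NA))
}

#' @rdname cha_schedule
#' @param mesh_order Subdivision order of the meshes the schedule will run
#'   on.
#' @details `coarse_to_fine_schedule()` builds a desk-scale analogue for
#'   meshes coarser than order 5: one step at `mesh_order - 1`, one at
#'   `mesh_order`, and a final vertex-wise step. Averaging radii follow the
#'   grid spacing (an order-`g` icosphere at nominal radius 100 mm has
#'   ~`13 * 2^(3 - g)` mm edges, which is what ties 13 mm searchlights to
#'   order-3 grids and 7 mm to order-4).
#' @export
coarse_to_fine_schedule <- function(mesh_order) {
  .assert(mesh_order >= 1, "`mesh_order` must be >= 1")
  cha_schedule(
    list(mesh_order - 1L, mesh_order, "full"),
    c(13 * 2^(3 - (mesh_order - 1)), 13 * 2^(3 - mesh_order), NA)
  )
}

#' @exportS3Method base::print
print.alignment_schedule <- function(x, ...) {
  cat(sprintf("<alignment_schedule> %d step(s)\n", length(x)))
  for (s in x) {
    cat(sprintf(
      "  step %d: grid order %s, averaging %s mm, alignment %g mm\n",
      s$step, as.character(s$grid_order), format(s$averaging_radius_mm),
      s$alignment_radius_mm
    ))
  }
  invisible(x)
}

# Per-step geometry (grid, averaging searchlights, alignment searchlights),
# cached across steps that share parameters.
.schedule_geometry <- function(schedule, left_mesh, right_mesh) {
  grids <- list(); aligns <- list()
  lapply(schedule, function(s) {
    gkey <- paste(s$grid_order, s$averaging_radius_mm)
    if (is.null(grids[[gkey]])) {
      grid <- build_target_grid(left_mesh, right_mesh, s$grid_order,
                                s$averaging_radius_mm)
      grids[[gkey]] <<- list(
        grid = grid,
        searchlights = grid_averaging_searchlights(grid, left_mesh,
                                                   right_mesh)
      )
    }
    akey <- format(s$alignment_radius_mm)
    if (is.null(aligns[[akey]])) {
      aligns[[akey]] <<- list(
        left = build_searchlight_set(left_mesh,
                                     radius_mm = s$alignment_radius_mm),
        right = build_searchlight_set(right_mesh,
                                      radius_mm = s$alignment_radius_mm)
      )
    }
    c(grids[[gkey]], list(alignment = aligns[[akey]]))
  })
}

# Multi-source iterative CHA core: fits chains from each source movie to one
# fixed target movie, recomputing the target profiles only once per step.
.iterative_cha_multi <- function(sources, target_movie, schedule,
                                 left_mesh, right_mesh) {
  stopifnot(inherits(schedule, "alignment_schedule"))
  target_movie <- if (target_movie$zscored) target_movie else
    zscore_runs(target_movie)
  W <- lapply(sources, function(ts) if (ts$zscored) ts else zscore_runs(ts))
  chains <- lapply(sources, function(ts) list())
  geom <- .schedule_geometry(schedule, left_mesh, right_mesh)

  for (s in seq_along(schedule)) {
    st <- schedule[[s]]
    g <- geom[[s]]
    prof_tgt <- list(
      left = connectivity_profile(target_movie, g$grid, g$searchlights,
                                  "left", left_mesh),
      right = connectivity_profile(target_movie, g$grid, g$searchlights,
                                   "right", right_mesh)
    )
    for (nm in names(W)) {
      step_obj <- tryCatch({
        M_L <- fit_searchlight_transform(
          connectivity_profile(W[[nm]], g$grid, g$searchlights, "left",
                               left_mesh),
          prof_tgt$left, g$alignment$left, method = "CHA", step = st$step)
        M_R <- fit_searchlight_transform(
          connectivity_profile(W[[nm]], g$grid, g$searchlights, "right",
                               right_mesh),
          prof_tgt$right, g$alignment$right, method = "CHA", step = st$step)
        # the chain keeps the original source label, not the running one
        M_L$source_subject <- sources[[nm]]$subject_id
        M_R$source_subject <- sources[[nm]]$subject_id
        transform_step(M_L, M_R)
      }, error = function(e) {
        stop("iterative CHA failed at step ", st$step, ": ",
             conditionMessage(e), call. = FALSE)
      })
      chains[[nm]] <- c(chains[[nm]], list(step_obj))
      W[[nm]] <- apply_transform(step_obj, W[[nm]])
    }
  }
  lapply(chains, function(steps) {
    structure(
      list(
        steps = steps, schedule = schedule, method = "CHA",
        source_subject = steps[[1]]$left$source_subject,
        target_subject = steps[[1]]$left$target_subject
      ),
      class = "transform_chain"
    )
  })
}

#' Iterative coarse-to-fine connectivity hyperalignment
#'
#' Runs the iterative CHA procedure for one ordered subject pair. Step 1 is
#' plain searchlight CHA on the untransformed source movie; the fitted
#' transforms are applied to the working copy of the source movie, which is
#' used in the next step to compute new connectivity profiles against
#' progressively denser target grids. The target subject's own movie is
#' never transformed; transforms are pairwise and directional (no common
#' model space). The two movies may be different stimuli of different
#' lengths (cross-movie CHA).
#'
#' @param source_movie,target_movie [time_series()] movie data of the source
#'   and target subject.
#' @param schedule An [alignment_schedule][cha_schedule].
#' @param left_mesh,right_mesh The template hemisphere meshes.
#' @return An object of class `transform_chain`: fields `steps` (list of
#'   [transform_step()], step 1 first), `schedule`, `method`,
#'   `source_subject`, `target_subject`.
#' @export
fit_iterative_cha <- function(source_movie, target_movie, schedule,
                              left_mesh, right_mesh) {
  .assert(nrow(source_movie$data) >= 3 && nrow(target_movie$data) >= 3,
          "movies need at least 3 timepoints")
  src <- stats::setNames(list(source_movie), source_movie$subject_id)
  .iterative_cha_multi(src, target_movie, schedule, left_mesh,
                       right_mesh)[[1]]
}

#' @exportS3Method base::print
print.transform_chain <- function(x, ...) {
  cat(sprintf(
    "<transform_chain> %s -> %s (%s): %d step(s)\n",
    x$source_subject, x$target_subject, x$method, length(x$steps)
  ))
  invisible(x)
}

#' Apply a transform chain to a time series
#'
#' Sequentially applies each step's transforms with run-wise z-scoring
#' between steps (the canonical composition; the interleaved z-scoring is
#' why a chain is not a single matrix product).
#'
#' @param chain A [transform_chain][fit_iterative_cha], or a single
#'   [transform_step()].
#' @param ts A [time_series()].
#' @param n_steps Apply only the first `n_steps` steps (a schedule prefix);
#'   default all.
#' @return The transformed `time_series`.
#' @export
apply_chain <- function(chain, ts, n_steps = NULL) {
  if (inherits(chain, "transform_step")) {
    return(apply_transform(chain, ts))
  }
  stopifnot(inherits(chain, "transform_chain"))
  steps <- chain$steps
  if (!is.null(n_steps)) steps <- steps[seq_len(n_steps)]
  if (length(steps) == 0) {
    warning("empty transform chain: returning z-scored input unchanged")
    return(if (ts$zscored) ts else zscore_runs(ts))
  }
  for (st in steps) ts <- apply_transform(st, ts)
  ts
}

#' Collapse a chain into a single matrix product (approximate)
#'
#' Multiplies the per-step sparse matrices `M_S ... M_1` for each
#' hemisphere. This is provided for inspection only: because the canonical
#' composition re-z-scores the data between steps, applying the collapsed
#' product is only an approximation of [apply_chain()].
#'
#' @inheritParams apply_chain
#' @return A list with sparse matrices `left` and `right`.
#' @export
collapse_chain <- function(chain) {
  stopifnot(inherits(chain, "transform_chain"))
  .assert(length(chain$steps) > 0, "empty chain")
  acc <- function(hemi) {
    Reduce(function(M, st) st[[hemi]]$values %*% M,
           chain$steps[-1], init = chain$steps[[1]][[hemi]]$values)
  }
  list(left = acc("left"), right = acc("right"))
}

#' Single-step identity (AA) chain
#'
#' @inheritParams identity_step
#' @return A `transform_chain` of one [identity_step()].
#' @export
identity_chain <- function(n_left, n_right, source_subject = "source",
                           target_subject = "target") {
  structure(
    list(
      steps = list(identity_step(n_left, n_right, source_subject,
                                 target_subject)),
      schedule = NULL, method = "AA",
      source_subject = source_subject, target_subject = target_subject
    ),
    class = "transform_chain"
  )
}
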