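#' Single-step schedule matching a cohort's mesh resolution
#'
#' The plain (step-1) CHA configuration for a desk-scale cohort: one step
#' whose target grid is the mesh's own order with 13 mm averaging
#' searchlights and 15 mm alignment searchlights (the canonical radii for
#' an order-3 grid at nominal radius 100 mm).
#'
#' @param cohort A [make_cohort()] bundle.
#' @return An [alignment_schedule][cha_schedule] of one step.
#' @export
cohort_step1_schedule <- function(cohort) {
  cha_schedule(list(cohort$manifest$params$mesh_order), 13)
}

#' Fit alignment chains from every other subject to one target
#'
#' Fits, for each source subject, the transform chain projecting that
#' subject's data into the target subject's cortical space. CHA chains use
#' the iterative schedule on the movie data (`source_movie` for sources,
#' `target_movie` for the target — different ids give cross-movie CHA);
#' RHA requires the same movie for both and is single-step; AA returns
#' identity chains.
#'
#' @param cohort A [make_cohort()] bundle.
#' @param target_id Target subject id.
#' @param method `"cha"`, `"rha"`, or `"aa"`.
#' @param schedule [alignment_schedule][cha_schedule] for CHA; defaults to
#'   [cohort_step1_schedule()].
#' @param source_movie,target_movie Movie ids used for the source and
#'   target connectomes.
#' @param source_ids Source subjects; default all except the target.
#' @return Named list of [transform_chain][fit_iterative_cha] objects.
#' @export
fit_chains_to_target <- function(cohort, target_id,
                                 method = c("cha", "rha", "aa"),
                                 schedule = NULL, source_movie = "A",
                                 target_movie = "A",
                                 source_ids = setdiff(cohort$subject_ids,
                                                      target_id)) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort_bundle"))
  .assert(target_id %in% cohort$subject_ids, "unknown target subject")
  .assert(length(source_ids) >= 1, "empty source set")
  nL <- n_vertices(cohort$left_mesh)
  nR <- n_vertices(cohort$right_mesh)

  if (method == "aa") {
    return(stats::setNames(lapply(source_ids, function(s) {
      identity_chain(nL, nR, s, target_id)
    }), source_ids))
  }
  if (method == "rha") {
    if (!identical(source_movie, target_movie)) {
      .stop_invalid(
        "RHA requires the same movie for source and target subjects ",
        "(response patterns must be time-locked to an identical stimulus)")
    }
    sl <- list(
      left = build_searchlight_set(cohort$left_mesh, radius_mm = 15),
      right = build_searchlight_set(cohort$right_mesh, radius_mm = 15)
    )
    tgt <- zscore_runs(cohort$movies[[target_id]][[target_movie]])
    return(stats::setNames(lapply(source_ids, function(s) {
      src <- zscore_runs(cohort$movies[[s]][[source_movie]])
      st <- transform_step(
        fit_rha_transform(src, tgt, sl$left, "left", cohort$left_mesh,
                          n_left_vertices = nL),
        fit_rha_transform(src, tgt, sl$right, "right", cohort$right_mesh,
                          n_left_vertices = nL)
      )
      structure(list(steps = list(st), schedule = NULL, method = "RHA",
                     source_subject = s, target_subject = target_id),
                class = "transform_chain")
    }), source_ids))
  }
  if (is.null(schedule)) schedule <- cohort_step1_schedule(cohort)
  sources <- stats::setNames(
    lapply(source_ids, function(s) cohort$movies[[s]][[source_movie]]),
    source_ids)
  .iterative_cha_multi(sources, cohort$movies[[target_id]][[target_movie]],
                       schedule, cohort$left_mesh, cohort$right_mesh)
}

#' Score predictions against own-localizer topographies
#'
#' For each target subject: computes the own-localizer topography per
#' category, the topography predicted from the other subjects through the
#' supplied chains, the whole-map Pearson correlation between them, and the
#' Cronbach's alpha of the own maps across runs (the noise-ceiling
#' estimate).
#'
#' @param cohort A [make_cohort()] bundle.
#' @param chains_by_target Named list: for each target id, the named list
#'   of chains from [fit_chains_to_target()].
#' @param method Label recorded in the output records.
#' @param categories Categories to score; default all.
#' @param mode Prediction mode passed to [predicted_topography()].
#' @param n_steps Optional schedule prefix.
#' @return A tibble with columns `subject_id`, `category`, `method`,
#'   `map_r`, `alpha`.
#' @export
score_predictions <- function(cohort, chains_by_target, method = "CHA",
                              categories = cohort$template$categories,
                              mode = "timeseries", n_steps = NULL) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  mask <- cohort$cortex_mask
  out <- lapply(names(chains_by_target), function(tid) {
    own <- own_topography(cohort$localizers[[tid]], cohort$design,
                          cohort$hrf, categories, cortex_mask = mask)
    run_maps <- lapply(seq_along(cohort$localizers[[tid]]), function(r) {
      X <- build_design_matrix(cohort$design, r, cohort$hrf, 2L)
      fit_contrast_tmap(cohort$localizers[[tid]][[r]], X, categories, mask)
    })
    pred <- predicted_topography(cohort$localizers,
                                 chains_by_target[[tid]], cohort$design,
                                 cohort$hrf, categories, mask, mode = mode,
                                 n_steps = n_steps)
    if (length(categories) == 1L) {
      own <- stats::setNames(list(own), categories)
      pred <- stats::setNames(list(pred), categories)
      run_maps <- lapply(run_maps, function(m)
        stats::setNames(list(m), categories))
    }
    dplyr::bind_rows(lapply(categories, function(cat_) {
      tibble::tibble(
        subject_id = tid, category = cat_, method = method,
        map_r = map_pearson(own[[cat_]], pred[[cat_]]),
        alpha = cronbach_alpha(lapply(run_maps, `[[`, cat_))
      )
    }))
  })
  dplyr::bind_rows(out)
}
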