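#' Seed x target connectivity profiles
#'
#' The representation CHA aligns: for every cortical vertex (seed) of one
#' hemisphere, its Pearson correlations with the whole-brain connectivity
#' targets, computed over the run-wise z-scored, concatenated time series.
#' After the correlation step each seed's row is normalized to zero mean and
#' unit variance (population convention); degenerate (constant) seeds or
#' targets yield correlation 0 with a warning.
#'
#' @param ts A [time_series()] (z-scored internally if needed).
#' @param grid A [target_grid][build_target_grid].
#' @param searchlights Averaging searchlights from
#'   [grid_averaging_searchlights()]; `NULL` for full grids.
#' @param hemisphere `"left"` or `"right"`: which hemisphere's cortical
#'   vertices serve as seeds.
#' @param mesh The [surface_mesh][build_icosphere] of the seed hemisphere
#'   (supplies the cortex mask).
#' @param normalize If `FALSE`, skip the row normalization (used by tests
#'   and by connectome-similarity analyses).
#' @return An object of class `connectivity_profile` with fields
#'   `subject_id`, `condition_id`, `hemisphere`, `seed_indices` (hemisphere-
#'   local cortical vertex indices), `target_grid`, `values`
#'   (seeds x targets), `normalized`, and `degenerate_seeds`.
#' @export
connectivity_profile <- function(ts, grid, searchlights = NULL,
                                 hemisphere = c("left", "right"),
                                 mesh, normalize = TRUE) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(ts, "time_series"), inherits(grid, "target_grid"),
            inherits(mesh, "surface_mesh"))
  .assert(nrow(ts$data) >= 3, "need at least 3 total timepoints")
  if (!ts$zscored) ts <- zscore_runs(ts)

  seeds_local <- cortex_indices(mesh)
  .assert(length(seeds_local) > 0, "empty seed set: no cortical vertices")
  offset <- if (hemisphere == "left") 0L else grid$n_left_vertices
  seeds_global <- seeds_local + offset

  Tn <- nrow(ts$data)
  S <- ts$data[, seeds_global, drop = FALSE]
  Tg <- target_timeseries(ts, grid, searchlights)
  # Run-wise z-scored data have zero mean per run, hence overall, and unit
  # pooled variance; targets are averages of such columns (zero mean) and
  # only need rescaling. Correlation over the concatenation is then a plain
  # cross product / n.
  sS <- sqrt(colMeans(S^2))
  sT <- sqrt(colMeans(Tg^2))
  degen_seed <- sS <= 1e-12
  degen_target <- sT <= 1e-12
  if (any(degen_seed) || any(degen_target)) {
    warning(sprintf(
      "degenerate (constant) columns: %d seed(s), %d target(s); correlations set to 0",
      sum(degen_seed), sum(degen_target)))
  }
  sS[degen_seed] <- 1
  sT[degen_target] <- 1
  C <- crossprod(sweep(S, 2L, sS, "/"), sweep(Tg, 2L, sT, "/")) / Tn
  C[degen_seed, ] <- 0
  C[, degen_target] <- 0
  C <- pmin(pmax(C, -1), 1)

  degen_row <- degen_seed
  if (normalize) {
    Zt <- .zscore_cols(t(C))
    degen_row <- degen_row | attr(Zt, "degenerate")
    C <- t(Zt)
  }
  structure(
    list(
      subject_id = ts$subject_id,
      condition_id = ts$condition_id,
      hemisphere = hemisphere,
      seed_indices = seeds_local,
      target_grid = grid,
      values = C,
      normalized = normalize,
      degenerate_seeds = unname(degen_row)
    ),
    class = "connectivity_profile"
  )
}

#' @exportS3Method base::print
print.connectivity_profile <- function(x, ...) {
  cat(sprintf(
    "<connectivity_profile> %s / %s (%s): %d seeds x %d targets%s\n",
    x$subject_id, x$condition_id, x$hemisphere,
    nrow(x$values), ncol(x$values),
    if (x$normalized) ", row-normalized" else ""
  ))
  invisible(x)
}
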