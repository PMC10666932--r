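#' Multi-run cortical surface time series
#'
#' Container for one subject's data under one condition (a movie or a
#' localizer run set): a timepoints x vertices matrix with both hemispheres
#' concatenated (left first) and a run table recording run boundaries.
#'
#' @param data Numeric matrix, total timepoints x total vertices; all values
#'   finite.
#' @param run_table Data frame with columns `run_id` and `n_timepoints`
#'   whose `n_timepoints` sum to `nrow(data)`.
#' @param subject_id,condition_id Labels.
#' @param tr_s Repetition time in seconds.
#' @return An object of class `time_series` with fields `data`, `run_table`,
#'   `subject_id`, `condition_id`, `tr_s`, `zscored`, and `degenerate`
#'   (logical per vertex, set by [zscore_runs()]).
#' @export
time_series <- function(data, run_table, subject_id = "subject",
                        condition_id = "condition", tr_s = 1) {
  data <- as.matrix(data)
  .assert(all(is.finite(data)), "time series data must be finite")
  .assert(is.data.frame(run_table) &&
            all(c("run_id", "n_timepoints") %in% names(run_table)),
          "`run_table` needs columns run_id and n_timepoints")
  .assert(sum(run_table$n_timepoints) == nrow(data),
          "run_table timepoints (", sum(run_table$n_timepoints),
          ") must sum to nrow(data) (", nrow(data), ")")
  run_table$n_timepoints <- as.integer(run_table$n_timepoints)
  structure(
    list(
      subject_id = subject_id,
      condition_id = condition_id,
      run_table = run_table,
      data = data,
      tr_s = tr_s,
      zscored = FALSE,
      degenerate = rep(FALSE, ncol(data))
    ),
    class = "time_series"
  )
}

#' @exportS3Method base::print
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %s / %s: %d timepoints in %d run(s) x %d vertices (TR %g s%s)\n",
    x$subject_id, x$condition_id, nrow(x$data), nrow(x$run_table),
    ncol(x$data), x$tr_s, if (x$zscored) ", z-scored" else ""
  ))
  invisible(x)
}

# Row indices of one run.
.run_rows <- function(ts, k) {
  ends <- cumsum(ts$run_table$n_timepoints)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  starts[k]:ends[k]
}

#' Z-score each run of a time series
#'
#' Standardizes every vertex's time course to mean 0 and unit variance
#' (population convention, divisor n) within each run independently.
#' Constant time courses map to all-zeros and are flagged in the
#' `degenerate` field. Idempotent on already-standardized input.
#'
#' @param ts A [time_series()].
#' @return A z-scored `time_series` with `zscored = TRUE`.
#' @export
zscore_runs <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  .assert(all(ts$run_table$n_timepoints >= 2),
          "every run needs at least 2 timepoints to z-score")
  degen <- rep(FALSE, ncol(ts$data))
  for (k in seq_len(nrow(ts$run_table))) {
    rows <- .run_rows(ts, k)
    Z <- .zscore_cols(ts$data[rows, , drop = FALSE])
    degen <- degen | attr(Z, "degenerate")
    ts$data[rows, ] <- Z
  }
  ts$degenerate <- ts$degenerate | degen
  ts$zscored <- TRUE
  ts
}

#' Searchlight-averaged connectivity-target time courses
#'
#' For a coarse grid, column `j` of the result is the unweighted mean over
#' the member vertices of target `j`'s averaging searchlight; the mean time
#' series is assigned to the target center. For a `"full"` grid, column `j`
#' is vertex `j`'s own time course.
#'
#' @param ts A [time_series()] covering the grid's meshes.
#' @param grid A [target_grid][build_target_grid].
#' @param searchlights Averaging searchlights from
#'   [grid_averaging_searchlights()] (ignored for full grids).
#' @return Numeric matrix, timepoints x targets.
#' @export
target_timeseries <- function(ts, grid, searchlights = NULL) {
  stopifnot(inherits(ts, "time_series"), inherits(grid, "target_grid"))
  nV <- grid$n_left_vertices + grid$n_right_vertices
  .assert(ncol(ts$data) == nV, "time series has ", ncol(ts$data),
          " vertices but the grid's meshes have ", nV)
  if (identical(grid$grid_order, "full")) {
    return(ts$data[, grid$target_indices, drop = FALSE])
  }
  .assert(!is.null(searchlights) &&
            length(searchlights) == length(grid$target_indices),
          "`searchlights` must supply one member set per target")
  sizes <- lengths(searchlights)
  if (any(sizes == 0)) {
    .stop_invalid("target(s) with zero cortical members: global index ",
                  paste(grid$target_indices[sizes == 0], collapse = ", "))
  }
  out <- matrix(0, nrow(ts$data), length(searchlights))
  for (j in seq_along(searchlights)) {
    m <- searchlights[[j]]
    out[, j] <- if (length(m) == 1L) ts$data[, m] else
      rowMeans(ts$data[, m, drop = FALSE])
  }
  out
}
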