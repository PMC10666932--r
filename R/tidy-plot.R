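#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a transform chain into one row per step and hemisphere
#'
#' @param x A [transform_chain][fit_iterative_cha].
#' @param ... Unused.
#' @return A tibble with step, hemisphere, grid order, radii and sparsity.
#' @export
tidy.transform_chain <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$steps), function(s) {
    st <- x$steps[[s]]
    sched <- if (!is.null(x$schedule)) x$schedule[[s]] else NULL
    dplyr::bind_rows(lapply(c("left", "right"), function(h) {
      M <- st[[h]]
      tibble::tibble(
        step = s, hemisphere = h, method = M$method,
        grid_order = if (!is.null(sched)) as.character(sched$grid_order)
          else NA_character_,
        alignment_radius_mm = M$alignment_radius_mm,
        n_vertices = nrow(M$values),
        nnz = Matrix::nnzero(M$values)
      )
    }))
  }))
}

#' @rdname tidy.transform_chain
#' @export
glance.transform_chain <- function(x, ...) {
  tibble::tibble(
    source_subject = x$source_subject, target_subject = x$target_subject,
    method = x$method, n_steps = length(x$steps)
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-subject records; `glance()` the method-level
#' means.
#'
#' @param x An [evaluation_report()].
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$records

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  x$records |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_r = mean(.data$map_r),
                     mean_alpha = mean(.data$alpha), .groups = "drop")
}

# Lambert azimuthal-ish flat coordinates for plotting one hemisphere.
.flatten_hemisphere <- function(mesh) {
  U <- mesh$vertices / mesh$nominal_radius_mm
  tibble::tibble(
    x = atan2(U[, 2], U[, 3]),
    y = asin(pmin(1, pmax(-1, U[, 1]))),
    cortical = mesh$cortex_mask
  )
}

#' Plot a per-vertex map on the flattened sphere
#'
#' Quick-look scatter rendering of a contrast map (or any per-vertex
#' vector) with one panel per hemisphere, masked vertices omitted.
#'
#' @param map A `contrast_map` or numeric vector over both hemispheres.
#' @param left_mesh,right_mesh The hemisphere meshes.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_contrast_map <- function(map, left_mesh, right_mesh, title = NULL) {
  v <- .map_values(map)
  df <- dplyr::bind_rows(
    dplyr::mutate(.flatten_hemisphere(left_mesh), hemisphere = "left",
                  value = v[seq_len(n_vertices(left_mesh))]),
    dplyr::mutate(.flatten_hemisphere(right_mesh), hemisphere = "right",
                  value = v[-seq_len(n_vertices(left_mesh))])
  )
  if (is.null(title) && inherits(map, "contrast_map")) {
    title <- sprintf("%s: %s (%s)", map$subject_id, map$category,
                     map$provenance)
  }
  ggplot2::ggplot(dplyr::filter(df, .data$cortical),
                  ggplot2::aes(.data$x, .data$y, colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey95",
                                    high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, colour = "t") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of an evaluation report
#'
#' Mean prediction correlation per method and category with standard-error
#' bars, plus the mean Cronbach's alpha (noise ceiling) as a black tick.
#'
#' @param object An [evaluation_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  s <- object$summary
  p <- ggplot2::ggplot(
    s, ggplot2::aes(.data$category, .data$mean_r, fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r - .data$se_r,
                   ymax = .data$mean_r + .data$se_r),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "map correlation (r)", fill = NULL) +
    ggplot2::theme_minimal()
  if (any(is.finite(s$mean_alpha))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_alpha, ymax = .data$mean_alpha),
      colour = "black", width = 0.8, linewidth = 0.4)
  }
  p
}

#' Histogram of a searchlight statistic map
#'
#' @param object A [searchlight_statistic_map()] /
#'   [connectome_similarity_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.searchlight_map <- function(object, ...) {
  df <- tibble::tibble(value = object$values[is.finite(object$values)])
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "#2166ac") +
    ggplot2::labs(x = object$kind,
                  y = "searchlights",
                  title = sprintf("%s (radius %g mm)", object$kind,
                                  object$radius_mm)) +
    ggplot2::theme_minimal()
}
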