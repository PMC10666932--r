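.map_values <- function(x) {
  if (inherits(x, "contrast_map")) x$values else as.numeric(x)
}

.map_mask <- function(x, mask = NULL) {
  v <- .map_values(x)
  if (is.null(mask)) {
    if (inherits(x, "contrast_map")) mask <- x$cortex_mask
    else mask <- rep(TRUE, length(v))
  }
  mask & is.finite(v)
}

#' Whole-map Pearson correlation between two topographies
#'
#' Correlation over cortical (unmasked, finite) vertices between a
#' subject's own contrast map and a predicted one. Zero variance on either
#' side is an error, not a silent 0: whole-map degeneracy signals a
#' pipeline bug.
#'
#' @param own,predicted `contrast_map` objects (or bare numeric vectors) on
#'   the same mesh.
#' @param mask Optional logical per-vertex mask overriding the maps' own.
#' @return Pearson r.
#' @export
map_pearson <- function(own, predicted, mask = NULL) {
  a <- .map_values(own); b <- .map_values(predicted)
  .assert(length(a) == length(b), "maps differ in length")
  if (inherits(own, "contrast_map") && inherits(predicted, "contrast_map")) {
    .assert(identical(own$category, predicted$category),
            "maps are for different categories")
  }
  keep <- .map_mask(own, mask) & .map_mask(predicted, mask)
  .assert(sum(keep) >= 3, "need at least 3 unmasked vertices")
  x <- a[keep]; y <- b[keep]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance on one side of map_pearson (degenerate map)")
  }
  cor(x, y)
}

#' Cronbach's alpha across localizer runs
#'
#' Reliability of a topography across runs, treating runs as items and
#' vertices as observations:
#' `alpha = k/(k-1) * (1 - sum_i Var(map_i) / Var(sum_i map_i))`, with
#' population variances over unmasked vertices. This is the noise-ceiling
#' estimate the prediction correlations are compared against.
#'
#' @param run_maps List of k >= 2 per-vertex maps (contrast maps or
#'   numerics) for the same category.
#' @param mask Optional logical per-vertex mask.
#' @return Alpha (at most 1; can be negative for unreliable maps).
#' @export
cronbach_alpha <- function(run_maps, mask = NULL) {
  .assert(length(run_maps) >= 2, "need k >= 2 run maps")
  keep <- Reduce(`&`, lapply(run_maps, .map_mask, mask = mask))
  .assert(sum(keep) >= 3, "need at least 3 unmasked vertices")
  M <- vapply(run_maps, function(m) .map_values(m)[keep],
              numeric(sum(keep)))
  k <- ncol(M)
  pvar <- function(x) mean((x - mean(x))^2)
  total <- pvar(rowSums(M))
  if (total <= 0) stop("zero total variance across run maps")
  k / (k - 1) * (1 - sum(apply(M, 2, pvar)) / total)
}

#' Searchlight map of a local statistic
#'
#' Computes [map_pearson()] (kind `"correlation"`) or [cronbach_alpha()]
#' (kind `"alpha"`) restricted to each searchlight's member vertices, at
#' the canonical 15 mm evaluation radius. Centers whose searchlight has
#' fewer than 3 valid members or degenerate variance yield `NA` (local
#' degeneracy is expected, not an error).
#'
#' @param a A contrast map (kind `"correlation"`) or list of run maps
#'   (kind `"alpha"`).
#' @param b Second contrast map for kind `"correlation"`.
#' @param searchlights A [searchlight_set][build_searchlight_set] whose
#'   member indices index into the maps (use global indices for
#'   whole-brain maps).
#' @param kind `"correlation"` or `"alpha"`.
#' @param mask Optional logical per-vertex mask.
#' @return An object of class `searchlight_map`: fields `centers`,
#'   `values` (one statistic per center, `NA` where degenerate),
#'   `radius_mm`, `kind`.
#' @export
searchlight_statistic_map <- function(a, b = NULL, searchlights,
                                      kind = c("correlation", "alpha"),
                                      mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(searchlights, "searchlight_set"))
  .assert(searchlights$radius_mm > 0, "radius must be > 0")
  if (kind == "correlation") {
    .assert(!is.null(b), "kind = 'correlation' needs both maps")
    va <- .map_values(a); vb <- .map_values(b)
    keep <- .map_mask(a, mask) & .map_mask(b, mask)
  } else {
    .assert(is.list(a) && length(a) >= 2,
            "kind = 'alpha' needs a list of >= 2 run maps")
    M <- vapply(a, .map_values, numeric(length(.map_values(a[[1]]))))
    keep <- Reduce(`&`, lapply(a, .map_mask, mask = mask))
  }
  pvar <- function(x) mean((x - mean(x))^2)
  vals <- vapply(searchlights$members, function(m) {
    m <- m[keep[m]]
    if (length(m) < 3) return(NA_real_)
    if (kind == "correlation") {
      x <- va[m]; y <- vb[m]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y)
    } else {
      S <- M[m, , drop = FALSE]
      total <- pvar(rowSums(S))
      if (total <= 0) return(NA_real_)
      k <- ncol(S)
      k / (k - 1) * (1 - sum(apply(S, 2, pvar)) / total)
    }
  }, numeric(1))
  structure(
    list(centers = searchlights$centers, values = vals,
         radius_mm = searchlights$radius_mm, kind = kind),
    class = "searchlight_map"
  )
}

#' @exportS3Method base::print
print.searchlight_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<searchlight_map> kind %s, radius %g mm: %d centers (%d valid), median %.3f\n",
    x$kind, x$radius_mm, length(x$centers), length(v),
    stats::median(v)
  ))
  invisible(x)
}

#' Searchlight similarity of two fine-grained connectomes
#'
#' For each searchlight, the Pearson correlation between the two
#' vectorized (members x targets) connectivity-profile blocks of the same
#' subject under two conditions (two movies, or two split halves of one
#' movie). High values indicate that different stimuli evoke the same
#' fine-scale connectivity structure.
#'
#' @param profile_a,profile_b [connectivity_profile()] objects for the same
#'   subject hemisphere and the same target grid (conditions differ).
#' @param searchlights A [searchlight_set][build_searchlight_set] on the
#'   seed hemisphere.
#' @return A `searchlight_map` of kind `"connectome_similarity"`.
#' @export
connectome_similarity_map <- function(profile_a, profile_b, searchlights) {
  stopifnot(inherits(profile_a, "connectivity_profile"),
            inherits(profile_b, "connectivity_profile"))
  .assert(identical(profile_a$target_grid$target_indices,
                    profile_b$target_grid$target_indices),
          "profiles use different target grids")
  .assert(identical(profile_a$seed_indices, profile_b$seed_indices),
          "profiles use different seed sets")
  row_of <- integer(max(profile_a$seed_indices))
  row_of[profile_a$seed_indices] <- seq_along(profile_a$seed_indices)
  A <- profile_a$values; B <- profile_b$values
  vals <- vapply(searchlights$members, function(m) {
    rows <- row_of[m]
    rows <- rows[rows > 0]
    if (length(rows) == 0) return(NA_real_)
    x <- as.vector(A[rows, , drop = FALSE])
    y <- as.vector(B[rows, , drop = FALSE])
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  structure(
    list(centers = searchlights$centers, values = vals,
         radius_mm = searchlights$radius_mm,
         kind = "connectome_similarity"),
    class = "searchlight_map"
  )
}

#' Fisher-z paired comparison of two methods' prediction correlations
#'
#' Fisher z-transforms (atanh) each subject's map correlation under the two
#' methods and runs a paired two-sided t-test on the differences, with
#' Bonferroni adjustment over the supplied family size. Correlations of
#' exactly +/-1 are clipped to +/-(1 - 1e-12) with a warning before the
#' transform. Identical paired samples (zero-variance differences) give
#' statistic 0 and p = 1.
#'
#' @param r_a,r_b Paired per-subject correlations for methods A and B
#'   (n >= 3).
#' @param method_a,method_b Labels.
#' @param n_comparisons Bonferroni family size.
#' @return A one-row [tibble][tibble::tibble] with the mean z difference,
#'   t statistic, raw and adjusted p-values.
#' @export
compare_methods <- function(r_a, r_b, method_a = "A", method_b = "B",
                            n_comparisons = 1L) {
  .assert(length(r_a) == length(r_b), "paired samples differ in length")
  .assert(length(r_a) >= 3, "need n >= 3 paired subjects")
  clip <- function(r) {
    if (any(abs(r) >= 1)) {
      warning("correlations of |r| = 1 clipped before Fisher transform")
      r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
    }
    r
  }
  d <- atanh(clip(r_a)) - atanh(clip(r_b))
  if (sd(d) <= 1e-15 * max(1, abs(mean(d)))) {
    # degenerate paired samples: identical (p = 1) or exactly shifted (p = 0)
    if (abs(mean(d)) <= 1e-15) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- t.test(d)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  tibble::tibble(
    method_a = method_a, method_b = method_b, n = length(d),
    mean_z_diff = mean(d), statistic = stat, p_value = p,
    p_adjusted = min(1, p * n_comparisons)
  )
}

#' Assemble an evaluation report
#'
#' Collects per-subject prediction records into the standard report: the
#' records themselves, group summaries (mean and standard error per method
#' and category), and Bonferroni-adjusted Fisher-z paired comparisons
#' between methods.
#'
#' @param records A data frame / tibble with columns `subject_id`,
#'   `category`, `method`, `map_r` and optionally `alpha`.
#' @param comparisons List of length-2 character vectors naming method
#'   pairs to compare (per category); defaults to all method pairs.
#' @return An object of class `evaluation_report` with elements `records`,
#'   `summary`, `comparisons` (all tibbles).
#' @export
evaluation_report <- function(records, comparisons = NULL) {
  records <- tibble::as_tibble(records)
  .assert(all(c("subject_id", "category", "method", "map_r") %in%
                names(records)), "records need subject_id/category/method/map_r")
  .assert(all(records$map_r >= -1 & records$map_r <= 1),
          "map_r outside [-1, 1]")
  summary <- records |>
    dplyr::group_by(.data$method, .data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_r = mean(.data$map_r),
      se_r = sd(.data$map_r) / sqrt(dplyr::n()),
      mean_alpha = if ("alpha" %in% names(records))
        mean(.data$alpha) else NA_real_,
      .groups = "drop"
    )
  methods <- unique(records$method)
  if (is.null(comparisons)) {
    comparisons <- if (length(methods) >= 2) {
      utils::combn(methods, 2, simplify = FALSE)
    } else list()
  }
  cats <- unique(records$category)
  fam <- length(comparisons) * length(cats)
  comp <- dplyr::bind_rows(lapply(comparisons, function(pair) {
    dplyr::bind_rows(lapply(cats, function(cat_) {
      wide <- records |>
        dplyr::filter(.data$category == cat_,
                      .data$method %in% pair) |>
        tidyr_pivot(pair)
      out <- compare_methods(wide[[pair[1]]], wide[[pair[2]]],
                             pair[1], pair[2],
                             n_comparisons = max(1L, fam))
      out$category <- cat_
      out
    }))
  }))
  structure(
    list(records = records, summary = summary, comparisons = comp),
    class = "evaluation_report"
  )
}

# minimal long-to-wide used by evaluation_report (avoids a tidyr dependency)
tidyr_pivot <- function(df, methods) {
  subjects <- unique(df$subject_id)
  out <- lapply(methods, function(m) {
    sub <- df[df$method == m, ]
    sub$map_r[match(subjects, sub$subject_id)]
  })
  names(out) <- methods
  tibble::as_tibble(out)
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d records, %d method x category cells\n",
              nrow(x$records), nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
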