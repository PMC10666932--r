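#' Block-design localizer specification
#'
#' Describes a category localizer: the ordered category list and, per run,
#' the blocks (category, onset, duration). The canonical dynamic localizer
#' has 5 categories (faces, bodies, scenes, objects, scrambled) with 10
#' blocks of 18 s per run, two per category.
#'
#' @param categories Character vector of category labels (at least 2).
#' @param runs List of data frames with columns `category`, `onset_s`,
#'   `duration_s` (one data frame per run).
#' @param tr_s Repetition time in seconds.
#' @param n_timepoints Integer vector of timepoints per run (recycled).
#' @param baseline_excluded Categories (e.g. a scrambled control) to leave
#'   out of the "all other categories" side of contrasts; default none.
#' @return An object of class `localizer_design`.
#' @export
localizer_design <- function(categories, runs, tr_s, n_timepoints,
                             baseline_excluded = character()) {
  .assert(length(categories) >= 2, "need at least 2 categories")
  .assert(!anyDuplicated(categories), "duplicate category labels")
  .assert(all(baseline_excluded %in% categories),
          "`baseline_excluded` must name known categories")
  n_timepoints <- rep_len(as.integer(n_timepoints), length(runs))
  for (r in seq_along(runs)) {
    blk <- runs[[r]]
    .assert(is.data.frame(blk) &&
              all(c("category", "onset_s", "duration_s") %in% names(blk)),
            "each run needs columns category/onset_s/duration_s")
    .assert(all(blk$category %in% categories),
            "run ", r, " references unknown categories")
    .assert(all(blk$onset_s >= 0), "run ", r, ": onsets must be >= 0")
    .assert(length(unique(blk$category)) >= 2,
            "run ", r, " must contain blocks of >= 2 distinct categories")
    o <- order(blk$onset_s)
    ends <- blk$onset_s[o] + blk$duration_s[o]
    .assert(all(utils::head(ends, -1) <= blk$onset_s[o][-1] + 1e-9),
            "run ", r, ": blocks overlap")
  }
  structure(
    list(categories = categories, runs = runs, tr_s = tr_s,
         n_timepoints = n_timepoints,
         baseline_excluded = baseline_excluded),
    class = "localizer_design"
  )
}

#' Haemodynamic response function specification
#'
#' The canonical double-gamma HRF (difference of two gamma densities, peak
#' normalized to 1) or `"none"` (the regressor is the raw boxcar, for
#' closed-form tests).
#'
#' @param model `"double_gamma"` or `"none"`.
#' @param peak_delay_s,undershoot_delay_s Delays (gamma shape x dispersion)
#'   of the positive peak and the undershoot, seconds.
#' @param peak_disp_s,undershoot_disp_s Dispersions of the two gammas.
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @param kernel_length_s Kernel support in seconds.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(model = c("double_gamma", "none"), peak_delay_s = 6,
                     undershoot_delay_s = 16, peak_disp_s = 1,
                     undershoot_disp_s = 1, undershoot_ratio = 6,
                     kernel_length_s = 32) {
  model <- match.arg(model)
  structure(
    list(model = model, peak_delay_s = peak_delay_s,
         undershoot_delay_s = undershoot_delay_s, peak_disp_s = peak_disp_s,
         undershoot_disp_s = undershoot_disp_s,
         undershoot_ratio = undershoot_ratio,
         kernel_length_s = kernel_length_s),
    class = "hrf_spec"
  )
}

#' Sample an HRF kernel at a repetition time
#'
#' @param hrf An [hrf_spec()].
#' @param tr_s Sampling interval in seconds.
#' @return Numeric kernel with peak value 1 (`model = "none"` gives the
#'   unit impulse).
#' @export
hrf_kernel <- function(hrf, tr_s) {
  stopifnot(inherits(hrf, "hrf_spec"))
  if (hrf$model == "none") return(1)
  t <- seq(0, hrf$kernel_length_s, by = tr_s)
  k <- dgamma(t, shape = hrf$peak_delay_s / hrf$peak_disp_s,
              scale = hrf$peak_disp_s) -
    dgamma(t, shape = hrf$undershoot_delay_s / hrf$undershoot_disp_s,
           scale = hrf$undershoot_disp_s) / hrf$undershoot_ratio
  k / max(k)
}

# Legendre polynomial P_n on [-1, 1], by the Bonnet recurrence.
.legendre <- function(x, n) {
  if (n == 0) return(rep(1, length(x)))
  if (n == 1) return(x)
  p0 <- rep(1, length(x)); p1 <- x
  for (k in 2:n) {
    p <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    p0 <- p1; p1 <- p
  }
  p1
}

#' Build a block-design GLM design matrix for one run
#'
#' One boxcar regressor per category (sampled at frame times
#' `(i - 1) * tr_s`), convolved with the HRF kernel and truncated to the run
#' length, followed by an intercept and Legendre-polynomial drift columns.
#' Column order: categories, intercept, drifts.
#'
#' @param design A [localizer_design()].
#' @param run_id Run index into `design$runs`.
#' @param hrf An [hrf_spec()].
#' @param n_drift Highest Legendre drift order (0 = intercept only).
#' @return Numeric matrix `n_timepoints x (C + 1 + n_drift)` with a
#'   `"categories"` attribute naming the category columns.
#' @export
build_design_matrix <- function(design, run_id, hrf = hrf_spec(),
                                n_drift = 2L) {
  stopifnot(inherits(design, "localizer_design"), inherits(hrf, "hrf_spec"))
  .assert(run_id >= 1 && run_id <= length(design$runs), "no such run")
  .assert(n_drift >= 0, "`n_drift` must be >= 0")
  Tn <- design$n_timepoints[run_id]
  tr <- design$tr_s
  tt <- (seq_len(Tn) - 1) * tr
  blk <- design$runs[[run_id]]
  run_end <- Tn * tr
  if (any(blk$onset_s + blk$duration_s > run_end + 1e-9)) {
    .stop_invalid("block extends past the end of run ", run_id)
  }
  kern <- hrf_kernel(hrf, tr)
  X <- matrix(0, Tn, length(design$categories))
  colnames(X) <- design$categories
  for (c_ in design$categories) {
    box <- rep(0, Tn)
    for (b in which(blk$category == c_)) {
      box[tt >= blk$onset_s[b] & tt < blk$onset_s[b] + blk$duration_s[b]] <- 1
    }
    if (all(box == 0)) {
      warning(sprintf("category '%s' has no blocks in run %d (zero column)",
                      c_, run_id))
    }
    reg <- if (length(kern) == 1L) box * kern else
      convolve(box, rev(kern), type = "open")[seq_len(Tn)]
    X[, c_] <- reg
  }
  xnorm <- seq(-1, 1, length.out = Tn)
  drifts <- if (n_drift >= 1) {
    vapply(seq_len(n_drift), function(n) .legendre(xnorm, n), numeric(Tn))
  } else NULL
  out <- cbind(X, intercept = 1, drifts)
  if (n_drift >= 1) {
    colnames(out)[(ncol(X) + 2):ncol(out)] <- paste0("drift", seq_len(n_drift))
  }
  attr(out, "categories") <- design$categories
  attr(out, "baseline_excluded") <- design$baseline_excluded
  out
}

# Contrast weight vector for "category vs all other categories":
# +1 on the target, -1/(C-1) on each other included category, 0 elsewhere.
.contrast_weights <- function(X, category) {
  cats <- attr(X, "categories")
  .assert(!is.null(cats), "design matrix lacks its 'categories' attribute")
  .assert(category %in% cats, "unknown category '", category, "'")
  excl <- setdiff(attr(X, "baseline_excluded"), category)
  others <- setdiff(cats, c(category, excl))
  .assert(length(others) >= 1, "no baseline categories left for contrast")
  w <- numeric(ncol(X))
  names(w) <- colnames(X)
  w[category] <- 1
  w[others] <- -1 / length(others)
  w
}

.new_contrast_map <- function(values, subject_id, category, provenance,
                              source_description, cortex_mask) {
  values[!cortex_mask] <- NA_real_
  structure(
    list(subject_id = subject_id, category = category, values = values,
         provenance = provenance, source_description = source_description,
         cortex_mask = cortex_mask),
    class = "contrast_map"
  )
}

#' @exportS3Method base::print
print.contrast_map <- function(x, ...) {
  v <- x$values[x$cortex_mask]
  cat(sprintf(
    "<contrast_map> %s / %s (%s): %d vertices (%d cortical), t in [%.2f, %.2f]\n",
    x$subject_id, x$category, x$provenance, length(x$values), length(v),
    min(v), max(v)
  ))
  invisible(x)
}

#' Per-run GLM t-contrast map(s)
#'
#' Ordinary least squares per vertex with contrast "target category vs all
#' other categories" (+1 / -1/(C-1) weights, 0 on nuisance columns):
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` with `s2 = RSS / (n - rank(X))`,
#' unthresholded. Masked vertices carry `NA`. Vertices with zero residual
#' variance get a signed sentinel (`+/-1e10`) with a warning.
#'
#' @param run_ts A single-run [time_series()] (raw or z-scored; the design
#'   includes an intercept).
#' @param X Design matrix from [build_design_matrix()] (must be full column
#'   rank).
#' @param category Category label, or a vector of labels to compute several
#'   contrasts from one fit.
#' @param cortex_mask Logical per vertex; defaults to all-cortical.
#' @return A `contrast_map`, or a named list of them if `category` has
#'   length > 1.
#' @export
fit_contrast_tmap <- function(run_ts, X, category,
                              cortex_mask = rep(TRUE, ncol(run_ts$data))) {
  stopifnot(inherits(run_ts, "time_series"))
  Y <- run_ts$data
  .assert(nrow(Y) == nrow(X), "design and data timepoints differ")
  qx <- qr(X)
  if (qx$rank < ncol(X)) .stop_invalid("design matrix is rank-deficient")
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- XtX_inv %*% crossprod(X, Y)
  RSS <- colSums((Y - X %*% B)^2)
  df <- nrow(Y) - ncol(X)
  .assert(df >= 1, "no residual degrees of freedom")
  s2 <- RSS / df
  # residual variance that is zero up to rounding (perfect fit)
  zero_res <- RSS <= 1e-16 * pmax(colSums(Y^2), .Machine$double.xmin)

  one_map <- function(cat_) {
    w <- .contrast_weights(X, cat_)
    num <- drop(w %*% B)
    se <- sqrt(s2 * drop(w %*% XtX_inv %*% w))
    tval <- num / se
    bad <- zero_res | se <= 0 | !is.finite(tval)
    if (any(bad & cortex_mask)) {
      warning(sprintf(
        "%d vertex(es) with zero residual variance: t set to signed sentinel",
        sum(bad & cortex_mask)))
      tval[bad] <- sign(num[bad]) * 1e10
    }
    .new_contrast_map(tval, run_ts$subject_id, cat_, "own",
                      sprintf("single run GLM (%s)", run_ts$condition_id),
                      cortex_mask)
  }
  if (length(category) == 1L) one_map(category) else
    stats::setNames(lapply(category, one_map), category)
}

# Mean of a list of contrast maps (all same category/mask).
.average_maps <- function(maps, provenance, source_description) {
  V <- vapply(maps, function(m) m$values, numeric(length(maps[[1]]$values)))
  out <- maps[[1]]
  out$values <- rowMeans(V)
  out$provenance <- provenance
  out$source_description <- source_description
  out
}

#' Own-localizer category topography
#'
#' A subject's own category-selective map: the arithmetic mean of the
#' unthresholded per-run GLM t maps across all localizer runs.
#'
#' @param runs List of single-run [time_series()] for one subject.
#' @param design A [localizer_design()].
#' @param hrf An [hrf_spec()].
#' @param category Category label (or vector of labels).
#' @param cortex_mask Logical per vertex.
#' @param n_drift Legendre drift order per run.
#' @return A `contrast_map` with `provenance = "own"` (or a named list).
#' @export
own_topography <- function(runs, design, hrf = hrf_spec(), category,
                           cortex_mask = rep(TRUE, ncol(runs[[1]]$data)),
                           n_drift = 2L) {
  .assert(length(runs) >= 1, "need at least one run")
  per_run <- lapply(seq_along(runs), function(r) {
    X <- build_design_matrix(design, r, hrf, n_drift)
    fit_contrast_tmap(runs[[r]], X, category, cortex_mask)
  })
  desc <- sprintf("mean over %d own localizer run(s)", length(runs))
  if (length(category) == 1L) {
    .average_maps(per_run, "own", desc)
  } else {
    stats::setNames(lapply(category, function(cat_) {
      .average_maps(lapply(per_run, `[[`, cat_), "own", desc)
    }), category)
  }
}

# Apply one chain to a pre-computed contrast map: each step's matrices hit
# the map as a 1-timepoint pattern, mean-centered over cortex before each
# multiplication, with no z-scoring between steps.
.transform_map <- function(chain, map) {
  v <- map$values
  mask <- map$cortex_mask
  steps <- if (inherits(chain, "transform_chain")) chain$steps else
    list(chain)
  for (st in steps) {
    v[!mask | !is.finite(v)] <- 0
    v <- v - mean(v[mask])
    nL <- ncol(st$left$values)
    v <- c(
      as.numeric(st$left$values %*% v[seq_len(nL)]),
      as.numeric(st$right$values %*% v[-seq_len(nL)])
    )
  }
  v[!mask] <- NA_real_
  map$values <- v
  map
}

#' Predict a subject's topography from other subjects' localizer data
#'
#' The core prediction operation: other subjects' localizer data are
#' projected into the target subject's cortical space through the fitted
#' transform chains, and the resulting per-run t maps are averaged with
#' equal weight across runs and source subjects.
#'
#' Two modes: `"timeseries"` (canonical) applies each chain to every
#' localizer run's time series and fits the GLM afterwards;
#' `"contrast_map"` fits each source's per-run t maps natively and applies
#' the chain matrices directly to the maps (mean-centered over cortex
#' before each multiplication, no z-scoring between steps). Identity chains
#' reproduce the anatomical-alignment (AA) baseline.
#'
#' @param localizers Named list: for each source subject, its list of
#'   single-run [time_series()].
#' @param chains Named list of [transform_chain][fit_iterative_cha] objects,
#'   one per source subject (names must match `localizers`); the target
#'   subject must not appear among the sources unless predicting from the
#'   self-chain deliberately.
#' @inheritParams own_topography
#' @param mode `"timeseries"` or `"contrast_map"`.
#' @param n_steps Optional schedule prefix passed to [apply_chain()].
#' @return A `contrast_map` with `provenance = "predicted"` (or a named
#'   list when `category` is a vector).
#' @export
predicted_topography <- function(localizers, chains, design,
                                 hrf = hrf_spec(), category,
                                 cortex_mask, mode = c("timeseries",
                                                       "contrast_map"),
                                 n_drift = 2L, n_steps = NULL) {
  mode <- match.arg(mode)
  .assert(length(chains) >= 1, "empty source set")
  .assert(all(names(chains) %in% names(localizers)),
          "every chain needs matching localizer data")
  sources <- names(chains)
  n_runs <- length(localizers[[sources[1]]])
  Xs <- lapply(seq_len(n_runs), function(r)
    build_design_matrix(design, r, hrf, n_drift))
  if (missing(cortex_mask)) {
    cortex_mask <- rep(TRUE, ncol(localizers[[sources[1]]][[1]]$data))
  }

  all_maps <- list()
  for (s in sources) {
    ch <- chains[[s]]
    for (r in seq_along(localizers[[s]])) {
      run <- localizers[[s]][[r]]
      if (mode == "timeseries") {
        run <- apply_chain(ch, zscore_runs(run), n_steps = n_steps)
        maps <- fit_contrast_tmap(run, Xs[[r]], category, cortex_mask)
      } else {
        maps <- fit_contrast_tmap(run, Xs[[r]], category, cortex_mask)
        sub_ch <- ch
        if (!is.null(n_steps) && inherits(ch, "transform_chain")) {
          sub_ch$steps <- ch$steps[seq_len(n_steps)]
        }
        maps <- if (length(category) == 1L) .transform_map(sub_ch, maps)
          else lapply(maps, function(m) .transform_map(sub_ch, m))
      }
      all_maps[[length(all_maps) + 1L]] <- maps
    }
  }
  desc <- sprintf("mean over %d source subject(s) x %d run(s), %s mode",
                  length(sources), n_runs, mode)
  target <- if (inherits(chains[[1]], "transform_chain"))
    chains[[1]]$target_subject else "target"
  finish <- function(maps) {
    m <- .average_maps(maps, "predicted", desc)
    m$subject_id <- target
    m
  }
  if (length(category) == 1L) {
    finish(all_maps)
  } else {
    stats::setNames(lapply(category, function(cat_) {
      finish(lapply(all_maps, `[[`, cat_))
    }), category)
  }
}
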