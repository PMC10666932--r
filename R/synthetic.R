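#' Shared functional template for a synthetic cohort
#'
#' The template models the functional architecture all synthetic subjects
#' share: `n_latents` smooth latent-signal loading maps (the spatial
#' structure movie responses and connectivity profiles inherit) and one
#' smooth tuning map per localizer category. Every map is a sum of
#' spherical Gaussian bumps (geodesic distance profile) with vertex centers
#' drawn uniformly over cortical vertices and standard-normal amplitudes;
#' maps are zero on masked vertices.
#'
#' @param left_mesh,right_mesh Template hemisphere meshes (with any medial
#'   wall mask already applied).
#' @param n_latents Number of latent movie components (>= 2).
#' @param n_categories Number of localizer categories (>= 2) or a character
#'   vector of category names.
#' @param bump_width_mm Gaussian bump width (SD of the geodesic profile).
#' @param bumps_per_map Bumps summed per map.
#' @param seed Integer seed; the template is deterministic given it.
#' @return An object of class `template_model` with fields `loadings`
#'   (vertices x latents), `tuning` (vertices x categories), `categories`,
#'   mesh references and the seed.
#' @export
make_template <- function(left_mesh, right_mesh, n_latents = 20,
                          n_categories = 5, bump_width_mm = 20,
                          bumps_per_map = 10, seed = 1L) {
  stopifnot(inherits(left_mesh, "surface_mesh"),
            inherits(right_mesh, "surface_mesh"))
  categories <- if (is.character(n_categories)) n_categories else
    paste0("cat", seq_len(n_categories))
  .assert(n_latents >= 2, "`n_latents` must be >= 2")
  .assert(length(categories) >= 2, "need >= 2 categories")
  .assert(is.finite(bump_width_mm) && bump_width_mm > 0,
          "`bump_width_mm` must be > 0")
  nL <- n_vertices(left_mesh); nR <- n_vertices(right_mesh)
  mask <- c(left_mesh$cortex_mask, right_mesh$cortex_mask)
  cortical <- which(mask)

  bump_map <- function() {
    centers <- sample(cortical, bumps_per_map, replace = TRUE)
    amps <- rnorm(bumps_per_map)
    v <- numeric(nL + nR)
    for (b in seq_len(bumps_per_map)) {
      c_ <- centers[b]
      if (c_ <= nL) {
        d <- .geodesic_rows(left_mesh, c_)[1, ]
        v[seq_len(nL)] <- v[seq_len(nL)] +
          amps[b] * exp(-d^2 / (2 * bump_width_mm^2))
      } else {
        d <- .geodesic_rows(right_mesh, c_ - nL)[1, ]
        v[nL + seq_len(nR)] <- v[nL + seq_len(nR)] +
          amps[b] * exp(-d^2 / (2 * bump_width_mm^2))
      }
    }
    v[!mask] <- 0
    v
  }
  .with_seed(seed, {
    loadings <- vapply(seq_len(n_latents), function(i) bump_map(),
                       numeric(nL + nR))
    tuning <- vapply(seq_along(categories), function(i) bump_map(),
                     numeric(nL + nR))
  })
  colnames(tuning) <- categories
  structure(
    list(loadings = loadings, tuning = tuning, categories = categories,
         left_mesh = left_mesh, right_mesh = right_mesh,
         bump_width_mm = bump_width_mm, bumps_per_map = bumps_per_map,
         seed = as.integer(seed)),
    class = "template_model"
  )
}

#' Planted ground truth for one synthetic subject
#'
#' Each subject's idiosyncratic topography is a planted block-orthogonal
#' misalignment of the template's vertex space: the cortical vertices of
#' each hemisphere are partitioned into patches by nearest coarse-grid
#' center (order `patch_order`), and each patch gets an independent random
#' orthogonal block. Block orthogonality keeps ground-truth recovery
#' well-posed: local orthogonal transforms are exactly hyperalignment's
#' hypothesis class, so this is a deliberately favorable-case simulator.
#'
#' Each block is a random rotation with bounded plane angles: the matrix
#' exponential of a random skew-symmetric matrix scaled so its largest
#' rotation angle is `max_rotation_deg`. Bounding the angle models real
#' topographic idiosyncrasy — a local rearrangement on top of a shared
#' coarse architecture — and is what keeps searchlight-averaged
#' connectivity targets anatomically comparable across subjects, the
#' premise connectivity hyperalignment rests on. `max_rotation_deg = Inf`
#' gives Haar-uniform orthogonal blocks (reflections allowed) instead; with
#' those, all coarse structure is scrambled and connectivity-based
#' alignment is uninformative by construction (useful as a negative
#' control).
#'
#' @param template A [make_template()] model.
#' @param patch_order Subdivision order of the patch centers (must be below
#'   the mesh order).
#' @param movie_noise_sd,localizer_noise_sd Noise levels, expressed as
#'   multiples of the mean cortical signal SD of the corresponding dataset.
#' @param max_rotation_deg Largest rotation angle of any eigenplane of a
#'   patch block, degrees; `Inf` for Haar-uniform blocks.
#' @param subject_id Label.
#' @param seed Integer seed.
#' @return An object of class `subject_ground_truth` with the per-hemisphere
#'   sparse orthogonal matrices (`R_left`, `R_right`), patch assignments,
#'   noise levels and seed.
#' @export
make_subject <- function(template, patch_order = 2L, movie_noise_sd = 1,
                         localizer_noise_sd = 1, max_rotation_deg = 60,
                         subject_id = "sub01", seed = 1L) {
  stopifnot(inherits(template, "template_model"))
  one_hemi <- function(mesh, hemi_seed) {
    .assert(patch_order < mesh$subdivision_order,
            "`patch_order` must be below the mesh order")
    n_centers <- 10L * 4L^patch_order + 2L
    centers <- seq_len(n_centers)
    centers <- centers[mesh$cortex_mask[centers]]
    cortical <- cortex_indices(mesh)
    D <- .geodesic_rows(mesh, centers)[, cortical, drop = FALSE]
    patch_of <- centers[max.col(-t(D), ties.method = "first")]
    R <- .with_seed(hemi_seed, {
      ii <- integer(0); jj <- integer(0); xx <- numeric(0)
      for (c_ in centers) {
        verts <- cortical[patch_of == c_]
        p <- length(verts)
        if (p == 0) next
        Q <- .random_rotation(p, max_rotation_deg)
        ii <- c(ii, rep(verts, times = p))
        jj <- c(jj, rep(verts, each = p))
        xx <- c(xx, as.vector(Q))
      }
      Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                           dims = c(n_vertices(mesh), n_vertices(mesh)))
    })
    list(R = R, patch_of = patch_of, centers = centers,
         cortical = cortical)
  }
  left <- one_hemi(template$left_mesh, .child_seed(seed, "patches", "left"))
  right <- one_hemi(template$right_mesh,
                    .child_seed(seed, "patches", "right"))
  structure(
    list(subject_id = subject_id, patch_order = as.integer(patch_order),
         max_rotation_deg = max_rotation_deg,
         R_left = left$R, R_right = right$R,
         patches = list(left = left[c("patch_of", "centers", "cortical")],
                        right = right[c("patch_of", "centers", "cortical")]),
         movie_noise_sd = movie_noise_sd,
         localizer_noise_sd = localizer_noise_sd,
         seed = as.integer(seed)),
    class = "subject_ground_truth"
  )
}

# Apply a subject's planted misalignment to template-space data (T x V).
.misalign <- function(subject, Z, nL) {
  left <- seq_len(nL)
  cbind(
    as.matrix(Matrix::tcrossprod(Z[, left, drop = FALSE], subject$R_left)),
    as.matrix(Matrix::tcrossprod(Z[, -left, drop = FALSE],
                                 subject$R_right))
  )
}

.split_runs <- function(X, n_runs, run_prefix) {
  Tn <- nrow(X)
  base <- Tn %/% n_runs
  sizes <- rep(base, n_runs)
  sizes[n_runs] <- Tn - base * (n_runs - 1)
  data.frame(run_id = paste0(run_prefix, seq_len(n_runs)),
             n_timepoints = sizes)
}

#' Simulate movie-viewing data for one subject
#'
#' Latent time courses are independent AR(1) series (unit marginal
#' variance), drawn once per `movie_id` and shared by every subject — all
#' subjects "watch the same movie" — while different movie ids get
#' independent time courses that share the template's spatial loadings.
#' Template-space data are the loadings-weighted latents; subject data are
#' the planted misalignment applied per timepoint, plus Gaussian noise with
#' SD `movie_noise_sd` times the mean cortical signal SD.
#'
#' @param template A [make_template()] model.
#' @param subject A [make_subject()] ground truth.
#' @param movie_id Movie label (e.g. `"A"` or `"B"`).
#' @param n_timepoints Total timepoints (>= 10).
#' @param ar_coeff AR(1) coefficient in (-1, 1).
#' @param n_runs Number of runs the series is split into.
#' @param tr_s Repetition time in seconds.
#' @return A [time_series()] (not yet z-scored).
#' @export
simulate_movie <- function(template, subject, movie_id = "A",
                           n_timepoints = 300, ar_coeff = 0.3, n_runs = 3,
                           tr_s = 1) {
  stopifnot(inherits(template, "template_model"),
            inherits(subject, "subject_ground_truth"))
  .assert(n_timepoints >= 10, "`n_timepoints` must be >= 10")
  .assert(abs(ar_coeff) < 1, "`ar_coeff` must satisfy |ar_coeff| < 1")
  L <- ncol(template$loadings)
  latents <- .with_seed(.child_seed(template$seed, "latents", movie_id), {
    E <- matrix(rnorm(L * n_timepoints), L, n_timepoints)
    X <- E
    X[, 1] <- E[, 1]
    for (t_ in 2:n_timepoints) {
      X[, t_] <- ar_coeff * X[, t_ - 1] +
        sqrt(1 - ar_coeff^2) * E[, t_]
    }
    X
  })
  Z <- t(template$loadings %*% latents)  # timepoints x vertices
  nL <- n_vertices(template$left_mesh)
  X <- .misalign(subject, Z, nL)
  mask <- c(template$left_mesh$cortex_mask, template$right_mesh$cortex_mask)
  noise_scale <- subject$movie_noise_sd * mean(.col_sd_pop(Z)[mask])
  if (noise_scale > 0) {
    X <- X + .with_seed(
      .child_seed(subject$seed, "movie-noise", movie_id),
      matrix(rnorm(length(X), sd = noise_scale), nrow(X), ncol(X)))
  }
  time_series(X, .split_runs(X, n_runs, paste0(movie_id, "-run")),
              subject_id = subject$subject_id,
              condition_id = paste0("movie-", movie_id), tr_s = tr_s)
}

#' Simulate block-design localizer runs for one subject
#'
#' The template-space signal at vertex `v`, time `t` is the sum over
#' categories of `tuning_c(v)` times the HRF-convolved category boxcar;
#' subject data apply the planted misalignment per timepoint and add
#' Gaussian noise with SD `localizer_noise_sd` times the mean cortical
#' signal SD.
#'
#' @inheritParams simulate_movie
#' @param design A [localizer_design()] whose categories match the
#'   template's.
#' @param hrf An [hrf_spec()].
#' @return A list of single-run [time_series()] objects.
#' @export
simulate_localizer <- function(template, subject, design,
                               hrf = hrf_spec()) {
  stopifnot(inherits(design, "localizer_design"))
  .assert(identical(design$categories, template$categories),
          "design categories must match the template's")
  nL <- n_vertices(template$left_mesh)
  mask <- c(template$left_mesh$cortex_mask, template$right_mesh$cortex_mask)
  signals <- lapply(seq_along(design$runs), function(r) {
    X <- build_design_matrix(design, r, hrf, n_drift = 0L)
    conv <- X[, design$categories, drop = FALSE]
    t(template$tuning %*% t(conv))  # timepoints x vertices
  })
  sig_sd <- mean(.col_sd_pop(do.call(rbind, signals))[mask])
  noise_scale <- subject$localizer_noise_sd * sig_sd
  lapply(seq_along(signals), function(r) {
    X <- .misalign(subject, signals[[r]], nL)
    if (noise_scale > 0) {
      X <- X + .with_seed(
        .child_seed(subject$seed, "localizer-noise", r),
        matrix(rnorm(length(X), sd = noise_scale), nrow(X), ncol(X)))
    }
    time_series(
      X,
      data.frame(run_id = paste0("loc-run", r), n_timepoints = nrow(X)),
      subject_id = subject$subject_id,
      condition_id = paste0("localizer-run", r), tr_s = design$tr_s)
  })
}

#' Canonical synthetic localizer design
#'
#' A desk-scale analogue of the dynamic category localizer: 5 categories
#' (faces, bodies, scenes, objects, scrambled), 10 blocks of 18 s per run
#' (two per category, order randomized per run), 10 s rest between blocks,
#' TR 2 s.
#'
#' @param n_runs Number of runs.
#' @param seed Seed for per-run block order.
#' @param categories Category labels.
#' @return A [localizer_design()].
#' @export
default_localizer_design <- function(n_runs = 4, seed = 1L,
                                     categories = c("faces", "bodies",
                                                    "scenes", "objects",
                                                    "scrambled")) {
  block_s <- 18; gap_s <- 10; tr_s <- 2
  runs <- .with_seed(.child_seed(seed, "localizer-design"), {
    lapply(seq_len(n_runs), function(r) {
      order_ <- sample(rep(categories, 2))
      onsets <- gap_s + (seq_along(order_) - 1) * (block_s + gap_s)
      data.frame(category = order_, onset_s = onsets, duration_s = block_s)
    })
  })
  total_s <- gap_s + length(categories) * 2 * (block_s + gap_s)
  localizer_design(categories, runs, tr_s = tr_s,
                   n_timepoints = ceiling(total_s / tr_s))
}

#' Generate a complete synthetic multi-subject cohort
#'
#' Builds the template meshes (order `mesh_order` icospheres at nominal
#' radius 100 mm with a polar-cap medial wall), the shared functional
#' template, per-subject planted misalignments, two movies (`"A"`, `"B"`)
#' with independent latent time courses but shared spatial structure, and a
#' multi-run block-design localizer per subject. All randomness derives
#' hierarchically from `master_seed` via stable child seeds, recorded in
#' the manifest; regenerating from the manifest reproduces every array
#' bitwise.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param mesh_order Mesh subdivision order.
#' @param master_seed Integer master seed.
#' @param n_latents,bump_width_mm,bumps_per_map Template parameters
#'   ([make_template()]).
#' @param patch_order Misalignment patch order ([make_subject()]).
#' @param max_rotation_deg Misalignment strength ([make_subject()]).
#' @param movie_noise_sd,localizer_noise_sd Noise levels (multiples of mean
#'   cortical signal SD).
#' @param n_timepoints,ar_coeff,n_movie_runs Movie parameters
#'   ([simulate_movie()]).
#' @param n_localizer_runs Localizer run count.
#' @param cap_angle_deg Polar-cap medial-wall half-angle.
#' @param categories Localizer category labels.
#' @return An object of class `cohort_bundle` with fields `left_mesh`,
#'   `right_mesh`, `cortex_mask`, `template`, `subjects`, `movies`
#'   (`movies[[subject]][[movie_id]]`), `localizers`, `design`, `hrf`,
#'   `subject_ids`, `manifest`.
#' @export
make_cohort <- function(n_subjects = 10, mesh_order = 3, master_seed = 42,
                        n_latents = 20, bump_width_mm = 20,
                        bumps_per_map = 10, patch_order = 2,
                        max_rotation_deg = 60,
                        movie_noise_sd = 1, localizer_noise_sd = 1,
                        n_timepoints = 300, ar_coeff = 0.3,
                        n_movie_runs = 3, n_localizer_runs = 4,
                        cap_angle_deg = 30,
                        categories = c("faces", "bodies", "scenes",
                                       "objects", "scrambled")) {
  .assert(n_subjects >= 2, "`n_subjects` must be >= 2")
  params <- list(
    n_subjects = n_subjects, mesh_order = mesh_order,
    master_seed = master_seed, n_latents = n_latents,
    bump_width_mm = bump_width_mm, bumps_per_map = bumps_per_map,
    patch_order = patch_order, max_rotation_deg = max_rotation_deg,
    movie_noise_sd = movie_noise_sd,
    localizer_noise_sd = localizer_noise_sd, n_timepoints = n_timepoints,
    ar_coeff = ar_coeff, n_movie_runs = n_movie_runs,
    n_localizer_runs = n_localizer_runs, cap_angle_deg = cap_angle_deg,
    categories = categories
  )
  left <- apply_polar_cap_mask(build_icosphere(mesh_order,
                                               hemisphere = "left"),
                               c(1, 0, 0), cap_angle_deg)
  right <- apply_polar_cap_mask(build_icosphere(mesh_order,
                                                hemisphere = "right"),
                                c(-1, 0, 0), cap_angle_deg)
  template <- make_template(left, right, n_latents = n_latents,
                            n_categories = categories,
                            bump_width_mm = bump_width_mm,
                            bumps_per_map = bumps_per_map,
                            seed = .child_seed(master_seed, "template"))
  design <- default_localizer_design(
    n_runs = n_localizer_runs, seed = .child_seed(master_seed, "design"),
    categories = categories)
  hrf <- hrf_spec()
  ids <- sprintf("sub%02d", seq_len(n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    make_subject(template, patch_order = patch_order,
                 movie_noise_sd = movie_noise_sd,
                 localizer_noise_sd = localizer_noise_sd,
                 max_rotation_deg = max_rotation_deg,
                 subject_id = ids[i],
                 seed = .child_seed(master_seed, "subject", ids[i]))
  })
  names(subjects) <- ids
  movies <- lapply(subjects, function(sub) {
    stats::setNames(lapply(c("A", "B"), function(m) {
      simulate_movie(template, sub, movie_id = m,
                     n_timepoints = n_timepoints, ar_coeff = ar_coeff,
                     n_runs = n_movie_runs)
    }), c("A", "B"))
  })
  localizers <- lapply(subjects, function(sub) {
    simulate_localizer(template, sub, design, hrf)
  })
  structure(
    list(
      left_mesh = left, right_mesh = right,
      cortex_mask = c(left$cortex_mask, right$cortex_mask),
      template = template, subjects = subjects, movies = movies,
      localizers = localizers, design = design, hrf = hrf,
      subject_ids = ids,
      manifest = list(schema = "chalign-cohort", version = 1L,
                      params = params)
    ),
    class = "cohort_bundle"
  )
}

#' @exportS3Method base::print
print.cohort_bundle <- function(x, ...) {
  p <- x$manifest$params
  cat(sprintf(
    "<cohort_bundle> %d subjects, order-%d meshes (%d vertices, %d cortical), 2 movies x %d tp, %d localizer runs\n",
    p$n_subjects, p$mesh_order, length(x$cortex_mask), sum(x$cortex_mask),
    p$n_timepoints, p$n_localizer_runs
  ))
  invisible(x)
}
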