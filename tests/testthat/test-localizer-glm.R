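two_cat_design <- function(n_runs = 1, tr = 2, n_tp = 60) {
  blocks <- data.frame(category = c("A", "B", "A", "B"),
                       onset_s = c(10, 40, 70, 100), duration_s = 16)
  localizer_design(c("A", "B"), rep(list(blocks), n_runs), tr_s = tr,
                   n_timepoints = n_tp)
}

test_that("design validation catches overlaps and degenerate runs", {
  blocks <- data.frame(category = c("A", "B"), onset_s = c(0, 10),
                       duration_s = c(15, 10))
  expect_error(localizer_design(c("A", "B"), list(blocks), 2, 30),
               "overlap", class = "chalign_invalid_argument")
  one_cat <- data.frame(category = "A", onset_s = 0, duration_s = 10)
  expect_error(localizer_design(c("A", "B"), list(one_cat), 2, 30),
               class = "chalign_invalid_argument")
  expect_error(localizer_design("A", list(), 2, 30),
               class = "chalign_invalid_argument")
})

test_that("with no HRF the regressor is the raw boxcar", {
  des <- two_cat_design()
  X <- build_design_matrix(des, 1, hrf_spec("none"), n_drift = 0)
  tt <- (seq_len(60) - 1) * 2
  boxA <- as.numeric((tt >= 10 & tt < 26) | (tt >= 70 & tt < 86))
  expect_identical(unname(X[, "A"]), boxA)
  expect_identical(colnames(X), c("A", "B", "intercept"))
  # a category absent from the run yields a zero column with a warning
  blocks <- data.frame(category = c("A", "A"), onset_s = c(0, 30),
                       duration_s = 10)
  suppressWarnings(
    des2 <- localizer_design(c("A", "B"), list(rbind(
      blocks, data.frame(category = "B", onset_s = 60, duration_s = 10))),
      2, 60))
  des2$runs[[1]] <- blocks  # drop B after validation to provoke it
  expect_warning(X2 <- build_design_matrix(des2, 1, hrf_spec("none"), 0),
                 "no blocks")
  expect_identical(unname(X2[, "B"]), rep(0, 60))
  # blocks past the run end error out
  des3 <- two_cat_design(n_tp = 50)
  expect_error(build_design_matrix(des3, 1, hrf_spec("none"), 0),
               "past the end", class = "chalign_invalid_argument")
})

test_that("the double-gamma kernel matches an independent evaluation of the two-gamma formula", {
  h <- hrf_spec()
  tr <- 0.01
  k <- hrf_kernel(h, tr)
  tt <- seq(0, h$kernel_length_s, by = tr)
  # independent formula: gamma densities written out explicitly
  gd <- function(t, shape, scale) {
    ifelse(t <= 0, ifelse(t == 0 & shape == 1, 1 / scale, 0),
           t^(shape - 1) * exp(-t / scale) / (scale^shape * gamma(shape)))
  }
  ref <- gd(tt, 6, 1) - gd(tt, 16, 1) / 6
  ref <- ref / max(ref)
  expect_equal(k, ref, tolerance = 1e-12)
  # peak location: the canonical 6/16 parameters peak near 5 s
  expect_equal(tt[which.max(k)], 5, tolerance = 0.05)
  # quadrature: the kernel integral matches fine-grid numerics
  expect_equal(sum(k) * tr, sum(ref) * tr, tolerance = 1e-10)
  expect_equal(max(k), 1)
})

test_that("t statistics on pure noise follow the Student-t null", {
  des <- two_cat_design(n_tp = 80)
  X <- build_design_matrix(des, 1, hrf_spec(), n_drift = 2)
  set.seed(31)
  nv <- 10000
  ts <- time_series(matrix(rnorm(80 * nv), 80, nv),
                    data.frame(run_id = "r1", n_timepoints = 80))
  map <- fit_contrast_tmap(ts, X, "A")
  ks <- suppressWarnings(
    stats::ks.test(map$values, stats::pt, df = 80 - ncol(X)))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted effects are recovered and t maps are affine invariant", {
  des <- two_cat_design(n_tp = 80)
  X <- build_design_matrix(des, 1, hrf_spec(), n_drift = 1)
  set.seed(32)
  nv <- 50
  beta <- matrix(rnorm(ncol(X) * nv), ncol(X), nv)
  Y <- X %*% beta + matrix(rnorm(80 * nv, sd = 1e-6), 80, nv)
  ts <- time_series(Y, data.frame(run_id = "r1", n_timepoints = 80))
  w <- chalign:::.contrast_weights(X, "A")
  map <- fit_contrast_tmap(ts, X, "A")
  # the contrast estimate itself reproduces c'beta
  fit <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(drop(w %*% fit), drop(w %*% beta), tolerance = 1e-3)
  # invariance to positive rescaling and additive constants per vertex
  ts2 <- ts
  ts2$data <- sweep(sweep(Y, 2, runif(nv, 0.5, 2), "*"), 2,
                    rnorm(nv, sd = 4), "+")
  map2 <- fit_contrast_tmap(ts2, X, "A")
  expect_equal(map$values, map2$values, tolerance = 1e-6)
})

test_that("two-category contrasts are antisymmetric under category exchange", {
  des <- two_cat_design(n_tp = 80)
  X <- build_design_matrix(des, 1, hrf_spec(), n_drift = 2)
  ts <- random_run_ts(80, 40, 1, seed = 33)
  mapA <- fit_contrast_tmap(ts, X, "A")
  mapB <- fit_contrast_tmap(ts, X, "B")
  expect_equal(mapA$values, -mapB$values, tolerance = 1e-10)
})

test_that("rank-deficient designs and zero residuals are handled per contract", {
  des <- two_cat_design(n_tp = 80)
  X <- build_design_matrix(des, 1, hrf_spec(), n_drift = 0)
  Xbad <- cbind(X, X[, 1])
  ts <- random_run_ts(80, 10, 1, seed = 34)
  expect_error(fit_contrast_tmap(ts, Xbad, "A"),
               "rank", class = "chalign_invalid_argument")
  exact <- ts
  exact$data <- X %*% matrix(rnorm(ncol(X) * 10), ncol(X), 10)
  expect_warning(map <- fit_contrast_tmap(exact, X, "A"),
                 "zero residual")
  expect_true(all(abs(map$values) == 1e10))
})

test_that("own topography averages per-run t maps", {
  co <- tiny_cohort()
  runs <- co$localizers$sub01
  mask <- co$cortex_mask
  per_run <- lapply(seq_along(runs), function(r) {
    X <- build_design_matrix(co$design, r, co$hrf, 2L)
    fit_contrast_tmap(runs[[r]], X, "faces", mask)
  })
  own <- own_topography(runs, co$design, co$hrf, "faces", mask)
  manual <- rowMeans(vapply(per_run, `[[`, numeric(length(mask)),
                            "values"))
  expect_equal(own$values, manual, tolerance = 1e-12)
  expect_identical(own$provenance, "own")
  single <- own_topography(runs[1], co$design, co$hrf, "faces", mask)
  expect_equal(single$values, per_run[[1]]$values, tolerance = 1e-12)
  expect_true(all(is.na(own$values[!mask])))
})

test_that("identity chains reproduce the plain cross-subject average (AA)", {
  co <- tiny_cohort()
  mask <- co$cortex_mask
  nL <- n_vertices(co$left_mesh); nR <- n_vertices(co$right_mesh)
  chains <- list(
    sub02 = identity_chain(nL, nR, "sub02", "sub01"),
    sub03 = identity_chain(nL, nR, "sub03", "sub01")
  )
  pred <- predicted_topography(co$localizers, chains, co$design, co$hrf,
                               "faces", mask, mode = "timeseries")
  native <- lapply(c("sub02", "sub03"), function(s) {
    lapply(seq_along(co$localizers[[s]]), function(r) {
      X <- build_design_matrix(co$design, r, co$hrf, 2L)
      fit_contrast_tmap(co$localizers[[s]][[r]], X, "faces", mask)$values
    })
  })
  manual <- rowMeans(do.call(cbind, lapply(unlist(native, recursive = FALSE),
                                           identity)))
  expect_equal(pred$values[mask], manual[mask], tolerance = 1e-9)
  expect_identical(pred$provenance, "predicted")
})

test_that("predicted maps are invariant to source ordering", {
  co <- tiny_cohort()
  chains <- fit_chains_to_target(co, "sub01", method = "cha")
  p1 <- predicted_topography(co$localizers, chains, co$design, co$hrf,
                             "bodies", co$cortex_mask)
  p2 <- predicted_topography(co$localizers, rev(chains), co$design,
                             co$hrf, "bodies", co$cortex_mask)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("predicting a subject from itself through its self-chain is exact", {
  co <- tiny_cohort()
  self <- fit_chains_to_target(co, "sub01", method = "cha",
                               source_ids = "sub01")
  pred <- predicted_topography(co$localizers, self, co$design, co$hrf,
                               "scenes", co$cortex_mask)
  own <- own_topography(co$localizers$sub01, co$design, co$hrf, "scenes",
                        co$cortex_mask)
  expect_gte(map_pearson(own, pred), 0.9999)
})

test_that("timeseries-mode and contrast-map-mode predictions agree closely", {
  co <- tiny_cohort()
  chains <- fit_chains_to_target(co, "sub01", method = "cha")
  rs <- vapply(c("faces", "objects"), function(cat_) {
    p_ts <- predicted_topography(co$localizers, chains, co$design,
                                 co$hrf, cat_, co$cortex_mask,
                                 mode = "timeseries")
    p_cm <- predicted_topography(co$localizers, chains, co$design,
                                 co$hrf, cat_, co$cortex_mask,
                                 mode = "contrast_map")
    map_pearson(p_ts, p_cm)
  }, numeric(1))
  expect_gte(mean(rs), 0.9)
})

test_that("noise-free localizers rank vertices like the planted tuning contrast", {
  co_nf <- fixture("noisefree_cohort", {
    make_cohort(n_subjects = 2, mesh_order = 3, master_seed = 55,
                localizer_noise_sd = 1e-3, n_localizer_runs = 2,
                n_timepoints = 100, n_movie_runs = 2)
  })
  mask <- co_nf$cortex_mask
  own <- own_topography(co_nf$localizers$sub01, co_nf$design, co_nf$hrf,
                        "faces", mask)
  # planted contrast, carried through the subject's misalignment
  tun <- co_nf$template$tuning
  contrast <- tun[, "faces"] - rowMeans(tun[, colnames(tun) != "faces"])
  nL <- n_vertices(co_nf$left_mesh)
  planted <- c(
    as.numeric(co_nf$subjects$sub01$R_left %*% contrast[seq_len(nL)]),
    as.numeric(co_nf$subjects$sub01$R_right %*% contrast[-seq_len(nL)]))
  rho <- stats::cor(own$values[mask], planted[mask], method = "spearman")
  expect_gte(rho, 0.99)
})
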