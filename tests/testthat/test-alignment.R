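test_that("orthogonal Procrustes recovers identity and planted rotations", {
  set.seed(21)
  A <- matrix(rnorm(4 * 12), 4)
  expect_equal(orthogonal_procrustes(A, A), diag(4), tolerance = 1e-8)
  G <- chalign:::.random_orthogonal(4)
  expect_equal(orthogonal_procrustes(A, G %*% A), G, tolerance = 1e-8)
})

test_that("the Procrustes solution is orthogonal and beats random orthogonal maps", {
  set.seed(22)
  for (rep in 1:20) {
    A <- matrix(rnorm(6 * 40), 6)
    G <- chalign:::.random_orthogonal(6)
    B <- G %*% A + matrix(rnorm(6 * 40, sd = 0.05), 6)
    R <- orthogonal_procrustes(A, B)
    expect_lt(max(abs(crossprod(R) - diag(6))), 1e-8)
    res <- norm(R %*% A - B, "F")
    for (q in 1:100) {
      Q <- chalign:::.random_orthogonal(6)
      expect_lte(res, norm(Q %*% A - B, "F") + 1e-10)
    }
  }
})

test_that("Procrustes rejects malformed input", {
  A <- matrix(rnorm(12), 3)
  expect_error(orthogonal_procrustes(A, t(A)),
               class = "chalign_invalid_argument")
  B <- A; B[1, 1] <- NA
  expect_error(orthogonal_procrustes(A, B),
               class = "chalign_invalid_argument")
})

test_that("self-alignment aggregates to a diagonal searchlight-count matrix", {
  mesh <- test_mesh(2, masked = TRUE)
  sl <- build_searchlight_set(mesh, radius_mm = 30)
  seeds <- cortex_indices(mesh)
  set.seed(23)
  vals <- matrix(rnorm(length(seeds) * 80), length(seeds))
  prof <- chalign:::.seed_pattern(vals, seeds, "left", "s1",
                                  n_vertices(mesh))
  M <- fit_searchlight_transform(prof, prof, sl)
  counts <- integer(n_vertices(mesh))
  for (m in sl$members) counts[m] <- counts[m] + 1L
  D <- as.matrix(M$values)
  expect_equal(unname(diag(D)), as.numeric(counts), tolerance = 1e-8)
  expect_lt(max(abs(D - diag(diag(D)))), 1e-8)
})

test_that("disjoint planted block rotations are recovered exactly", {
  mesh <- test_mesh(2)
  seeds <- cortex_indices(mesh)
  blocks <- split(seeds, rep(1:27, each = 6))
  sls <- manual_searchlights(blocks, n_vertices(mesh))
  set.seed(24)
  vals <- matrix(rnorm(length(seeds) * 60), length(seeds))
  Gs <- lapply(blocks, function(b) chalign:::.random_orthogonal(length(b)))
  tgt_vals <- vals
  for (k in seq_along(blocks)) {
    tgt_vals[blocks[[k]], ] <- Gs[[k]] %*% vals[blocks[[k]], ]
  }
  src <- chalign:::.seed_pattern(vals, seeds, "left", "s1",
                                 n_vertices(mesh))
  tgt <- chalign:::.seed_pattern(tgt_vals, seeds, "left", "s2",
                                 n_vertices(mesh))
  M <- fit_searchlight_transform(src, tgt, sls)
  for (k in seq_along(blocks)) {
    expect_equal(as.matrix(M$values[blocks[[k]], blocks[[k]]]),
                 Gs[[k]], tolerance = 1e-6, ignore_attr = TRUE)
  }
  # sparsity: nonzeros only where two vertices share a searchlight
  T_ <- methods::as(M$values, "TsparseMatrix")
  co <- matrix(FALSE, n_vertices(mesh), n_vertices(mesh))
  for (b in blocks) co[b, b] <- TRUE
  expect_true(all(co[cbind(T_@i + 1L, T_@j + 1L)]))
})

test_that("applying a transform matches the dense matrix-product oracle", {
  mesh <- test_mesh(2)
  nV <- n_vertices(mesh)
  set.seed(25)
  M_sparse <- Matrix::rsparsematrix(nV, nV, density = 0.05)
  M <- structure(
    list(source_subject = "a", target_subject = "b", hemisphere = "left",
         values = M_sparse, method = "CHA", step = 1L,
         alignment_radius_mm = 15),
    class = "transformation_matrix")
  ts <- zscore_runs(random_run_ts(40, nV, 2, seed = 26))
  out <- apply_transform(M, ts)
  dense <- ts$data %*% t(as.matrix(M_sparse))
  manual <- time_series(dense, ts$run_table)
  expect_equal(out$data, zscore_runs(manual)$data, tolerance = 1e-9)
  expect_identical(out$subject_id, "s1->b")
  expect_true(out$zscored)
})

test_that("identity and diagonal self-transforms preserve z-scored data", {
  co <- tiny_cohort()
  nL <- n_vertices(co$left_mesh); nR <- n_vertices(co$right_mesh)
  ts <- zscore_runs(co$movies$sub01$A)
  out <- apply_transform(identity_step(nL, nR), ts)
  expect_equal(out$data, ts$data, tolerance = 1e-12)
  # self CHA chain: per-vertex correlation 1 after re-z-scoring
  chain <- fit_iterative_cha(co$movies$sub01$A, co$movies$sub01$A,
                             cohort_step1_schedule(co),
                             co$left_mesh, co$right_mesh)
  W <- apply_chain(chain, ts)
  ok <- co$cortex_mask & !ts$degenerate
  r <- vapply(which(ok), function(v) cor(W$data[, v], ts$data[, v]),
              numeric(1))
  expect_gte(min(r), 0.999)
})

test_that("RHA demands time-locked runs and recovers planted blocks", {
  mesh <- test_mesh(2)
  nV <- n_vertices(mesh)
  src <- random_run_ts(60, 2 * nV, 2, seed = 27)
  short <- random_run_ts(40, 2 * nV, 2, seed = 28)
  sl <- build_searchlight_set(mesh, radius_mm = 30)
  expect_error(fit_rha_transform(src, short, sl, "left", mesh,
                                 n_left_vertices = nV),
               "same movie", class = "chalign_invalid_argument")

  # noise-free planted disjoint-block rotations on the left hemisphere
  seeds <- cortex_indices(mesh)
  blocks <- split(seeds, rep(1:27, each = 6))
  Gs <- lapply(blocks, function(b) chalign:::.random_orthogonal(length(b)))
  zsrc <- zscore_runs(src)
  tgt <- zsrc  # already flagged z-scored: the planted rotation is exact
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    tgt$data[, b] <- zsrc$data[, b] %*% t(Gs[[k]])
  }
  sls <- manual_searchlights(blocks, nV)
  M <- fit_rha_transform(zsrc, tgt, sls, "left", mesh,
                         n_left_vertices = nV)
  expect_identical(M$method, "RHA")
  for (k in seq_along(blocks)) {
    expect_equal(as.matrix(M$values[blocks[[k]], blocks[[k]]]),
                 Gs[[k]], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("a one-step schedule reproduces plain step-1 CHA exactly", {
  co <- tiny_cohort()
  sched <- cohort_step1_schedule(co)
  chain <- fit_iterative_cha(co$movies$sub01$A, co$movies$sub02$A, sched,
                             co$left_mesh, co$right_mesh)
  expect_length(chain$steps, 1L)
  # manual replay of step 1
  grid <- build_target_grid(co$left_mesh, co$right_mesh,
                            sched[[1]]$grid_order,
                            sched[[1]]$averaging_radius_mm)
  sls <- grid_averaging_searchlights(grid, co$left_mesh, co$right_mesh)
  al <- build_searchlight_set(co$left_mesh, radius_mm = 15)
  src <- zscore_runs(co$movies$sub01$A)
  tgt <- zscore_runs(co$movies$sub02$A)
  M <- fit_searchlight_transform(
    connectivity_profile(src, grid, sls, "left", co$left_mesh),
    connectivity_profile(tgt, grid, sls, "left", co$left_mesh), al)
  expect_identical(as.matrix(chain$steps[[1]]$left$values),
                   as.matrix(M$values))
})

test_that("chain application equals a manual two-pass replay", {
  co <- tiny_cohort()
  sched <- cha_schedule(list(2, 3), c(26, 13))
  chain <- fit_iterative_cha(co$movies$sub01$A, co$movies$sub02$A, sched,
                             co$left_mesh, co$right_mesh)
  expect_length(chain$steps, 2L)
  run <- co$localizers$sub01[[1]]
  out <- apply_chain(chain, zscore_runs(run))
  manual <- apply_transform(chain$steps[[2]],
                            apply_transform(chain$steps[[1]],
                                            zscore_runs(run)))
  expect_equal(out$data, manual$data, tolerance = 1e-12)
  # one-element chains behave as apply_transform
  ch1 <- chain; ch1$steps <- chain$steps[1]
  expect_equal(apply_chain(ch1, zscore_runs(run))$data,
               apply_transform(chain$steps[[1]], zscore_runs(run))$data,
               tolerance = 1e-12)
  # empty chains warn and return the z-scored input
  ch0 <- chain; ch0$steps <- list()
  expect_warning(same <- apply_chain(ch0, run), "empty")
  expect_equal(same$data, zscore_runs(run)$data, tolerance = 1e-12)
})

test_that("collapse_chain returns the ordered sparse product for inspection", {
  co <- tiny_cohort()
  sched <- cha_schedule(list(2, 3), c(26, 13))
  chain <- fit_iterative_cha(co$movies$sub01$A, co$movies$sub02$A, sched,
                             co$left_mesh, co$right_mesh)
  prod_ <- collapse_chain(chain)
  expect_equal(as.matrix(prod_$left),
               as.matrix(chain$steps[[2]]$left$values %*%
                           chain$steps[[1]]$left$values),
               tolerance = 1e-12)
})

test_that("transform chains tidy into per-step summaries", {
  co <- tiny_cohort()
  chain <- fit_iterative_cha(co$movies$sub01$A, co$movies$sub02$A,
                             cohort_step1_schedule(co),
                             co$left_mesh, co$right_mesh)
  td <- tidy(chain)
  expect_identical(nrow(td), 2L)  # one row per hemisphere
  expect_true(all(td$nnz > 0))
  gl <- glance(chain)
  expect_identical(gl$n_steps, 1L)
  expect_identical(gl$method, "CHA")
})
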