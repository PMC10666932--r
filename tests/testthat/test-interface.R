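test_that("the cohort container round-trips bitwise, including transforms", {
  co <- tiny_cohort()
  chains <- fit_chains_to_target(co, "sub01", method = "cha",
                                 source_ids = "sub02")
  path <- withr::local_tempfile(fileext = ".rds")
  write_cohort(co, path,
               transforms = list("sub02->sub01" = chains$sub02))
  back <- read_cohort(path)
  expect_identical(back$bundle$movies$sub01$A$data, co$movies$sub01$A$data)
  expect_identical(back$bundle$localizers$sub02[[1]]$data,
                   co$localizers$sub02[[1]]$data)
  expect_identical(back$bundle$manifest, co$manifest)
  # sparse transform triplets survive exactly
  M0 <- chains$sub02$steps[[1]]$left$values
  M1 <- back$transforms[["sub02->sub01"]]$steps[[1]]$left$values
  expect_identical(as.matrix(M0), as.matrix(M1))
})

test_that("containers with missing groups raise schema errors naming the group", {
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(schema = "chalign-container", subjects = list(),
               design = 1, manifest = 1), path)
  expect_error(read_cohort(path), "mesh",
               class = "chalign_invalid_argument")
  saveRDS(list(not = "a container"), path)
  expect_error(read_cohort(path), "schema")
})

test_that("GIFTI surfaces round-trip and reject malformed topology", {
  mesh <- test_mesh(2)
  path <- withr::local_tempfile(fileext = ".gii")
  write_gifti_surface(mesh, path)
  back <- read_gifti_surface(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-4)
  expect_identical(back$faces, mesh$faces)
  expect_identical(back$hemisphere, "left")
  expect_identical(back$subdivision_order, 2L)
  # vertices land exactly on the nominal sphere after rescaling
  expect_lt(max(abs(sqrt(rowSums(back$vertices^2)) - 100)), 1e-4)
  # triangle indices out of range are rejected
  g <- read_gifti(path)
  bad <- mesh
  bad$faces[1, 1] <- n_vertices(mesh) + 5L
  path2 <- withr::local_tempfile(fileext = ".gii")
  write_gifti_surface(bad, path2)
  expect_error(read_gifti_surface(path2), "out of range",
               class = "chalign_invalid_argument")
})

test_that("contrast maps round-trip through GIFTI with metadata and mask", {
  co <- tiny_cohort()
  own <- own_topography(co$localizers$sub01, co$design, co$hrf, "faces",
                        co$cortex_mask)
  path <- withr::local_tempfile(fileext = ".gii")
  write_gifti_map(own, path)
  back <- read_gifti_map(path)
  expect_s3_class(back, "contrast_map")
  expect_identical(back$category, "faces")
  expect_identical(back$provenance, "own")
  keep <- co$cortex_mask
  expect_equal(back$values[keep], own$values[keep], tolerance = 1e-4)
  expect_true(all(is.na(back$values[!keep])))
  expect_error(read_gifti_map(path, expected_n_vertices = 99),
               class = "chalign_invalid_argument")
})

test_that("time series round-trip through GIFTI with run boundaries intact", {
  ts <- random_run_ts(20, 30, n_runs = 2, seed = 61)
  path <- withr::local_tempfile(fileext = ".gii")
  write_gifti_timeseries(ts, path)
  back <- read_gifti_timeseries(path, expected_n_vertices = 30)
  expect_equal(back$data, ts$data, tolerance = 1e-5)
  expect_identical(back$run_table$run_id, ts$run_table$run_id)
  expect_identical(back$run_table$n_timepoints, ts$run_table$n_timepoints)
  expect_identical(back$subject_id, ts$subject_id)
})

test_that("ASCII-encoded GIFTI and text masks are readable", {
  vals <- c(0.5, -1.25, 3, 0)
  path <- withr::local_tempfile(fileext = ".gii")
  write_gifti(list(list(intent = "NIFTI_INTENT_NONE", data = vals,
                        datatype = "NIFTI_TYPE_FLOAT32")),
              path, encoding = "ASCII")
  g <- read_gifti(path)
  expect_equal(as.numeric(g$arrays[[1]]$data), vals, tolerance = 1e-12)
  mask_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "0", "1", "1"), mask_path)
  expect_identical(read_cortex_mask(mask_path),
                   c(TRUE, FALSE, TRUE, TRUE))
  gmask <- withr::local_tempfile(fileext = ".gii")
  write_gifti(list(list(intent = "NIFTI_INTENT_SHAPE",
                        data = c(1, 1, 0, 1),
                        datatype = "NIFTI_TYPE_UINT8")), gmask)
  expect_identical(read_cortex_mask(gmask), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("run configs resolve defaults, reject unknown keys, and echo stably", {
  cfg_file <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("[simulate]", "n_subjects = 4", "mesh_order = 3",
               "# a comment", "movie_noise_sd = 0.5"), cfg_file)
  cfg <- parse_run_config(cfg_file)
  expect_identical(cfg$n_subjects, 4L)
  expect_identical(cfg$movie_noise_sd, 0.5)
  expect_identical(cfg$n_localizer_runs, 4L)  # default echoed
  expect_identical(parse_run_config(cfg_file), cfg)
  writeLines("no_such_key = 1", cfg_file)
  expect_error(parse_run_config(cfg_file), "unknown",
               class = "chalign_config_error")
  writeLines("n_subjects = many", cfg_file)
  expect_error(parse_run_config(cfg_file), "integer",
               class = "chalign_config_error")
  expect_error(parse_run_config(overrides = list(steps = "soon")),
               class = "chalign_config_error")
})

test_that("schedule files parse into alignment schedules", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# step table", "2 26 15", "3 13 15", "full NA 15"), path)
  sched <- read_schedule_file(path)
  expect_length(sched, 3L)
  expect_identical(sched[[1]]$grid_order, 2L)
  expect_identical(sched[[3]]$grid_order, "full")
  expect_identical(sched[[2]]$averaging_radius_mm, 13)
})

test_that("the CLI runs the pipeline end to end on a toy cohort", {
  out <- withr::local_tempdir()
  cfg <- file.path(out, "toy.cfg")
  writeLines(c("n_subjects = 3", "mesh_order = 3", "n_timepoints = 120",
               "n_movie_runs = 2", "n_localizer_runs = 2",
               paste0("out_dir = ", out)), cfg)
  expect_identical(suppressMessages(
    cha_cli(c("simulate", "--config", cfg, "--seed", "5"))), 0L)
  expect_true(file.exists(file.path(out, "cohort.rds")))
  expect_identical(suppressMessages(
    cha_cli(c("align", "--config", cfg, "--method", "cha",
              "--steps", "1"))), 0L)
  expect_identical(suppressMessages(
    cha_cli(c("predict", "--config", cfg, "--baseline-aa",
              "--category", "faces"))), 0L)
  expect_identical(suppressMessages(
    cha_cli(c("evaluate", "--config", cfg))), 0L)
  expect_true(file.exists(file.path(out, "report.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  rec <- utils::read.delim(file.path(out, "report.tsv"))
  expect_identical(sort(unique(rec$method)), c("AA", "CHA"))
  expect_identical(nrow(rec), 6L)  # 3 subjects x 1 category x 2 methods
  expect_identical(suppressMessages(
    cha_cli(c("report", "--config", cfg))), 0L)
})

test_that("the CLI rejects invalid invocations with the documented exit codes", {
  out <- withr::local_tempdir()
  # cross-movie RHA violates the same-stimulus restriction: config error
  msgs <- capture.output(
    code <- cha_cli(c("align", "--method", "rha", "--cross-movie", "A:B",
                      "--out-dir", out)),
    type = "message")
  expect_identical(code, 2L)
  expect_true(any(grepl("same movie", msgs)))
  # predict before align: runtime error naming the transforms group
  cfg <- file.path(out, "toy.cfg")
  writeLines(c("n_subjects = 2", "mesh_order = 3", "n_timepoints = 60",
               "n_movie_runs = 1", "n_localizer_runs = 2",
               paste0("out_dir = ", out)), cfg)
  expect_identical(suppressMessages(
    cha_cli(c("simulate", "--config", cfg))), 0L)
  msgs <- capture.output(
    code <- cha_cli(c("predict", "--config", cfg)), type = "message")
  expect_identical(code, 1L)
  expect_true(any(grepl("transforms", msgs)))
  # unknown flags and subcommands give usage + exit 2
  expect_identical(suppressMessages(cha_cli(c("align", "--nope", "1"))),
                   2L)
  expect_identical(suppressMessages(cha_cli("frobnicate")), 2L)
})

test_that("identical configs and seeds reproduce identical containers", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  for (out in c(out1, out2)) {
    suppressMessages(cha_cli(c(
      "simulate", "--out-dir", out, "--seed", "9", "--n-subjects", "2",
      "--mesh-order", "3", "--n-timepoints", "60", "--n-movie-runs", "1",
      "--n-localizer-runs", "2")))
  }
  a <- read_cohort(file.path(out1, "cohort.rds"))
  b <- read_cohort(file.path(out2, "cohort.rds"))
  expect_identical(a$bundle$movies$sub01$A$data,
                   b$bundle$movies$sub01$A$data)
  expect_identical(a$bundle$localizers$sub02[[2]]$data,
                   b$bundle$localizers$sub02[[2]]$data)
})
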