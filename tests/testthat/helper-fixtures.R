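# Shared fixtures, memoized so expensive objects are built once per session.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_mesh <- function(order, masked = FALSE) {
  fixture(sprintf("mesh_%d_%s", order, masked), {
    m <- build_icosphere(order)
    if (masked) m <- apply_polar_cap_mask(m, c(1, 0, 0), 30)
    m
  })
}

# Small default-condition cohort for unit tests (3 subjects, short movies).
tiny_cohort <- function() {
  fixture("tiny_cohort", {
    make_cohort(n_subjects = 3, mesh_order = 3, master_seed = 101,
                n_timepoints = 150, n_movie_runs = 2, n_localizer_runs = 2)
  })
}

# Independent haversine great-circle oracle (lat/lon formulation).
haversine_distance <- function(mesh, i, j) {
  V <- mesh$vertices
  lat <- asin(V[, 3] / mesh$nominal_radius_mm)
  lon <- atan2(V[, 2], V[, 1])
  a <- sin((lat[j] - lat[i]) / 2)^2 +
    cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
  2 * mesh$nominal_radius_mm * asin(pmin(1, sqrt(a)))
}

random_run_ts <- function(n_tp, n_v, n_runs = 2, seed = 1,
                          subject_id = "s1") {
  set.seed(seed)
  time_series(matrix(rnorm(n_tp * n_v), n_tp, n_v),
              data.frame(run_id = paste0("r", seq_len(n_runs)),
                         n_timepoints = rep(n_tp / n_runs, n_runs)),
              subject_id = subject_id)
}

# A searchlight_set built directly from a membership list (for planted
# disjoint-block constructions).
manual_searchlights <- function(members, n_vertices,
                                hemisphere = "left", radius_mm = 10) {
  structure(
    list(radius_mm = radius_mm,
         centers = vapply(members, `[`, integer(1), 1),
         members = members, n_vertices = n_vertices,
         hemisphere = hemisphere),
    class = "searchlight_set"
  )
}
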