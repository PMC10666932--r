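.run_config_defaults <- function() {
  list(
    out_dir = ".",
    seed = 42L,
    n_subjects = 10L, mesh_order = 3L, n_latents = 20L,
    bump_width_mm = 20, bumps_per_map = 10L, patch_order = 2L,
    max_rotation_deg = 60, movie_noise_sd = 1, localizer_noise_sd = 1,
    n_timepoints = 300L, n_movie_runs = 3L, n_localizer_runs = 4L,
    cap_angle_deg = 30,
    method = "cha", mode = "timeseries", steps = 1L,
    schedule = "", cross_movie = "", pair = "", category = "",
    baseline_aa = FALSE,
    log_level = "info", jobs = 1L
  )
}

.config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("chalign_config_error",
                                             "error")))
}

#' Parse a run configuration
#'
#' Plain-text `key = value` configuration with optional `[section]`
#' headers (sections are organizational only; keys are global). Unknown
#' keys are errors. The returned config echoes every resolved default, so
#' dumping it re-runs to identical results.
#'
#' @param path Optional config file path.
#' @param overrides Named list of command-line overrides applied after the
#'   file.
#' @return A named list of class `run_config` with all defaults resolved.
#' @export
parse_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .run_config_defaults()
  from_file <- list()
  if (!is.null(path) && nzchar(path)) {
    if (!file.exists(path)) .config_error("config file not found: ", path)
    for (line in readLines(path, warn = FALSE)) {
      line <- sub("[#;].*$", "", line)
      line <- trimws(line)
      if (!nzchar(line) || grepl("^\\[.*\\]$", line)) next
      if (!grepl("=", line, fixed = TRUE)) {
        .config_error("malformed config line: '", line, "'")
      }
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      from_file[[key]] <- val
    }
  }
  apply_kv <- function(cfg, kv, origin) {
    for (key in names(kv)) {
      k <- gsub("-", "_", key)
      if (!k %in% names(cfg)) {
        .config_error("unknown ", origin, " key: '", key, "'")
      }
      proto <- .run_config_defaults()[[k]]
      v <- kv[[key]]
      cfg[[k]] <- if (is.logical(proto)) {
        if (is.logical(v)) v else
          tolower(as.character(v)) %in% c("1", "true", "yes")
      } else if (is.integer(proto)) {
        iv <- suppressWarnings(as.integer(v))
        if (is.na(iv)) .config_error("key '", key, "' needs an integer")
        iv
      } else if (is.numeric(proto)) {
        nv <- suppressWarnings(as.numeric(v))
        if (is.na(nv)) .config_error("key '", key, "' needs a number")
        nv
      } else as.character(v)
    }
    cfg
  }
  cfg <- apply_kv(cfg, from_file, "config")
  cfg <- apply_kv(cfg, overrides, "option")
  class(cfg) <- "run_config"
  cfg
}

# Stable short hash of the resolved configuration, for the run log.
.config_hash <- function(cfg) {
  .child_seed(0L, paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 17), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %s = %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read an alignment schedule from a whitespace-delimited text file
#'
#' One step per line: `grid_order averaging_radius_mm alignment_radius_mm`
#' (`full`/`NA` allowed for the last vertex-wise step).
#'
#' @param path Text file path.
#' @return An [alignment_schedule][cha_schedule].
#' @export
read_schedule_file <- function(path) {
  .assert(file.exists(path), "schedule file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  .assert(length(lines) >= 1, "empty schedule file")
  parts <- strsplit(lines, "\\s+")
  orders <- lapply(parts, function(p) {
    if (tolower(p[1]) == "full") "full" else as.integer(p[1])
  })
  avg <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])),
                numeric(1))
  align <- vapply(parts, function(p)
    if (length(p) >= 3) as.numeric(p[3]) else 15, numeric(1))
  cha_schedule(orders, avg, align)
}

# Desk-scale schedule with the requested number of steps: coarse grids
# first, the mesh's own order next, vertex-wise targets last.
.schedule_for_steps <- function(mesh_order, n_steps) {
  if (n_steps == 1) return(cha_schedule(list(mesh_order), 13))
  orders <- c(as.list(rep(mesh_order - 1L, max(0L, n_steps - 2L))),
              list(mesh_order, "full"))
  avg <- c(rep(13 * 2^(3 - (mesh_order - 1)), max(0L, n_steps - 2L)),
           13 * 2^(3 - mesh_order), NA)
  cha_schedule(orders, avg)
}
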