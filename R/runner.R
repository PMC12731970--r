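#' End-to-end pipeline runner
#'
#' `cmd_simulate()` replays a full study synthetically: it generates a
#' calibrated cohort through the render-and-measure pipeline, writes the
#' per-task metric records as CSV, runs the group-comparison battery, and
#' writes a JSON report plus a run manifest sufficient to reproduce the
#' run bit-for-bit. `cmd_measure()` is the standalone measurement stage:
#' it scores a directory of labelled screenshot PNGs.
#'
#' @name runner
NULL

#' Simulate a full cohort study
#'
#' @param out_dir output directory (created if missing).
#' @param config NULL for the built-in calibrated specification, a path to
#'   a cohort YAML, or a [cohort_spec()].
#' @param seed master seed; overrides the spec's seed.
#' @param groups optional subset of groups.
#' @param n_per_group optional named vector overriding cohort sizes.
#' @param screenshots write one labelled screenshot PNG per task
#'   (default FALSE).
#' @param analyze run [analyze_cohort()] and write the JSON/CSV report
#'   (default TRUE; needs >= 2 groups).
#' @param ks_reps Monte-Carlo replicates for the normality screen.
#' @return invisibly, a list with the records, the report (or NULL) and
#'   the written paths.
#' @export
cmd_simulate <- function(out_dir, config = NULL, seed = 1, groups = NULL,
                         n_per_group = NULL, screenshots = FALSE,
                         analyze = TRUE, ks_reps = 2000) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  spec <- if (is.null(config)) {
    calibrated_cohort_spec(seed = seed, groups = groups %||% GROUP_LEVELS)
  } else if (is.character(config)) {
    read_cohort_yaml(config, seed = seed, groups = groups)
  } else if (inherits(config, "cohort_spec")) {
    config
  } else stop("invalid config: need NULL, a YAML path or a cohort_spec")
  spec$seed <- as.integer(seed)
  if (!is.null(n_per_group)) {
    keep <- intersect(names(spec$profiles), names(n_per_group))
    spec$n_per_group[keep] <- as.integer(n_per_group[keep])
  }

  records <- generate_cohort(spec, keep_screenshots = screenshots)

  csv_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(records, csv_path, row.names = FALSE)
  paths <- c(metrics = csv_path)

  if (screenshots) {
    shots <- attr(records, "screenshots")
    shot_dir <- file.path(out_dir, "screenshots")
    dir.create(shot_dir, showWarnings = FALSE)
    for (i in seq_along(shots)) {
      nm <- sprintf("%s_task%d_tooth%d.png", records$participant_id[i],
                    records$task_index[i], records$tooth[i])
      write_screenshot_png(shots[[i]], file.path(shot_dir, nm))
    }
    paths <- c(paths, screenshots = shot_dir)
  }

  report <- NULL
  if (analyze && length(unique(records$group)) >= 2) {
    report <- analyze_cohort(records, ks_reps = ks_reps, seed = seed)
    write_report(report, json_path = file.path(out_dir, "report.json"),
                 csv_path = file.path(out_dir, "report.csv"))
    paths <- c(paths, report = file.path(out_dir, "report.json"))
  }

  manifest <- list(
    seed = spec$seed,
    groups = names(spec$profiles),
    n_per_group = as.list(spec$n_per_group),
    trials = spec$trials,
    camera = spec$camera,
    n_records = nrow(records),
    config_hash = fnv1a_hash(spec),
    package_version = as.character(utils::packageVersion("mirrorsim")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, manifest = file.path(out_dir, "manifest.json"))

  invisible(list(records = records, report = report, paths = paths))
}

# 32-bit FNV-1a over the JSON serialisation of an object.
fnv1a_hash <- function(obj) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass_deep(obj), auto_unbox = TRUE,
                                      digits = NA))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Measure a set of labelled screenshot PNGs
#'
#' One metric row per readable image; unreadable or format-violating files
#' are reported as warnings and skipped (the run continues). Time and
#' validity are absent (NA) for measurement-only records.
#'
#' @param paths character vector of PNG paths (or a directory, which is
#'   expanded to its `*.png` files).
#' @param out_csv optional output CSV path.
#' @param dm_diameter_mm calibration mirror diameter (default 20 mm).
#' @return data.frame of metric rows (one per successful image), with a
#'   `file` column.
#' @export
cmd_measure <- function(paths, out_csv = NULL, dm_diameter_mm = 20) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.png$", full.names = TRUE)
  rows <- list()
  for (p in paths) {
    rec <- tryCatch({
      ss <- read_screenshot_png(p)
      m <- measure(ss, dm_diameter_mm)
      r <- make_record(group = NA_character_, participant = NA_character_,
                       trial = NA_integer_, task_index = NA_integer_,
                       tooth = NA_integer_, m = m)
      r$file <- p
      r
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", p, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out_csv) && !is.null(out))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
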