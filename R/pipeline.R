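#' Write / read a surface grid as delimited text
#'
#' Plain-text grid format: one header line `# rows cols pitch_um`, then the
#' height matrix as whitespace-delimited numbers.
#'
#' @param profile A [height_profile()].
#' @param file Path to write to / read from.
#' @return `read_surface_grid` returns a [height_profile()];
#'   `write_surface_grid` returns `file` invisibly.
#' @export
write_surface_grid <- function(profile, file) {
  stopifnot(inherits(profile, "height_profile"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %.10g", nrow(profile$heights),
                     ncol(profile$heights), profile$pixel_pitch), con)
  write.table(profile$heights, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_surface_grid
#' @export
read_surface_grid <- function(file) {
  hdr <- strsplit(sub("^#\\s*", "", readLines(file, n = 1)), "\\s+")[[1]]
  hdr <- as.numeric(hdr)
  m <- as.matrix(read.table(file, skip = 1))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == hdr[1], ncol(m) == hdr[2])
  height_profile(m, hdr[3])
}

#' Write / read a trajectory trace as delimited text plus JSON sidecar
#'
#' The trace table (`time_s`, `position_deg`) is written tab-delimited; the
#' context labels, air flag, texture label and ground-truth event list (if
#' present) go to `<file>.json`.
#'
#' @param trace A [trajectory_trace()].
#' @param file Path of the trace table.
#' @return `read_trace` returns a [trajectory_trace()] (with `truth`
#'   attribute when stored); `write_trace` returns `file` invisibly.
#' @export
write_trace <- function(trace, file) {
  stopifnot(inherits(trace, "trajectory_trace"))
  write.table(data.frame(time_s = trace$time, position_deg = trace$position),
              file, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(context = unclass(trace$context), is_air = trace$is_air,
               texture = trace$texture)
  tru <- attr(trace, "truth")
  if (!is.null(tru)) side$truth <- tru
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  ctx <- sweep_context(whisker_id = side$context$whisker_id,
                       driving_speed = side$context$driving_speed,
                       distance = side$context$distance,
                       sample_rate = side$context$sample_rate,
                       sweep_angle = side$context$sweep_angle)
  tr <- trajectory_trace(tab$time_s, tab$position_deg, ctx,
                         is_air = isTRUE(side$is_air),
                         texture = if (is.null(side$texture)) NA_character_
                                   else side$texture)
  if (!is.null(side$truth)) {
    attr(tr, "truth") <- as.data.frame(side$truth)
  }
  tr
}

#' Serialize a dataset to a directory
#'
#' Surfaces as one grid file per texture, sweeps and air controls as
#' trace tables with JSON sidecars (including ground-truth slip lists), and
#' a `manifest.json` with the master seed and design.
#'
#' @param dataset A `slip_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "slip_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tx in names(dataset$surfaces)) {
    write_surface_grid(dataset$surfaces[[tx]],
                       file.path(dir, sprintf("surface_%s.txt", tx)))
  }
  for (k in seq_along(dataset$sweeps)) {
    write_trace(dataset$sweeps[[k]],
                file.path(dir, sprintf("sweep_%05d.tsv", k)))
  }
  for (k in seq_along(dataset$air)) {
    write_trace(dataset$air[[k]], file.path(dir, sprintf("air_%04d.tsv", k)))
  }
  manifest <- list(
    seed = dataset$seed, n_cycles = dataset$n_cycles,
    textures = lapply(dataset$textures, unclass),
    slip_models = lapply(dataset$slip_models, unclass),
    contexts = lapply(dataset$contexts, unclass))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Default pipeline configuration
#'
#' All defaults mirror the standard measurement protocol: 4000 samples/s,
#' 60 degree sweeps, 15 ms start trim, 2*SD air criterion, 30-250 Hz pass
#' band, 100 cycles per condition and perceptual blur thresholds 36 Hz /
#' 450 deg/s / 23600 deg/s^2.
#'
#' @param master_seed Integer master seed.
#' @param n_cycles Sweeps per texture x context.
#' @param speeds Driving speeds, deg/s.
#' @param whisker Whisker label.
#' @param distance Distance class.
#' @return A config list for [run_pipeline()].
#' @export
default_config <- function(master_seed = 1L, n_cycles = 100L,
                           speeds = c(600, 1200, 1800), whisker = "B",
                           distance = "H") {
  list(master_seed = as.integer(master_seed),
       textures = preset_textures(),
       slip_models = preset_slip_models(),
       contexts = lapply(speeds, function(sp) {
         sweep_context(whisker_id = whisker, driving_speed = sp,
                       distance = distance)
       }),
       n_cycles = as.integer(n_cycles), n_air = 20L,
       cut_ms = 15, k_threshold = 2,
       auc_variables = c("f", "i", "sv", "sa", "sr"),
       blur = blur_spec(), blur_fractions = c(1, 0.5, 0.3))
}

#' Run the full texture-coding pipeline
#'
#' Synthetic generation, surface statistics, kinematics and feature
#' extraction, pairwise AUC discriminability with neighboring-pair averages,
#' and the blurred classification tasks; optionally writes all tables and a
#' JSON manifest to `out_dir`.
#'
#' @param config Configuration list from [default_config()].
#' @param out_dir Optional output directory.
#' @param classify Run the (comparatively slow) classification stage
#'   (default `TRUE`).
#' @return List with `dataset`, `surface_summaries`, `features`, `auc`
#'   (tidy data.frame), `neighbor` (per-variable folded/raw means),
#'   `scores` (classification results or `NULL`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         classify = TRUE) {
  ds <- make_dataset(textures = config$textures,
                     slip_models = config$slip_models,
                     contexts = config$contexts,
                     n_cycles = config$n_cycles, n_air = config$n_air,
                     seed = config$master_seed)
  surf <- lapply(ds$surfaces, function(p) surface_summary(clean_profile(p)))
  feats <- build_feature_table(ds, cut_ms = config$cut_ms,
                               k = config$k_threshold)
  auc_tab <- do.call(rbind, lapply(config$auc_variables, function(v) {
    pairwise_auc(feats, v)
  }))
  nb <- NULL
  if (all(names(preset_textures()) %in% names(config$textures))) {
    nb <- lapply(setNames(nm = config$auc_variables), function(v) {
      neighbor_average(auc_tab[auc_tab$variable == v, ])
    })
  }
  scores <- NULL
  if (classify) {
    scores <- run_tasks(feats, blur_fractions = config$blur_fractions,
                        seed = child_seed(config$master_seed, 999L),
                        spec = config$blur)
  }
  res <- list(dataset = ds, surface_summaries = surf, features = feats,
              auc = auc_tab, neighbor = nb, scores = scores)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(feats$sweeps, file.path(out_dir, "features.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(feats$events)) {
      write.table(feats$events, file.path(out_dir, "events.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write.table(auc_tab, file.path(out_dir, "auc.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(scores)) {
      write.table(scores, file.path(out_dir, "scores.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest <- list(master_seed = config$master_seed,
                     n_cycles = config$n_cycles,
                     n_sweeps = length(ds$sweeps),
                     thresholds = as.list(feats$thresholds),
                     correlation_lengths = lapply(surf, `[[`,
                                                  "correlation_length"),
                     package_version = as.character(
                       utils::packageVersion("slipcode")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
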