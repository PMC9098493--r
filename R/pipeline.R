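default_config <- function() {
  list(seed = 1,
       # synthetic scene
       rows = 128, cols = 128, n_condensates = 3, condensate_radius = 4,
       fold = 5, background_level = 200, nucleoplasm_level = 2000,
       noise_sd = 100,
       # segmentation + stats
       k_sigma = 3, min_area = 4, min_nucleus_area = 50,
       size_threshold = 0.75, intensity_mode = "mean", pixel_size = NA,
       # light cycles
       on_s = 600, off_s = 600, n_cycles = 2, frame_interval = 60,
       k_on = 1 / 60, k_off = 1 / 60, fold_max = 5, residual = 0,
       # FRAP
       bleach_index = NA,
       # assays
       chip_convention = "paper", lumin_mode = "first_then_max",
       window_start = NA, window_end = NA)
}

#' Assemble a pipeline configuration
#'
#' Merges user settings over the package defaults; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param config named list (e.g. from [read_pipeline_config()]).
#' @return complete configuration list.
#' @export
pipeline_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop_with("config_error", "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  modifyList(base, config)
}

cycle_schedule_from <- function(cfg)
  light_schedule(rep(c(cfg$on_s, cfg$off_s), cfg$n_cycles),
                 rep(c("on", "off"), cfg$n_cycles))

scene_from <- function(cfg, seed) {
  dim <- c(cfg$rows, cfg$cols)
  scene_truth(dim = dim,
              condensates = disk_condensates(cfg$n_condensates,
                                             radius = cfg$condensate_radius,
                                             fold = cfg$fold, dim = dim),
              background_level = cfg$background_level,
              nucleoplasm_level = cfg$nucleoplasm_level,
              noise_sd = cfg$noise_sd, seed = seed)
}

#' Run a pipeline stage
#'
#' Dispatches one of the named subcommands, reads its inputs, writes its
#' artifacts into `out_dir` and appends a `run.log` recording the command,
#' seed, configuration and package version, so every run is reproducible
#' from its log.
#'
#' \describe{
#'   \item{`simulate`}{renders a synthetic condensate scene: `image.tif` +
#'     ground-truth sidecar `truth.csv` (frame, center_row, center_col,
#'     radius_px, fold).}
#'   \item{`quantify`}{segments every frame of `input` (TIFF) and writes
#'     `condensates.csv` (per-region measurements) and `stats.csv`
#'     (per-frame statistics).}
#'   \item{`frap`}{normalizes the FRAP trace in `input` (CSV, see
#'     [read_frap_csv()]) and fits the recovery: `normalized.csv` +
#'     `frap_fit.txt`.}
#'   \item{`cycles`}{computes the partition-ratio trajectory of the stack in
#'     `input` under the configured on/off schedule: `trajectory.csv` +
#'     `reversibility.csv`.}
#'   \item{`chip`}{adds adjusted-input and IP/Input columns to the Ct table
#'     in `input`: `chip_enrichment.csv`.}
#'   \item{`lumin`}{normalizes the luminescence table in `input` (columns
#'     `time_h`, then one per replicate): `lumin_normalized.csv`.}
#' }
#'
#' @param command one of `"simulate"`, `"quantify"`, `"frap"`, `"cycles"`,
#'   `"chip"`, `"lumin"`.
#' @param config named list of settings (see [pipeline_config()]) or a path
#'   to a `key: value` config file.
#' @param input input file (TIFF or CSV), where the command takes one.
#' @param out_dir output directory, created if needed.
#' @param seed overrides the config's seed.
#' @return invisibly, a list of the artifacts written (paths) and the main
#'   result object.
#' @export
run_pipeline <- function(command, config = list(), input = NULL,
                         out_dir = ".", seed = NULL) {
  command <- match.arg(command, c("simulate", "quantify", "frap", "cycles",
                                  "chip", "lumin"))
  config_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- read_pipeline_config(config)
  }
  cfg <- pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)

  result <- switch(command,
    simulate = {
      scene <- scene_from(cfg, seed = cfg$seed)
      img <- generate_condensate_image(scene)
      write_image_stack(img$image, out("image.tif"))
      truth <- cbind(frame = 1L,
                     data.frame(center_row = scene$condensates$row,
                                center_col = scene$condensates$col,
                                radius_px = scene$condensates$radius,
                                fold = scene$condensates$fold))
      write.csv(truth, out("truth.csv"), row.names = FALSE)
      list(artifacts = c(out("image.tif"), out("truth.csv")), value = img)
    },
    quantify = {
      frames <- read_image_stack(input)
      csets <- vector("list", length(frames))
      rows <- list()
      for (i in seq_along(frames)) {
        mask <- segment_nucleus(frames[[i]],
                                min_nucleus_area = cfg$min_nucleus_area)
        cs <- detect_condensates(frames[[i]], mask, k_sigma = cfg$k_sigma,
                                 min_area = cfg$min_area,
                                 context = "in_vivo")
        csets[[i]] <- cs
        if (cs$n)
          rows[[length(rows) + 1L]] <-
            cbind(frame_index = i, cs$regions,
                  nucleus_area_px = cs$nucleus_area,
                  nucleus_mean = cs$nucleus_mean_intensity,
                  background_mean = cs$background_mean_intensity,
                  context = cs$context)
      }
      cond <- if (length(rows)) do.call(rbind, rows) else
        data.frame(frame_index = integer(), label = integer(),
                   area = numeric(), perimeter = numeric(),
                   mean_intensity = numeric(), centroid_row = numeric(),
                   centroid_col = numeric(), nucleus_area_px = numeric(),
                   nucleus_mean = numeric(), background_mean = numeric(),
                   context = character())
      names(cond)[names(cond) == "area"] <- "area_px"
      names(cond)[names(cond) == "perimeter"] <- "perimeter_px"
      write.csv(cond, out("condensates.csv"), row.names = FALSE)
      stats <- condensate_stats_table(csets,
                                      size_threshold = cfg$size_threshold,
                                      intensity_mode = cfg$intensity_mode)
      write.csv(stats, out("stats.csv"), row.names = FALSE)
      list(artifacts = c(out("condensates.csv"), out("stats.csv")),
           value = stats)
    },
    frap = {
      trace <- read_frap_csv(input)
      norm <- normalize_frap(trace)
      write.csv(data.frame(time_s = norm$times,
                           normalized_intensity = norm$intensity),
                out("normalized.csv"), row.names = FALSE)
      fit <- if (is.na(cfg$bleach_index)) fit_recovery(norm)
             else fit_recovery(norm, bleach_index = cfg$bleach_index)
      writeLines(sprintf("%s: %.10g",
                         c("mobile_fraction", "rate_per_s", "half_time_s",
                           "f0", "plateau", "residual_sd"),
                         c(fit$mobile_fraction, fit$rate, fit$half_time,
                           fit$f0, fit$plateau, fit$residual_sd)),
                 out("frap_fit.txt"))
      list(artifacts = c(out("normalized.csv"), out("frap_fit.txt")),
           value = fit)
    },
    cycles = {
      frames <- read_image_stack(input)
      sched <- cycle_schedule_from(cfg)
      times <- (seq_along(frames) - 1) * cfg$frame_interval
      traj <- cycle_trajectory(frames, times, sched, k_sigma = cfg$k_sigma,
                               min_area = cfg$min_area,
                               min_nucleus_area = cfg$min_nucleus_area)
      write.csv(traj, out("trajectory.csv"), row.names = FALSE)
      rev <- do.call(rbind, lapply(unique(traj$cycle), function(cy) {
        idx <- tryCatch(reversibility_index(traj, cycle = cy),
                        error = function(e) NA_real_)
        data.frame(cycle = cy, reversibility_index = idx)
      }))
      write.csv(rev, out("reversibility.csv"), row.names = FALSE)
      list(artifacts = c(out("trajectory.csv"), out("reversibility.csv")),
           value = traj)
    },
    chip = {
      tab <- read_table_csv(input, c("region", "raw_input_ct", "sample_ct",
                                     "aliquot_fraction"))
      res <- chip_enrichment(tab, convention = cfg$chip_convention)
      write.csv(res, out("chip_enrichment.csv"), row.names = FALSE)
      list(artifacts = out("chip_enrichment.csv"), value = res)
    },
    lumin = {
      tab <- read_table_csv(input, "time_h")
      counts <- as.matrix(tab[setdiff(names(tab), "time_h")])
      norm <- normalize_luminescence(counts, mode = cfg$lumin_mode)
      res <- cbind(data.frame(time_h = tab$time_h), as.data.frame(norm))
      write.csv(res, out("lumin_normalized.csv"), row.names = FALSE)
      list(artifacts = out("lumin_normalized.csv"), value = res)
    })

  log_lines <- c(
    sprintf("command: %s", command),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %s", format(cfg$seed)),
    sprintf("package_version: %s", as.character(packageVersion("photobodykit"))),
    if (!is.null(config_path))
      sprintf("config_md5: %s", unname(tools::md5sum(config_path))),
    if (!is.null(input)) sprintf("input: %s", input),
    sprintf("config.%s: %s", names(cfg), vapply(cfg, format, character(1))))
  cat(paste0(log_lines, "\n"), file = out("run.log"), append = TRUE, sep = "")
  invisible(result)
}
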