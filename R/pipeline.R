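# End-to-end orchestration: one entry point over the whole pipeline, driven
# by a flat config (list or YAML file). Every run writes a log with the
# package version, seed, and parameter echo; all randomness flows from the
# single `seed` argument.

pipeline_subcommands <- c("simulate", "actin", "uptake", "eu", "closure", "report")

# pixel size for a manifest row: per-row column beats run config; NULL lets
# load_image() fall back to the image's JSON sidecar
manifest_pixel_size <- function(row, config) {
  if ("pixel_size_um" %in% names(row)) row[["pixel_size_um"]] else config$pixel_size_um
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) rlang::abort(sprintf("No such config file: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) rlang::abort("`config` must be a list or a YAML file path.")
  config
}

check_config_keys <- function(config, allowed, subcommand) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("Unknown config key(s) for '%s': %s (allowed: %s)",
                         subcommand, paste(unknown, collapse = ", "),
                         paste(allowed, collapse = ", ")))
  }
}

write_run_log <- function(out_dir, subcommand, seed, config) {
  log <- list(
    package = "epiwound",
    version = as.character(utils::packageVersion("epiwound")),
    subcommand = subcommand, seed = seed, timestamp = format(Sys.time()),
    config = config)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run a pipeline stage
#'
#' One flat config per run; explicit arguments override config entries.
#' Subcommands: `simulate` (all synthetic generators, with ground truth and
#' sidecars), `actin` (profiles -> ratios -> per-animal table), `uptake`
#' (image pairs -> particles per nucleus -> per-animal means), `eu`
#' (positive-fraction scoring), `closure` (area series -> percent curves ->
#' per-timepoint group summary), and `report` (group statistics on a tidy
#' CSV). Items in a manifest that fail are skipped with a logged reason; the
#' run errors only if every item fails.
#'
#' @param subcommand One of `"simulate"`, `"actin"`, `"uptake"`, `"eu"`,
#'   `"closure"`, `"report"`.
#' @param config Named list or YAML path; allowed keys depend on the
#'   subcommand (see the package vignette and the examples).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the run log and all sidecars.
#' @return Invisibly, a named list of the tables computed and files written.
#' @export
run_pipeline <- function(subcommand, config = list(), out_dir = "epiwound_out",
                         seed = 1) {
  subcommand <- match.arg(subcommand, pipeline_subcommands)
  config <- read_run_config(config)
  if (!is.null(config$seed)) { seed <- config$seed; config$seed <- NULL }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(subcommand,
    simulate = pipeline_simulate(config, out_dir, seed),
    actin = pipeline_actin(config, out_dir, seed),
    uptake = pipeline_uptake(config, out_dir, seed),
    eu = pipeline_eu(config, out_dir, seed),
    closure = pipeline_closure(config, out_dir, seed),
    report = pipeline_report(config, out_dir, seed))
  write_run_log(out_dir, subcommand, seed, config)
  invisible(res)
}

pipeline_simulate <- function(config, out_dir, seed) {
  check_config_keys(config, c("sheet", "uptake", "closure"), "simulate")
  sheet <- do.call(make_sheet_image, c(config$sheet, list(seed = seed)))
  save_image(sheet$image, file.path(out_dir, "sheet_phalloidin.tif"),
             metadata = list(seed = seed))
  readr::write_csv(sheet$truth$rois, file.path(out_dir, "sheet_rois.csv"),
                   progress = FALSE)
  jsonlite::write_json(sheet$truth[c("edge_amplitudes", "wound_radius_um",
                                     "true_ratios", "seed")],
                       file.path(out_dir, "sheet_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  up <- do.call(make_uptake_images, c(config$uptake, list(seed = seed + 1)))
  save_image(up$particle_image, file.path(out_dir, "uptake_particles.tif"),
             metadata = list(seed = seed + 1))
  save_image(up$nuclear_image, file.path(out_dir, "uptake_nuclei.tif"),
             metadata = list(seed = seed + 1))
  save_image(up$eu_image, file.path(out_dir, "uptake_eu.tif"),
             metadata = list(seed = seed + 1))
  jsonlite::write_json(list(n_particles = nrow(up$truth$particle_coords_um),
                            n_nuclei = nrow(up$truth$nucleus_coords_um),
                            eu_positive = up$truth$eu_positive, seed = seed + 1),
                       file.path(out_dir, "uptake_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cl <- do.call(make_closure_series, c(config$closure, list(seed = seed + 2)))
  readr::write_csv(cl$series, file.path(out_dir, "closure_series.csv"),
                   progress = FALSE)
  jsonlite::write_json(cl$truth, file.path(out_dir, "closure_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  list(sheet = sheet, uptake = up, closure = cl)
}

# Apply `fn` to each manifest row; failures are logged and skipped, and the
# stage errors only when nothing succeeds.
map_manifest <- function(manifest, fn, what) {
  out <- vector("list", nrow(manifest))
  reasons <- character(0)
  for (i in seq_len(nrow(manifest))) {
    out[[i]] <- tryCatch(fn(manifest[i, ]), error = function(e) {
      reasons <<- c(reasons, sprintf("%s row %d: %s", what, i, conditionMessage(e)))
      NULL
    })
  }
  for (r in reasons) rlang::inform(paste("skipped:", r))
  ok <- !vapply(out, is.null, logical(1))
  if (!any(ok)) {
    rlang::abort(sprintf("All %d %s item(s) failed; first reason: %s",
                         nrow(manifest), what, reasons[1]))
  }
  dplyr::bind_rows(out[ok])
}

pipeline_actin <- function(config, out_dir, seed) {
  check_config_keys(config, c("profile_manifest", "image", "rois",
                              "pixel_size_um", "smooth_sigma_um",
                              "baseline_window_um", "min_width_um",
                              "max_width_um", "min_prominence"),
                    "actin")
  params <- peak_params(
    min_width_um = config$min_width_um %||% 20,
    max_width_um = config$max_width_um %||% 40,
    min_prominence = config$min_prominence)
  args <- list(smooth_sigma_um = config$smooth_sigma_um %||% 2,
               baseline_window_um = config$baseline_window_um %||% 80,
               params = params)
  if (!is.null(config$profile_manifest)) {
    manifest <- readr::read_csv(config$profile_manifest, show_col_types = FALSE,
                                progress = FALSE)
    per_line <- map_manifest(manifest, function(row) {
      res <- do.call(analyze_profile, c(list(read_profile_csv(row$path)), args))
      keep <- intersect(c("animal", "wound", "line", "treatment"), names(row))
      dplyr::bind_cols(row[rep(1, nrow(res)), keep], res)
    }, "profile")
  } else if (!is.null(config$image) && !is.null(config$rois)) {
    img <- load_image(config$image, pixel_size_um = config$pixel_size_um)
    rois <- read_line_rois(config$rois)
    per_line <- do.call(analyze_actin_image, c(list(img, rois), args))
    if (!"animal" %in% names(per_line)) per_line$animal <- "animal1"
    if (!"wound" %in% names(per_line)) per_line$wound <- 1L
  } else {
    rlang::abort("actin needs either `profile_manifest` or `image` + `rois`.")
  }
  per_animal <- aggregate_ratios(per_line)
  write_results(per_line, file.path(out_dir, "actin_per_line.csv"))
  write_results(per_animal, file.path(out_dir, "actin_per_animal.csv"))
  list(per_line = per_line, per_animal = per_animal)
}

pipeline_uptake <- function(config, out_dir, seed) {
  check_config_keys(config, c("manifest", "pixel_size_um", "min_diameter_um",
                              "max_diameter_um", "intensity_threshold",
                              "min_nucleus_area_um2", "images_per_animal"),
                    "uptake")
  if (is.null(config$manifest)) rlang::abort("uptake needs a `manifest` CSV.")
  manifest <- readr::read_csv(config$manifest, show_col_types = FALSE,
                              progress = FALSE)
  params <- spot_params(
    min_diameter_um = config$min_diameter_um %||% 1,
    max_diameter_um = config$max_diameter_um %||% 4,
    intensity_threshold = config$intensity_threshold %||% 20)
  per_image <- map_manifest(manifest, function(row) {
    ps <- manifest_pixel_size(row, config)
    rec <- score_uptake_image(
      load_image(row$image_path_a, pixel_size_um = ps),
      load_image(row$image_path_b, pixel_size_um = ps),
      params = params,
      min_nucleus_area_um2 = config$min_nucleus_area_um2 %||% 20)
    keep <- intersect(c("animal", "treatment", "image"), names(row))
    dplyr::bind_cols(row[, keep], rec)
  }, "image pair")
  per_animal <- uptake_summary(per_image,
                               images_per_animal = config$images_per_animal %||% 4)
  write_results(per_image, file.path(out_dir, "uptake_per_image.csv"))
  write_results(per_animal, file.path(out_dir, "uptake_per_animal.csv"))
  out <- list(per_image = per_image, per_animal = per_animal)
  grps <- if ("treatment" %in% names(per_animal)) {
    split(per_animal$mean_normalized, per_animal$treatment)
  }
  if (length(grps) >= 2 && all(lengths(grps) >= 2)) {
    out$anova <- one_way_anova(grps)
  }
  out
}

pipeline_eu <- function(config, out_dir, seed) {
  check_config_keys(config, c("manifest", "pixel_size_um", "threshold",
                              "min_nucleus_area_um2"), "eu")
  if (is.null(config$manifest)) rlang::abort("eu needs a `manifest` CSV.")
  manifest <- readr::read_csv(config$manifest, show_col_types = FALSE,
                              progress = FALSE)
  per_image <- map_manifest(manifest, function(row) {
    ps <- manifest_pixel_size(row, config)
    res <- eu_positive_fraction(
      load_image(row$image_path_a, pixel_size_um = ps),
      load_image(row$image_path_b, pixel_size_um = ps),
      threshold = config$threshold %||% "otsu",
      min_nucleus_area_um2 = config$min_nucleus_area_um2 %||% 20)
    keep <- intersect(c("animal", "treatment", "image"), names(row))
    dplyr::bind_cols(row[, keep],
                     tibble::tibble(n_positive = res$n_positive,
                                    n_nuclei = res$n_nuclei,
                                    fraction = res$fraction,
                                    threshold = res$threshold))
  }, "image pair")
  write_results(per_image, file.path(out_dir, "eu_per_image.csv"))
  list(per_image = per_image)
}

pipeline_closure <- function(config, out_dir, seed) {
  check_config_keys(config, c("areas", "frame_interval_s",
                              "measure_every_k_frames", "rate_window_min",
                              "adjust"), "closure")
  if (is.null(config$areas)) rlang::abort("closure needs an `areas` CSV.")
  cfg <- closure_config(
    frame_interval_s = config$frame_interval_s %||% 11,
    measure_every_k_frames = config$measure_every_k_frames %||% 10,
    rate_window_min = config$rate_window_min %||% 10)
  areas <- read_area_csv(config$areas, frame_interval_s = cfg$frame_interval_s)
  need <- c("wound_id", "treatment")
  missing <- setdiff(need, names(areas))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("Areas CSV lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  curves <- areas |>
    dplyr::group_by(.data$wound_id, .data$treatment) |>
    dplyr::group_modify(~ percent_of_original(.x, cfg)) |>
    dplyr::ungroup()
  rates <- curves |>
    dplyr::group_by(.data$wound_id, .data$treatment) |>
    dplyr::group_modify(~ tibble::tibble(rate_pct_per_min =
                                           initial_closure_rate(.x, cfg))) |>
    dplyr::ungroup()
  summary <- group_closure_summary(curves, adjust = config$adjust %||% "none")
  write_results(curves, file.path(out_dir, "closure_percent.csv"))
  write_results(rates, file.path(out_dir, "closure_rates.csv"))
  write_results(summary, file.path(out_dir, "closure_summary.csv"))
  list(curves = curves, rates = rates, summary = summary)
}

pipeline_report <- function(config, out_dir, seed) {
  check_config_keys(config, c("data", "value_col", "group_col"), "report")
  if (is.null(config$data)) rlang::abort("report needs a `data` CSV.")
  df <- readr::read_csv(config$data, show_col_types = FALSE, progress = FALSE)
  vcol <- config$value_col %||% "value"
  gcol <- config$group_col %||% "group"
  if (!all(c(vcol, gcol) %in% names(df))) {
    rlang::abort(sprintf("Report data needs columns '%s' and '%s'.", vcol, gcol))
  }
  groups <- split(df[[vcol]], df[[gcol]])
  desc <- purrr::imap_dfr(groups, function(g, nm) {
    dplyr::bind_cols(tibble::tibble(group = nm), summarize_group(g))
  })
  lines <- c(utils::capture.output(print(desc)))
  out <- list(descriptives = desc)
  if (length(groups) == 2) {
    tt <- unpaired_t_test(groups[[1]], groups[[2]])
    out$t_test <- tt
    lines <- c(lines, "", utils::capture.output(print(tt)))
  }
  if (length(groups) >= 2) {
    av <- one_way_anova(groups)
    tk <- tukey_hsd(groups)
    out$anova <- av
    out$tukey <- tk
    lines <- c(lines, "", utils::capture.output(print(av)), "",
               utils::capture.output(print(tk)))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  write_results(desc, file.path(out_dir, "report_descriptives.csv"))
  out
}
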