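#' Default run configuration
#'
#' A fully populated configuration for [run_pipeline()]; any subset of it can
#' be overridden from a YAML file or a nested list. Every run is reproducible
#' from (configuration, seed): all internal seeds are derived from
#' `config$seed`, and the configuration is echoed into the output directory.
#'
#' @param seed master integer seed.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    mode = "invitro",
    seed = as.integer(seed),
    schedule = list(n = 16L, min_kpa = 330, max_kpa = 1840,
                    window_cap_kpa = 1200),
    reporters = c("bARG560", "bARG710"),
    noise = list(m = 1, sd_au = default_noise_sd()),
    thresholds = list(pixel_au = NULL, s_b_min_au = 175,
                      postcollapse_max_au = 100, alpha = 0.05),
    attenuation = NULL,
    nd_variant = "corrected",
    depth_correct = FALSE,
    scene = list(shape = c(48L, 48L), fraction_first = 0.5,
                 pixel_spacing_mm = 0.25, depth_offset_mm = 3),
    plate = list(n_variants = 96L, artifact_rate = 0.02, n_rep = 4L),
    seqdist = list(n_variants = 24L, matrix = "blosum62"),
    paths = list()
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (or takes a list), overlays it on
#' [default_run_config()] and validates the schema; violations are reported
#' together with the offending keys.
#'
#' @param config YAML path, nested list, or `run_config`.
#' @return validated `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config(seed = config$seed %||% 1L)
  merged <- utils::modifyList(base, config, keep.null = TRUE)
  class(merged) <- "run_config"
  validate_run_config(merged)
  merged
}

validate_run_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  chk(cfg$mode %in% c("invitro", "invivo"), "mode")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed")
  chk(is.numeric(cfg$schedule$n) && cfg$schedule$n >= 2, "schedule.n")
  chk(isTRUE(cfg$schedule$min_kpa > 0), "schedule.min_kpa")
  chk(isTRUE(cfg$schedule$max_kpa > cfg$schedule$min_kpa), "schedule.max_kpa")
  chk(isTRUE(cfg$schedule$window_cap_kpa <= cfg$schedule$max_kpa),
      "schedule.window_cap_kpa")
  chk(is.numeric(cfg$noise$m) && cfg$noise$m >= 0, "noise.m")
  chk(is.numeric(cfg$noise$sd_au) && cfg$noise$sd_au >= 0, "noise.sd_au")
  chk(cfg$nd_variant %in% c("corrected", "as_printed"), "nd_variant")
  chk(is.numeric(cfg$thresholds$alpha) && cfg$thresholds$alpha > 0 &&
        cfg$thresholds$alpha < 1, "thresholds.alpha")
  chk(all(cfg$reporters %in% names(default_reporters())), "reporters")
  if (!is.null(cfg$attenuation)) {
    chk(is.numeric(cfg$attenuation$alpha_db_cm_mhz) &&
          cfg$attenuation$alpha_db_cm_mhz >= 0, "attenuation.alpha_db_cm_mhz")
    chk(is.numeric(cfg$attenuation$freq_mhz) && cfg$attenuation$freq_mhz > 0,
        "attenuation.freq_mhz")
  }
  if (length(bad))
    stop("invalid run configuration; offending keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

config_schedule <- function(cfg) {
  if (!is.null(cfg$paths$schedule_csv))
    return(read_schedule_csv(cfg$paths$schedule_csv,
                             cfg$schedule$window_cap_kpa))
  pressure_schedule(seq(cfg$schedule$min_kpa, cfg$schedule$max_kpa,
                        length.out = cfg$schedule$n),
                    cfg$schedule$window_cap_kpa)
}

config_att <- function(cfg) {
  if (is.null(cfg$attenuation)) return(NULL)
  attenuation_model(cfg$attenuation$alpha_db_cm_mhz,
                    cfg$attenuation$freq_mhz)
}

pipeline_log <- function(out_dir) {
  path <- file.path(out_dir, "log.jsonl")
  function(event, ...) {
    rec <- c(list(event = event), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = path, append = TRUE, sep = "")
  }
}

#' Run one pipeline subcommand
#'
#' End-to-end driver binding the modules: each subcommand writes its
#' documented artifacts into `out_dir`, together with the echoed
#' configuration (`config.yaml`), a JSON-lines log of QC exclusions and
#' processing steps (`log.jsonl`) and a `manifest.json` recording the
#' subcommand, seed, package version, configuration hash and output files.
#'
#' Subcommands: `simulate-scene` (render a mixed two-reporter phantom to a
#' TIFF series), `simulate-plate` (synthetic screening plate CSVs),
#' `build-matrix` (multiplexing matrix CSV from rendered pure references, or
#' from series under `paths$reference_series`), `unmix` (threshold + NNLS
#' unmixing + normalized difference of a series from `paths$series`, or a
#' freshly rendered one), `screen` (QC + threshold/yield estimation +
#' acoustic-map fit of a plate from `paths$plate`, or a fresh one),
#' `seqdist` (variant library alignment distances), `demo` (scene to
#' channels end-to-end).
#'
#' @param config YAML path, nested list or `run_config`; see
#'   [default_run_config()].
#' @param subcommand one of the subcommands above.
#' @param out_dir output directory, created if missing.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config,
                         subcommand = c("demo", "simulate-scene",
                                        "simulate-plate", "build-matrix",
                                        "unmix", "screen", "seqdist"),
                         out_dir = "gvmux_out") {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "run_config")) validate_run_config(config)
  else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  log <- pipeline_log(out_dir)
  unlink(file.path(out_dir, "log.jsonl"))
  log("start", subcommand = subcommand, seed = cfg$seed)

  sched <- config_schedule(cfg)
  att <- config_att(cfg)
  models <- default_reporters()[cfg$reporters]
  pixel_cutoff <- cfg$thresholds$pixel_au %||%
    (if (cfg$mode == "invitro") 100 else 200)
  outputs <- character(0)
  add_out <- function(...) outputs <<- c(outputs, ...)

  render_demo_scene <- function(fraction, seed_offset = 0L) {
    conc <- setNames(c(fraction, 1 - fraction), names(models))
    scn <- phantom_scene(conc, shape = cfg$scene$shape,
                         pixel_spacing_mm = cfg$scene$pixel_spacing_mm,
                         depth_offset_mm = cfg$scene$depth_offset_mm)
    render_scene(scn, models, sched, att = att,
                 noise = noise_spec(cfg$noise$m,
                                    rep(cfg$noise$sd_au,
                                        length(sched$pressures)),
                                    seed = cfg$seed + seed_offset))
  }

  reference_matrix <- function() {
    if (!is.null(cfg$paths$matrix_csv))
      return(read_multiplex_matrix(cfg$paths$matrix_csv,
                                   sched$window_cap))
    refs <- lapply(seq_along(models), function(r) {
      conc <- setNames(as.numeric(seq_along(models) == r), names(models))
      scn <- phantom_scene(conc, shape = cfg$scene$shape,
                           pixel_spacing_mm = cfg$scene$pixel_spacing_mm,
                           depth_offset_mm = cfg$scene$depth_offset_mm)
      render_scene(scn, models, sched, att = att,
                   noise = noise_spec(cfg$noise$m,
                                      rep(cfg$noise$sd_au,
                                          length(sched$pressures)),
                                      seed = cfg$seed + 100L + r))
    })
    names(refs) <- names(models)
    build_multiplex_matrix(refs)
  }

  if (subcommand %in% c("simulate-scene", "demo", "unmix")) {
    series <- if (!is.null(cfg$paths$series_tiff))
      read_image_series(cfg$paths$series_tiff)
    else render_demo_scene(cfg$scene$fraction_first)
    p_series <- file.path(out_dir, "scene_series.tiff")
    write_image_series(series, p_series)
    add_out(p_series, paste0(p_series, ".json"))
    log("scene", frames = dim(series$frames)[3L],
        shape = dim(series$frames)[1:2])
  }

  if (subcommand %in% c("build-matrix", "demo", "unmix")) {
    M <- reference_matrix()
    p_matrix <- file.path(out_dir, "multiplex_matrix.csv")
    write_multiplex_matrix(M, p_matrix)
    add_out(p_matrix)
    log("matrix", reporters = M$reporters,
        pressures = ncol(M$M))
  }

  if (subcommand %in% c("unmix", "demo")) {
    mask <- threshold_pixels(series, cutoff = pixel_cutoff)
    log("threshold", cutoff_au = pixel_cutoff, pixels = sum(mask))
    cmap <- if (isTRUE(cfg$depth_correct) && !is.null(att)) {
      m2d <- build_m2d(models, att, series$depth_axis, sched)
      unmix_depth_corrected(series, m2d, mask)
    } else {
      unmix_pixelwise(series, M, mask)
    }
    p_cmap <- file.path(out_dir, "acoustic_channels.tiff")
    write_coefficient_map(cmap, p_cmap)
    add_out(p_cmap)
    nd <- normalized_difference(cmap, cfg$nd_variant)
    nd_summary <- data.frame(
      variant = nd$variant,
      defined_pixels = sum(!is.na(nd$nd)),
      mean_nd = mean(nd$nd, na.rm = TRUE))
    write.csv(nd_summary, file.path(out_dir, "nd_summary.csv"),
              row.names = FALSE)
    add_out(file.path(out_dir, "nd_summary.csv"))
    if (!is.null(series$rois$sample)) {
      cm <- channel_means(cmap, series$rois$sample & cmap$mask)
      write.csv(cm, file.path(out_dir, "channel_means.csv"),
                row.names = FALSE)
      add_out(file.path(out_dir, "channel_means.csv"))
      log("channels", means = setNames(cm$mean, cm$reporter))
    }
  }

  if (subcommand %in% c("simulate-plate", "screen")) {
    plate <- if (!is.null(cfg$paths$plate_csv))
      read_screen_plate(cfg$paths$plate_csv, sched$window_cap)
    else make_screen_plate(cfg$plate$n_variants,
                           artifact_rate = cfg$plate$artifact_rate,
                           schedule = sched, n_rep = cfg$plate$n_rep,
                           noise_sd = cfg$noise$sd_au, seed = cfg$seed)
    p_plate <- file.path(out_dir, "plate.csv")
    write_screen_plate(plate, p_plate)
    add_out(p_plate, sub("\\.csv$", "_curves.csv", p_plate))
    if (subcommand == "screen") {
      rec <- characterize_plate(plate,
                                s_b_min = cfg$thresholds$s_b_min_au,
                                postcollapse_max =
                                  cfg$thresholds$postcollapse_max_au,
                                alpha = cfg$thresholds$alpha,
                                control_seed = cfg$seed + 7L)
      for (i in which(!rec$kept))
        log("qc_exclusion", variant = rec$variant_id[i],
            low_expression = rec$low_expression[i],
            artifact = rec$artifact_excluded[i])
      write.csv(rec, file.path(out_dir, "screen_records.csv"),
                row.names = FALSE)
      add_out(file.path(out_dir, "screen_records.csv"))
      kept <- rec[rec$kept & !is.na(rec$P_o_hat), ]
      if (nrow(kept) >= 3L) {
        fitm <- fit_acoustic_map(kept$P_o_hat, kept$S_max_hat)
        jsonlite::write_json(fitm[c("a", "b", "r_squared", "n")],
                             file.path(out_dir, "acoustic_map_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        add_out(file.path(out_dir, "acoustic_map_fit.json"))
        log("acoustic_map", r_squared = fitm$r_squared, n = fitm$n)
      }
    }
  }

  if (subcommand == "seqdist") {
    parent <- if (!is.null(cfg$paths$parent_fasta))
      read_fasta_sequences(cfg$paths$parent_fasta)[[1L]]
    else synthetic_gvpc_parent()
    variants <- if (!is.null(cfg$paths$variants_fasta))
      read_fasta_sequences(cfg$paths$variants_fasta)
    else make_variant_sequences(parent, cfg$seqdist$n_variants,
                                seed = cfg$seed)
    tab <- distance_to_parent(variants, parent,
                              substitution = cfg$seqdist$matrix)
    write.csv(tab, file.path(out_dir, "sequence_distances.csv"),
              row.names = FALSE)
    add_out(file.path(out_dir, "sequence_distances.csv"))
    log("seqdist", n = nrow(tab), mean_D = mean(tab$D))
  }

  manifest <- list(
    subcommand = subcommand,
    seed = cfg$seed,
    package = "gvmux",
    version = as.character(utils::packageVersion("gvmux")),
    config_hash = unname(tools::md5sum(cfg_path)),
    inputs = cfg$paths,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done", outputs = basename(outputs))
  invisible(manifest)
}
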