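#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the input (a simulation
#' scenario or a fixture directory), stage toggles, analysis windows in
#' minutes (mirroring the experimental protocol phrasing), the optical
#' model, and the output directory. Windows are converted to frame indices
#' as half-open intervals `[floor(start*60*fps), floor(end*60*fps))`.
#'
#' @param scenario a [scenario_config()] (used when `input_path` is NULL).
#' @param input_path optional fixture directory readable by
#'   [read_acquisition()]; overrides `scenario` as pixel-data source.
#' @param out_dir output directory for artifacts.
#' @param stages named list of logical toggles: `registration`,
#'   `diffeomorphic`, `gsr_maps` (GSR applied to seed-pixel correlation maps
#'   only; quantitative statistics always use non-GSR data).
#' @param windows_min named list of minute windows: `normoxia`, `hypoxia`
#'   (connectivity), `baseline`, `plateau`, `dip`, `overshoot`
#'   (hemodynamics). Pass NULL for any window to skip that summary; defaults
#'   are the protocol windows for a 40-minute acquisition.
#' @param transition_margin_s margin excluded around epoch transitions when
#'   deriving baseline frames (manual gas switching makes the exact
#'   transition time imprecise).
#' @param edge_margin_px brain-mask erosion margin.
#' @param optical an [optical_model()].
#' @return object of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(), input_path = NULL,
                       out_dir = tempfile("hypoxamap_run_"),
                       stages = list(registration = FALSE,
                                     diffeomorphic = FALSE,
                                     gsr_maps = TRUE),
                       windows_min = list(normoxia = c(2.5, 7.5),
                                          hypoxia = c(12.5, 17.5),
                                          baseline = c(4.5, 9.5),
                                          plateau = c(14.5, 19.5),
                                          dip = c(10, 11),
                                          overshoot = c(20, 21)),
                       transition_margin_s = 30,
                       edge_margin_px = 5,
                       optical = optical_model()) {
  if (!is.null(input_path) && !dir.exists(input_path))
    stop("input_path does not exist: ", input_path)
  for (tog in c("registration", "diffeomorphic", "gsr_maps"))
    if (is.null(stages[[tog]])) stages[[tog]] <- FALSE
  structure(list(scenario = scenario, input_path = input_path,
                 out_dir = out_dir, stages = stages,
                 windows_min = windows_min,
                 transition_margin_s = transition_margin_s,
                 edge_margin_px = edge_margin_px, optical = optical),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in acquisition order: simulate (or read) the
#' interlaced stack, demultiplex the four colors, optionally co-register
#' each channel to its first frame, correct the fluorescence channel for
#' hemodynamic contamination, invert the modified Beer-Lambert law,
#' normalize to band-passed dF/F, extract the 8 atlas seeds, and compute
#' connectivity matrices and epoch summaries. Global signal regression is
#' applied only to the seed-pixel correlation maps. All artifacts are
#' written to `config$out_dir` together with a JSON manifest (stage status,
#' seed, config hash, file checksums).
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_done <- character(0)
  fail <- function(stage, e) stop(sprintf("pipeline stage '%s' failed: %s",
                                          stage, conditionMessage(e)),
                                  call. = FALSE)
  # -- acquisition ----------------------------------------------------------
  st <- "acquisition"
  sim <- NULL
  stack <- tryCatch({
    if (is.null(config$input_path)) {
      sim <- simulate_acquisition(config$scenario, config$optical)
      sim$stack
    } else read_acquisition(config$input_path)
  }, error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  timeline <- stack$metadata$epoch_timeline
  atlas <- if (!is.null(sim)) sim$truth$atlas else
    read_fixture_truth(config$input_path)$atlas
  # -- demultiplex ----------------------------------------------------------
  st <- "demultiplex"
  channels <- tryCatch(demultiplex(stack), error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  fps <- channels[[1]]$fps
  # -- co-registration ------------------------------------------------------
  st <- "co-registration"
  if (isTRUE(config$stages$registration)) {
    tryCatch({
      for (ch in names(channels)) {
        reg <- register_within(channels[[ch]],
                               diffeomorphic = isTRUE(config$stages$diffeomorphic))
        channels[[ch]] <- reg$stack
        utils::write.csv(reg$result,
                         file.path(config$out_dir,
                                   sprintf("registration_%s.csv", ch)),
                         row.names = FALSE)
      }
    }, error = function(e) fail(st, e))
    stages_done <- c(stages_done, st)
  }
  mean_blue <- apply(channels$blue$frames, c(1, 2), mean)
  mask <- make_brain_mask(mean_blue, atlas,
                          edge_margin_px = config$edge_margin_px)
  # -- hemodynamic correction ----------------------------------------------
  st <- "hemodynamic-correction"
  refl <- channels[c("green", "amber", "red")]
  corr <- tryCatch(hemodynamic_correction(channels$blue, refl, mask = mask),
                   error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  # -- hemodynamic signals --------------------------------------------------
  st <- "hemodynamic-signals"
  hemo <- tryCatch(
    beer_lambert_invert(refl, config$optical, epoch_timeline = timeline,
                        mask = mask,
                        baseline_margin_s = config$transition_margin_s),
    error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  traces <- data.frame(time_s = channels$green$timestamps,
                       hbo = whole_brain_trace(hemo, "hbo"),
                       hbr = whole_brain_trace(hemo, "hbr"),
                       hbt = whole_brain_trace(hemo, "hbt"),
                       so2 = whole_brain_trace(hemo, "so2"))
  utils::write.csv(traces, file.path(config$out_dir, "traces_hemo.csv"),
                   row.names = FALSE)
  # -- normalization --------------------------------------------------------
  st <- "normalization"
  fluo <- tryCatch(compute_dff(corr$corrected, mask = hemo$mask),
                   error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  # -- regions of interest --------------------------------------------------
  st <- "regions-of-interest"
  seeds <- tryCatch(extract_seeds(atlas, fluo$mask),
                    error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  tc_gcamp <- seed_timecourses(fluo$dff, seeds)
  tc_hbo <- seed_timecourses(hemo$hbo, seeds)
  utils::write.csv(data.frame(time_s = channels$blue$timestamps, tc_gcamp,
                              check.names = FALSE),
                   file.path(config$out_dir, "seed_timecourses_gcamp.csv"),
                   row.names = FALSE)
  # -- seed-pixel correlation maps (GSR per toggle) -------------------------
  st <- "correlation-maps"
  w_hyp <- config$windows_min$hypoxia
  has_hypoxia <- !is.null(timeline) && any(timeline$label == "hypoxia")
  tryCatch({
    maps_src <- if (isTRUE(config$stages$gsr_maps))
      global_signal_regression(fluo$dff, fluo$mask) else fluo$dff
    w_map <- if (has_hypoxia && !is.null(w_hyp) &&
                 w_hyp[2] * 60 * fps <= dim(maps_src)[3]) w_hyp * 60 else NULL
    spcm <- seed_pixel_correlation_map(
      maps_src, seed_timecourse(maps_src, seeds$pixels[[1]]), fluo$mask,
      window = w_map, fps = fps)
    utils::write.csv(spcm,
                     file.path(config$out_dir,
                               sprintf("spcm_%s.csv", seeds$seeds$region[1])),
                     row.names = FALSE)
  }, error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  # -- statistics -----------------------------------------------------------
  st <- "statistics"
  tryCatch({
    n_fr <- nrow(tc_gcamp)
    win_ok <- function(w) !is.null(w) && w[2] * 60 * fps <= n_fr + 1e-9
    if (win_ok(config$windows_min$normoxia) &&
        win_ok(config$windows_min$hypoxia) && has_hypoxia) {
      for (mod in c("gcamp", "hbo")) {
        tc <- if (mod == "gcamp") tc_gcamp else tc_hbo
        cm_n <- connectivity_matrix(tc, window = config$windows_min$normoxia * 60,
                                    fps = fps, modality = mod)
        cm_h <- connectivity_matrix(tc, window = config$windows_min$hypoxia * 60,
                                    fps = fps, modality = mod)
        utils::write.csv(cm_n$r, file.path(config$out_dir,
                                           sprintf("connectivity_%s_normoxia.csv", mod)))
        utils::write.csv(cm_h$r, file.path(config$out_dir,
                                           sprintf("connectivity_%s_hypoxia.csv", mod)))
        dz <- cm_h$z - cm_n$z
        utils::write.csv(dz, file.path(config$out_dir,
                                       sprintf("dz_%s.csv", mod)))
      }
    }
    if (win_ok(config$windows_min$plateau) &&
        win_ok(config$windows_min$baseline)) {
      wm <- config$windows_min[c("baseline", "plateau", "dip", "overshoot")]
      wm <- wm[!vapply(wm, is.null, logical(1))]
      if (all(c("dip", "overshoot") %in% names(wm)) &&
          all(vapply(wm, win_ok, logical(1)))) {
        summ <- do.call(rbind, lapply(c("hbo", "hbr", "hbt", "so2"),
                                      function(sp) {
          es <- quantify_epoch_dynamics(traces[[sp]], fps, windows_min = wm)
          cbind(species = sp, es$group)
        }))
        utils::write.csv(summ, file.path(config$out_dir, "epoch_summary.csv"),
                         row.names = FALSE)
      }
    }
  }, error = function(e) fail(st, e))
  stages_done <- c(stages_done, st)
  # -- manifest -------------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$|[.]png$", files)]
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  cfg_file <- file.path(config$out_dir, "config.yaml")
  save_run_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hypoxamap")),
    rng_seed = config$scenario$rng_seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stages_done,
    out_dir = config$out_dir,
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Serialize / load a run configuration
#'
#' YAML round-trip of everything needed to repeat a run (scenario, stages,
#' windows, margins, optical model table).
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (save) / a [run_config()] (load).
#' @export
save_run_config <- function(config, path) {
  sc <- config$scenario
  yaml::write_yaml(list(
    scenario = list(
      image_shape = sc$image_shape, fov_mm = sc$fov_mm,
      fps_per_channel = sc$fps_per_channel, duration_s = sc$duration_s,
      oxygen_level = sc$oxygen_level,
      epoch_timeline = lapply(seq_len(nrow(sc$epoch_timeline)), function(i)
        as.list(sc$epoch_timeline[i, ])),
      within_cluster_r = sc$within_cluster_r,
      between_cluster_r = sc$between_cluster_r,
      between_cluster_r_hypoxia = sc$between_cluster_r_hypoxia,
      calcium_sd = sc$calcium_sd, noise_sd = sc$noise_sd,
      motion_amplitude_px = sc$motion_amplitude_px, rng_seed = sc$rng_seed),
    input_path = config$input_path,
    out_dir = config$out_dir,
    stages = config$stages,
    windows_min = config$windows_min,
    transition_margin_s = config$transition_margin_s,
    edge_margin_px = config$edge_margin_px,
    optical_channels = lapply(seq_len(nrow(config$optical$channels)),
                              function(i) as.list(config$optical$channels[i, ])),
    optical_baselines = list(hbo = config$optical$baseline_hbo,
                             hbr = config$optical$baseline_hbr)
  ), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tl <- do.call(rbind, lapply(y$scenario$epoch_timeline, as.data.frame))
  sc <- scenario_config(
    image_shape = unlist(y$scenario$image_shape),
    fov_mm = unlist(y$scenario$fov_mm),
    fps_per_channel = y$scenario$fps_per_channel,
    duration_s = y$scenario$duration_s,
    epoch_timeline = tl,
    oxygen_level = y$scenario$oxygen_level,
    within_cluster_r = y$scenario$within_cluster_r,
    between_cluster_r = y$scenario$between_cluster_r,
    between_cluster_r_hypoxia = y$scenario$between_cluster_r_hypoxia,
    calcium_sd = y$scenario$calcium_sd,
    noise_sd = y$scenario$noise_sd,
    motion_amplitude_px = y$scenario$motion_amplitude_px,
    rng_seed = y$scenario$rng_seed)
  opt <- optical_model(
    channels = do.call(rbind, lapply(y$optical_channels, as.data.frame)),
    baseline_hbo = y$optical_baselines$hbo,
    baseline_hbr = y$optical_baselines$hbr)
  run_config(scenario = sc, input_path = y$input_path, out_dir = y$out_dir,
             stages = y$stages, windows_min = y$windows_min,
             transition_margin_s = y$transition_margin_s,
             edge_margin_px = y$edge_margin_px, optical = opt)
}

#' Produce summary figures for a pipeline run
#'
#' Reads the CSV artifacts of [run_pipeline()] and writes one PNG per figure
#' family: whole-brain hemodynamic traces with epoch shading, connectivity
#' matrix heatmaps, the hypoxia-normoxia dz heatmap, and the seed-pixel
#' correlation map. Families whose artifacts are absent (e.g. no hypoxia
#' epoch) are skipped with a message.
#'
#' @param out_dir a pipeline output directory containing `manifest.json`.
#' @return character vector of figure paths, invisibly.
#' @export
make_figures <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  cfg <- load_run_config(file.path(out_dir, "config.yaml"))
  made <- character(0)
  tr_file <- file.path(out_dir, "traces_hemo.csv")
  if (file.exists(tr_file)) {
    tr <- utils::read.csv(tr_file)
    f <- file.path(out_dir, "fig_traces.png")
    grDevices::png(f, width = 900, height = 600)
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    tl <- cfg$scenario$epoch_timeline
    shade <- function() {
      hyp <- tl[tl$label == "hypoxia", , drop = FALSE]
      for (i in seq_len(nrow(hyp)))
        graphics::rect(hyp$start_s[i] / 60, graphics::par("usr")[3],
                       hyp$end_s[i] / 60, graphics::par("usr")[4],
                       col = grDevices::adjustcolor("grey", 0.4), border = NA)
    }
    graphics::plot(tr$time_s / 60, tr$hbo, type = "l", col = "red",
                   xlab = "time (min)", ylab = "dHb (uM)",
                   main = "Whole-brain hemodynamics",
                   ylim = range(c(tr$hbo, tr$hbr, tr$hbt)))
    shade()
    graphics::lines(tr$time_s / 60, tr$hbr, col = "blue")
    graphics::lines(tr$time_s / 60, tr$hbt, col = "darkgreen")
    graphics::legend("topleft", c("HbO", "HbR", "HbT"),
                     col = c("red", "blue", "darkgreen"), lty = 1, bty = "n")
    graphics::plot(tr$time_s / 60, 100 * tr$so2, type = "l",
                   xlab = "time (min)", ylab = "sO2 (%)",
                   main = "Oxygen saturation")
    shade()
    grDevices::dev.off()
    made <- c(made, f)
  }
  heat <- function(mat, title, file, diverging = TRUE) {
    grDevices::png(file, width = 600, height = 550)
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
    lim <- if (diverging) max(abs(mat), na.rm = TRUE) else 1
    graphics::image(seq_len(ncol(mat)), seq_len(nrow(mat)),
                    t(mat[rev(seq_len(nrow(mat))), ]),
                    zlim = c(-lim, lim), col = pal, axes = FALSE,
                    xlab = "", ylab = "", main = title)
    graphics::axis(1, seq_len(ncol(mat)), colnames(mat), las = 2)
    graphics::axis(2, seq_len(nrow(mat)), rev(rownames(mat)), las = 2)
    grDevices::dev.off()
  }
  for (mod in c("gcamp", "hbo")) {
    cm_file <- file.path(out_dir, sprintf("connectivity_%s_hypoxia.csv", mod))
    dz_file <- file.path(out_dir, sprintf("dz_%s.csv", mod))
    if (file.exists(cm_file)) {
      m <- as.matrix(utils::read.csv(cm_file, row.names = 1))
      f <- file.path(out_dir, sprintf("fig_connectivity_%s.png", mod))
      heat(m, sprintf("Connectivity (%s, hypoxia window)", mod), f)
      made <- c(made, f)
    } else message("make_figures: no connectivity matrices for ", mod,
                   " (skipped)")
    if (file.exists(dz_file)) {
      m <- as.matrix(utils::read.csv(dz_file, row.names = 1))
      f <- file.path(out_dir, sprintf("fig_dz_%s.png", mod))
      heat(m, sprintf("dz hypoxia - normoxia (%s)", mod), f)
      made <- c(made, f)
    }
  }
  spcm_files <- list.files(out_dir, pattern = "^spcm_.*[.]csv$",
                           full.names = TRUE)
  for (sf in spcm_files) {
    m <- as.matrix(utils::read.csv(sf))
    f <- sub("[.]csv$", ".png", sub("spcm_", "fig_spcm_", sf))
    grDevices::png(f, width = 600, height = 550)
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
    graphics::image(t(m[rev(seq_len(nrow(m))), ]), zlim = c(-1, 1), col = pal,
                    axes = FALSE, main = basename(sf))
    grDevices::dev.off()
    made <- c(made, f)
  }
  invisible(made)
}
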