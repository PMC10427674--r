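#' Scenario configuration for the acquisition simulator
#'
#' Describes one simulated 4-color widefield acquisition: geometry, frame
#' rates, the normoxia/hypoxia epoch timeline, the target resting-state
#' correlation structure of the 8 cortical regions, the hypoxia hemodynamic
#' ramp parameters, and sensor noise / motion levels.
#'
#' The default timeline is the experimental protocol: 10 min normoxia,
#' 10 min of the hypoxic condition, 20 min normoxia. The default geometry is
#' 192x192 px over a 10x10 mm field of view at 20 Hz per color.
#'
#' @param image_shape integer (rows, cols).
#' @param fov_mm field of view in mm (rows, cols).
#' @param fps_per_channel per-color frame rate, Hz.
#' @param duration_s total acquisition length, seconds.
#' @param epoch_timeline data.frame(label, start_s, end_s); labels are
#'   "normoxia"/"hypoxia". Defaults to the protocol timeline scaled to
#'   `duration_s` in the 10/10/20-minute proportions when `oxygen_level < 21`,
#'   or a single normoxia epoch otherwise.
#' @param oxygen_level inspired oxygen during the hypoxia epoch, percent
#'   (one of 21, 12, 10, 8; 21 means pure normoxia).
#' @param within_cluster_r,between_cluster_r target Pearson correlations
#'   during normoxia for region pairs within / between macroclusters.
#' @param between_cluster_r_hypoxia between-cluster target during hypoxia.
#' @param calcium_sd standard deviation of simulated dF/F traces.
#' @param hemo_ramp_params list of hypoxia ramp parameters; see
#'   [default_hemo_ramp_params()]. Defaults depend on `oxygen_level`.
#' @param coupling_hbo_uM,coupling_ratio_hbr neurovascular coupling: local
#'   dHbO amplitude (uM) per standard deviation of the calcium trace, and the
#'   (negative) HbR:HbO amplitude ratio.
#' @param noise_sd sensor noise in counts (camera baseline ~10000 counts).
#' @param motion_amplitude_px amplitude of rigid frame jitter, px.
#' @param rng_seed integer seed; the simulation is bit-reproducible given it.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(image_shape = c(192, 192),
                            fov_mm = c(10, 10),
                            fps_per_channel = 20,
                            duration_s = 2400,
                            epoch_timeline = NULL,
                            oxygen_level = 8,
                            within_cluster_r = 0.8,
                            between_cluster_r = 0.5,
                            between_cluster_r_hypoxia = 0.1,
                            calcium_sd = 0.02,
                            hemo_ramp_params = NULL,
                            coupling_hbo_uM = 0.5,
                            coupling_ratio_hbr = -0.4,
                            noise_sd = 0,
                            motion_amplitude_px = 0,
                            rng_seed = 1L) {
  if (!oxygen_level %in% c(21, 12, 10, 8))
    stop("oxygen_level must be one of 21, 12, 10, 8")
  if (is.null(epoch_timeline)) epoch_timeline <-
      default_epoch_timeline(duration_s, oxygen_level)
  validate_timeline(epoch_timeline, duration_s)
  if (!(between_cluster_r >= 0 && between_cluster_r <= within_cluster_r &&
        within_cluster_r <= 1))
    stop("need 0 <= between_cluster_r <= within_cluster_r <= 1")
  if (is.null(hemo_ramp_params))
    hemo_ramp_params <- default_hemo_ramp_params(oxygen_level)
  structure(list(
    image_shape = as.integer(image_shape),
    fov_mm = fov_mm,
    fps_per_channel = fps_per_channel,
    duration_s = duration_s,
    epoch_timeline = epoch_timeline,
    oxygen_level = oxygen_level,
    within_cluster_r = within_cluster_r,
    between_cluster_r = between_cluster_r,
    between_cluster_r_hypoxia = between_cluster_r_hypoxia,
    calcium_sd = calcium_sd,
    hemo_ramp_params = hemo_ramp_params,
    coupling_hbo_uM = coupling_hbo_uM,
    coupling_ratio_hbr = coupling_ratio_hbr,
    noise_sd = noise_sd,
    motion_amplitude_px = motion_amplitude_px,
    rng_seed = as.integer(rng_seed)
  ), class = "scenario_config")
}

# Protocol timeline (10' normoxia / 10' hypoxia / 20' normoxia) scaled to
# duration_s; a single normoxia epoch at 21% oxygen.
default_epoch_timeline <- function(duration_s, oxygen_level) {
  if (oxygen_level >= 21) {
    return(data.frame(label = "normoxia", start_s = 0, end_s = duration_s,
                      stringsAsFactors = FALSE))
  }
  data.frame(
    label = c("normoxia", "hypoxia", "normoxia"),
    start_s = duration_s * c(0, 0.25, 0.5),
    end_s = duration_s * c(0.25, 0.5, 1),
    stringsAsFactors = FALSE
  )
}

validate_timeline <- function(tl, duration_s) {
  stopifnot(is.data.frame(tl),
            all(c("label", "start_s", "end_s") %in% names(tl)))
  if (!all(tl$label %in% c("normoxia", "hypoxia")))
    stop("epoch labels must be 'normoxia' or 'hypoxia'")
  if (is.unsorted(tl$start_s, strictly = TRUE) && nrow(tl) > 1)
    stop("epochs must be ordered by start time")
  if (any(tl$end_s <= tl$start_s)) stop("epochs must have positive length")
  if (nrow(tl) > 1 && any(abs(tl$start_s[-1] - tl$end_s[-nrow(tl)]) > 1e-9))
    stop("epochs must tile the acquisition without gaps or overlaps")
  if (abs(tl$start_s[1]) > 1e-9 || abs(tl$end_s[nrow(tl)] - duration_s) > 1e-9)
    stop("epochs must cover [0, duration_s]")
  invisible(tl)
}

#' Default hypoxia hemodynamic ramp parameters
#'
#' Amplitudes follow the whole-brain group means reported for the 12/10/8%
#' inspired-oxygen conditions: fast dHbR rise to a plateau (10.9/13.4/21.2 uM)
#' within about a minute; dHbO with a brief initial dip followed by a slower
#' rise (plateaus 7.8/20.0/28.0 uM, reached later at lower oxygen); on return
#' to normoxia an HbO overshoot (peaks ~14/29/55 uM) and an HbR undershoot
#' scaled by severity. At 21% oxygen all amplitudes are zero.
#'
#' @param oxygen_level percent inspired oxygen (21, 12, 10 or 8).
#' @return list of ramp parameters (amplitudes in uM, time constants in s).
#' @export
default_hemo_ramp_params <- function(oxygen_level = 8) {
  i <- match(oxygen_level, c(21, 12, 10, 8))
  if (is.na(i)) stop("oxygen_level must be one of 21, 12, 10, 8")
  list(
    hbr_plateau_uM   = c(0, 10.9, 13.4, 21.2)[i],
    hbr_tau_s        = 20,
    hbr_undershoot_uM = c(0, 2, 4, 6)[i],
    hbr_undershoot_tau_s = 40,
    hbo_plateau_uM   = c(0, 7.8, 20.0, 28.0)[i],
    hbo_tau_s        = c(60, 60, 110, 200)[i],
    hbo_dip_uM       = c(0, 4, 5, 6)[i],
    hbo_dip_tau_s    = 15,
    hbo_overshoot_uM = c(0, 14, 29, 55)[i],
    overshoot_tau_s  = 25,
    release_tau_s    = 25
  )
}

#' Region table of the pooled cortical atlas
#'
#' The 8 bilateral regions used for seed analysis — Motor (Mot),
#' Somatosensory (Sen), Retrosplenial (Ret) and Visual (Vis), left/right —
#' with their macrocluster membership (anterior = Mot + Sen,
#' posterior = Ret + Vis).
#'
#' @return data.frame with columns id, region, macrocluster, side.
#' @export
region_table <- function() {
  data.frame(
    id = 1:8,
    region = c("MotL", "MotR", "SenL", "SenR", "RetL", "RetR", "VisL", "VisR"),
    macrocluster = rep(c("anterior", "anterior", "posterior", "posterior"),
                       each = 2),
    side = rep(c("L", "R"), 4),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cortical atlas
#'
#' Builds a label image emulating the pooled Allen-atlas regions used for
#' seed analysis: 8 bilateral regions (MotL/R, SenL/R anterior; RetL/R, VisL/R
#' posterior) tiled over an elliptical "brain" footprint, separated at the
#' midline by a sagittal sinus stripe that is excluded from the brain mask
#' downstream. Row index increases from anterior to posterior.
#'
#' @param image_shape integer (rows, cols).
#' @param sinus_halfwidth_px half-width of the midline sinus stripe; default
#'   scales with image width.
#' @return list with `labels` (integer matrix, 0 = background), `brain`
#'   (logical matrix), `sinus` (logical matrix), and `regions`
#'   (data.frame id, region, macrocluster, side).
#' @export
synthetic_atlas <- function(image_shape = c(192, 192),
                            sinus_halfwidth_px = max(1L, round(image_shape[2] / 48))) {
  nr <- image_shape[1]; nc <- image_shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  brain <- ((rr - r0) / (0.45 * nr))^2 + ((cc - c0) / (0.45 * nc))^2 <= 1
  sinus <- brain & abs(cc - c0) <= sinus_halfwidth_px
  regions <- region_table()
  # 4 anterior->posterior bands (Mot, Sen, Ret, Vis) x left/right of the sinus
  band <- pmin(4L, pmax(1L, ceiling(4 * (rr - r0 + 0.45 * nr) /
                                      (0.9 * nr + 1e-9))))
  side <- ifelse(cc < c0, 1L, 2L)
  labels <- matrix(0L, nr, nc)
  inside <- brain & !sinus
  labels[inside] <- as.integer((band[inside] - 1L) * 2L + side[inside])
  list(labels = labels, brain = brain, sinus = sinus, regions = regions)
}
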