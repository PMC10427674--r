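#' Simulate correlated resting-state calcium dynamics
#'
#' Generates per-region dF/F traces as zero-mean, band-limited (0.3-3 Hz)
#' Gaussian processes whose epoch-wise correlation structure matches the
#' configured targets: `within_cluster_r` for pairs inside the same
#' macrocluster (anterior = Mot+Sen, posterior = Ret+Vis),
#' `between_cluster_r` between macroclusters during normoxia and
#' `between_cluster_r_hypoxia` during hypoxia.
#'
#' Band-limited noise is empirically whitened within each epoch segment and
#' then mixed with the Cholesky factor of the target correlation matrix, so
#' the empirical epoch-wise correlation matrix equals the target up to
#' numerical error; sub-windows of an epoch retain natural sampling
#' variability.
#'
#' @param config a [scenario_config()].
#' @return object of class `calcium_sim`: `traces` (frames x 8 matrix of
#'   dF/F, columns named by region), `time` (s), `fps`, `targets` (named list
#'   of 8x8 target correlation matrices), `regions`, `epoch_timeline`.
#' @export
simulate_calcium <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$rng_seed)
  fps <- config$fps_per_channel
  n <- round(config$duration_s * fps)
  regions <- region_table()
  targets <- list(
    normoxia = target_correlation(regions, config$within_cluster_r,
                                  config$between_cluster_r),
    hypoxia = target_correlation(regions, config$within_cluster_r,
                                 config$between_cluster_r_hypoxia)
  )
  chol_f <- lapply(targets, safe_chol, regions = regions)
  z <- matrix(stats::rnorm(n * 8), n, 8)
  z <- band_filter(z, fps)
  x <- matrix(0, n, 8)
  tl <- config$epoch_timeline
  for (k in seq_len(nrow(tl))) {
    idx <- frames_in_window(tl$start_s[k], tl$end_s[k], fps, n)
    L <- chol_f[[tl$label[k]]]
    seg <- z[idx, , drop = FALSE]
    if (length(idx) >= 16) {
      seg <- scale(seg, center = TRUE, scale = FALSE)
      seg <- seg %*% solve(chol(stats::cov(seg)))
    }
    x[idx, ] <- seg %*% L
  }
  x <- x * config$calcium_sd
  colnames(x) <- regions$region
  structure(list(traces = x, time = (seq_len(n) - 1) / fps, fps = fps,
                 targets = targets, regions = regions,
                 epoch_timeline = tl),
            class = "calcium_sim")
}

target_correlation <- function(regions, within_r, between_r) {
  same <- outer(regions$macrocluster, regions$macrocluster, "==")
  S <- ifelse(same, within_r, between_r)
  diag(S) <- 1
  dimnames(S) <- list(regions$region, regions$region)
  S
}

# Cholesky factor of a target correlation matrix; on failure, names the
# region pair that contributes most to the infeasibility.
safe_chol <- function(S, regions) {
  tryCatch(chol(S), error = function(e) {
    ev <- eigen(S, symmetric = TRUE)
    v <- abs(ev$vectors[, which.min(ev$values)])
    pair <- regions$region[order(v, decreasing = TRUE)[1:2]]
    stop(sprintf(
      "target correlation matrix is not positive semi-definite (offending pair: %s-%s)",
      pair[1], pair[2]), call. = FALSE)
  })
}

#' Simulate hypoxia hemodynamics
#'
#' Produces the two ground-truth hemodynamic components: (1) a global,
#' epoch-driven ramp shared by all brain pixels — dHbR rises quickly to a
#' plateau after hypoxia onset; dHbO shows a brief initial dip followed by a
#' slower rise; on return to normoxia dHbO overshoots and dHbR undershoots,
#' all scaled by the configured oxygen severity — and (2) a local
#' neurovascular component, the calcium trace of each region convolved with a
#' gamma impulse response (peak delay ~1.5 s, FWHM ~2 s), positive for HbO
#' and smaller/negative for HbR. Both components are zero during the
#' pre-hypoxia baseline.
#'
#' @param config a [scenario_config()].
#' @param calcium a [simulate_calcium()] result (or NULL to skip the local
#'   component).
#' @return object of class `hemo_sim` with `time`, `fps`, `global_hbo`,
#'   `global_hbr` (uM traces), `local_hbo`, `local_hbr` (frames x 8 uM), and
#'   the ramp parameters used.
#' @export
simulate_hemodynamics <- function(config, calcium = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  fps <- config$fps_per_channel
  n <- round(config$duration_s * fps)
  t <- (seq_len(n) - 1) / fps
  p <- config$hemo_ramp_params
  g_hbo <- numeric(n); g_hbr <- numeric(n)
  hyp <- config$epoch_timeline[config$epoch_timeline$label == "hypoxia", ,
                               drop = FALSE]
  for (k in seq_len(nrow(hyp))) {
    on <- hyp$start_s[k]; off <- hyp$end_s[k]
    d_on <- pmax(0, pmin(t, off) - on)      # time since onset, frozen at off
    during <- t >= on & t < off
    after <- t >= off
    d_off <- pmax(0, t - off)
    # HbR: fast saturating rise; release decay plus undershoot bump
    rise_r <- p$hbr_plateau_uM * (1 - exp(-d_on / p$hbr_tau_s))
    end_r <- p$hbr_plateau_uM * (1 - exp(-(off - on) / p$hbr_tau_s))
    g_hbr[during] <- g_hbr[during] + rise_r[during]
    g_hbr[after] <- g_hbr[after] + end_r * exp(-d_off[after] / p$release_tau_s) -
      p$hbr_undershoot_uM * gamma_bump(d_off[after], p$hbr_undershoot_tau_s)
    # HbO: slow saturating rise minus initial dip; release decay plus overshoot
    rise_o <- p$hbo_plateau_uM * (1 - exp(-d_on / p$hbo_tau_s)) -
      p$hbo_dip_uM * gamma_bump(d_on, p$hbo_dip_tau_s)
    end_o <- p$hbo_plateau_uM * (1 - exp(-(off - on) / p$hbo_tau_s))
    g_hbo[during] <- g_hbo[during] + rise_o[during]
    g_hbo[after] <- g_hbo[after] + end_o * exp(-d_off[after] / p$release_tau_s) +
      p$hbo_overshoot_uM * gamma_bump(d_off[after], p$overshoot_tau_s)
  }
  local_hbo <- matrix(0, n, 8); local_hbr <- matrix(0, n, 8)
  if (!is.null(calcium)) {
    h <- neurovascular_kernel(fps)
    if (length(h) > n) h <- h[seq_len(n)] / sum(h[seq_len(n)])
    for (r in 1:8) {
      conv <- stats::filter(calcium$traces[, r], h, sides = 1)
      conv[is.na(conv)] <- 0
      local_hbo[, r] <- config$coupling_hbo_uM * as.numeric(conv) /
        config$calcium_sd
      local_hbr[, r] <- config$coupling_ratio_hbr * local_hbo[, r]
    }
    colnames(local_hbo) <- colnames(local_hbr) <- colnames(calcium$traces)
  }
  structure(list(time = t, fps = fps, global_hbo = g_hbo, global_hbr = g_hbr,
                 local_hbo = local_hbo, local_hbr = local_hbr, params = p),
            class = "hemo_sim")
}

# Unit-peak bump (gamma-like), maximum 1 at d = tau.
gamma_bump <- function(d, tau) {
  (d / tau) * exp(1 - d / tau) * (d >= 0)
}

# Gamma impulse response, unit weight sum (acts as a delayed smoother so a
# sustained unit dF/F yields a unit-amplitude response); mode at 1.5 s.
neurovascular_kernel <- function(fps, shape = 4, scale = 0.5, length_s = 8) {
  u <- seq(0, length_s, by = 1 / fps)
  h <- stats::dgamma(u, shape = shape, scale = scale)
  h / sum(h)
}

#' Assemble per-pixel ground-truth maps
#'
#' Expands region-level calcium and hemodynamic simulations onto the pixel
#' grid of an atlas: every brain pixel carries the global hemodynamic ramp;
#' pixels inside a labelled region add that region's local neurovascular
#' component and its dF/F trace. Background pixels are zero.
#'
#' @param calcium a [simulate_calcium()] result.
#' @param hemo a [simulate_hemodynamics()] result.
#' @param atlas a [synthetic_atlas()] (its shape sets the map shape).
#' @return object of class `ground_truth`: list with `hbo`, `hbr`, `dff`
#'   ([rows, cols, frames] arrays), `atlas`, `calcium`, `hemo`.
#' @export
truth_maps <- function(calcium, hemo, atlas) {
  n <- length(hemo$time)
  shape <- dim(atlas$labels)
  npx <- prod(shape)
  lab <- as.integer(atlas$labels)
  brain <- as.logical(atlas$brain) & !as.logical(atlas$sinus)
  hbo <- matrix(0, npx, n); hbr <- matrix(0, npx, n); dff <- matrix(0, npx, n)
  hbo[brain, ] <- matrix(hemo$global_hbo, sum(brain), n, byrow = TRUE)
  hbr[brain, ] <- matrix(hemo$global_hbr, sum(brain), n, byrow = TRUE)
  for (r in 1:8) {
    px <- which(lab == r)
    if (!length(px)) next
    hbo[px, ] <- hbo[px, ] + matrix(hemo$local_hbo[, r], length(px), n,
                                    byrow = TRUE)
    hbr[px, ] <- hbr[px, ] + matrix(hemo$local_hbr[, r], length(px), n,
                                    byrow = TRUE)
    dff[px, ] <- matrix(calcium$traces[, r], length(px), n, byrow = TRUE)
  }
  structure(list(hbo = as_map_array(hbo, shape), hbr = as_map_array(hbr, shape),
                 dff = as_map_array(dff, shape), atlas = atlas,
                 calcium = calcium, hemo = hemo),
            class = "ground_truth")
}

#' Render the optical forward model
#'
#' Converts ground-truth concentration and dF/F maps into an interlaced
#' 4-color camera stack using the modified Beer-Lambert forward model:
#' reflectance channels follow
#' `R(t) = R0 * exp(-D * (eps_hbo * dHbO + eps_hbr * dHbR))` per pixel, and
#' the fluorescence channel is modulated both by neural dF/F and by
#' multiplicative hemodynamic attenuation at the excitation/emission bands.
#' Adds Gaussian sensor noise, optional rigid per-frame motion, and
#' interleaves frames in the fixed color order blue, green, amber, red at 4x
#' the per-channel rate.
#'
#' @param truth a [truth_maps()] result.
#' @param optical an [optical_model()].
#' @param config the [scenario_config()] used to build `truth`.
#' @return an `interlaced_stack` (see [interlaced_stack()]).
#' @export
render_optics <- function(truth, optical, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(optical, "optical_model"))
  set.seed(config$rng_seed + 1L)
  shape <- dim(truth$atlas$labels)
  n <- dim(truth$hbo)[3]
  brain <- truth$atlas$brain
  # Shared smooth scene texture so frames carry spatial structure
  texture <- 1 + 0.15 * smooth_field(shape)
  base_refl <- (2000 + 8000 * brain) * texture
  base_fluo <- (3000 + 9000 * brain) * texture
  A <- beer_lambert_matrix(optical$channels)
  hbo <- as_pixel_matrix(truth$hbo); hbr <- as_pixel_matrix(truth$hbr)
  chans <- vector("list", 4)
  names(chans) <- c("blue", "green", "amber", "red")
  att_f <- exp(-optical$fluo_pathlength_cm *
                 (optical$fluo_eps_hbo * hbo + optical$fluo_eps_hbr * hbr) * 1e-6)
  chans$blue <- as.numeric(base_fluo) * (1 + as_pixel_matrix(truth$dff)) * att_f
  for (ch in c("green", "amber", "red")) {
    chans[[ch]] <- as.numeric(base_refl) *
      exp(-(A[ch, "hbo"] * hbo + A[ch, "hbr"] * hbr))
  }
  fps_total <- 4 * config$fps_per_channel
  frames <- array(0, dim = c(shape[1], shape[2], 4L * n))
  for (k in 1:4) frames[, , seq(k, 4L * n, by = 4L)] <-
    as_map_array(chans[[k]], shape)
  motion <- NULL
  if (config$motion_amplitude_px > 0) {
    motion <- simulate_motion(4L * n, config$motion_amplitude_px)
    for (i in seq_len(4L * n)) {
      if (abs(motion$dx[i]) > 1e-12 || abs(motion$dy[i]) > 1e-12)
        frames[, , i] <- warp_affine(frames[, , i],
                                     translation_affine(motion$dx[i],
                                                        motion$dy[i]))
    }
  }
  if (config$noise_sd > 0)
    frames <- frames + stats::rnorm(length(frames), sd = config$noise_sd)
  n_clip <- sum(frames < 0)
  if (n_clip > 0) {
    frames[frames < 0] <- 0
    message(sprintf("render_optics: clipped %d negative intensities at 0",
                    n_clip))
  }
  frames[frames > 65535] <- 65535
  interlaced_stack(frames, fps_total,
                   color_order = c("blue", "green", "amber", "red"),
                   metadata = list(
                     fps_per_channel = config$fps_per_channel,
                     epoch_timeline = config$epoch_timeline,
                     fov_mm = config$fov_mm,
                     oxygen_level = config$oxygen_level,
                     motion_trace = motion,
                     rng_seed = config$rng_seed))
}

# Smooth zero-mean unit-scale Gaussian random field.
smooth_field <- function(shape, sigma = max(2, shape[2] / 16)) {
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  br <- EBImage::makeBrush(2 * ceiling(2 * sigma) + 1, "gaussian",
                           sigma = sigma)
  f <- EBImage::filter2(z, br)
  f <- f - mean(f)
  f / max(stats::sd(f), .Machine$double.eps)
}

# Smooth rigid jitter, clipped to +/- amplitude px.
simulate_motion <- function(n_frames, amplitude_px) {
  smooth1 <- function() {
    x <- stats::rnorm(n_frames)
    b <- signal::butter(2, 0.02, type = "low")
    x <- signal::filtfilt(b, x)
    amplitude_px * x / max(abs(x), .Machine$double.eps)
  }
  list(dx = smooth1(), dy = smooth1())
}

#' Run the full forward simulation
#'
#' Convenience wrapper: calcium, hemodynamics, ground-truth maps and optical
#' rendering in one call.
#'
#' @param config a [scenario_config()].
#' @param optical an [optical_model()].
#' @return list with `stack` (interlaced_stack), `truth` (ground_truth),
#'   `config`, `optical`.
#' @export
simulate_acquisition <- function(config, optical = optical_model()) {
  calcium <- simulate_calcium(config)
  hemo <- simulate_hemodynamics(config, calcium)
  atlas <- synthetic_atlas(config$image_shape)
  truth <- truth_maps(calcium, hemo, atlas)
  stack <- render_optics(truth, optical, config)
  list(stack = stack, truth = truth, config = config, optical = optical)
}
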