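#' Invert the modified Beer-Lambert law
#'
#' Converts the reflectance channels into per-pixel time series of hemoglobin
#' concentration changes. For each pixel and frame the over-determined linear
#' system
#' `-log(R_lambda(t) / R_lambda(0)) = D_lambda (eps_HbO,lambda dHbO + eps_HbR,lambda dHbR)`
#' is solved by ordinary least squares across the reflectance channels
#' (three equations, two unknowns). `R_lambda(0)` is the per-pixel temporal
#' mean over the baseline window (by default the first normoxia epoch).
#' Outputs are in uM; `dHbT = dHbO + dHbR` and
#' `sO2 = (HbO0 + dHbO) / (HbT0 + dHbT)` with the model's baseline
#' concentrations (60 and 40 uM).
#'
#' Pixels with non-positive intensities anywhere in the series are removed
#' from the mask (the logarithm is undefined there).
#'
#' @param reflectance named list of [channel_stack()] objects; names must
#'   match `optical$channels$channel`.
#' @param optical an [optical_model()].
#' @param baseline_frames integer frame indices of the baseline window; by
#'   default derived from `epoch_timeline` (first normoxia epoch) or the
#'   first 10% of frames if no timeline is given.
#' @param epoch_timeline optional timeline data.frame used to locate the
#'   baseline epoch.
#' @param mask optional logical matrix restricting the brain area.
#' @param baseline_margin_s seconds trimmed from the baseline epoch ends.
#' @return object of class `hemo_maps`: `hbo`, `hbr`, `hbt`, `so2`
#'   ([rows, cols, frames] arrays, uM and fraction), `mask`, `fps`.
#' @export
beer_lambert_invert <- function(reflectance, optical, baseline_frames = NULL,
                                epoch_timeline = NULL, mask = NULL,
                                baseline_margin_s = 0) {
  stopifnot(inherits(optical, "optical_model"))
  chans <- optical$channels$channel
  if (!all(chans %in% names(reflectance)))
    stop("reflectance channels missing: ",
         paste(setdiff(chans, names(reflectance)), collapse = ", "))
  reflectance <- reflectance[chans]
  d <- dim(reflectance[[1]]$frames)
  n <- d[3]; shape <- d[1:2]
  fps <- reflectance[[1]]$fps
  if (is.null(baseline_frames)) {
    baseline_frames <- if (!is.null(epoch_timeline)) {
      first_norm <- epoch_timeline[epoch_timeline$label == "normoxia", ][1, ]
      frames_in_window(first_norm$start_s + baseline_margin_s,
                       first_norm$end_s - baseline_margin_s, fps, n)
    } else seq_len(max(2L, floor(n / 10)))
  }
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  A <- beer_lambert_matrix(optical$channels)
  if (abs(det(crossprod(A))) < 1e-24)
    stop("singular extinction matrix: cannot separate HbO and HbR")
  P <- solve(crossprod(A), t(A))       # 2 x n_channels projector
  npx <- prod(shape)
  Y <- vector("list", length(chans))
  bad <- rep(FALSE, npx)
  for (k in seq_along(chans)) {
    X <- as_pixel_matrix(reflectance[[k]]$frames)
    bad <- bad | rowSums(X <= 0) > 0
    R0 <- rowMeans(X[, baseline_frames, drop = FALSE])
    bad <- bad | R0 <= 0
    Xr <- X / ifelse(R0 > 0, R0, 1)
    Xr[Xr <= 0] <- 1                    # excluded via mask below
    Y[[k]] <- -log(Xr)
  }
  if (any(bad & mask))
    message(sprintf("beer_lambert_invert: %d pixel(s) with non-positive intensity removed from mask",
                    sum(bad & mask)))
  mask <- mask & !matrix(bad, shape[1], shape[2])
  hbo <- matrix(0, npx, n); hbr <- matrix(0, npx, n)
  for (k in seq_along(chans)) {
    hbo <- hbo + P[1, k] * Y[[k]]
    hbr <- hbr + P[2, k] * Y[[k]]
  }
  hbt <- hbo + hbr
  maps <- structure(list(hbo = as_map_array(hbo, shape),
                         hbr = as_map_array(hbr, shape),
                         hbt = as_map_array(hbt, shape),
                         so2 = NULL, mask = mask, fps = fps,
                         baseline_frames = baseline_frames),
                    class = "hemo_maps")
  maps$so2 <- compute_so2(maps, optical)
  maps
}

#' Cerebral oxygen saturation
#'
#' `sO2(t) = (HbO0 + dHbO) / (HbT0 + dHbT)` per pixel and frame, as a
#' fraction. At zero concentration changes this is the baseline saturation
#' HbO0/HbT0 = 60/100 = 0.60. Pixel-frames where `HbT0 + dHbT <= 0` are set
#' to NA.
#'
#' @param hemo a `hemo_maps` object (or any list with `hbo` and `hbt`
#'   arrays in uM).
#' @param optical an [optical_model()] supplying the baselines.
#' @return array of sO2 fractions, same shape as `hemo$hbo`.
#' @export
compute_so2 <- function(hemo, optical = optical_model()) {
  denom <- optical$baseline_hbt + hemo$hbt
  so2 <- (optical$baseline_hbo + hemo$hbo) / denom
  so2[denom <= 0] <- NA_real_
  so2
}

#' Brain mask excluding the sagittal sinus and brain edges
#'
#' Starts from the atlas brain footprint, removes the midline sinus stripe
#' and erodes the boundary by `edge_margin_px` (disk-shaped structuring
#' element), mirroring the exclusion of the middle cerebral sinus and brain
#' edges from whole-brain statistics.
#'
#' @param mean_image mean intensity image (used only for shape checks; the
#'   synthetic atlas carries explicit brain/sinus annotations).
#' @param atlas atlas list with `brain` and `sinus` logical matrices.
#' @param edge_margin_px erosion margin in pixels (default 5).
#' @return logical matrix.
#' @export
make_brain_mask <- function(mean_image, atlas, edge_margin_px = 5) {
  stopifnot(all(dim(mean_image) == dim(atlas$brain)))
  mask <- atlas$brain & !atlas$sinus
  if (edge_margin_px > 0) {
    br <- EBImage::makeBrush(2 * edge_margin_px + 1, "disc")
    outside <- EBImage::dilate((!atlas$brain) * 1, br) > 0
    sinus_grown <- if (any(atlas$sinus))
      EBImage::dilate(atlas$sinus * 1, br) > 0 else atlas$sinus
    mask <- mask & !outside & !sinus_grown
  }
  if (!any(mask)) stop("brain mask is empty")
  mask
}

#' Exclude outliers from a time trace
#'
#' Values more than 3 standard deviations from the mean are set to NA. Mean
#' and standard deviation are computed once on the full trace (single pass).
#'
#' @param series numeric vector.
#' @param n_sd threshold in standard deviations (default 3).
#' @return the trace with outliers replaced by NA.
#' @export
exclude_outliers <- function(series, n_sd = 3) {
  s <- stats::sd(series, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(series)
  m <- mean(series, na.rm = TRUE)
  series[abs(series - m) > n_sd * s] <- NA_real_
  series
}

#' Quantify epoch-wise hemodynamic dynamics
#'
#' Summarizes one whole-brain mean trace per subject: the hypoxia plateau is
#' the mean over minutes 14.5-19.5, compared against the baseline mean over
#' minutes 4.5-9.5 of the same acquisition; the dip is the minimum within a
#' window after hypoxia onset (default minutes 10-11) and the overshoot the
#' maximum within a window after return to normoxia (default minutes 20-21).
#' Group summaries are mean +/- SEM over subjects (SEM = sd/sqrt(n)).
#'
#' @param traces numeric matrix (frames x subjects) or vector (one subject)
#'   of whole-brain mean values; outliers are excluded per subject first.
#' @param fps sampling rate, Hz.
#' @param windows_min named list of two-element minute windows: `baseline`,
#'   `plateau`, `dip`, `overshoot`.
#' @param remove_outliers logical; apply [exclude_outliers()] per trace.
#' @return object of class `epoch_summary`: `per_subject` data.frame
#'   (subject, baseline, plateau, dip, overshoot) and `group` data.frame
#'   (measure, mean, sem, n).
#' @export
quantify_epoch_dynamics <- function(traces, fps,
                                    windows_min = list(
                                      baseline = c(4.5, 9.5),
                                      plateau = c(14.5, 19.5),
                                      dip = c(10, 11),
                                      overshoot = c(20, 21)),
                                    remove_outliers = TRUE) {
  if (is.vector(traces)) traces <- matrix(traces, ncol = 1)
  n <- nrow(traces)
  idx <- lapply(windows_min, function(w) {
    if (w[2] * 60 * fps > n + 1e-9)
      stop(sprintf("window [%g, %g] min lies outside the acquisition",
                   w[1], w[2]))
    frames_in_window(w[1] * 60, w[2] * 60, fps, n)
  })
  per <- data.frame(subject = seq_len(ncol(traces)))
  vals <- apply(traces, 2, function(tr) {
    if (remove_outliers) tr <- exclude_outliers(tr)
    c(baseline = mean(tr[idx$baseline], na.rm = TRUE),
      plateau = mean(tr[idx$plateau], na.rm = TRUE),
      dip = min(tr[idx$dip], na.rm = TRUE),
      overshoot = max(tr[idx$overshoot], na.rm = TRUE))
  })
  per <- cbind(per, t(vals))
  grp <- data.frame(
    measure = c("baseline", "plateau", "dip", "overshoot"),
    mean = colMeans(t(vals)),
    sem = apply(t(vals), 2, stats::sd) / sqrt(ncol(traces)),
    n = ncol(traces)
  )
  rownames(grp) <- NULL
  structure(list(per_subject = per, group = grp, windows_min = windows_min,
                 fps = fps), class = "epoch_summary")
}

#' Whole-brain mean trace of a hemodynamic species
#'
#' @param maps a `hemo_maps` object.
#' @param species one of "hbo", "hbr", "hbt", "so2".
#' @return numeric vector, one value per frame (mean over the mask).
#' @export
whole_brain_trace <- function(maps, species = c("hbo", "hbr", "hbt", "so2")) {
  species <- match.arg(species)
  arr <- maps[[species]]
  m <- as_pixel_matrix(arr)
  colMeans(m[as.logical(maps$mask), , drop = FALSE], na.rm = TRUE)
}
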