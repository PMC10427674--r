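#' Regression-based hemodynamic correction of the fluorescence channel
#'
#' Hemoglobin absorption at the GCaMP excitation and emission bands modulates
#' the measured fluorescence. Because the three reflectance channels carry
#' the same hemodynamic information, regressing each pixel's fluorescence
#' trace on its reflectance traces (plus an intercept) and keeping the
#' residual removes most of the hemodynamic contamination without assuming
#' baseline concentrations or pathlength factors. The corrected trace is
#' `residual + intercept`, so its mean intensity level is preserved for the
#' downstream dF/F normalization.
#'
#' Reflectance traces are resampled onto the fluorescence timestamps by
#' linear interpolation before fitting. Pixels with rank-deficient
#' regressors (e.g. constant reflectance) fall back to an intercept-only
#' fit, counted in a message.
#'
#' @param fluo a [channel_stack()] (blue channel).
#' @param reflectance named list of reflectance [channel_stack()]s.
#' @param mask optional logical matrix; pixels outside are left untouched.
#' @param fit_frames optional frame indices to restrict the regression fit
#'   (e.g. normoxia epochs only); prediction/correction always covers the
#'   full acquisition. Default NULL fits on all frames.
#' @return list with `corrected` ([channel_stack()]), `coeffs` (pixels x
#'   (1 + n_channels) matrix of regression coefficients).
#' @export
hemodynamic_correction <- function(fluo, reflectance, mask = NULL,
                                   fit_frames = NULL) {
  stopifnot(inherits(fluo, "channel_stack"))
  d <- dim(fluo$frames)
  n <- d[3]; npx <- d[1] * d[2]
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  Yf <- as_pixel_matrix(fluo$frames)
  Xr <- lapply(reflectance, function(ch) {
    stopifnot(dim(ch$frames)[3] == n)
    m <- as_pixel_matrix(ch$frames)
    if (max(abs(ch$timestamps - fluo$timestamps)) > 1e-12) {
      t(apply(m, 1, function(tr)
        stats::approx(ch$timestamps, tr, xout = fluo$timestamps,
                      rule = 2)$y))
    } else m
  })
  nreg <- length(Xr)
  coeffs <- matrix(0, npx, nreg + 1)
  colnames(coeffs) <- c("intercept", names(reflectance))
  out <- Yf
  if (is.null(fit_frames)) fit_frames <- seq_len(n)
  n_fallback <- 0
  for (p in which(as.logical(mask))) {
    X <- cbind(1, vapply(Xr, function(m) m[p, ], numeric(n)))
    y <- Yf[p, ]
    qr_fit <- qr(X[fit_frames, , drop = FALSE])
    if (qr_fit$rank < ncol(X)) {
      n_fallback <- n_fallback + 1
      b <- c(mean(y[fit_frames]), rep(0, nreg))
    } else {
      b <- qr.coef(qr_fit, y[fit_frames])
    }
    coeffs[p, ] <- b
    out[p, ] <- y - X %*% b + b[1]
  }
  if (n_fallback > 0)
    message(sprintf("hemodynamic_correction: intercept-only fit for %d pixel(s) (rank-deficient regressors)",
                    n_fallback))
  list(corrected = channel_stack(fluo$channel, as_map_array(out, d[1:2]),
                                 fluo$fps, fluo$timestamps),
       coeffs = coeffs)
}

#' Band-passed dF/F normalization
#'
#' The baseline fluorescence F0 is the low-pass (< 0.3 Hz) component of each
#' pixel's trace; the signal of interest is the 0.3-3 Hz band-pass component.
#' `dF/F = band-pass(F) / F0`, computed with zero-phase 4th-order Butterworth
#' filters. Pixels whose F0 becomes non-positive anywhere are removed from
#' the mask.
#'
#' @param fluo corrected fluorescence [channel_stack()].
#' @param mask optional logical matrix.
#' @param band passband in Hz (default c(0.3, 3)).
#' @param baseline_cutoff low-pass cutoff for F0, Hz.
#' @return object of class `fluo_maps`: `dff` ([rows, cols, frames]), `f0`
#'   (pixel matrix of baseline traces is summarized by its temporal mean as
#'   a matrix), `mask`, `fps`.
#' @export
compute_dff <- function(fluo, mask = NULL, band = c(0.3, 3),
                        baseline_cutoff = 0.3) {
  stopifnot(inherits(fluo, "channel_stack"))
  fps <- fluo$fps
  if (fps <= 2 * band[2])
    stop(sprintf("fps %g Hz too low for a %g Hz band edge", fps, band[2]))
  d <- dim(fluo$frames)
  Y <- as_pixel_matrix(fluo$frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  px <- which(as.logical(mask))
  dff <- matrix(0, nrow(Y), ncol(Y))
  f0_mean <- matrix(NA_real_, d[1], d[2])
  bad <- logical(length(px))
  for (i in seq_along(px)) {
    y <- Y[px[i], ]
    f0 <- low_filter(y, fps, cutoff = baseline_cutoff)
    if (any(f0 <= 0)) { bad[i] <- TRUE; next }
    dff[px[i], ] <- band_filter(y, fps, low = band[1], high = band[2]) / f0
    f0_mean[px[i]] <- mean(f0)
  }
  if (any(bad)) {
    message(sprintf("compute_dff: %d pixel(s) with non-positive baseline removed from mask",
                    sum(bad)))
    mask[px[bad]] <- FALSE
  }
  structure(list(dff = as_map_array(dff, d[1:2]), f0 = f0_mean, mask = mask,
                 fps = fps, band = band),
            class = "fluo_maps")
}

#' Moving-window standard deviation of a trace
#'
#' Centered moving sample standard deviation (n-1 normalization); at 20 Hz
#' the default 10-frame window spans 500 ms. Edge windows are truncated to
#' the available frames, not padded.
#'
#' @param trace numeric vector.
#' @param window_frames window length in frames (default 10).
#' @return numeric vector of the same length.
#' @export
windowed_std <- function(trace, window_frames = 10) {
  n <- length(trace)
  if (window_frames < 2) stop("window must span at least 2 frames")
  if (n < window_frames) stop("trace shorter than the window")
  before <- floor((window_frames - 1) / 2)
  after <- window_frames - 1 - before
  vapply(seq_len(n), function(i) {
    stats::sd(trace[max(1, i - before):min(n, i + after)])
  }, numeric(1))
}
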