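# Internal helpers shared across modules.

# Zero-phase Butterworth band-pass, applied column-wise. The trace mean is
# removed first and the ends are odd-reflection padded before filtering, so
# a constant trace maps to exactly zero and edge transients stay small.
band_filter <- function(x, fps, low = 0.3, high = 3, order = 4) {
  ny <- fps / 2
  if (high >= ny) stop("band edge at or above Nyquist (", ny, " Hz)")
  b <- signal::butter(order, c(low, high) / ny, type = "pass")
  apply_filtfilt(x, b, padlen = ceiling(2 * fps / low), keep_mean = FALSE)
}

# Zero-phase Butterworth low-pass (passes DC: the mean is restored).
low_filter <- function(x, fps, cutoff = 0.3, order = 4) {
  ny <- fps / 2
  b <- signal::butter(order, cutoff / ny, type = "low")
  apply_filtfilt(x, b, padlen = ceiling(2 * fps / cutoff), keep_mean = TRUE)
}

apply_filtfilt <- function(x, b, padlen, keep_mean) {
  ff <- function(col) {
    n <- length(col)
    mu <- mean(col)
    col <- col - mu
    p <- min(n - 1, padlen)
    ext <- if (p >= 1)
      c(2 * col[1] - col[(p + 1):2], col, 2 * col[n] - col[(n - 1):(n - p)])
    else col
    y <- signal::filtfilt(b, ext)
    y <- y[(p + 1):(p + n)]
    if (keep_mean) y + mu else y
  }
  if (is.matrix(x)) apply(x, 2, ff) else ff(x)
}

# Frame indices (1-based) of the half-open time window [start_s, end_s);
# frame i covers time (i-1)/fps.
frames_in_window <- function(start_s, end_s, fps, n_frames) {
  i0 <- floor(start_s * fps) + 1L
  i1 <- floor(end_s * fps)
  idx <- seq.int(max(1L, i0), min(n_frames, i1))
  if (length(idx) == 0)
    stop(sprintf("window [%g, %g) s lies outside the acquisition", start_s,
                 end_s))
  idx
}

# Frame indices belonging to epochs with the given label, optionally trimmed
# by a transition margin at both ends of each epoch.
epoch_frames <- function(timeline, label, fps, n_frames, margin_s = 0) {
  rows <- timeline[timeline$label == label, , drop = FALSE]
  if (nrow(rows) == 0) return(integer(0))
  idx <- integer(0)
  for (k in seq_len(nrow(rows))) {
    s <- rows$start_s[k] + margin_s
    e <- rows$end_s[k] - margin_s
    if (e > s) idx <- c(idx, frames_in_window(s, e, fps, n_frames))
  }
  sort(unique(idx))
}

# Flatten [rows, cols, time] array to pixels x time matrix and back.
as_pixel_matrix <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1] * d[2], ncol = d[3])
}

as_map_array <- function(mat, shape) {
  array(mat, dim = c(shape[1], shape[2], ncol(mat)))
}
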