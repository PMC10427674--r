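#' Interlaced multicolor stack
#'
#' Container for a raw time-interlaced acquisition: frames cycle through the
#' illumination colors in a fixed order at `fps_total` Hz, so each color is
#' sampled at `fps_total / length(color_order)` Hz. Trailing frames that do
#' not complete a full color cycle are dropped with a message.
#'
#' @param frames numeric array [rows, cols, time], intensity counts (>= 0).
#' @param fps_total total camera frame rate, Hz.
#' @param color_order character vector of channel labels in cycle order.
#' @param metadata list of acquisition descriptors (epoch timeline, fov, ...).
#' @return object of class `interlaced_stack`.
#' @export
interlaced_stack <- function(frames, fps_total,
                             color_order = c("blue", "green", "amber", "red"),
                             metadata = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (min(frames) < 0) stop("intensities must be non-negative")
  nc <- length(color_order)
  n <- dim(frames)[3]
  n_keep <- nc * (n %/% nc)
  if (n_keep < n) {
    message(sprintf("dropping %d trailing frame(s) of an incomplete color cycle",
                    n - n_keep))
    frames <- frames[, , seq_len(n_keep), drop = FALSE]
  }
  structure(list(frames = frames, fps_total = fps_total,
                 color_order = color_order, metadata = metadata),
            class = "interlaced_stack")
}

#' @export
print.interlaced_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Interlaced stack: %d x %d px, %d frames at %g Hz (%s; %g Hz per color)\n",
              d[1], d[2], d[3], x$fps_total,
              paste(x$color_order, collapse = ","),
              x$fps_total / length(x$color_order)))
  invisible(x)
}

#' Single-channel stack
#'
#' @param channel channel label.
#' @param frames numeric array [rows, cols, time].
#' @param fps per-channel frame rate, Hz.
#' @param timestamps acquisition time of each frame, seconds.
#' @return object of class `channel_stack`.
#' @export
channel_stack <- function(channel, frames, fps, timestamps) {
  stopifnot(length(timestamps) == dim(frames)[3],
            !is.unsorted(timestamps, strictly = TRUE))
  structure(list(channel = channel, frames = frames, fps = fps,
                 timestamps = timestamps), class = "channel_stack")
}

#' Demultiplex an interlaced stack into per-color channels
#'
#' Channel k (0-based position in `color_order`) receives frames
#' k, k+n, k+2n, ...; its timestamps are offset by `k / fps_total` so the
#' within-cycle phase of each color is preserved. An 80 Hz, 4-color stack
#' yields 20 Hz per channel.
#'
#' @param stack an [interlaced_stack()].
#' @return named list of [channel_stack()] objects, one per color.
#' @export
demultiplex <- function(stack) {
  stopifnot(inherits(stack, "interlaced_stack"))
  nc <- length(stack$color_order)
  n <- dim(stack$frames)[3]
  fps <- stack$fps_total / nc
  out <- lapply(seq_len(nc), function(k) {
    idx <- seq(k, n, by = nc)
    channel_stack(stack$color_order[k],
                  stack$frames[, , idx, drop = FALSE],
                  fps = fps,
                  timestamps = (idx - 1) / stack$fps_total)
  })
  names(out) <- stack$color_order
  out
}

#' Re-interleave channel stacks into a single stack
#'
#' Inverse of [demultiplex()]: `interleave_channels(demultiplex(s))`
#' reproduces `s` frame for frame.
#'
#' @param channels named list of [channel_stack()] objects in cycle order.
#' @param metadata metadata for the rebuilt stack.
#' @return an [interlaced_stack()].
#' @export
interleave_channels <- function(channels, metadata = list()) {
  nc <- length(channels)
  n <- dim(channels[[1]]$frames)[3]
  d <- dim(channels[[1]]$frames)
  frames <- array(0, dim = c(d[1], d[2], nc * n))
  for (k in seq_len(nc)) frames[, , seq(k, nc * n, by = nc)] <-
    channels[[k]]$frames
  interlaced_stack(frames, fps_total = nc * channels[[1]]$fps,
                   color_order = names(channels), metadata = metadata)
}

#' Write a simulated acquisition to disk
#'
#' Persists an interlaced stack and its ground truth as a plain-file dataset:
#' a multi-page 16-bit TIFF (`stack.tif`), a YAML sidecar with the color
#' order, frame rates, epoch timeline and field of view (`sidecar.yaml`),
#' ground-truth CSV tables (calcium traces, global hemodynamics, region
#' table, optional motion trace) and the atlas as a 3-page integer TIFF
#' (labels, brain, sinus).
#'
#' @param stack an [interlaced_stack()].
#' @param truth a [truth_maps()] result, or NULL to write the stack alone.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(stack, truth, path) {
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create fixture directory: ", path)
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(i)
    round(stack$frames[, , i]) / 65535)
  r <- tryCatch(tiff::writeTIFF(pages, file.path(path, "stack.tif"),
                                bits.per.sample = 16, compression = "none"),
                error = function(e)
                  stop("failed to write ", file.path(path, "stack.tif"), ": ",
                       conditionMessage(e)))
  meta <- stack$metadata
  tl <- meta$epoch_timeline
  sidecar <- list(
    color_order = as.list(stack$color_order),
    fps_total = stack$fps_total,
    fps_per_channel = stack$fps_total / length(stack$color_order),
    n_frames = d[3],
    shape = as.integer(d[1:2]),
    fov_mm = if (!is.null(meta$fov_mm)) as.numeric(meta$fov_mm) else NULL,
    oxygen_level = meta$oxygen_level,
    epoch_timeline = if (!is.null(tl)) lapply(seq_len(nrow(tl)), function(i)
      list(label = tl$label[i], start_s = tl$start_s[i], end_s = tl$end_s[i]))
    else NULL
  )
  yaml::write_yaml(sidecar, file.path(path, "sidecar.yaml"))
  if (!is.null(truth)) {
    cal <- data.frame(time_s = truth$calcium$time, truth$calcium$traces,
                      check.names = FALSE)
    utils::write.csv(cal, file.path(path, "truth_calcium.csv"),
                     row.names = FALSE)
    hemo <- data.frame(time_s = truth$hemo$time,
                       global_hbo = truth$hemo$global_hbo,
                       global_hbr = truth$hemo$global_hbr)
    utils::write.csv(hemo, file.path(path, "truth_hemo.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$atlas$regions, file.path(path, "regions.csv"),
                     row.names = FALSE)
    tiff::writeTIFF(list(truth$atlas$labels / 65535,
                         truth$atlas$brain / 65535,
                         truth$atlas$sinus / 65535),
                    file.path(path, "atlas.tif"), bits.per.sample = 16,
                    compression = "none")
    if (!is.null(meta$motion_trace))
      utils::write.csv(data.frame(frame = seq_along(meta$motion_trace$dx),
                                  dx = meta$motion_trace$dx,
                                  dy = meta$motion_trace$dy),
                       file.path(path, "truth_motion.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an acquisition fixture
#'
#' Reads `stack.tif` + `sidecar.yaml` written by [write_fixture()] (or any
#' acquisition in that layout) and validates the metadata against the pixel
#' data.
#'
#' @param path dataset directory.
#' @return an [interlaced_stack()].
#' @export
read_acquisition <- function(path) {
  tif <- file.path(path, "stack.tif")
  yml <- file.path(path, "sidecar.yaml")
  if (!file.exists(yml)) stop("missing sidecar: ", yml)
  if (!file.exists(tif)) stop("missing stack: ", tif)
  sc <- yaml::read_yaml(yml)
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != sc$n_frames)
    stop(sprintf("frame count mismatch in %s: sidecar declares %d, file has %d",
                 tif, sc$n_frames, length(pages)))
  d <- dim(pages[[1]])
  if (!all(d == sc$shape))
    stop(sprintf("frame shape mismatch: sidecar %s, file %s",
                 paste(sc$shape, collapse = "x"), paste(d, collapse = "x")))
  frames <- array(0, dim = c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- round(pages[[i]] * 65535)
  tl <- NULL
  if (!is.null(sc$epoch_timeline))
    tl <- do.call(rbind, lapply(sc$epoch_timeline, as.data.frame))
  interlaced_stack(frames, fps_total = sc$fps_total,
                   color_order = unlist(sc$color_order),
                   metadata = list(fps_per_channel =
                                     sc$fps_total / length(sc$color_order),
                                   epoch_timeline = tl,
                                   fov_mm = sc$fov_mm,
                                   oxygen_level = sc$oxygen_level))
}

#' Read ground-truth tables of a fixture
#'
#' @param path dataset directory written by [write_fixture()].
#' @return list with `calcium` (data.frame), `hemo` (data.frame), `regions`
#'   (data.frame), `atlas` (labels/brain/sinus matrices), and `motion`
#'   (data.frame or NULL).
#' @export
read_fixture_truth <- function(path) {
  cal <- utils::read.csv(file.path(path, "truth_calcium.csv"),
                         check.names = FALSE)
  hemo <- utils::read.csv(file.path(path, "truth_hemo.csv"))
  regions <- utils::read.csv(file.path(path, "regions.csv"),
                             stringsAsFactors = FALSE)
  pages <- tiff::readTIFF(file.path(path, "atlas.tif"), all = TRUE)
  atlas <- list(labels = matrix(as.integer(round(pages[[1]] * 65535)),
                                nrow(pages[[1]])),
                brain = matrix(round(pages[[2]] * 65535) > 0, nrow(pages[[2]])),
                sinus = matrix(round(pages[[3]] * 65535) > 0, nrow(pages[[3]])),
                regions = regions)
  mfile <- file.path(path, "truth_motion.csv")
  motion <- if (file.exists(mfile)) utils::read.csv(mfile) else NULL
  list(calcium = cal, hemo = hemo, regions = regions, atlas = atlas,
       motion = motion)
}
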