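# Frame co-registration: affine transforms estimated by minimizing the mean
# squared error to a reference frame, with an optional smooth displacement
# field refinement. All geometry uses 0-based (row, col) pixel coordinates
# and bilinear resampling.

#' Affine matrix for a rigid translation
#'
#' Returns the 2x3 sampling matrix that shifts image content by
#' `(dr, dc)` pixels (row, col): the warped image samples the source at
#' `(r - dr, c - dc)`.
#'
#' @param dr,dc content shift in pixels along rows / columns.
#' @return 2x3 affine matrix.
#' @export
translation_affine <- function(dr, dc) {
  matrix(c(1, 0, -dr, 0, 1, -dc), 2, 3, byrow = TRUE)
}

identity_affine <- function() matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)

#' Invert a 2x3 affine sampling matrix
#' @param M 2x3 affine matrix.
#' @return 2x3 affine matrix of the inverse mapping.
#' @export
invert_affine <- function(M) {
  A <- M[, 1:2]; b <- M[, 3]
  Ai <- solve(A)
  cbind(Ai, -Ai %*% b)
}

# Core resampler: sample img at source coordinates (sr, sc), 0-based.
warp_coords <- function(img, sr, sc, fill = c("na", "edge", "zero"),
                        interp = c("bilinear", "nearest")) {
  fill <- match.arg(fill); interp <- match.arg(interp)
  nr <- nrow(img); nc <- ncol(img)
  out_shape <- if (is.matrix(sr)) dim(sr) else c(length(sr), 1L)
  sr <- as.vector(sr); sc <- as.vector(sc)
  valid <- sr >= 0 & sr <= nr - 1 & sc >= 0 & sc <= nc - 1
  sr <- pmin(pmax(sr, 0), nr - 1)
  sc <- pmin(pmax(sc, 0), nc - 1)
  if (interp == "nearest") {
    out <- img[cbind(round(sr) + 1, round(sc) + 1)]
  } else {
    r0 <- pmin(floor(sr), nr - 2); c0 <- pmin(floor(sc), nc - 2)
    wr <- sr - r0; wc <- sc - c0
    out <- (1 - wr) * (1 - wc) * img[cbind(r0 + 1, c0 + 1)] +
      wr * (1 - wc) * img[cbind(r0 + 2, c0 + 1)] +
      (1 - wr) * wc * img[cbind(r0 + 1, c0 + 2)] +
      wr * wc * img[cbind(r0 + 2, c0 + 2)]
  }
  if (fill == "na") out[!valid] <- NA_real_
  if (fill == "zero") out[!valid] <- 0
  matrix(out, out_shape[1], out_shape[2])
}

#' Apply a 2x3 affine transform to an image
#'
#' @param img numeric matrix.
#' @param M 2x3 affine sampling matrix (output (r,c,1) -> source (r,c)).
#' @param fill out-of-bounds handling: NA, clamp to edge, or zero.
#' @return warped matrix, same shape.
#' @export
warp_affine <- function(img, M, fill = "edge") {
  g <- coord_grid(dim(img))
  sr <- M[1, 1] * g$r + M[1, 2] * g$c + M[1, 3]
  sc <- M[2, 1] * g$r + M[2, 2] * g$c + M[2, 3]
  warp_coords(img, sr, sc, fill = fill)
}

coord_grid <- function(shape) {
  list(r = matrix(0:(shape[1] - 1), shape[1], shape[2]),
       c = matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE))
}

mse_to <- function(a, b) mean((a - b)^2, na.rm = TRUE)

presmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::filter2(img, EBImage::makeBrush(2 * ceiling(3 * sigma) + 1,
                                           "gaussian", sigma = sigma))
}

# Integer translation search by direct MSE minimization over a small range.
integer_shift <- function(moving, ref, max_shift = 5) {
  best <- c(0, 0); best_mse <- Inf
  for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
    m <- mse_to(warp_affine(moving, translation_affine(-dr, -dc), fill = "na"),
                ref)
    if (is.finite(m) && m < best_mse) { best_mse <- m; best <- c(dr, dc) }
  }
  best
}

#' Estimate the affine transform aligning one frame to a reference
#'
#' Minimizes the mean squared error between the warped moving frame and the
#' reference. Starts from an integer translation search, refines the
#' translation continuously, then (for `mode = "affine"`) refines all six
#' parameters by Nelder-Mead.
#'
#' Both images are Gaussian pre-smoothed (`presmooth_sigma`) for the
#' optimization, which suppresses the sub-pixel bias that interpolation
#' attenuation otherwise induces; the reported residuals are computed on the
#' unsmoothed images.
#'
#' @param moving,ref numeric matrices of equal shape.
#' @param mode "affine" or "translation".
#' @param max_shift search range of the integer initialization, px.
#' @param init optional 2x3 starting transform.
#' @param presmooth_sigma Gaussian sigma (px) of the pre-smoothing; 0 disables.
#' @return list with `M` (2x3), `mse_before`, `mse_after`, `converged`.
#' @export
estimate_affine <- function(moving, ref, mode = c("affine", "translation"),
                            max_shift = 5, init = NULL, presmooth_sigma = 1) {
  mode <- match.arg(mode)
  if (stats::sd(moving) == 0 || stats::sd(ref) == 0)
    stop("degenerate (constant) image: registration is undefined")
  mse_before <- mse_to(moving, ref)
  mov_s <- presmooth(moving, presmooth_sigma)
  ref_s <- presmooth(ref, presmooth_sigma)
  obj_t <- function(p) {
    m <- mse_to(warp_affine(mov_s, translation_affine(-p[1], -p[2]),
                            fill = "na"), ref_s)
    if (!is.finite(m)) 1e12 else m
  }
  p0 <- if (is.null(init)) integer_shift(mov_s, ref_s, max_shift) else
    init[, 3]
  ot <- stats::optim(p0, obj_t, method = "Nelder-Mead",
                     control = list(reltol = 1e-10, maxit = 400))
  M <- translation_affine(-ot$par[1], -ot$par[2])
  converged <- ot$convergence == 0
  if (mode == "affine") {
    obj_a <- function(p) {
      Mp <- matrix(c(1 + p[1], p[2], p[3], p[4], 1 + p[5], p[6]), 2, 3,
                   byrow = TRUE)
      m <- mse_to(warp_affine(mov_s, Mp, fill = "na"), ref_s)
      if (!is.finite(m)) 1e12 else m
    }
    pa0 <- c(0, 0, M[1, 3], 0, 0, M[2, 3])
    oa <- stats::optim(pa0, obj_a, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 1000,
                                      parscale = c(0.01, 0.01, 1, 0.01, 0.01, 1)))
    if (oa$value <= ot$value) {
      p <- oa$par
      M <- matrix(c(1 + p[1], p[2], p[3], p[4], 1 + p[5], p[6]), 2, 3,
                  byrow = TRUE)
      converged <- oa$convergence == 0
    }
  }
  mse_after <- mse_to(warp_affine(moving, M, fill = "na"), ref)
  list(M = M, mse_before = mse_before, mse_after = mse_after,
       converged = converged)
}

# Coarse smooth displacement field (rows x cols x 2, px): local translation
# estimated on a grid of blocks, Gaussian-smoothed and bilinearly upsampled.
estimate_displacement_field <- function(moving, ref, grid_n = 5,
                                        block_search = 2, sigma = 1) {
  nr <- nrow(moving); nc <- ncol(moving)
  centers_r <- round(seq(1, nr, length.out = grid_n + 2))[2:(grid_n + 1)]
  centers_c <- round(seq(1, nc, length.out = grid_n + 2))[2:(grid_n + 1)]
  half <- max(4, floor(min(nr, nc) / (2 * grid_n)))
  ur <- matrix(0, grid_n, grid_n); uc <- matrix(0, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    rs <- max(1, centers_r[i] - half):min(nr, centers_r[i] + half)
    cs <- max(1, centers_c[j] - half):min(nc, centers_c[j] + half)
    if (stats::sd(ref[rs, cs]) == 0) next
    s <- integer_shift(moving[rs, cs], ref[rs, cs], block_search)
    ur[i, j] <- -s[1]; uc[i, j] <- -s[2]
  }
  br <- EBImage::makeBrush(2 * ceiling(2 * sigma) + 1, "gaussian", sigma = sigma)
  ur <- EBImage::filter2(ur, br); uc <- EBImage::filter2(uc, br)
  g <- coord_grid(c(nr, nc))
  # map full-res coordinates into grid coordinates (0-based) and resample
  gr <- (g$r - (centers_r[1] - 1)) / (centers_r[2] - centers_r[1] + 1e-12)
  gc <- (g$c - (centers_c[1] - 1)) / (centers_c[2] - centers_c[1] + 1e-12)
  field <- array(0, dim = c(nr, nc, 2))
  field[, , 1] <- warp_coords(ur, gr, gc, fill = "edge")
  field[, , 2] <- warp_coords(uc, gr, gc, fill = "edge")
  field
}

#' Co-register every frame of a channel to a reference frame
#'
#' Each frame is aligned to the reference (by default the first frame of the
#' acquisition) with the affine transform that minimizes the mean squared
#' error, optionally followed by a smooth displacement-field refinement
#' (a coarse diffeomorphic stage). The frame is resampled once through the
#' composed transform. Frames whose registration would increase the MSE to
#' the reference keep the identity transform, with a warning.
#'
#' @param channel a [channel_stack()].
#' @param reference_index index of the reference frame (default 1).
#' @param mode "affine" or "translation".
#' @param diffeomorphic logical; add the displacement-field stage.
#' @param max_shift integer search range, px.
#' @return list with `stack` (registered [channel_stack()]) and `result`
#'   (data.frame: frame, a11..a23, mse_before, mse_after).
#' @export
register_within <- function(channel, reference_index = 1,
                            mode = c("affine", "translation"),
                            diffeomorphic = FALSE, max_shift = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(channel, "channel_stack"))
  n <- dim(channel$frames)[3]
  if (n < 2) stop("need at least 2 frames to register")
  ref <- channel$frames[, , reference_index]
  out <- channel$frames
  res <- data.frame(frame = seq_len(n), a11 = 1, a12 = 0, a13 = 0,
                    a21 = 0, a22 = 1, a23 = 0, mse_before = NA_real_,
                    mse_after = NA_real_)
  prev <- NULL
  n_fallback <- 0
  for (i in seq_len(n)) {
    mov <- channel$frames[, , i]
    if (i == reference_index) {
      res$mse_before[i] <- res$mse_after[i] <- 0
      next
    }
    est <- estimate_affine(mov, ref, mode = mode, max_shift = max_shift)
    M <- est$M
    g <- coord_grid(dim(ref))
    sr <- M[1, 1] * g$r + M[1, 2] * g$c + M[1, 3]
    sc <- M[2, 1] * g$r + M[2, 2] * g$c + M[2, 3]
    if (diffeomorphic) {
      warped <- warp_coords(mov, sr, sc, fill = "edge")
      field <- estimate_displacement_field(warped, ref)
      sr2 <- sr + field[, , 1]; sc2 <- sc + field[, , 2]
      if (mse_to(warp_coords(mov, sr2, sc2, fill = "na"), ref) < est$mse_after) {
        sr <- sr2; sc <- sc2
      }
    }
    warped <- warp_coords(mov, sr, sc, fill = "edge")
    m_after <- mse_to(warped, ref)
    if (m_after > est$mse_before) {
      n_fallback <- n_fallback + 1
      res$mse_before[i] <- res$mse_after[i] <- est$mse_before
      prev <- NULL
      next
    }
    out[, , i] <- warped
    res[i, c("a11", "a12", "a13", "a21", "a22", "a23")] <-
      c(M[1, ], M[2, ])
    res$mse_before[i] <- est$mse_before
    res$mse_after[i] <- m_after
    prev <- M
  }
  if (n_fallback > 0)
    warning(sprintf("registration kept the identity transform for %d frame(s)",
                    n_fallback))
  list(stack = channel_stack(channel$channel, out, channel$fps,
                             channel$timestamps),
       result = res)
}

#' Co-register a session to the reference session of the same subject
#'
#' Estimates the transform aligning a representative frame of a new session
#' onto the reference session (the subject's first acquisition), so that
#' atlas and ROIs defined on the reference can be carried to the new session.
#'
#' @param session_ref_frame,session_new_frame numeric matrices (same shape),
#'   typically temporal mean frames.
#' @param diffeomorphic logical; add a displacement-field refinement.
#' @return list with `M` (2x3 sampling matrix such that warping the new
#'   frame with it aligns to the reference), `M_inv`, optional `field`,
#'   `mse_before`, `mse_after`.
#' @export
register_between_days <- function(session_ref_frame, session_new_frame,
                                  diffeomorphic = FALSE) {
  stopifnot(all(dim(session_ref_frame) == dim(session_new_frame)))
  est <- estimate_affine(session_new_frame, session_ref_frame)
  field <- NULL
  if (diffeomorphic) {
    warped <- warp_affine(session_new_frame, est$M, fill = "edge")
    field <- estimate_displacement_field(warped, session_ref_frame)
  }
  list(M = est$M, M_inv = invert_affine(est$M), field = field,
       mse_before = est$mse_before, mse_after = est$mse_after)
}

#' Carry reference-session atlas labels onto a new session grid
#'
#' @param labels integer label matrix in reference-session coordinates.
#' @param reg a [register_between_days()] result.
#' @return integer label matrix in new-session coordinates (nearest-neighbor
#'   resampling; out-of-view pixels are 0).
#' @export
map_atlas <- function(labels, reg) {
  g <- coord_grid(dim(labels))
  M <- reg$M_inv
  sr <- M[1, 1] * g$r + M[1, 2] * g$c + M[1, 3]
  sc <- M[2, 1] * g$r + M[2, 2] * g$c + M[2, 3]
  out <- warp_coords(labels, sr, sc, fill = "zero", interp = "nearest")
  matrix(as.integer(out), nrow(labels), ncol(labels))
}
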