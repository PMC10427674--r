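#' Fisher z-transformation
#'
#' `z = atanh(r)` with |r| clipped at 1 - 1e-12 so perfect correlations stay
#' finite. Odd and monotone on (-1, 1).
#'
#' @param r correlation value(s).
#' @param clip clipping bound on |r|.
#' @return transformed value(s).
#' @export
fisher_z <- function(r, clip = 1 - 1e-12) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Global signal regression
#'
#' Computes the global signal `g(t)` (mask-mean over pixels per frame) and
#' replaces each pixel trace by its residual from the least-squares fit on
#' `(1, g)`. Residuals are exactly orthogonal to the global signal. Used
#' only for seed-pixel correlation maps; quantitative statistics are
#' computed on data without GSR.
#'
#' @param maps numeric array [rows, cols, frames].
#' @param mask logical matrix.
#' @return array of the same shape with regressed traces (pixels outside
#'   the mask are zeroed).
#' @export
global_signal_regression <- function(maps, mask) {
  d <- dim(maps)
  stopifnot(length(d) == 3, all(dim(mask) == d[1:2]), any(mask))
  Y <- as_pixel_matrix(maps)
  px <- which(as.logical(mask))
  g <- colMeans(Y[px, , drop = FALSE])
  gc <- g - mean(g)
  den <- sum(gc^2)
  if (den < .Machine$double.eps) {
    warning("global signal has zero variance; returning input unchanged")
    return(maps)
  }
  Ysub <- Y[px, , drop = FALSE]
  beta <- (Ysub %*% gc) / den
  resid <- Ysub - rowMeans(Ysub) - beta %*% rbind(gc)
  out <- matrix(0, nrow(Y), ncol(Y))
  out[px, ] <- resid
  as_map_array(out, d[1:2])
}

#' Extract seed definitions from an atlas
#'
#' For each of the 8 regions, the seed is the integer-rounded centroid of the
#' region's pixels expanded into a lattice disk of radius 3 px (squared
#' distance <= 9; 29 pixels when unmasked), intersected with the brain mask.
#' A centroid falling outside the mask is moved to the nearest in-mask pixel
#' (with a message).
#'
#' @param atlas atlas list with `labels` and `regions`.
#' @param brain_mask logical matrix.
#' @param radius_px disk radius (default 3).
#' @return object of class `seed_set`: data.frame `seeds` (region,
#'   macrocluster, row, col) and list `pixels` of n x 2 index matrices.
#' @export
extract_seeds <- function(atlas, brain_mask, radius_px = 3) {
  regions <- atlas$regions
  offs <- disk_offsets(radius_px)
  seeds <- regions[, c("id", "region", "macrocluster", "side")]
  seeds$row <- NA_integer_; seeds$col <- NA_integer_
  pixels <- vector("list", nrow(regions))
  names(pixels) <- regions$region
  mask_idx <- which(brain_mask, arr.ind = TRUE)
  for (k in seq_len(nrow(regions))) {
    px <- which(atlas$labels == regions$id[k], arr.ind = TRUE)
    if (nrow(px) == 0) stop("atlas region has no pixels: ", regions$region[k])
    ctr <- round(colMeans(px))
    if (!brain_mask[ctr[1], ctr[2]]) {
      dd <- (mask_idx[, 1] - ctr[1])^2 + (mask_idx[, 2] - ctr[2])^2
      ctr <- mask_idx[which.min(dd), ]
      message("extract_seeds: centroid of ", regions$region[k],
              " moved to nearest in-mask pixel")
    }
    disk <- cbind(ctr[1] + offs[, 1], ctr[2] + offs[, 2])
    keep <- disk[, 1] >= 1 & disk[, 1] <= nrow(brain_mask) &
      disk[, 2] >= 1 & disk[, 2] <= ncol(brain_mask)
    disk <- disk[keep, , drop = FALSE]
    disk <- disk[brain_mask[disk], , drop = FALSE]
    if (nrow(disk) == 0) stop("seed disk empty for region ", regions$region[k])
    seeds$row[k] <- ctr[1]; seeds$col[k] <- ctr[2]
    pixels[[k]] <- disk
  }
  structure(list(seeds = seeds, pixels = pixels, radius_px = radius_px),
            class = "seed_set")
}

# Lattice offsets of a disk with squared radius <= r^2.
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, ])
}

#' Seed time course
#'
#' Unweighted mean over the seed's pixel set, per frame.
#'
#' @param maps array [rows, cols, frames].
#' @param seed_pixels n x 2 matrix of (row, col) indices.
#' @return numeric vector (one value per frame).
#' @export
seed_timecourse <- function(maps, seed_pixels) {
  if (is.null(seed_pixels) || nrow(seed_pixels) == 0)
    stop("empty seed pixel set")
  d <- dim(maps)
  Y <- as_pixel_matrix(maps)
  idx <- (seed_pixels[, 2] - 1) * d[1] + seed_pixels[, 1]
  colMeans(Y[idx, , drop = FALSE])
}

#' Time courses for all seeds
#'
#' @param maps array [rows, cols, frames].
#' @param seedset a [extract_seeds()] result.
#' @return frames x seeds matrix, columns named by region.
#' @export
seed_timecourses <- function(maps, seedset) {
  tc <- vapply(seedset$pixels, function(px) seed_timecourse(maps, px),
               numeric(dim(maps)[3]))
  colnames(tc) <- seedset$seeds$region
  tc
}

#' Seed-pixel correlation map
#'
#' Pearson correlation between a seed's time course and every in-mask
#' pixel's trace over a time window, typically computed after global signal
#' regression.
#'
#' @param maps array [rows, cols, frames].
#' @param seed_trace numeric vector (e.g. from [seed_timecourse()]).
#' @param mask logical matrix.
#' @param window (start_s, end_s) window; NULL uses all frames.
#' @param fps frames per second (required with `window`).
#' @return matrix of correlations (NA outside the mask and for
#'   zero-variance pixels).
#' @export
seed_pixel_correlation_map <- function(maps, seed_trace, mask, window = NULL,
                                       fps = NULL) {
  d <- dim(maps)
  idx <- if (is.null(window)) seq_len(d[3]) else {
    stopifnot(!is.null(fps))
    frames_in_window(window[1], window[2], fps, d[3])
  }
  Y <- as_pixel_matrix(maps)[, idx, drop = FALSE]
  s <- seed_trace[idx]
  px <- which(as.logical(mask))
  Ysub <- Y[px, , drop = FALSE]
  Yc <- Ysub - rowMeans(Ysub)
  sc <- s - mean(s)
  num <- Yc %*% sc
  den <- sqrt(rowSums(Yc^2) * sum(sc^2))
  r <- as.numeric(num) / den
  r[den == 0 | rowSums(Yc^2) < .Machine$double.eps] <- NA_real_
  out <- matrix(NA_real_, d[1], d[2])
  out[px] <- r
  out
}

#' Seed-pair connectivity matrix
#'
#' Pairwise Pearson correlations between seed time courses over a window,
#' with the Fisher-z transformed copy. The experimental windows are minutes
#' 12.5-17.5 (hypoxia) and 2.5-7.5 (normoxia).
#'
#' @param x frames x seeds matrix of time courses, or an array
#'   [rows, cols, frames] together with `seedset`.
#' @param seedset a [extract_seeds()] result (when `x` is an array).
#' @param window (start_s, end_s); NULL uses all frames.
#' @param fps sampling rate, Hz (required with `window`).
#' @param modality label, e.g. "gcamp" or "hbo".
#' @return object of class `connectivity_matrix`: `r`, `z` (seeds x seeds),
#'   `window`, `modality`, `n_frames`.
#' @export
connectivity_matrix <- function(x, seedset = NULL, window = NULL, fps = NULL,
                                modality = "gcamp") {
  tc <- if (is.matrix(x)) x else seed_timecourses(x, seedset)
  n <- nrow(tc)
  idx <- if (is.null(window)) seq_len(n) else {
    stopifnot(!is.null(fps))
    frames_in_window(window[1], window[2], fps, n)
  }
  if (length(idx) < 30)
    stop(sprintf("only %d frames in window: correlation estimate unstable",
                 length(idx)))
  r <- stats::cor(tc[idx, , drop = FALSE])
  structure(list(r = r, z = fisher_z(r), window = window, modality = modality,
                 n_frames = length(idx)), class = "connectivity_matrix")
}

#' Unique seed pairs
#'
#' @param regions character vector of seed names.
#' @param macro character vector of macrocluster labels (same order).
#' @return data.frame seed_a, seed_b, within (logical: same macrocluster);
#'   28 rows for 8 seeds (12 within, 16 between).
#' @export
seed_pairs <- function(regions, macro) {
  idx <- utils::combn(length(regions), 2)
  data.frame(seed_a = regions[idx[1, ]], seed_b = regions[idx[2, ]],
             within = macro[idx[1, ]] == macro[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Hypoxia-normoxia epoch contrast of connectivity
#'
#' For each subject, the seed-pair correlations of the hypoxia and normoxia
#' windows are Fisher z-transformed and subtracted (`dz = z_hyp - z_norm`).
#' Across subjects, each of the 28 unique pairs is tested with the exact
#' Wilcoxon signed-rank test and Benjamini-Hochberg corrected; per-subject
#' means of within- and between-macrocluster pairs are compared with a
#' t-test (two-sample on the per-subject means, Welch unless an F-test
#' supports equal variances), gated by a normality check.
#'
#' @param hypoxia,normoxia lists (one element per subject) of
#'   [connectivity_matrix()] objects with matching seed order.
#' @param macro macrocluster labels in seed order; defaults to the pooled
#'   atlas regions.
#' @param min_subjects minimum cohort size for inferential tests.
#' @return object of class `epoch_contrast`: `dz` (seeds x seeds x subjects),
#'   `pairs` data.frame (seed_a, seed_b, within, mean_dz, p, q),
#'   `cluster_summary` data.frame per subject (within_mean, between_mean),
#'   `cluster_test` (t-test result plus q), `n`.
#' @export
epoch_contrast <- function(hypoxia, normoxia,
                           macro = region_table()$macrocluster,
                           min_subjects = 5) {
  stopifnot(length(hypoxia) == length(normoxia), length(hypoxia) >= 1)
  ns <- length(hypoxia)
  rn <- rownames(hypoxia[[1]]$r)
  dz <- array(NA_real_, dim = c(length(rn), length(rn), ns),
              dimnames = list(rn, rn, NULL))
  for (s in seq_len(ns)) dz[, , s] <- hypoxia[[s]]$z - normoxia[[s]]$z
  pairs <- seed_pairs(rn, macro)
  pairs$mean_dz <- NA_real_; pairs$p <- NA_real_
  ia <- match(pairs$seed_a, rn); ib <- match(pairs$seed_b, rn)
  run_tests <- ns >= min_subjects
  if (!run_tests)
    warning(sprintf("only %d subjects: inferential tests skipped", ns))
  for (k in seq_len(nrow(pairs))) {
    v <- dz[ia[k], ib[k], ]
    pairs$mean_dz[k] <- mean(v)
    if (run_tests && any(v != 0))
      pairs$p[k] <- wilcoxon_signed_rank(v)$p
  }
  pairs$q <- benjamini_hochberg(pairs$p)
  within_mean <- apply(dz, 3, function(m)
    mean(m[cbind(ia[pairs$within], ib[pairs$within])]))
  between_mean <- apply(dz, 3, function(m)
    mean(m[cbind(ia[!pairs$within], ib[!pairs$within])]))
  cluster_test <- NULL
  if (run_tests) {
    norm_ok <- ks_normality(within_mean - between_mean)$p > 0.05
    var_ok <- tryCatch(stats::var.test(within_mean, between_mean)$p.value > 0.05,
                       error = function(e) FALSE)
    if (stats::sd(within_mean) == 0 && stats::sd(between_mean) == 0 &&
        all(within_mean == between_mean)) {
      cluster_test <- list(statistic = 0, p = 1, normality_gate = norm_ok,
                           var_equal = TRUE, method = "t-test (degenerate)")
    } else {
      tt <- stats::t.test(within_mean, between_mean, var.equal = var_ok)
      cluster_test <- list(statistic = unname(tt$statistic),
                           p = tt$p.value, normality_gate = norm_ok,
                           var_equal = var_ok, method = tt$method)
    }
  }
  structure(list(dz = dz, pairs = pairs,
                 cluster_summary = data.frame(subject = seq_len(ns),
                                              within_mean = within_mean,
                                              between_mean = between_mean),
                 cluster_test = cluster_test, n = ns),
            class = "epoch_contrast")
}

#' Longitudinal normoxia connectivity screen
#'
#' Tests each unique seed pair for drift of its normoxia-window (minutes
#' 2.5-7.5) correlation across weekly sessions: a Friedman test per pair
#' (subjects as blocks, weeks as treatments), Benjamini-Hochberg corrected
#' over the 28 pairs; pairs significant after correction are followed up
#' with a Kruskal-Wallis test of each week against week 1.
#'
#' @param weekly list over weeks; each element a list over subjects of
#'   [connectivity_matrix()] objects. Subjects must match across weeks;
#'   subjects with a missing week are dropped from the affected pair with a
#'   message.
#' @param macro macrocluster labels in seed order.
#' @return data.frame per pair: seed_a, seed_b, friedman_chisq, p, q, and a
#'   `followup` attribute (list of per-week Kruskal-Wallis results for
#'   significant pairs).
#' @export
longitudinal_normoxia_screen <- function(weekly,
                                         macro = region_table()$macrocluster) {
  nw <- length(weekly)
  if (nw < 3) stop("need at least 3 weeks")
  ns <- unique(vapply(weekly, length, integer(1)))
  if (length(ns) != 1) stop("subject count differs across weeks")
  rn <- rownames(weekly[[1]][[1]]$r)
  pairs <- seed_pairs(rn, macro)
  ia <- match(pairs$seed_a, rn); ib <- match(pairs$seed_b, rn)
  pairs$friedman_chisq <- NA_real_; pairs$p <- NA_real_
  zarr <- array(NA_real_, dim = c(ns, nw, nrow(pairs)))
  for (w in seq_len(nw)) for (s in seq_len(ns)) {
    m <- weekly[[w]][[s]]
    if (is.null(m)) next
    zarr[s, w, ] <- m$z[cbind(ia, ib)]
  }
  for (k in seq_len(nrow(pairs))) {
    blocks <- zarr[, , k]
    keep <- stats::complete.cases(blocks)
    if (sum(keep) < ns)
      message(sprintf("pair %s-%s: dropped %d subject(s) with missing weeks",
                      pairs$seed_a[k], pairs$seed_b[k], ns - sum(keep)))
    if (sum(keep) < 2) next
    fr <- friedman(blocks[keep, , drop = FALSE])
    pairs$friedman_chisq[k] <- fr$statistic
    pairs$p[k] <- fr$p
  }
  pairs$q <- benjamini_hochberg(pairs$p)
  followup <- list()
  for (k in which(!is.na(pairs$q) & pairs$q < 0.05)) {
    blocks <- zarr[, , k]
    res <- lapply(2:nw, function(w) {
      kw <- kruskal_wallis(list(week1 = blocks[, 1], week = blocks[, w]))
      data.frame(week = w, statistic = kw$statistic, p = kw$p)
    })
    followup[[paste(pairs$seed_a[k], pairs$seed_b[k], sep = "-")]] <-
      do.call(rbind, res)
  }
  attr(pairs, "followup") <- followup
  pairs
}
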