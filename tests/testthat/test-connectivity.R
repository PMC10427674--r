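# Seeds, GSR, connectivity matrices, epoch contrasts, longitudinal screen.

test_that("GSR residuals are exactly orthogonal to the global signal", {
  set.seed(51)
  arr <- array(rnorm(12 * 12 * 300), c(12, 12, 300))
  mask <- matrix(TRUE, 12, 12)
  g <- apply(arr, 3, mean)
  res <- global_signal_regression(arr, mask)
  rs <- apply(matrix(res, 144, 300), 1, function(y) abs(cor(y, g)))
  expect_lt(max(rs), 1e-10)
})

test_that("GSR zeroes a spatially uniform movie and preserves independent noise", {
  tr <- sin(seq(0, 20, length.out = 200))
  uni <- array(rep(tr, each = 64), c(8, 8, 200))
  mask <- matrix(TRUE, 8, 8)
  expect_lt(max(abs(global_signal_regression(uni, mask))), 1e-12)
  set.seed(52)
  noise <- rnorm(200, sd = 0.1)
  arr <- uni
  arr[3, 3, ] <- tr + noise
  res <- global_signal_regression(arr, mask)
  expect_gt(cor(res[3, 3, ], noise), 0.99)
  # zero-variance global signal: unchanged with a warning
  const <- array(1, c(4, 4, 50))
  expect_warning(out <- global_signal_regression(const, matrix(TRUE, 4, 4)),
                 "zero variance")
  expect_identical(out, const)
})

test_that("seed disks have 29 lattice pixels and mirrored centroids", {
  atlas <- synthetic_atlas(c(64, 64))
  mask <- matrix(TRUE, 64, 64)
  seeds <- extract_seeds(atlas, mask)
  expect_equal(nrow(seeds$seeds), 8)
  expect_true(all(vapply(seeds$pixels, nrow, integer(1)) == 29))
  # left/right symmetry of the synthetic atlas: mirrored columns
  s <- seeds$seeds
  for (pair in list(c("MotL", "MotR"), c("VisL", "VisR"))) {
    cl <- s$col[s$region == pair[1]]; cr <- s$col[s$region == pair[2]]
    expect_equal(s$row[s$region == pair[1]], s$row[s$region == pair[2]])
    expect_equal(cl + cr, 64 + 1, tolerance = 1)
  }
  # centroid outside the mask is moved into it
  mask2 <- mask; mask2[s$row[1], s$col[1]] <- FALSE
  expect_message(s2 <- extract_seeds(atlas, mask2), "nearest in-mask")
  expect_true(mask2[s2$seeds$row[1], s2$seeds$col[1]])
})

test_that("seed time courses average their pixel sets", {
  arr <- array(0, c(6, 6, 10))
  arr[1, 1, ] <- 1; arr[1, 2, ] <- -1
  px <- rbind(c(1, 1), c(1, 2))
  expect_identical(seed_timecourse(arr, px), rep(0, 10))
  arr2 <- array(rep(sin(1:10), each = 36), c(6, 6, 10))
  expect_equal(seed_timecourse(arr2, px), sin(1:10))
  expect_error(seed_timecourse(arr, px[0, , drop = FALSE]), "empty")
  # averaging a disk beats a single pixel against the shared truth
  set.seed(53)
  truth <- sin(seq(0, 30, length.out = 500))
  arr3 <- array(rep(truth, each = 36), c(6, 6, 500)) +
    array(rnorm(36 * 500, sd = 1), c(6, 6, 500))
  disk <- as.matrix(expand.grid(2:5, 2:5))
  r_disk <- cor(seed_timecourse(arr3, disk), truth)
  r_one <- cor(arr3[3, 3, ], truth)
  expect_gt(r_disk, r_one)
})

test_that("seed-pixel correlation maps behave under self, flip and clusters", {
  cal <- simulate_calcium(scenario_config(image_shape = c(32, 32),
                                          duration_s = 300, oxygen_level = 21,
                                          within_cluster_r = 0.8,
                                          between_cluster_r = 0.2,
                                          rng_seed = 54))
  atlas <- synthetic_atlas(c(32, 32))
  hemo0 <- list(time = cal$time, fps = 20,
                global_hbo = numeric(6000), global_hbr = numeric(6000),
                local_hbo = matrix(0, 6000, 8), local_hbr = matrix(0, 6000, 8))
  truth <- truth_maps(cal, structure(hemo0, class = "hemo_sim"), atlas)
  mask <- atlas$brain & !atlas$sinus
  seeds <- extract_seeds(atlas, mask)
  # restrict the seed disk to pixels sharing the centroid's label so every
  # disk pixel carries the identical region trace
  own <- seeds$pixels[["MotL"]]
  own <- own[atlas$labels[own] == 1, , drop = FALSE]
  tc <- seed_timecourse(truth$dff, own)
  m <- seed_pixel_correlation_map(truth$dff, tc, mask)
  expect_equal(unname(m[own]), rep(1, nrow(own)), tolerance = 1e-9)
  own_cluster <- m[atlas$labels %in% 1:4]
  other_cluster <- m[atlas$labels %in% 5:8]
  expect_gt(mean(own_cluster), mean(other_cluster))
  # sign flip of one pixel negates its correlation
  flipped <- truth$dff
  flipped[10, 10, ] <- -flipped[10, 10, ]
  m2 <- seed_pixel_correlation_map(flipped, tc, mask)
  expect_equal(m2[10, 10], -m[10, 10], tolerance = 1e-12)
})

test_that("connectivity matrices match generator targets and the Fisher transform", {
  cal <- simulate_calcium(scenario_config(image_shape = c(16, 16),
                                          duration_s = 300, oxygen_level = 21,
                                          within_cluster_r = 0.8,
                                          between_cluster_r = 0.2,
                                          rng_seed = 55))
  cm <- connectivity_matrix(cal$traces, window = c(0, 300), fps = 20)
  expect_lt(max(abs(cm$r - cal$targets$normoxia)), 0.05)
  expect_equal(cm$z, fisher_z(cm$r))
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_true(is.finite(fisher_z(1)))
  # identical traces: r = 1, finite z
  two <- cbind(a = sin(1:100), b = sin(1:100))
  cm2 <- connectivity_matrix(two)
  expect_equal(cm2$r[1, 2], 1)
  expect_true(all(is.finite(cm2$z)))
  expect_error(connectivity_matrix(cal$traces, window = c(0, 1), fps = 20),
               "unstable")
})

test_that("8 seeds give 28 unique pairs partitioned 12 within / 16 between", {
  rt <- region_table()
  pr <- seed_pairs(rt$region, rt$macrocluster)
  expect_equal(nrow(pr), 28)
  expect_equal(sum(pr$within), 12)
  expect_equal(sum(!pr$within), 16)
})

test_that("epoch contrasts recover the between-cluster decorrelation of a cohort", {
  cohort <- trace_cohort(7, seed0 = 100)
  win_h <- c(12.5, 17.5) * 60; win_n <- c(2.5, 7.5) * 60
  hyp <- lapply(cohort, function(cal)
    connectivity_matrix(cal$traces, window = win_h, fps = 20))
  nor <- lapply(cohort, function(cal)
    connectivity_matrix(cal$traces, window = win_n, fps = 20))
  ec <- epoch_contrast(hyp, nor)
  bt <- ec$pairs[!ec$pairs$within, ]
  expect_true(all(bt$mean_dz < 0))
  expect_lt(max(abs(ec$pairs$mean_dz[ec$pairs$within])), 0.1)
  expect_lt(ec$cluster_test$p, 0.05)
  # antisymmetry: swapping epochs negates every dz
  ec_sw <- suppressWarnings(epoch_contrast(nor, hyp))
  expect_equal(ec_sw$dz, -ec$dz)
  # identical epochs: dz = 0, nothing significant
  ec0 <- epoch_contrast(hyp, hyp)
  expect_true(all(ec0$dz == 0))
  expect_false(any(stats::na.omit(ec0$pairs$q) < 0.05))
  expect_equal(ec0$cluster_test$p, 1)
})

test_that("the longitudinal screen is quiet under a stationary generator and flags a trend", {
  mk_cm <- function(z_pair, seed) {
    # stationary weekly matrices from short simulations
    cal <- simulate_calcium(scenario_config(image_shape = c(16, 16),
                                            duration_s = 300,
                                            oxygen_level = 21, rng_seed = seed))
    connectivity_matrix(cal$traces, window = c(0, 300), fps = 20)
  }
  weekly <- lapply(1:4, function(w)
    lapply(1:6, function(s) mk_cm(NULL, seed = 700 + 10 * w + s)))
  res <- longitudinal_normoxia_screen(weekly)
  expect_equal(nrow(res), 28)
  expect_false(any(stats::na.omit(res$q) < 0.05))
  expect_lt(mean(res$p < 0.05, na.rm = TRUE), 0.15)   # near the type-I level
  # inject a monotone week trend into one pair's z values
  weekly_tr <- weekly
  for (w in 1:4) for (s in 1:6) {
    m <- weekly_tr[[w]][[s]]
    m$z["MotL", "VisR"] <- m$z["VisR", "MotL"] <- 0.2 * w + 0.005 * s
    weekly_tr[[w]][[s]] <- m
  }
  res_tr <- longitudinal_normoxia_screen(weekly_tr)
  flagged <- res_tr[res_tr$seed_a == "MotL" & res_tr$seed_b == "VisR", ]
  expect_lt(flagged$q, 0.05)
  expect_true("MotL-VisR" %in% names(attr(res_tr, "followup")))
  # identical weeks: Friedman statistic 0 through the ties path
  same <- lapply(1:3, function(w) lapply(1:5, function(s) weekly[[1]][[s]]))
  res_same <- longitudinal_normoxia_screen(same)
  expect_true(all(res_same$friedman_chisq == 0))
})
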