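# Forward simulator: correlation ground truth, hypoxia ramps, optics.

test_that("simulated calcium reproduces the target correlation structure per epoch", {
  cfg <- scenario_config(image_shape = c(16, 16), duration_s = 600,
                         fps_per_channel = 20, oxygen_level = 8,
                         epoch_timeline = short_timeline(600, c(150, 300)),
                         within_cluster_r = 0.8, between_cluster_r = 0.2,
                         between_cluster_r_hypoxia = 0.0, rng_seed = 7)
  cal <- simulate_calcium(cfg)
  expect_equal(dim(cal$traces), c(12000, 8))
  expect_lt(max(abs(colMeans(cal$traces))), 0.01)
  # normoxia epoch has >= 6000 frames: empirical matrix within +/- 0.05
  idx_n <- which(cal$time < 150)
  idx_h <- which(cal$time >= 150 & cal$time < 300)
  expect_lt(max(abs(cor(cal$traces[idx_n, ]) - cal$targets$normoxia)), 0.05)
  expect_lt(max(abs(cor(cal$traces[idx_h, ]) - cal$targets$hypoxia)), 0.05)
  # epoch-split deltas negative for every inter-cluster pair
  dz <- fisher_z(cor(cal$traces[idx_h, ])) - fisher_z(cor(cal$traces[idx_n, ]))
  macro <- region_table()$macrocluster
  between <- outer(macro, macro, "!=")
  expect_true(all(dz[between] < 0))
})

test_that("uncorrelated configuration yields near-zero off-diagonal correlations", {
  cfg <- scenario_config(image_shape = c(16, 16), duration_s = 300,
                         oxygen_level = 21, within_cluster_r = 0,
                         between_cluster_r = 0, rng_seed = 3)
  cal <- simulate_calcium(cfg)
  C <- cor(cal$traces)
  expect_lt(max(abs(C[upper.tri(C)])), 3 / sqrt(nrow(cal$traces)))
})

test_that("an infeasible correlation target fails naming a region pair", {
  cfg <- small_scenario(seed = 1)
  cfg$within_cluster_r <- 0.1
  cfg$between_cluster_r_hypoxia <- 0.9   # 1 + 3w - 4b < 0: not PSD
  expect_error(simulate_calcium(cfg), "positive semi-definite.*-")
})

test_that("simulation is bit-reproducible given the seed", {
  a <- simulate_calcium(small_scenario(seed = 5))
  b <- simulate_calcium(small_scenario(seed = 5))
  expect_identical(a$traces, b$traces)
  s1 <- simulate_acquisition(small_scenario(shape = c(12, 12), duration_s = 6,
                                            noise_sd = 5, seed = 9))
  s2 <- simulate_acquisition(small_scenario(shape = c(12, 12), duration_s = 6,
                                            noise_sd = 5, seed = 9))
  expect_identical(s1$stack$frames, s2$stack$frames)
})

test_that("pure normoxia gives an identically zero global hemodynamic ramp", {
  cfg <- small_scenario(oxygen_level = 21)
  hem <- simulate_hemodynamics(cfg)
  expect_identical(max(abs(hem$global_hbo)), 0)
  expect_identical(max(abs(hem$global_hbr)), 0)
})

test_that("the HbR ramp reaches its configured plateau (closed-form check)", {
  cfg <- scenario_config(image_shape = c(8, 8), duration_s = 2400,
                         oxygen_level = 8, rng_seed = 2)
  hem <- simulate_hemodynamics(cfg)
  plateau_window <- hem$time >= 14.5 * 60 & hem$time < 19.5 * 60
  # closed form: A (1 - mean of exp(-(t-t_on)/tau) over the window)
  p <- cfg$hemo_ramp_params
  d <- hem$time[plateau_window] - 600
  expected <- mean(p$hbr_plateau_uM * (1 - exp(-d / p$hbr_tau_s)))
  expect_equal(mean(hem$global_hbr[plateau_window]), expected, tolerance = 1e-12)
  expect_equal(expected, p$hbr_plateau_uM, tolerance = 1e-6)
  # baseline strictly zero before onset
  expect_identical(max(abs(hem$global_hbr[hem$time < 600])), 0)
})

test_that("a calcium impulse produces a delayed local HbO response", {
  cfg <- small_scenario(oxygen_level = 21, duration_s = 60)
  n <- 60 * cfg$fps_per_channel
  imp <- matrix(0, n, 8); imp[200, 1] <- cfg$calcium_sd
  colnames(imp) <- region_table()$region
  cal <- structure(list(traces = imp, time = (seq_len(n) - 1) / 20, fps = 20),
                   class = "calcium_sim")
  hem <- simulate_hemodynamics(cfg, cal)
  lag_s <- (which.max(hem$local_hbo[, 1]) - 200) / 20
  expect_equal(lag_s, 1.5, tolerance = 0.15)   # gamma-kernel mode
  expect_identical(max(abs(hem$local_hbo[, 2])), 0)
  # HbR couples with the configured negative ratio
  expect_equal(hem$local_hbr[, 1], -0.4 * hem$local_hbo[, 1])
})

test_that("render_optics follows the Beer-Lambert forward model exactly", {
  atlas <- synthetic_atlas(c(12, 12))
  n <- 40
  hbo <- array(rep(c(rep(0, 20), rep(10, 20)), each = 144), c(12, 12, n))
  hbr <- array(rep(c(rep(0, 20), rep(5, 20)), each = 144), c(12, 12, n))
  truth <- structure(list(hbo = hbo, hbr = hbr,
                          dff = array(0, c(12, 12, n)), atlas = atlas),
                     class = "ground_truth")
  cfg <- small_scenario(shape = c(12, 12), duration_s = n / 20, seed = 4)
  opt <- optical_model()
  st <- render_optics(truth, opt, cfg)
  ch <- demultiplex(st)
  A <- cbind(opt$channels$pathlength_cm * opt$channels$eps_hbo,
             opt$channels$pathlength_cm * opt$channels$eps_hbr) * 1e-6
  for (k in seq_along(opt$channels$channel)) {
    fr <- ch[[opt$channels$channel[k]]]$frames
    logratio <- -log(fr[3, 3, 30] / fr[3, 3, 5])
    expect_equal(logratio, sum(A[k, ] * c(10, 5)), tolerance = 1e-9)
  }
  # zero concentration change, zero noise: constant reflectance frames
  expect_equal(ch$green$frames[, , 1], ch$green$frames[, , 15],
               tolerance = 1e-12)
})

test_that("interlacing runs at 4x the per-channel rate in fixed color order", {
  sim <- simulate_acquisition(small_scenario(shape = c(12, 12),
                                             duration_s = 5, seed = 6))
  expect_equal(sim$stack$fps_total, 80)
  expect_identical(sim$stack$color_order, c("blue", "green", "amber", "red"))
  ch <- demultiplex(sim$stack)
  expect_equal(ch$blue$fps, 20)
  expect_equal(vapply(ch, function(x) dim(x$frames)[3], numeric(1)),
               c(blue = 100, green = 100, amber = 100, red = 100))
})
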