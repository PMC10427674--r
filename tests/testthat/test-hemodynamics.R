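# Beer-Lambert inversion, oxygen saturation, masking, outliers, epoch
# summaries.

test_that("inversion recovers forward-rendered concentrations within 1% (noiseless)", {
  sim <- simulate_acquisition(small_scenario(shape = c(20, 20), seed = 31))
  ch <- demultiplex(sim$stack)
  hemo <- beer_lambert_invert(ch[c("green", "amber", "red")], sim$optical,
                              epoch_timeline = sim$config$epoch_timeline)
  mask <- make_brain_mask(apply(ch$blue$frames, c(1, 2), mean),
                          sim$truth$atlas, edge_margin_px = 2) & hemo$mask
  px <- which(mask)
  est <- colMeans(matrix(hemo$hbo, 400)[px, ])
  tru <- colMeans(matrix(sim$truth$hbo, 400)[px, ])
  expect_lt(max(abs(est - tru)) / max(abs(tru)), 0.01)
  est_r <- colMeans(matrix(hemo$hbr, 400)[px, ])
  tru_r <- colMeans(matrix(sim$truth$hbr, 400)[px, ])
  expect_lt(max(abs(est_r - tru_r)) / max(abs(tru_r)), 0.01)
  # conservation to machine precision
  expect_equal(hemo$hbt, hemo$hbo + hemo$hbr, tolerance = 1e-14)
})

test_that("flat reflectance inverts to zero concentration change and 60% sO2", {
  flat <- lapply(c(green = 1, amber = 1, red = 1), function(x)
    channel_stack("c", array(5000, c(4, 4, 50)), 20, (0:49) / 20))
  names(flat) <- c("green", "amber", "red")
  hemo <- beer_lambert_invert(flat, optical_model())
  expect_lt(max(abs(hemo$hbo)), 1e-10)
  expect_lt(max(abs(hemo$hbr)), 1e-10)
  expect_equal(unique(as.vector(hemo$so2)), 0.6, tolerance = 1e-12)
})

test_that("sO2 follows (HbO0 + dHbO) / (HbT0 + dHbT)", {
  opt <- optical_model()
  h <- list(hbo = array(20, c(1, 1, 1)), hbt = array(20, c(1, 1, 1)))
  expect_equal(as.vector(compute_so2(h, opt)), 80 / 120)
  h2 <- list(hbo = array(10, c(1, 1, 1)), hbt = array(20, c(1, 1, 1)))
  expect_equal(as.vector(compute_so2(h2, opt)), 70 / 120)
  h3 <- list(hbo = array(0, c(1, 1, 1)), hbt = array(-100, c(1, 1, 1)))
  expect_true(is.na(compute_so2(h3, opt)))
})

test_that("sO2 is invariant to a common gain on all reflectance channels", {
  sim <- simulate_acquisition(small_scenario(shape = c(12, 12), seed = 32))
  ch <- demultiplex(sim$stack)
  refl <- ch[c("green", "amber", "red")]
  h1 <- beer_lambert_invert(refl, sim$optical,
                            epoch_timeline = sim$config$epoch_timeline)
  refl_g <- lapply(refl, function(s) {
    s$frames <- s$frames * 1.7; s
  })
  h2 <- beer_lambert_invert(refl_g, sim$optical,
                            epoch_timeline = sim$config$epoch_timeline)
  expect_equal(h2$so2, h1$so2, tolerance = 1e-12)
})

test_that("whole-brain mean dHbO stays unbiased under 1% sensor noise", {
  cfg <- small_scenario(shape = c(24, 24), duration_s = 60, oxygen_level = 21,
                        noise_sd = 80, seed = 33)   # ~1% of brain counts
  sim <- simulate_acquisition(cfg)
  ch <- demultiplex(sim$stack)
  hemo <- beer_lambert_invert(ch[c("green", "amber", "red")], sim$optical,
                              epoch_timeline = cfg$epoch_timeline)
  mask <- make_brain_mask(apply(ch$blue$frames, c(1, 2), mean),
                          sim$truth$atlas, edge_margin_px = 2) & hemo$mask
  hemo$mask <- mask
  tr <- whole_brain_trace(hemo, "hbo")
  expect_lt(abs(mean(tr)), 0.5)   # true value is 0 uM throughout
})

test_that("brain mask excludes sinus and edges and covers the atlas regions", {
  atlas <- synthetic_atlas(c(48, 48))
  mean_img <- matrix(1, 48, 48)
  mask <- make_brain_mask(mean_img, atlas, edge_margin_px = 3)
  expect_false(any(mask & atlas$sinus))
  expect_lt(sum(mask), sum(atlas$brain))
  expect_gt(sum(mask & atlas$labels > 0), 0.5 * sum(atlas$labels > 0))
  # margin 0 and no exclusions: the full frame survives
  all_brain <- list(brain = matrix(TRUE, 10, 10),
                    sinus = matrix(FALSE, 10, 10))
  expect_true(all(make_brain_mask(matrix(1, 10, 10), all_brain,
                                  edge_margin_px = 0)))
  expect_error(make_brain_mask(mean_img,
                               list(brain = matrix(FALSE, 48, 48),
                                    sinus = matrix(FALSE, 48, 48)),
                               edge_margin_px = 0),
               "empty")
})

test_that("outlier exclusion removes 3-sd excursions and little else", {
  set.seed(8)
  x <- rnorm(1000); x[17] <- 10
  y <- exclude_outliers(x)
  expect_true(is.na(y[17]))
  expect_identical(exclude_outliers(rep(2, 50)), rep(2, 50))
  # Gaussian tail mass beyond 3 sd is ~0.27%
  set.seed(9)
  z <- exclude_outliers(rnorm(2e5))
  expect_equal(mean(is.na(z)), 2 * pnorm(-3), tolerance = 0.35)
})

test_that("epoch summaries pick up plateau, dip and overshoot", {
  cfg <- scenario_config(image_shape = c(8, 8), duration_s = 2400,
                         oxygen_level = 8, rng_seed = 34)
  hem <- simulate_hemodynamics(cfg)
  es <- quantify_epoch_dynamics(hem$global_hbr, fps = 20)
  expect_equal(es$group$mean[es$group$measure == "plateau"],
               cfg$hemo_ramp_params$hbr_plateau_uM, tolerance = 0.05 * 21.2)
  expect_equal(es$group$mean[es$group$measure == "baseline"], 0)
  # constant-zero trace: all summaries zero
  ez <- quantify_epoch_dynamics(rep(0, 2400 * 20), fps = 20)
  expect_true(all(ez$group$mean == 0))
  # a constructed bump at minute 20.4 is reported as the overshoot
  tr <- rep(0, 25 * 60 * 20)
  tr[seq(20.4 * 60 * 20, 20.4 * 60 * 20 + 10)] <- 7
  eb <- quantify_epoch_dynamics(tr, 20, remove_outliers = FALSE)
  expect_equal(eb$group$mean[eb$group$measure == "overshoot"], 7)
  # SEM definition over subjects
  two <- cbind(rep(1, 25 * 60 * 20), rep(3, 25 * 60 * 20))
  e2 <- quantify_epoch_dynamics(two, 20)
  expect_equal(e2$group$sem[e2$group$measure == "plateau"],
               sd(c(1, 3)) / sqrt(2))
  expect_error(quantify_epoch_dynamics(rep(0, 100), 20), "outside")
})
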