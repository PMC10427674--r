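# Hemodynamic correction of fluorescence and dF/F normalization.

test_that("correction removes hemodynamic contamination from a zero-signal analog", {
  # GFP-like scenario: no neural fluctuations, full hemodynamic contamination
  cfg <- small_scenario(shape = c(20, 20), seed = 41, calcium_sd = 1e-12)
  sim <- simulate_acquisition(cfg)
  ch <- demultiplex(sim$stack)
  mask <- make_brain_mask(apply(ch$blue$frames, c(1, 2), mean),
                          sim$truth$atlas, edge_margin_px = 2)
  corr <- hemodynamic_correction(ch$blue, ch[c("green", "amber", "red")],
                                 mask = mask)
  pre <- apply(ch$blue$frames, c(1, 2), sd)
  post <- apply(corr$corrected$frames, c(1, 2), sd)
  ratio <- (post / pre)[mask]
  expect_lte(max(ratio), 0.10)
  expect_lte(median(ratio), 0.05)
})

test_that("correction is a near no-op without contamination", {
  set.seed(42)
  n <- 400
  y <- 1000 + cumsum(rnorm(n)) * 0.1 + 20 * sin(2 * pi * (1:n) / 40)
  fluo <- channel_stack("blue", array(y, c(1, 1, n)), 20, (0:(n - 1)) / 20)
  refl <- lapply(c(green = 1, amber = 2, red = 3), function(k)
    channel_stack("r", array(5000 + rnorm(n), c(1, 1, n)), 20,
                  (0:(n - 1)) / 20))
  corr <- hemodynamic_correction(fluo, refl)
  expect_gt(cor(corr$corrected$frames[1, 1, ], y), 0.99)
  expect_lt(max(abs(corr$coeffs[1, -1] * sd(refl[[1]]$frames))), sd(y) * 0.2)
})

test_that("correction improves recovery of the true calcium signal", {
  cfg <- small_scenario(shape = c(20, 20), seed = 43, noise_sd = 10)
  sim <- simulate_acquisition(cfg)
  ch <- demultiplex(sim$stack)
  mask <- make_brain_mask(apply(ch$blue$frames, c(1, 2), mean),
                          sim$truth$atlas, edge_margin_px = 2)
  corr <- hemodynamic_correction(ch$blue, ch[c("green", "amber", "red")],
                                 mask = mask)
  seeds <- extract_seeds(sim$truth$atlas, mask)
  raw_tc <- seed_timecourse(ch$blue$frames, seeds$pixels[["SenL"]])
  cor_tc <- seed_timecourse(corr$corrected$frames, seeds$pixels[["SenL"]])
  truth <- sim$truth$calcium$traces[, "SenL"]
  expect_gt(abs(cor(cor_tc, truth)), abs(cor(raw_tc, truth)))
})

test_that("correction is idempotent up to tolerance", {
  cfg <- small_scenario(shape = c(12, 12), seed = 44)
  sim <- simulate_acquisition(cfg)
  ch <- demultiplex(sim$stack)
  refl <- ch[c("green", "amber", "red")]
  c1 <- hemodynamic_correction(ch$blue, refl)
  c2 <- hemodynamic_correction(c1$corrected, refl)
  sd1 <- apply(c1$corrected$frames, c(1, 2), sd)
  sd2 <- apply(c2$corrected$frames, c(1, 2), sd)
  expect_lt(max(abs(sd2 - sd1) / pmax(sd1, 1e-12)), 0.01)
})

test_that("dF/F passes the band and rejects drift and constants", {
  fps <- 20; t <- seq(0, 120, by = 1 / fps); n <- length(t)
  mid <- (n %/% 4):(3 * n %/% 4)
  mk <- function(y) channel_stack("blue", array(y, c(1, 1, n)), fps, t)
  d1 <- compute_dff(mk(1000 + 50 * sin(2 * pi * 1 * t)))
  expect_equal(max(d1$dff[1, 1, mid]), 50 / 1000, tolerance = 0.12)  # < 1 dB
  d2 <- compute_dff(mk(1000 + 50 * sin(2 * pi * 0.05 * t)))
  atten_db <- 20 * log10(max(abs(d2$dff[1, 1, mid])) / (50 / 1000))
  expect_lt(atten_db, -20)
  d3 <- compute_dff(mk(rep(777, n)))
  expect_identical(max(abs(d3$dff)), 0)
  expect_error(compute_dff(channel_stack("b", array(1, c(1, 1, 10)), 5,
                                         (0:9) / 5)),
               "too low")
})

test_that("dF/F is invariant to a global gain and masks non-positive baselines", {
  fps <- 20; t <- seq(0, 60, by = 1 / fps); n <- length(t)
  y <- 1000 + 30 * sin(2 * pi * t)
  a <- compute_dff(channel_stack("b", array(y, c(1, 1, n)), fps, t))
  b <- compute_dff(channel_stack("b", array(3.5 * y, c(1, 1, n)), fps, t))
  expect_equal(a$dff, b$dff, tolerance = 1e-10)
  expect_message(
    z <- compute_dff(channel_stack("b", array(c(y, -y), c(2, 1, n)),
                                   fps, t)),
    "non-positive baseline")
  expect_false(z$mask[2, 1])
})

test_that("region-mean dF/F tracks the simulated calcium", {
  cfg <- small_scenario(shape = c(20, 20), seed = 45, noise_sd = 100)
  sim <- simulate_acquisition(cfg)
  ch <- demultiplex(sim$stack)
  mask <- make_brain_mask(apply(ch$blue$frames, c(1, 2), mean),
                          sim$truth$atlas, edge_margin_px = 2)
  corr <- hemodynamic_correction(ch$blue, ch[c("green", "amber", "red")],
                                 mask = mask)
  fl <- compute_dff(corr$corrected, mask = mask)
  seeds <- extract_seeds(sim$truth$atlas, fl$mask)
  for (rg in c("SenL", "RetR")) {
    tc <- seed_timecourse(fl$dff, seeds$pixels[[rg]])
    expect_gt(cor(tc, sim$truth$calcium$traces[, rg]), 0.8)
  }
})

test_that("moving-window std matches its definition and localizes variance steps", {
  expect_identical(max(windowed_std(rep(3, 50))), 0)
  alt <- rep(c(1, -1), 30)
  ws <- windowed_std(alt, 10)
  expect_equal(ws[30], sd(alt[25:34]))       # centered 10-frame window
  expect_equal(ws[30], 1.054093, tolerance = 1e-6)
  step <- c(rep(0, 100), rnorm(100, sd = 5))
  ss <- windowed_std(step, 10)
  expect_lt(max(ss[1:90]), 2)
  expect_gt(mean(ss[106:150]), 2)
  expect_error(windowed_std(1:5, 10), "shorter")
  expect_error(windowed_std(1:50, 1), "at least 2")
})
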