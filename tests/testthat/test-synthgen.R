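test_that("EPSC kernel is peak-normalized, zero before onset, peaks at the analytic time", {
  k <- makeEpscKernel(100, 0.5, 5, onset = 10, dt = 0.1, sweepLen = 100)
  expect_equal(max(abs(k)), 100, tolerance = 0.001)
  expect_true(all(k[timesMs <- (seq_along(k) - 1) * 0.1 < 10][
    seq_len(sum((seq_along(k) - 1) * 0.1 < 10))] == 0))
  expect_true(all(k <= 0))   # inward current convention
  # analytic argmax of a difference of exponentials
  tpk <- 10 + 0.5 * 5 / (5 - 0.5) * log(5 / 0.5)
  expect_equal((which.max(abs(k)) - 1) * 0.1, tpk, tolerance = 0.1)
  expect_equal(makeEpscKernel(0, 0.5, 5, 10, 0.1, 50), rep(0, 500))
})

test_that("kernel rejects non-positive time constants and dt", {
  expect_error(makeEpscKernel(10, -1, 5, 0, 0.1, 10),
               class = "optomap_invalid_parameter")
  expect_error(makeEpscKernel(10, 5, 5, 0, 0.1, 10),
               class = "optomap_invalid_parameter")
  expect_error(makeEpscKernel(10, 0.5, 5, 0, 0, 10),
               class = "optomap_invalid_parameter")
})

test_that("config validity enforces the parameter invariants", {
  expect_error(synthConfig(p_release = 0), "p_release")
  expect_error(synthConfig(ko_scale = -1), "ko_scale")
  expect_error(synthConfig(tau_rise = 20, tau_decay = 15), "tau")
  expect_error(synthConfig(dt = -0.1), "dt")
  expect_error(synthConfig(spont_rate = -1), "spont_rate")
  expect_error(synthConfig(bad_field = 1),
               class = "optomap_invalid_parameter")
  expect_error(simulateGridExperiment(synthConfig(n_pairs = 0), "sCRACM"))
})

test_that("evoked rate helper inverts the window-rate integral", {
  r0 <- evokedRateForWindow(8.3, spontHz = 1.3, tauMs = 100)
  # independent numerical quadrature of the intensity over the window
  lambda <- function(t) r0 * exp(-t / 0.1)              # t in s post flash
  evokedCount <- integrate(lambda, 0.05, 0.35)$value
  windowRate <- 1.3 + evokedCount / 0.3
  expect_equal(windowRate, 8.3, tolerance = 1e-8)
})

test_that("the same seed and config give bit-identical datasets", {
  cfg <- tinyConfig(seed = 7)
  a <- simulateGridExperiment(cfg, "sCRACM")
  b <- simulateGridExperiment(cfg, "sCRACM")
  expect_identical(lapply(a$cells, sweepCurrents),
                   lapply(b$cells, sweepCurrents))
  expect_identical(a$truth, b$truth)
  sa <- simulateSrExperiment(tinyConfig(seed = 3), nSweeps = 2)
  sb <- simulateSrExperiment(tinyConfig(seed = 3), nSweeps = 2)
  expect_identical(lapply(sa$cells, sweepCurrents),
                   lapply(sb$cells, sweepCurrents))
})

test_that("seeded simulation restores the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulateGridExperiment(tinyConfig(seed = 1), "sCRACM"))
  expect_identical(.Random.seed, before)
})

test_that("in the noiseless limit every downstream pair ratio equals ko_scale exactly", {
  cfg <- synthConfig(seed = 3, n_pairs = 2, noise_sd = 0, direct_frac = 0,
                     ko_scale = 0.6, grid_rows = 6, grid_cols = 6,
                     soma_row = 3, soma_col = 3)
  sim <- simulateGridExperiment(cfg, "sCRACM")
  for (p in c("P01", "P02")) {
    wt <- cellResponses(sim$cells[[paste0(p, "_WT")]])$table
    ko <- cellResponses(sim$cells[[paste0(p, "_KO")]])$table
    expect_equal(ko$amplitude_pA, 0.6 * wt$amplitude_pA, tolerance = 1e-9)
  }
})

test_that("direct responses appear only near the soma and only in uncaging/AP modes", {
  cfg <- synthConfig(seed = 5, n_pairs = 1, direct_frac = 1)
  scr <- simulateGridExperiment(cfg, "sCRACM")
  expect_true(all(scr$truth$spots$direct_amp == 0))
  lsps <- simulateGridExperiment(cfg, "LSPS")
  sp <- lsps$truth$spots
  withDir <- sp[sp$direct_amp > 0, ]
  expect_gt(nrow(withDir), 0)
  grid <- gridGeometry(lsps$cells[[1]])
  soma <- somaPosition(lsps$cells[[1]])
  x <- grid$x0 + (withDir$grid_col - 1) * grid$x_spacing
  y <- grid$y0 - (withDir$grid_row - 1) * grid$y_spacing
  expect_true(all(sqrt((x - soma[1])^2 + (y - soma[2])^2) <= 50 + 1e-9))
})

test_that("every emitted sweep id appears in the ground truth", {
  sim <- simulateGridExperiment(tinyConfig(seed = 11), "AP_map")
  ids <- unlist(lapply(sim$cells, function(c) sweepInfo(c)$sweep_id))
  expect_setequal(ids, sim$truth$sweeps$sweep_id)
  led <- simulateLedExperiment(synthConfig(seed = 2, n_pairs = 2), nSweeps = 3)
  idsL <- unlist(lapply(led$cells, function(c) sweepInfo(c)$sweep_id))
  expect_setequal(idsL, led$truth$sweeps$sweep_id)
})

test_that("spontaneous baseline counts follow the Poisson law of the configured rate", {
  cfg <- synthConfig(seed = 21, evoked_rate0 = 0, noise_sd = 0,
                     sr_noise_sd = 0)
  # 12 one-second baselines at 1.3 Hz: expect 15.6 events
  counts12 <- withSeed(21, vapply(1:12, function(i) {
    sw <- simulateSrSweep(cfg)
    sum(sw$events$t_rel_ms >= -1000 & sw$events$t_rel_ms < 0)
  }, numeric(1)))
  expect_gte(sum(counts12), qpois(0.025, 15.6))
  expect_lte(sum(counts12), qpois(0.975, 15.6))
  # chi-square goodness of fit of per-sweep counts over 1,000 sweeps
  counts <- withSeed(22, vapply(1:1000, function(i) {
    sw <- simulateSrSweep(cfg)
    sum(sw$events$t_rel_ms >= -1000 & sw$events$t_rel_ms < 0)
  }, numeric(1)))
  kmax <- max(3, max(counts))
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  p <- dpois(0:kmax, 1.3)
  p[kmax + 1L] <- p[kmax + 1L] + ppois(kmax, 1.3, lower.tail = FALSE)
  # pool bins with small expectation
  keep <- (1000 * p) >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(p[keep], sum(p[!keep]))
  gof <- suppressWarnings(chisq.test(obs2, p = p2))
  expect_gt(gof$p.value, 0.01)
})

test_that("ground-truth evoked-window rate matches the calibrated target", {
  cfg <- synthConfig(seed = 31)   # default: 8.3 Hz over the 50-350 ms window
  n <- 400
  cnt <- withSeed(31, sum(vapply(1:n, function(i) {
    sw <- simulateSrSweep(cfg)
    sum(sw$events$t_rel_ms >= 50 & sw$events$t_rel_ms < 350)
  }, numeric(1))))
  expected <- 8.3 * 0.3 * n
  expect_gte(cnt, qpois(0.005, expected))
  expect_lte(cnt, qpois(0.995, expected))
})

test_that("zero rates give a noise-only sweep with an empty event list", {
  cfg <- synthConfig(seed = 1, spont_rate = 0, evoked_rate0 = 0,
                     sr_noise_sd = 0)
  sw <- withSeed(1, simulateSrSweep(cfg))
  expect_equal(sw$trace, rep(0, length(sw$trace)))
  expect_equal(nrow(sw$events), 0)
  expect_error(simulateSrSweep(cfg, rateScale = -1),
               class = "optomap_invalid_parameter")
})
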