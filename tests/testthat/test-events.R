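test_that("baseline subtraction zeroes the baseline window and preserves shape", {
  expect_equal(baselineSubtract(rep(-12, 100), DT, c(0, 5)), rep(0, 100))
  k <- synKernel()
  expect_equal(baselineSubtract(k - 30, DT, c(0, STIM_ON)), k)
  set.seed(1)
  x <- rnorm(1000)
  bs <- baselineSubtract(x, DT, c(0, 50))
  expect_equal(mean(bs[1:500]), 0, tolerance = 1e-12)
  expect_error(baselineSubtract(x, DT, c(90, 120)),
               class = "optomap_range_error")
})

test_that("sweep averaging is the pointwise mean with geometry checks", {
  k <- synKernel()
  expect_equal(averageSweeps(cbind(k, k)), k)
  expect_equal(averageSweeps(cbind(k, -k)), rep(0, length(k)))
  expect_error(averageSweeps(list(k, k[-1])),
               class = "optomap_incompatible_sweeps")
})

test_that("averaging N noisy repeats shrinks the residual RMS like 1/sqrt(N)", {
  set.seed(4)
  k <- synKernel()
  rms <- vapply(c(4, 64), function(n) {
    sqrt(mean((averageSweeps(replicate(n, k + rnorm(length(k), 0, 3))) - k)^2))
  }, numeric(1))
  expect_equal(rms[1] / rms[2], 4, tolerance = 0.35)
})

test_that("windowed peak takes the max magnitude and respects the window", {
  k <- makeEpscKernel(100, 2, 15, STIM_ON, DT, 150)
  expect_equal(peakAmplitude(k, DT, STIM_ON, c(5, 80)), 100,
               tolerance = 0.005)
  late <- makeEpscKernel(100, 2, 15, 90, DT, 150)
  expect_lt(peakAmplitude(late + 0, DT, 0, c(5, 80)), 1)
  two <- makeEpscKernel(60, 2, 15, STIM_ON + 10, DT, 150) +
    makeEpscKernel(80, 2, 15, STIM_ON + 40, DT, 150)
  expect_equal(peakAmplitude(two, DT, STIM_ON, c(5, 80)), 80,
               tolerance = 0.06 * 80)  # summed tail of the early kernel
  expect_equal(peakAmplitude(two, DT, STIM_ON, c(2, 30)), 60,
               tolerance = 0.01 * 60)
  expect_error(peakAmplitude(two, DT, 200, c(5, 80)),
               class = "optomap_range_error")
})

test_that("windowed mean amplitude equals the rectified integral over the window", {
  expect_equal(windowedMeanAmplitude(rep(0, 1000), DT, STIM_ON), 0)
  pulse <- rep(0, 1000)
  pulse[windowIdx(1000, DT, STIM_ON + 2, STIM_ON + 30)] <- -50
  expect_equal(windowedMeanAmplitude(pulse, DT, STIM_ON, c(2, 30)), 50)
  # quadrature oracle on the closed-form kernel, fully inside the window
  amp <- 40; tr <- 1; td <- 4
  k <- makeEpscKernel(amp, tr, td, STIM_ON + 5, DT, 150)
  tpk <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-tpk / td) - exp(-tpk / tr)
  f <- function(t) amp / norm * (exp(-t / td) - exp(-t / tr))
  oracle <- integrate(f, 0, 75 - 5)$value / 75
  expect_equal(windowedMeanAmplitude(k, DT, STIM_ON, c(5, 80)), oracle,
               tolerance = 0.01)
})

test_that("power normalization is homogeneous and validates power", {
  expect_equal(normalizeToPower(172, 172 / 2.2), 2.2)
  expect_equal(normalizeToPower(0, 3), 0)
  expect_equal(normalizeToPower(10, 4), 2 * normalizeToPower(10, 8))
  expect_error(normalizeToPower(10, 0), class = "optomap_invalid_input")
})

test_that("responses are classified direct, synaptic or mixed by latency and rise time", {
  set.seed(11)
  rd <- evokedResponse(avgTrace(dirKernel()), DT, STIM_ON)
  expect_equal(rd@classification, "direct")
  expect_lt(rd@onsetLatency, 5)
  expect_lt(rd@riseTime, 1)
  rs <- evokedResponse(avgTrace(synKernel(onset = STIM_ON + 8)), DT, STIM_ON)
  expect_equal(rs@classification, "synaptic")
  rm <- evokedResponse(avgTrace(synKernel(onset = STIM_ON + 12) + dirKernel()),
                       DT, STIM_ON)
  expect_equal(rm@classification, "mixed")
  rn <- evokedResponse(avgTrace(rep(0, 1500)), DT, STIM_ON)
  expect_equal(rn@classification, "none")
})

test_that("scaling a trace up never turns a direct label synaptic", {
  set.seed(12)
  base <- avgTrace(dirKernel(amp = 60))
  r0 <- evokedResponse(base, DT, STIM_ON)
  expect_equal(r0@classification, "direct")
  for (c_ in c(2, 5, 10)) {
    rc <- evokedResponse(base * c_, DT, STIM_ON)
    expect_false(rc@classification == "synaptic")
  }
})

test_that("direct subtraction recovers synaptic peaks and flags pure direct pixels", {
  set.seed(21)
  nTrials <- 25
  errs <- resid <- rep(NA_real_, nTrials)
  for (i in seq_len(nTrials)) {
    r <- evokedResponse(avgTrace(synKernel() + dirKernel()), DT, STIM_ON)
    r2 <- removeDirect(r)
    if (!isExcluded(r2)) errs[i] <- abs(amplitude(r2) / 60 - 1)
    rd <- removeDirect(evokedResponse(avgTrace(dirKernel()), DT, STIM_ON))
    expect_true(isExcluded(rd))   # pure direct pixels leave the map
    resid[i] <- peakAmplitude(responseTrace(rd), DT, STIM_ON, c(0, 80)) / 150
  }
  expect_gte(mean(!is.na(errs)), 0.9)
  expect_true(all(errs < 0.10, na.rm = TRUE))
  expect_true(all(resid < 0.05))
})

test_that("synaptic responses pass through direct subtraction unchanged", {
  set.seed(22)
  r <- evokedResponse(avgTrace(synKernel(onset = STIM_ON + 8)), DT, STIM_ON)
  expect_identical(removeDirect(r), r)
})

test_that("subtraction never increases the synaptic-window peak of a synaptic trace", {
  set.seed(23)
  for (i in 1:10) {
    tr <- avgTrace(synKernel(amp = runif(1, 20, 100)))
    r <- evokedResponse(tr, DT, STIM_ON)
    r2 <- removeDirect(r)
    expect_lte(amplitude(r2), amplitude(r) + 1e-9)
  }
})

test_that("event detection finds injected events and merges refractory pairs", {
  set.seed(31)
  dt <- 0.1
  n <- 20000
  onsets <- seq(100, 1900, by = 200)   # 10 events, well separated
  sig <- rep(0, n)
  for (o in onsets)
    sig <- sig + makeEpscKernel(15, 0.8, 6, o, dt, n * dt)
  ev <- eventTable(detectEvents(sig + rnorm(n, 0, 2), dt))
  expect_gte(nrow(ev), 9)
  expect_lte(nrow(ev), 11)
  expect_equal(mean(ev$amp_pA), 15, tolerance = 2 * 2 / sqrt(nrow(ev)) + 0.08 * 15)
  # detected onsets sit within ~1.5 ms of the true onsets
  d <- vapply(ev$t_ms, function(t) min(abs(t - onsets)), numeric(1))
  expect_lt(median(d), 1.5)
  # noiseless, eventless trace
  expect_equal(nrow(eventTable(detectEvents(rep(0, n), dt))), 0)
  # two events 1 ms apart merge into one
  pair <- makeEpscKernel(15, 0.8, 6, 100, dt, 300) +
    makeEpscKernel(15, 0.8, 6, 101, dt, 300)
  evp <- eventTable(detectEvents(pair, dt, noiseSd = 1))
  expect_equal(nrow(evp), 1)
})

test_that("noise-only false positives stay within the Gaussian exceedance expectation", {
  set.seed(32)
  fp <- sum(vapply(1:20, function(i)
    nrow(eventTable(detectEvents(rnorm(15000, 0, 3), 0.1))), numeric(1)))
  # bound: expected samples beyond 3 sigma across all sweeps
  expect_lte(fp, 20 * 15000 * 2 * pnorm(-3))
})

test_that("window labels follow the half-open spontaneous and evoked windows exactly", {
  qs <- new("QuantalEventSet",
            events = data.frame(
              sweep_id = "s", t_ms = c(-1000, -500, -0.001, 0, 49.9, 50,
                                       100, 349.999, 350, 400),
              amp_pA = 10, label = "unlabeled"),
            nSweeps = 1L,
            windows = list(spontaneous = c(-1000, 0), evoked = c(50, 350)))
  lab <- eventTable(windowEvents(qs))$label
  expect_equal(lab, c("spontaneous", "spontaneous", "spontaneous", "other",
                      "other", "evoked", "evoked", "evoked", "other",
                      "other"))
})

test_that("event rates divide counts by sweeps times window duration", {
  qs <- new("QuantalEventSet",
            events = data.frame(sweep_id = "s", t_ms = c(60, 100, 200),
                                amp_pA = c(10, 12, 14), label = "unlabeled"),
            nSweeps = 1L,
            windows = list(spontaneous = c(-1000, 0), evoked = c(50, 350)))
  er <- eventRates(windowEvents(qs))
  expect_equal(er$evoked_hz, 10)        # 3 events / 0.3 s
  expect_equal(er$spont_hz, 0)
  expect_true(is.na(er$spont_amp_pa))
  expect_equal(er$evoked_amp_pa, 12)
  expect_error(eventRates(qs), class = "optomap_invalid_input")  # unlabeled
  qs0 <- new("QuantalEventSet", events = qs@events[0, ], nSweeps = 0L,
             windows = qs@windows)
  expect_error(eventRates(qs0), class = "optomap_invalid_input")
})

test_that("detected rates recover the generator rates within the Poisson interval", {
  cfg <- synthConfig(seed = 41, n_pairs = 1)
  sim <- simulateSrExperiment(cfg, nSweeps = 13)
  er <- eventRates(detectCellEvents(sim$cells[["P01_WT"]]))
  expected <- 8.3 * 0.3 * 13
  ciLow <- qpois(0.025, expected) / (13 * 0.3)
  ciHigh <- qpois(0.975, expected) / (13 * 0.3)
  expect_gte(er$evoked_hz, ciLow * 0.85)   # detector miss margin
  expect_lte(er$evoked_hz, ciHigh)
})
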