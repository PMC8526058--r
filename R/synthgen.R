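#' @include AllClasses.R utils.R
NULL

# mode-specific grid geometry defaults: rows, cols, x/y spacing (um) and the
# grid pixel the soma sits on
.gridDefaults <- function(mode) {
  switch(mode,
    sCRACM = list(rows = 12, cols = 12, x_spacing = 50, y_spacing = 50,
                  soma_row = 5, soma_col = 6),
    AP_map = list(rows = 8, cols = 8, x_spacing = 75, y_spacing = 100,
                  soma_row = 3, soma_col = 4),
    LSPS   = list(rows = 16, cols = 16, x_spacing = 50, y_spacing = 60,
                  soma_row = 5, soma_col = 8),
    stopc("optomap_invalid_parameter", "unknown grid mode '%s'", mode))
}

#' Peak asynchronous-release rate for a target evoked-window rate
#'
#' Given the exponentially decaying post-flash release intensity
#' `r0 * exp(-(t - t_flash)/tau)`, returns the peak rate `r0` such that the
#' expected total event rate (including the spontaneous floor) measured over
#' the evoked window equals `targetHz`.
#'
#' @param targetHz desired mean event rate over the window, Hz.
#' @param spontHz spontaneous (baseline) rate, Hz.
#' @param tauMs decay constant of the evoked intensity, ms.
#' @param window evoked window, ms after the flash (half-open).
#' @return Peak evoked rate `r0`, Hz.
#' @export
#' @examples
#' evokedRateForWindow(8.3, spontHz = 1.3, tauMs = 100)
evokedRateForWindow <- function(targetHz, spontHz = 1.3, tauMs = 100,
                                window = c(50, 350)) {
  assertThat(targetHz >= spontHz, "optomap_invalid_parameter",
             "target window rate must be >= the spontaneous rate")
  tauS <- tauMs / 1000
  w <- window / 1000
  integral <- tauS * (exp(-w[1] / tauS) - exp(-w[2] / tauS)) # s per unit r0
  (targetHz - spontHz) * diff(w) / integral
}

#' Construct a synthetic-experiment configuration
#'
#' Defaults emulate the study conditions: 10 kHz sampling; a 2 ms-onset
#' stimulus; binomial quantal release (20 sites, p = 0.5) with lognormal
#' quantal sizes of mean 12 pA (CV 0.3); 3 pA Gaussian recording noise; a 40%
#' genotype reduction (`ko_scale = 0.6`); spontaneous rate 1.3 Hz and a
#' post-flash asynchronous-release intensity calibrated so the mean rate over
#' the 50-350 ms evoked window is 8.3 Hz; evoked quantal size 15 pA.
#' Grid geometry defaults are mode-specific and filled in by
#' [simulateGridExperiment()] (12x12 at 50 um for sCRACM, 8x8 at 75x100 um
#' for AP maps, 16x16 at 50x60 um for LSPS).
#'
#' @param seed integer RNG seed.
#' @param evoked_window_rate target mean event rate over the 50-350 ms evoked
#'   window, Hz, used to derive `evoked_rate0` when that is not given.
#' @param ... values for any other [SynthConfig-class] slot.
#' @return A validated [SynthConfig-class].
#' @export
#' @examples
#' cfg <- synthConfig(seed = 1, n_pairs = 3, noise_sd = 0)
synthConfig <- function(seed = 1L, ..., evoked_window_rate = 8.3) {
  defaults <- list(
    dt = 0.1, sweep_len = 150, stim_onset = 10,
    grid_rows = NA_real_, grid_cols = NA_real_,
    x_spacing = NA_real_, y_spacing = NA_real_,
    tau_rise = 2, tau_decay = 15,
    noise_sd = 3,
    n_sites = 20, p_release = 0.5,
    quantal_amp_mean = 12, quantal_amp_cv = 0.3,
    ko_scale = 0.6,
    direct_frac = 0.5, direct_onset = 2, direct_tau_rise = 0.3,
    direct_tau_decay = 3, direct_amp = 150, direct_radius = 50,
    led_power = 2, bulk_scale = 3.5,
    spont_rate = 1.3, evoked_rate0 = NA_real_, evoked_tau = 100,
    n_pairs = 15, evoked_amp_mean = 15, syn_latency = 7,
    field_amp = 80, field_sigma = 100, field_offset = 100,
    soma_row = NA_real_, soma_col = NA_real_,
    quantal_tau_rise = 0.8, quantal_tau_decay = 6,
    sr_noise_sd = 2, sr_ko_rate_scale = (6.7 - 1.3) / (8.3 - 1.3),
    sr_baseline = 1000, sr_post = 500)
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  assertThat(length(bad) == 0, "optomap_invalid_parameter",
             "unknown SynthConfig field(s): %s", paste(bad, collapse = ", "))
  defaults[names(dots)] <- dots
  if (is.na(defaults$evoked_rate0))
    defaults$evoked_rate0 <- evokedRateForWindow(
      evoked_window_rate, spontHz = defaults$spont_rate,
      tauMs = defaults$evoked_tau)
  do.call(new, c(list("SynthConfig", seed = as.integer(seed)), defaults))
}

#' Difference-of-exponentials EPSC kernel
#'
#' Returns a current trace (pA, inward negative) that is zero before `onset`
#' and follows `exp(-(t-onset)/tauDecay) - exp(-(t-onset)/tauRise)`,
#' normalized so the peak magnitude equals `amp`.
#'
#' @param amp peak magnitude, pA (>= 0).
#' @param tauRise,tauDecay rise and decay time constants, ms
#'   (`tauDecay > tauRise > 0`).
#' @param onset kernel onset, ms.
#' @param dt ms per sample.
#' @param sweepLen trace length, ms.
#' @return Numeric vector of length `sweepLen/dt`; the analytic time of peak
#'   is `onset + tauRise*tauDecay/(tauDecay - tauRise) * log(tauDecay/tauRise)`.
#' @export
#' @examples
#' k <- makeEpscKernel(100, 0.5, 5, onset = 10, dt = 0.1, sweepLen = 100)
#' max(abs(k))  # 100 to within 0.1%
makeEpscKernel <- function(amp, tauRise, tauDecay, onset, dt, sweepLen) {
  assertThat(isScalarNum(dt) && dt > 0, "optomap_invalid_parameter",
             "dt must be a positive scalar")
  assertThat(isScalarNum(tauRise) && isScalarNum(tauDecay) &&
             tauRise > 0 && tauDecay > tauRise, "optomap_invalid_parameter",
             "need tauDecay > tauRise > 0")
  assertThat(isScalarNum(amp) && amp >= 0, "optomap_invalid_parameter",
             "amp must be >= 0")
  n <- as.integer(round(sweepLen / dt))
  t <- timesMs(n, dt) - onset
  y <- numeric(n)
  pos <- t >= 0
  y[pos] <- exp(-t[pos] / tauDecay) - exp(-t[pos] / tauRise)
  tpk <- tauRise * tauDecay / (tauDecay - tauRise) * log(tauDecay / tauRise)
  peak <- exp(-tpk / tauDecay) - exp(-tpk / tauRise)
  -amp * y / peak
}

# grid pixel-center coordinates in the slice frame (row 1 = most pia-ward)
.gridCoords <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$cols) - 1) * grid$x_spacing,
       y = grid$y0 - (seq_len(grid$rows) - 1) * grid$y_spacing)
}

# isotropic 2-D Gaussian innervation field over the grid, peaked
# field_offset um pia-ward of the soma
.innervationField <- function(config, grid, soma) {
  co <- .gridCoords(grid)
  cx <- soma[1]
  cy <- soma[2] + config@field_offset
  dx2 <- outer(rep(1, grid$rows), (co$x - cx)^2)
  dy2 <- outer((co$y - cy)^2, rep(1, grid$cols))
  config@field_amp * exp(-(dx2 + dy2) / (2 * config@field_sigma^2))
}

# lognormal meanlog/sdlog for a given mean and CV
.lnormPars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# per-sweep synaptic scale factors with E[f] = 1: binomial release across
# n_sites sites, each released quantum lognormal. Returns length-n vector.
.releaseFactors <- function(n, config) {
  nrel <- rbinom(n, size = config@n_sites, prob = config@p_release)
  tot <- sum(nrel)
  f <- numeric(n)
  if (tot > 0) {
    lp <- .lnormPars(config@quantal_amp_mean, config@quantal_amp_cv)
    q <- rlnorm(tot, lp$meanlog, lp$sdlog)
    sums <- rowsum(q, rep.int(seq_len(n), nrel))
    f[as.integer(rownames(sums))] <- sums[, 1]
  }
  f / (config@n_sites * config@p_release * config@quantal_amp_mean)
}

#' Simulate a paired grid-photostimulation experiment
#'
#' Generates `n_pairs` pairs of neighboring WT/KO neurons that share one
#' latent presynaptic innervation field (an isotropic 2-D Gaussian peaked
#' `field_offset` um pia-ward of the soma, over the proximal apical
#' dendrites). KO synaptic amplitudes are scaled by `ko_scale`. Each grid
#' spot is stimulated `nReps` times in a seeded pseudorandom order; each
#' sweep is a difference-of-exponentials EPSC kernel scaled by a shared
#' binomial-release realization, plus (for LSPS and AP-map modes) an optional
#' fast direct response at spots within `direct_radius` um of the soma, plus
#' Gaussian recording noise. sCRACM experiments (TTX/4-AP) carry no direct or
#' polysynaptic components.
#'
#' @param config A [SynthConfig-class].
#' @param mode `"sCRACM"`, `"AP_map"` or `"LSPS"`.
#' @param nReps stimulations per grid spot (2-4 in the emulated protocol).
#' @return list with `cells` (list of [CellRecording-class], two per pair)
#'   and `truth` (list: `spots`, `sweeps` data.frames of true per-spot and
#'   per-sweep synaptic/direct amplitudes, and `ratio = ko_scale`).
#' @export
#' @examples
#' sim <- simulateGridExperiment(synthConfig(seed = 1, n_pairs = 1), "sCRACM")
#' sim$cells[[1]]
simulateGridExperiment <- function(config, mode = c("sCRACM", "AP_map", "LSPS"),
                                   nReps = 2) {
  mode <- match.arg(mode)
  validObject(config)
  assertThat(config@n_pairs >= 1, "optomap_invalid_parameter",
             "n_pairs must be >= 1")
  gd <- .gridDefaults(mode)
  grid <- list(
    rows = if (is.na(config@grid_rows)) gd$rows else as.integer(config@grid_rows),
    cols = if (is.na(config@grid_cols)) gd$cols else as.integer(config@grid_cols),
    x_spacing = if (is.na(config@x_spacing)) gd$x_spacing else config@x_spacing,
    y_spacing = if (is.na(config@y_spacing)) gd$y_spacing else config@y_spacing)
  grid$x0 <- 0
  grid$y0 <- (grid$rows - 1) * grid$y_spacing  # row 1 most pia-ward
  somaRC <- c(if (is.na(config@soma_row)) gd$soma_row else config@soma_row,
              if (is.na(config@soma_col)) gd$soma_col else config@soma_col)
  co <- .gridCoords(grid)
  soma <- c(co$x[somaRC[2]], co$y[somaRC[1]])
  directPossible <- mode %in% c("AP_map", "LSPS")
  nSpots <- grid$rows * grid$cols
  nSamp <- as.integer(round(config@sweep_len / config@dt))
  synShape <- makeEpscKernel(1, config@tau_rise, config@tau_decay,
                             config@stim_onset + config@syn_latency,
                             config@dt, config@sweep_len)
  dirShape <- makeEpscKernel(1, config@direct_tau_rise, config@direct_tau_decay,
                             config@stim_onset + config@direct_onset,
                             config@dt, config@sweep_len)
  # spot distance from soma, spot-major (column-major matrix order)
  spotRow <- rep(seq_len(grid$rows), times = grid$cols)
  spotCol <- rep(seq_len(grid$cols), each = grid$rows)
  dSoma <- sqrt((co$x[spotCol] - soma[1])^2 + (co$y[spotRow] - soma[2])^2)

  withSeed(config@seed, {
    cells <- list()
    spotsTruth <- list()
    sweepTruth <- list()
    for (p in seq_len(config@n_pairs)) {
      pid <- sprintf("P%02d", p)
      pairScale <- rlnorm(1, 0, 0.25)
      fieldWT <- .innervationField(config, grid, soma) * pairScale
      trueAmp <- list(WT = as.vector(fieldWT),
                      KO = as.vector(fieldWT) * config@ko_scale)
      # shared presynaptic release realization (same axons, same flash)
      f <- matrix(.releaseFactors(nSpots * nReps, config),
                  nrow = nSpots, ncol = nReps)
      order_ <- lapply(seq_len(nReps), function(r) sample.int(nSpots))
      for (g in c("WT", "KO")) {
        cid <- sprintf("%s_%s", pid, g)
        dirAmp <- numeric(nSpots)
        if (directPossible && config@direct_frac > 0) {
          near <- which(dSoma <= config@direct_radius)
          hit <- near[runif(length(near)) < config@direct_frac]
          dirAmp[hit] <- config@direct_amp * runif(length(hit), 0.8, 1.2)
        }
        synAmp <- trueAmp[[g]] * f            # nSpots x nReps
        sweepSpot <- unlist(lapply(order_, identity))
        sweepRep <- rep(seq_len(nReps), each = nSpots)
        synSweep <- synAmp[cbind(sweepSpot, sweepRep)]
        dirSweep <- dirAmp[sweepSpot]
        traces <- synShape %o% synSweep + dirShape %o% dirSweep
        if (config@noise_sd > 0)
          traces <- traces + matrix(rnorm(length(traces), 0, config@noise_sd),
                                    nrow = nSamp)
        ids <- sprintf("%s_r%d_%03d", cid, sweepRep, seq_len(nSpots))
        info <- data.frame(
          sweep_id = ids,
          stim_kind = if (mode == "LSPS") "uncage" else "laser",
          grid_row = spotRow[sweepSpot], grid_col = spotCol[sweepSpot],
          rep = sweepRep, power = config@led_power,
          stim_onset = config@stim_onset, holding = -70,
          stim_order = rep(seq_len(nSpots), nReps))
        cells[[cid]] <- CellRecording(
          traces, info, dt = config@dt, cellId = cid, genotype = g,
          pairId = pid, mode = mode, soma = soma, grid = grid,
          seed = config@seed)
        spotsTruth[[cid]] <- data.frame(
          cell_id = cid, grid_row = spotRow, grid_col = spotCol,
          syn_amp = trueAmp[[g]], direct_amp = dirAmp)
        sweepTruth[[cid]] <- data.frame(
          sweep_id = ids, cell_id = cid,
          grid_row = spotRow[sweepSpot], grid_col = spotCol[sweepSpot],
          syn_amp_sweep = synSweep, direct_amp = dirSweep)
      }
    }
    list(cells = cells,
         truth = list(spots = do.call(rbind, c(spotsTruth, make.row.names = FALSE)),
                      sweeps = do.call(rbind, c(sweepTruth, make.row.names = FALSE)),
                      ratio = config@ko_scale))
  })
}

#' Simulate a paired LED bulk-stimulation experiment
#'
#' One wide-field LED flash per sweep (no grid): each of `n_pairs` pairs
#' shares a latent callosal input amplitude (lognormal across pairs around
#' `n_sites * p_release * quantal_amp_mean`); per-sweep binomial-release
#' factors are shared within the pair and the KO amplitude is scaled by
#' `ko_scale`.
#'
#' @param config A [SynthConfig-class].
#' @param nSweeps flashes per cell (the emulated protocol used 3-10).
#' @return list with `cells` and `truth` as in [simulateGridExperiment()]
#'   (without grid columns).
#' @export
simulateLedExperiment <- function(config, nSweeps = 5) {
  validObject(config)
  nSamp <- as.integer(round(config@sweep_len / config@dt))
  synShape <- makeEpscKernel(1, config@tau_rise, config@tau_decay,
                             config@stim_onset + config@syn_latency,
                             config@dt, config@sweep_len)
  base <- config@n_sites * config@p_release * config@quantal_amp_mean *
    config@bulk_scale
  withSeed(config@seed, {
    cells <- list()
    sweepTruth <- list()
    for (p in seq_len(config@n_pairs)) {
      pid <- sprintf("P%02d", p)
      pairAmp <- base * rlnorm(1, 0, 0.3)
      f <- .releaseFactors(nSweeps, config)      # shared within the pair
      for (g in c("WT", "KO")) {
        cid <- sprintf("%s_%s", pid, g)
        amp <- pairAmp * if (g == "KO") config@ko_scale else 1
        synSweep <- amp * f
        traces <- synShape %o% synSweep
        if (config@noise_sd > 0)
          traces <- traces + matrix(rnorm(length(traces), 0, config@noise_sd),
                                    nrow = nSamp)
        ids <- sprintf("%s_s%02d", cid, seq_len(nSweeps))
        info <- data.frame(
          sweep_id = ids, stim_kind = "LED",
          grid_row = NA_integer_, grid_col = NA_integer_,
          rep = seq_len(nSweeps), power = config@led_power,
          stim_onset = config@stim_onset, holding = -70,
          stim_order = seq_len(nSweeps))
        cells[[cid]] <- CellRecording(
          traces, info, dt = config@dt, cellId = cid, genotype = g,
          pairId = pid, mode = "LED_bulk", soma = NULL, grid = NULL,
          seed = config@seed)
        sweepTruth[[cid]] <- data.frame(
          sweep_id = ids, cell_id = cid, grid_row = NA_integer_,
          grid_col = NA_integer_, syn_amp_sweep = synSweep, direct_amp = 0)
      }
    }
    list(cells = cells,
         truth = list(spots = NULL,
                      sweeps = do.call(rbind, c(sweepTruth, make.row.names = FALSE)),
                      ratio = config@ko_scale))
  })
}

#' Simulate and measure paired LED amplitudes without building containers
#'
#' Lightweight path for calibration studies that need many replicate
#' datasets (e.g. type-I error of the gated paired test over 1,000
#' simulated experiments): runs exactly the generative model of
#' [simulateLedExperiment()] and the measurement of [bulkAmplitude()]
#' (baseline subtraction, sweep averaging, smoothed windowed peak) but skips
#' the [CellRecording-class] containers. For a given config and sweep count
#' the returned amplitudes are identical to the full pipeline's.
#'
#' @param config A [SynthConfig-class].
#' @param nSweeps flashes per cell.
#' @param window analysis window, ms after stimulus onset.
#' @return data.frame with one row per pair: `pair_id`, `wt`, `ko` (measured
#'   peak amplitudes, pA).
#' @export
simulateLedPairMeasures <- function(config, nSweeps = 5, window = c(5, 80)) {
  validObject(config)
  nSamp <- as.integer(round(config@sweep_len / config@dt))
  synShape <- makeEpscKernel(1, config@tau_rise, config@tau_decay,
                             config@stim_onset + config@syn_latency,
                             config@dt, config@sweep_len)
  base <- config@n_sites * config@p_release * config@quantal_amp_mean *
    config@bulk_scale
  withSeed(config@seed, {
    out <- vector("list", config@n_pairs)
    for (p in seq_len(config@n_pairs)) {
      pairAmp <- base * rlnorm(1, 0, 0.3)
      f <- .releaseFactors(nSweeps, config)
      amp <- c(WT = pairAmp, KO = pairAmp * config@ko_scale)
      meas <- vapply(c("WT", "KO"), function(g) {
        traces <- synShape %o% (amp[[g]] * f)
        if (config@noise_sd > 0)
          traces <- traces + matrix(rnorm(length(traces), 0, config@noise_sd),
                                    nrow = nSamp)
        bs <- baselineSubtract(traces, config@dt, c(0, config@stim_onset))
        peakAmplitude(averageSweeps(bs), config@dt, config@stim_onset,
                      window, smoothMs = 1)
      }, numeric(1))
      out[[p]] <- data.frame(pair_id = sprintf("P%02d", p),
                             wt = meas[["WT"]], ko = meas[["KO"]])
    }
    rbindList(out)
  })
}

#' Simulate one strontium (asynchronous-release) sweep
#'
#' Events are drawn from a homogeneous Poisson process at `spont_rate` over
#' the whole sweep plus an inhomogeneous Poisson process with intensity
#' `evoked_rate0 * exp(-(t - t_flash)/evoked_tau)` after the flash. Each
#' event is an EPSC kernel with lognormal amplitude (spontaneous mean
#' `quantal_amp_mean`, evoked mean `evoked_amp_mean`, both CV
#' `quantal_amp_cv`), on Gaussian recording noise. Uses the current RNG
#' state; seed via [withSeed()] or use [simulateSrExperiment()].
#'
#' @param config A [SynthConfig-class]; the sweep spans `sr_baseline` ms
#'   before the flash and `sr_post` ms after it.
#' @param rateScale multiplier on the evoked intensity (the generator's
#'   genotype effect in Sr2+ mode).
#' @return list: `trace` (pA), `tFlash` (ms), and `events` data.frame with
#'   `t_ms` (sweep time), `t_rel_ms` (relative to flash), `amp_pA` --
#'   the detector-independent ground truth.
#' @export
simulateSrSweep <- function(config, rateScale = 1) {
  validObject(config)
  assertThat(rateScale >= 0, "optomap_invalid_parameter",
             "rateScale must be >= 0")
  dur <- config@sr_baseline + config@sr_post
  tFlash <- config@sr_baseline
  n <- as.integer(round(dur / config@dt))
  # spontaneous: homogeneous over the whole sweep
  nSpont <- rpois(1, config@spont_rate * dur / 1000)
  tSpont <- sort(runif(nSpont, 0, dur))
  # evoked: exponentially decaying intensity after the flash
  tau <- config@evoked_tau
  r0 <- config@evoked_rate0 * rateScale
  mu <- r0 / 1000 * tau * (1 - exp(-config@sr_post / tau))
  nEv <- rpois(1, mu)
  u <- runif(nEv)
  tEv <- tFlash - tau * log(1 - u * (1 - exp(-config@sr_post / tau)))
  lpS <- .lnormPars(config@quantal_amp_mean, config@quantal_amp_cv)
  lpE <- .lnormPars(config@evoked_amp_mean, config@quantal_amp_cv)
  amp <- c(rlnorm(nSpont, lpS$meanlog, lpS$sdlog),
           rlnorm(nEv, lpE$meanlog, lpE$sdlog))
  tAll <- c(tSpont, tEv)
  o <- order(tAll)
  tAll <- tAll[o]; amp <- amp[o]
  trace <- if (config@sr_noise_sd > 0) rnorm(n, 0, config@sr_noise_sd)
           else numeric(n)
  if (length(tAll)) {
    kern <- makeEpscKernel(1, config@quantal_tau_rise,
                           config@quantal_tau_decay, 0,
                           config@dt, min(dur, 10 * config@quantal_tau_decay))
    kl <- length(kern)
    for (i in seq_along(tAll)) {
      i0 <- as.integer(floor(tAll[i] / config@dt)) + 1L
      if (i0 > n) next
      seg <- seq.int(i0, min(n, i0 + kl - 1L))
      trace[seg] <- trace[seg] + amp[i] * kern[seq_along(seg)]
    }
  }
  list(trace = trace, tFlash = tFlash,
       events = data.frame(t_ms = tAll, t_rel_ms = tAll - tFlash,
                           amp_pA = amp))
}

#' Simulate a paired strontium quantal-release experiment
#'
#' Repeated flashes (one per sweep) on each cell of `n_pairs` WT/KO pairs.
#' The genotype effect in this mode is on evoked quantal *frequency*: the KO
#' evoked intensity is scaled by `sr_ko_rate_scale`, while spontaneous rate
#' and quantal amplitudes are genotype-independent.
#'
#' @param config A [SynthConfig-class].
#' @param nSweeps flashes per cell (the emulated protocol used 12-30).
#' @return list with `cells` (list of [CellRecording-class]) and `truth`
#'   (`events` data.frame with sweep and cell ids, and per-cell
#'   `rate_scale`).
#' @export
simulateSrExperiment <- function(config, nSweeps = 12) {
  validObject(config)
  dur <- config@sr_baseline + config@sr_post
  nSamp <- as.integer(round(dur / config@dt))
  withSeed(config@seed, {
    cells <- list()
    evTruth <- list()
    for (p in seq_len(config@n_pairs)) {
      pid <- sprintf("P%02d", p)
      for (g in c("WT", "KO")) {
        cid <- sprintf("%s_%s", pid, g)
        rs <- if (g == "KO") config@sr_ko_rate_scale else 1
        traces <- matrix(0, nSamp, nSweeps)
        evs <- vector("list", nSweeps)
        ids <- sprintf("%s_s%02d", cid, seq_len(nSweeps))
        for (s in seq_len(nSweeps)) {
          sw <- simulateSrSweep(config, rateScale = rs)
          traces[, s] <- sw$trace
          if (nrow(sw$events))
            evs[[s]] <- cbind(sweep_id = ids[s], cell_id = cid, sw$events)
        }
        info <- data.frame(
          sweep_id = ids, stim_kind = "LED",
          grid_row = NA_integer_, grid_col = NA_integer_,
          rep = seq_len(nSweeps), power = config@led_power,
          stim_onset = config@sr_baseline, holding = -70,
          stim_order = seq_len(nSweeps))
        cells[[cid]] <- CellRecording(
          traces, info, dt = config@dt, cellId = cid, genotype = g,
          pairId = pid, mode = "Sr2+", soma = NULL, grid = NULL,
          seed = config@seed)
        evTruth[[cid]] <- do.call(rbind, evs[!vapply(evs, is.null, TRUE)])
      }
    }
    list(cells = cells,
         truth = list(events = rbindList(evTruth),
                      rate_scale = config@sr_ko_rate_scale))
  })
}
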