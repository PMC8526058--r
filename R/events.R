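#' @include AllClasses.R AllGenerics.R utils.R
NULL

# ---------------------------------------------------------------------------
# basic trace algebra
# ---------------------------------------------------------------------------

#' Baseline-subtract a sweep
#'
#' Subtracts the mean of a pre-stimulus baseline window so the baseline mean
#' is zero; the trace shape is otherwise unchanged.
#'
#' @param x numeric trace (pA) or samples x sweeps matrix.
#' @param dt ms per sample.
#' @param window half-open baseline window (ms from trace start); must lie
#'   inside the trace.
#' @return `x` with the per-trace baseline mean removed.
#' @export
#' @examples
#' baselineSubtract(rep(-12, 100), dt = 0.1, window = c(0, 5))
baselineSubtract <- function(x, dt, window) {
  assertThat(length(window) == 2 && window[2] > window[1] && window[1] >= 0,
             "optomap_range_error", "baseline window must be (start, end), end > start >= 0")
  n <- if (is.matrix(x)) nrow(x) else length(x)
  assertThat(window[2] <= n * dt + 1e-9, "optomap_range_error",
             "baseline window [%g, %g) ms lies outside the %g ms trace",
             window[1], window[2], n * dt)
  idx <- windowIdx(n, dt, window[1], window[2])
  if (is.matrix(x)) sweep(x, 2, colMeans(x[idx, , drop = FALSE]))
  else x - mean(x[idx])
}

#' Average repeated sweeps
#'
#' Pointwise arithmetic mean of repeated sweeps of identical geometry.
#'
#' @param sweeps samples x sweeps numeric matrix, or list of equal-length
#'   numeric vectors.
#' @return Numeric mean trace.
#' @export
averageSweeps <- function(sweeps) {
  if (is.list(sweeps)) {
    lens <- lengths(sweeps)
    assertThat(length(unique(lens)) == 1, "optomap_incompatible_sweeps",
               "sweeps differ in length (%s)", paste(unique(lens), collapse = ", "))
    sweeps <- do.call(cbind, sweeps)
  }
  assertThat(is.matrix(sweeps) && ncol(sweeps) >= 1,
             "optomap_incompatible_sweeps", "no sweeps to average")
  rowMeans(sweeps)
}

#' Peak amplitude of an averaged response
#'
#' Maximum current magnitude of the (baseline-subtracted) trace within the
#' half-open analysis window `[stimOnset + window[1], stimOnset + window[2])`.
#'
#' @param x numeric trace, pA, baseline-subtracted.
#' @param dt ms per sample.
#' @param stimOnset stimulus onset, ms.
#' @param window analysis window, ms after stimulus onset (default the
#'   5-80 ms EPSC peak window).
#' @param smoothMs boxcar low-pass width, ms, applied before peak picking
#'   (0 = none); a short filter suppresses the upward bias that single-sample
#'   noise maxima add to the peak of a noisy average.
#' @return Peak magnitude, pA (>= 0).
#' @export
peakAmplitude <- function(x, dt, stimOnset, window = c(5, 80), smoothMs = 0) {
  if (smoothMs > 0) x <- .smooth(x, dt, widthMs = smoothMs)
  idx <- windowIdx(length(x), dt, stimOnset + window[1], stimOnset + window[2])
  max(abs(x[idx]))
}

#' Mean rectified amplitude over an analysis window
#'
#' Mean absolute (baseline-subtracted) current over the half-open window
#' `[stimOnset + window[1], stimOnset + window[2])` -- the 2-30 ms measure
#' used for action-potential-dependent maps to exclude polysynaptic
#' contamination, and the 5-80 ms area measure used for LSPS maps.
#'
#' @inheritParams peakAmplitude
#' @return Mean rectified amplitude, pA (>= 0).
#' @export
windowedMeanAmplitude <- function(x, dt, stimOnset, window = c(2, 30)) {
  idx <- windowIdx(length(x), dt, stimOnset + window[1], stimOnset + window[2])
  mean(abs(x[idx]))
}

#' Divide an amplitude by stimulation power
#'
#' @param amp amplitude(s), pA.
#' @param power stimulation power, mW (> 0).
#' @return amp / power, pA/mW.
#' @export
normalizeToPower <- function(amp, power) {
  assertThat(all(is.finite(power)) && all(power > 0),
             "optomap_invalid_input", "power must be > 0")
  amp / power
}

# noise SD from a pre-stimulus baseline window
.noiseSd <- function(x, dt, window) {
  sd(x[windowIdx(length(x), dt, window[1], window[2])])
}

# ---------------------------------------------------------------------------
# onset latency, rise time, classification
# ---------------------------------------------------------------------------

# first time (ms after stimOnset) the inward deflection stays above
# k * noise SD for >= sustainMs; NA if never
.onsetLatency <- function(m, dt, stimOnset, noiseSd, k = 3, sustainMs = 0.5) {
  thr <- max(k * noiseSd, 1e-9)
  i0 <- min(length(m), as.integer(floor(stimOnset / dt)) + 1L)
  above <- m >= thr
  above[seq_len(i0 - 1L)] <- FALSE
  r <- rle(above)
  need <- max(1L, as.integer(round(sustainMs / dt)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  (starts[hit[1]] - 1) * dt - stimOnset
}

# light boxcar smoothing for peak/trough logic on noisy averages
.smooth <- function(m, dt, widthMs = 0.5) {
  w <- max(1L, as.integer(round(widthMs / dt)))
  if (w <= 1L) return(m)
  s <- as.numeric(stats::filter(m, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- m[is.na(s)]
  s
}

# indices of strict-ish local maxima of m above thr, within idx range
.localMaxima <- function(m, thr) {
  n <- length(m)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  i[m[i] >= m[i - 1] & m[i] > m[i + 1] & m[i] > thr] + 0L
}

# 20-80% rise time (ms) of the component peaking at index pk
.riseTime2080 <- function(m, dt, pk) {
  peak <- m[pk]
  if (peak <= 0) return(NA_real_)
  crossBack <- function(frac) {
    lev <- frac * peak
    j <- pk
    while (j > 1 && m[j - 1] > lev) j <- j - 1
    if (j == 1) return((j - 1) * dt)
    # linear interpolation between j-1 and j
    (j - 2 + (lev - m[j - 1]) / (m[j] - m[j - 1])) * dt
  }
  crossBack(0.8) - crossBack(0.2)
}

#' Measure and classify an averaged evoked response
#'
#' Averages repeated sweeps, baseline-subtracts, measures amplitude (windowed
#' peak or mean), estimates onset latency (first inward deflection sustained
#' beyond `kSigma` times the baseline noise SD for `sustainMs`) and the
#' 20-80% rise time of the first response component, and classifies the
#' response:
#' \describe{
#'   \item{none}{amplitude below `ampThreshold`.}
#'   \item{direct}{onset latency < `directLatency` (5 ms) with 20-80% rise
#'     time < `directRiseMax` -- a non-synaptic response to direct
#'     photostimulation of the recorded neuron.}
#'   \item{mixed}{direct criteria met plus a second, slower component
#'     exceeding threshold after `directLatency`.}
#'   \item{synaptic}{everything else.}
#' }
#'
#' @param sweeps samples x sweeps matrix (or single numeric trace), pA.
#' @param dt ms per sample.
#' @param stimOnset stimulus onset, ms.
#' @param window analysis window, ms after onset.
#' @param metric `"peak"` or `"windowed_mean"`.
#' @param baselineWindow window used for baseline subtraction and noise
#'   estimation (default everything before the stimulus).
#' @param ampThreshold response threshold, pA; default 3x the baseline noise
#'   SD (at least 1 pA).
#' @param smoothMs boxcar low-pass width, ms, applied before the amplitude
#'   measurement (suppresses the upward noise bias of peak picking).
#' @param kSigma,sustainMs onset-detection parameters.
#' @param directLatency latency bound for direct responses, ms.
#' @param directRiseMax maximum 20-80% rise time of a direct response, ms.
#' @param gridIndex integer (row, col) of the stimulation spot, or NA.
#' @param power stimulation power, mW.
#' @return An [EvokedResponse-class].
#' @export
evokedResponse <- function(sweeps, dt, stimOnset, window = c(5, 80),
                           metric = c("peak", "windowed_mean"),
                           baselineWindow = c(0, stimOnset),
                           ampThreshold = NULL, kSigma = 3, sustainMs = 0.5,
                           directLatency = 5, directRiseMax = 1,
                           smoothMs = 0.5,
                           gridIndex = c(NA_integer_, NA_integer_),
                           power = NA_real_) {
  metric <- match.arg(metric)
  avg <- if (is.matrix(sweeps)) averageSweeps(sweeps) else as.numeric(sweeps)
  avg <- baselineSubtract(avg, dt, baselineWindow)
  sdn <- .noiseSd(avg, dt, baselineWindow)
  if (is.null(ampThreshold)) ampThreshold <- max(3 * sdn, 1)
  meas <- if (smoothMs > 0) .smooth(avg, dt, smoothMs) else avg
  amp <- if (metric == "peak") peakAmplitude(meas, dt, stimOnset, window)
         else windowedMeanAmplitude(meas, dt, stimOnset, window)
  m <- .smooth(-avg, dt)
  onset <- .onsetLatency(m, dt, stimOnset, sdn, k = kSigma,
                         sustainMs = sustainMs)
  # amplitude used for the classification threshold is always the peak
  peakAmp <- peakAmplitude(avg, dt, stimOnset, c(0, window[2]))
  cls <- "synaptic"
  rise <- NA_real_
  if (is.na(onset) || peakAmp < ampThreshold) {
    cls <- "none"
  } else if (onset < directLatency) {
    onIdx <- as.integer(floor((stimOnset + onset) / dt)) + 1L
    endIdx <- min(length(m),
                  as.integer(floor((stimOnset + window[2]) / dt)))
    cand <- .localMaxima(m[seq_len(endIdx)], max(3 * sdn, 1e-9))
    cand <- cand[cand >= onIdx]
    if (length(cand)) {
      p1 <- cand[1]
      rise <- .riseTime2080(m, dt, p1)
      if (!is.na(rise) && rise < directRiseMax) {
        # second, slower component after the direct latency bound?
        lat <- (cand - 1) * dt - stimOnset
        later <- cand[lat >= directLatency & m[cand] > ampThreshold]
        sep <- max(ampThreshold / 2, 3 * sdn)
        mixed <- FALSE
        for (j in later) {
          trough <- min(m[p1:j])
          if (m[j] - trough > sep) { mixed <- TRUE; break }
        }
        cls <- if (mixed) "mixed" else "direct"
      }
    }
  }
  new("EvokedResponse", trace = avg, dt = dt, stimOnset = stimOnset,
      amplitude = amp, onsetLatency = onset, riseTime = rise,
      classification = cls, window = window, excluded = FALSE,
      gridIndex = as.integer(gridIndex), power = power)
}

#' Classify an evoked response
#'
#' Re-runs the direct/synaptic/mixed classification of [evokedResponse()] on
#' an existing response object and returns the label.
#'
#' @param resp An [EvokedResponse-class] (baseline-subtracted).
#' @param ampThreshold,directLatency,directRiseMax see [evokedResponse()].
#' @return One of `"none"`, `"synaptic"`, `"direct"`, `"mixed"`.
#' @export
classifyResponse <- function(resp, ampThreshold = NULL, directLatency = 5,
                             directRiseMax = 1) {
  r <- evokedResponse(resp@trace, resp@dt, resp@stimOnset,
                      window = resp@window, ampThreshold = ampThreshold,
                      directLatency = directLatency,
                      directRiseMax = directRiseMax,
                      gridIndex = resp@gridIndex, power = resp@power)
  r@classification
}

# ---------------------------------------------------------------------------
# direct-response subtraction
# ---------------------------------------------------------------------------

# log-linear peel initial values for a double-exponential decay of y(t)
.peelInit <- function(t, y) {
  eps <- max(y, 1e-6) * 1e-6
  late <- t >= stats::median(t)
  fit2 <- try(stats::lm(log(pmax(y[late], eps)) ~ t[late]), silent = TRUE)
  tau2 <- 10; A2 <- max(y) / 2
  if (!inherits(fit2, "try-error") && is.finite(coef(fit2)[2]) &&
      coef(fit2)[2] < 0) {
    tau2 <- min(500, max(0.06, -1 / coef(fit2)[2]))
    A2 <- exp(coef(fit2)[1])
  }
  A2 <- unname(A2); tau2 <- unname(tau2)
  resid <- y - A2 * exp(-t / tau2)
  early <- t < stats::median(t) & resid > 0
  tau1 <- 1; A1 <- max(resid, max(y) / 2)
  if (sum(early) >= 3) {
    fit1 <- try(stats::lm(log(resid[early]) ~ t[early]), silent = TRUE)
    if (!inherits(fit1, "try-error") && is.finite(coef(fit1)[2]) &&
        coef(fit1)[2] < 0) {
      tau1 <- min(500, max(0.06, unname(-1 / coef(fit1)[2])))
      A1 <- unname(exp(coef(fit1)[1]))
    }
  }
  if (abs(tau1 - tau2) < 0.5) tau2 <- max(tau1 * 10, 1)
  st <- list(A1 = A1, tau1 = tau1, A2 = A2, tau2 = tau2)
  lapply(st, function(v) if (is.finite(v)) v else 1)
}

#' Subtract the direct-response component by double-exponential fitting
#'
#' For responses classified `direct` or `mixed`, fits
#' `A1*exp(-t/tau1) + A2*exp(-t/tau2)` to the decay of the direct component
#' (from its peak up to the onset of the synaptic component, or over the
#' analysis window for pure direct responses), extrapolates the fit over the
#' analysis window, subtracts it, and re-measures and re-classifies the
#' corrected response. Pure direct responses are additionally flagged
#' `excluded` so maps drop those pixels; a non-convergent fit flags the
#' response unusable. Responses classified `none` or `synaptic` are returned
#' unchanged.
#'
#' @param resp An [EvokedResponse-class].
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @return An [EvokedResponse-class] with the direct component removed.
#' @export
removeDirect <- function(resp, maxIter = 500) {
  if (!resp@classification %in% c("direct", "mixed")) return(resp)
  dt <- resp@dt
  m <- -resp@trace
  n <- length(m)
  onIdx <- as.integer(floor((resp@stimOnset +
                               max(resp@onsetLatency, 0)) / dt)) + 1L
  searchEnd <- min(n, as.integer(floor((resp@stimOnset + 6) / dt)))
  p1 <- onIdx + which.max(m[onIdx:searchEnd]) - 1L
  winEnd <- min(n, as.integer(floor((resp@stimOnset + resp@window[2]) / dt)))
  ms <- .smooth(m, dt)
  sdn <- .noiseSd(resp@trace, dt, c(0, resp@stimOnset))
  # fit only while the direct decay is above the noise floor ...
  floorLev <- max(3 * sdn, 0.05 * m[p1])
  below <- which(ms[seq.int(p1, winEnd)] < floorLev)
  fitEnd <- if (length(below)) p1 + below[1] - 2L else winEnd
  if (resp@classification == "mixed") {
    # ... and only up to the trough preceding the synaptic component
    cand <- .localMaxima(ms[seq_len(winEnd)], 0)
    cand <- cand[(cand - 1) * dt - resp@stimOnset >= 5 & cand > p1]
    if (length(cand)) {
      j <- cand[which.max(ms[cand])]
      # back off 1 ms from the trough: the synaptic rise already
      # contaminates the trough itself
      fitEnd <- min(fitEnd,
                    p1 + which.min(ms[p1:j]) - 1L - as.integer(round(1 / dt)))
    }
  }
  if (fitEnd - p1 < 5) fitEnd <- min(winEnd, p1 + 5L)
  tt <- (seq.int(p1, fitEnd) - p1) * dt
  yy <- m[seq.int(p1, fitEnd)]
  st <- .peelInit(tt, yy)
  # order the components fast/slow and keep the taus separated
  if (st$tau1 > st$tau2) st <- list(A1 = st$A2, tau1 = st$tau2,
                                    A2 = st$A1, tau2 = st$tau1)
  st$tau1 <- min(st$tau1, 100); st$tau2 <- min(st$tau2, 100)
  if (st$tau2 < 2 * st$tau1) st$tau1 <- st$tau2 / 5
  # Levenberg-Marquardt on the decay; amplitudes free (the post-peak rise
  # term of a difference-of-exponentials is negative), taus bounded so the
  # extrapolated tail stays a decay; best of two starts
  dblexp <- function(p, t) p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4])
  starts <- list(
    c(A1 = st$A1, tau1 = st$tau1, A2 = st$A2, tau2 = st$tau2),
    c(A1 = yy[1] / 2, tau1 = 1, A2 = yy[1] / 2, tau2 = 10))
  fit <- NULL
  for (s in starts) {
    f <- try(minpack.lm::nls.lm(
      par = s, fn = function(p) yy - dblexp(p, tt),
      lower = c(-Inf, 0.05, -Inf, 0.05), upper = c(Inf, 100, Inf, 100),
      control = minpack.lm::nls.lm.control(maxiter = maxIter)),
      silent = TRUE)
    if (inherits(f, "try-error") || any(!is.finite(f$par))) next
    # physical decay: the slower component must have non-negative
    # amplitude, else the extrapolated tail is a cancellation artifact
    slowA <- if (f$par[2] >= f$par[4]) f$par[1] else f$par[3]
    if (slowA < 0) next
    if (is.null(fit) || mean(f$fvec^2) < mean(fit$fvec^2)) fit <- f
  }
  fitOk <- !is.null(fit) &&
    sqrt(mean(fit$fvec^2)) <= max(3 * sdn, 0.05 * m[p1])
  if (!fitOk) {
    resp@excluded <- TRUE
    return(resp)
  }
  text <- (seq.int(p1, winEnd) - p1) * dt
  pred <- dblexp(fit$par, text)
  # the subtracted component is a decaying inward current: clamp the
  # extrapolation to [0, just above the direct peak]
  pred <- pmin(pmax(pred, 0), 1.5 * m[p1])
  if (any(!is.finite(pred))) {
    resp@excluded <- TRUE
    return(resp)
  }
  corrected <- resp@trace
  corrected[seq.int(p1, winEnd)] <- corrected[seq.int(p1, winEnd)] + pred
  # the stretch from direct onset to the end of the fitted decay region is
  # direct-only by construction (for mixed responses it precedes the
  # synaptic component; for pure direct there is no synaptic component), so
  # the corrected trace is zeroed there rather than left with fit residue
  corrected[seq.int(onIdx, max(p1, fitEnd))] <- 0
  out <- evokedResponse(corrected, dt, resp@stimOnset, window = resp@window,
                        gridIndex = resp@gridIndex, power = resp@power)
  if (resp@classification == "direct") out@excluded <- TRUE
  out
}

# ---------------------------------------------------------------------------
# quantal event detection and windowing
# ---------------------------------------------------------------------------

#' Detect quantal events in a continuous trace
#'
#' Threshold-crossing detection of inward (negative) quantal events on a
#' lightly smoothed trace: local minima whose magnitude relative to a local
#' pre-event baseline exceeds `kSigma` times the noise SD and that stay
#' beyond threshold for at least `minWidth` ms (single-sample noise
#' excursions do not), separated by at least `minIei` ms (closer candidates
#' are merged into the larger event). Event time is reported as the 20%
#' rising-phase crossing, i.e. an estimate of event onset, so window
#' boundaries are not shifted by the kernel's time to peak.
#'
#' @param x numeric baseline-subtracted trace, pA (inward negative).
#' @param dt ms per sample.
#' @param kSigma detection threshold in noise SDs.
#' @param minIei minimum inter-event interval, ms.
#' @param minWidth minimum time the deflection stays beyond threshold, ms.
#' @param noiseSd noise SD, pA; when NULL, estimated from the median absolute
#'   successive difference of the raw trace (insensitive to the slow event
#'   waveforms riding on the noise).
#' @param sweepId sweep label stored with the events.
#' @return A [QuantalEventSet-class] with unlabeled events (`t_ms` in sweep
#'   time); see [windowEvents()].
#' @export
detectEvents <- function(x, dt, kSigma = 3, minIei = 2, minWidth = 0.5,
                         noiseSd = NULL, sweepId = "sweep1") {
  n <- length(x)
  sdn <- if (is.null(noiseSd)) mad(diff(x), center = 0) / sqrt(2) else noiseSd
  thr <- max(kSigma * sdn, 1e-9)
  xs <- .smooth(x, dt, widthMs = 0.3)
  i <- 2:(n - 1)
  cand <- i[xs[i] <= xs[i - 1] & xs[i] < xs[i + 1] & xs[i] < -thr]
  empty <- data.frame(sweep_id = character(), t_ms = numeric(),
                      amp_pA = numeric(), label = character())
  windows <- list(spontaneous = c(-1000, 0), evoked = c(50, 350))
  if (!length(cand))
    return(new("QuantalEventSet", events = empty, nSweeps = 1L,
               windows = windows))
  # refractory merge: keep deepest first, drop neighbors within minIei
  gap <- as.integer(round(minIei / dt))
  keep <- logical(length(cand))
  taken <- integer()
  for (j in order(xs[cand])) {
    if (!length(taken) || all(abs(cand[j] - taken) >= gap)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  cand <- sort(cand[keep])
  pre2 <- as.integer(round(2 / dt))
  pre6 <- as.integer(round(6 / dt))
  needW <- max(1L, as.integer(round(minWidth / dt)))
  # trough value read from a local quadratic fit of the raw trace (+-1 ms):
  # taking the minimum of a noisy trace would overestimate amplitudes
  qw <- as.integer(round(1 / dt))
  tq <- (-qw):qw
  Xq <- cbind(1, tq, tq^2)
  Hq <- solve(crossprod(Xq), t(Xq))
  troughValue <- function(i0) {
    if (i0 - qw < 1 || i0 + qw > n) return(xs[i0])
    cf <- Hq %*% x[(i0 - qw):(i0 + qw)]
    if (cf[3] <= 0) return(xs[i0])
    ts <- max(min(-cf[2] / (2 * cf[3]), qw), -qw)
    cf[1] + cf[2] * ts + cf[3] * ts^2
  }
  tms <- amps <- numeric(length(cand))
  ok <- logical(length(cand))
  for (j in seq_along(cand)) {
    i0 <- cand[j]
    b <- median(x[max(1, i0 - pre6):max(1, i0 - pre2)])
    amp <- b - troughValue(i0)
    if (amp <= thr) next
    # sustained-crossing check around the trough
    lo <- i0; while (lo > 1 && xs[lo - 1] < b - thr) lo <- lo - 1
    hi <- i0; while (hi < n && xs[hi + 1] < b - thr) hi <- hi + 1
    if (hi - lo + 1L < needW) next
    # walk back to the 20% rising crossing
    lev <- b - 0.2 * amp
    k <- i0
    while (k > 1 && xs[k - 1] < lev) k <- k - 1
    t20 <- if (k == 1) 0 else
      (k - 2 + (lev - xs[k - 1]) / (xs[k] - xs[k - 1])) * dt
    tms[j] <- t20; amps[j] <- amp; ok[j] <- TRUE
  }
  if (any(ok)) {
    # a noise blip on the rising phase of an event walks back to the same
    # 20% crossing as the event itself: deduplicate by onset, keeping the
    # larger amplitude
    tms <- tms[ok]; amps <- amps[ok]
    keep2 <- rep(TRUE, length(tms))
    for (j in order(-amps)) {
      if (!keep2[j]) next
      dup <- which(keep2 & abs(tms - tms[j]) < minIei & seq_along(tms) != j &
                     amps <= amps[j])
      keep2[dup] <- FALSE
    }
    o <- order(tms[keep2])
    ev <- data.frame(sweep_id = sweepId, t_ms = tms[keep2][o],
                     amp_pA = amps[keep2][o], label = "unlabeled")
  } else ev <- empty
  new("QuantalEventSet", events = ev, nSweeps = 1L, windows = windows)
}

#' Pool detected events across the sweeps of a cell
#'
#' Runs [detectEvents()] on each (median-subtracted) sweep of a Sr2+
#' recording and labels the pooled events with [windowEvents()] relative to
#' the flash.
#'
#' @param cell A [CellRecording-class] in Sr2+ mode.
#' @param ... passed to [detectEvents()].
#' @return A labeled [QuantalEventSet-class] with `nSweeps = ncol(cell)`.
#' @export
detectCellEvents <- function(cell, ...) {
  cur <- sweepCurrents(cell)
  info <- sweepInfo(cell)
  dt <- dtMs(cell)
  evs <- lapply(seq_len(ncol(cur)), function(s) {
    x <- cur[, s] - median(cur[, s])
    es <- detectEvents(x, dt, sweepId = info$sweep_id[s], ...)
    ev <- eventTable(es)
    ev$t_ms <- ev$t_ms - info$stim_onset[s]   # relative to flash
    ev
  })
  pooled <- do.call(rbind, evs)
  qs <- new("QuantalEventSet", events = pooled,
            nSweeps = as.integer(ncol(cur)),
            windows = list(spontaneous = c(-1000, 0), evoked = c(50, 350)))
  windowEvents(qs)
}

#' Label events by analysis window
#'
#' Assigns each event to the spontaneous window [-1000, 0) ms, the evoked
#' window [50, 350) ms, or `other`. Windows are half-open in ms relative to
#' the flash; an event at exactly +350 ms (or +49.9 ms) is `other`.
#'
#' @param events A [QuantalEventSet-class].
#' @param tFlash flash time, ms, subtracted from event times before labeling
#'   (0 when times are already relative to the flash).
#' @return The [QuantalEventSet-class] with `t_ms` relative to the flash and
#'   labels filled in.
#' @export
windowEvents <- function(events, tFlash = 0) {
  ev <- events@events
  t <- ev$t_ms - tFlash
  w <- events@windows
  lab <- rep("other", length(t))
  lab[t >= w$spontaneous[1] & t < w$spontaneous[2]] <- "spontaneous"
  lab[t >= w$evoked[1] & t < w$evoked[2]] <- "evoked"
  ev$t_ms <- t
  ev$label <- lab
  events@events <- ev
  events
}

#' Spontaneous and evoked event rates and amplitudes
#'
#' Rates are counts divided by (number of sweeps x window duration): 1.0 s
#' for the spontaneous window, 0.3 s for the evoked window. Amplitudes are
#' means over the labeled events (NA when a window holds no events).
#'
#' @param events A labeled [QuantalEventSet-class].
#' @return Named list: `spont_hz`, `evoked_hz`, `spont_amp_pa`,
#'   `evoked_amp_pa`, `n_sweeps`.
#' @export
eventRates <- function(events) {
  assertThat(events@nSweeps >= 1, "optomap_invalid_input",
             "event set spans zero sweeps")
  ev <- events@events
  assertThat(all(ev$label != "unlabeled"), "optomap_invalid_input",
             "events are unlabeled; run windowEvents() first")
  w <- events@windows
  durS <- diff(w$spontaneous) / 1000
  durE <- diff(w$evoked) / 1000
  sp <- ev[ev$label == "spontaneous", ]
  evo <- ev[ev$label == "evoked", ]
  list(spont_hz = nrow(sp) / (events@nSweeps * durS),
       evoked_hz = nrow(evo) / (events@nSweeps * durE),
       spont_amp_pa = if (nrow(sp)) mean(sp$amp_pA) else NA_real_,
       evoked_amp_pa = if (nrow(evo)) mean(evo$amp_pA) else NA_real_,
       n_sweeps = events@nSweeps)
}

# ---------------------------------------------------------------------------
# per-cell response tables
# ---------------------------------------------------------------------------

#' Measure every stimulation spot of a grid recording
#'
#' Groups sweeps by grid spot, averages repeats, measures and classifies each
#' averaged response, and (when `subtractDirect`) applies [removeDirect()] to
#' direct and mixed responses.
#'
#' @param cell A [CellRecording-class] from a grid mode.
#' @param window,metric,ampThreshold,directRiseMax see [evokedResponse()].
#' @param subtractDirect fit and subtract direct components (LSPS / AP-map
#'   analysis); pure direct spots stay excluded.
#' @return list: `table` -- data.frame (cell_id, grid_row, grid_col,
#'   amplitude_pA, classification, onset_ms, excluded, power_mW) -- and
#'   `responses`, the corresponding [EvokedResponse-class] list.
#' @export
cellResponses <- function(cell, window = c(5, 80),
                          metric = c("peak", "windowed_mean"),
                          ampThreshold = NULL, directRiseMax = 1,
                          subtractDirect = mapMode(cell) %in% c("LSPS", "AP_map")) {
  metric <- match.arg(metric)
  info <- sweepInfo(cell)
  assertThat(all(!is.na(info$grid_row)), "optomap_invalid_input",
             "cell '%s' has sweeps without grid positions", cellId(cell))
  cur <- sweepCurrents(cell)
  dt <- dtMs(cell)
  key <- paste(info$grid_row, info$grid_col)
  spots <- split(seq_len(ncol(cur)), key)
  resps <- vector("list", length(spots))
  rows <- vector("list", length(spots))
  for (k in seq_along(spots)) {
    idx <- spots[[k]]
    on <- unique(info$stim_onset[idx])
    assertThat(length(on) == 1, "optomap_incompatible_sweeps",
               "sweeps of one spot differ in stim_onset")
    r <- evokedResponse(cur[, idx, drop = FALSE], dt, on, window = window,
                        metric = metric, ampThreshold = ampThreshold,
                        directRiseMax = directRiseMax,
                        gridIndex = c(info$grid_row[idx[1]],
                                      info$grid_col[idx[1]]),
                        power = info$power[idx[1]])
    if (subtractDirect && r@classification %in% c("direct", "mixed"))
      r <- removeDirect(r)
    resps[[k]] <- r
    rows[[k]] <- data.frame(
      cell_id = cellId(cell), grid_row = r@gridIndex[1],
      grid_col = r@gridIndex[2], amplitude_pA = r@amplitude,
      classification = r@classification, onset_ms = r@onsetLatency,
      excluded = r@excluded, power_mW = r@power)
  }
  tab <- do.call(rbind, rows)
  o <- order(tab$grid_row, tab$grid_col)
  list(table = tab[o, , drop = FALSE], responses = resps[o])
}

#' Amplitude of a bulk-stimulation recording
#'
#' Averages all sweeps of an LED bulk recording and measures the peak of the
#' averaged EPSC (5-80 ms window by default), plus the per-sweep trial peaks
#' used for coefficient-of-variation analysis.
#'
#' @param cell A [CellRecording-class] (LED bulk or NMDAR protocol).
#' @param window analysis window, ms after stimulus onset (use c(5, 150) for
#'   slow NMDAR EPSCs).
#' @return list: `amplitude_pA`, `norm_pA_mW`, `trial_amps`, `power_mW`.
#' @export
bulkAmplitude <- function(cell, window = c(5, 80)) {
  cur <- sweepCurrents(cell)
  info <- sweepInfo(cell)
  dt <- dtMs(cell)
  on <- unique(info$stim_onset)
  assertThat(length(on) == 1, "optomap_incompatible_sweeps",
             "bulk sweeps differ in stim_onset")
  bs <- baselineSubtract(cur, dt, c(0, on))
  avg <- averageSweeps(bs)
  amp <- peakAmplitude(avg, dt, on, window, smoothMs = 1)
  trial <- apply(bs, 2, peakAmplitude, dt = dt, stimOnset = on,
                 window = window, smoothMs = 1)
  pw <- info$power[1]
  list(amplitude_pA = amp, norm_pA_mW = normalizeToPower(amp, pw),
       trial_amps = as.numeric(trial), power_mW = pw)
}
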