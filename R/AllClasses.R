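#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# SynthConfig -- parameters of a synthetic mapping / quantal experiment
# ---------------------------------------------------------------------------

#' SynthConfig: parameters of a synthetic photostimulation experiment
#'
#' Holds every tunable of the synthetic-experiment generator: sampling,
#' stimulus timing, grid geometry, EPSC kernel kinetics, binomial quantal
#' release, direct (non-synaptic) response shape, asynchronous-release rates
#' for strontium experiments, and the multiplicative genotype effect
#' `ko_scale` applied to synaptic (never direct) amplitudes.
#'
#' @slot seed integer RNG seed; the same seed and config give a bit-identical
#'   dataset.
#' @slot dt ms per sample (default 0.1, i.e. 10 kHz).
#' @slot sweep_len sweep length, ms.
#' @slot stim_onset stimulus onset within the sweep, ms.
#' @slot grid_rows,grid_cols photostimulation grid size (NA = mode default).
#' @slot x_spacing,y_spacing grid spacing, um (NA = mode default).
#' @slot tau_rise,tau_decay synaptic EPSC kernel time constants, ms.
#' @slot noise_sd Gaussian recording noise SD, pA.
#' @slot n_sites,p_release binomial release-site count and probability.
#' @slot quantal_amp_mean,quantal_amp_cv lognormal quantal size mean (pA) and CV.
#' @slot ko_scale multiplicative genotype effect on synaptic amplitude
#'   (evoked release rate in Sr2+ mode).
#' @slot direct_frac probability that a spot within `direct_radius` um of the
#'   soma carries a direct response (LSPS / AP-map modes only).
#' @slot direct_onset,direct_tau_rise,direct_tau_decay,direct_amp direct
#'   response onset (ms, < 5), kinetics (ms) and amplitude (pA).
#' @slot direct_radius radius around the soma, um, within which direct
#'   responses may occur.
#' @slot led_power LED power, mW, used for power normalization.
#' @slot bulk_scale multiple of the single-spot quantal content recruited by
#'   wide-field LED stimulation (sets bulk EPSCs to the few-hundred-pA range
#'   of power-adjusted recordings).
#' @slot spont_rate spontaneous event rate, Hz.
#' @slot evoked_rate0,evoked_tau peak rate (Hz) and decay constant (ms) of the
#'   exponentially decaying asynchronous-release intensity after the flash.
#' @slot n_pairs number of WT/KO neighbor pairs.
#' @slot evoked_amp_mean mean lognormal amplitude of evoked quantal events,
#'   pA (spontaneous events use `quantal_amp_mean`).
#' @slot syn_latency synaptic onset latency after the stimulus, ms
#'   (presynaptic spike initiation and conduction; > 5 ms so the direct
#'   classification rule is discriminative).
#' @slot field_amp,field_sigma,field_offset innervation field: peak mean
#'   synaptic amplitude (pA), isotropic Gaussian SD (um), and pia-ward offset
#'   of the field peak from the soma (um).
#' @slot soma_row,soma_col grid pixel on which the soma sits (NA = mode
#'   default).
#' @slot quantal_tau_rise,quantal_tau_decay kinetics of single quantal
#'   events, ms (faster than the compound evoked EPSC, as for miniature
#'   AMPAR EPSCs).
#' @slot sr_noise_sd recording noise of Sr2+ sweeps, pA (quantal-event
#'   recordings require lower noise than mapping sweeps).
#' @slot sr_ko_rate_scale multiplicative genotype effect on the evoked
#'   asynchronous-release intensity in Sr2+ mode; the default scales the
#'   7 Hz above-baseline evoked rate so the KO evoked-window rate is 6.7 Hz
#'   against 8.3 Hz in WT (a >20% reduction in evoked quantal frequency with
#'   unchanged amplitude).
#' @slot sr_baseline,sr_post Sr2+ sweep: baseline length before the flash and
#'   post-flash length, ms.
#' @export
setClass("SynthConfig", representation(
  seed = "integer",
  dt = "numeric", sweep_len = "numeric", stim_onset = "numeric",
  grid_rows = "numeric", grid_cols = "numeric",
  x_spacing = "numeric", y_spacing = "numeric",
  tau_rise = "numeric", tau_decay = "numeric",
  noise_sd = "numeric",
  n_sites = "numeric", p_release = "numeric",
  quantal_amp_mean = "numeric", quantal_amp_cv = "numeric",
  ko_scale = "numeric",
  direct_frac = "numeric", direct_onset = "numeric",
  direct_tau_rise = "numeric", direct_tau_decay = "numeric",
  direct_amp = "numeric", direct_radius = "numeric",
  led_power = "numeric", bulk_scale = "numeric",
  spont_rate = "numeric", evoked_rate0 = "numeric", evoked_tau = "numeric",
  n_pairs = "numeric", evoked_amp_mean = "numeric", syn_latency = "numeric",
  field_amp = "numeric", field_sigma = "numeric", field_offset = "numeric",
  soma_row = "numeric", soma_col = "numeric",
  quantal_tau_rise = "numeric", quantal_tau_decay = "numeric",
  sr_noise_sd = "numeric", sr_ko_rate_scale = "numeric",
  sr_baseline = "numeric", sr_post = "numeric"
))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  chk <- function(ok, m) if (!isTRUE(ok)) msgs <<- c(msgs, m)
  chk(object@dt > 0, "dt must be > 0")
  chk(object@tau_rise > 0 && object@tau_decay > object@tau_rise,
      "need tau_decay > tau_rise > 0")
  chk(object@p_release > 0 && object@p_release <= 1,
      "p_release must be in (0, 1]")
  chk(object@ko_scale > 0, "ko_scale must be > 0")
  chk(object@noise_sd >= 0, "noise_sd must be >= 0")
  chk(object@spont_rate >= 0, "spont_rate must be >= 0")
  chk(object@evoked_rate0 >= 0, "evoked_rate0 must be >= 0")
  chk(object@n_pairs >= 1, "n_pairs must be >= 1")
  chk(object@quantal_amp_cv >= 0, "quantal_amp_cv must be >= 0")
  chk(object@direct_frac >= 0 && object@direct_frac <= 1,
      "direct_frac must be in [0, 1]")
  chk(object@direct_onset < 5, "direct_onset must be < 5 ms")
  chk(object@sweep_len > object@stim_onset, "sweep_len must exceed stim_onset")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# CellRecording -- all sweeps and geometry for one neuron
# ---------------------------------------------------------------------------

#' CellRecording: every sweep recorded from one neuron
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. The single assay
#' `"current"` is a samples x sweeps matrix of membrane current in pA (signed;
#' inward currents are negative). `colData` carries per-sweep stimulus
#' metadata (`sweep_id`, `stim_kind`, `grid_row`, `grid_col`, `rep`, `power`,
#' `stim_onset`, `holding`, `stim_order`). `metadata()` carries cell-level
#' fields: `dt` (ms/sample), `soma` (x, y in um, slice frame), `genotype`
#' ("WT"/"KO"), `pair_id`, `cell_id`, `mode`, `grid` (geometry list), `seed`.
#'
#' @export
setClass("CellRecording", contains = "SummarizedExperiment")

.REQ_SWEEP_COLS <- c("sweep_id", "stim_kind", "power", "stim_onset")

setValidity("CellRecording", function(object) {
  msgs <- character()
  md <- S4Vectors::metadata(object)
  cd <- SummarizedExperiment::colData(object)
  if (!"current" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'current' is required")
  miss <- setdiff(.REQ_SWEEP_COLS, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  for (f in c("dt", "genotype", "cell_id", "mode"))
    if (is.null(md[[f]])) msgs <- c(msgs, paste0("metadata lacks '", f, "'"))
  if (!is.null(md$dt) && !(isScalarNum(md$dt) && md$dt > 0))
    msgs <- c(msgs, "metadata dt must be a positive scalar")
  if (!length(msgs) && ncol(object) > 0) {
    n <- nrow(object)
    bad <- cd$stim_onset < 0 | cd$stim_onset > n * md$dt
    if (any(bad)) msgs <- c(msgs, "stim_onset outside the trace span")
    stim <- cd$stim_kind != "none"
    if (any(stim & !(cd$power > 0)))
      msgs <- c(msgs, "power must be > 0 for stimulated sweeps")
    if (anyDuplicated(cd$sweep_id))
      msgs <- c(msgs, "duplicate sweep_id")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CellRecording
#'
#' @param currents numeric matrix, samples x sweeps, current in pA (inward
#'   negative).
#' @param info data.frame of per-sweep metadata, one row per column of
#'   `currents`; must contain `sweep_id`, `stim_kind`, `power`, `stim_onset`.
#' @param dt ms per sample.
#' @param cellId,genotype,pairId,mode cell-level metadata.
#' @param soma numeric (x, y) soma position in um, slice frame, or NULL.
#' @param grid grid geometry list (`rows`, `cols`, `x_spacing`, `y_spacing`,
#'   `x0`, `y0` = center of grid pixel (1, 1)), or NULL for non-grid modes.
#' @param seed integer seed recorded for provenance, or NA.
#' @return A [CellRecording-class] object.
#' @export
CellRecording <- function(currents, info, dt, cellId, genotype,
                          pairId = NA_character_, mode = "LED_bulk",
                          soma = NULL, grid = NULL, seed = NA_integer_) {
  currents <- as.matrix(currents)
  info <- S4Vectors::DataFrame(info)
  colnames(currents) <- info$sweep_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(current = currents), colData = info,
    metadata = list(dt = dt, soma = soma, genotype = genotype,
                    pair_id = pairId, cell_id = cellId, mode = mode,
                    grid = grid, seed = seed))
  new("CellRecording", se)
}

setMethod("show", "CellRecording", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("CellRecording '%s' (%s, pair %s, mode %s)\n",
              md$cell_id, md$genotype, md$pair_id, md$mode))
  cat(sprintf("  %d sweeps x %d samples @ %g ms/sample (%g ms)\n",
              ncol(object), nrow(object), md$dt, nrow(object) * md$dt))
  if (!is.null(md$grid))
    cat(sprintf("  grid %d x %d, %g x %g um spacing\n", md$grid$rows,
                md$grid$cols, md$grid$x_spacing, md$grid$y_spacing))
  if (!is.null(md$soma))
    cat(sprintf("  soma at (%g, %g) um\n", md$soma[1], md$soma[2]))
})

# ---------------------------------------------------------------------------
# EvokedResponse -- averaged, measured, classified response at one spot
# ---------------------------------------------------------------------------

#' EvokedResponse: the averaged evoked response at one stimulation spot
#'
#' @slot trace baseline-subtracted mean trace over repeats, pA.
#' @slot dt ms per sample.
#' @slot stimOnset stimulus onset, ms.
#' @slot amplitude measured amplitude, pA (positive magnitude).
#' @slot onsetLatency first sustained threshold crossing after the stimulus,
#'   ms relative to stimulus onset (NA if no response).
#' @slot riseTime 20-80% rise time of the first response component, ms.
#' @slot classification one of "none", "synaptic", "direct", "mixed".
#' @slot window analysis window (ms relative to stimulus onset).
#' @slot excluded TRUE for responses excluded from maps (pure direct, or
#'   failed direct-subtraction fits).
#' @slot gridIndex integer (row, col) or NA.
#' @slot power stimulation power, mW.
#' @export
setClass("EvokedResponse", representation(
  trace = "numeric", dt = "numeric", stimOnset = "numeric",
  amplitude = "numeric", onsetLatency = "numeric", riseTime = "numeric",
  classification = "character", window = "numeric", excluded = "logical",
  gridIndex = "integer", power = "numeric"))

setValidity("EvokedResponse", function(object) {
  msgs <- character()
  if (!object@classification %in% c("none", "synaptic", "direct", "mixed"))
    msgs <- c(msgs, "bad classification")
  if (!is.na(object@amplitude) && object@amplitude < 0)
    msgs <- c(msgs, "amplitude must be >= 0")
  if (object@classification == "direct" &&
      !is.na(object@onsetLatency) && object@onsetLatency >= 5)
    msgs <- c(msgs, "direct classification requires onset latency < 5 ms")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EvokedResponse", function(object) {
  cat(sprintf(
    "EvokedResponse: %s, %.1f pA, onset %.2f ms, window [%g, %g) ms%s\n",
    object@classification, object@amplitude, object@onsetLatency,
    object@window[1], object@window[2],
    if (object@excluded) " [excluded]" else ""))
})

# ---------------------------------------------------------------------------
# InputMap / GroupMap -- 2-D spatial maps of input strength
# ---------------------------------------------------------------------------

.MASK_LEVELS <- c("valid", "direct_excluded", "unsampled")

#' InputMap: per-cell 2-D grid of synaptic input strengths
#'
#' Values are input strength (pA, or pA/mW after power normalization) at each
#' stimulation pixel; a pixel's value refers to its center. Coordinates: x is
#' lateral (medial to lateral positive), y vertical with pia-ward positive;
#' row 1 is the most pia-ward row, y decreases down rows.
#'
#' @slot values numeric matrix; NA on masked pixels.
#' @slot mask character matrix over `"valid"`, `"direct_excluded"`,
#'   `"unsampled"`.
#' @slot pixelSize (x, y) pixel size, um.
#' @slot frame `"slice"`, `"soma_aligned"` or `"barrel_aligned"`.
#' @slot origin (x, y) of the center of pixel (1, 1) in the current frame, um.
#' @slot soma (x, y) soma position in the current frame, um (NA if unknown).
#' @slot meta list: cell id, genotype, pair id, power, normalized flag.
#' @export
setClass("InputMap", representation(
  values = "matrix", mask = "matrix", pixelSize = "numeric",
  frame = "character", origin = "numeric", soma = "numeric", meta = "list"))

setValidity("InputMap", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msgs <- c(msgs, "values and mask dimensions differ")
  if (!all(object@mask %in% .MASK_LEVELS))
    msgs <- c(msgs, "mask entries must be valid/direct_excluded/unsampled")
  if (!all(object@pixelSize > 0)) msgs <- c(msgs, "pixelSize must be > 0")
  if (!object@frame %in% c("slice", "soma_aligned", "barrel_aligned"))
    msgs <- c(msgs, "unknown frame")
  v <- object@values[object@mask == "valid"]
  if (any(!is.finite(v))) msgs <- c(msgs, "valid pixels must be finite")
  if (any(v < 0, na.rm = TRUE)) msgs <- c(msgs, "valid pixels must be >= 0")
  if (!all(is.na(object@values[object@mask != "valid"])))
    msgs <- c(msgs, "masked pixels must carry NA")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "InputMap", function(object) {
  cat(sprintf(
    "InputMap %d x %d px (%g x %g um), frame %s, %d valid / %d direct-excluded / %d unsampled\n",
    nrow(object@values), ncol(object@values), object@pixelSize[1],
    object@pixelSize[2], object@frame, sum(object@mask == "valid"),
    sum(object@mask == "direct_excluded"), sum(object@mask == "unsampled")))
})

#' GroupMap: genotype-averaged input map with a minimum-sampling mask
#'
#' @slot values per-pixel mean over contributing valid cell pixels; NA where
#'   fewer than `minN` cells contribute.
#' @slot n integer matrix of contributing cells per pixel.
#' @slot minN minimum cells per pixel for the pixel to be shown.
#' @slot label group (genotype) label.
#' @slot pixelSize,frame,origin as in [InputMap-class].
#' @export
setClass("GroupMap", representation(
  values = "matrix", n = "matrix", minN = "numeric", label = "character",
  pixelSize = "numeric", frame = "character", origin = "numeric"))

setValidity("GroupMap", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@n)))
    msgs <- c(msgs, "values and n dimensions differ")
  if (any(!is.na(object@values[object@n < object@minN])))
    msgs <- c(msgs, "pixels below minN must be NA")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroupMap", function(object) {
  cat(sprintf(
    "GroupMap '%s': %d x %d px (%g x %g um), frame %s, min n = %d, %d shown pixels\n",
    object@label, nrow(object@values), ncol(object@values),
    object@pixelSize[1], object@pixelSize[2], object@frame,
    as.integer(object@minN), sum(!is.na(object@values))))
})

# ---------------------------------------------------------------------------
# QuantalEventSet -- detected quantal events with window labels
# ---------------------------------------------------------------------------

#' QuantalEventSet: detected quantal events across sweeps
#'
#' Event times are in ms; after [windowEvents()] they are relative to the
#' flash and each event carries a window label: spontaneous for t in
#' [-1000, 0) ms, evoked for t in [50, 350) ms, otherwise other (half-open
#' windows).
#'
#' @slot events data.frame with columns `sweep_id`, `t_ms`, `amp_pA`,
#'   `label`.
#' @slot nSweeps number of sweeps the events were pooled from.
#' @slot windows list of window definitions (ms relative to flash).
#' @export
setClass("QuantalEventSet", representation(
  events = "data.frame", nSweeps = "integer", windows = "list"))

setValidity("QuantalEventSet", function(object) {
  msgs <- character()
  need <- c("sweep_id", "t_ms", "amp_pA", "label")
  if (!all(need %in% names(object@events)))
    msgs <- c(msgs, paste0("events needs columns ",
                           paste(need, collapse = ", ")))
  if (object@nSweeps < 0) msgs <- c(msgs, "nSweeps must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "QuantalEventSet", function(object) {
  tab <- table(factor(object@events$label,
                      c("spontaneous", "evoked", "other", "unlabeled")))
  cat(sprintf(
    "QuantalEventSet: %d events over %d sweeps (%d spontaneous, %d evoked, %d other, %d unlabeled)\n",
    nrow(object@events), object@nSweeps, tab["spontaneous"], tab["evoked"],
    tab["other"], tab["unlabeled"]))
})

# ---------------------------------------------------------------------------
# TestResult -- one statistical comparison
# ---------------------------------------------------------------------------

#' TestResult: outcome of one (normality-gated) statistical test
#'
#' @slot test test actually run: "paired t", "Wilcoxon", "unpaired t",
#'   "Mann-Whitney" or "ANOVA interaction".
#' @slot statistic test statistic (t, V/W or F).
#' @slot df degrees of freedom (length 2 for the ANOVA F).
#' @slot p two-sided p value.
#' @slot n number of pairs / observations.
#' @slot normality named list of the two normality-test p values
#'   (`dagostino_pearson`, `anderson_darling`) and the gate verdict, or empty
#'   when no gate applies.
#' @export
setClass("TestResult", representation(
  test = "character", statistic = "numeric", df = "numeric", p = "numeric",
  n = "integer", normality = "list"))

setValidity("TestResult", function(object) {
  msgs <- character()
  ok <- c("paired t", "Wilcoxon", "unpaired t", "Mann-Whitney",
          "ANOVA interaction")
  if (!object@test %in% ok) msgs <- c(msgs, "unknown test name")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msgs <- c(msgs, "p must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TestResult", function(object) {
  dfs <- if (length(object@df)) paste(round(object@df, 2), collapse = ", ")
         else "-"
  cat(sprintf("TestResult: %s, statistic = %.4g, df = %s, p = %.4g, n = %d\n",
              object@test, object@statistic, dfs, object@p, object@n))
  if (length(object@normality))
    cat(sprintf(
      "  normality gate: D'Agostino-Pearson p = %.3g, Anderson-Darling p = %.3g -> %s\n",
      object@normality$dagostino_pearson, object@normality$anderson_darling,
      if (isTRUE(object@normality$normal)) "parametric" else "non-parametric"))
})

# ---------------------------------------------------------------------------
# PipelineConfig / PipelineResults
# ---------------------------------------------------------------------------

#' PipelineConfig: configuration of an end-to-end analysis run
#'
#' Mode-consistent measurement defaults: sCRACM and LED_bulk measure the peak
#' of the averaged EPSC 5-80 ms after stimulus onset; AP_map averages the
#' rectified EPSC 2-30 ms after onset (excluding polysynaptic contamination);
#' LSPS averages 5-80 ms after onset; Sr2+ uses the spontaneous [-1000, 0)
#' and evoked [50, 350) ms event windows.
#'
#' @slot mode one of "sCRACM", "AP_map", "LSPS", "LED_bulk", "Sr2+".
#' @slot window analysis window, ms after stimulus onset.
#' @slot metric "peak" or "windowed_mean".
#' @slot minN minimum cells per pixel in group maps.
#' @slot region named list of analysis regions, each c(xmin, xmax, ymin,
#'   ymax) um in the aligned frame.
#' @slot alpha significance level of the normality gate.
#' @slot normalizePower divide amplitudes by stimulation power before mapping
#'   and pairing.
#' @slot ampThreshold response-detection threshold, pA.
#' @slot directRiseMax maximum 20-80% rise time of a direct response, ms.
#' @slot inputDir directory of an existing dataset ("" = simulate).
#' @slot synth [SynthConfig-class] used when simulating.
#' @slot seed integer seed of the run.
#' @export
setClass("PipelineConfig", representation(
  mode = "character", window = "numeric", metric = "character",
  minN = "numeric", region = "list", alpha = "numeric",
  normalizePower = "logical", ampThreshold = "numeric",
  directRiseMax = "numeric", inputDir = "character", synth = "ANY",
  seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (!object@mode %in% c("sCRACM", "AP_map", "LSPS", "LED_bulk", "Sr2+"))
    msgs <- c(msgs, "unknown mode")
  if (!object@metric %in% c("peak", "windowed_mean"))
    msgs <- c(msgs, "metric must be 'peak' or 'windowed_mean'")
  if (length(object@window) != 2 || diff(object@window) <= 0)
    msgs <- c(msgs, "window must be (start, end) with end > start")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: mode %s, %s over [%g, %g) ms, min n = %d, %s, seed %d\n",
    object@mode, object@metric, object@window[1], object@window[2],
    as.integer(object@minN),
    if (object@normalizePower) "power-normalized" else "raw pA", object@seed))
})

#' PipelineResults: bundle produced by [runPipeline()]
#'
#' @slot responses per-spot response table (cell, grid position, amplitude,
#'   classification, onset).
#' @slot cellMaps list of per-cell soma-aligned [InputMap-class]s.
#' @slot groupMaps list of per-genotype [GroupMap-class]s.
#' @slot pairs paired-measure table (pair_id, metric, wt, ko).
#' @slot tests tidy statistics table (metric, test, statistic, df, p, n).
#' @slot events per-cell [QuantalEventSet-class]s (Sr2+ mode).
#' @slot manifest run manifest: config, seed, package version, config hash.
#' @export
setClass("PipelineResults", representation(
  responses = "data.frame", cellMaps = "list", groupMaps = "list",
  pairs = "data.frame", tests = "data.frame", events = "list",
  manifest = "list"))

setMethod("show", "PipelineResults", function(object) {
  cat(sprintf(
    "PipelineResults (%s): %d response rows, %d cell maps, %d group maps, %d pair rows, %d tests\n",
    object@manifest$mode, nrow(object@responses), length(object@cellMaps),
    length(object@groupMaps), nrow(object@pairs), nrow(object@tests)))
})
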