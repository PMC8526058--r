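#' @include AllClasses.R AllGenerics.R utils.R io.R
NULL

# mode-consistent measurement defaults
.modeDefaults <- function(mode) {
  switch(mode,
    sCRACM   = list(window = c(5, 80), metric = "peak"),
    AP_map   = list(window = c(2, 30), metric = "windowed_mean"),
    LSPS     = list(window = c(5, 80), metric = "windowed_mean"),
    LED_bulk = list(window = c(5, 80), metric = "peak"),
    "Sr2+"   = list(window = c(50, 350), metric = "peak"),
    stopc("optomap_invalid_parameter", "unknown mode '%s'", mode))
}

#' Construct a pipeline configuration
#'
#' Fills mode-consistent defaults (see [PipelineConfig-class]) and validates
#' the result.
#'
#' @param mode `"sCRACM"`, `"AP_map"`, `"LSPS"`, `"LED_bulk"` or `"Sr2+"`.
#' @param window analysis window override, ms after stimulus onset.
#' @param metric `"peak"` or `"windowed_mean"` (mode default when NULL).
#' @param minN minimum cells per group-map pixel.
#' @param region named list of aligned-frame analysis rectangles
#'   c(xmin, xmax, ymin, ymax) um; the default `proximal` region covers the
#'   perisomatic and proximal apical dendritic field.
#' @param alpha normality-gate significance level.
#' @param normalizePower divide amplitudes by stimulation power (default
#'   TRUE).
#' @param ampThreshold response threshold, pA (NA = 3x baseline noise SD).
#' @param directRiseMax direct-response rise-time bound, ms.
#' @param inputDir existing dataset directory ("" = simulate from `synth`).
#' @param synth [SynthConfig-class] used when simulating.
#' @param seed integer seed; overrides the seed in `synth`.
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(mode, window = NULL, metric = NULL, minN = 8,
                           region = list(proximal = c(-100, 100, -25, 175)),
                           alpha = 0.05, normalizePower = TRUE,
                           ampThreshold = NA_real_, directRiseMax = 1,
                           inputDir = "", synth = NULL, seed = 1L) {
  md <- .modeDefaults(mode)
  if (is.null(window)) window <- md$window
  if (is.null(metric)) metric <- md$metric
  if (!is.null(synth)) {
    assertThat(is(synth, "SynthConfig"), "optomap_invalid_parameter",
               "synth must be a SynthConfig")
    synth@seed <- as.integer(seed)
  }
  cfg <- new("PipelineConfig", mode = mode, window = window, metric = metric,
             minN = minN, region = region, alpha = alpha,
             normalizePower = normalizePower, ampThreshold = ampThreshold,
             directRiseMax = directRiseMax, inputDir = inputDir,
             synth = synth, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# long pair table + per-metric gated tests from a per-cell metric data.frame
# (columns: cell_id, pair_id, genotype, <metrics...>)
.pairAndTest <- function(cellTab, metrics, alpha) {
  pairsOut <- list()
  testsOut <- list()
  for (m in metrics) {
    wide <- merge(
      cellTab[cellTab$genotype == "WT", c("pair_id", m)],
      cellTab[cellTab$genotype == "KO", c("pair_id", m)],
      by = "pair_id", suffixes = c("_wt", "_ko"))
    pr <- data.frame(pair_id = wide$pair_id, metric = m,
                     wt = wide[[paste0(m, "_wt")]],
                     ko = wide[[paste0(m, "_ko")]])
    pairsOut[[m]] <- pr
    res <- try(pairedCompare(pr, alpha = alpha), silent = TRUE)
    if (!inherits(res, "try-error"))
      testsOut[[m]] <- data.frame(
        metric = m, test = res@test, statistic = res@statistic,
        df = if (length(res@df)) res@df[1] else NA_real_, p = res@p,
        n = res@n)
  }
  list(pairs = rbindList(pairsOut), tests = rbindList(testsOut))
}

.emptyDF <- function() data.frame()

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or reads) a dataset, converts sweeps to responses or quantal
#' events, assembles aligned maps and group maps for grid modes, evaluates
#' per-pair metrics and runs the normality-gated paired statistics, and
#' returns everything with a machine-readable run manifest. Fully
#' deterministic given the seed.
#'
#' @param config A [PipelineConfig-class].
#' @param quiet suppress per-stage INFO messages.
#' @return A [PipelineResults-class].
#' @export
#' @examples
#' cfg <- pipelineConfig("LED_bulk",
#'                       synth = synthConfig(n_pairs = 6), seed = 7)
#' res <- runPipeline(cfg, quiet = TRUE)
#' res@tests
runPipeline <- function(config, quiet = FALSE) {
  validObject(config)
  mode <- config@mode
  if (nzchar(config@inputDir)) {
    cells <- readDataset(config@inputDir)
    modes <- unique(vapply(cells, mapMode, ""))
    assertThat(length(modes) <= 1 && all(modes == mode),
               "optomap_schema_error",
               "config mode '%s' does not match dataset mode '%s'",
               mode, paste(modes, collapse = ","))
    truth <- NULL
  } else {
    assertThat(is(config@synth, "SynthConfig"), "optomap_invalid_parameter",
               "no input directory and no synth config")
    sim <- switch(mode,
      LED_bulk = simulateLedExperiment(config@synth),
      "Sr2+" = simulateSrExperiment(config@synth),
      simulateGridExperiment(config@synth, mode))
    cells <- sim$cells
    truth <- sim$truth
  }
  msg_info(quiet, "pipeline %s: %d cells", mode, length(cells))
  ampThr <- if (is.na(config@ampThreshold)) NULL else config@ampThreshold

  responses <- .emptyDF(); pairs <- .emptyDF(); tests <- .emptyDF()
  cellMaps <- list(); groupMaps <- list(); events <- list()

  if (length(cells) == 0) {
    cfgList <- configToList(config)
    return(new("PipelineResults", responses = responses, cellMaps = cellMaps,
               groupMaps = groupMaps, pairs = pairs, tests = tests,
               events = events,
               manifest = list(mode = mode, seed = config@seed,
                               package_version =
                                 as.character(packageVersion("optomap")),
                               config = cfgList,
                               config_hash = .configHash(cfgList),
                               truth_available = FALSE)))
  }

  if (mode %in% c("sCRACM", "AP_map", "LSPS")) {
    tabs <- list(); metricRows <- list()
    for (cell in cells) {
      cr <- cellResponses(cell, window = config@window,
                          metric = config@metric, ampThreshold = ampThr,
                          directRiseMax = config@directRiseMax)
      tabs[[cellId(cell)]] <- cr$table
      map <- buildCellMap(cr$table, gridGeometry(cell),
                          soma = somaPosition(cell),
                          meta = list(cell_id = cellId(cell),
                                      genotype = genotype(cell),
                                      pair_id = pairId(cell),
                                      power = cr$table$power_mW[1]))
      if (config@normalizePower) map <- normalizeMap(map)
      aligned <- alignToSoma(map)
      cellMaps[[cellId(cell)]] <- aligned
      met <- suppressWarnings(regionMean(aligned, config@region$proximal))
      metricRows[[cellId(cell)]] <- data.frame(
        cell_id = cellId(cell), pair_id = pairId(cell),
        genotype = genotype(cell), region_mean = met)
    }
    responses <- do.call(rbind, c(tabs, make.row.names = FALSE))
    nExcl <- sum(responses$excluded | responses$classification == "direct")
    msg_info(quiet, "  %d spots measured, %d direct-excluded pixels",
             nrow(responses), nExcl)
    cellTab <- rbindList(metricRows)
    pt <- .pairAndTest(cellTab, "region_mean", config@alpha)
    pairs <- pt$pairs %||% .emptyDF(); tests <- pt$tests %||% .emptyDF()
    for (g in c("WT", "KO")) {
      gm <- cellMaps[vapply(cellMaps, function(m) m@meta$genotype, "") == g]
      if (length(gm))
        groupMaps[[g]] <- averageGroup(lapply(gm, interpolateHalf),
                                       minN = config@minN, label = g)
    }
  } else if (mode == "LED_bulk") {
    rows <- list()
    for (cell in cells) {
      ba <- bulkAmplitude(cell, window = config@window)
      cv <- if (length(ba$trial_amps) >= 3 && mean(ba$trial_amps) > 0)
        coefficientOfVariation(ba$trial_amps) else NA_real_
      rows[[cellId(cell)]] <- data.frame(
        cell_id = cellId(cell), pair_id = pairId(cell),
        genotype = genotype(cell), amplitude_pA = ba$amplitude_pA,
        norm_pA_mW = ba$norm_pA_mW, cv = cv, power_mW = ba$power_mW,
        n_sweeps = length(ba$trial_amps))
    }
    responses <- do.call(rbind, c(rows, make.row.names = FALSE))
    metrics <- c("amplitude_pA",
                 if (config@normalizePower) "norm_pA_mW", "cv")
    pt <- .pairAndTest(responses, metrics, config@alpha)
    pairs <- pt$pairs %||% .emptyDF(); tests <- pt$tests %||% .emptyDF()
  } else { # Sr2+
    rows <- list()
    for (cell in cells) {
      qs <- detectCellEvents(cell)
      events[[cellId(cell)]] <- qs
      er <- eventRates(qs)
      rows[[cellId(cell)]] <- data.frame(
        cell_id = cellId(cell), pair_id = pairId(cell),
        genotype = genotype(cell), spont_hz = er$spont_hz,
        evoked_hz = er$evoked_hz, spont_amp_pa = er$spont_amp_pa,
        evoked_amp_pa = er$evoked_amp_pa, n_sweeps = er$n_sweeps)
    }
    responses <- do.call(rbind, c(rows, make.row.names = FALSE))
    msg_info(quiet, "  %d events detected",
             sum(vapply(events, function(e) nrow(eventTable(e)), 1L)))
    pt <- .pairAndTest(responses,
                       c("spont_hz", "evoked_hz", "spont_amp_pa",
                         "evoked_amp_pa"), config@alpha)
    pairs <- pt$pairs %||% .emptyDF(); tests <- pt$tests %||% .emptyDF()
  }
  if (nrow(pairs)) {
    dropped <- sum(!is.finite(pairs$wt) | !is.finite(pairs$ko))
    if (dropped) msg_info(quiet, "  %d incomplete pair rows dropped", dropped)
  }
  cfgList <- configToList(config)
  manifest <- list(mode = mode, seed = config@seed,
                   package_version = as.character(packageVersion("optomap")),
                   config = cfgList, config_hash = .configHash(cfgList))
  res <- new("PipelineResults", responses = responses, cellMaps = cellMaps,
             groupMaps = groupMaps, pairs = pairs, tests = tests,
             events = events,
             manifest = c(manifest, list(truth_available = !is.null(truth))))
  attr(res, "truth") <- truth
  res
}

#' Ground truth attached to a simulated pipeline run
#'
#' @param results A [PipelineResults-class] from a simulated run.
#' @return The generator truth list, or NULL for datasets read from disk.
#' @export
pipelineTruth <- function(results) attr(results, "truth")
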