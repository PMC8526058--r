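#' @include AllClasses.R utils.R
NULL

.SCHEMA_VERSION <- "1.0"

# classed wrapper so malformed JSON surfaces as a parse error naming the file
.readJson <- function(path) {
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e) stopc("optomap_parse_error",
                                     "cannot parse %s: %s", path,
                                     conditionMessage(e)))
}

# S4 config -> plain named list (for JSON serialization / hashing)
configToList <- function(x) {
  out <- lapply(slotNames(x), function(s) slot(x, s))
  names(out) <- slotNames(x)
  if (!is.null(out$synth) && is(out$synth, "SynthConfig"))
    out$synth <- configToList(out$synth)
  out
}

# stable md5 of a serializable object via its canonical JSON
.configHash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

#' Write a dataset of cell recordings to disk
#'
#' One tabular trace file per cell (columns `sweep_id`, `sample_index`,
#' `current_pA`) plus a JSON sidecar with the sweep metadata and cell-level
#' fields (dt, soma, grid geometry, genotype, pair id, mode, seed), a
#' dataset-level `dataset.json`, and optionally the generator ground truth as
#' `ground_truth.json`.
#'
#' @param cells named list of [CellRecording-class]s (the `cells` element of
#'   a simulation result).
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list to store alongside.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(cells, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cells, cellId, "")
  mode <- if (length(cells)) mapMode(cells[[1]]) else NA_character_
  seed <- if (length(cells)) S4Vectors::metadata(cells[[1]])$seed else NA
  jsonlite::write_json(
    list(schema_version = .SCHEMA_VERSION, mode = mode, seed = seed,
         cells = as.list(unname(ids))),
    file.path(dir, "dataset.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  for (cell in cells) {
    cid <- cellId(cell)
    cur <- sweepCurrents(cell)
    n <- nrow(cur)
    long <- data.table::data.table(
      sweep_id = rep(colnames(cur), each = n),
      sample_index = rep.int(seq_len(n) - 1L, ncol(cur)),
      # %.17g guarantees the doubles round-trip exactly through the text
      current_pA = sprintf("%.17g", as.vector(cur)))
    data.table::fwrite(long, file.path(dir, sprintf("traces_%s.csv", cid)))
    md <- S4Vectors::metadata(cell)
    sidecar <- list(
      schema_version = .SCHEMA_VERSION, cell_id = cid,
      dt = md$dt, genotype = md$genotype, pair_id = md$pair_id,
      mode = md$mode, seed = md$seed,
      soma = if (is.null(md$soma)) NULL else as.numeric(md$soma),
      grid = md$grid,
      sweeps = sweepInfo(cell))
    jsonlite::write_json(sidecar, file.path(dir, sprintf("cell_%s.json", cid)),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  }
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  invisible(dir)
}

#' Read a dataset of cell recordings
#'
#' Reads what [writeDataset()] wrote, validating the schema: numeric fields
#' round-trip exactly and metadata verbatim. Malformed files raise classed
#' errors (`optomap_version_error`, `optomap_schema_error`,
#' `optomap_parse_error`) naming the offending file (and sweep where
#' applicable).
#'
#' @param dir dataset directory.
#' @return named list of [CellRecording-class]s (empty list for an empty but
#'   valid dataset).
#' @export
readDataset <- function(dir) {
  dsFile <- file.path(dir, "dataset.json")
  assertThat(file.exists(dsFile), "optomap_schema_error",
             "no dataset.json in '%s'", dir)
  ds <- .readJson(dsFile)
  assertThat(identical(ds$schema_version, .SCHEMA_VERSION),
             "optomap_version_error",
             "unknown schema version '%s' in %s (expected %s)",
             as.character(ds$schema_version %||% "<missing>"), dsFile,
             .SCHEMA_VERSION)
  cells <- list()
  for (cid in ds$cells) {
    scFile <- file.path(dir, sprintf("cell_%s.json", cid))
    trFile <- file.path(dir, sprintf("traces_%s.csv", cid))
    assertThat(file.exists(scFile), "optomap_schema_error",
               "missing sidecar %s", scFile)
    assertThat(file.exists(trFile), "optomap_schema_error",
               "missing trace file %s", trFile)
    sc <- .readJson(scFile)
    for (f in c("dt", "genotype", "mode", "sweeps"))
      assertThat(!is.null(sc[[f]]), "optomap_schema_error",
                 "sidecar %s lacks field '%s'", scFile, f)
    assertThat(is.numeric(sc$dt) && sc$dt > 0, "optomap_schema_error",
               "sidecar %s: dt must be a positive number", scFile)
    info <- as.data.frame(sc$sweeps)
    long <- data.table::fread(trFile, showProgress = FALSE)
    need <- c("sweep_id", "sample_index", "current_pA")
    assertThat(all(need %in% names(long)), "optomap_schema_error",
               "%s lacks column(s): %s", trFile,
               paste(setdiff(need, names(long)), collapse = ", "))
    if (!is.numeric(long$current_pA) || anyNA(long$current_pA)) {
      suppressWarnings(cur <- as.numeric(long$current_pA))
      badRow <- which(!is.finite(cur))[1]
      stopc("optomap_parse_error",
            "%s: non-numeric current_pA in sweep '%s' (row %d)",
            trFile, as.character(long$sweep_id[badRow]), badRow)
    }
    counts <- table(long$sweep_id)
    assertThat(length(unique(as.integer(counts))) == 1,
               "optomap_schema_error",
               "%s: sweeps differ in sample count", trFile)
    assertThat(setequal(names(counts), info$sweep_id),
               "optomap_schema_error",
               "%s: trace sweep ids do not match the sidecar", trFile)
    n <- as.integer(counts[1])
    long <- long[order(match(long$sweep_id, info$sweep_id),
                       long$sample_index), ]
    cur <- matrix(long$current_pA, nrow = n,
                  ncol = nrow(info))
    grid <- if (!is.null(sc$grid)) as.list(sc$grid) else NULL
    cells[[cid]] <- tryCatch(
      CellRecording(
        cur, info, dt = sc$dt, cellId = sc$cell_id, genotype = sc$genotype,
        pairId = sc$pair_id %||% NA_character_, mode = sc$mode,
        soma = if (is.null(sc$soma)) NULL else as.numeric(sc$soma),
        grid = grid,
        seed = if (is.null(sc$seed)) NA_integer_ else as.integer(sc$seed)),
      error = function(e) stopc("optomap_schema_error",
                                "invalid recording in %s: %s", scFile,
                                conditionMessage(e)))
  }
  cells
}

#' Read generator ground truth stored with a dataset
#'
#' @param dir dataset directory.
#' @return The ground-truth list, or NULL if none was stored.
#' @export
readGroundTruth <- function(dir) {
  f <- file.path(dir, "ground_truth.json")
  if (!file.exists(f)) return(NULL)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

# map -> CSV matrix + JSON header (NaN encodes masked pixels)
.writeMap <- function(values, header, stem) {
  m <- values
  m[is.na(m)] <- NaN
  data.table::fwrite(data.table::as.data.table(m),
                     paste0(stem, ".csv"), col.names = FALSE)
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

#' Write a pipeline result bundle to disk
#'
#' Emits the per-spot response table, per-pair metrics, the tidy statistics
#' table, group-map matrices (CSV plus JSON header; NaN encodes masked
#' pixels), per-cell event tables when present, and the machine-readable run
#' manifest. Output is deterministic: re-running the same seeded pipeline
#' and writing again gives byte-identical files.
#'
#' @param bundle A [PipelineResults-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeResults <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(bundle@responses))
    data.table::fwrite(bundle@responses, file.path(dir, "responses.csv"))
  if (nrow(bundle@pairs))
    data.table::fwrite(bundle@pairs, file.path(dir, "pairs.csv"))
  if (nrow(bundle@tests))
    data.table::fwrite(bundle@tests, file.path(dir, "tests.csv"))
  for (g in names(bundle@groupMaps)) {
    gm <- bundle@groupMaps[[g]]
    .writeMap(mapValues(gm),
              list(label = gm@label, frame = gm@frame,
                   pixel_size_um = gm@pixelSize, origin_um = gm@origin,
                   min_n = gm@minN, mask_encoding = "NaN = masked"),
              file.path(dir, sprintf("groupmap_%s", g)))
  }
  if (length(bundle@events)) {
    ev <- do.call(rbind, lapply(names(bundle@events), function(cid) {
      tab <- eventTable(bundle@events[[cid]])
      if (nrow(tab)) cbind(cell_id = cid, tab) else NULL
    }))
    if (!is.null(ev)) data.table::fwrite(ev, file.path(dir, "events.csv"))
  }
  jsonlite::write_json(bundle@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
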