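#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("sweepCurrents", "CellRecording", function(x)
  SummarizedExperiment::assay(x, "current"))
#' @rdname accessors
setMethod("sweepInfo", "CellRecording", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))
#' @rdname accessors
setMethod("dtMs", "CellRecording", function(x) S4Vectors::metadata(x)$dt)
#' @rdname accessors
setMethod("genotype", "CellRecording", function(x)
  S4Vectors::metadata(x)$genotype)
#' @rdname accessors
setMethod("pairId", "CellRecording", function(x)
  S4Vectors::metadata(x)$pair_id)
#' @rdname accessors
setMethod("cellId", "CellRecording", function(x)
  S4Vectors::metadata(x)$cell_id)
#' @rdname accessors
setMethod("mapMode", "CellRecording", function(x)
  S4Vectors::metadata(x)$mode)
#' @rdname accessors
setMethod("somaPosition", "CellRecording", function(x)
  S4Vectors::metadata(x)$soma)
#' @rdname accessors
setMethod("gridGeometry", "CellRecording", function(x)
  S4Vectors::metadata(x)$grid)

#' @rdname accessors
setMethod("amplitude", "EvokedResponse", function(x) x@amplitude)
#' @rdname accessors
setMethod("classification", "EvokedResponse", function(x) x@classification)
#' @rdname accessors
setMethod("onsetLatency", "EvokedResponse", function(x) x@onsetLatency)
#' @rdname accessors
setMethod("responseTrace", "EvokedResponse", function(x) x@trace)
#' @rdname accessors
setMethod("isExcluded", "EvokedResponse", function(x) x@excluded)
#' @rdname accessors
setMethod("dtMs", "EvokedResponse", function(x) x@dt)

#' @rdname accessors
setMethod("mapValues", "InputMap", function(x) x@values)
#' @rdname accessors
setMethod("mapMask", "InputMap", function(x) x@mask)
#' @rdname accessors
setMethod("mapFrame", "InputMap", function(x) x@frame)
#' @rdname accessors
setMethod("pixelSize", "InputMap", function(x) x@pixelSize)
#' @rdname accessors
setMethod("mapOrigin", "InputMap", function(x) x@origin)
#' @rdname accessors
setMethod("somaPosition", "InputMap", function(x) x@soma)

#' @rdname accessors
setMethod("mapValues", "GroupMap", function(x) x@values)
#' @rdname accessors
setMethod("mapFrame", "GroupMap", function(x) x@frame)
#' @rdname accessors
setMethod("pixelSize", "GroupMap", function(x) x@pixelSize)
#' @rdname accessors
setMethod("mapOrigin", "GroupMap", function(x) x@origin)
#' @rdname accessors
setMethod("pixelN", "GroupMap", function(x) x@n)

#' @rdname accessors
setMethod("eventTable", "QuantalEventSet", function(x) x@events)
#' @rdname accessors
setMethod("nSweeps", "QuantalEventSet", function(x) x@nSweeps)
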