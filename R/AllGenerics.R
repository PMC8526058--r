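#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small camelCase accessors for the package's S4 classes; user code should
#' use these rather than reaching into slots.
#'
#' @param x An optomap object.
#' @return The corresponding field.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sweepCurrents", function(x) standardGeneric("sweepCurrents"))
#' @rdname accessors
#' @export
setGeneric("sweepInfo", function(x) standardGeneric("sweepInfo"))
#' @rdname accessors
#' @export
setGeneric("dtMs", function(x) standardGeneric("dtMs"))
#' @rdname accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))
#' @rdname accessors
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))
#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("mapMode", function(x) standardGeneric("mapMode"))
#' @rdname accessors
#' @export
setGeneric("somaPosition", function(x) standardGeneric("somaPosition"))
#' @rdname accessors
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))
#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
#' @rdname accessors
#' @export
setGeneric("onsetLatency", function(x) standardGeneric("onsetLatency"))
#' @rdname accessors
#' @export
setGeneric("responseTrace", function(x) standardGeneric("responseTrace"))
#' @rdname accessors
#' @export
setGeneric("isExcluded", function(x) standardGeneric("isExcluded"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))
#' @rdname accessors
#' @export
setGeneric("mapFrame", function(x) standardGeneric("mapFrame"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))
#' @rdname accessors
#' @export
setGeneric("pixelN", function(x) standardGeneric("pixelN"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("nSweeps", function(x) standardGeneric("nSweeps"))

#' Align an input map to the soma
#'
#' Translates map coordinates so the soma sits at the origin of the aligned
#' frame (x = 0 lateral, y = 0 vertical, pia-ward positive); pixel values are
#' unchanged.
#'
#' @param map An [InputMap-class] with a known soma position.
#' @return An [InputMap-class] in the `soma_aligned` frame.
#' @export
setGeneric("alignToSoma", function(map) standardGeneric("alignToSoma"))

#' Align an input map to the home barrel
#'
#' Applies the per-axis affine alignment used for LSPS maps: scale by
#' (reference width / home width, reference height / home height) about the
#' home-barrel center, then translate the barrel center to the origin;
#' medial-lateral orientation is preserved. Values are resampled bilinearly
#' with conservative mask propagation.
#'
#' @param map An [InputMap-class] in the slice frame.
#' @param homeBarrel,referenceBarrel rectangles c(xmin, xmax, ymin, ymax), um.
#' @return An [InputMap-class] in the `barrel_aligned` frame.
#' @export
setGeneric("alignToBarrel", function(map, homeBarrel, referenceBarrel)
  standardGeneric("alignToBarrel"))

#' Halve map pixel size by bilinear interpolation
#'
#' Resamples the map onto a grid whose pixel dimensions are halved (50 um
#' pixels become 25 um), as used for genotype-averaged color maps. Bilinear
#' interpolation reproduces affine fields exactly; an output pixel that
#' touches any masked input pixel is itself masked (conservative mask
#' propagation: interpolation never fabricates values where direct responses
#' were deleted).
#'
#' @param map An [InputMap-class] on a regular grid.
#' @return An [InputMap-class] with halved pixel size.
#' @export
setGeneric("interpolateHalf", function(map) standardGeneric("interpolateHalf"))

#' Vertical profile of input strength
#'
#' Averages valid pixels within each horizontal row of a soma-aligned map and
#' returns the profile against vertical distance from the soma (pia-ward
#' positive).
#'
#' @param map A soma-aligned [InputMap-class] or [GroupMap-class].
#' @return data.frame with columns `y_um`, `mean`, `n`; rows with no valid
#'   pixels have `mean` NA.
#' @export
setGeneric("verticalProfile", function(map) standardGeneric("verticalProfile"))

#' Mean input strength within a region
#'
#' Mean of valid pixel values whose centers fall inside a rectangular region
#' of the aligned frame.
#'
#' @param map An [InputMap-class] or [GroupMap-class].
#' @param region c(xmin, xmax, ymin, ymax) in um (aligned-frame coordinates).
#' @param normalizePower divide by the stimulation power stored in the map
#'   metadata.
#' @return Mean input strength, or NA (with a warning) when the region
#'   contains no valid pixel.
#' @export
setGeneric("regionMean", function(map, region, normalizePower = FALSE)
  standardGeneric("regionMean"))
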