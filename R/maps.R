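#' @include AllClasses.R AllGenerics.R utils.R
NULL

# pixel-center coordinates of a map (x over columns, y over rows; y decreases
# down rows, pia-ward positive)
.mapCoords <- function(origin, pixelSize, nr, nc) {
  list(x = origin[1] + (seq_len(nc) - 1) * pixelSize[1],
       y = origin[2] - (seq_len(nr) - 1) * pixelSize[2])
}

#' Assemble a per-cell input map from spot responses
#'
#' Places each measured spot amplitude at its grid pixel. Spots whose
#' response was classified pure direct (or flagged excluded, e.g. after a
#' failed subtraction fit) are masked `direct_excluded` and carry no value;
#' grid pixels never stimulated are masked `unsampled`.
#'
#' @param responses data.frame with columns `grid_row`, `grid_col`,
#'   `amplitude_pA`, `classification`, `excluded` (the `table` element of
#'   [cellResponses()]).
#' @param grid grid geometry list (`rows`, `cols`, `x_spacing`, `y_spacing`,
#'   `x0`, `y0`).
#' @param soma (x, y) soma position, um, slice frame (optional).
#' @param meta metadata list (cell id, genotype, pair id, power).
#' @return An [InputMap-class] in the slice frame.
#' @export
buildCellMap <- function(responses, grid, soma = c(NA_real_, NA_real_),
                         meta = list()) {
  assertThat(all(c("grid_row", "grid_col", "amplitude_pA") %in%
                   names(responses)), "optomap_invalid_input",
             "responses must have grid_row, grid_col, amplitude_pA")
  assertThat(!anyDuplicated(responses[, c("grid_row", "grid_col")]),
             "optomap_inconsistent_input",
             "duplicate grid indices in response table")
  assertThat(all(responses$grid_row >= 1 & responses$grid_row <= grid$rows &
                   responses$grid_col >= 1 & responses$grid_col <= grid$cols),
             "optomap_inconsistent_input", "grid index outside the grid")
  vals <- matrix(NA_real_, grid$rows, grid$cols)
  mask <- matrix("unsampled", grid$rows, grid$cols)
  idx <- cbind(responses$grid_row, responses$grid_col)
  excl <- (if ("excluded" %in% names(responses)) responses$excluded else FALSE) |
    (if ("classification" %in% names(responses))
       responses$classification == "direct" else FALSE)
  mask[idx] <- ifelse(excl, "direct_excluded", "valid")
  vals[idx[!excl, , drop = FALSE]] <- responses$amplitude_pA[!excl]
  new("InputMap", values = vals, mask = mask,
      pixelSize = c(grid$x_spacing, grid$y_spacing), frame = "slice",
      origin = c(grid$x0, grid$y0), soma = as.numeric(soma), meta = meta)
}

#' Power-normalize an input map
#'
#' Divides valid pixel values by the stimulation power so maps from cells
#' recorded at different powers are comparable (pA/mW).
#'
#' @param map An [InputMap-class].
#' @param power power in mW; defaults to `meta$power` of the map.
#' @return The normalized [InputMap-class] (`meta$normalized = TRUE`).
#' @export
normalizeMap <- function(map, power = NULL) {
  if (is.null(power)) power <- map@meta$power
  assertThat(isScalarNum(power) && power > 0, "optomap_invalid_input",
             "power must be a positive scalar")
  map@values <- map@values / power
  map@meta$normalized <- TRUE
  map
}

#' @rdname alignToSoma
setMethod("alignToSoma", "InputMap", function(map) {
  assertThat(all(is.finite(map@soma)), "optomap_invalid_input",
             "soma position unknown; cannot align")
  map@origin <- map@origin - map@soma
  map@soma <- c(0, 0)
  map@frame <- "soma_aligned"
  map
})

# bilinear sample of (values, mask) at fractional grid position (fr, fc);
# conservative: any masked pixel with nonzero weight masks the sample
.bilinearAt <- function(values, mask, fr, fc) {
  nr <- nrow(values); nc <- ncol(values)
  if (fr < 1 - 1e-9 || fr > nr + 1e-9 || fc < 1 - 1e-9 || fc > nc + 1e-9)
    return(list(value = NA_real_, mask = "unsampled"))
  fr <- min(max(fr, 1), nr); fc <- min(max(fc, 1), nc)
  r0 <- floor(fr); r1 <- min(r0 + 1, nr)
  c0 <- floor(fc); c1 <- min(c0 + 1, nc)
  wr <- fr - r0; wc <- fc - c0
  rr <- c(r0, r1, r0, r1); cc <- c(c0, c0, c1, c1)
  ww <- c((1 - wr) * (1 - wc), wr * (1 - wc), (1 - wr) * wc, wr * wc)
  use <- ww > 1e-12
  mk <- mask[cbind(rr[use], cc[use])]
  if (any(mk != "valid")) {
    lab <- if (any(mk == "direct_excluded")) "direct_excluded" else "unsampled"
    return(list(value = NA_real_, mask = lab))
  }
  list(value = sum(ww[use] * values[cbind(rr[use], cc[use])]), mask = "valid")
}

# resample a map onto explicit fractional source positions
.resampleMap <- function(map, frMat, fcMat) {
  nrOut <- nrow(frMat); ncOut <- ncol(frMat)
  vals <- matrix(NA_real_, nrOut, ncOut)
  msk <- matrix("unsampled", nrOut, ncOut)
  for (r in seq_len(nrOut)) {
    for (c in seq_len(ncOut)) {
      s <- .bilinearAt(map@values, map@mask, frMat[r, c], fcMat[r, c])
      vals[r, c] <- s$value
      msk[r, c] <- s$mask
    }
  }
  list(values = vals, mask = msk)
}

#' @rdname alignToBarrel
setMethod("alignToBarrel", "InputMap", function(map, homeBarrel,
                                                referenceBarrel) {
  hw <- homeBarrel[2] - homeBarrel[1]; hh <- homeBarrel[4] - homeBarrel[3]
  rw <- referenceBarrel[2] - referenceBarrel[1]
  rh <- referenceBarrel[4] - referenceBarrel[3]
  assertThat(hw > 0 && hh > 0 && rw > 0 && rh > 0, "optomap_invalid_input",
             "degenerate barrel rectangle")
  sx <- rw / hw; sy <- rh / hh
  cx <- mean(homeBarrel[1:2]); cy <- mean(homeBarrel[3:4])
  nr <- nrow(map@values); nc <- ncol(map@values)
  co <- .mapCoords(map@origin, map@pixelSize, nr, nc)
  # aligned-frame extent of the transformed map, sampled on the original
  # pixel pitch
  ux <- sort((range(co$x) - cx) * sx)
  uy <- sort((range(co$y) - cy) * sy)
  px <- map@pixelSize[1]; py <- map@pixelSize[2]
  ncOut <- as.integer(floor((ux[2] - ux[1]) / px + 1e-9)) + 1L
  nrOut <- as.integer(floor((uy[2] - uy[1]) / py + 1e-9)) + 1L
  xOut <- ux[1] + (seq_len(ncOut) - 1) * px
  yOut <- uy[2] - (seq_len(nrOut) - 1) * py
  # back-map aligned coordinates into fractional source-grid positions
  xSrc <- cx + xOut / sx
  ySrc <- cy + yOut / sy
  fc <- (xSrc - map@origin[1]) / px + 1
  fr <- (map@origin[2] - ySrc) / py + 1
  rs <- .resampleMap(map, matrix(fr, nrOut, ncOut),
                     matrix(fc, nrOut, ncOut, byrow = TRUE))
  somaOut <- if (all(is.finite(map@soma)))
    c((map@soma[1] - cx) * sx, (map@soma[2] - cy) * sy)
  else map@soma
  new("InputMap", values = rs$values, mask = rs$mask,
      pixelSize = map@pixelSize, frame = "barrel_aligned",
      origin = c(xOut[1], yOut[1]), soma = somaOut, meta = map@meta)
})

#' @rdname interpolateHalf
setMethod("interpolateHalf", "InputMap", function(map) {
  nr <- nrow(map@values); nc <- ncol(map@values)
  nrOut <- 2L * nr - 1L; ncOut <- 2L * nc - 1L
  fr <- matrix(1 + (seq_len(nrOut) - 1) / 2, nrOut, ncOut)
  fc <- matrix(1 + (seq_len(ncOut) - 1) / 2, nrOut, ncOut, byrow = TRUE)
  rs <- .resampleMap(map, fr, fc)
  new("InputMap", values = rs$values, mask = rs$mask,
      pixelSize = map@pixelSize / 2, frame = map@frame,
      origin = map@origin, soma = map@soma, meta = map@meta)
})

#' Genotype-average aligned maps with a minimum-sampling mask
#'
#' Averages aligned per-cell maps pixel by pixel over their valid
#' contributions on the union grid, records the per-pixel cell count, and
#' masks (blacks out) pixels sampled by fewer than `minN` cells.
#'
#' @param maps list of [InputMap-class]s in the same frame, with equal pixel
#'   size and commensurate pixel centers.
#' @param minN minimum contributing cells per shown pixel.
#' @param label group label (e.g. genotype).
#' @return A [GroupMap-class].
#' @export
averageGroup <- function(maps, minN = 8, label = "") {
  assertThat(length(maps) >= 1, "optomap_incompatible_maps", "no maps given")
  ref <- maps[[1]]
  for (m in maps) {
    assertThat(m@frame == ref@frame, "optomap_incompatible_maps",
               "maps are in different frames (%s vs %s)", m@frame, ref@frame)
    assertThat(max(abs(m@pixelSize - ref@pixelSize)) < 1e-6,
               "optomap_incompatible_maps", "maps differ in pixel size")
    off <- (m@origin - ref@origin) / ref@pixelSize
    assertThat(max(abs(off - round(off))) < 1e-6, "optomap_incompatible_maps",
               "map pixel centers are not commensurate across cells")
  }
  px <- ref@pixelSize
  # global integer pixel indices relative to the reference origin
  colOff <- vapply(maps, function(m)
    as.integer(round((m@origin[1] - ref@origin[1]) / px[1])), 1L)
  rowOff <- vapply(maps, function(m)
    as.integer(round((ref@origin[2] - m@origin[2]) / px[2])), 1L)
  rowLo <- min(rowOff); colLo <- min(colOff)
  rowHi <- max(rowOff + vapply(maps, function(m) nrow(m@values), 1L) - 1L)
  colHi <- max(colOff + vapply(maps, function(m) ncol(m@values), 1L) - 1L)
  nr <- rowHi - rowLo + 1L; nc <- colHi - colLo + 1L
  sums <- matrix(0, nr, nc); n <- matrix(0L, nr, nc)
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    r0 <- rowOff[k] - rowLo; c0 <- colOff[k] - colLo
    valid <- m@mask == "valid"
    rr <- row(m@values)[valid] + r0
    cc <- col(m@values)[valid] + c0
    sums[cbind(rr, cc)] <- sums[cbind(rr, cc)] + m@values[valid]
    n[cbind(rr, cc)] <- n[cbind(rr, cc)] + 1L
  }
  vals <- ifelse(n >= minN & n > 0, sums / pmax(n, 1L), NA_real_)
  origin <- c(ref@origin[1] + colLo * px[1], ref@origin[2] - rowLo * px[2])
  new("GroupMap", values = vals, n = n, minN = minN, label = label,
      pixelSize = px, frame = ref@frame, origin = origin)
}

.verticalProfileImpl <- function(values, mask, origin, pixelSize, frame) {
  assertThat(frame == "soma_aligned", "optomap_invalid_frame",
             "vertical profiling needs a soma-aligned map (frame is '%s')",
             frame)
  nr <- nrow(values)
  y <- origin[2] - (seq_len(nr) - 1) * pixelSize[2]
  mean_ <- n_ <- numeric(nr)
  for (r in seq_len(nr)) {
    ok <- mask[r, ] == "valid"
    n_[r] <- sum(ok)
    mean_[r] <- if (n_[r]) mean(values[r, ok]) else NA_real_
  }
  data.frame(y_um = y, mean = mean_, n = as.integer(n_))
}

#' @rdname verticalProfile
setMethod("verticalProfile", "InputMap", function(map)
  .verticalProfileImpl(map@values, map@mask, map@origin, map@pixelSize,
                       map@frame))

#' @rdname verticalProfile
setMethod("verticalProfile", "GroupMap", function(map)
  .verticalProfileImpl(map@values,
                       ifelse(is.na(map@values), "unsampled", "valid"),
                       map@origin, map@pixelSize, map@frame))

.regionMeanImpl <- function(values, mask, origin, pixelSize, region) {
  assertThat(length(region) == 4 && region[2] >= region[1] &&
               region[4] >= region[3], "optomap_invalid_input",
             "region must be c(xmin, xmax, ymin, ymax)")
  co <- .mapCoords(origin, pixelSize, nrow(values), ncol(values))
  inX <- co$x >= region[1] - 1e-9 & co$x <= region[2] + 1e-9
  inY <- co$y >= region[3] - 1e-9 & co$y <= region[4] + 1e-9
  sel <- outer(inY, inX) & mask == "valid"
  if (!any(sel)) {
    warning("region contains no valid pixels; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  mean(values[sel])
}

#' @rdname regionMean
setMethod("regionMean", "InputMap", function(map, region,
                                             normalizePower = FALSE) {
  v <- .regionMeanImpl(map@values, map@mask, map@origin, map@pixelSize,
                       region)
  if (normalizePower) {
    assertThat(isScalarNum(map@meta$power %||% NA_real_) &&
                 (map@meta$power %||% 0) > 0, "optomap_invalid_input",
               "map metadata lacks a positive power")
    v <- v / map@meta$power
  }
  v
})

#' @rdname regionMean
setMethod("regionMean", "GroupMap", function(map, region,
                                             normalizePower = FALSE) {
  assertThat(!normalizePower, "optomap_invalid_input",
             "group maps carry no single power; normalize per cell instead")
  .regionMeanImpl(map@values,
                  ifelse(is.na(map@values), "unsampled", "valid"),
                  map@origin, map@pixelSize, region)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
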