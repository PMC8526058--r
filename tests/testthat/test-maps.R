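gridGeom <- function(rows = 3, cols = 3, xs = 50, ys = 50)
  list(rows = rows, cols = cols, x_spacing = xs, y_spacing = ys,
       x0 = 0, y0 = (rows - 1) * ys)

test_that("cell maps place amplitudes at grid pixels and mask exclusions", {
  resp <- expand.grid(grid_row = 1:3, grid_col = 1:3)
  resp$amplitude_pA <- as.numeric(1:9)
  resp$classification <- "synaptic"
  resp$excluded <- FALSE
  m <- buildCellMap(resp, gridGeom())
  expect_equal(mapValues(m), matrix(1:9, 3, 3))
  expect_true(all(mapMask(m) == "valid"))
  # one direct spot -> masked, others untouched
  resp2 <- resp
  resp2$classification[5] <- "direct"
  resp2$amplitude_pA[5] <- NA
  m2 <- buildCellMap(resp2, gridGeom())
  expect_equal(mapMask(m2)[2, 2], "direct_excluded")
  expect_true(is.na(mapValues(m2)[2, 2]))
  expect_equal(mapValues(m2)[-5], mapValues(m)[-5])
  # all-zero map is valid
  resp$amplitude_pA <- 0
  expect_true(all(mapValues(buildCellMap(resp, gridGeom())) == 0))
  # unsampled spots masked
  m3 <- buildCellMap(resp[1:5, ], gridGeom())
  expect_equal(sum(mapMask(m3) == "unsampled"), 4)
  # duplicates rejected
  expect_error(buildCellMap(resp[c(1, 1, 2), ], gridGeom()),
               class = "optomap_inconsistent_input")
})

test_that("soma alignment translates coordinates and is translation-invariant", {
  v <- matrix(runif(9), 3, 3)
  m <- mkMap(v, origin = c(0, 100), soma = c(50, 50))
  a <- alignToSoma(m)
  expect_equal(mapFrame(a), "soma_aligned")
  expect_equal(mapOrigin(a), c(-50, 50))
  expect_equal(mapValues(a), v)
  expect_equal(somaPosition(a), c(0, 0))
  # translating grid and soma jointly changes nothing after alignment
  m2 <- mkMap(v, origin = c(0, 100) + c(123, -77), soma = c(50, 50) + c(123, -77))
  a2 <- alignToSoma(m2)
  expect_equal(mapOrigin(a2), mapOrigin(a))
  expect_equal(mapValues(a2), mapValues(a))
  expect_error(alignToSoma(mkMap(v)), class = "optomap_invalid_input")
})

test_that("cells with identical soma-relative fields give identical aligned maps", {
  cfg <- synthConfig(seed = 13, n_pairs = 2, noise_sd = 0, direct_frac = 0,
                     p_release = 1, quantal_amp_cv = 0,
                     grid_rows = 5, grid_cols = 5, soma_row = 3, soma_col = 3)
  sim <- simulateGridExperiment(cfg, "sCRACM")
  maps <- lapply(sim$cells[c("P01_WT", "P02_WT")], function(cell) {
    tab <- cellResponses(cell)$table
    alignToSoma(buildCellMap(tab, gridGeometry(cell),
                             soma = somaPosition(cell)))
  })
  # same innervation field up to the pair scale: normalize and compare
  v1 <- mapValues(maps[[1]]) / max(mapValues(maps[[1]]))
  v2 <- mapValues(maps[[2]]) / max(mapValues(maps[[2]]))
  expect_equal(v1, v2, tolerance = 1e-6)
  expect_equal(mapOrigin(maps[[1]]), mapOrigin(maps[[2]]))
})

test_that("barrel alignment applies the per-axis scale about the barrel center", {
  v <- matrix(runif(16, 1, 2), 4, 4)
  m <- mkMap(v, px = c(50, 50), origin = c(0, 150))
  home <- c(25, 325, -25, 175)   # 300 x 200 um
  ref <- c(0, 250, 0, 200)       # 250 x 200 um -> sx = 0.8333, sy = 1
  b <- alignToBarrel(m, home, ref)
  expect_equal(mapFrame(b), "barrel_aligned")
  expect_equal(250 / 300, 0.83333, tolerance = 1e-4)
  # identity scale = pure translation; commensurate center -> exact values
  home2 <- c(25, 125, 25, 125)   # center (75, 75): not pixel-commensurate
  home3 <- c(0, 100, 0, 100)     # center (50, 50): on the pixel lattice
  b3 <- alignToBarrel(m, home3, home3 + 7)  # same size rectangle
  inBoth <- !is.na(mapValues(b3))
  expect_true(any(inBoth))
  expect_equal(mapValues(b3)[inBoth],
               v[cbind(row(v)[inBoth], col(v)[inBoth])], tolerance = 1e-12)
  # uniform maps stay uniform under resampling
  u <- mkMap(matrix(7, 4, 4), origin = c(0, 150))
  bu <- alignToBarrel(u, home, ref)
  expect_true(all(mapValues(bu)[!is.na(mapValues(bu))] == 7))
  expect_error(alignToBarrel(m, c(0, 0, 0, 100), ref),
               class = "optomap_invalid_input")
})

test_that("halving interpolation is exact on affine fields and halves pixel size", {
  u <- mkMap(matrix(3, 4, 4))
  iu <- interpolateHalf(u)
  expect_true(all(mapValues(iu) == 3))
  expect_equal(pixelSize(iu), c(25, 25))
  expect_equal(dim(mapValues(iu)), c(7, 7))
  # linear ramp in x reproduced exactly at half-pixel positions
  ramp <- outer(rep(1, 4), seq(0, 30, by = 10))
  ir <- interpolateHalf(mkMap(ramp))
  expect_equal(ir@values, outer(rep(1, 7), seq(0, 30, by = 5)))
  # conservative mask propagation: any masked contributor masks the output
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  msk <- matrix("valid", 3, 3); msk[2, 2] <- "direct_excluded"
  im <- interpolateHalf(mkMap(v, mask = msk))
  expect_equal(mapMask(im)[3, 3], "direct_excluded")
  expect_equal(mapMask(im)[2, 3], "direct_excluded")
  expect_equal(mapMask(im)[1, 1], "valid")
})

test_that("group averaging means valid pixels and applies the minimum-n mask", {
  mk <- function(val) mkMap(matrix(val, 2, 2), frame = "soma_aligned")
  g8 <- averageGroup(lapply(1:8, mk), minN = 8)
  expect_equal(mapValues(g8), matrix(4.5, 2, 2))
  expect_equal(pixelN(g8), matrix(8L, 2, 2))
  g7 <- averageGroup(lapply(1:7, mk), minN = 8)
  expect_true(all(is.na(mapValues(g7))))
  # all-masked map contributes zero counts
  blank <- mkMap(matrix(NA_real_, 2, 2),
                 mask = matrix("unsampled", 2, 2), frame = "soma_aligned")
  gb <- averageGroup(c(lapply(1:8, mk), list(blank)), minN = 8)
  expect_equal(pixelN(gb), matrix(8L, 2, 2))
  expect_equal(mapValues(gb), matrix(4.5, 2, 2))
  # incompatible frames rejected
  expect_error(averageGroup(list(mk(1), mkMap(matrix(1, 2, 2)))),
               class = "optomap_incompatible_maps")
})

test_that("group pixels equal the mean of their contributors on random fixtures", {
  set.seed(55)
  for (rep_ in 1:5) {
    maps <- lapply(1:6, function(i) {
      v <- matrix(runif(12, 0, 20), 3, 4)
      msk <- matrix(sample(c("valid", "unsampled"), 12, TRUE, c(0.8, 0.2)),
                    3, 4)
      v[msk != "valid"] <- NA
      # random commensurate offsets exercise the union grid
      off <- sample(-1:1, 2, TRUE)
      mkMap(v, mask = msk, frame = "soma_aligned",
            origin = c(off[1] * 50, 100 + off[2] * 50))
    })
    g <- averageGroup(maps, minN = 1)
    co <- list(x = mapOrigin(g)[1] + (seq_len(ncol(mapValues(g))) - 1) * 50,
               y = mapOrigin(g)[2] - (seq_len(nrow(mapValues(g))) - 1) * 50)
    for (r in seq_len(nrow(mapValues(g)))) for (c_ in seq_len(ncol(mapValues(g)))) {
      contrib <- unlist(lapply(maps, function(m) {
        xs <- mapOrigin(m)[1] + (seq_len(ncol(mapValues(m))) - 1) * 50
        ys <- mapOrigin(m)[2] - (seq_len(nrow(mapValues(m))) - 1) * 50
        ri <- match(round(co$y[r], 6), round(ys, 6))
        ci <- match(round(co$x[c_], 6), round(xs, 6))
        if (is.na(ri) || is.na(ci)) return(NULL)
        if (mapMask(m)[ri, ci] != "valid") return(NULL)
        mapValues(m)[ri, ci]
      }))
      if (length(contrib)) expect_equal(mapValues(g)[r, c_], mean(contrib))
      else expect_true(is.na(mapValues(g)[r, c_]))
    }
  }
})

test_that("adding a map never masks a previously shown group pixel", {
  set.seed(56)
  mk <- function() {
    v <- matrix(runif(9), 3, 3)
    mkMap(v, frame = "soma_aligned")
  }
  maps <- lapply(1:10, function(i) mk())
  g1 <- averageGroup(maps[1:8], minN = 8)
  g2 <- averageGroup(maps, minN = 8)
  was <- !is.na(mapValues(g1))
  expect_true(all(!is.na(mapValues(g2))[was]))
})

test_that("vertical profiles average rows against distance from soma", {
  m <- mkMap(matrix(c(1, 5, 3, 7), 2, 2), frame = "soma_aligned",
             origin = c(0, 50), soma = c(0, 0))
  pr <- verticalProfile(m)
  expect_equal(pr$mean, c(2, 6))
  expect_equal(pr$y_um, c(50, 0))
  flat <- verticalProfile(mkMap(matrix(4, 5, 5), frame = "soma_aligned"))
  expect_true(all(flat$mean == 4))
  expect_error(verticalProfile(mkMap(matrix(1, 2, 2), frame = "slice")),
               class = "optomap_invalid_frame")
})

test_that("the profile of a generator field peaks one pixel from the configured offset", {
  cfg <- synthConfig(seed = 17, n_pairs = 1, noise_sd = 0, direct_frac = 0,
                     field_offset = 100)
  sim <- simulateGridExperiment(cfg, "sCRACM")
  cell <- sim$cells[["P01_WT"]]
  tab <- cellResponses(cell)$table
  m <- alignToSoma(buildCellMap(tab, gridGeometry(cell),
                                soma = somaPosition(cell)))
  pr <- verticalProfile(m)
  expect_lte(abs(pr$y_um[which.max(pr$mean)] - 100), 50)
})

test_that("region means cover valid pixels only and flag empty regions", {
  u <- mkMap(matrix(10, 4, 4), frame = "soma_aligned", origin = c(0, 150))
  expect_equal(regionMean(u, c(-1000, 1000, -1000, 1000)), 10)
  expect_equal(regionMean(u, c(50, 50, 100, 100)), 10)  # single pixel
  expect_warning(v <- regionMean(u, c(500, 600, 500, 600)), "no valid")
  expect_true(is.na(v))
  # quadrature oracle on the generator's Gaussian innervation field
  cfg <- synthConfig(seed = 1)
  field <- function(x, y) 80 * exp(-((x - 0)^2 + (y - 100)^2) / (2 * 100^2))
  xs <- seq(-100, 100, by = 50); ys <- seq(-0, 150, by = 50)
  v <- outer(ys, xs, function(y, x) field(x, y))[rev(seq_along(ys)), , drop = FALSE]
  m <- mkMap(v, frame = "soma_aligned", origin = c(-100, 150))
  got <- regionMean(m, c(-100, 100, 0, 150))
  # fine-grid quadrature over pixel areas covered by the centers
  fx <- seq(-125, 125, by = 1); fy <- seq(-25, 175, by = 1)
  oracle <- mean(outer(fy, fx, function(y, x) field(x, y)))
  expect_equal(got, oracle, tolerance = 0.02 * oracle)
})

test_that("aligned-frame region means are invariant to rigid slice translation", {
  set.seed(77)
  v <- matrix(runif(16, 0, 5), 4, 4)
  r1 <- regionMean(alignToSoma(mkMap(v, origin = c(0, 150), soma = c(100, 50))),
                   c(-100, 100, -50, 100))
  r2 <- regionMean(alignToSoma(mkMap(v, origin = c(40, 130), soma = c(140, 30))),
                   c(-100, 100, -50, 100))
  expect_equal(r1, r2)
})
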