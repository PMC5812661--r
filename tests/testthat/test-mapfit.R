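test_that("background noise estimation inverts the Rayleigh mean", {
  # noiseless series -> 0
  ph <- buildPhantom(dim = c(24, 24), seed = 1)
  s <- simulateAcquisitions(ph, teMeta(), sigma = 0)
  expect_equal(estimateBackgroundNoise(s), 0)

  # all-constant background c -> c / sqrt(pi/2)
  sc <- voxelSeries(rep(3, 5), teMeta())
  sc@imageData <- array(7, c(10, 10, 1, 5))
  bg <- squarePolygon(1, 4, 1, 4)
  expect_equal(estimateBackgroundNoise(sc, bg), 7 / sqrt(pi / 2))

  # simulated sigma recovered from a ~500-pixel background ROI
  sigma <- 20
  img <- array(addRicianNoise(numeric(24 * 24 * 5), sigma, seed = 5),
               c(24, 24, 1, 5))
  sn <- new("AcquisitionSeries", imageData = img, meta = teMeta())
  est <- estimateBackgroundNoise(sn, squarePolygon(1, 10, 1, 10))
  expect_equal(est, sigma, tolerance = 0.1)

  # overlap with a foreground mask warns but proceeds
  fg <- array(FALSE, c(24, 24)); fg[1:5, 1:5] <- TRUE
  expect_warning(estimateBackgroundNoise(sn, squarePolygon(1, 10, 1, 10),
                                         foregroundMask = fg), "overlap")
  # polygon rasterizing to nothing errors
  off <- squarePolygon(100, 102, 100, 102)
  expect_error(estimateBackgroundNoise(sn, off), "zero voxels")
})

test_that("squared-subtraction bias correction clamps at zero", {
  expect_identical(correctRicianBias(5, 3), 4)
  expect_identical(correctRicianBias(5, 0), 5)
  expect_identical(correctRicianBias(2, 3), 0)
  expect_error(correctRicianBias(-1, 0), "S must")
})

test_that("bias correction reduces the low-SNR magnitude bias", {
  a <- 3; sigma <- 1  # SNR 3
  m <- addRicianNoise(rep(a, 5e4), sigma, seed = 21)
  noiseLevel <- sigma * sqrt(pi / 2)
  biasRaw <- abs(mean(m) - a)
  biasCor <- abs(mean(correctRicianBias(m, noiseLevel)) - a)
  expect_lt(biasCor, biasRaw)
})

test_that("T1 fit recovers a noiseless voxel to numerical precision", {
  truth <- c(S0 = 1000, INV = 1.95, T1star = 600)
  ti <- 90 + (0:59) * 144
  y <- abs(irTruefispSignal(truth[1], truth[2], truth[3], ti))
  fit <- fitT1Map(voxelSeries(y, tiMeta()))
  maps <- parameterMaps(fit)
  expect_equal(mapValues(maps$S0)[1], truth[["S0"]], tolerance = 1e-6)
  expect_equal(mapValues(maps$INV)[1], truth[["INV"]], tolerance = 1e-6)
  expect_equal(mapValues(maps$T1_star)[1], truth[["T1star"]],
               tolerance = 1e-6)
  expect_equal(mapValues(maps$T1)[1],
               as.numeric(t1FromApparent(600, 1.95, 60)), tolerance = 1e-6)
})

test_that("T1 fit masks degenerate voxels instead of raising", {
  y <- rep(0, 60)
  fit <- fitT1Map(voxelSeries(y, tiMeta()))
  expect_false(fitDiagnostics(fit)$converged[1])
  expect_true(is.na(mapValues(parameterMaps(fit)$T1)[1]))
  # too few samples for a 3-parameter model
  expect_error(fitT1Map(voxelSeries(c(1, 2, 3), tiMeta(c(90, 234, 378)))),
               "at least 4")
})

test_that("T2 fit recovers a noiseless voxel with a noise floor", {
  y <- multiEchoSignal(1000, 32, 40, c(11, 33, 55, 77, 99))
  fit <- fitT2Map(voxelSeries(y, teMeta()))
  maps <- parameterMaps(fit)
  expect_equal(mapValues(maps$S0)[1], 1000, tolerance = 1e-6)
  expect_equal(mapValues(maps$T2)[1], 32, tolerance = 1e-6)
  expect_equal(mapValues(maps$N)[1], 40, tolerance = 1e-4)
})

test_that("log-linear initialization makes the clean T2 fit immediate", {
  y <- multiEchoSignal(800, 45, 0, c(11, 33, 55, 77, 99))
  fit <- fitT2Map(voxelSeries(y, teMeta()))
  expect_true(fitDiagnostics(fit)$converged[1])
  expect_lte(fitDiagnostics(fit)$iterations[1], 10)
  expect_equal(mapValues(parameterMaps(fit)$T2)[1], 45, tolerance = 1e-6)
  expect_error(fitT2Map(voxelSeries(1:3, teMeta(c(11, 33, 55)))), "at least 4")
})

test_that("ADC map is the exact inverse of the diffusion forward model", {
  s0 <- matrix(runif(100, 200, 1500), 10)
  adcTrue <- matrix(runif(100, 0.4e-3, 2.5e-3), 10)
  sb <- dwiSignal(s0, adcTrue, 800)
  map <- computeAdcMap(s0, sb, 800)
  expect_equal(mapValues(map), adcTrue, tolerance = 1e-12)
  # identity and 1/b checks
  expect_equal(mapValues(computeAdcMap(s0, s0, 800))[1, 1], 0)
  m <- computeAdcMap(matrix(exp(1)), matrix(1), 800)
  expect_equal(mapValues(m)[1, 1], 1.25e-3, tolerance = 1e-12)
  # liver baseline value round trip
  sb2 <- dwiSignal(1000, 1.54e-3, 800)
  expect_equal(mapValues(computeAdcMap(matrix(1000), matrix(sb2), 800))[1, 1],
               1.54e-3, tolerance = 1e-12)
})

test_that("ADC map masks non-physical voxels and rejects shape mismatch", {
  b0 <- matrix(c(100, 0, 50, 100), 2)
  bb <- matrix(c(50, 10, -1, 120), 2)   # ok, b0<=0, S(b)<0, S(b)>S(b0)
  map <- computeAdcMap(b0, bb, 800)
  expect_identical(as.vector(mapMask(map)), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(is.na(mapValues(map)[!mapMask(map)])))
  expect_error(computeAdcMap(matrix(1, 2, 2), matrix(1, 3, 3), 800),
               "identical shapes")
})

test_that("MTR map reports percent and masks out-of-range voxels", {
  m0 <- matrix(c(100, 100, 0, 100), 2)
  ms <- matrix(c(34, 100, 50, 150), 2)  # 66%, 0%, invalid M0, -50%
  map <- computeMtrMap(m0, ms)
  v <- mapValues(map)
  expect_equal(v[1, 1], 66)
  expect_equal(v[2, 1], 0)
  expect_true(is.na(v[1, 2]))   # M0 <= 0
  expect_true(is.na(v[2, 2]))   # below -10 percent gate
  expect_identical(mapUnits(map), "percent")
  # phantom-typical value round trip
  pr <- mtSignalPair(1000, 0.662)
  mm <- computeMtrMap(matrix(pr$off), matrix(pr$on))
  expect_equal(mapValues(mm)[1, 1], 66.2, tolerance = 1e-12)
})

test_that("masked voxels never leak NaN into maps and diagnostics agree", {
  # a mix of fittable and degenerate voxels
  ti <- 90 + (0:59) * 144
  good <- abs(irTruefispSignal(1000, 1.95, 600, ti))
  img <- array(0, c(2, 1, 1, 60))
  img[1, 1, 1, ] <- good
  s <- new("AcquisitionSeries", imageData = img, meta = tiMeta())
  fit <- fitT1Map(s)
  for (m in parameterMaps(fit)) {
    expect_true(all(is.finite(mapValues(m)[mapMask(m)])))
    expect_true(all(is.na(mapValues(m)[!mapMask(m)])))
    # every non-converged voxel is masked in every derived map
    expect_true(all(!mapMask(m)[!fitDiagnostics(fit)$converged]))
  }
})
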