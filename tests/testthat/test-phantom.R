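test_that("phantom geometry is deterministic and volume-exact", {
  expect_error(buildPhantom(liverAxes = c(0, 0)), "degenerate")
  expect_error(buildPhantom(targetVolume = 0), "degenerate")

  p1 <- buildPhantom(dim = c(28, 28), seed = 5)
  p2 <- buildPhantom(dim = c(28, 28), seed = 5)
  expect_identical(phantomLabels(p1), phantomLabels(p2))
  p3 <- buildPhantom(dim = c(28, 28), seed = 6)
  expect_false(identical(phantomLabels(p1), phantomLabels(p3)))

  # voxel count x voxel volume matches the requested volume within one voxel
  vox <- c(0.5, 0.5); thk <- 1.0
  voxVol <- prod(vox) * thk
  ph <- buildPhantom(dim = c(40, 40, 18), voxelSize = vox,
                     sliceThickness = thk, targetVolume = 557.3,
                     nVessels = 0L)
  measured <- sum(liverMask(ph)) * voxVol
  expect_lte(abs(measured - 557.3), voxVol)
})

test_that("default T1 protocol has 60 inversion times starting 90, 234", {
  meta <- protocolMeta("ir_truefisp")
  ti <- variableValues(meta)
  expect_length(ti, 60)
  expect_equal(ti[1], 90)
  expect_equal(ti[2], 234)
  expect_true(all(diff(ti) == 144))
  expect_equal(variableValues(protocolMeta("multi_echo")),
               c(11, 33, 55, 77, 99))
  expect_equal(variableValues(protocolMeta("dwi")), c(0, 800))
})

test_that("noiseless simulation equals the forward model exactly", {
  tis <- tissueTruth()
  ph <- buildPhantom(dim = c(3, 3), liverAxes = c(5, 5), nVessels = 0L)
  meta <- teMeta()
  s <- simulateAcquisitions(ph, meta, sigma = 0)
  expected <- multiEchoSignal(tis$S0, tis$T2, tis$N, variableValues(meta))
  expect_equal(as.vector(s@imageData[2, 2, 1, ]), expected)
  # determinism of the noisy path
  a <- simulateAcquisitions(ph, meta, sigma = 15, seed = 3)
  b <- simulateAcquisitions(ph, meta, sigma = 15, seed = 3)
  expect_identical(imageData(a), imageData(b))
})

test_that("noiseless acquisitions round-trip through the fitters", {
  ph <- buildPhantom(dim = c(20, 20), seed = 2)
  mask <- liverMask(ph)
  for (ck in c("ir_truefisp", "multi_echo", "dwi", "mt_flash")) {
    s <- simulateAcquisitions(ph, protocolMeta(ck), sigma = 0)
    fit <- fitParameterMaps(s, mask = mask)
    p <- c(ir_truefisp = "T1", multi_echo = "T2", dwi = "ADC",
           mt_flash = "MTR")[[ck]]
    mp <- if (is(fit, "MapFitResult")) parameterMaps(fit)[[p]] else fit
    gt <- groundTruthMap(ph, p)
    rel <- abs(mapValues(mp) - mapValues(gt)) / abs(mapValues(gt))
    expect_true(all(rel[mapMask(mp)] <= 1e-6),
                info = paste("contrast", ck))
    expect_true(all(mapMask(mp)[mask]), info = paste("contrast", ck))
  }
})

test_that("cohort simulation honours the censoring structure exactly", {
  co <- simulateCohort(seed = 3)
  tab <- co$table
  ref <- referenceGroupValues()
  # generated (group, day, parameter) cells match the reference cells
  gen <- unique(tab[, c("group", "day", "parameter")])
  expected <- unique(ref[, c("group", "day", "parameter")])
  expect_identical(
    nrow(merge(gen, expected)), nrow(expected))
  expect_identical(nrow(gen), nrow(expected))
  # PLF truncated after day 3
  expect_identical(sort(unique(tab$day[tab$group == "PLF"])), c(0, 1, 2, 3))
  # exactly one ePH animal lacks T2 on days 5 and 7
  t2 <- tab[tab$parameter == "T2" & tab$group == "ePH", ]
  perAnimal <- table(t2$animal_id)
  expect_identical(sum(perAnimal == 4L), 1L)
  expect_identical(sum(perAnimal == 6L), 6L)
  # one record per (animal, day, parameter)
  expect_false(any(duplicated(tab[, c("animal_id", "day", "parameter")])))
})

test_that("cohort draws collapse onto group means at zero SD", {
  co <- simulateCohort(seed = 8, sdScale = 0)
  s <- groupSummary(co$table)
  ref <- referenceGroupValues()
  m <- merge(s, ref, by = c("group", "day", "parameter"))
  expect_equal(m$mean.x, m$mean.y)
  expect_true(all(m$sd.x == 0))
})

test_that("cohort group means converge by the law of large numbers", {
  spec <- cohortSpec(groupSizes = c(cPH = 10000L, ePH = 1L, PLF = 1L,
                                    SHAM = 1L),
                     values = referenceGroupValues(), t2DropoutEph = 0L)
  co <- simulateCohort(spec, seed = 17)
  d0 <- co$table[co$table$group == "cPH" & co$table$day == 0 &
                   co$table$parameter == "T1", ]
  expect_equal(mean(d0$value), 997.0, tolerance = 3 / 997)
})

test_that("cohort tables are bit-identical under a fixed seed", {
  a <- simulateCohort(seed = 123)
  b <- simulateCohort(seed = 123)
  expect_identical(a$table, b$table)
})
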