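test_that("noiseless homogeneous phantom has exactly baseline intensity in the cord", {
  ph <- generatePhantom(smallSpec(noiseSigma = 0, globalScale = 1))
  cord <- gridValues(ph$volume)[gridValues(ph$mask) == 1]
  expect_true(all(cord == 250))
  # CSF sheath and background surround the cord with their own intensities
  outside <- gridValues(ph$volume)[gridValues(ph$mask) == 0]
  expect_setequal(unique(outside), c(60, 420))
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- smallSpec(noiseSigma = 20, seed = 42,
                    lesions = list(LesionSpec(33, sharpness = 0.3)))
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(gridValues(a$volume), gridValues(b$volume))
  expect_identical(gridValues(a$mask), gridValues(b$mask))
})

test_that("phantom generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  generatePhantom(smallSpec(noiseSigma = 10, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("lesion contribution matches brute-force evaluation of the analytic field", {
  les <- LesionSpec(44, axialSigma = 3, amplitude = 0.5, sharpness = 1,
                    radius = 2)
  spec <- smallSpec(noiseSigma = 0, lesions = list(les))
  ph <- generatePhantom(spec)
  v <- gridValues(ph$volume); m <- gridValues(ph$mask)
  sp <- voxelSpacing(ph$volume); d <- dim(v)

  # independent scalar-loop reconstruction of cord-voxel intensities
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  expected <- array(NA_real_, d)
  p <- 1 + 9 * 1
  for (k in seq_len(d[3])) {
    ax <- exp(-((k - 1) - 44)^2 / (2 * 3^2))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (m[i, j, k] == 1) {
        rl <- sqrt(((i - cx) * sp[1])^2 + ((j - cy) * sp[2])^2)
        expected[i, j, k] <- 250 + 0.5 * 250 * ax * exp(-(rl / 2)^(2 * p))
      }
    }
  }
  got <- v[m == 1]
  expect_equal(got, expected[!is.na(expected)], tolerance = 1e-12)

  # lesion-center slice mean exceeds a remote slice mean by the brute-force amount
  sm <- bruteSliceMeans(v, m)
  expect_gt(sm[45], sm[11])
  curve <- as.data.frame(extractSICurve(ph$volume, ph$mask))
  expect_equal(curve$mean_si_au[45] - curve$mean_si_au[11],
               sm[45] - sm[11], tolerance = 1e-12)
})

test_that("noiseless global_scale scales every cord voxel exactly; mask is invariant", {
  base <- generatePhantom(smallSpec(seed = 3))
  for (s in c(0.5, 3.7)) {
    scaled <- generatePhantom(smallSpec(seed = 3, globalScale = s))
    expect_equal(gridValues(scaled$volume), gridValues(base$volume) * s,
                 tolerance = 1e-13)
    expect_identical(gridValues(scaled$mask), gridValues(base$mask))
  }
  noisy <- generatePhantom(smallSpec(seed = 3, noiseSigma = 25))
  expect_identical(gridValues(noisy$mask), gridValues(base$mask))
})

test_that("invalid phantom specs are rejected with the violated field named", {
  expect_error(smallSpec(cordRadius = -1), "cordRadius", class = "specError")
  expect_error(smallSpec(cordRadius = 12), "in-plane", class = "specError")
  expect_error(smallSpec(noiseSigma = -2), "noiseSigma", class = "specError")
  expect_error(smallSpec(globalScale = 0), "globalScale", class = "specError")
  expect_error(
    smallSpec(landmarks = c(C2 = 6L, C3 = 17L, C4 = 28L, C5 = 39L,
                            C6 = 50L, C7 = 200L)),
    "inside the grid", class = "specError")
  expect_error(
    smallSpec(landmarks = c(C2 = 17L, C3 = 6L, C4 = 28L, C5 = 39L,
                            C6 = 50L, C7 = 61L)),
    "increasing", class = "specError")
})

test_that("classical segmenter recovers the noiseless phantom exactly", {
  ph <- generatePhantom(smallSpec(globalScale = 1.8))
  seg <- segmentPhantomClassical(ph$volume)
  expect_equal(diceCoefficient(seg, ph$mask), 1.0)
})

test_that("classical segmenter fails cleanly on an all-zero volume", {
  flat <- VolumeImage(array(0, c(32, 32, 40)))
  expect_error(segmentPhantomClassical(flat), class = "segmentationError")
})

test_that("central canal option brightens the cord center but keeps the mask", {
  on <- generatePhantom(smallSpec(centralCanal = TRUE))
  off <- generatePhantom(smallSpec())
  expect_identical(gridValues(on$mask), gridValues(off$mask))
  expect_gt(mean(gridValues(on$volume)[gridValues(on$mask) == 1]), 250)
})
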