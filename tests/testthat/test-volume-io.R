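test_that("DICOM series round-trips a volume bit-exactly", {
  set.seed(11)
  v <- volume(array(round(runif(16^3, -1000, 2000)), c(16, 16, 16)),
              spacing = c(0.7, 0.7, 1.0), origin = c(-10, -20, 5))
  dir <- withr::local_tempdir()
  write_dicom_series(v, dir)
  v2 <- read_volume(dir)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)
})

test_that("slice spacing is inferred from positions and gaps are rejected", {
  v <- volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
  dir <- withr::local_tempdir()
  files <- write_dicom_series(v, dir)
  expect_equal(read_volume(dir)$spacing[3], 1.0)
  # removing a middle slice breaks the inter-slice consistency
  file.remove(files[4])
  expect_error(read_volume(dir), "inconsistent slice spacing")
})

test_that("mixed series and non-axial orientations are rejected", {
  v <- volume(array(0, c(4, 8, 8)))
  dir <- withr::local_tempdir()
  write_dicom_series(v, dir)
  # second series written into the same directory
  v2 <- volume(array(0, c(4, 8, 8)), origin = c(0, 0, 100))
  dir2 <- withr::local_tempdir()
  f2 <- write_dicom_series(v2, dir2)
  file.copy(f2, file.path(dir, paste0("other_", basename(f2))))
  expect_error(read_volume(dir), "mixed series")
})

test_that("independent DICOM reader agrees with ours on a synthetic series", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  has_pydicom <- tryCatch(
    system2("python", c("-c", shQuote("import pydicom")), stdout = FALSE,
            stderr = FALSE) == 0,
    error = function(e) FALSE)
  skip_if_not(has_pydicom, "pydicom not importable")
  set.seed(3)
  v <- volume(array(round(runif(8 * 8 * 8, -1000, 1000)), c(8, 8, 8)))
  dir <- withr::local_tempdir()
  write_dicom_series(v, dir)
  out <- tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import pydicom, glob, numpy as np\n",
    "fs = sorted(glob.glob('%s/*.dcm'))\n",
    "sl = [pydicom.dcmread(f) for f in fs]\n",
    "sl.sort(key=lambda d: float(d.ImagePositionPatient[2]))\n",
    "a = np.stack([d.pixel_array * float(d.RescaleSlope) + ",
    "float(d.RescaleIntercept) for d in sl])\n",
    "np.savetxt('%s', a.reshape(len(sl), -1), fmt='%%.1f')\n"), dir, out)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  expect_equal(system2("python", sf), 0L)
  a <- as.matrix(read.table(out))
  for (s in 1:8) {
    ours <- as.numeric(t(v$voxels[s, , ]))
    expect_equal(unname(a[s, ]), ours)
  }
})

test_that("8-bit windowing maps endpoints, midpoint and clips", {
  v <- array(c(-1000, 500, 2000, 3000, -2000, 350), c(1, 2, 3))
  g <- to_grayscale8(v, c(-1000, 2000))
  expect_equal(as.numeric(g), c(0, 128, 255, 255, 0, 115))
  # midpoint: 127.5 rounds half-up to 128
  expect_equal(g[1, 2, 1], 128L)
  expect_error(to_grayscale8(v, c(100, 100)), "degenerate window")
})

test_that("8-bit conversion is monotone in intensity", {
  set.seed(5)
  x <- sort(runif(200, -1500, 2500))
  g <- to_grayscale8(array(x, c(1, 1, 200)), c(-200, 1200))
  expect_true(all(diff(as.numeric(g)) >= 0))
})

test_that("8-bit PNG slices round-trip", {
  set.seed(6)
  img <- matrix(sample(0:255, 24 * 16, TRUE), 24, 16)
  p <- withr::local_tempfile(fileext = ".png")
  write_gray8(img, p)
  expect_equal(read_gray8(p), img)
})

test_that("dataset split reproduces the 8:2 arithmetic and partitions", {
  s <- split_dataset(sprintf("c%03d", 1:518), 0.2, seed = 9)
  expect_length(s$train_ids, 415)
  expect_length(s$test_ids, 103)
  expect_error(split_dataset(c("a", "a", "b"), 0.2, 1), "duplicate")
  # determinism
  s2 <- split_dataset(sprintf("c%03d", 1:518), 0.2, seed = 9)
  expect_identical(s, s2)
  # partition property over a spread of sizes
  set.seed(10)
  for (n in c(2, 3, 7, 10, 33, 100, 518, 1000)) {
    ids <- sample(100000, n)
    sp <- split_dataset(ids, 0.2, seed = n)
    expect_setequal(c(sp$train_ids, sp$test_ids), ids)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_length(sp$test_ids, floor(0.2 * n))
  }
})

test_that("bone segmentation follows the >= threshold convention", {
  v <- volume(array(c(299, 300, 301, -1000), c(1, 2, 2)))
  m <- segment_bone(v, 300)
  expect_equal(as.integer(m$voxels), c(0L, 1L, 1L, 0L))
  expect_equal(sum(segment_bone(v, 1e6)$voxels), 0) # empty mask is legal
  u <- volume(array(300, c(2, 2, 2)))
  expect_true(all(segment_bone(u, 300)$voxels == 1L))
  # voxelwise oracle on the shared phantom
  ph <- test_phantom()
  expect_equal(sum(test_bone()$voxels), sum(ph$volume$voxels >= 300))
})
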