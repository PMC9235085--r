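test_that("defect specs validate their geometry", {
  expect_error(defect_spec("sphere", c(0, 0, 0), list(radius = -1), 1), "radius")
  expect_error(defect_spec("cuboid", c(0, 0, 0), list(lengths = c(1, 1)), 1))
  expect_error(defect_spec("semicylinder", c(0, 0, 0),
                           list(radius = 5, length = 10, axis = c(0, 0, 1),
                                flat_normal = c(0, 0, 1)), 2),
               "perpendicular")
  s <- defect_spec("semicylinder", c(0, 0, 0),
                   list(radius = 5, length = 10, axis = c(0, 0, 2),
                        flat_normal = c(3, 0, 0)), 2)
  expect_equal(sum(s$size$axis^2), 1)
})

test_that("sampled defect specs land on the requested subunit within bounds", {
  ph <- test_phantom()
  specs <- lapply(1:300, function(i)
    sample_defect_spec(ph, 2, c(10, 30), seed = i))
  sp <- ph$volume$spacing
  for (s in specs) {
    ai <- round(s$center / sp) + 1 # (x,y,z) -> (col,row,slice)
    expect_equal(ph$labels[ai[3], ai[2], ai[1]], 2L)
    sz <- switch(s$shape,
      sphere = s$size$radius * 2,
      cuboid = s$size$lengths,
      semicylinder = c(s$size$radius * 2, s$size$length))
    expect_true(all(sz >= 10 & sz <= 30))
  }
  expect_setequal(unique(vapply(specs, `[[`, "", "shape")),
                  c("sphere", "cuboid", "semicylinder"))
  # determinism
  expect_identical(sample_defect_spec(ph, 2, c(10, 30), seed = 1),
                   sample_defect_spec(ph, 2, c(10, 30), seed = 1))
  empty <- ph; empty$labels <- array(0L, dim(ph$labels))
  expect_error(sample_defect_spec(empty, 1, c(10, 30), 1), "empty")
})

test_that("carved voxel counts match brute-force membership oracles", {
  # solid bone block
  v <- volume(array(700, c(21, 21, 21)))
  b <- segment_bone(v, 300)
  # axis-aligned cuboid centered on a voxel center: odd edge counts
  spec <- defect_spec("cuboid", c(10, 10, 10), list(lengths = c(5, 7, 3)), 1)
  cd <- carve_defect(v, b, spec)
  # independent brute-force count over voxel centers
  cnt <- 0
  for (x in 0:20) for (y in 0:20) for (z in 0:20)
    if (abs(x - 10) <= 2.5 && abs(y - 10) <= 3.5 && abs(z - 10) <= 1.5)
      cnt <- cnt + 1
  expect_equal(sum(cd$mask), cnt)
  expect_equal(cnt, 5 * 7 * 3)
  # sphere radius 5
  spec2 <- defect_spec("sphere", c(10, 10, 10), list(radius = 5), 1)
  cd2 <- carve_defect(v, b, spec2)
  cnt2 <- 0
  for (x in 0:20) for (y in 0:20) for (z in 0:20)
    if ((x - 10)^2 + (y - 10)^2 + (z - 10)^2 <= 25) cnt2 <- cnt2 + 1
  expect_equal(sum(cd2$mask), cnt2)
})

test_that("carving is an identity outside the shape and restorable", {
  d <- test_defect()
  ph <- test_phantom()
  expect_gt(sum(d$mask), 0)
  # untouched outside the mask
  expect_identical(d$volume$voxels[d$mask == 0], ph$volume$voxels[d$mask == 0])
  # carved region is bone and filled with soft tissue
  expect_true(all(test_bone()$voxels[d$mask == 1] == 1L))
  expect_true(all(d$volume$voxels[d$mask == 1] == 40))
  # composition: restoring masked voxels reproduces the normal volume
  restored <- d$volume$voxels
  restored[d$mask == 1] <- ph$volume$voxels[d$mask == 1]
  expect_identical(restored, ph$volume$voxels)
})

test_that("tiny and out-of-grid defects behave per contract", {
  v <- volume(array(700, c(8, 8, 8)))
  b <- segment_bone(v, 300)
  # radius smaller than half a voxel, centered between voxel centers
  tiny <- defect_spec("sphere", c(3.5, 3.5, 3.5), list(radius = 0.4), 1)
  cd <- carve_defect(v, b, tiny)
  expect_equal(sum(cd$mask), 0)
  expect_identical(cd$volume$voxels, v$voxels)
  far <- defect_spec("sphere", c(100, 100, 100), list(radius = 2), 1)
  expect_error(carve_defect(v, b, far), "outside")
})

test_that("slice pairs cover exactly the mask-intersecting slices", {
  d <- test_defect()
  ph <- test_phantom()
  pairs <- test_pairs()
  slices <- which(apply(d$mask, 1, function(m) any(m != 0)))
  expect_length(pairs, length(slices))
  expect_equal(vapply(pairs, `[[`, 1L, "slice_index"), slices)
  for (p in pairs) {
    expect_true(all(p$defect[p$mask == 0] == p$truth[p$mask == 0]))
    expect_true(all(p$mask %in% c(0, 1)))
  }
  # empty mask -> empty list
  expect_length(make_slice_pairs(ph$volume, ph$volume,
                                 array(0L, dim(d$mask))), 0)
  expect_error(make_slice_pairs(ph$volume, ph$volume, array(0L, c(2, 2, 2))),
               "identical shape")
})

test_that("slice pairs resample to a configured resolution", {
  d <- test_defect()
  pairs <- make_slice_pairs(test_phantom()$volume, d$volume, d$mask,
                            resolution = 128)
  expect_equal(dim(pairs[[1]]$truth), c(128, 128))
  expect_true(all(pairs[[1]]$mask %in% c(0, 1)))
})

test_that("defect specs round-trip through JSON", {
  ph <- test_phantom()
  for (seed in 1:5) {
    s <- sample_defect_spec(ph, 4, c(10, 25), seed = seed)
    f <- withr::local_tempfile(fileext = ".json")
    write_defect_spec(s, f)
    s2 <- read_defect_spec(f)
    expect_equal(s2$shape, s$shape)
    expect_equal(s2$center, s$center)
    expect_equal(unlist(s2$size), unlist(s$size), tolerance = 1e-12)
    expect_equal(s2$subunit, s$subunit)
  }
})

test_that("phantoms write to disk with DICOM series and a JSON sidecar", {
  ph <- generate_head_phantom(head_phantom_config(grid = c(16, 24, 24)))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  v <- read_volume(file.path(dir, "volume"))
  expect_identical(v$voxels, ph$volume$voxels)
  lab <- read_volume(file.path(dir, "labels"))
  expect_identical(array(as.integer(lab$voxels), dim(lab$voxels)), ph$labels)
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$plane_x, ph$geometry$plane_x)
})

test_that("slice pairs export as PNG triplets with a manifest", {
  pairs <- test_pairs()[1:2]
  dir <- withr::local_tempdir()
  man <- write_slice_pairs(pairs, dir)
  expect_equal(nrow(man), 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  p1 <- pairs[[1]]
  back <- read_gray8(file.path(dir, sprintf("%s_s%04d_truth.png",
                                            p1$case_id, p1$slice_index)))
  expect_equal(back, p1$truth)
})
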