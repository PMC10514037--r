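test_that("NIfTI round trip preserves data and geometry", {
  set.seed(11)
  vol <- image_volume(array(rnorm(4 * 5 * 3), c(4, 5, 3)),
                      spacing = c(1.2, 0.8, 2.5),
                      origin = c(-10, 5, 2), modality = "PET")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, "nifti", modality = "PET")
  expect_lt(max(abs(back$data - vol$data)), 1e-6)
  expect_lt(max(abs(back$spacing - vol$spacing)), 1e-6)
  expect_lt(max(abs(back$origin - vol$origin)), 1e-6)
  expect_lt(max(abs(back$direction - vol$direction)), 1e-6)
})

test_that("synthetic DICOM series round trips, including rescale", {
  hu <- array(sample(-1000:2000, 6 * 5 * 3, replace = TRUE), c(6, 5, 3))
  vol <- image_volume(hu, spacing = c(0.98, 0.98, 3.27),
                      origin = c(-120, -100, 40), modality = "CT")
  dir <- tempfile()
  write_dicom_series(vol, dir)
  back <- read_volume(dir, "dicom-series")
  expect_identical(back$modality, "CT")
  expect_equal(back$data, vol$data)  # integer HU stored losslessly
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)

  # non-integer PET-like data goes through the rescale slope
  pet <- image_volume(array(runif(6 * 5 * 3, 0, 5000), c(6, 5, 3)),
                      spacing = c(5.47, 5.47, 3.27), modality = "PET")
  dir2 <- tempfile()
  write_dicom_series(pet, dir2)
  back2 <- read_volume(dir2, "dicom-series")
  expect_lt(max(abs(back2$data - pet$data)), 5000 / 60000)
})

test_that("non-uniform DICOM slice spacing is a hard error naming the slice", {
  vol <- image_volume(array(0L, c(4, 4, 4)), spacing = c(1, 1, 2),
                      modality = "CT")
  dir <- tempfile()
  write_dicom_series(vol, dir)
  # rewrite the last slice 2x further away
  bnctdose:::write_dicom_slice(file.path(dir, "slice_0004.dcm"),
                               vol$data[, , 4], vol$spacing,
                               c(0, 0, 10), vol$direction, "CT")
  expect_error(read_volume(dir, "dicom-series"),
               "slice_0004")
  expect_error(read_volume(tempfile(), "nifti"), "does not exist")
})

test_that("contour rasterization follows the voxel-center rule", {
  ref <- vol3(array(0, c(10, 10, 2)))
  # square [3.5, 5.5] x [3.5, 5.5] covers centers (4,4),(4,5),(5,4),(5,5)
  sq <- function(z) list(x = c(3.5, 5.5, 5.5, 3.5),
                         y = c(3.5, 3.5, 5.5, 5.5), z = z)
  roi <- rasterize_roi(list(sq(0), sq(1)), ref)
  expect_equal(apply(roi$mask, 3, sum), c(4, 4))
  expect_true(all(roi$mask[5:6, 5:6, ]))

  # full-volume rectangle -> everything inside
  big <- list(list(x = c(-1, 10, 10, -1), y = c(-1, -1, 10, 10), z = 0))
  expect_true(all(rasterize_roi(big, ref)$mask[, , 1]))

  expect_error(rasterize_roi(list(list(x = c(0, 1), y = c(0, 1), z = 0)),
                             ref), "fewer than 3")
  tiny <- list(list(x = c(3.1, 3.4, 3.4, 3.1), y = c(3.1, 3.1, 3.4, 3.4),
                    z = 0))
  expect_error(rasterize_roi(tiny, ref), "empty ROI")
})

test_that("rasterized circle matches the brute-force even-odd oracle", {
  ref <- vol3(array(0, c(30, 30, 1)))
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  cx <- 14.3; cy <- 15.2; r <- 10.15
  ct <- list(x = cx + r * cos(theta), y = cy + r * sin(theta), z = 0)
  roi <- rasterize_roi(list(ct), ref)
  centers <- expand.grid(x = 0:29, y = 0:29)
  oracle <- pip_oracle(centers$x, centers$y, ct$x, ct$y)
  expect_equal(as.vector(roi$mask[, , 1]), oracle)
  # and the count agrees with the analytic center-in-circle rule
  expect_equal(sum(roi$mask),
               sum((centers$x - cx)^2 + (centers$y - cy)^2 <= r^2))
})

test_that("rasterization agrees with the oracle on random convex polygons", {
  ref <- vol3(array(0, c(25, 25, 1)))
  set.seed(42)
  for (rep in 1:5) {
    th <- seq(0, 2 * pi, length.out = 41)[-41]
    a <- runif(1, 5, 11); b <- runif(1, 5, 11); rot <- runif(1, 0, pi)
    x0 <- runif(1, 10, 14); y0 <- runif(1, 10, 14)
    x <- x0 + a * cos(th) * cos(rot) - b * sin(th) * sin(rot)
    y <- y0 + a * cos(th) * sin(rot) + b * sin(th) * cos(rot)
    roi <- rasterize_roi(list(list(x = x, y = y, z = 0)), ref)
    centers <- expand.grid(x = 0:24, y = 0:24)
    expect_equal(as.vector(roi$mask[, , 1]),
                 pip_oracle(centers$x, centers$y, x, y))
  }
})

test_that("resampling is exact on its own grid, constants and affine fields", {
  set.seed(7)
  src <- vol3(array(rnorm(6 * 6 * 4), c(6, 6, 4)), modality = "PET")
  same <- resample_to(src, src)
  expect_identical(same$data, src$data)
  expect_identical(attr(same, "n_outside"), 0L)

  const <- vol3(array(3.5, c(4, 4, 4)), spacing = c(2, 2, 2))
  fine <- vol3(array(0, c(7, 7, 7)), spacing = c(1, 1, 1),
               origin = c(0, 0, 0))
  out <- resample_to(const, fine)
  expect_lt(max(abs(out$data - 3.5)), 1e-12)
  expect_identical(attr(out, "n_outside"), 0L)

  # linear ramp f(x) = x at 2 mm, resampled to 1 mm: exact at new centers
  ramp <- vol3(array(rep(seq(0, 10, by = 2), 9), c(6, 3, 3)),
               spacing = c(2, 1, 1))
  fine <- vol3(array(0, c(11, 3, 3)), spacing = c(1, 1, 1))
  out <- resample_to(ramp, fine)
  expect_equal(out$data[, 2, 2], 0:10, tolerance = 1e-12)

  # trilinear reproduces any affine field exactly inside the extent
  g <- expand.grid(i = 0:5, j = 0:5, k = 0:3)
  aff_vals <- 2 + 0.3 * g$i * 1.5 - 0.7 * g$j * 2 + 0.1 * g$k * 3
  src <- vol3(array(aff_vals, c(6, 6, 4)), spacing = c(1.5, 2, 3))
  ref <- vol3(array(0, c(8, 8, 5)), spacing = c(0.9, 1.1, 2.1),
              origin = c(0.2, 0.3, 0.1))
  out <- resample_to(src, ref)
  gi <- expand.grid(i = 0:7, j = 0:7, k = 0:4)
  phys_x <- 0.2 + 0.9 * gi$i; phys_y <- 0.3 + 1.1 * gi$j
  phys_z <- 0.1 + 2.1 * gi$k
  expected <- 2 + 0.3 * phys_x - 0.7 * phys_y + 0.1 * phys_z
  inside <- phys_x <= 7.5 & phys_y <= 10 & phys_z <= 9
  expect_lt(max(abs(out$data[inside] - expected[inside])), 1e-9)
  expect_true(all(out$data[!inside] == 0))
  expect_identical(attr(out, "n_outside"), sum(!inside))

  far <- vol3(array(0, c(3, 3, 3)), origin = c(1000, 1000, 1000))
  expect_error(resample_to(src, far), "do not overlap")
})
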