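test_that("voxel SUV follows the decay-corrected uptake formula", {
  pet <- vol3(array(1000, c(3, 3, 3)), modality = "PET")
  ctx <- suv_context(3.7e8, 70, acf = 2.0)
  suv <- compute_suv_map(pet, ctx)
  expect_equal(suv$data[1], 1000 * 2 * 70 / 3.7e8, tolerance = 1e-12)
  expect_identical(suv$modality, "SUV")

  # zero intensity -> zero SUV
  zero <- compute_suv_map(vol3(array(0, c(2, 2, 2)), modality = "PET"),
                          ctx)
  expect_true(all(zero$data == 0))

  # measurement one half-life before the scan: decay factor 1/2 in the
  # denominator doubles the SUV exactly
  ctx2 <- suv_context(3.7e8, 70, measurement_time = 109.771,
                      scan_time = 0, acf = 2.0)
  suv2 <- compute_suv_map(pet, ctx2)
  expect_equal(suv2$data, 2 * suv$data, tolerance = 1e-12)

  expect_error(suv_context(0, 70), "injected dose")
  expect_error(suv_context(3.7e8, -1), "body weight")
})

test_that("SUV map scales linearly in intensity and ACF, inversely in dose", {
  set.seed(3)
  base <- array(runif(27, 10, 100), c(3, 3, 3))
  suv_of <- function(int, acf, dose)
    compute_suv_map(vol3(int, modality = "PET"),
                    suv_context(dose, 70, acf = acf))$data
  s1 <- suv_of(base, 1, 3.7e8)
  expect_equal(suv_of(3 * base, 1, 3.7e8), 3 * s1, tolerance = 1e-12)
  expect_equal(suv_of(base, 2.5, 3.7e8), 2.5 * s1, tolerance = 1e-12)
  expect_equal(suv_of(base, 1, 2 * 3.7e8), s1 / 2, tolerance = 1e-12)
})

test_that("ROI mean SUV is the unweighted arithmetic mean", {
  ref <- vol3(array(0, c(5, 5, 4)))
  mask <- array(FALSE, c(5, 5, 4)); mask[2:4, 2:4, 2:3] <- TRUE
  roi <- roi_mask(mask, ref)

  suv <- vol3(array(2.5, c(5, 5, 4)), modality = "PET")
  expect_equal(suv_mean(suv, roi), 2.5)

  two <- array(0, c(5, 5, 4)); two[2, 2, 2] <- 1; two[3, 3, 3] <- 3
  m2 <- array(FALSE, c(5, 5, 4)); m2[2, 2, 2] <- m2[3, 3, 3] <- TRUE
  expect_equal(suv_mean(vol3(two), roi_mask(m2, ref)), 2.0)

  set.seed(9)
  rnd <- array(runif(100), c(5, 5, 4))
  s <- 0
  for (i in which(mask)) s <- s + rnd[i]  # brute-force summation oracle
  expect_equal(suv_mean(vol3(rnd), roi), s / sum(mask),
               tolerance = 1e-12)
  expect_error(roi_mask(array(FALSE, c(5, 5, 4)), ref), "empty ROI")
})

test_that("per-voxel TNR is consistent with the ROI-level definition", {
  ref <- vol3(array(0, c(6, 6, 4)))
  tmask <- array(FALSE, c(6, 6, 4)); tmask[2:4, 2:4, 2:3] <- TRUE
  nmask <- array(FALSE, c(6, 6, 4)); nmask[6, , ] <- TRUE
  tumor <- roi_mask(tmask, ref); normal <- roi_mask(nmask, ref)

  set.seed(21)
  suv_data <- array(runif(144, 0.5, 4), c(6, 6, 4))
  suv <- vol3(suv_data, modality = "PET")
  tnr <- compute_tnr_map(suv, tumor, normal)
  # mean of voxel TNRs equals SUV_mean,tumor / SUV_mean,normal
  expect_equal(tnr$summary[["mean"]],
               suv_mean(suv, tumor) / suv_mean(suv, normal),
               tolerance = 1e-12)
  expect_equal(mean(tnr$values), tnr$summary[["mean"]], tolerance = 1e-12)
  expect_true(all(tnr$values >= 0))

  # tumor SUV equal to the normal mean -> TNR exactly 1 everywhere
  flat <- suv_data
  flat[tmask] <- mean(suv_data[nmask])
  tnr1 <- compute_tnr_map(vol3(flat), tumor, normal)
  expect_equal(tnr1$values, rep(1, roi_size(tumor)), tolerance = 1e-12)

  zero <- vol3(array(0, c(6, 6, 4)))
  expect_error(compute_tnr_map(zero, tumor, normal), "baseline")
})

test_that("TNR histogram counts and cumulative curve are exact", {
  ref <- vol3(array(0, c(4, 1, 1)))
  roi <- roi_mask(array(TRUE, c(4, 1, 1)), ref)
  tnr <- tnr_map_from_values(c(1, 2, 3, 4), roi)

  h <- tnr_histogram(tnr, n_bins = 2)
  expect_equal(h$count, c(2, 2))
  expect_equal(h$cum_volume_fraction[1], 1.0)

  # uniform TNR: one occupied bin, cumulative curve a step from 1
  hu <- tnr_histogram(tnr_map_from_values(rep(2, 4), roi), n_bins = 5)
  expect_equal(sum(hu$count > 0), 1L)
  expect_equal(hu$cum_volume_fraction[1], 1.0)

  # 1000 random values against a direct recount oracle
  set.seed(4)
  v <- runif(1000, 0.8, 4.2)
  big_roi <- roi_mask(array(TRUE, c(10, 10, 10)),
                      vol3(array(0, c(10, 10, 10))))
  hb <- tnr_histogram(tnr_map_from_values(v, big_roi), n_bins = 17)
  expect_equal(sum(hb$count), 1000L)
  for (b in seq_len(nrow(hb))) {
    hi <- if (b == nrow(hb)) v <= hb$bin_high[b] + 1e-12
          else v < hb$bin_high[b]
    expect_equal(hb$count[b], sum(v >= hb$bin_low[b] & hi))
    expect_equal(hb$cum_volume_fraction[b], mean(v >= hb$bin_low[b]))
  }
  expect_true(all(diff(hb$cum_volume_fraction) <= 0))
})
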