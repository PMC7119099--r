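test_that("fat fraction reproduces the defining arithmetic exactly", {
  dims <- c(4, 6, 6)
  z <- function(v) volume_image(array(v, dims))
  expect_true(all(compute_fat_fraction(z(500), z(0))$data == 0))
  expect_true(all(compute_fat_fraction(z(123), z(123))$data == 500))
  # 100 units fat out of 1000 total = grey value 100 = 10.0% fat
  expect_true(all(compute_fat_fraction(z(900), z(100))$data == 100))
})

test_that("air voxels are zeroed and flagged instead of NaN", {
  w <- volume_image(array(c(0, 10, 0, 5, 0, 0, 1, 2), c(2, 2, 2)))
  f <- volume_image(array(c(0, 10, 0, 5, 0, 0, 3, 2), c(2, 2, 2)))
  ff <- compute_fat_fraction(w, f)
  expect_true(all(ff$data[w$data + f$data == 0] == 0))
  expect_identical(ff$valid, array(as.integer(w$data + f$data > 0), c(2, 2, 2)))
  expect_true(all(ff$data >= 0 & ff$data <= 1000))
})

test_that("fat fraction is invariant to a common intensity scale", {
  set.seed(5)
  w <- volume_image(array(runif(64, 1, 50), c(4, 4, 4)))
  f <- volume_image(array(runif(64, 1, 50), c(4, 4, 4)))
  a <- compute_fat_fraction(w, f)
  b <- compute_fat_fraction(volume_image(w$data * 7.3),
                            volume_image(f$data * 7.3))
  expect_identical(a$data, b$data)
})

test_that("fat fraction rejects mismatched grids and negative values", {
  w <- volume_image(array(1, c(4, 4, 4)))
  expect_error(compute_fat_fraction(w, volume_image(array(1, c(4, 4, 5)))),
               "grid")
  expect_error(compute_fat_fraction(w, volume_image(array(1, c(4, 4, 4)),
                                                    spacing = c(2, 1, 1))),
               "grid")
  f <- volume_image(array(1, c(4, 4, 4)))
  f$data[1] <- -1
  expect_error(compute_fat_fraction(w, f), "non-negative")
})

test_that("registering an image to itself recovers the identity", {
  p <- prepped_phantom(2L)
  reg <- register_rigid(p$corrected, p$hand, p$corrected,
                        registration_config(max_iter = 300L))
  expect_lt(max(abs(reg$transform$rotation)), 0.1)
  expect_lt(max(abs(reg$transform$translation)), 0.1)
  expect_true(reg$metric > 0)
})

test_that("VOI transfer with the identity transform is the identity", {
  p <- prepped_phantom(2L)
  m <- p$hand
  out <- transfer_voi(m, rigid_transform(), p$corrected)
  expect_identical(out$data, m$data)
})

test_that("a one-voxel translation shifts the mask by one voxel", {
  arr <- array(0L, c(4, 8, 8)); arr[2:3, 3:5, 3:5] <- 1L
  img <- volume_image(array(0, c(4, 8, 8)), spacing = c(1, 1, 3))
  m <- binary_mask(arr, reference = img)
  tf <- rigid_transform(translation = c(1, 0, 0))  # +1 voxel along x (col)
  out <- transfer_voi(m, tf, img)
  shifted <- array(0L, c(4, 8, 8)); shifted[2:3, 3:5, 4:6] <- 1L
  expect_identical(out$data, shifted)
})

test_that("transfer there-and-back loses little to resampling", {
  p <- prepped_phantom(2L)
  m <- p$hand
  tf <- rigid_transform(rotation = c(0, 0, 4), translation = c(2.3, -1.1, 0.8),
                        center = c(48, 48, 36))
  fwd <- transfer_voi(m, tf, p$corrected)
  back <- transfer_voi(fwd, invert_transform(tf), p$corrected)
  expect_gte(dice_coef(back$data, m$data), 0.95)
})

test_that("known phantom transform is recovered and the VOI transfers", {
  sp <- phantom_spec(seed = 13L,
                     dixon_transform = rigid_transform(rotation = c(0, 0, 5),
                                                       translation = c(4, 0, 0)))
  ph <- generate_hand_phantom(sp)
  bc <- correct_bias_field(ph$t1)
  hm <- extract_hand_mask(bc$corrected)
  ff <- compute_fat_fraction(ph$water, ph$fat)
  reg <- register_rigid(bc$corrected, hm, ff)
  idx <- which(hm$data == 1)
  pts <- voxel_coords(bc$corrected)[idx, , drop = FALSE]
  err <- apply_transform(reg$transform, pts) -
    apply_transform(ph$truth$transform, pts)
  err_vox <- sweep(abs(err), 2, bc$corrected$spacing, "/")
  expect_lt(max(colMeans(err_vox)), 0.5)
  Rr <- handquant:::rotation_matrix(reg$transform$rotation)
  Rt <- handquant:::rotation_matrix(ph$truth$transform$rotation)
  ang <- acos(pmin(1, (sum(diag(t(Rr) %*% Rt)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)

  voi <- binary_mask((ph$truth$labels_t1 ==
                        ph$truth$label_codes[["muscle"]]) * 1L,
                     reference = ph$t1)
  transferred <- transfer_voi(voi, reg$transform, ff)
  truth_d <- (ph$truth$labels_dixon ==
                ph$truth$label_codes[["muscle"]]) * 1L
  expect_gte(dice_coef(transferred$data, truth_d), 0.90)
})

test_that("mean fat fraction in the transferred VOI matches the construction", {
  sp <- phantom_spec(seed = 21L, noise_sd = 0)
  ph <- generate_hand_phantom(sp)
  ff <- compute_fat_fraction(ph$water, ph$fat)
  voi <- binary_mask((ph$truth$labels_t1 ==
                        ph$truth$label_codes[["muscle"]]) * 1L,
                     reference = ph$t1)
  transferred <- transfer_voi(voi, ph$truth$transform, ff)
  mean_ff <- mean(ff$data[transferred$data == 1])
  expect_lt(abs(mean_ff - 1000 * sp$fat_fractions[["muscle"]]), 5)
})
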