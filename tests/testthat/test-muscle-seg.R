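test_that("feature table has one finite row per hand voxel", {
  p <- prepped_phantom(2L)
  tab <- extract_voxel_features(p$corrected, p$hand)
  expect_equal(nrow(tab), sum(p$hand$data))
  expect_true(all(vapply(tab, function(x) all(is.finite(x)), logical(1))))
  expect_error(
    extract_voxel_features(p$corrected,
                           binary_mask(array(0L, dim(p$hand$data)),
                                       reference = p$corrected)),
    "empty")
})

test_that("local texture features vanish on a constant image", {
  img <- volume_image(array(5, c(6, 12, 12)))
  hand <- binary_mask(array(1L, c(6, 12, 12)), reference = img)
  tab <- extract_voxel_features(img, hand)
  expect_true(all(tab$sd_r1 == 0))
  expect_true(all(tab$sd_r2 == 0))
  expect_true(all(tab$grad_mag == 0))
})

test_that("local mean at radius 1 matches a brute-force neighbourhood average", {
  set.seed(42)
  arr <- array(runif(5 * 9 * 9), c(5, 9, 9))
  img <- volume_image(arr)
  hand <- binary_mask(array(1L, dim(arr)), reference = img)
  tab <- extract_voxel_features(img, hand,
                                feature_config(box_radii = 1L,
                                               smooth_sigmas = 1,
                                               use_distance = FALSE,
                                               use_slice_pos = FALSE))
  idx <- attr(tab, "voxel_index")
  # brute force for an interior voxel: in-plane 3x3 average on its slice
  probe <- which(arrayInd(idx, dim(arr))[, 2] == 5 &
                 arrayInd(idx, dim(arr))[, 3] == 5 &
                 arrayInd(idx, dim(arr))[, 1] == 3)[1]
  expected <- mean(arr[3, 4:6, 4:6])
  expect_equal(tab$mean_r1[probe], expected, tolerance = 1e-12)
})

test_that("classifier separates well-separated clusters and is deterministic", {
  set.seed(7)
  n <- 400
  feats <- data.frame(intensity = c(rnorm(n, 0), rnorm(n, 10)),
                      grad_mag = c(rnorm(n, 5), rnorm(n, -5)))
  labels <- rep(c("background", "muscle"), each = n)
  attr(feats, "fingerprint") <- "test"
  clf <- train_classifier(feats, labels, trees = 50L, seed = 1L)
  expect_gte(clf$oob_accuracy, 0.99)
  probe <- data.frame(intensity = rnorm(50, 10), grad_mag = rnorm(50, -5))
  p1 <- predict(clf$forest, probe)
  clf2 <- train_classifier(feats, labels, trees = 50L, seed = 1L)
  expect_identical(p1, predict(clf2$forest, probe))
  expect_error(train_classifier(feats, rep("muscle", 2 * n)), "both classes")
})

test_that("muscle VOI is contained in the hand mask and reproducible", {
  clf <- test_classifier()
  p <- prepped_phantom(201L)
  m1 <- classify_muscle(p$corrected, p$hand, clf)
  expect_true(all(m1$data <= p$hand$data))
  m2 <- classify_muscle(p$corrected, p$hand, clf)
  expect_identical(m1$data, m2$data)
})

test_that("classification refuses a mismatched feature configuration", {
  clf <- test_classifier()
  p <- prepped_phantom(201L)
  other <- feature_config(box_radii = 1L)
  expect_error(classify_muscle(p$corrected, p$hand, clf, other),
               "fingerprint")
})

test_that("random forest segments unseen phantoms with high Dice", {
  clf <- test_classifier()
  for (seed in c(201L, 202L)) {
    p <- prepped_phantom(seed)
    m <- classify_muscle(p$corrected, p$hand, clf)
    truth <- (p$ph$truth$labels_t1 ==
                p$ph$truth$label_codes[["muscle"]]) * 1L
    expect_gte(dice_coef(m$data, truth), 0.85)
  }
})

test_that("Gaussian cleanup matches a direct-count oracle on pure Gaussian data", {
  set.seed(123)
  n <- 1e5
  vals <- rnorm(n, 100, 10)
  side <- c(50, 50, 40)
  img <- volume_image(array(vals, side))
  voi <- binary_mask(array(1L, side), reference = img)
  res <- gaussian_cleanup(img, voi)
  mu <- res$report$mean; sg <- res$report$sd
  oracle_fraction <- mean(vals >= mu - 2 * sg & vals <= mu + 2 * sg)
  expect_equal(res$report$retained_fraction, oracle_fraction,
               tolerance = 1e-12)
  # the +-2 sigma band of a Gaussian holds about 95.4% of its mass
  expect_lt(abs(res$report$retained_fraction - 0.954), 0.005)
})

test_that("cleanup removes hyperintense contaminants, sparing true muscle", {
  set.seed(99)
  n_m <- 20000; n_c <- 1000  # 5% vessel-like contamination at mu + 6 sigma
  vals <- c(rnorm(n_m, 100, 10), rnorm(n_c, 160, 2))
  img <- volume_image(array(vals, c(21, 50, 20)))
  voi <- binary_mask(array(1L, c(21, 50, 20)), reference = img)
  res <- gaussian_cleanup(img, voi)
  kept <- res$mask$data == 1
  contaminant <- array(c(rep(FALSE, n_m), rep(TRUE, n_c)), c(21, 50, 20))
  expect_gte(mean(!kept[contaminant]), 0.95)
  expect_lte(mean(!kept[!contaminant]), 0.06)
})

test_that("cleanup handles degenerate and undersized VOIs", {
  img <- volume_image(array(7, c(5, 10, 10)))
  voi <- binary_mask(array(1L, c(5, 10, 10)), reference = img)
  res <- gaussian_cleanup(img, voi)
  expect_true(res$report$degenerate)
  expect_identical(res$mask$data, voi$data)

  tiny <- binary_mask(array(c(rep(1L, 10), rep(0L, 490)), c(5, 10, 10)),
                      reference = img)
  expect_error(gaussian_cleanup(img, tiny), "too small")
})

test_that("bounds restriction keeps exactly the in-window slices", {
  p <- prepped_phantom(2L)
  m <- p$hand
  nsl <- dim(m$data)[1]
  all_b <- analysis_bounds(0, nsl - 1)
  expect_identical(restrict_to_bounds(m, all_b)$data, m$data)
  one <- analysis_bounds(5, 5)
  r <- restrict_to_bounds(m, one)
  expect_equal(sum(r$data), sum(m$data[6, , ]))
  expect_equal(sum(r$data[-6, , ]), 0)
  expect_error(restrict_to_bounds(m, analysis_bounds(0, nsl)), "exceed")
})
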