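test_that("subset partition is round-robin with balanced sizes", {
  s <- subset_partition(502L, 8L)
  expect_equal(sort(unique(table(s))), c(62, 63))
  expect_equal(as.numeric(table(s)[1]), 63)
  expect_true(all(diff(s)[diff(s) != -7] == 1))  # consecutive MCEs differ
  expect_equal(subset_partition(10L, 1L), rep(1L, 10))
  expect_error(subset_partition(4L, 8L), "more subsets")
})

test_that("OSEM keeps the truth as a fixed point on consistent data", {
  srm <- toy_system(n_vox = 12, n_bins = 50, seed = 2)
  x_true <- runif(12, 0.5, 2)
  y <- as.numeric(srm$A %*% x_true)
  rec <- osem(y, srm, n_subsets = 1, n_iter = 3, init = x_true)
  expect_equal(rec$x, x_true, tolerance = 1e-10)
})

test_that("MLEM log-likelihood is non-decreasing on noisy data", {
  srm <- toy_system(n_vox = 10, n_bins = 60, seed = 5)
  x_true <- runif(10, 1, 4) * 50
  set.seed(9)
  y <- rpois(60, as.numeric(srm$A %*% x_true))
  rec <- osem(y, srm, n_subsets = 1, n_iter = 30, track_loglik = TRUE)
  expect_true(all(diff(rec$trace$loglik) > -1e-7))
})

test_that("all-zero data collapse the image to zero in one iteration", {
  srm <- toy_system()
  srm$n_mce <- 2L
  rec <- osem(rep(0, nrow(srm$A)), srm, n_subsets = 2, n_iter = 1)
  expect_true(all(rec$x == 0))
})

test_that("zero-sensitivity voxels are frozen at zero with a warning", {
  srm <- toy_system(n_vox = 8, n_bins = 30, seed = 3)
  srm$A[, 4] <- 0
  expect_warning(rec <- osem(rep(1, 30), srm, n_subsets = 1, n_iter = 2),
                 "frozen")
  expect_equal(rec$x[4], 0)
})

test_that("OSEM with several subsets keeps MLEM fixed points", {
  srm <- toy_system(n_vox = 9, n_bins = 48, seed = 8)
  srm$n_mce <- 4L                      # treat the toy rows as 4 modules
  x_true <- runif(9, 0.5, 2)
  y <- as.numeric(srm$A %*% x_true)
  rec <- osem(y, srm, n_subsets = 4, n_iter = 4, init = x_true)
  expect_equal(rec$x, x_true, tolerance = 1e-10)
})

test_that("noiseless reconstruction recovers ROI means within 5 percent", {
  h <- mini_helmet(16)
  det <- detector_spec()
  aps <- aperture_set(h, "lofthole_1.0")
  grid <- volume_grid(20L, 4)
  co <- scespect:::.coord_arrays(grid)
  act <- array(0, grid$n)
  s1 <- (co$x - 16)^2 + co$y^2 + co$z^2 <= 12^2
  s2 <- (co$x + 16)^2 + co$y^2 + co$z^2 <= 12^2
  act[s1] <- 3; act[s2] <- 1.5
  mask <- which(co$x^2 + co$y^2 + co$z^2 <= 32^2)
  srm <- build_srm(h, det, aps, grid, mask = mask,
                   options = response_options(collapse_doi = TRUE),
                   window = 48)
  vol <- activity_volume(grid, act)
  y <- forward_project(srm, vol)
  truth <- as.numeric(act)[mask]
  rec <- osem(y, srm, n_subsets = 8, n_iter = 200, truth = truth)
  it <- stopping_iteration(rec$trace$nrmse, "noiseless_plateau")
  expect_lte(it, 200)
  # interior ROI means (two voxels eroded from the sphere surface)
  in1 <- which((co$x - 16)^2 + co$y^2 + co$z^2 <= 4^2)
  in2 <- which((co$x + 16)^2 + co$y^2 + co$z^2 <= 4^2)
  expect_rel_equal(mean(rec$image[in1]), 3, 0.05)
  expect_rel_equal(mean(rec$image[in2]), 1.5, 0.05)
})

test_that("stopping rules select the minimum or the plateau", {
  expect_equal(stopping_iteration(c(0.5, 0.3, 0.35), "noisy_min"), 2L)
  tr <- 0.2 + 0.8 * exp(-(1:20))
  expect_equal(stopping_iteration(tr, "noiseless_plateau"),
               which(abs(diff(tr)) < 1e-4)[1] + 1L)
  expect_equal(stopping_iteration(0.4, "noiseless_plateau"), 1L)
  expect_warning(stopping_iteration(seq(1, 0.5, length.out = 5),
                                    "noiseless_plateau"),
                 "plateau")
})

test_that("Gaussian post-filter has the right width and preserves mass", {
  img <- array(0, c(31, 31, 31))
  img[16, 16, 16] <- 1
  f <- gaussian_post_filter(img, fwhm_mm = 6, voxel_mm = 2)
  expect_equal(sum(f), 1, tolerance = 1e-6)
  prof <- f[, 16, 16]
  fw <- profile_fwhm(prof, pos = (seq_len(31) - 16) * 2)
  expect_lt(abs(fw - 6), 1)                     # within half a voxel
  const <- array(2.5, c(9, 9, 9))
  expect_equal(gaussian_post_filter(const, 6, 2), const, tolerance = 1e-12)
  expect_error(gaussian_post_filter(img, fwhm_mm = 0), "positive")
})
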