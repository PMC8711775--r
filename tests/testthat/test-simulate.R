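test_that("forward projection is the linear action of the system matrix", {
  h <- mini_helmet(8)
  aps <- aperture_set(h, "lofthole_1.5")
  grid <- volume_grid(c(4, 4, 4), 2)
  srm <- build_srm(h, detector_spec(), aps, grid, mask = 1:64, window = 32,
                   bin = 2)
  zero <- activity_volume(grid, array(0, grid$n))
  expect_true(all(forward_project(srm, zero)$values == 0))
  act <- array(runif(64), grid$n)
  v1 <- activity_volume(grid, act)
  v2 <- activity_volume(grid, 2 * act)
  expect_equal(forward_project(srm, v2)$values,
               2 * forward_project(srm, v1)$values, tolerance = 1e-12)
  # single-voxel unit emitter reproduces the matrix column
  one <- array(0, grid$n); one[17] <- 1
  y <- forward_project(srm, activity_volume(grid, one))
  expect_equal(y$values, as.numeric(srm$A[, 17]), tolerance = 1e-12)
  # expected-count conservation: sum(ybar) = sum_i x_i s_i
  expect_equal(sum(forward_project(srm, v1)$values),
               sum(Matrix::colSums(srm$A) * as.numeric(act)),
               tolerance = 1e-10)
  expect_error(forward_project(srm, uniform_fov(volume_grid(8, 2))),
               "grid")
})

test_that("streamed projection of points matches the matrix route", {
  h <- mini_helmet(8)
  aps <- aperture_set(h, "ring_250")
  grid <- volume_grid(c(4, 4, 4), 2)
  srm <- build_srm(h, detector_spec(), aps, grid, mask = 1:64, window = 32,
                   bin = 2)
  w <- runif(64)
  dense <- as.numeric(srm$A %*% w)
  streamed <- project_points(h, detector_spec(), aps,
                             scespect:::.grid_centers(grid), w,
                             window = 32, bin = 2)
  expect_equal(streamed, dense, tolerance = 1e-12)
})

test_that("Poisson noise is seeded, mean-preserving and zero-safe", {
  ps <- structure(list(values = rep(7, 1e5), bins = NULL, n_bins = 1e5,
                       counts = FALSE, acquisition = NULL, seed = NULL),
                  class = "projection_set")
  a <- add_poisson(ps, seed = 123)
  b <- add_poisson(ps, seed = 123)
  expect_identical(a$values, b$values)
  expect_true(all(a$values == round(a$values)))
  expect_lt(abs(mean(a$values) - 7), 3 * sqrt(7 / 1e5))
  expect_lt(abs(var(a$values) / 7 - 1), 0.05)
  ps0 <- ps; ps0$values <- rep(0, 10)
  expect_true(all(add_poisson(ps0)$values == 0))
  psn <- ps; psn$values[1] <- -1
  expect_error(add_poisson(psn), "nonnegative")
})

test_that("point projections show the aperture footprints", {
  h <- full_helmet()
  det <- detector_spec()
  opts <- response_options(penetration = FALSE)  # crisp geometric footprints
  # micro-ring: an annulus of narrow width around the module centre
  img <- render_point_projection(h, det, aperture_defaults("ring_250"),
                                 c(0, 0, 0), options = opts)
  nz <- which(img > 0, arr.ind = TRUE)
  r <- sqrt(((nz[, 1] - 0.5) * 0.25 - 10)^2 + ((nz[, 2] - 0.5) * 0.25 - 10)^2)
  expect_gt(nrow(nz), 100)
  expect_true(all(r > 3.2 & r < 4.6))            # narrow annulus
  expect_lt(diff(range(r)), 3 * 0.25)            # width <= 3 pixels
  # two points through a slit perpendicular to their separation: disjoint
  slit <- aperture_defaults("slit_150x6"); slit$theta <- 90
  i1 <- render_point_projection(h, det, slit, c(-2, 0, 0), options = opts)
  i2 <- render_point_projection(h, det, slit, c(2, 0, 0), options = opts)
  expect_gt(sum(i1 > 0), 0)
  expect_equal(sum(i1 > 0 & i2 > 0), 0L)
  # on-axis lofthole: footprint centred on the module
  i3 <- render_point_projection(h, det, aperture_defaults("lofthole_1.5"),
                                c(0, 0, 0), options = opts)
  w <- i3 / sum(i3)
  cu <- sum(((seq_len(80) - 0.5) * 0.25 - 10) * rowSums(w))
  expect_lt(abs(cu), 0.3)
  expect_error(render_point_projection(h, det, slit, c(200, 0, 0)),
               "outside")
})
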