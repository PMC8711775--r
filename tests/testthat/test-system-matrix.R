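test_that("on-axis pinhole response matches the closed-form solid angle", {
  h1 <- one_mce_helmet()
  det <- detector_spec()
  aps <- aperture_set(h1, "lofthole_1.0")
  # penetration and CZT absorption disabled: pure geometric solid angle
  s <- point_sensitivity(h1, det, aps, c(0, 0, 0),
                         options = response_options(penetration = FALSE,
                                                    detector_absorption = FALSE))
  expected <- open_area(aperture_defaults("lofthole_1.0")) /
    (4 * pi * 183.23^2)                       # 1.861e-6
  expect_rel_equal(s[1], expected, 0.10)      # pixel-centre quadrature
  # adding CZT absorption multiplies by the 5-mm interaction probability
  s_czt <- point_sensitivity(h1, det, aps, c(0, 0, 0),
                             options = response_options(penetration = FALSE))
  expect_rel_equal(s_czt[1] / s[1], 1 - exp(-0.354 * 5), 0.002)
})

test_that("DOI layer absorption follows Beer-Lambert per oblique chord", {
  h1 <- one_mce_helmet()
  det <- detector_spec()
  aps <- aperture_set(h1, "lofthole_1.0")
  col <- voxel_response(h1, det, aps, c(0, 0, 0),
                        options = response_options(penetration = FALSE,
                                                   floor = 1e-30))
  v <- col@x                    # nonzero values in bin order (layer fastest)
  m <- matrix(v, nrow = 5)      # rows = DOI layers for each lit pixel
  q <- exp(-0.354)              # per-1-mm normal-incidence survival
  ratios <- m[2, ] / m[1, ]
  expect_lt(max(abs(ratios - q)), 0.002)      # near-normal incidence
  expect_rel_equal(mean(m[1, ] / colSums(m)), (1 - q) / (1 - q^5), 0.002)
})

test_that("a fully shadowed voxel yields an empty response column", {
  h1 <- one_mce_helmet()
  aps <- aperture_set(h1, "lofthole_0.5")
  # far lateral voxel outside the acceptance cone of the single module
  col <- voxel_response(h1, detector_spec(), aps, c(0, -90, 40),
                        options = response_options(floor = 1e-12))
  expect_equal(length(col@i), 0L)
})

test_that("build_srm columns equal individual voxel responses", {
  h <- mini_helmet(12)
  det <- detector_spec()
  aps <- aperture_set(h, "lofthole_1.0")
  grid <- volume_grid(c(4, 4, 4), 2)
  mask <- c(22L, 43L)
  srm <- build_srm(h, det, aps, grid, mask = mask, window = 40)
  ctr <- scespect:::.grid_centers(grid, mask)
  for (k in 1:2) {
    col <- voxel_response(h, det, aps, ctr[k, ], window = 40)
    expect_equal(as.numeric(srm$A[, k]), as.numeric(col), tolerance = 0)
  }
  expect_error(voxel_response(h, det, aps, c(100, 0, 0), grid = grid),
               "outside")
})

test_that("sensitivity map equals the stored column sums exactly", {
  h <- mini_helmet(12)
  aps <- aperture_set(h, "ring_250")
  grid <- volume_grid(c(6, 6, 6), 4)
  srm <- build_srm(h, detector_spec(), aps, grid, mask = 1:216, window = 32,
                   bin = 2)
  sm <- sensitivity_map(srm)
  expect_identical(as.numeric(sm$values)[srm$mask_idx],
                   Matrix::colSums(srm$A))
  prof <- sensitivity_profiles(sm, "lateral")
  expect_equal(nrow(prof), 6)
  expect_error(sensitivity_profiles(sm, "diagonal"))
})

test_that("stored and reloaded system matrices are bit-identical", {
  h <- mini_helmet(8)
  aps <- aperture_set(h, "slit_250x5", seed = 5)
  srm <- build_srm(h, detector_spec(), aps, volume_grid(c(3, 3, 3), 4),
                   mask = c(5L, 14L, 23L), window = 40, bin = 2)
  base <- file.path(tempdir(), "srm_roundtrip")
  save_srm(srm, base)
  back <- load_srm(base)
  expect_identical(back$A@x, srm$A@x)
  expect_identical(back$A@i, srm$A@i)
  expect_identical(back$mask_idx, srm$mask_idx)
  expect_identical(dim(back$A), dim(srm$A))
})

test_that("Monte-Carlo area sampling reproduces the single-MCE response", {
  h1 <- one_mce_helmet()
  det <- detector_spec()
  for (v in c("lofthole_3.0", "ring_250")) {
    aps <- aperture_set(h1, v)
    q <- point_sensitivity(h1, det, aps, c(0, 0, 0))
    mc <- scespect:::cpp_mc_sensitivity(
      c(0, 0, 0), scespect:::.mce_matrix(h1)[1, ],
      scespect:::.ap_params(aperture_defaults(v)),
      scespect:::.det_list(det, h1$f), 2e6,
      unclass(response_options()))
    # agreement within 3 SE plus the pixel-centre quadrature bound (the
    # footprint boundary is discretised at one 250-um pixel)
    expect_lt(abs(q[1] - mc$estimate), 3 * mc$se + 0.05 * mc$estimate)
  }
})

test_that("sensitivity decreases as tungsten attenuation increases", {
  h1 <- one_mce_helmet()
  det <- detector_spec()
  mus <- c(2, 3.64, 6)
  for (v in c("lofthole_1.0", "ring_250")) {
    s <- vapply(mus, function(m) {
      aps <- aperture_set(h1, aperture_defaults(v, mu_w = m))
      point_sensitivity(h1, det, aps, c(0, 0, 0))[1]
    }, numeric(1))
    expect_true(all(diff(s) < 0))
  }
})

test_that("aperture SNR is invariant under rigid rotation of the system", {
  h <- full_helmet()
  ap <- aperture_defaults("lofthole_1.0")
  # pole module vs an equatorial module: same aperture, rotated frame
  s1 <- aperture_snr(h, detector_spec(), ap, stride = 8L, mce = 1L)
  equatorial <- which(h$mces$ring == 11)[1]
  s2 <- aperture_snr(h, detector_spec(), ap, stride = 8L, mce = equatorial)
  expect_rel_equal(s2, s1, 0.05)   # voxel-lattice orientation residual
})

test_that("an impenetrable aperture gives the infinite-SNR sentinel", {
  h <- mini_helmet(8)
  ap <- aperture_defaults("lofthole_1.0", mu_w = Inf)
  expect_warning(s <- aperture_snr(h, detector_spec(), ap, stride = 12L),
                 "infinite")
  expect_identical(s[1], Inf)
})

test_that("the resource guard refuses oversized builds with guidance", {
  h <- mini_helmet(12)
  aps <- aperture_set(h, "ring_250")
  expect_error(build_srm(h, detector_spec(), aps, volume_grid(48, 4),
                         max_nnz = 1e4),
               "coarsen the grid")
})
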