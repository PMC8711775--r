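test_that("open areas match the published aperture set", {
  expect_equal(open_area(aperture_defaults("lofthole_1.0")), pi / 4,
               tolerance = 1e-12)
  expect_equal(signif(open_area(aperture_defaults("lofthole_1.0")), 3), 0.785)
  expect_equal(open_area(aperture_defaults("slit_150x6")), 0.9)
  expect_equal(open_area(aperture_defaults("slit_250x5")), 1.25)
  expect_equal(signif(open_area(aperture_defaults("ring_250")), 3), 5.69)
  expect_equal(signif(open_area(aperture_defaults("lofthole_3.0")), 3), 7.07)
})

test_that("default variants carry the published angles and slab splits", {
  s6 <- aperture_defaults("slit_150x6")
  expect_equal(c(s6$alpha_short, s6$beta_short), c(27.3, 29.4))
  expect_equal(c(s6$alpha_long, s6$beta_long), c(35.3, 21.1))
  expect_equal(c(s6$t_u, s6$t_l), c(9, 11))
  r <- aperture_defaults("ring_250")
  expect_equal(c(r$alpha, r$beta), c(36.3, 32.7))
  expect_equal(c(r$t_u, r$t_l), c(7, 13))
  expect_equal(c(r$r_outer, r$r_inner), c(3.75, 3.5))
  expect_error(aperture_defaults("nope"), "valid variants")
  expect_error(aperture_spec("lofthole", t_u = 5, t_l = 5), "20-mm slab")
  expect_error(aperture_spec("micro_slit", width = 1, length = 5), ">= 10")
})

test_that("slit rotations form the exact 360/n multiset, seeded", {
  a <- assign_slit_rotations(502, seed = 3)
  expect_equal(sort(a), (0:501) * 360 / 502)
  expect_equal(diff(sort(a))[1], 0.717, tolerance = 1e-3)
  expect_setequal(assign_slit_rotations(4, 1), c(0, 90, 180, 270))
  expect_identical(assign_slit_rotations(100, 7),
                   assign_slit_rotations(100, 7))
  expect_false(identical(assign_slit_rotations(100, 7),
                         assign_slit_rotations(100, 8)))
  expect_error(assign_slit_rotations(0), "positive")
})

test_that("axial open rays have zero path; solid regions block the slab", {
  for (v in c("lofthole_1.0", "slit_250x5", "ring_250")) {
    a <- aperture_defaults(v)
    ctr <- if (a$kind == "micro_ring")
      c(mean(c(a$r_inner, a$r_outer)), 0) else c(0, 0)
    expect_equal(path_length_in_tungsten(a, c(ctr, -100), c(ctr, 100)), 0)
  }
  # only the lofthole keeps full-thickness tungsten far from the opening;
  # slit and ring channels flare across most of the slab footprint
  lh <- aperture_defaults("lofthole_1.0")
  expect_equal(path_length_in_tungsten(lh, c(9, 9, -100), c(9, 9, 100)), 20,
               tolerance = 1e-9)
  for (v in c("slit_250x5", "ring_250")) {
    a <- aperture_defaults(v)
    expect_gt(path_length_in_tungsten(a, c(9, 9, -100), c(9, 9, 100)), 5)
    expect_lt(transmission(a, c(9, 9, -100), c(9, 9, 100)), 1e-25)
  }
})

test_that("analytic path agrees with the 5-um ray-march oracle", {
  set.seed(11)
  step <- 0.005
  for (v in c("lofthole_1.0", "lofthole_0.5", "slit_250x5", "slit_150x6",
              "ring_250")) {
    a <- aperture_defaults(v)
    n <- 150
    org <- cbind(runif(n, -60, 60), runif(n, -60, 60), -183.23)
    tgt <- cbind(runif(n, -9, 9), runif(n, -9, 9), 15.27)
    pa <- path_length_in_tungsten(a, org, tgt, method = "analytic")
    pm <- path_length_in_tungsten(a, org, tgt, method = "march", step = step)
    expect_lt(max(abs(pa - pm)), 2 * step)
  }
})

test_that("transmission is exp(-mu x), exactly 1 on the open channel", {
  a <- aperture_defaults("lofthole_1.0")
  expect_identical(transmission(a, c(0, 0, -50), c(0, 0, 50)), 1)
  expect_lt(transmission(a, c(9, 9, -100), c(9, 9, 100)), 1e-30)
  set.seed(4)
  org <- cbind(runif(200, -40, 40), runif(200, -40, 40), -183.23)
  tgt <- cbind(runif(200, -9, 9), runif(200, -9, 9), 15.27)
  x <- path_length_in_tungsten(a, org, tgt)
  tr <- transmission(a, org, tgt)
  expect_true(all(tr >= 0 & tr <= 1))
  # monotone non-increasing in the tungsten chord
  o <- order(x)
  expect_true(all(diff(tr[o]) <= 1e-12))
  # independent composition check against the marched chord
  xm <- path_length_in_tungsten(a, org, tgt, method = "march", step = 0.005)
  keep <- xm < 5            # transmissions large enough to compare
  expect_lt(max(abs(log(pmax(tr[keep], 1e-300)) + a$mu_w * xm[keep])),
            a$mu_w * 0.01)
})

test_that("rays classify into signal, noise and blocked", {
  a <- aperture_defaults("lofthole_1.0")
  expect_equal(classify_ray(a, c(0, 0, -50), c(0, 0, 50)), "signal")
  # knife-edge graze: aim just outside the 0.5-mm opening radius
  grazing <- classify_ray(a, c(0.52, 0, -20), c(0.52, 0, 20))
  expect_equal(grazing, "noise")
  expect_equal(classify_ray(a, c(9, 9, -100), c(9, 9, 100)), "blocked")
})

test_that("open_area matches 2-D Monte-Carlo membership integration", {
  set.seed(99)
  for (v in c("lofthole_1.0", "slit_250x5", "ring_250")) {
    a <- aperture_defaults(v)
    # tight sampling box around the opening keeps the Monte-Carlo error small
    box <- switch(a$kind,
                  lofthole = c(0.75, 0.75),
                  micro_slit = c(2 * a$width, a$length / 2 + 1),
                  micro_ring = rep(a$r_outer + 0.5, 2))
    n <- 1e6
    xy <- cbind(runif(n, -box[1], box[1]), runif(n, -box[2], box[2]))
    # vertical hair rays crossing the aperture plane probe the bottleneck
    p <- path_length_in_tungsten(a, cbind(xy, -1e-3), cbind(xy, 1e-3))
    mc_area <- mean(p <= 0) * 4 * box[1] * box[2]
    expect_rel_equal(mc_area, open_area(a), 0.005)
  }
})

test_that("the exit cone confines the FOV-centre projection on the module", {
  f <- 183.23 / 12
  for (v in c("lofthole_1.0", "lofthole_3.0", "slit_250x5", "slit_150x6",
              "ring_250")) {
    a <- aperture_defaults(v)
    # boundary of the opening in the aperture plane
    t <- seq(0, 2 * pi, length.out = 73)[-73]
    bd <- switch(a$kind,
      lofthole = cbind(cos(t), sin(t)) * a$diameter / 2,
      micro_slit = cbind(c(t, t) * 0 +
                           c(rep(a$width / 2, 72), rep(-a$width / 2, 72)),
                         rep(seq(-a$length / 2, a$length / 2,
                                 length.out = 72), 2)),
      micro_ring = cbind(cos(t), sin(t)) * a$r_outer)
    # straight continuation from the FOV centre through the boundary
    land <- bd * (183.23 + f) / 183.23
    expect_true(all(abs(land) <= 10))
  }
})

test_that("tungsten attenuation table is sane at SPECT energies", {
  expect_rel_equal(tungsten_mu(140), 3.64, 0.02)   # NIST-derived, mm^-1
  expect_true(tungsten_mu(250) < tungsten_mu(100))
  expect_error(tungsten_mu(50))
})
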