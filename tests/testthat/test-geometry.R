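test_that("default helmet reproduces the published module counts", {
  h <- full_helmet()
  expect_equal(nrow(h$mces), 502L)
  expect_equal(sum(h$mces$ring <= 11), 345L)   # hemisphere + top cover
  expect_equal(sum(h$mces$ring >= 12), 157L)   # neck section
  expect_equal(length(h$ring_counts), 19L)     # 18 rings + top cover
  expect_equal(h$f / h$D_a, 1 / 12)
})

test_that("every aperture centre sits on the focal sphere, axis at origin", {
  h <- full_helmet()
  ctr <- as.matrix(h$mces[, c("cx", "cy", "cz")])
  expect_lt(max(abs(sqrt(rowSums(ctr^2)) - h$D_a)), 1e-9)
  ax <- as.matrix(h$mces[, c("ax", "ay", "az")])
  align <- rowSums(ax * (-ctr / sqrt(rowSums(ctr^2))))
  expect_lt(max(abs(align - 1)), 1e-12)
  # orthonormal right-handed in-plane basis, w = outward axis
  u <- as.matrix(h$mces[, c("ux", "uy", "uz")])
  v <- as.matrix(h$mces[, c("vx", "vy", "vz")])
  w <- as.matrix(h$mces[, c("wx", "wy", "wz")])
  expect_lt(max(abs(rowSums(u * v))), 1e-12)
  expect_lt(max(abs(rowSums(u * w))), 1e-12)
  expect_lt(max(abs(rowSums(u^2) - 1)), 1e-12)
  expect_lt(max(abs(w + ax)), 1e-12)
})

test_that("neck rings cover only the rear half, frontal opening is empty", {
  h <- full_helmet()
  neck <- h$mces[h$mces$ring >= 12, ]
  expect_true(all(neck$azimuth_deg > 0 & neck$azimuth_deg < 180))
  # frontal (-y) direction: no neck module within 90 degrees of azimuth 270
  expect_false(any(abs(neck$azimuth_deg - 270) < 90))
})

test_that("detector footprints of distinct modules do not intersect", {
  h <- full_helmet()
  det_r <- h$D_a + h$f
  ctr <- as.matrix(h$mces[, c("wx", "wy", "wz")]) * det_r
  u <- as.matrix(h$mces[, c("ux", "uy", "uz")])
  v <- as.matrix(h$mces[, c("vx", "vy", "vz")])
  # exact separating-axis test for flat convex squares in 3D: axes are the
  # two face normals and the four edge-direction cross products
  w <- as.matrix(full_helmet()$mces[, c("wx", "wy", "wz")])
  corners <- function(i) {
    s <- rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1)) * 10
    t(ctr[i, ] + t(s %*% rbind(u[i, ], v[i, ])))
  }
  separated <- function(i, j) {
    ci <- corners(i); cj <- corners(j)
    axes <- rbind(w[i, ], w[j, ],
                  t(apply(expand.grid(1:2, 1:2), 1, function(k) {
                    e1 <- rbind(u[i, ], v[i, ])[k[1], ]
                    e2 <- rbind(u[j, ], v[j, ])[k[2], ]
                    c(e1[2] * e2[3] - e1[3] * e2[2],
                      e1[3] * e2[1] - e1[1] * e2[3],
                      e1[1] * e2[2] - e1[2] * e2[1])
                  })))
    for (r in seq_len(nrow(axes))) {
      a <- axes[r, ]
      if (sum(a^2) < 1e-12) next
      pi_ <- ci %*% a; pj <- cj %*% a
      if (max(pi_) < min(pj) - 1e-9 || max(pj) < min(pi_) - 1e-9)
        return(TRUE)
    }
    FALSE
  }
  nn <- 0L
  for (i in seq_len(nrow(ctr))) {
    d <- sweep(ctr, 2, ctr[i, ])
    near <- which(rowSums(d^2) > 0 & rowSums(d^2) < 30^2)
    near <- near[near > i]
    for (j in near) if (!separated(i, j)) nn <- nn + 1L
  }
  expect_equal(nn, 0L)
})

test_that("helmet construction is deterministic and validates ring counts", {
  expect_identical(build_helmet()$mces, build_helmet()$mces)
  cfg <- helmet_config(ring_counts = rep(10L, 19))
  expect_error(build_helmet(cfg), "sum to 190")
})

test_that("MCE frames round-trip and place the FOV centre at -D_a", {
  h <- full_helmet()
  set.seed(1)
  for (i in c(1L, 57L, 400L)) {
    fr <- mce_frame(h, i)
    expect_equal(drop(fr$to_local(c(0, 0, 0))), c(0, 0, -183.23),
                 tolerance = 1e-9)
    p <- matrix(rnorm(30, sd = 80), 10)
    expect_lt(max(abs(fr$to_world(fr$to_local(p)) - p)), 1e-9)
    # detector-plane centre maps to distance D_a + f from the origin
    dc <- drop(fr$to_world(c(0, 0, h$f)))
    expect_equal(sqrt(sum(dc^2)), h$D_a + h$f, tolerance = 1e-9)
  }
})

test_that("pixel centres follow the 250-um pitch and 1-mm DOI layers", {
  h <- full_helmet()
  det <- detector_spec()
  p1 <- pixel_center(h, 1, det, 39, 39, 0)
  p2 <- pixel_center(h, 1, det, 40, 39, 0)
  expect_equal(sqrt(sum((p2 - p1)^2)), 0.25, tolerance = 1e-12)
  l0 <- pixel_center(h, 1, det, 10, 10, 0)
  l4 <- pixel_center(h, 1, det, 10, 10, 4)
  expect_equal(sqrt(sum((l4 - l0)^2)), 4, tolerance = 1e-12)
  fr <- mce_frame(h, 1)
  expect_equal(drop(fr$to_local(pixel_center(h, 1, det, 39, 39, 0)))[1:2],
               c(-0.125, -0.125), tolerance = 1e-12)
  expect_error(pixel_center(h, 1, det, 80, 0, 0), "out of range")
  expect_error(pixel_center(h, 1, det, 0, 0, 5), "out of range")
})

test_that("detector invariants hold and layout table exports", {
  det <- detector_spec()
  expect_equal(det$n_pix_u * det$pitch, 20)
  expect_equal(det$n_doi_layers * det$layer_thickness, det$thickness)
  expect_error(detector_spec(n_doi_layers = 4), "tile")
  f <- tempfile(fileext = ".tsv")
  tab <- helmet_table(full_helmet(), f)
  expect_true(file.exists(f))
  expect_equal(nrow(read.table(f, header = TRUE)), 502)
})
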