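test_that("affine registration recovers translations (vs exhaustive shift oracle) and scale", {
  # structure-rich smooth image: translation is constrained everywhere
  set.seed(61)
  img <- flow4d:::gauss_smooth3(array(rnorm(24^3), c(24L, 24L, 24L)), 1.5)
  # integer-shift target: tgt(x) = img(x - s), s = (3, -2, 1)
  tgt <- array(0, dim(img))
  tgt[4:24, 1:22, 2:24] <- img[1:21, 3:24, 1:23]
  # oracle: exhaustive integer-shift search maximizing correlation
  shifts <- expand.grid(sx = -4:4, sy = -4:4, sz = -4:4)
  sc <- function(a, s) {
    i <- pmin(pmax(1:24 - s[1], 1), 24); j <- pmin(pmax(1:24 - s[2], 1), 24)
    k <- pmin(pmax(1:24 - s[3], 1), 24)
    stats::cor(as.vector(a[i, j, k]), as.vector(tgt))
  }
  cors <- apply(shifts, 1, function(s) sc(img, s))
  expect_equal(unlist(shifts[which.max(cors), ], use.names = FALSE), c(3, -2, 1))
  aff <- register_affine(img, tgt, reg_params(3, 5))
  # pull-back: a target point samples the source at x + t with t = -s
  ctr <- c(11.5, 11.5, 11.5)
  moved <- apply_affine(aff, rbind(ctr))
  expect_lt(max(abs(moved - (ctr - c(3, -2, 1)))), 0.5)

  # identity case
  aff0 <- register_affine(img, img, reg_params(3, 5))
  expect_lt(max(abs(aff0$matrix - diag(3))), 1e-3)
  expect_lt(max(abs(aff0$translation)), 1e-3)

  # 1.1x scaling about the centre (oracle: 1-parameter scan of the scale
  # axis puts the correlation optimum at 1/1.1)
  blob <- blob_image(c(24L, 24L, 24L))
  g <- as.matrix(expand.grid(0:23, 0:23, 0:23))
  pts <- sweep(sweep(g, 2, ctr, "-") / 1.1, 2, ctr, "+")
  tgt_s <- array(flow4d:::interp_trilinear(blob, pts, oob = "clamp"), dim(blob))
  scan <- vapply(seq(0.85, 1.0, by = 0.005), function(s) {
    w <- sweep(sweep(g, 2, ctr, "-") * s, 2, ctr, "+")
    1 - stats::cor(flow4d:::interp_trilinear(blob, w, oob = 0), as.vector(tgt_s))
  }, 0)
  expect_equal(seq(0.85, 1.0, by = 0.005)[which.min(scan)], 1 / 1.1,
               tolerance = 0.01)
  affs <- register_affine(blob, tgt_s, reg_params(3, 5))
  scale_est <- det(affs$matrix)^(1 / 3)
  expect_gt(scale_est, 1 / 1.13)   # pull-back matrix ~ 1/1.1
  expect_lt(scale_est, 1 / 1.07)
  expect_error(register_affine(array(1, c(8, 8, 8)), img), "constant")
})

test_that("morphon registration is exact on identity and recovers a known smooth warp", {
  img <- blob_image(c(32L, 32L, 32L))
  f0 <- register_morphon(img, img, reg_params(3, 5))
  expect_lte(max(abs(f0$d)), 0.1)
  fl <- sine_field_vox(dim(img), amplitude = 2)
  tgt <- warp_known(img, fl)
  f <- register_morphon(img, tgt, reg_params(3, 5))
  supp <- img > 0.1 * max(img)
  epe <- sqrt((f$d[, , , 1] - fl$dx)^2 + (f$d[, , , 2] - fl$dy)^2 +
              (f$d[, , , 3] - fl$dz)^2)
  expect_lte(mean(epe[supp]), 0.5)
  expect_gt(min(flow4d:::interior(jacobian_determinant(f))), 0)
  expect_gt(min(flow4d:::interior(jacobian_determinant(f0))), 0)
  expect_error(register_morphon(img, img[1:16, , ]), "grids|3D|dim")
  bad <- img; bad[1] <- NaN
  expect_error(register_morphon(img, bad), "NaN")
})

test_that("raising sigma_elastic never increases the field's total variation", {
  img <- blob_image(c(24L, 24L, 24L))
  tgt <- warp_known(img, sine_field_vox(dim(img), 2))
  tv <- function(f) {
    s <- 0
    for (c3 in 1:3) {
      gr <- flow4d:::gradient3(array(f$d[, , , c3], dim(img)))
      s <- s + sum(abs(gr[[1]]) + abs(gr[[2]]) + abs(gr[[3]]))
    }
    s
  }
  tvs <- vapply(c(0.8, 1.5, 2.5), function(se)
    tv(register_morphon(img, tgt, reg_params(3, 5, sigma_elastic = se))), 0)
  expect_true(all(diff(tvs) <= 0))
})

test_that("warping follows the pull-back convention", {
  img <- blob_image(c(16L, 16L, 16L))
  msk <- (img > 0.3) * 1
  # identity affine + zero field: bit-exact in mask mode
  z <- flow4d:::zero_field(dim(img))
  expect_identical(warp_image(msk, affine = affine_transform(), field = z,
                              mode = "mask"), msk == 1)
  expect_equal(warp_image(img, field = z), img)
  # d = (1, 0, 0) voxel shifts a step edge by one voxel (index-shift oracle)
  step <- array(0, c(16, 16, 16)); step[9:16, , ] <- 1
  dmm <- array(0, c(16, 16, 16, 3)); dmm[, , , 1] <- 1
  sh <- warp_image(step, field = displacement_field(dmm))
  expect_equal(sh[1:15, , ], step[2:16, , ])
  # binary sphere moved by a known field: Dice vs the analytic moved sphere
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  sph <- array((g$x - 8)^2 + (g$y - 8)^2 + (g$z - 8)^2 <= 16, c(16, 16, 16))
  dmm2 <- array(0, c(16, 16, 16, 3)); dmm2[, , , 2] <- -2.4   # pull-back: moves +2.4
  moved <- warp_image(sph * 1, field = displacement_field(dmm2), mode = "mask")
  truth <- array((g$x - 8)^2 + (g$y - 10.4)^2 + (g$z - 8)^2 <= 16, c(16, 16, 16))
  expect_gte(dice_coefficient(moved, truth), 0.9)
})

test_that("field inversion has closed forms and small composition residuals", {
  d3 <- c(16L, 16L, 16L)
  cst <- array(rep(c(1.5, -2, 0.5), each = prod(d3)), c(d3, 3))
  fi <- invert_field(displacement_field(cst))
  expect_equal(fi$d[5, 5, 5, ], c(-1.5, 2, -0.5), tolerance = 1e-9)
  z <- flow4d:::zero_field(d3)
  expect_true(all(invert_field(z)$d == 0))
  f <- vox_field(sine_field_vox(c(24L, 24L, 24L), 2))
  fi2 <- invert_field(f, tol = 0.05)
  expect_lt(attr(fi2, "residual"), 0.05)
})

test_that("warp then inverse-warp recovers a smooth image inside the object", {
  d3 <- c(24L, 24L, 24L)
  g <- expand.grid(x = 0:23, y = 0:23, z = 0:23)
  img <- array(exp(-((g$x - 11.5)^2 + (g$y - 11.5)^2 + (g$z - 11.5)^2) / 80), d3)
  f <- vox_field(sine_field_vox(d3, 2))
  fi <- invert_field(f, tol = 0.05)
  w2 <- warp_image(warp_image(img, field = f), field = fi)
  inner <- flow4d:::interior(abs(w2 - img) * (img > 0.15), 3)
  expect_lte(sqrt(mean(inner[flow4d:::interior(img, 3) > 0.15]^2)) /
               diff(range(img)), 0.02)
})

test_that("point mapping inverts the pull-back chain", {
  pts <- rbind(c(5, 5, 5), c(10, 8, 3))
  expect_equal(unclass(map_points(pts, affine_transform()))[, ], pts,
               ignore_attr = TRUE)
  # pure pull-back translation t: forward map shifts points by -t
  aff <- affine_transform(translation = c(2, -1, 3))
  mp <- map_points(pts, aff)
  expect_equal(mp[1, ], pts[1, ] - c(2, -1, 3), ignore_attr = TRUE)
  # round trip through a smooth field: x + d_inv, then forward chain
  d3 <- c(20L, 20L, 20L)
  f <- vox_field(sine_field_vox(d3, 1.5))
  p0 <- rbind(c(9, 9, 9), c(6, 12, 10), c(13, 7, 11))
  mp2 <- map_points(p0, field = f)
  darr <- lapply(1:3, function(c3) array(f$d[, , , c3], d3))
  back <- mp2 + cbind(flow4d:::interp_trilinear(darr[[1]], mp2, oob = "clamp"),
                      flow4d:::interp_trilinear(darr[[2]], mp2, oob = "clamp"),
                      flow4d:::interp_trilinear(darr[[3]], mp2, oob = "clamp"))
  expect_lt(max(abs(back - p0)), 0.1)
  # far-outside points are flagged, not dropped
  mp3 <- map_points(rbind(c(100, 100, 100)), field = f)
  expect_true(attr(mp3, "oob")[1])
  expect_equal(nrow(mp3), 1L)
})

test_that("Jacobian determinant has its closed forms", {
  d3 <- c(12L, 12L, 12L)
  expect_equal(jacobian_determinant(flow4d:::zero_field(d3)),
               array(1, d3))
  # uniform scaling d(x) = 0.1 x: det = 1.1^3 in the interior
  g <- expand.grid(x = 0:11, y = 0:11, z = 0:11)
  dmm <- array(0, c(d3, 3))
  dmm[, , , 1] <- 0.1 * g$x; dmm[, , , 2] <- 0.1 * g$y; dmm[, , , 3] <- 0.1 * g$z
  jd <- jacobian_determinant(displacement_field(dmm))
  expect_equal(max(abs(flow4d:::interior(jd) - 1.1^3)), 0, tolerance = 1e-6)
})
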