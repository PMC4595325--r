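test_that("PCA plane fitting recovers exact and noisy planes and rejects degenerate input", {
  set.seed(51)
  uv <- as.matrix(expand.grid(u = seq(-10, 10, 2), v = seq(-10, 10, 2)))
  pts <- cbind(uv[, 1] + 3, uv[, 2] - 1, rep(5, nrow(uv)))
  p <- fit_plane_pca(pts, ref_normal = c(0, 0, 1))
  expect_gte(abs(sum(p$normal * c(0, 0, 1))), 0.999)
  expect_equal(p$origin[3], 5, tolerance = 1e-9)
  # sign follows the reference normal
  p2 <- fit_plane_pca(pts, ref_normal = c(0, 0, -1))
  expect_lt(sum(p2$normal * c(0, 0, 1)), 0)
  # noisy tilted plane: oracle = svd of the centred points
  nrm <- c(1, 2, 2) / 3
  b1 <- c(2, -1, 0) / sqrt(5); b2 <- c(nrm[2] * b1[3] - nrm[3] * b1[2],
                                       nrm[3] * b1[1] - nrm[1] * b1[3],
                                       nrm[1] * b1[2] - nrm[2] * b1[1])
  ptsn <- uv[, 1] %o% b1 + uv[, 2] %o% b2 +
    matrix(rnorm(3 * nrow(uv), sd = 0.1), ncol = 3)
  pn <- fit_plane_pca(ptsn, ref_normal = nrm)
  sv <- svd(sweep(ptsn, 2, colMeans(ptsn)))
  expect_gte(abs(sum(pn$normal * sv$v[, 3])), 1 - 1e-9)
  expect_gte(abs(sum(pn$normal * nrm)), 0.995)
  expect_error(fit_plane_pca(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("disk-filter mask smoothing rounds and enlarges but never shrinks", {
  expect_true(all(!smooth_plane_mask(matrix(FALSE, 30, 30))))
  # centred disk of radius 10 px grows into a disk of radius in [10, 19]
  g <- expand.grid(i = 1:61, j = 1:61)
  disk <- matrix((g$i - 31)^2 + (g$j - 31)^2 <= 100, 61, 61)
  sm <- smooth_plane_mask(disk, radius_px = 9, keep_frac = 0.1)
  # oracle: brute-force convolution with the normalized disk kernel
  k <- flow4d:::disk_kernel(9)
  conv <- matrix(0, 61, 61)
  for (ii in 1:61) for (jj in 1:61) {
    acc <- 0
    for (a in -9:9) for (b in -9:9) {
      if (k[a + 10, b + 10] == 0) next
      ia <- ii + a; jb <- jj + b
      if (ia >= 1 && ia <= 61 && jb >= 1 && jb <= 61 && disk[ia, jb]) acc <- acc + k[a + 10, b + 10]
    }
    conv[ii, jj] <- acc
  }
  expect_identical(sm, (conv >= 0.1 - 1e-12) | disk)
  rad <- sqrt(sum(sm) / pi)
  expect_gte(rad, 10); expect_lte(rad, 19)
  expect_true(all(sm[disk]))
  # never shrinks on 50 random blob masks
  set.seed(52)
  for (r in 1:50) {
    m <- matrix(FALSE, 40, 40)
    nb <- sample(1:4, 1)
    for (b in seq_len(nb)) {
      c0 <- sample(8:32, 2); rr <- sample(3:7, 1)
      gg <- expand.grid(i = 1:40, j = 1:40)
      m <- m | matrix((gg$i - c0[1])^2 + (gg$j - c0[2])^2 <= rr^2, 40, 40)
    }
    expect_gte(sum(smooth_plane_mask(m)), sum(m))
  }
})

test_that("plane sampling interpolates constants exactly and fails off-grid", {
  d <- c(12L, 12L, 12L, 2L)
  v0 <- c(10, -20, 35)
  fl <- flow_from_vel(array(v0[1], d), array(v0[2], d), array(v0[3], d),
                      magnitude = array(1, d))
  seg <- segmentation4d(array(1L, d), 1L)
  pl <- flow_plane("p", c(5.5, 5.5, 5.5), c(0, 0, 1), extent = c(3, 3))
  smp <- sample_plane(fl, seg, pl, vessel_code = 1L, spacing = 1)
  expect_true(all(abs(smp$velocity[, , 1, 1] - v0[1]) < 1e-9))
  expect_true(all(abs(smp$velocity[, , 2, 3] - v0[3]) < 1e-9))
  expect_true(all(smp$mask))
  far <- flow_plane("far", c(500, 500, 500), c(0, 0, 1), extent = c(3, 3))
  expect_error(sample_plane(fl, seg, far, vessel_code = 1L, spacing = 1),
               "outside")
})

test_that("flow rate and net volume have their closed forms", {
  mk_sample <- function(vn, mask, spacing = 1) {
    nu <- nrow(mask); nv <- ncol(mask)
    vel <- array(0, c(nu, nv, 1, 3)); vel[, , 1, 3] <- vn
    structure(list(velocity = vel, mask = array(mask, c(nu, nv, 1)),
                   normal = c(0, 0, 1), pixel_area = spacing^2,
                   spacing = spacing, plane_name = "m", vessel_code = 1L),
              class = "plane_sample")
  }
  s <- mk_sample(matrix(50, 10, 10), matrix(TRUE, 10, 10))
  expect_equal(flow_rate(s, 1), 50)            # 50 cm/s * 100 mm^2 * 0.01
  expect_equal(flow_rate(mk_sample(matrix(0, 5, 5), matrix(TRUE, 5, 5)), 1), 0)
  expect_warning(q0 <- flow_rate(mk_sample(matrix(3, 5, 5),
                                           matrix(FALSE, 5, 5)), 1), "empty")
  expect_equal(q0, 0)
  # linearity in velocity
  s2 <- s; s2$velocity <- 3 * s$velocity
  expect_equal(flow_rate(s2, 1), 3 * flow_rate(s, 1))
  # Poiseuille profile at 0.5 mm spacing vs the analytic v_max pi R^2 / 2
  sp <- 0.5
  uv <- expand.grid(u = seq(-14, 14, sp), v = seq(-14, 14, sp))
  r2 <- uv$u^2 + uv$v^2
  n1 <- length(seq(-14, 14, sp))
  vn <- matrix(ifelse(r2 <= 100, 100 * (1 - r2 / 100), 0), n1, n1)
  sP <- mk_sample(vn, matrix(r2 <= 100, n1, n1), spacing = sp)
  expect_equal(flow_rate(sP, 1), 100 * pi * 100 / 2 * 1e-2, tolerance = 0.03)

  expect_equal(net_flow_volume(rep(60, 20), 50), 60)
  expect_equal(net_flow_volume(rep(0, 7), 52.8), 0)
  # half-sine systole 0.3 s sampled every 52.8 ms vs the exact integral
  tm <- (1:20 - 0.5) * 0.0528
  q <- ifelse(tm <= 0.3, 157.08 * sin(pi * tm / 0.3), 0)
  expect_equal(net_flow_volume(q, 52.8), 2 * 157.08 * 0.3 / pi, tolerance = 0.05)
})

test_that("linear regression matches the explicit normal equations", {
  r1 <- linear_regression(1:10, 1:10)
  expect_equal(r1$slope, 1); expect_equal(r1$r_squared, 1)
  r2 <- linear_regression(1:10, 2 * (1:10) + 1)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)
  expect_equal(r2$r_squared, 1)
  set.seed(53)
  x <- rnorm(30); y <- 1.7 * x - 0.4 + rnorm(30, sd = 0.3)
  r3 <- linear_regression(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r3$slope, beta[2], tolerance = 1e-10)
  res <- y - X %*% beta
  se <- sqrt(sum(res^2) / 28 * solve(t(X) %*% X)[2, 2])
  p_oracle <- 2 * stats::pt(abs(beta[2] / se), df = 28, lower.tail = FALSE)
  expect_equal(r3$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(r3$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
})

test_that("Dice coefficient covers its closed forms", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
  expect_equal(dice_coefficient(a, b), 1 / 2 * 2 * 1 / 2)  # one shared of 2+2
  expect_equal(dice_coefficient(array(FALSE, c(2, 2, 1)),
                                array(FALSE, c(2, 2, 1))), 1)
  expect_error(dice_coefficient(a, array(TRUE, c(4, 1, 1))), "grid mismatch")
})
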