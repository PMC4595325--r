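test_that("static tissue is the low-variation shell, per the per-voxel std oracle", {
  d <- c(10L, 10L, 10L, 5L)
  mag <- array(2, d)
  vx <- array(0, d); vy <- array(0, d); vz <- array(0, d)
  mag[4:7, 4:7, , ] <- 100                       # vessel block, pulsatile
  mag[c(2, 9), , , ] <- 50; mag[, c(2, 9), , ] <- 50   # static shell
  for (t in 1:5) vz[4:7, 4:7, , t] <- 60 * sin(pi * t / 5)
  fl <- flow_from_vel(vx, vy, vz, magnitude = mag)
  st <- detect_static_tissue(fl, mag_frac = 0.1, vel_std_max = 2)
  # oracle: direct per-voxel temporal std of speed
  sp <- sqrt(matrix(fl$vx, ncol = 5)^2 + matrix(fl$vy, ncol = 5)^2 +
             matrix(fl$vz, ncol = 5)^2)
  sd_vox <- apply(sp, 1, stats::sd)
  magmean <- rowMeans(matrix(mag, ncol = 5))
  thr <- 0.1 * stats::quantile(magmean, 0.95, names = FALSE)
  expect_identical(as.vector(st$mask), magmean > 0 & magmean >= thr & sd_vox <= 2)
  expect_false(any(st$mask[4:7, 4:7, ]))
  expect_true(all(st$mask[2, , ]))
  expect_true(all(st$weights[!st$mask] == 0) && all(st$weights <= 1))
})

test_that("static-tissue limit and degenerate cases behave", {
  d <- c(6L, 6L, 6L, 3L)
  mag <- array(0, d); mag[2:5, 2:5, 2:5, ] <- 7
  fl <- flow_from_vel(array(30, d), array(0, d), array(0, d), magnitude = mag)
  st <- detect_static_tissue(fl, mag_frac = 0, vel_std_max = Inf)
  expect_identical(as.vector(st$mask), as.vector(mag[, , , 1] > 0))
  expect_true(all(st$weights[mag[, , , 1] > 0] == 1))
  fl0 <- flow_from_vel(array(0, d), array(0, d), array(0, d),
                       magnitude = array(0, d))
  expect_error(detect_static_tissue(fl0), "static tissue")
})

test_that("temporal unwrapping corrects aliased jumps and is idempotent", {
  mk <- function(series, venc = 120) {
    d <- c(1L, 1L, 1L, length(series))
    flow_from_vel(array(series, d), array(0, d), array(0, d), venc = venc)
  }
  un <- unwrap_temporal(mk(c(100, 110, -115)))
  expect_equal(as.vector(un$vx), c(100, 110, 125))
  s2 <- c(10, 40, 80, 110, 119)           # wrap-free: identity
  expect_equal(as.vector(unwrap_temporal(mk(s2))$vx), s2)
  # idempotence and 2*venc-multiple property on random aliased series
  set.seed(21)
  for (r in 1:20) {
    true <- cumsum(c(runif(1, -100, 100), runif(7, -110, 110)))
    wrapped <- ((true + 120) %% 240) - 120
    wrapped[1] <- true[1] - 240 * round((true[1]) / 240)  # anchor frame unaliased
    u1 <- as.vector(unwrap_temporal(mk(wrapped))$vx)
    u2 <- as.vector(unwrap_temporal(mk(u1))$vx)
    expect_equal(u1, u2)
    k <- (u1 - wrapped) / 240
    expect_equal(k, round(k), tolerance = 1e-9)
    expect_true(all(abs(diff(u1)) <= 120 + 1e-9))
  }
})

test_that("unwrapping matches the exhaustive minimum-jump oracle", {
  # oracle: search all per-frame corrections k in -2..2 (anchored at frame 1)
  # minimizing the total successive jump
  oracle <- function(v, venc = 120) {
    ks <- expand.grid(rep(list(-2:2), length(v) - 1L))
    best <- v; bestcost <- sum(pmax(abs(diff(v)) - venc, 0)) + sum(abs(diff(v)))
    for (i in seq_len(nrow(ks))) {
      cand <- v + c(0, 2 * venc * as.numeric(ks[i, ]))
      cost <- sum(abs(diff(cand)))
      if (cost < bestcost - 1e-9) { best <- cand; bestcost <- cost }
    }
    best
  }
  set.seed(22)
  for (r in 1:10) {
    true <- cumsum(c(runif(1, -110, 110), runif(3, -100, 100)))
    wrapped <- ((true + 120) %% 240) - 120
    wrapped[1] <- true[1]   # keep anchor unaliased (|true[1]| < venc)
    d <- c(1L, 1L, 1L, 4L)
    fl <- flow_from_vel(array(wrapped, d), array(0, d), array(0, d))
    expect_equal(as.vector(unwrap_temporal(fl)$vx), oracle(wrapped),
                 tolerance = 1e-9)
  }
})

test_that("background polynomial is recovered exactly on noise-free static tissue", {
  d3 <- c(12L, 12L, 12L)
  nt <- 4L
  B <- cbind(c(0.5, 0.01, 0, 0, 0, 0, -0.002, 0, 0, 0),
             c(-0.2, 0, 0.03, 0, 0.004, 0, 0, 0.001, 0, 0),
             c(0.1, 0, 0, -0.05, 0, 0.002, 0, 0, -0.003, 0))
  off <- flow4d:::poly2_design(d3) %*% B
  mk <- function(extra = 0) {
    arr <- function(c3) array(rep(off[, c3], nt), c(d3, nt)) + extra
    flow_from_vel(arr(1), arr(2), arr(3), magnitude = array(10, c(d3, nt)))
  }
  fl <- mk()
  st <- detect_static_tissue(fl, mag_frac = 0.1, vel_std_max = 5)
  bm <- fit_background(fl, st)
  expect_lt(max(abs(bm$coeffs - B)), 1e-6)
  # oracle: plain normal-equations solve on the exact design
  X <- flow4d:::poly2_design(d3)
  beta <- solve(crossprod(X), crossprod(X, rowMeans(matrix(fl$vx, ncol = nt))))
  expect_equal(unname(bm$coeffs[, 1]), as.vector(beta), tolerance = 1e-8)
  corr <- correct_background(fl, bm)
  expect_lt(max(abs(rowMeans(matrix(corr$vx, ncol = nt)))), 0.01)
  expect_identical(corr$magnitude, fl$magnitude)
  # zero offset -> all coefficients 0
  fl0 <- flow_from_vel(array(0, c(d3, nt)), array(0, c(d3, nt)),
                       array(0, c(d3, nt)), magnitude = array(10, c(d3, nt)))
  bm0 <- fit_background(fl0, detect_static_tissue(fl0, 0.1, 5))
  expect_lt(max(abs(bm0$coeffs)), 1e-9)
})

test_that("background correction is linear and never worsens static-tissue RMS", {
  d3 <- c(10L, 10L, 10L); nt <- 3L
  set.seed(23)
  noise <- array(rnorm(prod(d3) * nt, sd = 0.5), c(d3, nt))
  grad <- array(rep(flow4d:::poly2_design(d3) %*%
                      c(1, 0.2, -0.1, 0.05, 0, 0, 0, 0.01, 0, 0), nt), c(d3, nt))
  fl <- flow_from_vel(grad + noise, noise, -noise, magnitude = array(5, c(d3, nt)))
  st <- detect_static_tissue(fl, 0.1, Inf)
  bm <- fit_background(fl, st)
  corr <- correct_background(fl, bm)
  wrms <- function(f) {
    v <- rowMeans(matrix(f$vx, ncol = nt))
    w <- as.vector(st$weights)
    sqrt(sum(w * v^2) / sum(w))
  }
  expect_lte(wrms(corr), wrms(fl) + 1e-12)
  # constant model subtracts exactly that constant from every value
  bmc <- bm; bmc$coeffs[] <- 0; bmc$coeffs[1, ] <- c(2, -1, 0.5)
  cc <- correct_background(fl, bmc)
  expect_equal(cc$vx, fl$vx - 2, tolerance = 1e-12)
  expect_equal(cc$vy, fl$vy + 1, tolerance = 1e-12)
})

test_that("degenerate static sets make the background fit fail", {
  d3 <- c(8L, 8L, 8L); nt <- 2L
  z <- array(0, c(d3, nt))
  fl <- flow_from_vel(z, z, z, magnitude = array(1, c(d3, nt)))
  st <- detect_static_tissue(fl, 0, Inf)
  st$weights[] <- 0
  w9 <- st$weights; w9[1:9] <- 1
  st9 <- list(mask = w9 > 0, weights = w9)
  expect_error(fit_background(fl, st9), "at least 10")
  # coplanar voxels: rank-deficient design
  wpl <- st$weights; wpl[, , 4] <- 1
  stpl <- list(mask = wpl > 0, weights = wpl)
  expect_error(fit_background(fl, stpl), "rank")
})
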