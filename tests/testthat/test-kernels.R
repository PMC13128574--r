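# Compiled kernels against plain-R oracles and finite differences.

naive_conv3d <- function(x, w, b, stride, pad) {
  d <- dim(x); B <- d[1]; C <- d[2]; D <- d[3]; H <- d[4]; W <- d[5]
  wd <- dim(w); Co <- wd[1]; Ci <- wd[2]; kd <- wd[3]; kh <- wd[4]; kw <- wd[5]
  Do <- (D + 2 * pad[1] - kd) %/% stride[1] + 1
  Ho <- (H + 2 * pad[2] - kh) %/% stride[2] + 1
  Wo <- (W + 2 * pad[3] - kw) %/% stride[3] + 1
  y <- array(0, c(B, Co, Do, Ho, Wo))
  for (bb in 1:B) for (co in 1:Co) for (od in 1:Do) for (oh in 1:Ho)
    for (ow in 1:Wo) {
      acc <- b[co]
      for (ci in 1:Ci) for (i in 1:kd) for (j in 1:kh) for (k in 1:kw) {
        id <- (od - 1) * stride[1] + i - 1 - pad[1]
        ih <- (oh - 1) * stride[2] + j - 1 - pad[2]
        iw <- (ow - 1) * stride[3] + k - 1 - pad[3]
        if (id >= 0 && id < D && ih >= 0 && ih < H && iw >= 0 && iw < W)
          acc <- acc + x[bb, ci, id + 1, ih + 1, iw + 1] * w[co, ci, i, j, k]
      }
      y[bb, co, od, oh, ow] <- acc
    }
  y
}

test_that("conv3d forward matches a naive R convolution for all strides", {
  set.seed(1)
  x <- rand_vol(c(2, 3, 4, 5, 6))
  w <- array(rnorm(4 * 3 * 27), c(4, 3, 3, 3, 3))
  b <- rnorm(4)
  for (st in list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 2L, 2L))) {
    got <- anisoseg:::conv3d_fw_cpp(x, w, b, st, c(1L, 1L, 1L), 1L)
    expect_equal(got, naive_conv3d(x, w, b, st, c(1, 1, 1)), tolerance = 1e-12)
  }
  # depthwise path
  wg <- array(rnorm(3 * 9), c(3, 1, 1, 3, 3))
  got <- anisoseg:::conv3d_fw_cpp(x, wg, rep(0, 3), c(1L, 1L, 1L),
                                  c(0L, 1L, 1L), 3L)
  for (cc in 1:3) {
    ref <- naive_conv3d(x[, cc, , , , drop = FALSE],
                        array(wg[cc, 1, , , ], c(1, 1, 1, 3, 3)), 0,
                        c(1, 1, 1), c(0, 1, 1))
    expect_equal(got[, cc, , , ], ref[, 1, , , ], tolerance = 1e-12)
  }
})

test_that("conv3d backward matches finite differences", {
  set.seed(2)
  x <- rand_vol(c(1, 3, 3, 5, 5))
  w <- array(rnorm(2 * 3 * 9, sd = 0.5), c(2, 3, 1, 3, 3))
  b <- rnorm(2)
  st <- c(1L, 2L, 2L); pad <- c(0L, 1L, 1L)
  gy <- rand_vol(dim(anisoseg:::conv3d_fw_cpp(x, w, b, st, pad, 1L)))
  bw <- anisoseg:::conv3d_bw_cpp(x, w, gy, st, pad, 1L)
  f <- function(xx, ww, bb)
    sum(anisoseg:::conv3d_fw_cpp(xx, ww, bb, st, pad, 1L) * gy)
  eps <- 1e-6; base <- f(x, w, b)
  for (ii in c(4, 60, 150)) {
    xp <- x; xp[ii] <- xp[ii] + eps
    expect_equal((f(xp, w, b) - base) / eps, bw$gx[ii], tolerance = 1e-4)
  }
  for (ii in c(3, 40)) {
    wp <- w; wp[ii] <- wp[ii] + eps
    expect_equal((f(x, wp, b) - base) / eps, bw$gw[ii], tolerance = 1e-4)
  }
  bp <- b; bp[2] <- bp[2] + eps
  expect_equal((f(x, w, bp) - base) / eps, bw$gb[2], tolerance = 1e-4)
})

test_that("the fused directional scan matches projections + reference scan", {
  set.seed(3)
  L <- 9L; C <- 4L; S <- 2L; N <- 3L
  x <- array(rnorm(L * C * S), c(L, C, S))
  w <- selective_weights(C, N, seed = 7)
  ref <- sapply(seq_len(S), function(s)
    selective_scan_reference(matrix(x[, , s], L, C), w))
  got <- anisoseg:::dirscan_fw_cpp(x, w$w_delta, w$b_delta, w$W_B, w$b_B,
                                   w$W_C, w$b_C, w$A, FALSE)$y
  expect_equal(as.vector(got), as.vector(ref), tolerance = 1e-9)
})

test_that("the fused scan adjoint matches finite differences for every input", {
  set.seed(4)
  L <- 7L; C <- 3L; S <- 2L; N <- 4L
  x <- array(rnorm(L * C * S), c(L, C, S))
  w <- selective_weights(C, N, seed = 8)
  gy <- array(rnorm(L * C * S), c(L, C, S))
  fw <- anisoseg:::dirscan_fw_cpp(x, w$w_delta, w$b_delta, w$W_B, w$b_B,
                                  w$W_C, w$b_C, w$A, TRUE)
  bw <- anisoseg:::dirscan_bw_cpp(x, w$w_delta, w$b_delta, w$W_B, w$b_B,
                                  w$W_C, w$b_C, w$A,
                                  fw$delta, fw$Bm, fw$Cm, fw$H, gy)
  f <- function(x, w) sum(anisoseg:::dirscan_fw_cpp(
    x, w$w_delta, w$b_delta, w$W_B, w$b_B, w$W_C, w$b_C, w$A, FALSE)$y * gy)
  base <- f(x, w); eps <- 1e-7
  for (ii in c(1, 15, 30)) {
    xp <- x; xp[ii] <- xp[ii] + eps
    expect_equal((f(xp, w) - base) / eps, bw$gx[ii], tolerance = 1e-3)
  }
  fields <- list(w_delta = "gwd", b_delta = "gbd", W_B = "gWB", b_B = "gbB",
                 W_C = "gWC", b_C = "gbC", A = "gA")
  for (nm in names(fields)) {
    ii <- min(2, length(w[[nm]]))
    wp <- w; wp[[nm]][ii] <- wp[[nm]][ii] + eps
    expect_equal((f(x, wp) - base) / eps, bw[[fields[[nm]]]][ii],
                 tolerance = 1e-3)
  }
})

test_that("layer normalization kernel matches the R reference and finite differences", {
  set.seed(5)
  x <- rand_vol(c(2, 5, 3, 4, 4))
  gm <- runif(5, 0.5, 1.5); bt <- rnorm(5)
  expect_equal(anisoseg:::ag_layernorm(x, gm, bt),
               anisoseg:::ag_layernorm_r_reference(x, gm, bt),
               tolerance = 1e-12)
  gy <- rand_vol(dim(x))
  anisoseg:::ag_tape_begin()
  on.exit(anisoseg:::ag_tape_end())
  xn <- anisoseg:::ag_leaf(x); gn <- anisoseg:::ag_leaf(gm)
  bn <- anisoseg:::ag_leaf(bt)
  loss <- anisoseg:::ag_sum(anisoseg:::ag_mul(
    anisoseg:::ag_layernorm(xn, gn, bn), gy))
  anisoseg:::ag_backward(loss)
  f <- function(x, gm, bt) sum(anisoseg:::ag_layernorm_r_reference(x, gm, bt) * gy)
  base <- f(x, gm, bt); eps <- 1e-6
  for (ii in c(3, 100)) {
    xp <- x; xp[ii] <- xp[ii] + eps
    expect_equal((f(xp, gm, bt) - base) / eps, xn$grad[ii], tolerance = 1e-4)
  }
  gp <- gm; gp[2] <- gp[2] + eps
  expect_equal((f(x, gp, bt) - base) / eps, gn$grad[2], tolerance = 1e-4)
  bp <- bt; bp[4] <- bp[4] + eps
  expect_equal((f(x, gm, bp) - base) / eps, bn$grad[4], tolerance = 1e-4)
})
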