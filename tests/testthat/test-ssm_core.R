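# Discretized state-space model: zero-order hold, recurrence, kernel
# convolution, selective variant.

test_that("zero-order hold matches the scalar closed form and its limits", {
  # A = 0 limit: A_bar = 1, B_bar = delta * B
  p <- ssm_params(A = 0, B = 3, C_out = 1, delta = 0.7)
  dz <- discretize_zoh(p)
  expect_equal(dz$A_bar[1, 1], 1)
  expect_equal(dz$B_bar[1, 1], 0.7 * 3)

  # scalar closed form: A = -1, B = 1, delta = ln 2 -> A_bar = B_bar = 0.5
  p <- ssm_params(A = -1, B = 1, C_out = 1, delta = log(2))
  dz <- discretize_zoh(p)
  expect_equal(dz$A_bar[1, 1], 0.5)
  expect_equal(dz$B_bar[1, 1], 0.5)

  # delta -> 0: A_bar -> 1, B_bar -> 0
  p <- ssm_params(A = -2.5, B = 4, C_out = 1, delta = 1e-12)
  dz <- discretize_zoh(p)
  expect_equal(dz$A_bar[1, 1], 1, tolerance = 1e-9)
  expect_lt(abs(dz$B_bar[1, 1]), 1e-10)

  expect_error(ssm_params(A = -1, B = 1, C_out = 1, delta = 0),
               "strictly positive")
  expect_error(ssm_params(A = -1, B = 1, C_out = 1, delta = -1),
               "strictly positive")
})

test_that("ZOH agrees with the closed form on 1000 random draws incl. small |dA|", {
  set.seed(11)
  n <- 1000
  A <- -exp(runif(n, log(1e-10), log(10)))   # spans the small-argument regime
  B <- rnorm(n)
  delta <- exp(runif(n, log(1e-4), log(1)))
  p <- ssm_params(A = matrix(A, ncol = 1), B = matrix(B, ncol = 1),
                  C_out = matrix(1, n, 1), delta = delta)
  dz <- discretize_zoh(p)
  ref_A <- exp(delta * A)
  ref_B <- expm1(delta * A) / A * B      # cancellation-free closed form
  expect_equal(as.vector(dz$A_bar), ref_A, tolerance = 1e-12)
  expect_equal(as.vector(dz$B_bar), ref_B, tolerance = 1e-8)
  expect_true(all(dz$A_bar > 0 & dz$A_bar <= 1))  # A <= 0 => A_bar in (0, 1]
})

test_that("ssm_scan single-step and zero-input behaviour", {
  p <- ssm_params(A = matrix(c(-1, -2), 1), B = matrix(c(0.5, 1.5), 1),
                  C_out = matrix(c(2, -1), 1), delta = 0.3)
  expect_equal(ssm_scan(p, rep(0, 10)), rep(0, 10))
  dz <- discretize_zoh(p)
  y1 <- ssm_scan(p, 1)                      # L = 1
  expect_equal(y1, sum(p$C_out * dz$B_bar))
})

test_that("recurrence and kernel convolution are dual (100 random LTI draws)", {
  set.seed(21)
  for (L in c(1L, 8L, 64L)) {
    worst <- 0
    for (i in 1:100) {
      C <- sample(1:3, 1); N <- sample(1:8, 1)
      p <- ssm_params(A = -matrix(runif(C * N, 0.05, 3), C, N),
                      B = matrix(rnorm(C * N), C, N),
                      C_out = matrix(rnorm(C * N), C, N),
                      delta = runif(C, 0.01, 0.5))
      x <- matrix(rnorm(L * C), L, C)
      worst <- max(worst, max(abs(ssm_scan(p, x) - kernel_convolve(p, x))))
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("hand-unrolled geometric kernel: A_bar = 0.5 gives y = (1, .5, .25)", {
  # pick continuous parameters whose ZOH discretization is A_bar = 0.5,
  # B_bar = 1 with delta = 1
  A <- log(0.5)
  B <- A / (0.5 - 1)
  p <- ssm_params(A = A, B = B, C_out = 1, delta = 1)
  dz <- discretize_zoh(p)
  expect_equal(dz$A_bar[1, 1], 0.5)
  expect_equal(dz$B_bar[1, 1], 1)
  expect_equal(kernel_convolve(p, c(1, 0, 0)), c(1, 0.5, 0.25))
  # strongly contractive state: memoryless kernel, y ~ C B_bar x elementwise
  pm <- ssm_params(A = -1e4, B = 2, C_out = 3, delta = 1)
  x <- c(1, -2, 0.5)
  dzm <- discretize_zoh(pm)
  expect_equal(kernel_convolve(pm, x), 3 * dzm$B_bar[1, 1] * x, tolerance = 1e-12)
})

test_that("impulse response decays monotonically for stable A", {
  set.seed(5)
  # sign-definite readout: every mode contributes a positive decaying term
  p <- ssm_params(A = -matrix(runif(8, 0.1, 2), 1),
                  B = matrix(abs(rnorm(8)), 1),
                  C_out = matrix(abs(rnorm(8)), 1), delta = 0.2)
  y <- abs(ssm_scan(p, c(1, rep(0, 31))))
  expect_true(all(diff(y[-1]) <= 1e-12))
})

test_that("the scan is causal", {
  set.seed(6)
  p <- ssm_params(A = -matrix(runif(4, 0.1, 1), 2, 2),
                  B = matrix(rnorm(4), 2, 2), C_out = matrix(rnorm(4), 2, 2),
                  delta = c(0.1, 0.3))
  x <- matrix(rnorm(40), 20, 2)
  y <- ssm_scan(p, x)
  for (t in c(5, 13)) {
    x2 <- x; x2[t, ] <- x2[t, ] + rnorm(2)
    y2 <- ssm_scan(p, x2)
    expect_equal(y2[seq_len(t - 1), ], y[seq_len(t - 1), ])
    expect_false(isTRUE(all.equal(y2[t, ], y[t, ])))
  }
})

test_that("selective scan reduces to the LTI scan when projections are frozen", {
  set.seed(31)
  N <- 4L
  delta0 <- 0.17
  Bvec <- rnorm(N); Cvec <- rnorm(N); Avec <- -runif(N, 0.2, 2)
  w <- list(A = matrix(Avec, 1), w_delta = 0, b_delta = log(expm1(delta0)),
            W_B = matrix(0, 1, N), b_B = Bvec,
            W_C = matrix(0, 1, N), b_C = Cvec)
  p <- ssm_params(A = matrix(Avec, 1), B = matrix(Bvec, 1),
                  C_out = matrix(Cvec, 1), delta = delta0)
  x <- rnorm(24)
  expect_equal(selective_scan(x, w), ssm_scan(p, x), tolerance = 1e-6)
})

test_that("selective scan matches a per-step reference loop and handles edge cases", {
  set.seed(32)
  C <- 3L; N <- 5L; L <- 16L
  w <- selective_weights(C, N, seed = 99)
  x <- matrix(rnorm(L * C), L, C)
  expect_equal(selective_scan(x, w), selective_scan_reference(x, w),
               tolerance = 1e-10)
  # zero input, zero bias -> zero output
  w0 <- w; w0$b_B <- numeric(N); w0$b_C <- numeric(N)
  expect_equal(selective_scan(matrix(0, L, C), w0), matrix(0, L, C))
  # non-finite projected step size -> numeric error naming the index
  wpos <- w; wpos$w_delta <- abs(wpos$w_delta) + 0.1
  xbad <- x; xbad[3, 2] <- Inf
  expect_error(selective_scan(xbad, wpos), "non-finite step size")
})
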