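# Dice, weighted BCE and the composite / head-specific totals.

test_that("Dice loss hand values and limits", {
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0), epsilon = 0), 0.5)
  t <- c(1, 0, 1, 1, 0)
  expect_lt(dice_loss(t, t, epsilon = 1e-12), 1e-10)       # perfect overlap
  expect_gt(dice_loss(1 - t, t, epsilon = 1e-12), 1 - 1e-6) # disjoint sets
  expect_error(dice_loss(c(1, 0), c(1, 0, 1)), "shape mismatch")
  set.seed(1)
  for (i in 1:20) {
    p <- runif(30); tt <- rbinom(30, 1, 0.4)
    v <- dice_loss(p, tt)
    expect_gte(v, 0); expect_lt(v, 1)
  }
})

test_that("Dice gradient matches the closed form -2t^2/(t+p)^2", {
  # two-element reduction at eps = 0: single voxel with t = 1
  for (p0 in c(0.2, 0.5, 0.9)) {
    eps <- 1e-6
    fd <- (dice_loss(p0 + eps, 1, epsilon = 0) -
             dice_loss(p0 - eps, 1, epsilon = 0)) / (2 * eps)
    expect_equal(fd, -2 * 1 / (1 + p0)^2, tolerance = 1e-4)
  }
  # analytic gradient used by the tape agrees with finite differences
  set.seed(2)
  p <- runif(12, 0.05, 0.95); tt <- rbinom(12, 1, 0.5)
  anisoseg:::ag_tape_begin()
  pn <- anisoseg:::ag_leaf(p)
  anisoseg:::ag_backward(dice_loss(pn, tt, epsilon = 1e-6))
  g <- pn$grad
  anisoseg:::ag_tape_end()
  eps <- 1e-7
  for (ii in c(1, 7)) {
    pp <- p; pp[ii] <- pp[ii] + eps
    fd <- (dice_loss(pp, tt, epsilon = 1e-6) - dice_loss(p, tt, epsilon = 1e-6)) / eps
    expect_equal(fd, g[ii], tolerance = 1e-4)
  }
})

test_that("WBCE weights follow the printed two-branch form", {
  # W_f = 0.5: both branches give unit weights
  G <- c(1, 1, 0, 0)
  w <- wbce_weights(G)
  expect_equal(w$W_f, 0.5)
  expect_equal(w$W, rep(1, 4))
  # W_f = 0.25 (second branch): foreground 1/3, background 1
  G <- c(1, 0, 0, 0)
  w <- wbce_weights(G)
  expect_equal(w$W_f, 0.25)
  expect_equal(w$W, c(1 / 3, 1, 1, 1))
  # W_f = 0.75 (first branch, as printed): foreground 1, background 3
  G <- c(1, 1, 1, 0)
  w <- wbce_weights(G)
  expect_equal(w$W, c(1, 1, 1, 3))
  # single-class patch: all-ones fallback with a warning
  expect_warning(w <- wbce_weights(rep(0, 8)), "single-class")
  expect_equal(w$W, rep(1, 8))
})

test_that("weight mass ratio between classes follows W_f/(1-W_f)", {
  set.seed(3)
  for (i in 1:20) {
    G <- rbinom(200, 1, runif(1, 0.1, 0.9))
    if (mean(G) %in% c(0, 1)) next
    w <- wbce_weights(G)
    wf <- mean(G)
    r <- wf / (1 - wf)
    if (wf > 0.5) {
      expect_equal(unique(w$W[G == 1]), 1)
      expect_equal(unique(w$W[G == 0]), r)
    } else {
      expect_equal(unique(w$W[G == 1]), r)
      expect_equal(unique(w$W[G == 0]), 1)
    }
  }
})

test_that("WBCE hand values, linearity and bounds", {
  G <- c(1, 1, 0, 0)
  expect_lt(wbce_loss(G, G), 1e-6)                     # perfect prediction
  expect_equal(wbce_loss(rep(0.5, 4), G), log(2), tolerance = 1e-9)
  W <- c(2, 2, 2, 2)
  expect_equal(wbce_loss(rep(0.5, 4), G, W = W), 2 * log(2), tolerance = 1e-9)
  expect_error(wbce_loss(c(0.5, 0.5), c(1, 0, 1)), "shape mismatch")
})

test_that("both losses decrease as predictions move toward the target", {
  set.seed(4)
  for (i in 1:10) {
    G <- rbinom(50, 1, 0.4)
    if (mean(G) %in% c(0, 1)) next
    p0 <- runif(50, 0.05, 0.95)
    p1 <- p0 + 0.5 * (G - p0)            # halfway toward the target
    expect_lt(dice_loss(p1, G), dice_loss(p0, G))
    expect_lt(wbce_loss(p1, G), wbce_loss(p0, G))
  }
})

test_that("composite and total losses combine the terms as specified", {
  G <- c(1, 0, 1, 0); p <- c(1, 1, 0, 0)
  sp_d <- loss_spec(alpha = 1, beta = 0, epsilon = 1e-9)
  sp_w <- loss_spec(alpha = 0, beta = 1)
  sp_b <- loss_spec(alpha = 1, beta = 1, epsilon = 1e-9)
  expect_equal(composite_loss(p, G, sp_d), dice_loss(p, G, 1e-9))
  expect_equal(composite_loss(p, G, sp_w), wbce_loss(p, G))
  expect_equal(composite_loss(p, G, sp_b),
               dice_loss(p, G, 1e-9) + wbce_loss(p, G))
  expect_error(loss_spec(alpha = 0, beta = 0), "not both zero")
  expect_error(loss_spec(epsilon = 0), "positive")

  # affinity scheme: composite over the stacked 3-channel array
  set.seed(5)
  Ga <- array(rbinom(3 * 2 * 4 * 4, 1, 0.5), c(1, 3, 2, 4, 4))
  Ya <- array(runif(3 * 2 * 4 * 4, 0.1, 0.9), c(1, 3, 2, 4, 4))
  expect_equal(total_loss(Ya, Ga, loss_spec(scheme = "affinity")),
               composite_loss(Ya, Ga, loss_spec(scheme = "affinity")))
  expect_error(total_loss(Ya[, 1:2, , , , drop = FALSE],
                          Ga[, 1:2, , , , drop = FALSE],
                          loss_spec(scheme = "affinity")), "3 channels")

  # mask+boundary: sum of per-channel composites; perfect channels ~ 0
  Gm <- array(rbinom(2 * 2 * 4 * 4, 1, 0.5), c(1, 2, 2, 4, 4))
  expect_lt(total_loss(Gm, Gm, loss_spec(scheme = "mask_boundary")), 1e-5)
  # boundary term isolated: mask channel perfect
  Ym <- Gm
  Ym[1, 2, , , ] <- array(runif(2 * 4 * 4, 0.1, 0.9), c(2, 4, 4))
  sp <- loss_spec(scheme = "mask_boundary")
  lone <- composite_loss(Ym[, 2, , , , drop = FALSE],
                         Gm[, 2, , , , drop = FALSE], sp)
  expect_equal(total_loss(Ym, Gm, sp), lone +
                 composite_loss(Gm[, 1, , , , drop = FALSE],
                                Gm[, 1, , , , drop = FALSE], sp),
               tolerance = 1e-9)
})
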