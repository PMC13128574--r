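# Dice loss, foreground-proportion-weighted binary cross-entropy, and the
# composite / head-specific totals.  All losses accept plain arrays or
# autodiff nodes (the analytic gradients feed the training tape).

#' Loss specification
#'
#' @param alpha weight of the Dice term.
#' @param beta weight of the weighted-BCE term.
#' @param epsilon Dice smoothing factor.
#' @param scheme `"affinity"`: one composite loss over the stacked affinity
#'   channels; `"mask_boundary"`: the sum of composite losses over the
#'   semantic-mask and instance-boundary channels.
#' @param weights_from `"target"` computes the foreground proportion from the
#'   ground truth (stationary weights); `"prediction"` follows the
#'   literal prediction-based definition.
#' @export
loss_spec <- function(alpha = 1, beta = 1, epsilon = 1e-6,
                      scheme = c("affinity", "mask_boundary"),
                      weights_from = c("target", "prediction")) {
  scheme <- match.arg(scheme)
  weights_from <- match.arg(weights_from)
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0))
    stop("loss_spec: alpha and beta must be non-negative and not both zero")
  if (epsilon <= 0) stop("loss_spec: epsilon must be positive")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 scheme = scheme, weights_from = weights_from),
            class = "loss_spec")
}

#' Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(t) + sum(p) + eps)`, in `[0, 1)`.
#' The per-voxel gradient at `eps = 0` reduces to `-2 t^2 / (t + p)^2` in the
#' two-element reduction.
#'
#' @param p predicted probabilities in `[0, 1]` (array or autodiff node).
#' @param t targets in `{0, 1}` (soft targets permitted).
#' @param epsilon smoothing factor.
#' @export
dice_loss <- function(p, t, epsilon = 1e-6) {
  vp <- ag_value(p); vt <- ag_value(t)
  if (length(vp) != length(vt)) stop("dice_loss: shape mismatch")
  St <- sum(vt); Sp <- sum(vp); Spt <- sum(vp * vt)
  denom <- St + Sp + epsilon
  v <- 1 - (2 * Spt + epsilon) / denom
  if (!is_ag(p)) return(v)
  ag_node(v, list(p), function(g) {
    gp <- -g * (2 * vt * denom - (2 * Spt + epsilon)) / denom^2
    list(gp)
  })
}

#' Foreground-proportion weights for weighted BCE
#'
#' The foreground proportion `W_f = sum(G) / (D*H*W)` selects one of two
#' weighting branches: when `W_f > 0.5` the background voxels are weighted by
#' `W_f / (1 - W_f)` and foreground by 1; when `W_f <= 0.5` the foreground
#' voxels are weighted by `W_f / (1 - W_f)` and background by 1.  The two
#' branches agree (all-ones) at `W_f = 0.5`.  Single-class patches fall back
#' to all-ones weights with a warning.
#'
#' @param G binary target array.
#' @return list with `W` (per-voxel weights) and `W_f`.
#' @export
wbce_weights <- function(G) {
  G <- ag_value(G)
  W_f <- mean(G)
  if (W_f == 0 || W_f == 1) {
    warning("wbce_weights: single-class patch; falling back to unit weights")
    W <- if (is.null(dim(G))) rep(1, length(G)) else array(1, dim(G))
    return(list(W = W, W_f = W_f))
  }
  r <- W_f / (1 - W_f)
  W <- if (W_f > 0.5) G + r * (1 - G) else r * G + (1 - G)
  list(W = W, W_f = W_f)
}

#' Weighted binary cross-entropy
#'
#' Mean over voxels of `W_i * BCE(Y_i, G_i)` with the weight map of
#' [wbce_weights()] (or externally supplied weights); predictions are clamped
#' away from {0, 1}.
#'
#' @param Y predicted probabilities (array or autodiff node).
#' @param G binary targets.
#' @param W optional per-voxel weights; computed from `G` by default.
#' @param clamp probability clamp.
#' @export
wbce_loss <- function(Y, G, W = NULL, clamp = 1e-7) {
  vY <- ag_value(Y); vG <- ag_value(G)
  if (length(vY) != length(vG)) stop("wbce_loss: shape mismatch")
  if (is.null(W)) W <- wbce_weights(vG)$W
  n <- length(vY)
  Yc <- pmin(pmax(vY, clamp), 1 - clamp)
  if (!is.null(dim(vY))) dim(Yc) <- dim(vY)
  v <- sum(W * -(vG * log(Yc) + (1 - vG) * log(1 - Yc))) / n
  if (!is.finite(v)) stop("wbce_loss: non-finite loss value")
  if (!is_ag(Y)) return(v)
  ag_node(v, list(Y), function(g) {
    inside <- (vY > clamp) & (vY < 1 - clamp)
    gp <- g * W * (Yc - vG) / (Yc * (1 - Yc)) / n * inside
    list(gp)
  })
}

#' Composite segmentation loss
#'
#' `alpha * Dice + beta * WBCE`.
#'
#' @inheritParams wbce_loss
#' @param spec a [loss_spec()].
#' @export
composite_loss <- function(Y, G, spec = loss_spec()) {
  W <- if (spec$weights_from == "target") wbce_weights(ag_value(G))$W
       else wbce_weights(ag_value(Y))$W
  d <- dice_loss(Y, G, spec$epsilon)
  wb <- wbce_loss(Y, G, W = W)
  if (is_ag(d) || is_ag(wb))
    ag_add(ag_mul(d, spec$alpha), ag_mul(wb, spec$beta))
  else spec$alpha * d + spec$beta * wb
}

#' Head-specific total loss
#'
#' Affinity scheme: one composite loss over all affinity channels jointly.
#' Mask+boundary scheme: sum of the composite losses of the semantic-mask
#' channel and the instance-boundary channel.
#'
#' @param Y predicted probabilities, `(B, C, D, H, W)` (array or node).
#' @param G targets of the same shape.
#' @param spec a [loss_spec()]; `scheme` must match the channel count
#'   (3 for affinity, 2 for mask+boundary).
#' @export
total_loss <- function(Y, G, spec = loss_spec()) {
  dY <- dim(ag_value(Y))
  nc <- if (length(dY) == 5L) dY[2] else stop("total_loss: expected a 5-axis array")
  if (spec$scheme == "affinity") {
    if (nc != 3L) stop("total_loss: affinity scheme expects 3 channels")
    composite_loss(Y, ag_value(G), spec)
  } else {
    if (nc != 2L) stop("total_loss: mask_boundary scheme expects 2 channels")
    vG <- ag_value(G)
    lm <- composite_loss(ag_chan_slice(Y, 1L), vG[, 1L, , , , drop = FALSE], spec)
    lb <- composite_loss(ag_chan_slice(Y, 2L), vG[, 2L, , , , drop = FALSE], spec)
    if (is_ag(lm) || is_ag(lb)) ag_add(lm, lb) else lm + lb
  }
}
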