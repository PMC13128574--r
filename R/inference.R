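# Sliding-window prediction with Gaussian-weighted blending of overlapping
# patches, mitigating boundary artifacts on large volumes.

#' Plan a sliding-window tiling
#'
#' Window corner positions cover every voxel; the last window per axis is
#' clamped to the volume edge.  Positions are sorted lexicographically.
#'
#' @param volume_shape `(D, H, W)` extents.
#' @param patch window extents `(D, H, W)`.
#' @param stride step between window corners, `<= patch` per axis.
#' @param blend_sigma_fraction Gaussian sigma as a fraction of the patch
#'   extent per axis.
#' @return list of class `tiling_plan` with 1-based corner `positions`.
#' @export
plan_tiling <- function(volume_shape, patch = c(8L, 256L, 256L),
                        stride = c(4L, 128L, 128L),
                        blend_sigma_fraction = 1 / 8) {
  patch <- as.integer(patch); stride <- as.integer(stride)
  if (any(stride <= 0L)) stop("plan_tiling: stride must be positive")
  if (any(stride > patch)) stop("plan_tiling: stride must not exceed the patch")
  vs <- as.integer(volume_shape)
  pad <- pmax(patch - vs, 0L)           # reflective padding if volume < patch
  padded <- vs + pad
  axis_pos <- function(n, p, s) {
    pos <- seq.int(1L, by = s, length.out = max(1L, ceiling((n - p) / s) + 1L))
    pos <- pmin(pos, n - p + 1L)
    sort(unique(pos))
  }
  pos <- expand.grid(d = axis_pos(padded[1], patch[1], stride[1]),
                     h = axis_pos(padded[2], patch[2], stride[2]),
                     w = axis_pos(padded[3], patch[3], stride[3]))
  pos <- pos[order(pos$d, pos$h, pos$w), , drop = FALSE]
  structure(list(patch = patch, stride = stride, volume_shape = vs,
                 pad = pad, positions = as.matrix(pos),
                 blend_sigma_fraction = blend_sigma_fraction),
            class = "tiling_plan")
}

#' Separable Gaussian blending weights for a patch
#'
#' Centered on the patch, normalized to peak 1, strictly positive.
#'
#' @param patch_shape `(D, H, W)` extents.
#' @param sigma_fraction sigma as a fraction of each extent.
#' @export
gaussian_weight <- function(patch_shape, sigma_fraction = 1 / 8) {
  stopifnot(sigma_fraction > 0)
  axis_w <- function(n) {
    c0 <- (n - 1) / 2
    w <- exp(-((seq_len(n) - 1 - c0)^2) / (2 * (sigma_fraction * n)^2))
    w / max(w)
  }
  wd <- axis_w(patch_shape[1]); wh <- axis_w(patch_shape[2]); ww <- axis_w(patch_shape[3])
  outer(outer(wd, wh), ww)
}

reflect_pad <- function(vol, pad) {
  for (ax in 1:3) {
    if (pad[ax] == 0L) next
    n <- dim(vol)[ax]
    ref <- if (n == 1L) rep(1L, pad[ax]) else
      rep(c(seq.int(n - 1L, 1L), seq.int(2L, n)), length.out = pad[ax])
    idx <- c(seq_len(n), ref[seq_len(pad[ax])])
    vol <- switch(ax, vol[idx, , , drop = FALSE], vol[, idx, , drop = FALSE],
                  vol[, , idx, drop = FALSE])
  }
  vol
}

#' Gaussian-blended sliding-window prediction
#'
#' Accumulates `sum(w * sigmoid(logits)) / sum(w)` over all windows of the
#' plan.  The per-voxel weight sum is strictly positive, so a model emitting
#' a constant logit yields exactly the constant probability (the weights
#' normalize out), and the result is independent of window visitation order
#' up to floating-point accumulation.
#'
#' @param model either a built network (see [build_network()]) or a function
#'   mapping a `(1, 1, D, H, W)` patch to logits `(1, C, D, H, W)`.
#' @param volume `(D, H, W)` image array.
#' @param plan a [plan_tiling()]; defaults to the plan for this volume.
#' @param verbose log the running probability range.
#' @return probability array `(C, D, H, W)` in `[0, 1]`.
#' @export
blended_predict <- function(model, volume, plan = NULL, verbose = FALSE) {
  if (is.null(plan)) plan <- plan_tiling(dim(volume))
  fwd <- if (is.function(model)) model else function(p) net_forward(model, p)
  p <- plan$patch
  vol <- reflect_pad(volume, plan$pad)
  w <- gaussian_weight(p, plan$blend_sigma_fraction)
  at1 <- plan$positions[1, ]
  first <- fwd(array(vol[at1[1]:(at1[1] + p[1] - 1L),
                         at1[2]:(at1[2] + p[2] - 1L),
                         at1[3]:(at1[3] + p[3] - 1L)], c(1, 1, p)))
  nC <- dim(first)[2]
  acc <- array(0, c(nC, dim(vol)))
  den <- array(0, dim(vol))
  for (i in seq_len(nrow(plan$positions))) {
    at <- plan$positions[i, ]
    di <- at[1]:(at[1] + p[1] - 1L)
    hi <- at[2]:(at[2] + p[2] - 1L)
    wi <- at[3]:(at[3] + p[3] - 1L)
    logits <- if (i == 1L) first else
      fwd(array(vol[di, hi, wi], c(1, 1, p)))
    if (any(!is.finite(logits)))
      stop(sprintf("blended_predict: non-finite logits in window %d", i))
    pr <- 1 / (1 + exp(-logits))
    for (cc in seq_len(nC))
      acc[cc, di, hi, wi] <- acc[cc, di, hi, wi] + w * pr[1, cc, , , ]
    den[di, hi, wi] <- den[di, hi, wi] + w
    if (verbose)
      message(sprintf("window %d/%d  prob range [%.4f, %.4f]",
                      i, nrow(plan$positions), min(pr), max(pr)))
  }
  out <- acc / rep(den, each = nC)
  dim(out) <- c(nC, dim(vol))
  out[, seq_len(plan$volume_shape[1]), seq_len(plan$volume_shape[2]),
      seq_len(plan$volume_shape[3]), drop = FALSE]
}
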