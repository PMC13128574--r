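# Composite building blocks: channel attention, the residual visual
# state-space module (RVSSM), residual convolution blocks, the anisotropic
# (SAA) and isotropic (SIA) adaptation modules, and down-/up-sampling.
#
# Each block is a list(kind, cfg, params).  Forward functions accept the
# parameter subtree either as plain arrays (inference) or as autodiff leaf
# nodes (training); the ag_* primitives dispatch on the input type.

init_conv_params <- function(cin, cout, kernel, groups = 1L) {
  fan_in <- (cin / groups) * prod(kernel)
  list(w = array(rnorm(cout * (cin / groups) * prod(kernel), sd = sqrt(2 / fan_in)),
                 c(cout, cin / groups, kernel)),
       b = numeric(cout))
}

init_ln_params <- function(channels) list(g = rep(1, channels), b = numeric(channels))

# one directional selective-scan parameter set (see selective_weights())
init_dir_params <- function(channels, N, delta_range = c(1e-3, 1e-1),
                            with_C = TRUE) {
  dt0 <- exp(runif(channels, log(delta_range[1]), log(delta_range[2])))
  p <- list(
    A = -matrix(rep(as.numeric(seq_len(N)), each = channels), channels, N),
    w_delta = rnorm(channels, sd = 0.1),
    b_delta = log(expm1(dt0)),
    W_B = matrix(rnorm(channels * N, sd = 1 / sqrt(channels)), channels, N),
    b_B = numeric(N))
  if (with_C) {
    p$W_C <- matrix(rnorm(channels * N, sd = 1 / sqrt(channels)), channels, N)
    p$b_C <- numeric(N)
  }
  p
}

# ---- directional scan on the tape --------------------------------------

# x: (L,C,S) sequence (array or node); p: directional params; pC: params
# holding W_C/b_C (may be p itself, or shared between directions)
dir_scan_fwd <- function(p, pC, x) {
  ag_dirscan(x, list(w_delta = p$w_delta, b_delta = p$b_delta,
                     W_B = p$W_B, b_B = p$b_B,
                     W_C = pC$W_C, b_C = pC$b_C, A = p$A))
}

# scan a (B,C,D,H,W) tensor (array or node) along direction `dir`
vol_dir_scan <- function(p, pC, x, dir, shape) {
  code <- scan_dir_code(dir)
  xs <- ag_scan_perm(x, shape, code, scan_seq_dims(shape, dir))
  ys <- dir_scan_fwd(p, pC, xs)
  ag_scan_unperm(ys, shape, code)
}

# ---- VSSM ---------------------------------------------------------------

make_vssm <- function(channels, scan_kind, N = 16L, expand = 2L,
                      orders = c("dhw", "whd")) {
  E <- channels * expand
  p <- list(
    proj_main = init_conv_params(channels, E, c(1L, 1L, 1L)),
    proj_gate = init_conv_params(channels, E, c(1L, 1L, 1L)),
    dw = init_conv_params(E, E, c(1L, 3L, 3L), groups = E),
    ln_s = init_ln_params(E),
    proj_out = init_conv_params(E, channels, c(1L, 1L, 1L)))
  if (scan_kind == "2d-expanded") {
    p$dirs <- lapply(.scan_dirs_planar, function(d) init_dir_params(E, N))
    names(p$dirs) <- .scan_dirs_planar
  } else if (scan_kind == "bidirectional") {
    p$fwd <- init_dir_params(E, N, with_C = FALSE)
    p$bwd <- init_dir_params(E, N, with_C = FALSE)
    p$shared_C <- list(W_C = matrix(rnorm(E * N, sd = 1 / sqrt(E)), E, N),
                       b_C = numeric(N))
  } else if (scan_kind == "3d-expanded") {
    p$dir <- init_dir_params(E, N)
  } else stop(sprintf("unknown scan kind '%s'", scan_kind))
  list(kind = "vssm", params = p,
       cfg = list(channels = channels, E = E, scan_kind = scan_kind,
                  N = N, order = orders[1]))
}

fwd_vssm <- function(p, cfg, x) {
  shp <- dim(ag_value(x))
  E <- cfg$E
  main <- ag_conv3d(x, p$proj_main$w, p$proj_main$b)
  gate <- ag_conv3d(x, p$proj_gate$w, p$proj_gate$b)
  main <- ag_silu(ag_conv3d(main, p$dw$w, p$dw$b, groups = E))
  sshape <- c(shp[1], E, shp[3], shp[4], shp[5])
  y <- switch(cfg$scan_kind,
    "2d-expanded" = {
      acc <- NULL
      for (d in .scan_dirs_planar) {
        yd <- vol_dir_scan(p$dirs[[d]], p$dirs[[d]], main, d, sshape)
        acc <- if (is.null(acc)) yd else ag_add(acc, yd)
      }
      ag_mul(acc, 0.25)
    },
    "bidirectional" = ag_add(
      vol_dir_scan(p$fwd, p$shared_C, main, "z-forward", sshape),
      vol_dir_scan(p$bwd, p$shared_C, main, "z-backward", sshape)),
    "3d-expanded" = vol_dir_scan(p$dir, p$dir, main, cfg$order, sshape))
  y <- ag_layernorm(y, p$ln_s$g, p$ln_s$b)
  out <- ag_mul(y, ag_silu(gate))
  ag_conv3d(out, p$proj_out$w, p$proj_out$b)
}

# ---- channel attention --------------------------------------------------

#' Create a channel-attention (squeeze-excite style) block
#'
#' Global average pool over the spatial axes, a two-layer bottleneck with
#' reduction ratio `reduction`, sigmoid gates in (0,1), and channel-wise
#' rescaling of the input.
#'
#' @param channels number of input channels; must be `>= reduction`.
#' @param reduction bottleneck reduction ratio.
#' @export
make_channel_attention <- function(channels, reduction = 4L) {
  if (channels < reduction)
    stop("channel_attention: channels must be >= reduction")
  Cr <- max(1L, channels %/% reduction)
  list(kind = "channel_attention",
       params = list(
         W1 = matrix(rnorm(channels * Cr, sd = 1 / sqrt(channels)), channels, Cr),
         b1 = numeric(Cr),
         W2 = matrix(rnorm(Cr * channels, sd = 1 / sqrt(Cr)), Cr, channels),
         b2 = numeric(channels)),
       cfg = list(channels = channels, reduction = reduction))
}

fwd_channel_attention <- function(p, cfg, x) {
  s <- ag_chan_pool(x)
  s <- ag_silu(ag_add_rowvec(ag_matmul(s, p$W1), p$b1))
  s <- ag_sigmoid(ag_add_rowvec(ag_matmul(s, p$W2), p$b2))
  ag_chan_scale(x, s)
}

#' Apply a channel-attention block
#'
#' @param f a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param block a block from [make_channel_attention()].
#' @return array of the input shape; the output/input ratio is constant over
#'   space within each channel.
#' @export
channel_attention <- function(f, block) {
  fwd_channel_attention(block$params, block$cfg, vol_data(f))
}

# ---- RVSSM --------------------------------------------------------------

#' Create a residual visual state-space module (RVSSM)
#'
#' Stage 1: layer-normalize, apply the gated selective-scan VSSM routed
#' through the configured scanning strategy, add a skip connection.
#' Stage 2: layer-normalize, apply channel attention, add a skip connection.
#'
#' @param channels feature channels.
#' @param scan_kind `"2d-expanded"`, `"3d-expanded"` or `"bidirectional"`.
#' @param N state dimension of the selective scan.
#' @param order volumetric axis order for `"3d-expanded"`.
#' @param reduction channel-attention reduction ratio.
#' @param ssm_off if `TRUE` both inner branches are dropped and the module
#'   is the identity (ablation baseline).
#' @export
make_rvssm <- function(channels, scan_kind, N = 16L, order = "dhw",
                       reduction = 4L, ssm_off = FALSE) {
  params <- if (ssm_off) list() else list(
    ln1 = init_ln_params(channels),
    vssm = make_vssm(channels, scan_kind, N, orders = order)$params,
    ln2 = init_ln_params(channels),
    ca = make_channel_attention(channels, reduction)$params)
  list(kind = "rvssm", params = params,
       cfg = list(channels = channels, scan_kind = scan_kind, N = N,
                  E = channels * 2L, order = order, reduction = reduction,
                  ssm_off = ssm_off))
}

fwd_rvssm <- function(p, cfg, x) {
  if (isTRUE(cfg$ssm_off)) return(x)
  h <- ag_add(fwd_vssm(p$vssm, cfg, ag_layernorm(x, p$ln1$g, p$ln1$b)), x)
  ag_add(fwd_channel_attention(p$ca, cfg, ag_layernorm(h, p$ln2$g, p$ln2$b)), h)
}

#' Apply an RVSSM block
#' @param f a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param block a block from [make_rvssm()].
#' @export
rvssm <- function(f, block) fwd_rvssm(block$params, block$cfg, vol_data(f))

# ---- convolution blocks -------------------------------------------------

# conv + layer norm + smooth gated activation
make_conv_block <- function(cin, cout, kernel) {
  list(kind = "conv_block",
       params = list(conv = init_conv_params(cin, cout, kernel),
                     ln = init_ln_params(cout)),
       cfg = list(cin = cin, cout = cout, kernel = kernel))
}

fwd_conv_block <- function(p, cfg, x, stride = c(1L, 1L, 1L)) {
  ag_silu(ag_layernorm(ag_conv3d(x, p$conv$w, p$conv$b, stride = stride),
                       p$ln$g, p$ln$b))
}

#' Create a residual convolution block
#'
#' conv -> norm -> activation -> conv -> norm, added to the input, then a
#' final activation; channels and spatial extents are preserved
#' (same-padding, odd kernels).
#'
#' @param channels input = output channels.
#' @param kernel length-3 kernel extents `(d, h, w)`, all odd; anisotropic
#'   choices are `c(1,3,3)` (in-plane) and `c(3,1,1)` (axial).
#' @export
make_residual_block <- function(channels, kernel = c(1L, 3L, 3L)) {
  if (any(kernel %% 2L == 0L)) stop("residual_block: kernel extents must be odd")
  list(kind = "residual_block",
       params = list(conv1 = init_conv_params(channels, channels, kernel),
                     ln1 = init_ln_params(channels),
                     conv2 = init_conv_params(channels, channels, kernel),
                     ln2 = init_ln_params(channels)),
       cfg = list(channels = channels, kernel = kernel))
}

fwd_residual_block <- function(p, cfg, x) {
  y <- ag_silu(ag_layernorm(ag_conv3d(x, p$conv1$w, p$conv1$b), p$ln1$g, p$ln1$b))
  y <- ag_layernorm(ag_conv3d(y, p$conv2$w, p$conv2$b), p$ln2$g, p$ln2$b)
  ag_silu(ag_add(y, x))
}

#' Apply a residual convolution block
#' @param f a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param block a block from [make_residual_block()].
#' @export
residual_block <- function(f, block) {
  x <- vol_data(f)
  if (dim(x)[2] != block$cfg$channels)
    stop("residual_block: channel mismatch")
  fwd_residual_block(block$params, block$cfg, x)
}

# ---- SAA / SIA ----------------------------------------------------------

#' Create an SSM-based anisotropic adaptation (SAA) module
#'
#' Two branches over the input: (1) RVSSM with planar four-direction
#' expanded scanning followed by a 1x3x3 convolution and a 1x3x3 residual
#' block (in-plane feature learning); (2) RVSSM with bidirectional depth
#' scanning followed by a 3x1x1 convolution and residual block (axial).
#' The branch outputs are concatenated to `2C` channels and a bare 1x1x1
#' convolution restores `C`.
#'
#' @param channels feature channels.
#' @param N selective-scan state dimension.
#' @param ssm_off drop the SSM branches (pure anisotropic-convolution
#'   ablation baseline).
#' @export
make_saa <- function(channels, N = 16L, ssm_off = FALSE) {
  list(kind = "saa",
       params = list(
         rv_plane = make_rvssm(channels, "2d-expanded", N, ssm_off = ssm_off)$params,
         conv_plane = make_conv_block(channels, channels, c(1L, 3L, 3L))$params,
         rs_plane = make_residual_block(channels, c(1L, 3L, 3L))$params,
         rv_axis = make_rvssm(channels, "bidirectional", N, ssm_off = ssm_off)$params,
         conv_axis = make_conv_block(channels, channels, c(3L, 1L, 1L))$params,
         rs_axis = make_residual_block(channels, c(3L, 1L, 1L))$params,
         fuse = init_conv_params(2L * channels, channels, c(1L, 1L, 1L))),
       cfg = list(channels = channels, N = N, ssm_off = ssm_off))
}

fwd_saa <- function(p, cfg, x) {
  C <- cfg$channels
  cfg_p <- list(channels = C, E = 2L * C, scan_kind = "2d-expanded",
                N = cfg$N, ssm_off = cfg$ssm_off)
  cfg_a <- modifyList(cfg_p, list(scan_kind = "bidirectional"))
  b1 <- fwd_rvssm(p$rv_plane, cfg_p, x)
  b1 <- fwd_conv_block(p$conv_plane, NULL, b1)
  b1 <- fwd_residual_block(p$rs_plane, NULL, b1)
  b2 <- fwd_rvssm(p$rv_axis, cfg_a, x)
  b2 <- fwd_conv_block(p$conv_axis, NULL, b2)
  b2 <- fwd_residual_block(p$rs_axis, NULL, b2)
  ag_conv3d(ag_concat_c(b1, b2), p$fuse$w, p$fuse$b)
}

#' Apply an SAA module
#' @param f a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param block a block from [make_saa()].
#' @export
saa_module <- function(f, block) fwd_saa(block$params, block$cfg, vol_data(f))

#' Create an SSM-based isotropic adaptation (SIA) module
#'
#' Two cascaded units, each an RVSSM with a volumetric expanded scan followed
#' by a 3x3x3 convolution and a 3x3x3 residual block; the two units use
#' different scan orders (depth-outermost, then width-outermost).
#'
#' @inheritParams make_saa
#' @param orders the two volumetric scan orders.
#' @export
make_sia <- function(channels, N = 16L, orders = c("dhw", "whd"),
                     ssm_off = FALSE) {
  unit <- function(ord) list(
    rv = make_rvssm(channels, "3d-expanded", N, order = ord, ssm_off = ssm_off)$params,
    conv = make_conv_block(channels, channels, c(3L, 3L, 3L))$params,
    rs = make_residual_block(channels, c(3L, 3L, 3L))$params)
  list(kind = "sia",
       params = list(u1 = unit(orders[1]), u2 = unit(orders[2])),
       cfg = list(channels = channels, N = N, orders = orders,
                  ssm_off = ssm_off))
}

fwd_sia <- function(p, cfg, x) {
  for (i in 1:2) {
    u <- if (i == 1) p$u1 else p$u2
    cfg_u <- list(channels = cfg$channels, E = 2L * cfg$channels,
                  scan_kind = "3d-expanded", N = cfg$N,
                  order = cfg$orders[i], ssm_off = cfg$ssm_off)
    x <- fwd_rvssm(u$rv, cfg_u, x)
    x <- fwd_conv_block(u$conv, NULL, x)
    x <- fwd_residual_block(u$rs, NULL, x)
  }
  x
}

#' Apply an SIA module
#' @param f a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param block a block from [make_sia()].
#' @export
sia_module <- function(f, block) fwd_sia(block$params, block$cfg, vol_data(f))

# ---- down/up-sampling ---------------------------------------------------

#' Create a strided-convolution down-sampling layer
#'
#' Spatial extents are divided by the stride (ceiling); the kernel is
#' `c(1,3,3)` when the depth stride is 1 and `c(3,3,3)` otherwise.
#'
#' @param cin,cout channel counts.
#' @param stride length-3 stride with entries in `{1, 2}`.
#' @export
make_downsample <- function(cin, cout, stride) {
  if (!all(stride %in% c(1L, 2L))) stop("downsample: stride entries must be 1 or 2")
  kernel <- if (stride[1] == 1L) c(1L, 3L, 3L) else c(3L, 3L, 3L)
  list(kind = "downsample",
       params = init_conv_params(cin, cout, kernel),
       cfg = list(cin = cin, cout = cout, stride = as.integer(stride),
                  kernel = kernel))
}

fwd_downsample <- function(p, cfg, x) {
  d <- dim(ag_value(x))
  if (any(d[3:5] < cfg$stride))
    stop("downsample: spatial extent smaller than stride")
  ag_conv3d(x, p$w, p$b, stride = cfg$stride)
}

#' Apply a down-sampling layer
#' @param f a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param block a block from [make_downsample()].
#' @export
downsample <- function(f, block) fwd_downsample(block$params, block$cfg, vol_data(f))

interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) { M[, 1] <- 1; return(M) }
  pos <- if (n_out == 1L) 0 else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  j0 <- pmin(floor(pos), n_in - 2)
  fr <- pos - j0
  for (i in seq_len(n_out)) {
    M[i, j0[i] + 1] <- M[i, j0[i] + 1] + (1 - fr[i])
    M[i, j0[i] + 2] <- M[i, j0[i] + 2] + fr[i]
  }
  M
}

# trilinear interpolation to target (D,H,W) via per-axis contractions
ag_trilinear <- function(x, target) {
  d <- dim(ag_value(x))
  for (ax in 3:5) {
    n_in <- dim(ag_value(x))[ax]
    n_out <- target[ax - 2]
    if (n_out == n_in) next
    M <- interp_matrix(n_in, n_out)
    perm <- c(setdiff(1:5, ax), ax)
    xp <- ag_aperm(x, perm)
    dp <- dim(ag_value(xp))
    xm <- ag_reshape(xp, c(prod(dp[1:4]), dp[5]))
    ym <- ag_matmul(xm, t(M))
    yp <- ag_reshape(ym, c(dp[1:4], n_out))
    x <- ag_aperm(yp, order(perm))
  }
  x
}

#' Create an up-sampling layer (trilinear + channel adjust)
#'
#' Trilinear interpolation (end-aligned, exact on affine ramps) to the target
#' extents, followed by a 1x1x1 convolution for channel adjustment.
#'
#' @param cin,cout channel counts.
#' @export
make_upsample <- function(cin, cout) {
  list(kind = "upsample",
       params = init_conv_params(cin, cout, c(1L, 1L, 1L)),
       cfg = list(cin = cin, cout = cout))
}

fwd_upsample <- function(p, cfg, x, target) {
  ag_conv3d(ag_trilinear(x, target), p$w, p$b)
}

#' Apply an up-sampling layer
#' @param f a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param block a block from [make_upsample()].
#' @param target length-3 target spatial extents `(D,H,W)`.
#' @export
upsample <- function(f, block, target) {
  fwd_upsample(block$params, block$cfg, vol_data(f), target)
}
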