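# Encoder / bottleneck / decoder assembly with skip connections, parameter
# bookkeeping, and the AdamW training step.

#' Network configuration
#'
#' @param in_channels input channels (1 for grayscale EM).
#' @param head `"affinity"` (3 nearest-neighbour affinity channels along
#'   z, y, x) or `"mask_boundary"` (semantic mask + instance boundary).
#' @param stage_widths four stage channel widths.  The default lands the
#'   model near the few-million-parameter scale.
#' @param ds_strides four down-sampling stride triples; the default keeps
#'   the depth axis at full resolution until the bottleneck, and includes a
#'   stride-1 third stage (no resolution change) exactly as scheduled.
#' @param patch_size training/inference patch `(D, H, W)`.
#' @param N selective-scan state dimension.
#' @param ssm_off build the convolution-only ablation baseline.
#' @return list of class `network_config`.
#' @export
network_config <- function(in_channels = 1L,
                           head = c("affinity", "mask_boundary"),
                           stage_widths = c(16L, 32L, 64L, 96L),
                           ds_strides = list(c(1L, 2L, 2L), c(1L, 2L, 2L),
                                             c(1L, 1L, 1L), c(2L, 2L, 2L)),
                           patch_size = c(8L, 256L, 256L),
                           N = 16L, ssm_off = FALSE) {
  head <- match.arg(head)
  stopifnot(length(stage_widths) == 4L, length(ds_strides) == 4L,
            prod(patch_size) > 0)
  out_channels <- if (head == "affinity") 3L else 2L
  structure(list(in_channels = as.integer(in_channels), head = head,
                 out_channels = out_channels,
                 stage_widths = as.integer(stage_widths),
                 ds_strides = lapply(ds_strides, as.integer),
                 patch_size = as.integer(patch_size), N = as.integer(N),
                 ssm_off = isTRUE(ssm_off)),
            class = "network_config")
}

check_patch_compat <- function(config, dhw) {
  s <- Reduce(`*`, config$ds_strides)  # cumulative stride per axis
  for (ax in 1:3)
    if (dhw[ax] %% s[ax] != 0L)
      stop(sprintf(
        "patch extent %d on axis %d is not divisible by the cumulative stride %d",
        dhw[ax], ax, s[ax]))
  invisible(TRUE)
}

#' Build the segmentation network
#'
#' Encoder: a stem convolution, three SAA modules with a skip connection at
#' each resolution, and three strided down-sampling layers following the
#' configured schedule (the stride-1 third stage changes channels only).
#' Bottleneck: an isotropic down-sample, two SIA modules with different
#' volumetric scan orders, an up-sample back, and an isotropic convolution
#' module.  Decoder: three anisotropic convolution (AC) modules consuming
#' the skips after trilinear up-sampling, and a head convolution.
#'
#' @param config a [network_config()].
#' @param seed integer seed; two builds with the same seed have identical
#'   parameters.
#' @return list of class `aniso_network` with `$blocks`, `$config`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  check_patch_compat(config, config$patch_size)
  set.seed(seed)
  w <- config$stage_widths
  N <- config$N; off <- config$ssm_off
  blocks <- list(
    stem = make_conv_block(config$in_channels, w[1], c(1L, 3L, 3L)),
    saa1 = make_saa(w[1], N, ssm_off = off),
    ds1 = make_downsample(w[1], w[2], config$ds_strides[[1]]),
    saa2 = make_saa(w[2], N, ssm_off = off),
    ds2 = make_downsample(w[2], w[3], config$ds_strides[[2]]),
    saa3 = make_saa(w[3], N, ssm_off = off),
    ds3 = make_downsample(w[3], w[4], config$ds_strides[[3]]),
    ds4 = make_downsample(w[4], w[4], config$ds_strides[[4]]),
    sia1 = make_sia(w[4], N, orders = c("dhw", "whd"), ssm_off = off),
    sia2 = make_sia(w[4], N, orders = c("dhw", "whd"), ssm_off = off),
    up_bn = make_upsample(w[4], w[4]),
    ic = list(kind = "ic",
              params = list(conv = make_conv_block(w[4], w[4], c(3L, 3L, 3L))$params,
                            rs = make_residual_block(w[4], c(3L, 3L, 3L))$params),
              cfg = list(channels = w[4])),
    up3 = make_upsample(w[4], w[3]),
    ac3 = make_ac(2L * w[3], w[3]),
    up2 = make_upsample(w[3], w[2]),
    ac2 = make_ac(2L * w[2], w[2]),
    up1 = make_upsample(w[2], w[1]),
    ac1 = make_ac(2L * w[1], w[1]),
    head = list(kind = "head",
                params = init_conv_params(w[1], config$out_channels, c(1L, 3L, 3L)),
                cfg = list()))
  structure(list(blocks = blocks, config = config, seed = seed),
            class = "aniso_network")
}

# anisotropic convolution module of the decoder: 1x3x3 conv + residual block
make_ac <- function(cin, cout) {
  list(kind = "ac",
       params = list(conv = make_conv_block(cin, cout, c(1L, 3L, 3L))$params,
                     rs = make_residual_block(cout, c(1L, 3L, 3L))$params),
       cfg = list(cin = cin, cout = cout))
}

fwd_ac <- function(p, cfg, x) {
  fwd_residual_block(p$rs, NULL, fwd_conv_block(p$conv, NULL, x))
}

# Full forward pass.  `params` mirrors model$blocks[[.]]$params, possibly
# wrapped as autodiff leaves.  Returns list(logits, skips).
network_forward <- function(model, params, x, want_skips = FALSE) {
  cfg <- model$config
  b <- model$blocks
  d <- dim(ag_value(x))
  check_patch_compat(cfg, d[3:5])
  if (d[2] != cfg$in_channels)
    stop(sprintf("input has %d channels, config expects %d", d[2], cfg$in_channels))
  x0 <- fwd_conv_block(params$stem, NULL, x)
  s1 <- fwd_saa(params$saa1, b$saa1$cfg, x0)
  x1 <- fwd_downsample(params$ds1, b$ds1$cfg, s1)
  s2 <- fwd_saa(params$saa2, b$saa2$cfg, x1)
  x2 <- fwd_downsample(params$ds2, b$ds2$cfg, s2)
  s3 <- fwd_saa(params$saa3, b$saa3$cfg, x2)
  s4 <- fwd_downsample(params$ds3, b$ds3$cfg, s3)
  bn <- fwd_downsample(params$ds4, b$ds4$cfg, s4)
  bn <- fwd_sia(params$sia1, b$sia1$cfg, bn)
  bn <- fwd_sia(params$sia2, b$sia2$cfg, bn)
  d4 <- dim(ag_value(s4))[3:5]
  bn <- fwd_upsample(params$up_bn, NULL, bn, d4)
  bn <- fwd_residual_block(params$ic$rs, NULL,
                           fwd_conv_block(params$ic$conv, NULL, bn))
  d3 <- dim(ag_value(s3))[3:5]
  u <- fwd_upsample(params$up3, NULL, bn, d3)
  u <- fwd_ac(params$ac3, NULL, ag_concat_c(u, s3))
  d2 <- dim(ag_value(s2))[3:5]
  u <- fwd_upsample(params$up2, NULL, u, d2)
  u <- fwd_ac(params$ac2, NULL, ag_concat_c(u, s2))
  d1 <- dim(ag_value(s1))[3:5]
  u <- fwd_upsample(params$up1, NULL, u, d1)
  u <- fwd_ac(params$ac1, NULL, ag_concat_c(u, s1))
  logits <- ag_conv3d(u, params$head$w, params$head$b)
  if (want_skips)
    list(logits = logits,
         skips = list(ag_value(s1), ag_value(s2), ag_value(s3), ag_value(s4)))
  else list(logits = logits)
}

model_params <- function(model) lapply(model$blocks, `[[`, "params")

#' Forward pass (inference)
#'
#' @param model an [build_network()] model.
#' @param patch numeric `(B, in_channels, D, H, W)` array (or
#'   [feature_volume()]); `H`, `W` must be divisible by the cumulative
#'   in-plane stride (8 by default) and `D` by the cumulative depth stride (2).
#' @param want_skips also return the four encoder skip tensors.
#' @return logits array `(B, out_channels, D, H, W)`, or a list with
#'   `logits` and `skips` when `want_skips = TRUE`.
#' @export
net_forward <- function(model, patch, want_skips = FALSE) {
  out <- network_forward(model, model_params(model), vol_data(patch),
                         want_skips = want_skips)
  if (want_skips) list(logits = ag_value(out$logits), skips = out$skips)
  else ag_value(out$logits)
}

#' Count trainable parameters
#'
#' @param model a built network.
#' @param per_stage also return the per-block breakdown.
#' @export
count_parameters <- function(model, per_stage = FALSE) {
  counts <- vapply(model$blocks, function(blk)
    sum(vapply(flatten_params(blk$params), length, integer(1))), integer(1))
  if (per_stage) list(total = sum(counts), per_stage = counts) else sum(counts)
}

flatten_params <- function(tree, prefix = "") {
  if (is.numeric(tree)) return(setNames(list(tree), prefix))
  out <- list()
  for (nm in names(tree))
    out <- c(out, flatten_params(tree[[nm]],
                                 if (prefix == "") nm else paste0(prefix, ".", nm)))
  out
}

wrap_params <- function(tree, registry, prefix = "") {
  if (is.numeric(tree)) {
    leaf <- ag_leaf(tree)
    registry[[prefix]] <- leaf
    return(leaf)
  }
  out <- vector("list", length(tree)); names(out) <- names(tree)
  for (nm in names(tree))
    out[[nm]] <- wrap_params(tree[[nm]], registry,
                             if (prefix == "") nm else paste0(prefix, ".", nm))
  out
}

set_flat_params <- function(tree, flat, prefix = "") {
  if (is.numeric(tree)) {
    v <- flat[[prefix]]
    if (!is.null(dim(tree))) dim(v) <- dim(tree)
    return(v)
  }
  for (nm in names(tree))
    tree[[nm]] <- set_flat_params(tree[[nm]], flat,
                                  if (prefix == "") nm else paste0(prefix, ".", nm))
  tree
}

#' Create AdamW optimizer state
#'
#' @param model the network to optimize.
#' @param lr learning rate.
#' @param beta1,beta2 moment decays.
#' @param eps numerical floor.
#' @param weight_decay decoupled weight decay.
#' @export
adamw_state <- function(model, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 1e-2) {
  flat <- flatten_params(model_params(model))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L,
       m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0))
}

#' One training step
#'
#' Runs a forward pass on the tape, evaluates the configured loss, runs the
#' backward pass, and applies one AdamW update.  Deterministic for a fixed
#' seed and single-threaded execution.
#'
#' @param model a built network (modified copy returned).
#' @param patch `(B, in_channels, D, H, W)` input array.
#' @param target `(B, out_channels, D, H, W)` binary target array.
#' @param spec a [loss_spec()]; its `scheme` must match the head.
#' @param opt optimizer state from [adamw_state()].
#' @return list with updated `model`, `opt` and the scalar `loss`.
#' @export
train_step <- function(model, patch, target, spec, opt) {
  registry <- new.env(parent = emptyenv())
  ag_tape_begin()
  on.exit(ag_tape_end(), add = TRUE)
  wrapped <- wrap_params(model_params(model), registry)
  out <- network_forward(model, wrapped, vol_data(patch))
  probs <- ag_sigmoid(out$logits)
  loss <- total_loss(probs, target, spec)
  loss_val <- ag_value(loss)
  if (!is.finite(loss_val))
    stop(sprintf("train_step: non-finite loss (%g); aborting", loss_val))
  ag_backward(loss)
  grads <- lapply(as.list(registry), function(n)
    if (is.null(n$grad)) n$value * 0 else n$grad)
  flat <- flatten_params(model_params(model))
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    step <- opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    flat[[nm]] <- flat[[nm]] - step - opt$lr * opt$weight_decay * flat[[nm]]
  }
  newp <- set_flat_params(model_params(model), flat)
  for (nm in names(model$blocks)) model$blocks[[nm]]$params <- newp[[nm]]
  list(model = model, opt = opt, loss = loss_val)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a plain-text JSON archive of the named parameter arrays
#' together with the network configuration.
#'
#' @param model a built network.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  flat <- flatten_params(model_params(model))
  payload <- list(
    config = unclass(model$config), seed = model$seed,
    params = lapply(flat, function(x)
      list(dim = if (is.null(dim(x))) length(x) else dim(x), data = as.vector(x))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- payload$config
  config <- network_config(in_channels = cf$in_channels, head = cf$head,
                           stage_widths = cf$stage_widths,
                           ds_strides = if (is.matrix(cf$ds_strides))
                             lapply(seq_len(nrow(cf$ds_strides)), function(i) cf$ds_strides[i, ])
                           else cf$ds_strides,
                           patch_size = cf$patch_size, N = cf$N,
                           ssm_off = isTRUE(cf$ssm_off))
  model <- build_network(config, seed = payload$seed)
  flat <- lapply(payload$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) > 1) dim(v) <- p$dim
    v
  })
  newp <- set_flat_params(model_params(model), flat)
  for (nm in names(model$blocks)) model$blocks[[nm]]$params <- newp[[nm]]
  model
}
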