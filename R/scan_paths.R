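# Directional scanning: permutation operators that unfold (B,C,D,H,W)
# feature volumes into 1D sequences and fold the processed sequences back.
#
# Index convention: 0-based reasoning, row-major in-plane; depth (D) is the
# axis of anisotropy; "row-forward" traverses each row left to right
# (x/W innermost), "col-forward" runs down each column (y/H innermost).

.scan_dirs_planar <- c("row-forward", "row-backward", "col-forward", "col-backward")
.scan_dirs_3d <- c("dhw", "whd")
.scan_dirs_bidir <- c("z-forward", "z-backward")

#' Construct a feature volume
#'
#' A 5-axis array `(batch, channel, depth, height, width)` with physical
#' voxel sizes `(z, y, x)` in nanometres.  Serial-section EM volumes are
#' anisotropic: the z (cutting axis) voxel size is typically 5-10x the
#' in-plane size.
#'
#' @param data numeric 5-d array `(B, C, D, H, W)`.
#' @param voxel_size numeric length-3 `(z, y, x)` in nm.
#' @export
feature_volume <- function(data, voxel_size = c(30, 6, 6)) {
  stopifnot(length(dim(data)) == 5L, all(dim(data) >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(data = data, voxel_size = voxel_size), class = "feature_volume")
}

vol_data <- function(vol) if (inherits(vol, "feature_volume")) vol$data else vol

.scan_cache <- new.env(parent = emptyenv())

# Returns list(idx, dims = c(L, C, S)) with idx a permutation such that
# seq_flat = vol_flat[idx]; sequence layout is (L, C, S), t fastest.
scan_index <- function(shape, dir) {
  key <- paste(c(shape, dir), collapse = "|")
  hit <- .scan_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- scan_index_cpp(as.integer(shape), scan_dir_code(dir))
  out <- list(idx = idx, dims = scan_seq_dims(shape, dir))
  .scan_cache[[key]] <- out
  out
}

scan_dir_code <- function(dir) {
  code <- match(dir, c("row-forward", "row-backward", "col-forward",
                       "col-backward", "dhw", "z-backward", "whd"))
  if (dir == "z-forward") code <- 5L
  if (is.na(code)) stop(sprintf("unknown scan direction '%s'", dir))
  code
}

scan_seq_dims <- function(shape, dir) {
  if (scan_dir_code(dir) <= 4L) c(shape[4] * shape[5], shape[2], shape[1] * shape[3])
  else c(shape[3] * shape[4] * shape[5], shape[2], shape[1])
}

scan_index_inverse <- function(shape, dir) {
  key <- paste(c(shape, dir, "inv"), collapse = "|")
  hit <- .scan_cache[[key]]
  if (!is.null(hit)) return(hit)
  inv <- invert_permutation_cpp(scan_index(shape, dir)$idx)
  .scan_cache[[key]] <- inv
  inv
}

#' Unfold a feature volume into ordered 1D sequences
#'
#' @param vol a [feature_volume()] or plain `(B,C,D,H,W)` array.
#' @param dir one of `"row-forward"`, `"row-backward"`, `"col-forward"`,
#'   `"col-backward"` (planar; one sequence per batch-and-slice),
#'   `"dhw"`, `"whd"` (volumetric axis orders), or `"z-forward"`,
#'   `"z-backward"` (depth-outermost bidirectional layout).
#' @return list with `x` (array `(L, channels, sequences)`), `dir`, `shape`.
#' @seealso [fold()] for the exact inverse.
#' @export
unfold <- function(vol, dir) {
  x <- vol_data(vol)
  shape <- dim(x)
  si <- scan_index(shape, dir)
  xs <- as.vector(x)[si$idx]
  dim(xs) <- si$dims
  list(x = xs, dir = dir, shape = shape)
}

#' Fold sequences back into a feature volume
#'
#' Exact inverse permutation of [unfold()]: `fold(unfold(v, d), d)` restores
#' `v` bitwise for every direction.
#'
#' @param seq a sequence batch as returned by [unfold()], or a plain
#'   `(L, channels, sequences)` array.
#' @param dir scanning direction used to unfold.
#' @param shape the `(B,C,D,H,W)` extents of the original volume.
#' @export
fold <- function(seq, dir = seq$dir, shape = seq$shape) {
  x <- if (is.list(seq)) seq$x else seq
  si <- scan_index(shape, dir)
  if (length(x) != prod(shape))
    stop("fold: sequence length does not match the target shape")
  v <- numeric(length(x))
  v[si$idx] <- as.vector(x)
  dim(v) <- shape
  v
}

apply_ssm <- function(ssm, x) {
  y <- ssm(x)
  if (!identical(dim(y), dim(x)))
    stop("scan: the sequence transform changed the sequence shape")
  y
}

#' Planar four-direction expanded scanning
#'
#' Every depth slice is independently unfolded along the four planar
#' directions, each sequence is processed by `ssm`, folded back, and the four
#' outputs are merged by arithmetic mean (keeping the activation scale
#' independent of the direction count).  No information crosses depth slices.
#'
#' @param vol a [feature_volume()] or `(B,C,D,H,W)` array.
#' @param ssm a sequence transform: function mapping an
#'   `(L, channels, sequences)` array to one of the same shape (identity and
#'   cumulative sums are useful test probes; [selective_scan()] in production).
#' @return array of the input shape.
#' @export
scan_2d_expanded <- function(vol, ssm) {
  x <- vol_data(vol)
  shape <- dim(x)
  acc <- array(0, shape)
  for (dir in .scan_dirs_planar)
    acc <- acc + fold(apply_ssm(ssm, unfold(x, dir)$x), dir, shape)
  acc / length(.scan_dirs_planar)
}

#' Volumetric expanded scanning
#'
#' Unfolds the entire volume in a single axis order so that the recurrence
#' propagates across slices (long-range volumetric context), applies `ssm`,
#' and folds back.
#'
#' @inheritParams scan_2d_expanded
#' @param order `"dhw"` (depth-outermost) or `"whd"` (width-outermost).
#' @export
scan_3d_expanded <- function(vol, ssm, order = "dhw") {
  x <- vol_data(vol)
  if (!order %in% .scan_dirs_3d)
    stop(sprintf("unknown volumetric scan order '%s'", order))
  shape <- dim(x)
  fold(apply_ssm(ssm, unfold(x, order)$x), order, shape)
}

#' Bidirectional depth scanning
#'
#' Runs a forward recursion over the depth-outermost unfolding and a backward
#' recursion over its reversal, then sums the two outputs
#' (`y_t = C(s_fwd + s_bwd)` when both recursions share the output
#' projection).
#'
#' @inheritParams scan_2d_expanded
#' @param ssm_fwd,ssm_bwd sequence transforms for the two directions
#'   (independent parameters sharing the output projection in production).
#' @export
scan_bidirectional <- function(vol, ssm_fwd, ssm_bwd) {
  x <- vol_data(vol)
  shape <- dim(x)
  fold(apply_ssm(ssm_fwd, unfold(x, "z-forward")$x), "z-forward", shape) +
    fold(apply_ssm(ssm_bwd, unfold(x, "z-backward")$x), "z-backward", shape)
}
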