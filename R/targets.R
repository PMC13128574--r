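# Conversion of instance label volumes to training targets.

#' Construct a label volume
#'
#' @param labels non-negative integer array `(D, H, W)`; 0 is background;
#'   instance ids need not be consecutive.
#' @param voxel_size physical `(z, y, x)` voxel size in nm.
#' @export
label_volume <- function(labels, voxel_size = c(30, 6, 6)) {
  stopifnot(length(dim(labels)) == 3L, all(is.finite(labels)), all(labels >= 0))
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "label_volume")
}

lab_data <- function(x) if (inherits(x, "label_volume")) x$labels else x

#' Nearest-neighbour affinity targets
#'
#' Channel `k` at voxel `v` is 1 iff `v` and its -1 neighbour along axis `k`
#' (1 = z, 2 = y, 3 = x) carry the same nonzero label; voxels without a
#' neighbour (volume face) get 0.
#'
#' @param lab a [label_volume()] or `(D, H, W)` integer array.
#' @return numeric array `(3, D, H, W)`.
#' @export
labels_to_affinities <- function(lab) {
  L <- lab_data(lab)
  d <- dim(L)
  aff <- array(0, c(3, d))
  if (d[1] > 1)
    aff[1, -1, , ] <- (L[-1, , ] == L[-d[1], , ]) & (L[-1, , ] > 0)
  if (d[2] > 1)
    aff[2, , -1, ] <- (L[, -1, ] == L[, -d[2], ]) & (L[, -1, ] > 0)
  if (d[3] > 1)
    aff[3, , , -1] <- (L[, , -1] == L[, , -d[3]]) & (L[, , -1] > 0)
  aff
}

# in-plane 4-neighbour different-label test, per slice
slice_boundary <- function(sl) {
  d <- dim(sl)
  b <- matrix(FALSE, d[1], d[2])
  if (d[1] > 1) {
    ne <- sl[-1, ] != sl[-d[1], ]
    b[-1, ] <- b[-1, ] | ne
    b[-d[1], ] <- b[-d[1], ] | ne
  }
  if (d[2] > 1) {
    ne <- sl[, -1] != sl[, -d[2]]
    b[, -1] <- b[, -1] | ne
    b[, -d[2]] <- b[, -d[2]] | ne
  }
  b & (sl > 0)
}

dilate_inplane <- function(b, iter) {
  d <- dim(b)
  for (i in seq_len(iter)) {
    nb <- b
    if (d[1] > 1) { nb[-1, ] <- nb[-1, ] | b[-d[1], ]; nb[-d[1], ] <- nb[-d[1], ] | b[-1, ] }
    if (d[2] > 1) { nb[, -1] <- nb[, -1] | b[, -d[2]]; nb[, -d[2]] <- nb[, -d[2]] | b[, -1] }
    b <- nb
  }
  b
}

#' Semantic mask + instance boundary targets
#'
#' Channel 1 is the foreground mask `(label > 0)`.  Channel 2 marks voxels
#' within `thickness` in-plane voxels of a different-label voxel (the
#' instance contour).  Boundaries are computed per z-slice because the depth
#' axis is several-fold coarser than the in-plane axes.
#'
#' @param lab a [label_volume()] or `(D, H, W)` integer array.
#' @param thickness in-plane boundary thickness in voxels (>= 1).
#' @return numeric array `(2, D, H, W)`.
#' @export
labels_to_mask_boundary <- function(lab, thickness = 1L) {
  stopifnot(thickness >= 1L)
  L <- lab_data(lab)
  d <- dim(L)
  out <- array(0, c(2, d))
  out[1, , , ] <- L > 0
  for (z in seq_len(d[1])) {
    b <- slice_boundary(L[z, , ])
    if (thickness > 1L) b <- dilate_inplane(b, thickness - 1L) & (L[z, , ] > 0)
    out[2, z, , ] <- b
  }
  out
}
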