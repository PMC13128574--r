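# Training-time augmentation: geometric transforms applied identically to
# image and labels (nearest-neighbour for labels), degradations applied to
# the image only.  Free 3D rotation is excluded because the depth axis is
# physically coarser; rotations are in-plane multiples of 90 degrees and
# elastic deformation is in-plane only.

.augment_ops <- c("rotation", "scaling", "flipping", "elastic",
                  "missing_parts", "missing_slices", "motion_blur",
                  "dislocation")

rotate90_once <- function(a) {
  # (z, y, x) -> (z, x, H - 1 - y): transpose in-plane then reverse the new
  # last axis
  d <- dim(a)
  out <- aperm(a, c(1, 3, 2))
  out[, , seq(d[2], 1)]
}

warp_inplane <- function(a, map_y, map_x, nearest) {
  # map_*: (H, W) source coordinates (fractional); same warp per slice
  d <- dim(a)
  y0 <- pmin(pmax(map_y, 1), d[2]); x0 <- pmin(pmax(map_x, 1), d[3])
  if (nearest) {
    yi <- round(y0); xi <- round(x0)
    idx <- cbind(as.vector(yi), as.vector(xi))
    out <- a
    for (z in seq_len(d[1])) {
      sl <- a[z, , ]
      out[z, , ] <- matrix(sl[idx], d[2], d[3])
    }
    out
  } else {
    yf <- floor(y0); xf <- floor(x0)
    yc <- pmin(yf + 1, d[2]); xc <- pmin(xf + 1, d[3])
    wy <- y0 - yf; wx <- x0 - xf
    out <- a
    for (z in seq_len(d[1])) {
      sl <- a[z, , ]
      v <- sl[cbind(as.vector(yf), as.vector(xf))] * (1 - wy) * (1 - wx) +
        sl[cbind(as.vector(yc), as.vector(xf))] * wy * (1 - wx) +
        sl[cbind(as.vector(yf), as.vector(xc))] * (1 - wy) * wx +
        sl[cbind(as.vector(yc), as.vector(xc))] * wy * wx
      out[z, , ] <- matrix(v, d[2], d[3])
    }
    out
  }
}

#' Apply the training augmentation pipeline
#'
#' Operations are applied in the order given.  `rotation` (in-plane multiple
#' of 90 degrees), `scaling` (in-plane zoom, factor U(0.9, 1.1)), `flipping`
#' (random in-plane axis) and `elastic` (smooth in-plane displacement field)
#' transform image and labels identically, with nearest-neighbour sampling
#' for labels.  `missing_parts` (zeroed in-plane rectangles),
#' `missing_slices` (whole z-slices zeroed), `motion_blur` (1D in-plane
#' kernel) and `dislocation` (one slice translated in-plane) degrade the
#' image only.  Deterministic per seed.
#'
#' @param image `(D, H, W)` intensity array.
#' @param labels `(D, H, W)` integer array or [label_volume()].
#' @param ops character vector, subset of the eight operations above.
#' @param seed integer seed.
#' @return list with transformed `image` and `labels`.
#' @export
augment <- function(image, labels, ops, seed = 1L) {
  lab <- lab_data(labels)
  stopifnot(identical(dim(image), dim(lab)))
  bad <- setdiff(ops, .augment_ops)
  if (length(bad))
    stop(sprintf("augment: unknown operation(s): %s", paste(bad, collapse = ", ")))
  set.seed(seed)
  d <- dim(image)
  for (op in ops) {
    if (op == "rotation") {
      k <- sample(0:3, 1)
      if (d[2] == d[3]) {
        for (i in seq_len(k)) { image <- rotate90_once(image); lab <- rotate90_once(lab) }
      }
    } else if (op == "scaling") {
      f <- runif(1, 0.9, 1.1)
      cy <- (1 + d[2]) / 2; cx <- (1 + d[3]) / 2
      gy <- matrix(seq_len(d[2]), d[2], d[3])
      gx <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
      my <- cy + (gy - cy) / f; mx <- cx + (gx - cx) / f
      image <- warp_inplane(image, my, mx, nearest = FALSE)
      lab <- warp_inplane(lab, my, mx, nearest = TRUE)
    } else if (op == "flipping") {
      ax <- sample(2:3, 1)
      image <- if (ax == 2) image[, seq(d[2], 1), , drop = FALSE] else
        image[, , seq(d[3], 1), drop = FALSE]
      lab <- if (ax == 2) lab[, seq(d[2], 1), , drop = FALSE] else
        lab[, , seq(d[3], 1), drop = FALSE]
    } else if (op == "elastic") {
      amp <- 2.5
      dy <- amp * smooth_field(d[2], d[3], cell = 16L)
      dx <- amp * smooth_field(d[2], d[3], cell = 16L)
      gy <- matrix(seq_len(d[2]), d[2], d[3])
      gx <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
      image <- warp_inplane(image, gy + dy, gx + dx, nearest = FALSE)
      lab <- warp_inplane(lab, gy + dy, gx + dx, nearest = TRUE)
    } else if (op == "missing_parts") {
      k <- sample(1:3, 1)
      for (i in seq_len(k)) {
        z <- sample(d[1], 1)
        hh <- sample(4:max(4, d[2] %/% 4), 1); ww <- sample(4:max(4, d[3] %/% 4), 1)
        y0 <- sample(d[2] - hh + 1, 1); x0 <- sample(d[3] - ww + 1, 1)
        image[z, y0:(y0 + hh - 1), x0:(x0 + ww - 1)] <- 0
      }
    } else if (op == "missing_slices") {
      k <- min(sample(1:2, 1), d[1])
      zs <- sample(d[1], k)
      image[zs, , ] <- 0
    } else if (op == "motion_blur") {
      len <- 5L
      horiz <- sample(c(TRUE, FALSE), 1)
      kern <- rep(1 / len, len)
      half <- len %/% 2
      for (z in seq_len(d[1])) {
        sl <- image[z, , ]
        pad <- if (horiz)
          cbind(sl[, rep(1, half)], sl, sl[, rep(d[3], half)])
        else rbind(sl[rep(1, half), ], sl, sl[rep(d[2], half), ])
        out <- sl * 0
        for (j in seq_len(len))
          out <- out + kern[j] * (if (horiz) pad[, j:(j + d[3] - 1)]
                                  else pad[j:(j + d[2] - 1), ])
        image[z, , ] <- out
      }
    } else if (op == "dislocation") {
      z <- sample(d[1], 1)
      sy <- sample(-3:3, 1); sx <- sample(-3:3, 1)
      sl <- image[z, , ]
      out <- matrix(0, d[2], d[3])
      ys <- seq_len(d[2]) - sy; xs <- seq_len(d[3]) - sx
      ok_y <- ys >= 1 & ys <= d[2]; ok_x <- xs >= 1 & xs <= d[3]
      out[ok_y, ok_x] <- sl[ys[ok_y], xs[ok_x]]
      image[z, , ] <- out
    }
  }
  list(image = image, labels = lab)
}
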