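# Volume I/O: multipage TIFF stacks (one page per z-slice).  Images are
# stored as 32-bit float in [0,1]; label volumes as 16-bit unsigned.

#' Read a volume from a multipage TIFF stack
#'
#' @param path file path.
#' @param labels if `TRUE` decode 16-bit integer labels.
#' @return `(D, H, W)` array (integer when `labels = TRUE`).
#' @export
read_volume <- function(path, labels = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  out <- array(0, d)
  for (z in seq_len(d[1])) out[z, , ] <- pages[[z]]
  if (labels) out <- array(as.integer(round(out * 65535)), d)
  out
}

#' Write a volume as a multipage TIFF stack
#'
#' @param vol `(D, H, W)` array or [label_volume()].
#' @param path file path.
#' @param labels if `TRUE` encode integer labels as 16-bit (ids up to 65535).
#' @export
write_volume <- function(vol, path, labels = inherits(vol, "label_volume")) {
  v <- if (inherits(vol, "label_volume")) vol$labels else v <- vol
  d <- dim(v)
  stopifnot(length(d) == 3L)
  if (labels) {
    if (max(v) > 65535) stop("write_volume: label ids exceed 16-bit range")
    pages <- lapply(seq_len(d[1]), function(z) matrix(v[z, , ] / 65535, d[2], d[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    pages <- lapply(seq_len(d[1]), function(z)
      matrix(pmin(pmax(v[z, , ], 0), 1), d[2], d[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}
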