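# Synthetic anisotropic EM-like volumes: neurite-like tubes crossing
# slices, mitochondria-like ellipsoids, procedural texture and noise.
# The generators are deliberately simple; their job is to give the network
# learnable structure and the metrics nontrivial inputs, not EM realism.

#' Synthetic volume specification
#'
#' @param shape `(D, H, W)` extents.
#' @param voxel_size `(z, y, x)` nm; the default emulates serial-section EM
#'   with a 5x coarser cutting axis.
#' @param n_instances number of instances to place.
#' @param noise_sigma Gaussian pixel noise s.d. (intensities live in
#'   `[0, 1]`).
#' @param texture_scale amplitude of the smooth background texture.
#' @param seed integer seed fixing all randomness.
#' @export
synth_spec <- function(shape = c(8L, 64L, 64L), voxel_size = c(30, 6, 6),
                       n_instances = 4L, noise_sigma = 0.03,
                       texture_scale = 0.1, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            voxel_size[1] >= max(voxel_size[2:3]), n_instances >= 1L)
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 n_instances = as.integer(n_instances),
                 noise_sigma = noise_sigma, texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# smooth 2D noise field by bilinear upsampling of a coarse grid
smooth_field <- function(h, w, cell = 8L) {
  gh <- max(2L, ceiling(h / cell) + 1L); gw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(rnorm(gh * gw), gh, gw)
  Mh <- interp_matrix(gh, h); Mw <- interp_matrix(gw, w)
  Mh %*% g %*% t(Mw)
}

rasterize_disk <- function(lab, z, cy, cx, r, id) {
  d <- dim(lab)
  ys <- max(1L, floor(cy - r)):min(d[2], ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(d[3], ceiling(cx + r))
  for (y in ys) for (x in xs)
    if ((y - cy)^2 + (x - cx)^2 <= r^2 && lab[z, y, x] == 0L)
      lab[z, y, x] <- id
  lab
}

largest_component_only <- function(lab, id) {
  m <- lab == id
  if (!any(m)) return(lab)
  cc <- label_components_cpp(m, dim(lab))
  tab <- tabulate(cc[cc > 0])
  keep <- which.max(tab)
  lab[m & cc != keep] <- 0L
  lab
}

render_image <- function(lab, spec, fg_level = NULL) {
  d <- dim(lab)
  img <- array(0.65, d)
  for (z in seq_len(d[1]))
    img[z, , ] <- img[z, , ] + spec$texture_scale * smooth_field(d[2], d[3])
  if (!is.null(fg_level)) img[lab > 0] <- fg_level + img[lab > 0] - 0.65
  # dark membranes at in-plane label transitions (incl. the background rim)
  for (z in seq_len(d[1])) {
    b <- slice_boundary(lab[z, , ])
    sl <- img[z, , ]; sl[b] <- sl[b] - 0.45
    img[z, , ] <- sl
  }
  img <- img + rnorm(length(img), sd = spec$noise_sigma)
  pmin(pmax(img, 0), 1)
}

#' Generate a neurite-like labeled volume
#'
#' Random-walk tubes span the full depth axis (each label appears in every
#' z-slice), with in-plane drift between consecutive slices emulating
#' neurites cut obliquely by the sectioning plane.  Later tubes are carved
#' around earlier ones; each label is reduced to its largest 6-connected
#' component.  The image carries dark membranes at label transitions, smooth
#' texture and Gaussian noise.  Deterministic per seed.
#'
#' @param spec a [synth_spec()].
#' @param max_tries bounded retries when the volume is too crowded.
#' @return list with `image` (array `(D,H,W)` in `[0,1]`) and `labels`
#'   (a [label_volume()]).
#' @export
generate_neuron_like <- function(spec = synth_spec(), max_tries = 20L) {
  set.seed(spec$seed)
  d <- spec$shape
  for (try in seq_len(max_tries)) {
    lab <- array(0L, d)
    # jittered-grid starts: neuropil is densely packed, so tubes are laid
    # out to tile the plane rather than scattered at random
    ncol_g <- ceiling(sqrt(spec$n_instances * d[3] / d[2]))
    nrow_g <- ceiling(spec$n_instances / ncol_g)
    cell_h <- d[2] / nrow_g; cell_w <- d[3] / ncol_g
    centers <- expand.grid(gy = seq_len(nrow_g), gx = seq_len(ncol_g))
    centers <- centers[sample(nrow(centers)), , drop = FALSE][seq_len(spec$n_instances), ]
    starts <- cbind((centers$gy - 0.5) * cell_h + runif(spec$n_instances, -2, 2),
                    (centers$gx - 0.5) * cell_w + runif(spec$n_instances, -2, 2))
    starts[, 1] <- pmin(pmax(starts[, 1], 4), d[2] - 3)
    starts[, 2] <- pmin(pmax(starts[, 2], 4), d[3] - 3)
    radii <- runif(spec$n_instances, 0.45, 0.7) * min(cell_h, cell_w)
    for (i in seq_len(spec$n_instances)) {
      cy <- starts[i, 1]; cx <- starts[i, 2]
      for (z in seq_len(d[1])) {
        lab <- rasterize_disk(lab, z, cy, cx, radii[i], i)
        cy <- min(max(cy + rnorm(1, sd = 1.5), 1 + radii[i]), d[2] - radii[i])
        cx <- min(max(cx + rnorm(1, sd = 1.5), 1 + radii[i]), d[3] - radii[i])
      }
      lab <- largest_component_only(lab, i)
    }
    counts <- vapply(seq_len(spec$n_instances), function(i) sum(lab == i), numeric(1))
    zspan <- vapply(seq_len(spec$n_instances), function(i)
      length(unique(which(apply(lab == i, 1, any)))), numeric(1))
    if (all(counts > 0) && all(zspan >= min(2L, d[1]))) {
      img <- render_image(lab, spec)
      return(list(image = img, labels = label_volume(lab, spec$voxel_size)))
    }
  }
  stop("generate_neuron_like: volume too small for the requested instances")
}

rasterize_ellipsoid <- function(lab, cz, cy, cx, rz, ry, rx, id) {
  d <- dim(lab)
  zs <- max(1L, floor(cz - rz)):min(d[1], ceiling(cz + rz))
  for (z in zs) {
    f <- 1 - ((z - cz) / rz)^2
    if (f <= 0) next
    ryz <- ry * sqrt(f); rxz <- rx * sqrt(f)
    ys <- max(1L, floor(cy - ryz)):min(d[2], ceiling(cy + ryz))
    xs <- max(1L, floor(cx - rxz)):min(d[3], ceiling(cx + rxz))
    for (y in ys) for (x in xs)
      if (((y - cy) / ryz)^2 + ((x - cx) / rxz)^2 <= 1 && lab[z, y, x] == 0L)
        lab[z, y, x] <- id
  }
  lab
}

#' Generate a mitochondria-like labeled volume
#'
#' Anisotropically squashed random ellipsoids on a textured background; the
#' z semi-axis is scaled by the voxel-size ratio so physical shapes are
#' roughly isotropic.  Instance in-plane radii cycle through a small /
#' medium / large size law so that, given enough room, all three AP-75
#' strata (< 5k, 5k-30k, > 30k voxels) are populated.  Deterministic per
#' seed.
#'
#' @inheritParams generate_neuron_like
#' @export
generate_mito_like <- function(spec = synth_spec(shape = c(32L, 128L, 128L),
                                                 n_instances = 6L),
                               max_tries = 20L) {
  set.seed(spec$seed)
  d <- spec$shape
  aniso <- spec$voxel_size[2] / spec$voxel_size[1]   # in-plane / z size ratio
  law <- c(small = 8, medium = 18, large = 36)       # in-plane radius (vox)
  for (try in seq_len(max_tries)) {
    lab <- array(0L, d)
    kinds <- rep(names(law), length.out = spec$n_instances)
    placed <- 0L
    for (i in seq_len(spec$n_instances)) {
      r <- law[[kinds[i]]] * runif(1, 0.85, 1.15)
      r <- min(r, (min(d[2], d[3]) - 2) / 2)
      rz <- max(1.5, r * aniso * 2)
      rz <- min(rz, (d[1] - 1) / 2)
      cz <- runif(1, 1 + rz, d[1] - rz)
      cy <- runif(1, 1 + r, d[2] - r)
      cx <- runif(1, 1 + r, d[3] - r)
      lab <- rasterize_ellipsoid(lab, cz, cy, cx, rz, r * runif(1, 0.8, 1),
                                 r, i)
      lab <- largest_component_only(lab, i)
      if (sum(lab == i) > 0) placed <- placed + 1L
    }
    if (placed == spec$n_instances) {
      img <- render_image(lab, spec, fg_level = 0.35)
      return(list(image = img, labels = label_volume(lab, spec$voxel_size)))
    }
  }
  stop("generate_mito_like: volume too small for the requested instances")
}
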