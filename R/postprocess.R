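# Conversion of network outputs back to instance segmentations.

#' Marker-controlled watershed instance extraction
#'
#' Markers are the 6-connected components of
#' `(mask_prob > seed_threshold) & (boundary_prob < 1 - seed_threshold)`.
#' A priority flood on the elevation `boundary_prob - mask_prob` grows the
#' markers inside `mask_prob > mask_threshold`; components smaller than
#' `min_size` voxels are removed.  Deterministic for fixed inputs.
#'
#' @param mask_prob,boundary_prob `(D, H, W)` probability arrays in `[0,1]`.
#' @param seed_threshold marker threshold.
#' @param mask_threshold flooding domain threshold.
#' @param min_size minimum instance size in voxels.
#' @return a [label_volume()].
#' @export
watershed_instances <- function(mask_prob, boundary_prob,
                                seed_threshold = 0.9, mask_threshold = 0.8,
                                min_size = 128L) {
  stopifnot(identical(dim(mask_prob), dim(boundary_prob)),
            all(mask_prob >= 0 & mask_prob <= 1),
            all(boundary_prob >= 0 & boundary_prob <= 1))
  d <- dim(mask_prob)
  seeds <- (mask_prob > seed_threshold) & (boundary_prob < 1 - seed_threshold)
  markers <- label_components_cpp(seeds, d)
  if (max(markers) == 0L) {
    warning("watershed_instances: no markers found; returning empty segmentation")
    return(label_volume(array(0L, d)))
  }
  domain <- mask_prob > mask_threshold
  lab <- watershed_flood_cpp(boundary_prob - mask_prob, markers, domain, d)
  lab <- filter_min_size(lab, min_size)
  label_volume(relabel_consecutive_cpp(lab))
}

filter_min_size <- function(lab, min_size) {
  if (min_size <= 1L) return(lab)
  tab <- tabulate(lab[lab > 0])
  drop <- which(tab < min_size)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Affinity agglomeration (union-find stand-in post-processor)
#'
#' Greedy union-find over voxel pairs whose connecting affinity exceeds
#' `merge_threshold`, processed in decreasing affinity order with
#' lexicographic tie-breaks.  Voxels with no supra-threshold incident
#' affinity become background.  This is a simple, deterministic in-package
#' agglomerator; externally produced segmentations can be evaluated directly
#' with the metric functions when a different post-processor is preferred.
#'
#' @param aff `(3, D, H, W)` affinity array in `[0,1]`
#'   (see [labels_to_affinities()]).
#' @param merge_threshold affinities strictly above this value merge.
#' @param min_size minimum instance size in voxels.
#' @return a [label_volume()].
#' @export
affinities_to_instances <- function(aff, merge_threshold = 0.5, min_size = 1L) {
  stopifnot(length(dim(aff)) == 4L, dim(aff)[1] == 3L,
            all(aff >= 0 & aff <= 1))
  d <- dim(aff)[2:4]
  lab <- affinity_agglomerate_cpp(aff, as.integer(d), merge_threshold)
  lab <- filter_min_size(lab, min_size)
  label_volume(relabel_consecutive_cpp(lab))
}
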