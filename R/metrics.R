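# Instance-segmentation evaluation: split/merge variation of information,
# adapted Rand error, and size-stratified AP-75.

#' Contingency table between two labelings
#'
#' Counts `n_ij` of voxels with ground-truth label `i` and segmentation
#' label `j` as a sparse matrix, optionally excluding ground-truth
#' background voxels.
#'
#' @param seg,gt integer label arrays of the same shape (or
#'   [label_volume()]s).
#' @param ignore_background drop voxels with `gt == 0`.
#' @return a `Matrix::sparseMatrix` with gt labels in rows (dimnames carry
#'   the original ids).
#' @export
contingency_table <- function(seg, gt, ignore_background = TRUE) {
  seg <- lab_data(seg); gt <- lab_data(gt)
  if (!identical(dim(seg), dim(gt)))
    stop("contingency_table: shape mismatch")
  s <- as.vector(seg); g <- as.vector(gt)
  if (ignore_background) {
    keep <- g > 0
    s <- s[keep]; g <- g[keep]
  }
  if (length(g) == 0) stop("contingency_table: no foreground voxels")
  gi <- factor(g); si <- factor(s)
  Matrix::sparseMatrix(i = as.integer(gi), j = as.integer(si), x = 1,
                       dims = c(nlevels(gi), nlevels(si)),
                       dimnames = list(levels(gi), levels(si)))
}

entropy_from_p <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Variation of information between segmentations
#'
#' Reports the two conditional entropies of the normalized contingency
#' table: `H(seg | gt)` (the split/over-segmentation component under the
#' conventional reading) and `H(gt | seg)` (merge/over-merging), and their
#' sum.  Lower is better; any bijective relabeling gives 0.
#'
#' @inheritParams contingency_table
#' @param log_base logarithm base (2 = bits).
#' @return named vector `c(voi_split, voi_merge, voi_total)`.
#' @export
voi <- function(seg, gt, log_base = 2, ignore_background = TRUE) {
  ct <- contingency_table(seg, gt, ignore_background)
  n <- sum(ct)
  p <- ct / n
  Hjoint <- entropy_from_p(p@x, log_base)
  Hg <- entropy_from_p(Matrix::rowSums(p), log_base)
  Hs <- entropy_from_p(Matrix::colSums(p), log_base)
  split <- Hjoint - Hg   # H(seg | gt)
  merge <- Hjoint - Hs   # H(gt | seg)
  c(voi_split = split, voi_merge = merge, voi_total = split + merge)
}

#' Adapted Rand error
#'
#' `1 - F` where `F` is the F-score of pairwise Rand precision and recall
#' computed from the contingency table (pairs of voxels placed in the same
#' segment), ignoring ground-truth background by default.  0 for perfect
#' (relabeled) agreement.
#'
#' @inheritParams contingency_table
#' @export
arand <- function(seg, gt, ignore_background = TRUE) {
  ct <- contingency_table(seg, gt, ignore_background)
  pairs2 <- function(x) sum(x * (x - 1) / 2)
  both <- pairs2(ct@x)
  in_seg <- pairs2(Matrix::colSums(ct))
  in_gt <- pairs2(Matrix::rowSums(ct))
  precision <- if (in_seg > 0) both / in_seg else 1
  recall <- if (in_gt > 0) both / in_gt else 1
  if (precision + recall == 0) return(1)
  1 - 2 * precision * recall / (precision + recall)
}

instance_sizes <- function(lab) {
  v <- as.vector(lab)
  v <- v[v > 0]
  if (!length(v)) return(integer(0))
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}

size_stratum <- function(sizes, small = 5000L, large = 30000L) {
  ifelse(sizes < small, "small", ifelse(sizes > large, "large", "medium"))
}

# precision-recall area: predictions ranked by confidence (voxel count),
# AP = mean of precision at each true-positive hit over all gt instances
ap_from_ranked <- function(is_tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(is_tp)) return(0)
  tp_cum <- cumsum(is_tp)
  prec <- tp_cum / seq_along(is_tp)
  sum(prec[is_tp]) / n_gt
}

#' Size-stratified average precision at IoU 0.75
#'
#' Each ground-truth instance is matched (greedily, by decreasing IoU, one
#' to one) to the predicted instance of maximal IoU; matches with
#' IoU >= `iou_threshold` are true positives, unmatched ground truth are
#' false negatives and unmatched predictions false positives.  Predictions
#' are ranked by voxel count as a confidence proxy and AP is the area under
#' the resulting precision-recall curve.  Instances are stratified by voxel
#' count: small `< 5000`, large `> 30000`, medium in between; an empty
#' stratum is reported as `NA` (absent), not zero.
#'
#' @param pred,gt integer label arrays on the same grid.
#' @param iou_threshold IoU needed for a true positive.
#' @return list with `ap` (named: small, medium, large, all) and `counts`
#'   (TP/FP/FN per stratum).
#' @export
ap75 <- function(pred, gt, iou_threshold = 0.75) {
  pred <- lab_data(pred); gt <- lab_data(gt)
  if (!identical(dim(pred), dim(gt))) stop("ap75: shape mismatch")
  gt_sizes <- instance_sizes(gt)
  pr_sizes <- instance_sizes(pred)
  gt_ids <- names(gt_sizes); pr_ids <- names(pr_sizes)
  # overlaps via contingency on foreground of either labeling
  keep <- gt > 0 | pred > 0
  g <- as.vector(gt)[keep]; s <- as.vector(pred)[keep]
  ov <- list()
  if (length(gt_ids) && length(pr_ids)) {
    fg <- g > 0 & s > 0
    if (any(fg)) {
      tab <- table(g[fg], s[fg])
      for (i in rownames(tab)) for (j in colnames(tab)) {
        inter <- tab[i, j]
        if (inter > 0) {
          un <- gt_sizes[[i]] + pr_sizes[[j]] - inter
          ov[[length(ov) + 1]] <- data.frame(gt = i, pred = j,
                                             iou = inter / un,
                                             stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- data.frame(gt = character(0), pred = character(0), iou = numeric(0))
  if (length(ov)) {
    ov <- do.call(rbind, ov)
    ov <- ov[ov$iou >= iou_threshold, , drop = FALSE]
    ov <- ov[order(-ov$iou, ov$gt, ov$pred), , drop = FALSE]
    used_gt <- character(0); used_pred <- character(0)
    for (r in seq_len(nrow(ov))) {
      if (ov$gt[r] %in% used_gt || ov$pred[r] %in% used_pred) next
      matches <- rbind(matches, ov[r, ])
      used_gt <- c(used_gt, ov$gt[r]); used_pred <- c(used_pred, ov$pred[r])
    }
  }
  gt_str <- size_stratum(gt_sizes)
  pr_str <- size_stratum(pr_sizes)
  strata <- c("small", "medium", "large", "all")
  ap <- setNames(rep(NA_real_, 4), strata)
  counts <- list()
  for (st in strata) {
    gt_in <- if (st == "all") gt_ids else gt_ids[gt_str == st]
    if (!length(gt_in)) { counts[[st]] <- c(TP = 0L, FP = 0L, FN = 0L); next }
    # predictions in scope: matched to an in-stratum gt, or unmatched with
    # their own size in the stratum
    matched_in <- matches$pred[matches$gt %in% gt_in]
    unmatched <- setdiff(pr_ids, matches$pred)
    pr_in <- c(matched_in,
               if (st == "all") unmatched else unmatched[pr_str[unmatched] == st])
    ord <- pr_in[order(-pr_sizes[pr_in])]
    is_tp <- ord %in% matched_in
    ap[st] <- ap_from_ranked(is_tp, length(gt_in))
    counts[[st]] <- c(TP = sum(is_tp), FP = sum(!is_tp),
                      FN = length(gt_in) - sum(is_tp))
  }
  list(ap = ap, counts = counts, matches = matches)
}

#' Full metric report
#'
#' @inheritParams voi
#' @param metrics subset of `c("voi", "arand", "ap75")`.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(pred, gt, metrics = c("voi", "arand", "ap75"),
                          log_base = 2, ignore_background = TRUE) {
  out <- list()
  if ("voi" %in% metrics)
    out <- c(out, as.list(voi(pred, gt, log_base, ignore_background)))
  if ("arand" %in% metrics)
    out$arand <- arand(pred, gt, ignore_background)
  if ("ap75" %in% metrics) {
    a <- ap75(pred, gt)
    out$ap75 <- as.list(a$ap)
    out$ap75_counts <- a$counts
  }
  structure(out, class = "metric_report")
}
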