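# Shared fixtures, built in code at test time.

# two well-separated cuboid instances in a (D, H, W) volume
two_cube_labels <- function(d = c(6L, 24L, 24L)) {
  lab <- array(0L, d)
  zr <- if (d[1] >= 4L) 2:(d[1] - 1L) else seq_len(d[1])
  mid_h <- d[2] %/% 2L; mid_w <- d[3] %/% 2L
  lab[zr, 2:max(2L, mid_h - 2L), 2:max(2L, mid_w - 2L)] <- 1L
  lab[zr, min(d[2] - 1L, mid_h + 3L):(d[2] - 1L),
      min(d[3] - 1L, mid_w + 3L):(d[3] - 1L)] <- 2L
  lab
}

# random labeling with k instances over n voxels (plus background)
random_labels <- function(shape, k, p_bg = 0.2) {
  v <- sample(0:k, prod(shape), replace = TRUE,
              prob = c(p_bg, rep((1 - p_bg) / k, k)))
  array(as.integer(v), shape)
}

rand_vol <- function(shape) array(rnorm(prod(shape)), shape)

# cumulative-sum sequence transform on an (L, channels, sequences) array
cumsum_seq <- function(s) apply(s, c(2, 3), cumsum)

# brute-force pairwise Rand error (unordered voxel pairs, gt background
# dropped) -- the O(n^2) oracle
arand_bruteforce <- function(seg, gt) {
  keep <- as.vector(gt) > 0
  s <- as.vector(seg)[keep]; g <- as.vector(gt)[keep]
  n <- length(g)
  same_both <- 0; same_seg <- 0; same_gt <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      bs <- s[i] == s[j]; bg <- g[i] == g[j]
      same_seg <- same_seg + bs
      same_gt <- same_gt + bg
      same_both <- same_both + (bs && bg)
    }
  p <- if (same_seg > 0) same_both / same_seg else 1
  r <- if (same_gt > 0) same_both / same_gt else 1
  if (p + r == 0) return(1)
  1 - 2 * p * r / (p + r)
}

# brute-force conditional entropies from explicit probabilities
voi_bruteforce <- function(seg, gt, base = 2) {
  keep <- as.vector(gt) > 0
  s <- as.vector(seg)[keep]; g <- as.vector(gt)[keep]
  n <- length(g)
  joint <- table(g, s) / n
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) / log(base) }
  split <- H(as.vector(joint)) - H(rowSums(joint))
  merge <- H(as.vector(joint)) - H(colSums(joint))
  c(split, merge, split + merge)
}

# reference per-step selective-scan loop (zero-order hold at every t)
selective_scan_reference <- function(x, w) {
  L <- nrow(x); C <- ncol(x); N <- ncol(w$A)
  y <- matrix(0, L, C)
  h <- array(0, c(C, N))
  for (t in seq_len(L)) {
    Bt <- as.vector(x[t, ] %*% w$W_B) + w$b_B
    Ct <- as.vector(x[t, ] %*% w$W_C) + w$b_C
    for (cc in seq_len(C)) {
      dt <- log1p(exp(w$w_delta[cc] * x[t, cc] + w$b_delta[cc]))
      u <- dt * w$A[cc, ]
      ab <- exp(u)
      phi <- ifelse(abs(u) > 1e-8, (ab - 1) / w$A[cc, ], dt)
      h[cc, ] <- ab * h[cc, ] + phi * Bt * x[t, cc]
      y[t, cc] <- sum(Ct * h[cc, ])
    }
  }
  y
}
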