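# Reference implementation of the discretized state-space model (SSM):
# zero-order-hold discretization, sequential recurrence, the equivalent
# global-convolution kernel, and the selective (input-dependent) variant.

#' Construct a set of state-space model parameters
#'
#' The continuous-time model is `h'(t) = A h(t) + B x(t)`, `y(t) = C h(t)`
#' with a diagonal state transition over `N` hidden states per channel.
#' A positive step size `delta` converts it to the discrete recurrence via
#' zero-order hold (see [discretize_zoh()]).
#'
#' @param A numeric matrix `(channels x N)` of diagonal state-transition
#'   entries (negative-leaning for stability).  A vector is treated as a
#'   single channel.
#' @param B,C_out numeric matrices `(channels x N)`: input and output
#'   projections per channel.
#' @param delta positive step size; scalar or one value per channel.
#' @return An object of class `ssm_params`.
#' @examples
#' p <- ssm_params(A = -1, B = 1, C_out = 1, delta = log(2))
#' discretize_zoh(p)
#' @export
ssm_params <- function(A, B, C_out, delta) {
  to_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  A <- to_mat(A); B <- to_mat(B); C_out <- to_mat(C_out)
  stopifnot(all(dim(A) == dim(B)), all(dim(A) == dim(C_out)))
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("ssm_params: step size delta must be strictly positive")
  C <- nrow(A)
  delta <- rep_len(delta, C)
  structure(list(A = A, B = B, C_out = C_out, delta = delta,
                 N = ncol(A), channels = C),
            class = "ssm_params")
}

#' Zero-order-hold discretization
#'
#' Converts continuous parameters `(A, B)` with step size `delta` to their
#' discrete counterparts: `A_bar = exp(delta * A)` and
#' `B_bar = (delta A)^{-1} (exp(delta A) - I) * delta B`, evaluated
#' elementwise over the diagonal state.  When `|delta * A|` falls below a
#' small-argument threshold the analytic limit `B_bar -> delta * B` is used
#' to avoid catastrophic cancellation.
#'
#' @param params an [ssm_params()] object.
#' @param small threshold on `|delta * A|` below which the limit form is used.
#' @return list with matrices `A_bar` and `B_bar`, `(channels x N)`.
#' @export
discretize_zoh <- function(params, small = 1e-8) {
  stopifnot(inherits(params, "ssm_params"))
  if (any(params$delta <= 0))
    stop("discretize_zoh: step size delta must be strictly positive")
  u <- sweep(params$A, 1, params$delta, "*")
  A_bar <- exp(u)
  B_bar <- ifelse(abs(u) > small, (A_bar - 1) / params$A, params$delta)
  dim(B_bar) <- dim(params$A)
  B_bar <- B_bar * params$B
  list(A_bar = A_bar, B_bar = B_bar)
}

normalize_seq <- function(x, channels) {
  # accepts vector (L), matrix (L x C) or array (L, C, S); returns (L, C, S)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[2] != channels)
    stop(sprintf("sequence has %d channels but params have %d",
                 dim(x)[2], channels))
  x
}

#' Run the discrete SSM recurrence over a sequence
#'
#' Applies `h_t = A_bar h_{t-1} + B_bar x_t`, `y_t = C h_t` left-to-right
#' with a zero initial hidden state; each channel carries its own diagonal
#' state of dimension `N`.
#'
#' @param params an [ssm_params()] object.
#' @param x input sequence: vector (length L), matrix `(L x channels)` or
#'   array `(L, channels, sequences)`.
#' @return array of the same shape as the normalized input.
#' @seealso [kernel_convolve()] for the equivalent global convolution.
#' @export
ssm_scan <- function(params, x) {
  stopifnot(inherits(params, "ssm_params"))
  xin <- x
  x <- normalize_seq(x, params$channels)
  d <- dim(x); L <- d[1]; C <- d[2]; S <- d[3]
  dz <- discretize_zoh(params)
  y <- array(0, d)
  for (s in seq_len(S)) {
    h <- matrix(0, C, params$N)
    for (t in seq_len(L)) {
      h <- dz$A_bar * h + dz$B_bar * x[t, , s]
      y[t, , s] <- rowSums(params$C_out * h)
    }
  }
  if (is.null(dim(xin))) as.vector(y) else { dim(y) <- dim(xin); y }
}

#' Compute the SSM output via its global-convolution kernel
#'
#' For time-invariant parameters the recurrence collapses to a causal
#' convolution with the structured kernel
#' `K = (C B_bar, C A_bar B_bar, ..., C A_bar^(M-1) B_bar)` where `M` is the
#' sequence length.  Agrees with [ssm_scan()] to numerical precision.
#'
#' @inheritParams ssm_scan
#' @export
kernel_convolve <- function(params, x) {
  stopifnot(inherits(params, "ssm_params"))
  xin <- x
  x <- normalize_seq(x, params$channels)
  d <- dim(x); L <- d[1]; C <- d[2]; S <- d[3]
  dz <- discretize_zoh(params)
  y <- array(0, d)
  for (cc in seq_len(C)) {
    # K[m] = sum_n C[n] * A_bar[n]^(m-1) * B_bar[n]
    pw <- outer(seq_len(L) - 1, dz$A_bar[cc, ],
                function(m, a) a^m)                         # (L x N)
    K <- as.vector(pw %*% (params$C_out[cc, ] * dz$B_bar[cc, ]))
    for (s in seq_len(S)) {
      xs <- x[, cc, s]
      y[, cc, s] <- vapply(seq_len(L), function(t)
        sum(K[seq_len(t)] * xs[t - seq_len(t) + 1]), numeric(1))
    }
  }
  if (is.null(dim(xin))) as.vector(y) else { dim(y) <- dim(xin); y }
}

#' Initialize selective-scan projection weights
#'
#' The selective variant produces `delta`, `B` and `C` per time step from the
#' input: `delta[t, c] = softplus(w_delta[c] * x[t, c] + b_delta[c])` (a
#' per-channel affine map) and `B_t = x_t W_B + b_B`, `C_t = x_t W_C + b_C`
#' (dense channel-to-state maps shared across channels).
#'
#' @param channels,N dimensions of the map.
#' @param seed optional integer seed for reproducible initialization.
#' @param delta_range `log10` range of the softplus bias initialization; the
#'   default draws the initial step size log-uniform in `[1e-3, 1e-1]`.
#' @return list of weights accepted by [selective_scan()].
#' @export
selective_weights <- function(channels, N = 16L, seed = NULL,
                              delta_range = c(1e-3, 1e-1)) {
  if (!is.null(seed)) set.seed(seed)
  dt0 <- exp(runif(channels, log(delta_range[1]), log(delta_range[2])))
  list(
    A = -matrix(rep(as.numeric(seq_len(N)), each = channels), channels, N),
    w_delta = rnorm(channels, sd = 0.1),
    b_delta = log(expm1(dt0)),               # softplus inverse
    W_B = matrix(rnorm(channels * N, sd = 1 / sqrt(channels)), channels, N),
    b_B = numeric(N),
    W_C = matrix(rnorm(channels * N, sd = 1 / sqrt(channels)), channels, N),
    b_C = numeric(N)
  )
}

#' Selective (input-dependent) state-space scan
#'
#' Same recurrence as [ssm_scan()] but with per-step zero-order-hold
#' discretization driven by projections of the input (see
#' [selective_weights()]).  With zero projection weights the step size and
#' state projections are constant and the operation reduces exactly to the
#' time-invariant scan.
#'
#' @param x input sequence: vector, `(L x channels)` matrix or
#'   `(L, channels, sequences)` array.
#' @param weights projection weights from [selective_weights()].
#' @return array shaped like the input.
#' @export
selective_scan <- function(x, weights) {
  xin <- x
  C <- nrow(weights$A); N <- ncol(weights$A)
  x <- normalize_seq(x, C)
  d <- dim(x); L <- d[1]; S <- d[3]
  delta <- array(0, d)
  for (s in seq_len(S)) {
    xs <- matrix(x[, , s], L, C)
    delta[, , s] <- log1p(exp(sweep(sweep(xs, 2, weights$w_delta, "*"),
                                    2, weights$b_delta, "+")))
  }
  if (any(!is.finite(delta))) {
    bad <- which(!is.finite(delta))[1]
    stop(sprintf("selective_scan: non-finite step size at index %d", bad))
  }
  Bm <- array(0, c(L, N, S)); Cm <- array(0, c(L, N, S))
  for (s in seq_len(S)) {
    xs <- matrix(x[, , s], L, C)
    Bm[, , s] <- sweep(xs %*% weights$W_B, 2, weights$b_B, "+")
    Cm[, , s] <- sweep(xs %*% weights$W_C, 2, weights$b_C, "+")
  }
  y <- selscan_fw_cpp(x, delta, Bm, Cm, weights$A, FALSE)$y
  if (is.null(dim(xin))) as.vector(y) else { dim(y) <- dim(xin); y }
}
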