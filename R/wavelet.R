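# Periodized orthogonal discrete wavelet transform.
#
# Analysis convention (matching the common "periodization" mode):
#   a[k] = sum_m h[m] x[(2k + L/2 - m) mod N],  k = 0 .. N/2 - 1
# with the highpass filter g[k] = (-1)^(k+1) h[L-1-k] (quadrature mirror).
# The transform is orthonormal, so synthesis is the transpose of analysis
# and reconstruction is exact for even N at every level.

.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401784997278, 0.032883011666982945,
          0.030841381835986965, -0.18703481171888114,
          -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
)

.wavelet_hg <- function(wavelet) {
  h <- .wavelet_filters[[wavelet]]
  if (is.null(h))
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "))
  L <- length(h)
  g <- (-1)^(seq_len(L)) * rev(h)  # g[k] = (-1)^(k+1) h[L-1-k], 0-based
  list(h = h, g = g, L = L)
}

# One analysis step; x must have even length.
.dwt_step <- function(x, h, g) {
  N <- length(x)
  L <- length(h)
  half <- N / 2
  a <- numeric(half)
  d <- numeric(half)
  base <- 2 * (seq_len(half) - 1) + L / 2   # 0-based target index 2k + L/2
  for (m in seq_len(L)) {
    idx <- (base - (m - 1)) %% N + 1
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis step (transpose of the analysis operator).
.idwt_step <- function(a, d, h, g) {
  half <- length(a)
  N <- 2 * half
  L <- length(h)
  x <- numeric(N)
  base <- 2 * (seq_len(half) - 1) + L / 2
  for (m in seq_len(L)) {
    # targets 2k + L/2 - (m-1) mod N are pairwise distinct for fixed m
    idx <- (base - (m - 1)) %% N + 1
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

# Multilevel periodized DWT. Returns list(a = coarse, d = list of detail
# vectors, finest first).
wavelet_dwt <- function(x, wavelet = "db4", level = 4) {
  f <- .wavelet_hg(wavelet)
  N <- length(x)
  if (level < 1) stop("wavelet_dwt: level must be >= 1")
  if (N < 2^level)
    stop("wavelet_dwt: signal of length ", N,
         " too short for level ", level)
  if (N %% 2^level != 0)
    stop("wavelet_dwt: length must be divisible by 2^level (periodized)")
  d <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- .dwt_step(a, f$h, f$g)
    a <- s$a
    d[[j]] <- s$d
  }
  list(a = a, d = d, wavelet = wavelet, level = level)
}

wavelet_idwt <- function(coeffs) {
  f <- .wavelet_hg(coeffs$wavelet)
  a <- coeffs$a
  for (j in rev(seq_len(coeffs$level)))
    a <- .idwt_step(a, coeffs$d[[j]], f$h, f$g)
  a
}

#' Wavelet threshold denoising of an RF trace
#'
#' Multilevel wavelet decomposition with soft or hard thresholding of the
#' detail coefficients, then reconstruction — the standard approach for
#' stripping high-frequency noise off physiological pulse signals while
#' keeping the pulse morphology.
#'
#' Thresholding with threshold `t`:
#' * soft: `sign(x) * max(|x| - t, 0)` (shrinks retained coefficients),
#' * hard: `x * 1[|x| > t]` (keeps retained coefficients unchanged).
#'
#' The default threshold is the universal rule
#' `t = sigma_hat * sqrt(2 log N)` with the noise scale `sigma_hat`
#' estimated from the median absolute deviation of the finest detail band
#' (`MAD / 0.6745`).
#'
#' Signals whose length is not divisible by `2^level` are reflection-padded
#' at the tail for the (periodized) transform and truncated back after
#' reconstruction.
#'
#' @param trace An [rf_trace()] (or numeric vector).
#' @param wavelet `"db4"` (default), `"db2"` or `"haar"`.
#' @param level Decomposition depth (default 4). The trace must hold at
#'   least `2^level` samples.
#' @param mode `"soft"` (default) or `"hard"`.
#' @param rule `"universal"` (default) or `"manual"` (then give `threshold`).
#' @param threshold Manual threshold value (MHz), used when
#'   `rule = "manual"`.
#' @return Denoised trace, same class and length as the input.
#' @examples
#' tr <- generate_rf_trace(pulsation_params(seed = 1), equivalent_circuit(), 60)
#' den <- wavelet_denoise(tr)
#' @export
wavelet_denoise <- function(trace, wavelet = "db4", level = 4,
                            mode = c("soft", "hard"),
                            rule = c("universal", "manual"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  is_trace <- inherits(trace, "rf_trace")
  x <- if (is_trace) trace$values else as.numeric(trace)
  N <- length(x)
  if (N < 2^level)
    stop("wavelet_denoise: trace of length ", N,
         " too short for level ", level)
  block <- 2^level
  M <- ceiling(N / block) * block
  xp <- if (M > N) c(x, x[N - seq_len(M - N)]) else x  # reflect tail
  co <- wavelet_dwt(xp, wavelet = wavelet, level = level)
  if (rule == "universal") {
    sigma <- stats::median(abs(co$d[[1]] - stats::median(co$d[[1]]))) / 0.6745
    thr <- sigma * sqrt(2 * log(length(xp)))
  } else {
    if (is.null(threshold)) stop("wavelet_denoise: manual rule needs threshold")
    thr <- threshold
  }
  co$d <- lapply(co$d, threshold_coefficients, threshold = thr, mode = mode)
  y <- wavelet_idwt(co)[seq_len(N)]
  if (is_trace) {
    trace$values <- y
    trace
  } else y
}

#' Soft/hard coefficient thresholding
#'
#' @param x Numeric coefficients.
#' @param threshold Non-negative threshold.
#' @param mode `"soft"` or `"hard"`.
#' @return Thresholded coefficients.
#' @examples
#' threshold_coefficients(c(3, -0.5), 1, "soft")  # 2, 0
#' @export
threshold_coefficients <- function(x, threshold, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  if (threshold < 0) stop("threshold must be >= 0")
  if (mode == "soft") sign(x) * pmax(abs(x) - threshold, 0)
  else x * (abs(x) > threshold)
}
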