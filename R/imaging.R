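#' Sliding-window specification
#'
#' Fixed-length sliding window over an RF trace. The defaults — a window of
#' 300 samples with a step of 60 — yield 16 overlapping windows per minute
#' of 20 Hz signal.
#'
#' @param length Window length in samples (> 0, default 300).
#' @param step Step in samples (0 < step <= length, default 60).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length = 300, step = 60) {
  if (length <= 0) stop("window_spec: length must be > 0")
  if (step <= 0 || step > length)
    stop("window_spec: step must satisfy 0 < step <= length")
  structure(list(length = as.integer(length), step = as.integer(step)),
            class = "window_spec")
}

#' Slice a trace into sliding windows
#'
#' Returns `floor((N - length)/step) + 1` fully contained segments in
#' left-to-right order (none when the trace is shorter than the window).
#'
#' @param trace An [rf_trace()] or numeric vector.
#' @param spec A [window_spec()].
#' @return List of numeric segments of length `spec$length`.
#' @examples
#' length(slide_windows(numeric(1200), window_spec(300, 60)))  # 16
#' @export
slide_windows <- function(trace, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  x <- if (inherits(trace, "rf_trace")) trace$values else as.numeric(trace)
  N <- length(x)
  if (N < spec$length) return(list())
  starts <- seq(1L, N - spec$length + 1L, by = spec$step)
  lapply(starts, function(s) x[s:(s + spec$length - 1L)])
}

#' Render a signal segment as a waveform image
#'
#' Draws the segment as a black connected polyline on a white canvas — the
#' time-series-to-image encoding consumed by the texture feature extractors.
#' No axes, ticks or margins are drawn.
#'
#' Vertical scaling:
#' * `y_mode = "per_window"`: the segment's own min–max spans the canvas,
#'   so every window fills the full height (amplitude information is lost);
#' * `y_mode = "global"`: a caller-supplied `y_range` (e.g. the
#'   per-recording range) is used, so windows with smaller pulses draw
#'   flatter lines — required for amplitude-driven classification.
#'
#' @param segment Numeric vector, length >= 2.
#' @param canvas `c(width, height)` in pixels. Default width = segment
#'   length (one abscissa column per sample) and height 300.
#' @param y_mode `"per_window"` or `"global"`.
#' @param y_range Numeric `c(lo, hi)` in MHz, required for `"global"`.
#' @return Integer matrix (height x width) with values 0 (ink) / 255
#'   (background).
#' @examples
#' img <- render_waveform(sin(seq(0, 6 * pi, length.out = 300)))
#' dim(img)
#' @export
render_waveform <- function(segment, canvas = c(length(segment), 300),
                            y_mode = c("per_window", "global"),
                            y_range = NULL) {
  y_mode <- match.arg(y_mode)
  n <- length(segment)
  if (n < 2) stop("render_waveform: need at least 2 samples")
  W <- as.integer(canvas[1])
  H <- as.integer(canvas[2])
  if (W < 2 || H < 2) stop("render_waveform: canvas must be at least 2x2")
  if (y_mode == "global") {
    if (is.null(y_range) || length(y_range) != 2 || y_range[2] < y_range[1])
      stop("render_waveform: y_mode = 'global' requires a valid y_range")
    lo <- y_range[1]
    hi <- y_range[2]
  } else {
    lo <- min(segment)
    hi <- max(segment)
  }
  v <- if (W == n) segment else
    approx(seq_len(n), segment, xout = seq(1, n, length.out = W))$y
  rows <- if (hi > lo)
    1L + as.integer(floor((H - 1) * (hi - pmin(pmax(v, lo), hi)) / (hi - lo) + 0.5))
  else rep(1L + as.integer(floor((H - 1) / 2 + 0.5)), W)
  img <- matrix(255L, nrow = H, ncol = W)
  for (i in seq_len(W - 1L)) {
    span <- rows[i]:rows[i + 1L]          # vertical join to the next column
    img[span, i] <- 0L
  }
  img[rows[W], W] <- 0L
  img
}

# Catmull-Rom-class bicubic kernel, a = -0.5.
.bicubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# Interpolation weight matrix mapping n_in samples to n_out positions
# (pixel-center alignment; border indices clamped / replicated).
.bicubic_weights <- function(n_in, n_out) {
  W <- matrix(0, nrow = n_out, ncol = n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5      # 0-based source coordinate
    base <- floor(src)
    for (k in -1:2) {
      j <- base + k
      w <- .bicubic_kernel(src - j)
      jc <- min(max(j, 0), n_in - 1)           # replicate border
      W[i, jc + 1] <- W[i, jc + 1] + w
    }
  }
  W
}

#' Bicubic resize of a grayscale image
#'
#' Separable bicubic interpolation (Catmull-Rom-class kernel, `a = -0.5`)
#' to the analysis resolution, with output clipped to `[0, 255]`. This
#' resampling introduces the gray-level transitions along the waveform that
#' the texture features operate on.
#'
#' @param image Numeric/integer matrix with values in `[0, 255]`.
#' @param out_w,out_h Output width and height in pixels (default 100 each).
#' @return Numeric `out_h x out_w` matrix in `[0, 255]`.
#' @examples
#' img <- render_waveform(sin(seq(0, 6 * pi, length.out = 300)))
#' dim(resize_bicubic(img))  # 100 100
#' @export
resize_bicubic <- function(image, out_w = 100, out_h = 100) {
  if (!is.matrix(image) || nrow(image) == 0 || ncol(image) == 0)
    stop("resize_bicubic: input image must be a nonempty matrix")
  Wr <- .bicubic_weights(nrow(image), out_h)
  Wc <- .bicubic_weights(ncol(image), out_w)
  out <- Wr %*% image %*% t(Wc)
  pmin(pmax(out, 0), 255)
}

#' Convert a trace into analysis-ready waveform images
#'
#' Splits the trace into consecutive one-minute blocks (windows never span
#' block boundaries, so each full minute yields 16 windows at the default
#' 300/60 spec on 20 Hz data), renders each window and resizes it to
#' 100 x 100.
#'
#' @param trace An [rf_trace()].
#' @param spec A [window_spec()].
#' @param y_mode,y_range Passed to [render_waveform()].
#' @param canvas_height Render canvas height in pixels (width = window
#'   length).
#' @param out_w,out_h Analysis resolution (default 100 x 100).
#' @return List of `out_h x out_w` matrices.
#' @export
trace_to_images <- function(trace, spec = window_spec(),
                            y_mode = "global", y_range = NULL,
                            canvas_height = 300, out_w = 100, out_h = 100) {
  stopifnot(inherits(trace, "rf_trace"))
  block <- as.integer(trace$fs * 60)
  x <- trace$values
  n_blocks <- length(x) %/% block
  if (n_blocks == 0) {          # shorter than a minute: single block
    blocks <- list(x)
  } else {
    blocks <- lapply(seq_len(n_blocks), function(b)
      x[((b - 1) * block + 1):(b * block)])
  }
  imgs <- list()
  for (bl in blocks) {
    for (seg in slide_windows(bl, spec)) {
      rendered <- render_waveform(seg, canvas = c(spec$length, canvas_height),
                                  y_mode = y_mode, y_range = y_range)
      imgs[[length(imgs) + 1L]] <- resize_bicubic(rendered, out_w, out_h)
    }
  }
  imgs
}
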