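# Image feature families for waveform images.
#
# The fixed layout on a 100 x 100 grayscale image is
#   7 Hu moments + 16 GLCM statistics (global, 23 dims)
#   + 4,356 HOG + 10,000 LBP values (local, 14,356 dims)
# = 14,379 dimensions in total. The dimensional contract is exact and
# load-bearing for the downstream selection stage, so every extractor
# documents the conventions that pin its count down.

.glcm_stats <- c("contrast", "entropy", "energy", "idm")
.glcm_dirs <- c(0, 45, 90, 135)

#' Names of the full feature layout
#'
#' @param family Optional subset: any of `"hu"`, `"glcm"`, `"hog"`,
#'   `"lbp"`. Default: all four in canonical order.
#' @return Character vector of stable per-dimension identifiers.
#' @examples
#' length(feature_names())  # 14379
#' @export
feature_names <- function(family = c("hu", "glcm", "hog", "lbp")) {
  family <- match.arg(family, several.ok = TRUE)
  out <- character(0)
  if ("hu" %in% family) out <- c(out, paste0("hu_", 1:7))
  if ("glcm" %in% family)
    out <- c(out, paste0("glcm_", rep(.glcm_stats, each = 4), "_",
                         rep(.glcm_dirs, 4)))
  if ("hog" %in% family) out <- c(out, sprintf("hog_%04d", 1:4356))
  if ("lbp" %in% family) out <- c(out, sprintf("lbp_%05d", 1:10000))
  out
}

#' Feature family of each feature name
#'
#' @param names Feature identifiers as produced by [feature_names()].
#' @return Character vector of family prefixes (`"hu"`, `"glcm"`, ...).
#' @export
feature_family <- function(names) sub("_.*$", "", names)

.check_image <- function(image) {
  if (!is.matrix(image)) stop("expected a grayscale image matrix")
  image
}

#' Hu invariant moments
#'
#' The seven classical moment invariants computed from normalized central
#' moments of the intensity image; invariant to translation, scale and
#' rotation of the pattern. They summarize the gross shape of the waveform
#' trace on the canvas.
#'
#' @param image Grayscale matrix (intensities 0–255).
#' @return Named numeric vector of length 7.
#' @examples
#' img <- render_waveform(sin(seq(0, 6 * pi, length.out = 300)))
#' hu_moments(255 - resize_bicubic(img))
#' @export
hu_moments <- function(image) {
  I <- .check_image(image)
  m00 <- sum(I)
  if (m00 <= 0) stop("hu_moments: moments undefined for an all-zero image")
  nr <- nrow(I)
  nc <- ncol(I)
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)   # column coordinate
  y <- matrix(rep(0:(nr - 1), nc), nr, nc)          # row coordinate
  xbar <- sum(x * I) / m00
  ybar <- sum(y * I) / m00
  dx <- x - xbar
  dy <- y - ybar
  mu <- function(p, q) sum(dx^p * dy^q * I)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  stats::setNames(c(h1, h2, h3, h4, h5, h6, h7), feature_names("hu"))
}

#' Gray-level co-occurrence matrix features
#'
#' Quantizes the image to `levels` gray levels (equal-width bins over
#' 0–255), builds the symmetric normalized co-occurrence matrix `P` at the
#' given pixel distance for each direction, and emits four texture
#' statistics per direction:
#' contrast `sum p(i,j) (i-j)^2`, entropy `-sum p log2 p`,
#' energy `sum p^2`, and the inverse difference moment (homogeneity)
#' `sum p / (1 + (i-j)^2)`.
#'
#' Output order is statistic-major, direction-minor:
#' `contrast_0, contrast_45, contrast_90, contrast_135, entropy_0, ...`.
#' Directions follow the image convention (row index grows downward):
#' 0° = horizontal neighbor, 90° = vertical, 45°/135° = diagonals.
#'
#' @param image Grayscale matrix (0–255).
#' @param directions Angles in degrees, subset of `c(0, 45, 90, 135)`.
#' @param distance Pixel-pair distance (default 1).
#' @param levels Number of gray levels after quantization (default 8).
#' @return Named numeric vector, one value per statistic x direction.
#' @examples
#' glcm_features(matrix(128, 100, 100))["glcm_energy_0"]  # 1
#' @export
glcm_features <- function(image, directions = c(0, 45, 90, 135),
                          distance = 1, levels = 8) {
  I <- .check_image(image)
  if (!all(directions %in% c(0, 45, 90, 135)))
    stop("glcm_features: directions must be among 0, 45, 90, 135")
  q <- pmin(floor(I / (256 / levels)), levels - 1)   # 0 .. levels-1
  nr <- nrow(q)
  nc <- ncol(q)
  d <- distance
  offsets <- list(`0` = c(0, d), `45` = c(-d, d),
                  `90` = c(-d, 0), `135` = c(-d, -d))
  stat_vals <- matrix(NA_real_, nrow = 4, ncol = length(directions),
                      dimnames = list(.glcm_stats, directions))
  for (j in seq_along(directions)) {
    off <- offsets[[as.character(directions[j])]]
    r1 <- max(1, 1 - off[1]):min(nr, nr - off[1])
    c1 <- max(1, 1 - off[2]):min(nc, nc - off[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    counts <- matrix(tabulate(a * levels + b + 1, nbins = levels^2),
                     levels, levels, byrow = TRUE)
    counts <- counts + t(counts)                      # symmetric
    P <- counts / sum(counts)
    lev <- 0:(levels - 1)
    dif2 <- outer(lev, lev, function(i, k) (i - k)^2)
    nz <- P > 0
    stat_vals["contrast", j] <- sum(P * dif2)
    stat_vals["entropy", j] <- -sum(P[nz] * log2(P[nz]))
    stat_vals["energy", j] <- sum(P^2)
    stat_vals["idm", j] <- sum(P / (1 + dif2))
  }
  out <- as.vector(t(stat_vals))                      # statistic-major
  stats::setNames(out, paste0("glcm_", rep(.glcm_stats, each = length(directions)),
                              "_", rep(directions, 4)))
}

#' Histogram-of-oriented-gradients features
#'
#' Signed-gradient HOG on a 100 x 100 image with the configuration that
#' yields exactly 4,356 dimensions:
#' * centered-difference gradients (replicate-padded borders),
#' * signed orientation over 0–360° in 9 bins of 40°, magnitude-weighted,
#' * 8 x 8 pixel cells tiled from the top-left corner (12 x 12 full cells;
#'   the 4-pixel remainder is dropped),
#' * blocks of 2 x 2 cells with a one-cell stride (11 x 11 blocks), each
#'   36-value block L2-normalized,
#' * concatenation row-major over blocks, then cells within the block
#'   (row-major), then orientation bins: `11 * 11 * 4 * 9 = 4356`.
#'
#' @param image Grayscale matrix (0–255), at least 96 x 96.
#' @param cell Cell side in pixels (default 8).
#' @param block_cells Cells per block side (default 2).
#' @param bins Orientation bins over 0–360° (default 9).
#' @return Named numeric vector of length 4,356 (all values >= 0 after
#'   block normalization of non-negative magnitudes).
#' @export
hog_features <- function(image, cell = 8, block_cells = 2, bins = 9) {
  I <- .check_image(image)
  nr <- nrow(I)
  nc <- ncol(I)
  # centered differences with replicated borders
  up <- I[c(1, 1:(nr - 1)), , drop = FALSE]
  down <- I[c(2:nr, nr), , drop = FALSE]
  left <- I[, c(1, 1:(nc - 1)), drop = FALSE]
  right <- I[, c(2:nc, nc), drop = FALSE]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 360
  bin <- pmin(floor(ang / (360 / bins)), bins - 1)    # 0 .. bins-1
  n_cells_r <- nr %/% cell
  n_cells_c <- nc %/% cell
  keep_r <- seq_len(n_cells_r * cell)
  keep_c <- seq_len(n_cells_c * cell)
  cr <- (keep_r - 1) %/% cell                          # cell row, 0-based
  cc <- (keep_c - 1) %/% cell
  cell_idx <- outer(cr, cc, function(a, b) a * n_cells_c + b)
  key <- cell_idx * bins + bin[keep_r, keep_c] + 1     # 1-based histogram slot
  hist <- numeric(n_cells_r * n_cells_c * bins)
  agg <- rowsum(as.vector(mag[keep_r, keep_c]), as.vector(key))
  hist[as.integer(rownames(agg))] <- agg[, 1]
  cell_hist <- function(r, c) hist[((r * n_cells_c + c) * bins + 1):
                                     ((r * n_cells_c + c) * bins + bins)]
  nb_r <- n_cells_r - block_cells + 1
  nb_c <- n_cells_c - block_cells + 1
  out <- numeric(nb_r * nb_c * block_cells^2 * bins)
  blen <- block_cells^2 * bins
  pos <- 0L
  for (br in 0:(nb_r - 1)) {
    for (bc in 0:(nb_c - 1)) {
      v <- c(cell_hist(br, bc), cell_hist(br, bc + 1),
             cell_hist(br + 1, bc), cell_hist(br + 1, bc + 1))
      nrm <- sqrt(sum(v^2))
      if (nrm > 1e-12) v <- v / nrm
      out[(pos + 1):(pos + blen)] <- v
      pos <- pos + blen
    }
  }
  stats::setNames(out, sprintf("hog_%04d", seq_along(out)))
}

#' Local binary pattern codes
#'
#' Scans the image with a 3 x 3 neighborhood and encodes, for every pixel,
#' which of its 8 neighbors are at least as bright as the center. Neighbors
#' are read clockwise from the top-left corner, first neighbor = most
#' significant bit; ties set the bit (`neighbor >= center`). Borders are
#' replicate-padded so the code map has the same size as the image; it is
#' flattened row-major (row 1 first).
#'
#' @param image Grayscale matrix (0–255).
#' @return Named integer vector of length `nrow * ncol` with codes in
#'   0–255 (10,000 values for a 100 x 100 image).
#' @examples
#' lbp_features(matrix(7, 100, 100))[1]  # 255: all neighbors >= center
#' @export
lbp_features <- function(image) {
  I <- .check_image(image)
  nr <- nrow(I)
  nc <- ncol(I)
  P <- matrix(0, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- I
  P[1, ] <- P[2, ]; P[nr + 2, ] <- P[nr + 1, ]
  P[, 1] <- P[, 2]; P[, nc + 2] <- P[, nc + 1]
  rr <- 2:(nr + 1)
  cc <- 2:(nc + 1)
  # clockwise from top-left: TL, T, TR, R, BR, B, BL, L
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, nr, nc)
  for (k in seq_along(offs)) {
    nb <- P[rr + offs[[k]][1], cc + offs[[k]][2]]
    code <- code + as.integer(2^(8 - k)) * (nb >= I)
  }
  v <- as.integer(t(code))                         # row-major flatten
  stats::setNames(v, sprintf("lbp_%05d", seq_along(v)))
}

#' Extract the full waveform-image feature vector
#'
#' Concatenates the four families in canonical order
#' (Hu, GLCM, HOG, LBP) into the fixed 14,379-dimension layout:
#' 23 global dimensions (7 Hu + 16 GLCM) and 14,356 local ones
#' (4,356 HOG + 10,000 LBP).
#'
#' @param image 100 x 100 grayscale matrix (0–255).
#' @return Named numeric vector of length 14,379.
#' @examples
#' img <- resize_bicubic(render_waveform(sin(seq(0, 6 * pi, length.out = 300))))
#' length(extract_all(img))  # 14379
#' @export
extract_all <- function(image) {
  I <- .check_image(image)
  if (!all(dim(I) == c(100, 100)))
    stop("extract_all: expected a 100 x 100 image")
  c(hu_moments(I), glcm_features(I), hog_features(I), lbp_features(I))
}
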