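# Brute-force double-loop oracles for the image feature extractors.
# Deliberately naive and independent of the package implementations.

oracle_hu <- function(I) {
  nr <- nrow(I); nc <- ncol(I)
  m <- function(p, q) {
    s <- 0
    for (r in 1:nr) for (c in 1:nc) s <- s + (c - 1)^p * (r - 1)^q * I[r, c]
    s
  }
  m00 <- m(0, 0)
  xb <- m(1, 0) / m00; yb <- m(0, 1) / m00
  mu <- function(p, q) {
    s <- 0
    for (r in 1:nr) for (c in 1:nc)
      s <- s + ((c - 1) - xb)^p * ((r - 1) - yb)^q * I[r, c]
    s
  }
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# Co-occurrence statistics for one direction by explicit pair enumeration.
oracle_glcm_dir <- function(I, dr, dc, levels = 8) {
  q <- pmin(floor(I / (256 / levels)), levels - 1)
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in 1:nr) for (c in 1:nc) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- q[r, c] + 1; j <- q[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  P <- counts / sum(counts)
  contrast <- 0; entropy <- 0; energy <- 0; idm <- 0
  for (i in 1:levels) for (j in 1:levels) {
    p <- P[i, j]
    contrast <- contrast + p * (i - j)^2
    if (p > 0) entropy <- entropy - p * log2(p)
    energy <- energy + p^2
    idm <- idm + p / (1 + (i - j)^2)
  }
  c(contrast = contrast, entropy = entropy, energy = energy, idm = idm)
}

# Pixel-by-pixel HOG with the same stated conventions (centered difference,
# replicate border, signed 0-360 hard binning, L2 block norm).
oracle_hog <- function(I, cell, block_cells = 2, bins = 9) {
  nr <- nrow(I); nc <- ncol(I)
  at <- function(r, c) I[min(max(r, 1), nr), min(max(c, 1), nc)]
  n_cr <- nr %/% cell; n_cc <- nc %/% cell
  hist <- array(0, dim = c(n_cr, n_cc, bins))
  for (r in seq_len(n_cr * cell)) for (c in seq_len(n_cc * cell)) {
    gx <- (at(r, c + 1) - at(r, c - 1)) / 2
    gy <- (at(r + 1, c) - at(r - 1, c)) / 2
    mag <- sqrt(gx^2 + gy^2)
    ang <- (atan2(gy, gx) * 180 / pi) %% 360
    b <- min(floor(ang / (360 / bins)), bins - 1) + 1
    cr <- (r - 1) %/% cell + 1; cc2 <- (c - 1) %/% cell + 1
    hist[cr, cc2, b] <- hist[cr, cc2, b] + mag
  }
  out <- c()
  for (br in seq_len(n_cr - block_cells + 1))
    for (bc in seq_len(n_cc - block_cells + 1)) {
      v <- c(hist[br, bc, ], hist[br, bc + 1, ],
             hist[br + 1, bc, ], hist[br + 1, bc + 1, ])
      nrm <- sqrt(sum(v^2))
      if (nrm > 1e-12) v <- v / nrm
      out <- c(out, v)
    }
  out
}

oracle_lbp <- function(I) {
  nr <- nrow(I); nc <- ncol(I)
  at <- function(r, c) I[min(max(r, 1), nr), min(max(c, 1), nc)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  codes <- integer(nr * nc)
  k <- 0
  for (r in 1:nr) for (c in 1:nc) {
    k <- k + 1
    code <- 0
    for (b in 1:8)
      if (at(r + offs[[b]][1], c + offs[[b]][2]) >= I[r, c])
        code <- code + 2^(8 - b)
    codes[k] <- as.integer(code)
  }
  codes
}
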