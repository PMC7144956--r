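# Internal numeric helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; NULL seed
# uses (and advances) the caller's RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.asMatrix <- function(x) {
  if (is(x, "MRImage2D")) x@data else as.matrix(x)
}

.spacingOf <- function(x, spacing = NULL) {
  if (!is.null(spacing)) return(spacing)
  if (is(x, "MRImage2D") || is(x, "LabelMask")) return(pixelSpacing(x))
  1
}

# Separable Gaussian smoothing with mirrored edges; sigma in pixels.
gaussSmooth <- function(m, sigma) {
  m <- as.matrix(m)
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  smooth1 <- function(mat) {
    # mirror-pad rows, convolve down columns via banded matrix product
    n <- nrow(mat)
    idx <- c(pmin(pmax(rev(seq_len(r)), 1L), n), seq_len(n),
             pmin(pmax(n - seq_len(r) + 1L, 1L), n))
    padded <- mat[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(kern))
      out <- out + kern[j] * padded[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(m))))
}

# Euclidean distance (in pixels) from each pixel to the nearest TRUE pixel
# of `mask`, computed only up to maxd; Inf beyond.
distToMask <- function(mask, maxd) {
  d <- matrix(Inf, nrow(mask), ncol(mask))
  d[mask] <- 0
  if (maxd < 1) return(d)
  nr <- nrow(mask); nc <- ncol(mask)
  w <- ceiling(maxd)
  for (di in -w:w) for (dj in -w:w) {
    if (di == 0 && dj == 0) next
    dd <- sqrt(di^2 + dj^2)
    if (dd > maxd) next
    src_r <- max(1, 1 - di):min(nr, nr - di)
    src_c <- max(1, 1 - dj):min(nc, nc - dj)
    shifted <- matrix(FALSE, nr, nc)
    shifted[src_r + di, src_c + dj] <- mask[src_r, src_c]
    d[shifted] <- pmin(d[shifted], dd)
  }
  d
}

# Filled ellipse mask; center and semi-axes in mm, (row, col) order.
ellipseMask <- function(dim, spacing, center, radii) {
  r <- (seq_len(dim[1]) - 0.5) * spacing
  c_ <- (seq_len(dim[2]) - 0.5) * spacing
  rr <- outer((r - center[1])^2 / radii[1]^2, rep(1, dim[2]))
  cc <- outer(rep(1, dim[1]), (c_ - center[2])^2 / radii[2]^2)
  (rr + cc) <= 1
}

# Bilinear interpolation of values on grid (rowsAt, colsAt) to a full
# nr x nc raster; grid coordinates are 1-based pixel indices.
bilinearUpsample <- function(grid, rowsAt, colsAt, nr, nc) {
  ri <- findInterval(seq_len(nr), rowsAt, all.inside = TRUE)
  ci <- findInterval(seq_len(nc), colsAt, all.inside = TRUE)
  r0 <- rowsAt[ri]; r1 <- rowsAt[ri + 1L]
  c0 <- colsAt[ci]; c1 <- colsAt[ci + 1L]
  fr <- pmin(pmax((seq_len(nr) - r0) / (r1 - r0), 0), 1)
  fc <- pmin(pmax((seq_len(nc) - c0) / (c1 - c0), 0), 1)
  g00 <- grid[ri, ci, drop = FALSE]
  g10 <- grid[ri + 1L, ci, drop = FALSE]
  g01 <- grid[ri, ci + 1L, drop = FALSE]
  g11 <- grid[ri + 1L, ci + 1L, drop = FALSE]
  wr <- matrix(fr, nr, nc)
  wc <- matrix(fc, nr, nc, byrow = TRUE)
  g00 * (1 - wr) * (1 - wc) + g10 * wr * (1 - wc) +
    g01 * (1 - wr) * wc + g11 * wr * wc
}

# Short stable hex digest (FNV-1a) of an R object, for config provenance.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648) , b) + (h >= 2147483648) * 2147483648
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536; hi <- (h - lo) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}
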