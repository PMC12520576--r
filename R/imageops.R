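# Fast image primitives on plain numeric matrices (grey levels 0-255).
# A separable shift-and-add Gaussian blur and a histogram Otsu threshold;
# both avoid per-frame FFTs, which dominate the cost of rendering and
# analysing multi-thousand-frame stacks.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable Gaussian blur with edge replication.
fast_gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  w <- gaussian_kernel_1d(sigma)
  r <- (length(w) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- m * w[r + 1]
  for (d in seq_len(r)) {
    out <- out +
      w[r + 1 - d] * m[c(rep(1L, d), seq_len(nr - d)), , drop = FALSE] +
      w[r + 1 + d] * m[c(seq_len(nr - d) + d, rep(nr, d)), , drop = FALSE]
  }
  m2 <- out
  out <- m2 * w[r + 1]
  for (d in seq_len(r)) {
    out <- out +
      w[r + 1 - d] * m2[, c(rep(1L, d), seq_len(nc - d)), drop = FALSE] +
      w[r + 1 + d] * m2[, c(seq_len(nc - d) + d, rep(nc, d)), drop = FALSE]
  }
  out
}

# Otsu threshold of a grey-level matrix (maximises between-class variance on
# a 256-bin histogram); returns the threshold level.
otsu_level <- function(m) {
  v <- pmin(pmax(as.integer(m), 0L), 255L)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  which.max(sb) - 1 + 0.5
}

# Bilinear interpolation of matrix values at fractional (row, col) positions.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Sub-pixel radius of a dark disk on a bright background: the radial
# intensity profile around (cr, cc) crosses its steepest ascent exactly at
# the (blurred) edge; locate it by a parabolic fit on the radial gradient.
refine_radius_profile <- function(img, cr, cc, r0, half_window = 3,
                                  step = 0.25, n_angles = 64) {
  theta <- seq(0, 2 * pi, length.out = n_angles + 1)[-1]
  st <- sin(theta); ct <- cos(theta)
  rs <- r0 + seq(-half_window, half_window, by = step)
  prof <- vapply(rs, function(r) {
    rr <- cr + r * st; cc2 <- cc + r * ct
    ok <- rr >= 1 & rr <= nrow(img) & cc2 >= 1 & cc2 <= ncol(img)
    if (sum(ok) < n_angles / 2) return(NA_real_)
    mean(bilinear_sample(img, rr[ok], cc2[ok]))
  }, numeric(1))
  g <- diff(prof)
  if (all(is.na(g))) return(r0)
  i <- which.max(g)
  off <- 0
  if (i > 1 && i < length(g) && !anyNA(g[(i - 1):(i + 1)])) {
    den <- g[i - 1] - 2 * g[i] + g[i + 1]
    if (abs(den) > 1e-12) off <- 0.5 * (g[i - 1] - g[i + 1]) / den
    off <- max(min(off, 1), -1)
  }
  rs[i] + step / 2 + off * step
}
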