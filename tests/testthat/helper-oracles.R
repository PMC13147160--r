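# Fixture builders and independent oracles used across test files.

make_disk <- function(r, N = 2 * r + 20, cx = N / 2, cy = N / 2) {
  yy <- row(matrix(0, N, N)); xx <- col(matrix(0, N, N))
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

make_rect <- function(h, w, N = max(h, w) + 20, r0 = 10, c0 = 10) {
  m <- matrix(FALSE, N, N + w)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# Textbook Welch's t-test: statistic, Welch-Satterthwaite df, two-sided p.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Hand-coded Benjamini-Hochberg step-up: sort ascending, p_(i) * m / i,
# running minimum from the largest rank down, cap at 1, original order.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# a small ready-made track: square cell translating dx px per frame
translating_track_frames <- function(n_frames = 12, dx = 2, side = 8,
                                     N = 64, interval_s = 20,
                                     pixel_size = 1) {
  frames <- lapply(seq_len(n_frames), function(t) {
    m <- matrix(0L, N, N)
    c0 <- 5 + (t - 1) * dx
    m[20:(20 + side - 1), c0:(c0 + side - 1)] <- 1L
    mask_frame(m, t - 1L, interval_s, pixel_size)
  })
  frames
}
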