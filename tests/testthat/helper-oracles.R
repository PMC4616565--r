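# Brute-force oracles used to cross-check the vectorized implementations.

# Median filter: explicit neighborhood sort with edge replication.
oracle_median_3x3 <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- frame
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    vals <- numeric(9); k <- 0
    for (dr in -1:1) for (dc in -1:1) {
      k <- k + 1
      vals[k] <- frame[min(max(r + dr, 1), nr), min(max(cc + dc, 1), nc)]
    }
    out[r, cc] <- sort(vals)[5]
  }
  out
}

# Mean and population-SD images by an explicit loop over frames.
oracle_stat_model <- function(px) {
  d <- dim(px)
  m <- matrix(0, d[1], d[2]); s <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    v <- px[r, cc, ]
    m[r, cc] <- sum(v) / d[3]
    s[r, cc] <- sqrt(sum((v - m[r, cc])^2) / d[3])
  }
  list(mean = m, sd = s)
}

# Two-pass population variance of one frame.
oracle_frame_variance <- function(frame) {
  mu <- sum(frame) / length(frame)
  sum((frame - mu)^2) / length(frame)
}

# Per-frame ROI means by explicit loops over member pixels.
oracle_roi_trace <- function(px, members) {
  nf <- dim(px)[3]
  out <- numeric(nf)
  for (t in seq_len(nf)) {
    acc <- 0
    for (i in seq_len(nrow(members)))
      acc <- acc + px[members[i, 1], members[i, 2], t]
    out[t] <- acc / nrow(members)
  }
  out
}

# A small synthetic experiment, quick enough for unit tests.
small_fixture <- function(..., shape = c(48L, 48L), frames = 24L, seed = 11L) {
  generate_fixture(fixture_spec(shape = shape, frames = frames, seed = seed,
                                injection_radius = 3, ...))
}

# A two-compartment test image: bright disk on a dim field.
two_compartment_image <- function(n = 40L, center = c(20L, 20L), radius = 6) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  disk <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  img <- matrix(0.1, n, n)
  img[disk] <- 0.8
  list(image = img, disk = disk)
}

# A hand-made cell mask object for classifier tests.
manual_cell_mask <- function(mask, threshold = 0.01) {
  structure(list(mask = mask, threshold = threshold, opening_radius = 0L),
            class = "cell_mask")
}
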