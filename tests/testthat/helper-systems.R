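# Shared fixtures, built in code.

# Mueller-Brown stationary points located independently by Newton iteration
# on the analytic gradient (the oracle of record for path tests).
mb_system <- function(...) toy_system("mueller-brown", temperature = 0, ...)

mb_stationary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mb <- mb_system()
      cache <<- list(
        min_a = find_stationary_point(mb, c(-0.55, 1.44)),
        min_b = find_stationary_point(mb, c(0.6, 0.03)),
        min_c = find_stationary_point(mb, c(-0.05, 0.47)),
        saddle_1 = find_stationary_point(mb, c(-0.8, 0.6)),
        saddle_2 = find_stationary_point(mb, c(0.2, 0.3)))
    }
    cache
  }
})

# Finite-difference gradient of a scalar function of a coordinate matrix.
fd_gradient <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Well-separated tight blobs of conformations with known labels.  Each blob
# is built around its own random base SHAPE (not a rigid copy), so the blobs
# stay far apart in superposed RMSD.
planted_blob_pool <- function(n_per = 10, n_particles = 5, n_blobs = 2,
                              shape_scale = 6, spread = 0.2, seed = 99) {
  set.seed(seed)
  frames <- list()
  labels <- integer(0)
  for (b in seq_len(n_blobs)) {
    base <- matrix(rnorm(n_particles * 3, sd = shape_scale), n_particles, 3)
    for (r in seq_len(n_per)) {
      frames[[length(frames) + 1]] <- base +
        spread * matrix(rnorm(n_particles * 3), n_particles, 3)
      labels <- c(labels, b)
    }
  }
  list(pool = conformation_pool(frames), labels = labels)
}

# Arc position of a point's projection on a polyline: returns
# c(projection distance, arc length at the projection).
arc_position_on <- function(mat, point) {
  best <- c(Inf, NA)
  s <- c(0, cumsum(sqrt(rowSums(diff(mat)^2))))
  for (k in seq_len(nrow(mat) - 1)) {
    a <- mat[k, ]; b <- mat[k + 1, ]
    ab <- b - a
    t0 <- min(max(sum((point - a) * ab) / sum(ab^2), 0), 1)
    d <- sqrt(sum((a + t0 * ab - point)^2))
    if (d < best[1]) best <- c(d, s[k] + t0 * sqrt(sum(ab^2)))
  }
  best
}
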