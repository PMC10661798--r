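# Independent oracles used to validate the package's implementations.
# Each is a deliberately naive, direct computation kept separate from
# the code path it checks.

# Exhaustive all-pairs Feret: maximum pairwise distance over ALL points
# (no convex hull), with the same smallest-angle tie rule.
oracle_feret <- function(p) {
  p <- unique(as.matrix(p)[, 1:2, drop = FALSE])
  n <- nrow(p)
  best <- -1
  fas <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- p[j, 1] - p[i, 1]; dy <- p[j, 2] - p[i, 2]
    d <- sqrt(dx^2 + dy^2)
    fa <- (atan2(-dy, dx) * 180 / pi) %% 180
    if (d > best + 1e-12) {
      best <- d; fas <- fa
    } else if (abs(d - best) <= 1e-12) {
      fas <- c(fas, fa)
    }
  }
  list(LD = best, FA = min(fas))
}

# Dense-rasterization centroid of a convex polygon: mean position of
# grid points (spacing h) inside the polygon (half-plane test).
oracle_raster_centroid <- function(poly, h = 0.02) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  # ensure counterclockwise orientation for the half-plane signs
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) { x <- rev(x); y <- rev(y) }
  gx <- seq(min(x) + h / 2, max(x), by = h)
  gy <- seq(min(y) + h / 2, max(y), by = h)
  G <- expand.grid(x = gx, y = gy)
  inside <- rep(TRUE, nrow(G))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- x[j] - x[i]; ey <- y[j] - y[i]
    inside <- inside & (ex * (G$y - y[i]) - ey * (G$x - x[i]) >= 0)
  }
  c(mean(G$x[inside]), mean(G$y[inside]))
}

# Random convex polygon: convex hull of random points, re-sampled
# until it has at least `min_v` vertices.
random_convex_polygon <- function(min_v = 7, scale = 10) {
  repeat {
    p <- cbind(runif(30, 0, scale), runif(30, 0, scale))
    h <- grDevices::chull(p)
    if (length(h) >= min_v) return(p[h, , drop = FALSE])
  }
}

# Direct empirical-CDF Watson U2 oracle (double summation over the
# pooled order statistics via ecdf evaluation); valid for tie-free
# samples.
oracle_watson_u2 <- function(a, b, period = 360) {
  x <- a / period; y <- b / period
  n <- length(x); m <- length(y); N <- n + m
  t_all <- sort(c(x, y))
  Fa <- vapply(t_all, function(v) sum(x <= v), numeric(1)) / n
  Fb <- vapply(t_all, function(v) sum(y <= v), numeric(1)) / m
  d <- Fa - Fb
  max(n * m / N^2 * (sum(d^2) - sum(d)^2 / N), 0)
}

# Circular mean / resultant length by direct unit-vector summation.
oracle_circmean <- function(deg) {
  v <- complex(argument = deg * pi / 180)
  s <- mean(v)
  list(mean = (Arg(s) * 180 / pi) %% 360, R = Mod(s))
}

# Rotate image-coordinate points by `theta` degrees (counterclockwise
# in the y-up frame) about `center`.
rotate_points <- function(p, theta, center = c(0, 0)) {
  th <- theta * pi / 180
  dx <- p[, 1] - center[1]
  dy <- -(p[, 2] - center[2])          # to y-up
  rx <- dx * cos(th) - dy * sin(th)
  ry <- dx * sin(th) + dy * cos(th)
  cbind(center[1] + rx, center[2] - ry) # back to image coords
}
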