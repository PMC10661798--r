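# von Mises sampling (Best & Fisher 1979 wrapped-Cauchy envelope rejection).
# kappa = 0 degenerates to the circular uniform distribution.

#' Sample from the von Mises distribution
#'
#' Draws directions (degrees) from the von Mises distribution with mean
#' direction `mu` and concentration `kappa`. `kappa = 0` gives the
#' circular uniform distribution; large `kappa` concentrates tightly
#' around `mu` (circular standard deviation ~ `1/sqrt(kappa)` radians).
#'
#' @param mu mean direction in degrees.
#' @param kappa nonnegative concentration parameter.
#' @param n number of draws.
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible and does not disturb the caller's RNG state.
#' @return `n` angles in degrees in `[0, 360)`.
#' @export
sample_von_mises <- function(mu, kappa, n, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("`n` must be a positive integer")
  if (length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    stop("`kappa` must be a nonnegative real")
  }
  n <- as.integer(n)
  draw <- function() {
    if (kappa == 0) return(stats::runif(n, 0, 360))
    mu_r <- deg2rad(mu)
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(0)
    while (length(out) < n) {
      todo <- n - length(out)
      m <- max(16L, ceiling(todo * 1.3))
      u1 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- stats::runif(m)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      u3 <- stats::runif(m)
      th <- mu_r + sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      out <- c(out, th[ok])
    }
    wrap_angle(rad2deg(out[seq_len(n)]), 360)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Independent per-component substreams derived from one integer seed, so
# adding a generator component never perturbs the draws of another.
derive_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((s * 48271 + as.numeric(k) * 8191 + 12345) %% 2147483647)
}
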