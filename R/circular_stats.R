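# Circular summaries and tests: mean direction / resultant length,
# Rayleigh uniformity test, Watson's two-sample U2 homogeneity test,
# circular histogram binning. Axial (180-degree-periodic) samples are
# handled by the standard doubling construction.

#' Circular mean direction and mean resultant length
#'
#' For a directional sample the mean direction and mean resultant length
#' R are computed from the unit-vector sum. Axial samples (period 180)
#' are doubled before averaging and the mean is halved afterwards; the
#' reported R is that of the doubled angles.
#'
#' @param sample an [angle_sample] (or numeric vector of degrees,
#'   treated as directional).
#' @return a list with `mean` (degrees in `[0, period)`, `NA` when R is
#'   numerically zero), `R` in `[0, 1]`, and `n`.
#' @export
circular_mean_R <- function(sample) {
  s <- as_angle_sample(sample)
  mult <- if (s$period == 180) 2 else 1
  th <- deg2rad(s$angles * mult)
  n <- length(th)
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-12) {
    mu <- NA_real_
  } else {
    mu <- wrap_angle(rad2deg(atan2(S, C)) / mult, s$period)
  }
  list(mean = mu, R = R, n = n)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that directions are uniformly distributed
#' on the circle against a unimodal alternative. The statistic is
#' `Z = n R^2`; the p-value uses the standard series approximation
#' (accurate for n >= 5; smaller samples get a flagged p).
#'
#' @param sample an [angle_sample] or numeric vector of degrees.
#' @return a list with `Z`, `p`, `R`, `n` and `small_n` (TRUE when the
#'   asymptotic p is unreliable because n < 5).
#' @export
rayleigh_test <- function(sample) {
  s <- as_angle_sample(sample)
  cm <- circular_mean_R(s)
  n <- cm$n
  Z <- n * cm$R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(Z = Z, p = p, R = cm$R, n = n, small_n = n < 5)
}

# U2 from a pre-sorted pooled sample: `isa` marks members of the first
# sample among the sorted pooled values. Tie blocks (equal pooled
# values) get the average of the CDF-difference over the block.
u2_from_sorted <- function(ts, isa, n, m, has_ties) {
  N <- n + m
  d <- cumsum(isa) / n - cumsum(!isa) / m
  if (has_ties) {
    blk <- cumsum(c(TRUE, diff(ts) > 0))
    d <- stats::ave(d, blk)
  }
  u2 <- n * m / N^2 * (sum(d^2) - sum(d)^2 / N)
  max(u2, 0)
}

#' Watson's two-sample U2 statistic
#'
#' Nonparametric statistic for homogeneity of two circular samples:
#' with `d_k` the difference of empirical CDF fractions at each pooled
#' order statistic, `U2 = (n m / N^2) * (sum d_k^2 - (sum d_k)^2 / N)`.
#' Invariant to joint rotation of both samples and to swapping the
#' sample labels. Ties are handled by the average-rank convention.
#'
#' @param a,b [angle_sample]s with the same period (numeric vectors are
#'   accepted and treated as directional).
#' @return the U2 statistic (nonnegative scalar).
#' @export
watson_u2 <- function(a, b) {
  a <- as_angle_sample(a); b <- as_angle_sample(b)
  if (a$period != b$period) stop("samples have different periods")
  n <- length(a$angles); m <- length(b$angles)
  t_all <- c(a$angles, b$angles) / a$period
  ord <- order(t_all)
  ts <- t_all[ord]
  isa <- rep(c(TRUE, FALSE), c(n, m))[ord]
  u2_from_sorted(ts, isa, n, m, has_ties = anyDuplicated(ts) > 0)
}

# Large-sample critical points for two-sample U2.
.watson_crit <- c("0.1" = 0.152, "0.05" = 0.187, "0.01" = 0.268,
                  "0.001" = 0.385)

#' Watson's two-sample U2 test with permutation or asymptotic p-value
#'
#' The permutation p-value (default) randomly relabels the pooled sample
#' and is valid at any sample size:
#' `p = (1 + #\{permuted U2 >= observed\}) / (n_permutations + 1)`.
#' The asymptotic method brackets the p-value between the standard
#' large-sample critical points (0.187 at alpha = 0.05, 0.268 at
#' alpha = 0.01); `p_value` then reports the conservative upper bound of
#' the bracket, with the bracket in `p_lower`/`p_upper`.
#'
#' @param a,b [angle_sample]s with the same period.
#' @param method `"permutation"` or `"asymptotic"`.
#' @param n_permutations number of relabelings (>= 999 recommended).
#' @param seed integer seed for the permutation draw.
#' @return an object of class `watson_test`: `U2`, `n`, `m`, `p_value`,
#'   `method`, `n_permutations`, `seed`, `p_lower`, `p_upper`,
#'   `small_n` (asymptotic method with min(n, m) < 8).
#' @export
watson_u2_pvalue <- function(a, b, method = c("permutation", "asymptotic"),
                             n_permutations = 999, seed = 1L) {
  method <- match.arg(method)
  a <- as_angle_sample(a); b <- as_angle_sample(b)
  if (a$period != b$period) stop("samples have different periods")
  n <- length(a$angles); m <- length(b$angles); N <- n + m
  obs <- watson_u2(a, b)
  res <- list(U2 = obs, n = n, m = m, method = method,
              n_permutations = NA_integer_, seed = NA_integer_,
              p_lower = NA_real_, p_upper = NA_real_, small_n = FALSE,
              labels = c(a$label %||% "a", b$label %||% "b"))
  if (method == "permutation") {
    if (n_permutations < 999) {
      stop("permutation method needs n_permutations >= 999")
    }
    t_all <- sort(c(a$angles, b$angles) / a$period)
    has_ties <- anyDuplicated(t_all) > 0
    perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        isa <- logical(N)
        isa[sample.int(N, n)] <- TRUE
        u2_from_sorted(t_all, isa, n, m, has_ties)
      }, numeric(1))
    })
    res$p_value <- (1 + sum(perm >= obs)) / (n_permutations + 1)
    res$n_permutations <- as.integer(n_permutations)
    res$seed <- as.integer(seed)
  } else {
    res$small_n <- min(n, m) < 8
    crit <- .watson_crit
    alphas <- as.numeric(names(crit))
    below <- alphas[obs >= crit]          # alphas at which we reject
    res$p_upper <- if (length(below)) min(below) else 1
    res$p_lower <- if (obs >= crit[["0.001"]]) 0 else {
      above <- alphas[obs < crit]   # alphas we fail to reject at: p > alpha
      max(above)
    }
    res$p_value <- res$p_upper
  }
  structure(res, class = "watson_test")
}

#' @export
print.watson_test <- function(x, ...) {
  cat("Watson's two-sample U2 test of homogeneity\n")
  cat(sprintf("  groups: %s (n = %d) vs %s (m = %d)\n",
              x$labels[1], x$n, x$labels[2], x$m))
  cat(sprintf("  U2 = %.5f\n", x$U2))
  if (x$method == "permutation") {
    cat(sprintf("  p = %.4g (permutation, %d relabelings, seed %d)\n",
                x$p_value, x$n_permutations, x$seed))
  } else {
    cat(sprintf("  p in (%g, %g] (asymptotic bracket)%s\n",
                x$p_lower, x$p_upper,
                if (x$small_n) "  [warning: min(n, m) < 8]" else ""))
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Bin angles for a circular bar (rose) plot
#'
#' Counts angles in `n_bins` half-open bins `[k w, (k+1) w)` of width
#' `w = period / n_bins`.
#'
#' @param sample an [angle_sample] or numeric vector of degrees.
#' @param n_bins number of bins (>= 2, dividing the period evenly).
#' @return a data frame with `bin_start`, `bin_end` (degrees) and
#'   `count`; counts sum to the sample size.
#' @export
bin_angles <- function(sample, n_bins = 24) {
  s <- as_angle_sample(sample)
  if (n_bins < 2 || s$period %% n_bins != 0) {
    stop("`n_bins` must be >= 2 and divide the period evenly")
  }
  w <- s$period / n_bins
  idx <- pmin(floor(s$angles / w), n_bins - 1)  # guard x == period - eps
  counts <- tabulate(idx + 1L, nbins = n_bins)
  data.frame(bin_start = (0:(n_bins - 1)) * w,
             bin_end = (1:n_bins) * w,
             count = counts)
}
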