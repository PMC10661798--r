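# Microsphere tracking: bandpass spot detection with sub-pixel centroid
# refinement, greedy gated nearest-neighbour track linking, and
# per-track movement directions for circular comparison between groups.

# Separable Gaussian blur with replicated edges.
gauss_blur <- function(M, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h):h)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur_rows <- function(M) {
    Mp <- rbind(M[rep(1L, h), , drop = FALSE], M,
                M[rep(nrow(M), h), , drop = FALSE])
    out <- matrix(0, nrow(M), ncol(M))
    for (t in seq_along(k)) {
      out <- out + k[t] * Mp[t:(t + nrow(M) - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(M))))
}

#' Detect particles in a grayscale frame
#'
#' Local maxima of a bandpass-filtered frame (difference of Gaussians
#' at `sigma` and `4 sigma`) above a relative threshold, refined to
#' sub-pixel positions by the intensity-weighted centroid of a window
#' scaled to `sigma`. Deterministic for fixed inputs, and invariant to
#' rescaling of frame intensities (the threshold is relative).
#'
#' @param frame numeric matrix (rows = y, cols = x).
#' @param sigma expected spot scale in pixels.
#' @param threshold relative threshold in `(0, 1)`, as a fraction of
#'   the maximum bandpass response.
#' @return data frame `x, y, intensity` (pixel coordinates, origin
#'   top-left, pixel centers at half-integers); zero rows (with a
#'   warning) for a blank frame.
#' @export
detect_particles <- function(frame, sigma = 1.5, threshold = 0.2) {
  stopifnot(is.matrix(frame), sigma > 0)
  bp <- gauss_blur(frame, sigma) - gauss_blur(frame, 4 * sigma)
  bp[bp < 0] <- 0
  mx <- max(bp)
  if (mx <= 0) {
    warning("blank frame: no particles detected")
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0)))
  }
  H <- nrow(bp); W <- ncol(bp)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- bp
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  ismax <- ctr > threshold * mx
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & ctr >= pad[(2 + di):(H + 1 + di),
                                (2 + dj):(W + 1 + dj)]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0)))
  }
  w <- max(1L, ceiling(2 * sigma))
  out <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    i0 <- max(1L, i - w); i1 <- min(H, i + w)
    j0 <- max(1L, j - w); j1 <- min(W, j + w)
    win <- bp[i0:i1, j0:j1]
    tot <- sum(win)
    ic <- (i0:i1) - 0.5; jc <- (j0:j1) - 0.5
    data.frame(x = sum(win %*% cbind(jc)) / tot,
               y = sum(ic %*% win) / tot,
               intensity = bp[i, j])
  })
  det <- do.call(rbind, out)
  det[order(det$y, det$x), , drop = FALSE]
}

#' Detect particles in every frame of a stack
#'
#' @param frames list of matrices (or a single matrix).
#' @inheritParams detect_particles
#' @return data frame `frame, x, y, intensity`.
#' @export
detect_stack <- function(frames, sigma = 1.5, threshold = 0.2) {
  if (is.matrix(frames)) frames <- list(frames)
  out <- lapply(seq_along(frames), function(f) {
    d <- suppressWarnings(detect_particles(frames[[f]], sigma, threshold))
    if (nrow(d)) cbind(frame = f, d) else
      data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                 intensity = numeric(0))
  })
  do.call(rbind, out)
}

#' Link detections into trajectories
#'
#' Frame-to-frame one-to-one nearest-neighbour assignment, greedy by
#' ascending distance and gated at `max_disp`; tracks may bridge up to
#' `max_gap` missing frames. Detections that cannot be linked start new
#' tracks, so every detection belongs to exactly one track.
#'
#' @param detections data frame `frame, x, y` (e.g. from
#'   [detect_stack()]).
#' @param max_disp maximum linking distance in pixels; default is 3x
#'   the median per-frame nearest-neighbour step.
#' @param max_gap number of missing frames a track may bridge.
#' @return data frame `track_id, frame, x, y`, ordered by track and
#'   frame.
#' @export
link_trajectories <- function(detections, max_disp = NULL, max_gap = 0) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  det <- detections[order(detections$frame), ]
  if (nrow(det) == 0) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  }
  if (is.null(max_disp)) max_disp <- default_max_disp(det)
  if (max_disp <= 0) stop("`max_disp` must be positive")

  frames <- sort(unique(det$frame))
  track_of <- integer(nrow(det))     # assignment per detection row
  last_x <- numeric(0); last_y <- numeric(0)
  last_f <- integer(0)               # per active track
  track_ids <- integer(0)
  next_id <- 1L
  for (f in frames) {
    rows <- which(det$frame == f)
    alive <- which(f - last_f <= max_gap + 1L)
    assigned_det <- rep(FALSE, length(rows))
    assigned_trk <- rep(FALSE, length(alive))
    if (length(alive) && length(rows)) {
      dmat <- outer(last_x[alive], det$x[rows], "-")^2 +
        outer(last_y[alive], det$y[rows], "-")^2
      cand <- which(dmat <= max_disp^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        for (k in ord) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (!assigned_trk[ti] && !assigned_det[di]) {
            assigned_trk[ti] <- TRUE; assigned_det[di] <- TRUE
            trk <- alive[ti]
            track_of[rows[di]] <- track_ids[trk]
            last_x[trk] <- det$x[rows[di]]
            last_y[trk] <- det$y[rows[di]]
            last_f[trk] <- f
          }
        }
      }
    }
    for (di in which(!assigned_det)) {
      track_of[rows[di]] <- next_id
      last_x <- c(last_x, det$x[rows[di]])
      last_y <- c(last_y, det$y[rows[di]])
      last_f <- c(last_f, f)
      track_ids <- c(track_ids, next_id)
      next_id <- next_id + 1L
    }
    # retire tracks that can no longer be extended
    keep <- f - last_f <= max_gap
    last_x <- last_x[keep]; last_y <- last_y[keep]
    last_f <- last_f[keep]; track_ids <- track_ids[keep]
  }
  out <- data.frame(track_id = track_of, frame = det$frame,
                    x = det$x, y = det$y)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

default_max_disp <- function(det) {
  frames <- sort(unique(det$frame))
  if (length(frames) < 2) return(5)
  steps <- numeric(0)
  for (k in seq_len(min(5L, length(frames) - 1L))) {
    a <- det[det$frame == frames[k], ]
    b <- det[det$frame == frames[k + 1L], ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
    steps <- c(steps, apply(d, 1, min))
  }
  if (!length(steps)) 5 else 3 * stats::median(steps)
}

#' Per-track summaries
#'
#' Net first-to-last displacement and its direction (the primary
#' movement direction, robust to jitter), plus the circular mean of
#' per-step directions as a secondary measure.
#'
#' @param tracks data frame `track_id, frame, x, y`.
#' @return data frame `track_id, n_points, net_displacement, direction,
#'   step_direction` (directions `NA` where undefined).
#' @export
track_summaries <- function(tracks) {
  out <- lapply(split(tracks, tracks$track_id), function(p) {
    p <- p[order(p$frame), ]
    np <- nrow(p)
    dx <- p$x[np] - p$x[1]; dy <- p$y[np] - p$y[1]
    net <- sqrt(dx^2 + dy^2)
    stepdir <- NA_real_
    if (np >= 2) {
      sd_ang <- direction_deg(diff(p$x), diff(p$y))
      sd_ang <- sd_ang[!is.na(sd_ang)]
      if (length(sd_ang)) {
        stepdir <- circular_mean_R(angle_sample(sd_ang, 360))$mean
      }
    }
    data.frame(track_id = p$track_id[1], n_points = np,
               net_displacement = net,
               direction = if (net > 0) direction_deg(dx, dy) else NA_real_,
               step_direction = stepdir)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Movement-direction sample from tracks
#'
#' One direction per track whose net displacement reaches `min_disp`
#' (excluding Brownian-only tracks), as an [angle_sample] for circular
#' comparison.
#'
#' @param tracks data frame `track_id, frame, x, y`.
#' @param min_disp minimum net displacement in pixels.
#' @param label group label for the sample.
#' @return an [angle_sample] with period 360.
#' @export
direction_sample <- function(tracks, min_disp = 2, label = NULL) {
  s <- track_summaries(tracks)
  s <- s[!is.na(s$direction) & s$net_displacement >= min_disp, ]
  if (nrow(s) == 0) stop("no track reaches `min_disp`: empty direction sample")
  angle_sample(s$direction, period = 360, label = label)
}

#' Compare movement directions of two groups
#'
#' Watson's two-sample U2 homogeneity test on the per-track direction
#' samples of two groups (e.g. wild-type-like vs mutant-like flow).
#'
#' @param sample_a,sample_b [angle_sample]s of movement directions.
#' @param method,n_permutations,seed passed to [watson_u2_pvalue()].
#' @return a `watson_test` object annotated with group labels.
#' @export
compare_flow <- function(sample_a, sample_b,
                         method = c("permutation", "asymptotic"),
                         n_permutations = 999, seed = 1L) {
  watson_u2_pvalue(sample_a, sample_b, method = method,
                   n_permutations = n_permutations, seed = seed)
}
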