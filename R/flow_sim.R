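# Synthetic near-wall flow: microspheres advected by a direction field
# (coherent unidirectional, as over a healthy ciliated wall, or a
# smooth spatially disorganized field emulating turbulent flow) plus
# Brownian noise, rendered as Gaussian spots in an image stack.

#' Flow-field configuration
#'
#' @param regime `"coherent"` (a single global flow direction) or
#'   `"disorganized"` (a smooth swirl field whose directions span the
#'   full circle).
#' @param mean_direction flow direction in degrees (coherent regime).
#' @param speed_px_per_frame advection speed.
#' @param diffusion_px standard deviation of the per-frame Brownian
#'   step (each axis).
#' @param n_particles,n_frames stack dimensions.
#' @param domain_size `c(width, height)` in pixels.
#' @param spot_sigma Gaussian spot width for rendering.
#' @param min_separation minimum initial particle separation (beads at
#'   the working dilution are well separated; this keeps detection
#'   identifiable).
#' @param spawn_inset margin from the border for initial positions.
#' @param seed integer seed.
#' @return an object of class `flow_config`.
#' @export
flow_config <- function(regime = c("coherent", "disorganized"),
                        mean_direction = 45, speed_px_per_frame = 2,
                        diffusion_px = 0.3, n_particles = 100,
                        n_frames = 50, domain_size = c(256, 256),
                        spot_sigma = 1.5, min_separation = 6,
                        spawn_inset = 10, seed = 1L) {
  regime <- match.arg(regime)
  if (n_particles < 1 || n_frames < 1) {
    stop("`n_particles` and `n_frames` must be positive")
  }
  if (speed_px_per_frame <= 0) stop("`speed_px_per_frame` must be positive")
  if (diffusion_px < 0) stop("`diffusion_px` must be nonnegative")
  structure(list(regime = regime,
                 mean_direction = wrap_angle(mean_direction, 360),
                 speed_px_per_frame = speed_px_per_frame,
                 diffusion_px = diffusion_px,
                 n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames),
                 domain_size = as.integer(domain_size),
                 spot_sigma = spot_sigma,
                 min_separation = min_separation,
                 spawn_inset = spawn_inset,
                 seed = as.integer(seed)),
            class = "flow_config")
}

# Direction (degrees) of the flow field at (x, y). The disorganized
# field is a smooth swirl about the domain center: tangential to
# circles, so directions span the full 360 degrees.
flow_field_direction <- function(config, x, y) {
  if (config$regime == "coherent") {
    rep(config$mean_direction, length(x))
  } else {
    cx <- config$domain_size[1] / 2
    cy <- config$domain_size[2] / 2
    radial <- rad2deg(atan2(-(y - cy), x - cx))
    wrap_angle(radial + 90, 360)
  }
}

#' Generate a synthetic microsphere flow video with ground truth
#'
#' Particles advance each frame by `speed * direction_field(position)`
#' plus an isotropic Gaussian step of scale `diffusion_px`, and are
#' dropped once they leave the domain. Frames render each active
#' particle as a unit-amplitude Gaussian spot.
#'
#' @param config a [flow_config()].
#' @return list with `frames` (list of H x W matrices in `[0, 1]`),
#'   `truth` (list of `positions` — data frame `particle_id, frame, x,
#'   y` — and `net` — per-particle net displacement and direction), and
#'   `config`.
#' @export
generate_flow_video <- function(config) {
  stopifnot(inherits(config, "flow_config"))
  W <- config$domain_size[1]; H <- config$domain_size[2]
  np <- config$n_particles; nf <- config$n_frames
  ins <- config$spawn_inset

  pos0 <- with_seed(derive_seed(config$seed, 11L), {
    p <- poisson_disk_seeds(np, W - 2 * ins, H - 2 * ins,
                            r = config$min_separation)
    p + ins
  })
  steps <- with_seed(derive_seed(config$seed, 12L), {
    if (config$diffusion_px > 0) {
      array(stats::rnorm(np * nf * 2, 0, config$diffusion_px),
            dim = c(np, nf, 2))
    } else array(0, dim = c(np, nf, 2))
  })

  x <- pos0[, 1]; y <- pos0[, 2]
  active <- rep(TRUE, np)
  frames <- vector("list", nf)
  pos_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    frames[[f]] <- render_spots(x[active], y[active], W, H,
                                config$spot_sigma)
    pos_rows[[f]] <- data.frame(particle_id = which(active),
                                frame = f, x = x[active], y = y[active])
    th <- deg2rad(flow_field_direction(config, x, y))
    x <- x + config$speed_px_per_frame * cos(th) + steps[, f, 1]
    y <- y - config$speed_px_per_frame * sin(th) + steps[, f, 2]
    active <- active & x >= 0 & x < W & y >= 0 & y < H
  }
  positions <- do.call(rbind, pos_rows)
  positions <- positions[order(positions$particle_id, positions$frame), ]
  rownames(positions) <- NULL

  net <- do.call(rbind, lapply(split(positions, positions$particle_id),
    function(p) {
      dx <- p$x[nrow(p)] - p$x[1]; dy <- p$y[nrow(p)] - p$y[1]
      data.frame(particle_id = p$particle_id[1], n_frames = nrow(p),
                 net_displacement = sqrt(dx^2 + dy^2),
                 direction = direction_deg(dx, dy))
    }))
  rownames(net) <- NULL

  list(frames = frames, truth = list(positions = positions, net = net),
       config = config)
}

# Additively render unit-amplitude Gaussian spots into an H x W frame.
# Pixel centers at (col - 0.5, row - 0.5).
render_spots <- function(x, y, W, H, sigma) {
  fr <- matrix(0, nrow = H, ncol = W)
  if (length(x) == 0) return(fr)
  w <- ceiling(4 * sigma)
  for (k in seq_along(x)) {
    j0 <- max(1L, floor(x[k] - w)); j1 <- min(W, ceiling(x[k] + w))
    i0 <- max(1L, floor(y[k] - w)); i1 <- min(H, ceiling(y[k] + w))
    if (j0 > j1 || i0 > i1) next
    jc <- (j0:j1) - 0.5; ic <- (i0:i1) - 0.5
    gx <- exp(-(jc - x[k])^2 / (2 * sigma^2))
    gy <- exp(-(ic - y[k])^2 / (2 * sigma^2))
    fr[i0:i1, j0:j1] <- fr[i0:i1, j0:j1] + outer(gy, gx)
  }
  pmin(fr, 1)
}
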