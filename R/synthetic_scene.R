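# Synthetic epithelial mosaic with ground truth. Cells are a discrete
# Voronoi tessellation of Poisson-disk seeds (one Lloyd relaxation
# step), giving convex, roughly isotropic cells. Each cell's basal-body
# patch centroid is offset from the cell centroid by a controllable
# fraction of the equivalent radius, in a direction drawn from a von
# Mises distribution around the global polarity direction; basal bodies
# scatter in an ellipse elongated along an axial von Mises axis, and
# each carries one basal-foot point displaced in a von Mises direction
# (rotational polarity). Point tables are authoritative; the label
# image is a derived view.

#' Scene configuration for the synthetic epithelium
#'
#' @param n_cells number of cells.
#' @param domain_size `c(width, height)` in pixels.
#' @param mu_global global polarity direction, degrees in `[0, 360)`.
#' @param kappa_trans von Mises concentration of the per-cell
#'   patch-offset direction (0 = uniform, i.e. no translational
#'   polarity coordination).
#' @param kappa_rot concentration of basal-foot directions (rotational
#'   polarity).
#' @param kappa_feret concentration (axial) of the patch elongation
#'   axis.
#' @param offset_frac patch-centroid offset as a fraction of the
#'   equivalent cell radius, in `[0, 1)`.
#' @param bb_per_patch basal bodies per patch.
#' @param foot_offset_px distance from each basal body to its basal
#'   foot.
#' @param bb_min_sep minimum spacing between basal bodies within a
#'   patch; basal bodies keep a lattice-like spacing wider than the
#'   basal-foot length, which is what makes foot-to-nearest-body
#'   pairing well posed. Default twice `foot_offset_px`.
#' @param patch_ax,patch_bx semi-axes of the basal-body scatter
#'   ellipse, as fractions of the equivalent cell radius (major,
#'   minor).
#' @param seed integer seed; expands to independent per-component
#'   substreams.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(n_cells = 200, domain_size = c(640, 640),
                         mu_global = 90, kappa_trans = 8, kappa_rot = 8,
                         kappa_feret = 8, offset_frac = 0.35,
                         bb_per_patch = 16, foot_offset_px = 1.5,
                         bb_min_sep = 2 * foot_offset_px,
                         patch_ax = 0.45, patch_bx = 0.2, seed = 1L) {
  if (n_cells < 1) stop("`n_cells` must be positive")
  if (any(c(kappa_trans, kappa_rot, kappa_feret) < 0)) {
    stop("kappa values must be nonnegative (0 means uniform)")
  }
  if (offset_frac < 0 || offset_frac >= 1) stop("`offset_frac` must be in [0, 1)")
  if (bb_per_patch < 1) stop("`bb_per_patch` must be positive")
  if (foot_offset_px <= 0) stop("`foot_offset_px` must be positive")
  area_per_cell <- prod(domain_size) / n_cells
  if (area_per_cell < 16) stop("domain too small for `n_cells` Poisson-disk seeds")
  structure(list(n_cells = as.integer(n_cells),
                 domain_size = as.integer(domain_size),
                 mu_global = wrap_angle(mu_global, 360),
                 kappa_trans = kappa_trans, kappa_rot = kappa_rot,
                 kappa_feret = kappa_feret, offset_frac = offset_frac,
                 bb_per_patch = as.integer(bb_per_patch),
                 foot_offset_px = foot_offset_px,
                 bb_min_sep = bb_min_sep,
                 patch_ax = patch_ax, patch_bx = patch_bx,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Preset scene configurations
#'
#' `"wildtype"`: coordinated polarity (offset_frac 0.35, all kappas 8).
#' `"mutant"`: weak, uncoordinated polarity (offset_frac 0.10, all
#' kappas 0), emulating randomly oriented, centrally located patches.
#'
#' @param preset `"wildtype"` or `"mutant"`.
#' @param ... overrides passed to [scene_config()].
#' @export
scene_preset <- function(preset = c("wildtype", "mutant"), ...) {
  preset <- match.arg(preset)
  args <- if (preset == "wildtype") {
    list()
  } else {
    list(kappa_trans = 0, kappa_rot = 0, kappa_feret = 0,
         offset_frac = 0.10)
  }
  do.call(scene_config, utils::modifyList(args, list(...)))
}

# Poisson-disk seeds by dart throwing; shrinks the exclusion radius if
# the target count cannot be placed (deterministic under the RNG state).
poisson_disk_seeds <- function(n, W, H, r = NULL) {
  if (is.null(r)) r <- 0.7 * sqrt(W * H / n)
  pts <- matrix(numeric(0), ncol = 2)
  repeat {
    attempts <- 0L
    while (nrow(pts) < n && attempts < 400L * n) {
      cand <- c(stats::runif(1, 0, W), stats::runif(1, 0, H))
      if (nrow(pts) == 0 ||
          min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= r^2) {
        pts <- rbind(pts, cand)
      }
      attempts <- attempts + 1L
    }
    if (nrow(pts) >= n) break
    r <- r * 0.85
  }
  unname(pts)
}

# Blue-noise scatter inside an axis-aligned ellipse: dart throwing
# with a minimum separation, relaxed geometrically if the ellipse
# cannot hold `n` points at that spacing.
scatter_ellipse <- function(n, a, b, min_sep) {
  pts <- matrix(numeric(0), ncol = 2)
  sep2 <- min_sep^2
  attempts <- 0L
  while (nrow(pts) < n) {
    rr <- sqrt(stats::runif(1)); ph <- stats::runif(1, 0, 2 * pi)
    cand <- c(a * rr * cos(ph), b * rr * sin(ph))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= sep2) {
      pts <- rbind(pts, cand)
      attempts <- 0L
    } else if ((attempts <- attempts + 1L) > 60L * n) {
      sep2 <- sep2 * 0.7
      attempts <- 0L
    }
  }
  unname(pts)
}

# Discrete Voronoi assignment of pixel centers to the nearest seed.
voronoi_label <- function(seeds, W, H) {
  px <- rep(seq_len(W) - 0.5, each = H)   # column-major: matrix is H x W
  py <- rep(seq_len(H) - 0.5, times = W)
  best <- rep(Inf, W * H)
  lab <- integer(W * H)
  for (k in seq_len(nrow(seeds))) {
    d <- (px - seeds[k, 1])^2 + (py - seeds[k, 2])^2
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- k
  }
  matrix(lab, nrow = H, ncol = W)
}

#' Generate a synthetic epithelial mosaic with ground truth
#'
#' @param config a [scene_config()].
#' @return list with:
#'   * `label` — H x W integer label matrix (background-free partition,
#'     cells 1..n);
#'   * `points` — data frame `cell_id, x, y, kind` with `kind` in
#'     `{"bb", "foot"}` (foot rows follow their basal body rows in
#'     order);
#'   * `truth` — list of `cells` (per-cell true offset direction
#'     `psi_true`, `td_true`, axis `axis_true`, measured-from-pixels
#'     centroid and `r_eq`, `clipped` flag) and `bbs` (per basal body:
#'     true position, foot position, true foot direction
#'     `foot_angle_true`);
#'   * `config` — the input configuration.
#' @export
generate_mosaic <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  W <- config$domain_size[1]; H <- config$domain_size[2]
  n <- config$n_cells

  seeds <- with_seed(derive_seed(config$seed, 1L),
                     poisson_disk_seeds(n, W, H))
  # one Lloyd relaxation step: move each seed to its region centroid
  lab0 <- voronoi_label(seeds, W, H)
  cs <- cells_from_label(lab0)
  seeds2 <- cbind(cs$cx, cs$cy)[order(cs$cell_id), , drop = FALSE]
  label <- voronoi_label(seeds2, W, H)
  cells <- cells_from_label(label)

  psi <- sample_von_mises(config$mu_global, config$kappa_trans, n,
                          seed = derive_seed(config$seed, 2L))
  # axial sampling: draw on doubled angles, halve
  axis2 <- sample_von_mises(2 * config$mu_global, config$kappa_feret, n,
                            seed = derive_seed(config$seed, 3L))
  axis <- wrap_angle(axis2 / 2, 180)

  nbb <- config$bb_per_patch
  foot_dirs <- sample_von_mises(config$mu_global, config$kappa_rot,
                                n * nbb,
                                seed = derive_seed(config$seed, 4L))
  dim(foot_dirs) <- c(nbb, n)

  inside <- function(x, y, id) {
    i <- floor(y) + 1L; j <- floor(x) + 1L
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    ok[ok] <- label[cbind(i[ok], j[ok])] == id
    ok
  }

  bb_rows <- vector("list", n)
  cell_truth <- vector("list", n)
  scatter_seed <- derive_seed(config$seed, 5L)
  with_seed(scatter_seed, {
    for (i in seq_len(n)) {
      cl <- cells[i, ]
      td_true <- config$offset_frac * cl$r_eq
      pc <- c(cl$cx + td_true * cos(deg2rad(psi[i])),
              cl$cy - td_true * sin(deg2rad(psi[i])))
      a <- config$patch_ax * cl$r_eq
      b <- config$patch_bx * cl$r_eq
      th <- deg2rad(axis[i])
      u <- c(cos(th), -sin(th))       # major axis, image coords
      v <- c(-sin(th), -cos(th))      # minor axis (perpendicular)
      clipped <- FALSE
      for (try in seq_len(25L)) {
        sc <- scatter_ellipse(nbb, a, b, config$bb_min_sep)
        e1 <- sc[, 1]; e2 <- sc[, 2]
        bx <- pc[1] + e1 * u[1] + e2 * v[1]
        by <- pc[2] + e1 * u[2] + e2 * v[2]
        fth <- deg2rad(foot_dirs[, i])
        fx <- bx - config$foot_offset_px * cos(fth)
        fy <- by + config$foot_offset_px * sin(fth)
        if (all(inside(bx, by, cl$cell_id)) &&
            all(inside(fx, fy, cl$cell_id))) break
        if (try == 25L) clipped <- TRUE
      }
      if (clipped) {
        # pull out-of-cell points toward the cell centroid until inside
        pull <- function(x, y) {
          bad <- !inside(x, y, cl$cell_id)
          it <- 0L
          while (any(bad) && it < 50L) {
            x[bad] <- x[bad] + 0.1 * (cl$cx - x[bad])
            y[bad] <- y[bad] + 0.1 * (cl$cy - y[bad])
            bad <- !inside(x, y, cl$cell_id)
            it <- it + 1L
          }
          cbind(x, y)
        }
        bbp <- pull(bx, by); bx <- bbp[, 1]; by <- bbp[, 2]
        ftp <- pull(fx, fy); fx <- ftp[, 1]; fy <- ftp[, 2]
      }
      bb_rows[[i]] <- data.frame(
        cell_id = cl$cell_id, bb_index = seq_len(nbb),
        x = bx, y = by, foot_x = fx, foot_y = fy,
        foot_angle_true = foot_dirs[, i])
      cell_truth[[i]] <- data.frame(
        cell_id = cl$cell_id, cx = cl$cx, cy = cl$cy, r_eq = cl$r_eq,
        psi_true = psi[i], td_true = td_true, axis_true = axis[i],
        border = cl$border, clipped = clipped)
    }
  })
  bbs <- do.call(rbind, bb_rows)
  truth_cells <- do.call(rbind, cell_truth)

  points <- rbind(
    data.frame(cell_id = bbs$cell_id, x = bbs$x, y = bbs$y, kind = "bb"),
    data.frame(cell_id = bbs$cell_id, x = bbs$foot_x, y = bbs$foot_y,
               kind = "foot"))
  points <- points[order(points$cell_id, points$kind), ]
  rownames(points) <- NULL

  list(label = label, points = points,
       truth = list(cells = truth_cells, bbs = bbs),
       config = config)
}
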