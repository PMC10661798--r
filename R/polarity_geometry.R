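# Per-cell polarity measurements: translational distance (TD) and
# basal-body patch angle (TA) from the cell centroid C and the basal-body
# patch centroid BC; Feret's angle (FA) and longest diameter (LD) of the
# patch; rotational-polarity vectors from basal-foot points to their
# nearest basal bodies.

#' Area-weighted centroid of a simple polygon
#'
#' Shoelace-formula centroid; independent of vertex orientation and of
#' whether the first vertex is repeated at the end.
#'
#' @param boundary a two-column matrix or data frame of vertex
#'   coordinates (x, y), >= 3 vertices, simple (non-self-intersecting).
#' @return numeric `c(x, y)`.
#' @export
polygon_centroid <- function(boundary) {
  p <- as.matrix(boundary)
  if (ncol(p) < 2) stop("`boundary` needs x and y columns")
  p <- p[, 1:2, drop = FALSE]
  # drop a repeated closing vertex
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) stop("a polygon needs at least 3 distinct vertices")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  A <- sum(cross) / 2
  if (abs(A) < 1e-12) stop("degenerate (zero-area) polygon")
  cx <- sum((x + xn) * cross) / (6 * A)
  cy <- sum((y + yn) * cross) / (6 * A)
  c(x = cx, y = cy)
}

#' Translational distance between cell and patch centroids
#'
#' Euclidean distance TD between the cell centroid C and the basal-body
#' patch centroid BC.
#'
#' @param C,BC points as numeric `c(x, y)`.
#' @return distance in pixels.
#' @export
translational_distance <- function(C, BC) {
  if (!all(is.finite(C)) || !all(is.finite(BC))) stop("non-finite point")
  sqrt(sum((as.numeric(BC) - as.numeric(C))^2))
}

#' Basal-body patch angle
#'
#' Direction TA of the vector from the cell centroid C to the patch
#' centroid BC, in degrees counterclockwise from +x in a y-up frame
#' (coordinates are image coordinates with y downward, so TA is
#' `atan2(-dy, dx)`).
#'
#' @param C,BC points as numeric `c(x, y)` in image coordinates.
#' @return degrees in `[0, 360)`; `NA` when C == BC (undefined angle,
#'   flagged rather than an error).
#' @export
bb_patch_angle <- function(C, BC) {
  d <- as.numeric(BC) - as.numeric(C)
  direction_deg(d[1], d[2])
}

#' Feret's angle and longest diameter of a point set
#'
#' LD is the maximum pairwise distance of the points (computed over the
#' convex-hull vertices); FA is the axial orientation of a maximizing
#' pair, in `[0, 180)`. When several pairs attain the maximum the
#' smallest FA is reported.
#'
#' @param points two-column matrix or data frame of (x, y) in image
#'   coordinates; >= 2 distinct points.
#' @return list with `LD` (pixels) and `FA` (degrees in `[0, 180)`).
#' @export
ferets_angle <- function(points) {
  p <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  if (nrow(p) < 2) stop("Feret's angle needs at least 2 distinct points")
  hull <- if (nrow(p) > 3) {
    h <- tryCatch(grDevices::chull(p[, 1], p[, 2]), error = function(e) NULL)
    if (is.null(h) || length(h) < 2) seq_len(nrow(p)) else h
  } else seq_len(nrow(p))
  q <- p[hull, , drop = FALSE]
  k <- nrow(q)
  ij <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  dx <- q[ij[, 2], 1] - q[ij[, 1], 1]
  dy <- q[ij[, 2], 2] - q[ij[, 1], 2]
  d2 <- dx^2 + dy^2
  dmax <- max(d2)
  best <- which(d2 >= dmax * (1 - 1e-12))
  fa <- wrap_angle(rad2deg(atan2(-dy[best], dx[best])), 180)
  list(LD = sqrt(dmax), FA = min(fa))
}

#' Rotational-polarity vectors from basal feet to basal bodies
#'
#' Pairs each basal-foot point with its nearest basal-body point within
#' a distance gate, one-to-one, greedily by ascending distance (ties
#' broken by lower point index). The vector direction from foot to
#' basal body reports the rotational polarity of that basal body.
#'
#' @param foot_points,bb_points two-column matrices or data frames of
#'   (x, y) in image coordinates; both nonempty.
#' @param max_gate maximum pairing distance in pixels; default is twice
#'   the median foot-to-nearest-bb spacing.
#' @return list with `vectors` (data frame: `foot_id`, `bb_id`,
#'   `foot_x`, `foot_y`, `bb_x`, `bb_y`, `angle` degrees in `[0, 360)`,
#'   `length` px) and `unmatched_feet` (integer indices of feet left
#'   unpaired).
#' @export
rotational_vectors <- function(foot_points, bb_points, max_gate = NULL) {
  fp <- as.matrix(foot_points)[, 1:2, drop = FALSE]
  bp <- as.matrix(bb_points)[, 1:2, drop = FALSE]
  if (nrow(fp) < 1 || nrow(bp) < 1) stop("both point sets must be nonempty")
  dmat <- outer(fp[, 1], bp[, 1], "-")^2 + outer(fp[, 2], bp[, 2], "-")^2
  if (is.null(max_gate)) {
    nn <- sqrt(apply(dmat, 1, min))
    max_gate <- 2 * stats::median(nn)
  }
  if (max_gate <= 0) stop("`max_gate` must be positive")
  idx <- which(dmat <= max_gate^2, arr.ind = TRUE)
  fid <- integer(0); bid <- integer(0)
  if (nrow(idx) > 0) {
    d <- dmat[idx]
    ord <- order(d, idx[, 1], idx[, 2])
    f_used <- logical(nrow(fp)); b_used <- logical(nrow(bp))
    for (k in ord) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (!f_used[i] && !b_used[j]) {
        f_used[i] <- TRUE; b_used[j] <- TRUE
        fid <- c(fid, i); bid <- c(bid, j)
      }
    }
  }
  if (length(fid)) {
    o <- order(fid)
    fid <- fid[o]; bid <- bid[o]
    dx <- bp[bid, 1] - fp[fid, 1]
    dy <- bp[bid, 2] - fp[fid, 2]
    vec <- data.frame(
      foot_id = fid, bb_id = bid,
      foot_x = fp[fid, 1], foot_y = fp[fid, 2],
      bb_x = bp[bid, 1], bb_y = bp[bid, 2],
      angle = direction_deg(dx, dy),
      length = sqrt(dx^2 + dy^2)
    )
  } else {
    vec <- data.frame(foot_id = integer(0), bb_id = integer(0),
                      foot_x = numeric(0), foot_y = numeric(0),
                      bb_x = numeric(0), bb_y = numeric(0),
                      angle = numeric(0), length = numeric(0))
  }
  list(vectors = vec,
       unmatched_feet = setdiff(seq_len(nrow(fp)), fid))
}

#' Cell records from a label image
#'
#' Extracts per-cell geometry from a label matrix (background 0, cells
#' 1..n): pixel-mass centroid, area, equivalent radius (radius of the
#' circle with equal area), and whether the cell touches the image
#' border (truncated cells are excluded from summaries by default).
#' Pixel centers are at `(col - 0.5, row - 0.5)`, origin top-left.
#'
#' @param label integer matrix of cell labels.
#' @return data frame: `cell_id`, `cx`, `cy`, `area`, `r_eq`, `border`.
#' @export
cells_from_label <- function(label) {
  label <- as.matrix(label)
  ids <- sort(unique(as.vector(label)))
  ids <- ids[ids > 0]
  nr <- nrow(label); nc <- ncol(label)
  rows <- row(label); cols <- col(label)
  out <- lapply(ids, function(id) {
    sel <- label == id
    r <- rows[sel]; cl <- cols[sel]
    area <- length(r)
    data.frame(cell_id = id,
               cx = mean(cl) - 0.5, cy = mean(r) - 0.5,
               area = area, r_eq = sqrt(area / pi),
               border = any(r == 1 | r == nr | cl == 1 | cl == nc))
  })
  do.call(rbind, out)
}

#' Cell records from a polygons table
#'
#' Alternative input path: per-cell boundary polygons given as a long
#' table. Centroid and area come from the shoelace formula.
#'
#' @param polys data frame with columns `cell_id`, `vertex_index`, `x`,
#'   `y`.
#' @return data frame as in [cells_from_label()] (`border` is FALSE;
#'   polygon inputs are assumed untruncated).
#' @export
cells_from_polygons <- function(polys) {
  stopifnot(all(c("cell_id", "vertex_index", "x", "y") %in% names(polys)))
  ids <- sort(unique(polys$cell_id))
  out <- lapply(ids, function(id) {
    p <- polys[polys$cell_id == id, ]
    p <- p[order(p$vertex_index), c("x", "y")]
    cen <- polygon_centroid(p)
    x <- p$x; y <- p$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    area <- abs(sum(x * yn - xn * y) / 2)
    data.frame(cell_id = id, cx = cen[["x"]], cy = cen[["y"]],
               area = area, r_eq = sqrt(area / pi), border = FALSE)
  })
  do.call(rbind, out)
}

#' Per-cell polarity measurements
#'
#' Joins cell records with basal-body points and computes, per cell:
#' the patch centroid (unweighted mean of its basal-body points),
#' translational distance TD and its cell-size-normalized form
#' `TD_norm = TD / r_eq`, the patch angle TA, and the patch Feret
#' measurements LD and FA (patch-level by default; `per_bb = TRUE`
#' instead reports, per cell, the circular-axial mean of the Feret
#' angles of each basal body's 3-nearest-neighbour neighbourhood).
#'
#' @param cells data frame from [cells_from_label()] or
#'   [cells_from_polygons()].
#' @param points data frame with `cell_id`, `x`, `y` (basal-body
#'   positions; a `kind` column, if present, is filtered to `"bb"`).
#' @param per_bb compute FA per basal-body neighbourhood instead of per
#'   patch.
#' @return data frame: `cell_id`, `n_bb`, `TD`, `TD_norm`, `TA`, `FA`,
#'   `LD`, `border`. `TA` is `NA` when TD = 0; `FA`/`LD` are `NA` for
#'   single-point patches.
#' @export
measure_polarity <- function(cells, points, per_bb = FALSE) {
  if ("kind" %in% names(points)) points <- points[points$kind == "bb", ]
  stopifnot(all(c("cell_id", "x", "y") %in% names(points)))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    p <- points[points$cell_id == cl$cell_id, c("x", "y")]
    n_bb <- nrow(p)
    if (n_bb == 0) {
      return(data.frame(cell_id = cl$cell_id, n_bb = 0L, TD = NA_real_,
                        TD_norm = NA_real_, TA = NA_real_, FA = NA_real_,
                        LD = NA_real_, border = cl$border))
    }
    BC <- c(mean(p$x), mean(p$y))
    C <- c(cl$cx, cl$cy)
    TD <- translational_distance(C, BC)
    TA <- bb_patch_angle(C, BC)
    if (n_bb >= 2 && nrow(unique(p)) >= 2) {
      if (per_bb) {
        fa <- per_bb_feret(as.matrix(p))
        fer <- ferets_angle(p)
        fer$FA <- fa
      } else {
        fer <- ferets_angle(p)
      }
    } else {
      fer <- list(LD = NA_real_, FA = NA_real_)
    }
    data.frame(cell_id = cl$cell_id, n_bb = n_bb, TD = TD,
               TD_norm = TD / cl$r_eq, TA = TA, FA = fer$FA, LD = fer$LD,
               border = cl$border)
  })
  do.call(rbind, out)
}

# Axial mean of Feret angles of each point's 3-nearest-neighbour
# neighbourhood; a local variant of the patch-level Feret orientation.
per_bb_feret <- function(p) {
  n <- nrow(p)
  k <- min(3L, n - 1L)
  d <- as.matrix(stats::dist(p))
  fa <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k + 1L)]  # includes i itself
    ferets_angle(p[nb, , drop = FALSE])$FA
  }, numeric(1))
  circular_mean_R(angle_sample(fa, period = 180))$mean
}

#' Group summaries of polarity measurements
#'
#' Per-group sample size, mean +/- SEM of TD and TD_norm, circular
#' summaries of TA (directional) and FA (axial), and — with exactly two
#' groups — a two-tailed Welch t-test on TD.
#'
#' @param measurements data frame from [measure_polarity()] plus a
#'   `group` column.
#' @param include_border include cells flagged as touching the image
#'   border (default FALSE: truncated polygons bias centroids).
#' @return list with `summary` (one row per group) and `t_test` (list
#'   with `t`, `df`, `p`, or NULL unless exactly two groups with
#'   n >= 2 each).
#' @export
summarize_cells <- function(measurements, include_border = FALSE) {
  stopifnot("group" %in% names(measurements))
  m <- measurements
  if (!include_border && "border" %in% names(m)) m <- m[!m$border, ]
  m <- m[!is.na(m$TD), ]
  groups <- unique(m$group)
  rows <- lapply(groups, function(g) {
    x <- m[m$group == g, ]
    n <- nrow(x)
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    ta <- x$TA[!is.na(x$TA)]
    fa <- x$FA[!is.na(x$FA)]
    ta_s <- if (length(ta)) circular_mean_R(angle_sample(ta, 360)) else
      list(mean = NA_real_, R = NA_real_)
    fa_s <- if (length(fa)) circular_mean_R(angle_sample(fa, 180)) else
      list(mean = NA_real_, R = NA_real_)
    data.frame(group = g, n = n,
               td_mean = mean(x$TD), td_sem = if (n >= 2) sem(x$TD) else NA,
               td_norm_mean = mean(x$TD_norm),
               td_norm_sem = if (n >= 2) sem(x$TD_norm) else NA,
               ta_mean = ta_s$mean, ta_R = ta_s$R,
               fa_mean = fa_s$mean, fa_R = fa_s$R)
  })
  summary <- do.call(rbind, rows)
  t_test <- NULL
  if (length(groups) == 2 && all(summary$n >= 2)) {
    tt <- stats::t.test(TD ~ group, data = m)
    t_test <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value,
                   groups = as.character(groups))
  }
  list(summary = summary, t_test = t_test)
}
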