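#' @keywords internal
"_PACKAGE"

# Angle conventions used throughout the package
# ---------------------------------------------
# External unit is degrees. Directions are measured counterclockwise from
# the +x axis in a y-up frame. Image coordinates have y pointing down
# (origin top-left), so the direction of an image-space displacement
# (dx, dy) is atan2(-dy, dx). Directional data live in [0, 360);
# axial data (orientations defined modulo a half turn) live in [0, 180).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap angles into a period
#'
#' @param x angles in degrees.
#' @param period 360 for directional data, 180 for axial data.
#' @return angles wrapped into `[0, period)`.
#' @export
wrap_angle <- function(x, period = 360) {
  out <- x %% period
  # guard against -1e-16 %% 360 == 360 after floating point
  out[out >= period] <- out[out >= period] - period
  out
}

#' Direction of an image-space displacement
#'
#' Converts a displacement in image coordinates (x rightward, y downward)
#' into a direction in degrees, counterclockwise from +x in a y-up frame.
#'
#' @param dx,dy displacement components in image coordinates (pixels).
#' @return direction in degrees in `[0, 360)`; `NA` where both are zero.
#' @export
direction_deg <- function(dx, dy) {
  ang <- rad2deg(atan2(-dy, dx))
  ang <- wrap_angle(ang, 360)
  ang[dx == 0 & dy == 0] <- NA_real_
  ang
}

#' Construct an angle sample
#'
#' A labelled collection of angles with a declared period: 360 for
#' directional data (e.g. basal-body patch angles, flow directions),
#' 180 for axial data (e.g. Feret's angles), which are analysed by
#' doubling, averaging and halving.
#'
#' @param angles numeric vector of angles in degrees; wrapped into
#'   `[0, period)`.
#' @param period 360 or 180.
#' @param label optional group label.
#' @return an object of class `angle_sample`.
#' @export
angle_sample <- function(angles, period = 360, label = NULL) {
  if (!period %in% c(360, 180)) {
    stop("`period` must be 360 (directional) or 180 (axial)")
  }
  angles <- as.numeric(angles)
  if (length(angles) < 1L) stop("an angle sample needs at least one angle")
  if (anyNA(angles)) stop("angle sample contains NA")
  structure(
    list(angles = wrap_angle(angles, period), period = period,
         label = label),
    class = "angle_sample"
  )
}

#' @export
print.angle_sample <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("angle_sample%s: n = %d, period = %d\n",
              lab, length(x$angles), x$period))
  invisible(x)
}

as_angle_sample <- function(x, period = 360, label = NULL) {
  if (inherits(x, "angle_sample")) x else angle_sample(x, period, label)
}
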