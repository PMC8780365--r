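#' Scene configuration
#'
#' Bundles everything the pipeline needs to know about a camera view: the
#' region of interest (ROI) polygon in image pixels, the 3x3 ground-plane
#' homography `H` (mapping top-view metric coordinates to image pixels; the
#' pipeline applies `H^-1`), the image-to-real scale, the social safety
#' distance, the density-map bandwidth and grid geometry, and the frame rate.
#'
#' @param roi Matrix or data frame with two columns (`u`, `v`) giving the ROI
#'   polygon vertices in pixel coordinates (>= 3 vertices, image y down).
#' @param homography 3x3 numeric matrix mapping top-view (metres) to image
#'   pixels, or a length-9 row-major vector. Must be invertible. Set
#'   `inverse_convention = TRUE` if a calibration file stores the
#'   image-to-world direction instead.
#' @param scale Image-to-real scale \eqn{\alpha_s} (metres per homography
#'   output unit); 1 when `homography` already works in metres.
#' @param safety_distance Social safety distance `r` in metres; pairs at or
#'   below it violate.
#' @param map_resolution Gaussian kernel bandwidth \eqn{\delta} (metres) for
#'   occupancy/crowd density maps.
#' @param cell_size Density-grid cell edge in metres.
#' @param xlim,ylim Numeric length-2 top-view extents (metres) of the density
#'   grid; must cover the ROI's ground footprint.
#' @param fps Frame rate of the source, frames per second.
#' @param inverse_convention If `TRUE`, `homography` is inverted on input.
#' @return An object of class `scene_config` (a named list).
#' @export
scene_config <- function(roi, homography, scale = 1, safety_distance = 2,
                         map_resolution = 1, cell_size = 0.1,
                         xlim, ylim, fps = 25, inverse_convention = FALSE) {
  roi <- as.matrix(as.data.frame(roi))
  if (ncol(roi) != 2 || nrow(roi) < 3) {
    stop("`roi` must be a polygon with >= 3 two-column vertices", call. = FALSE)
  }
  storage.mode(roi) <- "double"
  colnames(roi) <- c("u", "v")
  H <- as_homography(homography)
  if (inverse_convention) H <- solve(H)
  d <- det(H)
  if (!is.finite(d) || abs(d) < 1e-15) {
    stop("`homography` must be invertible", call. = FALSE)
  }
  stopifnot(scale > 0, safety_distance > 0, map_resolution > 0, cell_size > 0)
  xlim <- sort(as.numeric(xlim))
  ylim <- sort(as.numeric(ylim))
  stopifnot(length(xlim) == 2, length(ylim) == 2, diff(xlim) > 0, diff(ylim) > 0)
  structure(
    list(
      roi = roi, homography = H, scale = scale,
      safety_distance = safety_distance, map_resolution = map_resolution,
      cell_size = cell_size, xlim = xlim, ylim = ylim, fps = fps
    ),
    class = "scene_config"
  )
}

as_homography <- function(h) {
  if (is.matrix(h)) {
    stopifnot(all(dim(h) == c(3, 3)))
    m <- h
  } else {
    stopifnot(length(h) == 9)
    m <- matrix(as.numeric(h), 3, 3, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  m
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat("  ROI vertices:    ", nrow(x$roi), "\n")
  cat("  scale (m/unit):  ", format(x$scale), "\n")
  cat("  safety distance: ", format(x$safety_distance), "m\n")
  cat("  map bandwidth:   ", format(x$map_resolution), "m, cell",
      format(x$cell_size), "m\n")
  cat("  grid extent:     x", sprintf("[%g, %g]", x$xlim[1], x$xlim[2]),
      " y", sprintf("[%g, %g]", x$ylim[1], x$ylim[2]), "\n")
  cat("  frame rate:      ", format(x$fps), "fps\n")
  invisible(x)
}

#' Read or write a scene configuration as JSON
#'
#' The on-disk format stores the homography as a row-major 9-vector and the
#' ROI as an n x 2 array, keeping the file plain text and diff-friendly.
#'
#' @param scene A [scene_config()] object.
#' @param path File path.
#' @return `read_scene_config()` returns a `scene_config`;
#'   `write_scene_config()` returns `path` invisibly.
#' @export
write_scene_config <- function(scene, path) {
  stopifnot(inherits(scene, "scene_config"))
  payload <- list(
    roi = unname(apply(scene$roi, 1, as.numeric, simplify = FALSE)),
    homography = as.numeric(t(scene$homography)),
    scale = scene$scale,
    safety_distance = scene$safety_distance,
    map_resolution = scene$map_resolution,
    cell_size = scene$cell_size,
    xlim = scene$xlim,
    ylim = scene$ylim,
    fps = scene$fps
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi <- if (is.list(p$roi)) do.call(rbind, p$roi) else p$roi
  scene_config(
    roi = roi, homography = p$homography, scale = p$scale,
    safety_distance = p$safety_distance, map_resolution = p$map_resolution,
    cell_size = p$cell_size, xlim = p$xlim, ylim = p$ylim, fps = p$fps
  )
}
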