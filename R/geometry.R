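#' Camera geometry for the scene simulator
#'
#' A pinhole camera: intrinsics `K`, rotation `R` (world to camera axes) and
#' translation `T0 = -R %*% position`. The world frame is metric with z up;
#' the image frame has the origin at the top-left corner and v increasing
#' downward. The convenience form takes a camera `position` and a `target`
#' point on the ground and builds a look-at rotation whose image-vertical
#' axis points downward in the world.
#'
#' @param focal Focal length in pixels (square pixels assumed).
#' @param image_size Length-2 integer (width, height) in pixels; the
#'   principal point is the image centre.
#' @param position Length-3 camera centre in world metres.
#' @param target Length-3 world point the optical axis looks at.
#' @param K,rotation,translation Explicit intrinsics/extrinsics; when given
#'   they override the look-at construction.
#' @return Object of class `camera_geometry`.
#' @export
camera_geometry <- function(focal = 800, image_size = c(1280, 960),
                            position = c(6, -8, 6), target = c(6, 5, 0),
                            K = NULL, rotation = NULL, translation = NULL) {
  if (is.null(K)) {
    K <- matrix(c(focal, 0, image_size[1] / 2,
                  0, focal, image_size[2] / 2,
                  0, 0, 1), 3, 3, byrow = TRUE)
  }
  if (is.null(rotation)) {
    f <- target - position
    nf <- sqrt(sum(f^2))
    if (nf < 1e-12) stop("camera target coincides with its position", call. = FALSE)
    f <- f / nf
    up <- c(0, 0, 1)
    r <- c(f[2] * up[3] - f[3] * up[2],
           f[3] * up[1] - f[1] * up[3],
           f[1] * up[2] - f[2] * up[1])
    nr <- sqrt(sum(r^2))
    if (nr < 1e-12) stop("camera looking straight down the world z axis; supply `rotation`", call. = FALSE)
    r <- r / nr
    dwn <- c(f[2] * r[3] - f[3] * r[2],
             f[3] * r[1] - f[1] * r[3],
             f[1] * r[2] - f[2] * r[1])
    rotation <- rbind(r, dwn, f)
    dimnames(rotation) <- NULL
  }
  if (is.null(translation)) translation <- -as.numeric(rotation %*% position)
  stopifnot(all(dim(K) == c(3, 3)), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-8) {
    stop("`rotation` must be orthonormal", call. = FALSE)
  }
  structure(
    list(K = K, R = rotation, T0 = as.numeric(translation),
         image_size = as.numeric(image_size)),
    class = "camera_geometry"
  )
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat("<camera_geometry> focal", x$K[1, 1], "px, image",
      paste(x$image_size, collapse = "x"), "\n")
  invisible(x)
}

#' Ground-plane homography of a pinhole camera
#'
#' Restricting the projection to world points with z = 0 gives the 3x3 map
#' `K [r1 r2 T0]` from ground coordinates to image pixels. The returned
#' matrix absorbs the image-to-real scale so that it matches the convention
#' of [scene_config()]: `image_to_topview()` applied to a projected ground
#' point recovers the metric world coordinates.
#'
#' @param cam A [camera_geometry()].
#' @param scale Image-to-real scale \eqn{\alpha_s}.
#' @return Invertible 3x3 matrix.
#' @export
homography_from_camera <- function(cam, scale = 1) {
  stopifnot(inherits(cam, "camera_geometry"), scale > 0)
  G <- cam$K %*% cbind(cam$R[, 1], cam$R[, 2], cam$T0)
  G %*% diag(c(scale, scale, 1))
}

#' Map image pixels to top-view metres and back
#'
#' The top-view transform applies the inverse homography to the homogeneous
#' pixel point, performs the perspective division, and scales the result to
#' metres: `[x, y] = scale * norm(H^-1 [u, v, 1]^T)`. Points mapping too
#' close to the plane at infinity (|w| below `tol`) are degenerate and raise
#' an error.
#'
#' @param points Data frame (or matrix) with columns `u`, `v` in pixels for
#'   `image_to_topview()`, or `x`, `y` in metres for `topview_to_image()`.
#' @param scene A [scene_config()].
#' @param tol Degeneracy tolerance on the homogeneous divisor.
#' @return A tibble with columns `x`, `y` (metres) or `u`, `v` (pixels).
#' @examples
#' sc <- scene_config(roi = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
#'                    homography = diag(3), xlim = c(0, 10), ylim = c(0, 10))
#' image_to_topview(data.frame(u = 4, v = 6), sc)
#' @export
image_to_topview <- function(points, scene, tol = 1e-12) {
  uv <- as_xy(points, c("u", "v"))
  q <- solve(scene$homography) %*% rbind(uv[, 1], uv[, 2], 1)
  w <- q[3, ]
  if (any(abs(w) < tol)) {
    stop("degenerate pixel point at the horizon of the ground plane", call. = FALSE)
  }
  tibble::tibble(x = as.numeric(scene$scale * q[1, ] / w),
                 y = as.numeric(scene$scale * q[2, ] / w))
}

#' @rdname image_to_topview
#' @export
topview_to_image <- function(points, scene, tol = 1e-12) {
  xy <- as_xy(points, c("x", "y"))
  q <- scene$homography %*% rbind(xy[, 1] / scene$scale, xy[, 2] / scene$scale, 1)
  w <- q[3, ]
  if (any(abs(w) < tol)) {
    stop("degenerate top-view point maps to the horizon", call. = FALSE)
  }
  tibble::tibble(u = as.numeric(q[1, ] / w), v = as.numeric(q[2, ] / w))
}

#' Project 3D world points through a pinhole camera
#'
#' `[u, v, 1]^T` is proportional to `(1/scale) K [R | T0] [x, y, z, 1]^T`
#' followed by the perspective division. Points behind the camera (or on its
#' principal plane) are degenerate.
#'
#' @param points Data frame or matrix with columns `x`, `y`, `z` in metres.
#' @param cam A [camera_geometry()].
#' @param scale Image-to-real scale \eqn{\alpha_s}.
#' @param tol Minimum forward depth (camera units) accepted.
#' @return Tibble with pixel columns `u`, `v`.
#' @export
project_world_to_image <- function(points, cam, scale = 1, tol = 1e-9) {
  xyz <- as_xy(points, c("x", "y", "z"))
  p <- (cam$K %*% (cam$R %*% t(xyz) + cam$T0)) / scale
  w <- p[3, ]
  if (any(w < tol)) {
    stop("point at or behind the camera plane cannot be projected", call. = FALSE)
  }
  tibble::tibble(u = as.numeric(p[1, ] / w), v = as.numeric(p[2, ] / w))
}

# coerce a data frame / matrix to a numeric matrix with the named columns
as_xy <- function(points, cols) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= length(cols))
    m <- points[, seq_along(cols), drop = FALSE]
  } else {
    points <- as.data.frame(points)
    stopifnot(all(cols %in% names(points)))
    m <- as.matrix(points[cols])
  }
  storage.mode(m) <- "double"
  m
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting with an explicit on-boundary check, so points on a
#' polygon edge or vertex count as inside. Used for the ROI filter and the
#' track demotion rule.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Two-column matrix of polygon vertices.
#' @param tol Absolute tolerance of the on-boundary test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  poly <- as_xy(poly, c("u", "v"))
  nv <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:nv, 1)]; ye <- ys[c(2:nv, 1)]
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (!is.finite(x) || !is.finite(y)) return(NA)
    # boundary: distance from point to each edge segment
    dx <- xe - xs; dy <- ye - ys
    len2 <- dx * dx + dy * dy
    t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, ((x - xs) * dx + (y - ys) * dy) / len2)))
    d2 <- (xs + t * dx - x)^2 + (ys + t * dy - y)^2
    if (any(d2 <= tol^2)) return(TRUE)
    crosses <- ((ys > y) != (ye > y)) &
      (x < xs + (y - ys) * (xe - xs) / (ye - ys))
    sum(crosses) %% 2 == 1
  }, logical(1))
}
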