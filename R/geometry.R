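#' Cone-beam projection geometry
#'
#' Describes one source/detector pair in room (isocenter) coordinates: a point
#' X-ray source, a flat detector given by its center and two orthonormal
#' in-plane axes, the detector pixel pitch and the image size. Pixel
#' coordinates are 0-based with x = column, y = row and the principal point at
#' the image geometric center `((W-1)/2, (H-1)/2)`.
#'
#' @param source mm triple, source position.
#' @param detector_center mm triple, center of the detector plane.
#' @param u,v unit mm triples spanning the detector plane (u = +x/columns,
#'   v = +y/rows); must be orthonormal.
#' @param pixel_pitch detector pixel size in mm/px.
#' @param image_size integer pair `(width, height)` in px.
#' @return an object of class `projection_geometry`.
#' @export
projection_geometry <- function(source, detector_center, u, v,
                                pixel_pitch, image_size) {
  source <- as.numeric(source); detector_center <- as.numeric(detector_center)
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(source) == 3L, length(detector_center) == 3L,
            length(u) == 3L, length(v) == 3L)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-8 || abs(sqrt(sum(v^2)) - 1) > 1e-8)
    stop("detector axes u, v must be unit vectors")
  if (abs(sum(u * v)) > 1e-8)
    stop("detector axes u, v must be orthogonal")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size <= 0L))
    stop("image_size must be positive (width, height)")
  n <- cross3(u, v)
  if (abs(sum((detector_center - source) * n)) < 1e-9)
    stop("source lies on the detector plane")
  structure(list(source = source, detector_center = detector_center,
                 u = u, v = v, pixel_pitch = pixel_pitch,
                 image_size = image_size),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> %d x %d px @ %.3g mm/px\n",
              x$image_size[1], x$image_size[2], x$pixel_pitch))
  cat(sprintf("  source (%.1f, %.1f, %.1f) mm, detector center (%.1f, %.1f, %.1f) mm\n",
              x$source[1], x$source[2], x$source[3],
              x$detector_center[1], x$detector_center[2], x$detector_center[3]))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default stereo kV imaging geometry
#'
#' Builds a two-view stereo pair resembling a floor/ceiling-mounted kV
#' fluoroscopy system: sources at `sad` mm from the isocenter, detectors at
#' `sid - sad` mm behind it, the two view axes rotated about the SI (Y) axis.
#' The exact clinical parameters of such systems are not public; these
#' defaults are realistic placeholders and every quantity is configurable.
#'
#' @param angles_deg rotation of each view axis about +Y, degrees.
#' @param sad source-axis (isocenter) distance, mm.
#' @param sid source-imager distance, mm.
#' @param pixel_pitch detector pixel pitch, mm/px.
#' @param image_size `(width, height)` px.
#' @return list of `projection_geometry`, one per angle.
#' @export
stereo_geometry <- function(angles_deg = c(-45, 45), sad = 2000, sid = 3000,
                            pixel_pitch = 0.4, image_size = c(256L, 256L)) {
  lapply(angles_deg, function(a) {
    th <- a * pi / 180
    # view axis in the XZ plane; +Z view at angle 0
    axis <- c(sin(th), 0, cos(th))
    u <- c(cos(th), 0, -sin(th))     # in-plane, horizontal
    v <- c(0, 1, 0)                  # SI axis = image rows
    projection_geometry(source = -sad * axis,
                        detector_center = (sid - sad) * axis,
                        u = u, v = v,
                        pixel_pitch = pixel_pitch, image_size = image_size)
  })
}

#' Project a room-frame point onto the detector
#'
#' Intersects the ray from the source through `point` with the detector plane
#' and expresses the intersection in 0-based pixel coordinates.
#'
#' @param geom a `projection_geometry`.
#' @param point mm triple (must not coincide with the source and must lie on
#'   the detector side of the source).
#' @return numeric `(x, y)` in px.
#' @export
project_point <- function(geom, point) {
  point <- as.numeric(point)
  dir <- point - geom$source
  if (sqrt(sum(dir^2)) < 1e-12) stop("point coincides with the source")
  n <- cross3(geom$u, geom$v)
  denom <- sum(dir * n)
  numer <- sum((geom$detector_center - geom$source) * n)
  if (abs(denom) < 1e-12 * sqrt(sum(dir^2)))
    stop("ray is parallel to the detector plane")
  lambda <- numer / denom
  if (lambda <= 0)
    stop("point lies behind the source")
  hit <- geom$source + lambda * dir
  rel <- hit - geom$detector_center
  cx <- (geom$image_size[1] - 1) / 2
  cy <- (geom$image_size[2] - 1) / 2
  c(x = sum(rel * geom$u) / geom$pixel_pitch + cx,
    y = sum(rel * geom$v) / geom$pixel_pitch + cy)
}

#' Back-project a pixel into a room-frame ray
#'
#' @param geom a `projection_geometry`.
#' @param px numeric `(x, y)` pixel coordinates (0-based).
#' @return list with `origin` (the source) and unit `direction`.
#' @export
pixel_ray <- function(geom, px) {
  cx <- (geom$image_size[1] - 1) / 2
  cy <- (geom$image_size[2] - 1) / 2
  det_pt <- geom$detector_center +
    (px[1] - cx) * geom$pixel_pitch * geom$u +
    (px[2] - cy) * geom$pixel_pitch * geom$v
  d <- det_pt - geom$source
  list(origin = geom$source, direction = d / sqrt(sum(d^2)))
}

#' Triangulate a point from two stereo views
#'
#' Back-projects one pixel per view and returns the midpoint of the common
#' perpendicular segment between the two rays, with half the segment length
#' as the triangulation residual.
#'
#' @param geom_a,geom_b `projection_geometry` of the two views.
#' @param p_a,p_b pixel coordinates `(x, y)` in each view.
#' @return list with `point` (mm triple) and `residual_mm`.
#' @export
triangulate <- function(geom_a, p_a, geom_b, p_b) {
  ra <- pixel_ray(geom_a, p_a)
  rb <- pixel_ray(geom_b, p_b)
  da <- ra$direction; db <- rb$direction
  cosang <- abs(sum(da * db))
  if (cosang > cos(0.1 * pi / 180))
    stop("degenerate stereo geometry: rays are near-parallel (< 0.1 deg)")
  # closest points: solve [1 -d; d -1] in the (da, db) basis
  w0 <- ra$origin - rb$origin
  a <- sum(da * da); b <- sum(da * db); cc <- sum(db * db)
  d <- sum(da * w0); e <- sum(db * w0)
  den <- a * cc - b * b
  s <- (b * e - cc * d) / den
  t <- (a * e - b * d) / den
  pa <- ra$origin + s * da
  pb <- rb$origin + t * db
  list(point = (pa + pb) / 2,
       residual_mm = sqrt(sum((pa - pb)^2)) / 2)
}

#' Read / write projection geometry as JSON
#'
#' @param geom a `projection_geometry` or a list of them.
#' @param path JSON file path.
#' @return `read_geometry` returns a `projection_geometry` or a list of them.
#' @export
write_geometry <- function(geom, path) {
  as_l <- function(g) list(source = g$source,
                           detector_center = g$detector_center,
                           u = g$u, v = g$v,
                           pixel_pitch = g$pixel_pitch,
                           image_size = g$image_size)
  obj <- if (inherits(geom, "projection_geometry")) as_l(geom)
         else lapply(geom, as_l)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  from_l <- function(o)
    projection_geometry(unlist(o$source), unlist(o$detector_center),
                        unlist(o$u), unlist(o$v),
                        o$pixel_pitch, unlist(o$image_size))
  if (!is.null(obj$source)) from_l(obj) else lapply(obj, from_l)
}
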