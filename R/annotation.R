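#' Image line segment in raster coordinates
#'
#' A straight line through two annotated points, in raster pixel coordinates
#' (origin top-left, u rightward, v downward, real-valued; sub-pixel
#' positions are kept unrounded). Annotated laser lines must not be
#' horizontal: a horizontal line never meets a reference row.
#'
#' @param u1,v1,u2,v2 Endpoint coordinates, pixels.
#' @return An object of class `image_line`.
#' @examples
#' image_line(465, 433, 517, 290)
#' @export
image_line <- function(u1, v1, u2, v2) {
  vals <- c(u1, v1, u2, v2)
  if (!all(is.finite(vals))) stop("endpoints must be finite", call. = FALSE)
  if (u1 == u2 && v1 == v2)
    stop("endpoints must be distinct", call. = FALSE)
  if (abs(v2 - v1) <= 1e-9)
    stop("line is horizontal (|dv| <= 1e-9 px); cannot cut reference rows",
         call. = FALSE)
  structure(list(u1 = u1, v1 = v1, u2 = u2, v2 = v2), class = "image_line")
}

#' @export
print.image_line <- function(x, ...) {
  cat(sprintf("<image_line> (%.2f, %.2f) -- (%.2f, %.2f)\n",
              x$u1, x$v1, x$u2, x$v2))
  invisible(x)
}

# horizontal position of the (extended) line at raster row v
line_u_at <- function(line, v) {
  line$u1 + (v - line$v1) * (line$u2 - line$u1) / (line$v2 - line$v1)
}

# du/dv slope
line_slope <- function(line) (line$u2 - line$u1) / (line$v2 - line$v1)

#' Annotation of one still image
#'
#' Two annotated laser-line segments plus the raster rows of the two
#' reference rows. Line identity (left/right) is assigned by horizontal
#' position at the near row, not by argument order.
#'
#' @param line_left,line_right [image_line()] objects (reordered if needed).
#' @param near_row_v,far_row_v Raster v of the near (lower, larger v) and
#'   far reference row.
#' @param width,height Image dimensions in pixels.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(line_left, line_right, near_row_v, far_row_v,
                           width, height) {
  .assert_class(line_left, "image_line", "line_left")
  .assert_class(line_right, "image_line", "line_right")
  stopifnot(is.numeric(near_row_v), is.numeric(far_row_v),
            is.numeric(width), is.numeric(height), width >= 2, height >= 2)
  if (near_row_v <= far_row_v)
    stop("`near_row_v` must exceed `far_row_v` (near row lower in raster)",
         call. = FALSE)
  if (line_u_at(line_left, near_row_v) > line_u_at(line_right, near_row_v)) {
    tmp <- line_left
    line_left <- line_right
    line_right <- tmp
  }
  if (line_u_at(line_right, far_row_v) <= line_u_at(line_left, far_row_v))
    stop("lines cross between the reference rows; check annotation",
         call. = FALSE)
  structure(list(line_left = line_left, line_right = line_right,
                 near_row_v = near_row_v, far_row_v = far_row_v,
                 width = as.numeric(width), height = as.numeric(height)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %g x %g px, rows v = %.1f (near), %.1f (far)\n",
    x$width, x$height, x$near_row_v, x$far_row_v))
  invisible(x)
}

#' Intersection of two image lines
#'
#' Exact 2x2 linear solve for the common point of two annotated lines; for
#' the two laser lines this is the vanishing point, which may lie outside
#' the raster.
#'
#' @param a,b [image_line()] objects.
#' @return Named numeric vector `u`, `v` (raster pixels).
#' @export
line_intersection <- function(a, b) {
  .assert_class(a, "image_line", "a")
  .assert_class(b, "image_line", "b")
  sa <- line_slope(a)
  sb <- line_slope(b)
  # parallel within ~1e-12 rad of direction difference
  if (abs(atan(sa) - atan(sb)) < 1e-12)
    stop(paste("lines are parallel: vanishing point at infinity;",
               "treat as zero pan/tilt and use the simple-case estimators"),
         call. = FALSE)
  v <- unname((b$u1 - a$u1 + sa * a$v1 - sb * b$v1) / (sa - sb))
  c(u = unname(a$u1 + sa * (v - a$v1)), v = v)
}

#' Pixel measurements from an annotation
#'
#' Converts two annotated laser lines plus two reference rows into the seven
#' pixel quantities of [image_measurements()] via the vanishing-point
#' construction. The slope quantities (`n1`, `n2`, `m`) are measured at the
#' near reference row, the row with the largest lever arm from the vanishing
#' point; by the slope invariance of the estimators any other row would give
#' identical pose, length, area and height.
#'
#' @param ann An [annotation_set()] object.
#' @return An [image_measurements()] object.
#' @export
measurements_from_annotation <- function(ann) {
  .assert_class(ann, "annotation_set", "ann")
  uln <- line_u_at(ann$line_left, ann$near_row_v)
  urn <- line_u_at(ann$line_right, ann$near_row_v)
  ulf <- line_u_at(ann$line_left, ann$far_row_v)
  urf <- line_u_at(ann$line_right, ann$far_row_v)
  n_prime <- urn - uln
  n_dprime <- urf - ulf
  if (n_dprime <= 0 || n_prime <= n_dprime)
    stop("rows swapped or lines diverge upward (need n' > n'' > 0)",
         call. = FALSE)
  vp <- line_intersection(ann$line_left, ann$line_right)
  m <- ann$near_row_v - vp[["v"]]
  if (m <= 0)
    stop("lines diverge toward horizon; check annotation", call. = FALSE)
  image_measurements(
    n_prime = n_prime, n_dprime = n_dprime,
    n0 = uln,
    n1 = vp[["u"]] - uln, n2 = urn - vp[["u"]],
    m0 = ann$height - ann$near_row_v,
    m = m)
}

.ann_flat_fields <- c("line_left_u1", "line_left_v1", "line_left_u2",
                      "line_left_v2", "line_right_u1", "line_right_v1",
                      "line_right_u2", "line_right_v2",
                      "near_row_v", "far_row_v",
                      "image_width_px", "image_height_px")

#' Read an annotation file
#'
#' Canonical dialect is JSON with objects `line_left`/`line_right` (fields
#' `u1`, `v1`, `u2`, `v2`), scalars `near_row_v`, `far_row_v`,
#' `image_width_px`, `image_height_px`. A flat CSV dialect with columns
#' `line_left_u1`, ... is also accepted. Extra metadata keys are tolerated;
#' missing fields raise a schema error naming the field.
#'
#' @param path Path to a `.json` or `.csv` annotation file.
#' @return An [annotation_set()] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path))
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rec <- as.list(utils::read.csv(path)[1L, ])
    missing <- setdiff(.ann_flat_fields, names(rec))
    if (length(missing))
      stop(sprintf("annotation schema error: missing field(s) %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    left <- image_line(rec$line_left_u1, rec$line_left_v1,
                       rec$line_left_u2, rec$line_left_v2)
    right <- image_line(rec$line_right_u1, rec$line_right_v1,
                        rec$line_right_u2, rec$line_right_v2)
    return(annotation_set(left, right, rec$near_row_v, rec$far_row_v,
                          rec$image_width_px, rec$image_height_px))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("line_left", "line_right", "near_row_v", "far_row_v",
              "image_width_px", "image_height_px"))
    if (is.null(obj[[f]]))
      stop(sprintf("annotation schema error: missing field '%s'", f),
           call. = FALSE)
  mk_line <- function(rec, name) {
    for (f in c("u1", "v1", "u2", "v2"))
      if (is.null(rec[[f]]))
        stop(sprintf("annotation schema error: missing field '%s.%s'",
                     name, f), call. = FALSE)
    image_line(rec$u1, rec$v1, rec$u2, rec$v2)
  }
  annotation_set(mk_line(obj$line_left, "line_left"),
                 mk_line(obj$line_right, "line_right"),
                 obj$near_row_v, obj$far_row_v,
                 obj$image_width_px, obj$image_height_px)
}

#' Write an annotation file
#'
#' Lossless counterpart of [read_annotation()]; dialect chosen by
#' extension (`.csv` flat, JSON otherwise).
#'
#' @param ann An [annotation_set()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  .assert_class(ann, "annotation_set", "ann")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    row <- data.frame(
      line_left_u1 = ann$line_left$u1, line_left_v1 = ann$line_left$v1,
      line_left_u2 = ann$line_left$u2, line_left_v2 = ann$line_left$v2,
      line_right_u1 = ann$line_right$u1, line_right_v1 = ann$line_right$v1,
      line_right_u2 = ann$line_right$u2, line_right_v2 = ann$line_right$v2,
      near_row_v = ann$near_row_v, far_row_v = ann$far_row_v,
      image_width_px = ann$width, image_height_px = ann$height)
    utils::write.csv(row, path, row.names = FALSE)
  } else {
    obj <- list(
      line_left = ann$line_left[c("u1", "v1", "u2", "v2")],
      line_right = ann$line_right[c("u1", "v1", "u2", "v2")],
      near_row_v = ann$near_row_v, far_row_v = ann$far_row_v,
      image_width_px = ann$width, image_height_px = ann$height)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
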