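#' Parameters for the laser-line detector
#'
#' @param green_excess_threshold Fraction of the maximal normalised green
#'   excess a pixel must exceed to count as laser signal, in (0, 1).
#' @param min_row_support Minimal fraction of signal-bearing rows that must
#'   contain exactly two line clusters, in (0, 1].
#' @param robust_fit_iterations Maximal reweighting iterations of the
#'   straight-line fit.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(green_excess_threshold = 0.25,
                             min_row_support = 0.5,
                             robust_fit_iterations = 20) {
  stopifnot(green_excess_threshold > 0, green_excess_threshold < 1,
            min_row_support > 0, min_row_support <= 1,
            robust_fit_iterations >= 1)
  structure(list(green_excess_threshold = green_excess_threshold,
                 min_row_support = min_row_support,
                 robust_fit_iterations = robust_fit_iterations),
            class = "detection_params")
}

# iteratively reweighted straight-line fit u ~ v, discarding outliers
# beyond 2.5 median absolute deviations
.robust_line_fit <- function(v, u, iterations) {
  keep <- rep(TRUE, length(v))
  fit <- NULL
  for (i in seq_len(iterations)) {
    fit <- stats::lm.fit(cbind(1, v[keep]), u[keep])
    res <- u - (fit$coefficients[1] + fit$coefficients[2] * v)
    s <- stats::mad(res[keep])
    if (s < 1e-9) break
    new_keep <- abs(res) <= 2.5 * s
    if (sum(new_keep) < 2L || identical(new_keep, keep)) break
    keep <- new_keep
  }
  res <- u - (fit$coefficients[1] + fit$coefficients[2] * v)
  list(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]],
       keep = keep, rms = sqrt(mean(res[keep]^2)))
}

#' Detect the two laser lines in a synthetic still image
#'
#' Scores every pixel by its normalised green excess `G - (R + B)/2`,
#' thresholds, clusters the surviving pixels of each row into at most two
#' groups by horizontal position, takes the intensity-weighted centroid of
#' each group, and fits a straight line per group by iterative reweighting
#' (points beyond 2.5 median absolute deviations are discarded). Centroid
#' extraction gives sub-pixel line positions without any accumulator
#' binning.
#'
#' @param image An `height x width x 3` RGB array in [0, 1], or a path to a
#'   PNG file.
#' @param params A [detection_params()] object.
#' @return A list with `line_left` and `line_right` ([image_line()]s,
#'   ordered by horizontal position at the lowest usable row) and
#'   `diagnostics` (rows with signal, rows with exactly two clusters,
#'   per-line RMS residual in pixels).
#' @export
detect_laser_lines <- function(image, params = detection_params()) {
  .assert_class(params, "detection_params", "params")
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("`image` must be an RGB array or a PNG path", call. = FALSE)
  H <- dim(image)[1]
  W <- dim(image)[2]
  score <- image[, , 2] - (image[, , 1] + image[, , 3]) / 2
  score[score < 0] <- 0
  smax <- max(score)
  if (smax <= 0)
    stop("detection failure: no green excess found in image", call. = FALSE)
  score <- score / smax
  thr <- params$green_excess_threshold
  hot <- which(score > thr, arr.ind = TRUE)     # sparse above-threshold set
  by_row <- split(hot[, "col"], hot[, "row"])
  rows_signal <- length(by_row)
  pts <- lapply(names(by_row), function(nm) {
    js <- sort(by_row[[nm]])
    i <- as.integer(nm)
    # split into runs of consecutive columns (gap > 2 px starts a new run)
    grp <- cumsum(c(0, diff(js) > 2))
    if (grp[length(grp)] != 1L) return(NULL)    # need exactly two clusters
    cent <- vapply(split(js, grp), function(g)
      sum((g - 1) * score[i, g]) / sum(score[i, g]), numeric(1))
    c(v = i - 1, u_left = min(cent), u_right = max(cent))
  })
  good <- do.call(rbind, pts)
  n_good <- if (is.null(good)) 0L else nrow(good)
  if (rows_signal == 0L || n_good < 10L ||
      n_good < params$min_row_support * rows_signal)
    stop(sprintf(paste0(
      "detection failure: %d of %d signal rows contain exactly two line ",
      "clusters (need >= %.0f%% and >= 10 rows)"),
      n_good, rows_signal, 100 * params$min_row_support), call. = FALSE)
  fl <- .robust_line_fit(good[, "v"], good[, "u_left"],
                         params$robust_fit_iterations)
  fr <- .robust_line_fit(good[, "v"], good[, "u_right"],
                         params$robust_fit_iterations)
  v0 <- min(good[, "v"])
  v1 <- max(good[, "v"])
  mk <- function(f) image_line(f$intercept + f$slope * v0, v0,
                               f$intercept + f$slope * v1, v1)
  left <- mk(fl)
  right <- mk(fr)
  if (line_u_at(left, v1) > line_u_at(right, v1)) {
    tmp <- left; left <- right; right <- tmp
    tmp <- fl; fl <- fr; fr <- tmp
  }
  list(line_left = left, line_right = right,
       diagnostics = list(rows_signal = rows_signal,
                          rows_two_clusters = n_good,
                          rows_kept_left = sum(fl$keep),
                          rows_kept_right = sum(fr$keep),
                          rms_left = fl$rms, rms_right = fr$rms))
}

#' Annotation set from a detected line pair
#'
#' Wraps [detect_laser_lines()] output into an [annotation_set()], placing
#' the reference rows at the 90th and 10th percentile of the rows where
#' both lines were found (sub-pixel positions kept unrounded).
#'
#' @param image RGB array or PNG path.
#' @param width,height Image dimensions in pixels; taken from the array
#'   when omitted.
#' @param params A [detection_params()] object.
#' @param near_row_v,far_row_v Optional explicit reference rows.
#' @return An [annotation_set()] object.
#' @export
annotation_from_image <- function(image, width = NULL, height = NULL,
                                  params = detection_params(),
                                  near_row_v = NULL, far_row_v = NULL) {
  if (is.character(image)) image <- png::readPNG(image)
  if (is.null(width)) width <- dim(image)[2]
  if (is.null(height)) height <- dim(image)[1]
  det <- detect_laser_lines(image, params)
  vs <- c(det$line_left$v1, det$line_left$v2)
  if (is.null(near_row_v)) near_row_v <- vs[1] + 0.9 * (vs[2] - vs[1])
  if (is.null(far_row_v)) far_row_v <- vs[1] + 0.1 * (vs[2] - vs[1])
  annotation_set(det$line_left, det$line_right, near_row_v, far_row_v,
                 width, height)
}
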