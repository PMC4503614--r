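#' Read a rig/camera configuration file
#'
#' Reads a YAML or JSON configuration with the keys `alpha_h_deg`,
#' `alpha_v_deg`, `image_width_px`, `image_height_px`,
#' `laser_separation_cm` and optionally `laser_separation_sigma_cm`
#' (default 0.5 cm).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with components `cam` ([camera_intrinsics()]) and `rig`
#'   ([laser_rig()]).
#' @export
read_rig_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  required <- c("alpha_h_deg", "alpha_v_deg", "image_width_px",
                "image_height_px", "laser_separation_cm")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sigma <- cfg$laser_separation_sigma_cm
  if (is.null(sigma)) sigma <- 0.5
  list(cam = camera_intrinsics(cfg$alpha_h_deg, cfg$alpha_v_deg,
                               cfg$image_width_px, cfg$image_height_px),
       rig = laser_rig(cfg$laser_separation_cm, delta_l = sigma))
}

#' Write a rig/camera configuration file
#'
#' @param cam A [camera_intrinsics()] object.
#' @param rig A [laser_rig()] object.
#' @param path Output path; format chosen by extension (`.json` or YAML
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_rig_config <- function(cam, rig, path) {
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(rig, "laser_rig", "rig")
  cfg <- list(alpha_h_deg = cam$alpha_h, alpha_v_deg = cam$alpha_v,
              image_width_px = cam$width, image_height_px = cam$height,
              laser_separation_cm = rig$l,
              laser_separation_sigma_cm = rig$delta_l)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a measurement set from CSV or JSON
#'
#' Expects fields `n_prime`, `n_dprime`, `n0`, `n1`, `n2`, `m0`, `m`
#' (pixels, real-valued); a CSV must have them as columns in its first row.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return An [image_measurements()] object.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    stop(sprintf("measurement file not found: %s", path), call. = FALSE)
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    as.list(utils::read.csv(path)[1L, ])
  required <- c("n_prime", "n_dprime", "n0", "n1", "n2", "m0", "m")
  missing <- setdiff(required, names(rec))
  if (length(missing))
    stop(sprintf("measurement input is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  image_measurements(rec$n_prime, rec$n_dprime, rec$n0,
                     rec$n1, rec$n2, rec$m0, rec$m)
}

#' Write a measurement set to CSV or JSON
#'
#' @param meas An [image_measurements()] object.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(meas, path) {
  .assert_class(meas, "image_measurements", "meas")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(meas), path, auto_unbox = TRUE, digits = NA)
  else
    utils::write.csv(as.data.frame(meas), path, row.names = FALSE)
  invisible(path)
}
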