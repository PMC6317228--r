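#' Polar cam profile realizing one pulse period per revolution
#'
#' @param angles_deg Uniform angle grid over `[0, 360)`.
#' @param radii_mm Profile radius at each angle (mm), all positive.
#' @param base_radius_mm Radius corresponding to waveform value 0.
#' @param stroke_mm Radial lift corresponding to waveform value 1. Must
#'   satisfy `base_radius_mm > stroke_mm > 0` so the profile cannot
#'   self-intersect (convexity is not guaranteed and is noted on export).
#' @param checksum Optional fingerprint of the source waveform.
#' @return An object of class `cam_profile`.
#' @export
cam_profile <- function(angles_deg, radii_mm, base_radius_mm, stroke_mm,
                        checksum = NULL) {
  if (!(stroke_mm > 0) || !(base_radius_mm > stroke_mm)) {
    stop("cam geometry requires base_radius_mm > stroke_mm > 0", call. = FALSE)
  }
  n <- length(angles_deg)
  stopifnot(length(radii_mm) == n, n >= 16)
  if (any(radii_mm <= 0)) stop("cam radii must be positive", call. = FALSE)
  d <- diff(angles_deg)
  if (any(d <= 0) || max(abs(d - 360 / n)) > 1e-9 * 360) {
    stop("angle grid must be uniform over [0, 360)", call. = FALSE)
  }
  structure(
    list(angles_deg = as.numeric(angles_deg), radii_mm = as.numeric(radii_mm),
         base_radius_mm = base_radius_mm, stroke_mm = stroke_mm,
         checksum = checksum),
    class = "cam_profile"
  )
}

#' @export
print.cam_profile <- function(x, ...) {
  cat(sprintf(
    "<cam_profile> %d points, base %.3g mm, stroke %.3g mm, radius range [%.4g, %.4g] mm\n",
    length(x$angles_deg), x$base_radius_mm, x$stroke_mm,
    min(x$radii_mm), max(x$radii_mm)
  ))
  invisible(x)
}

#' Convert a normalized pulse waveform into a circular cam profile
#'
#' The normalized period is mapped to one revolution (360 degrees) and the
#' waveform value to radial lift above the base circle:
#' `r(angle) = base_radius_mm + stroke_mm * u(angle / 360)`. Angle 0 is
#' anchored at the diastolic foot (waveform minimum), so rotating the cam at
#' constant speed reproduces the pulse starting from end-diastole.
#'
#' @param x A [sampled_waveform()] normalized to `[0, 1]`, or a
#'   [fourier_series()]. A series is evaluated densely and min-max normalized
#'   as part of the conversion (a truncated series is not `[0, 1]`-bounded in
#'   general); a non-normalized sampled waveform is normalized with a warning.
#' @param base_radius_mm,stroke_mm Cam geometry (mm);
#'   `base_radius_mm > stroke_mm > 0`.
#' @param n_points Angle grid size (default 3600, i.e. 0.1 degree
#'   machining-grade resolution).
#' @return A [cam_profile()] whose checksum fingerprints the source samples.
#' @examples
#' cam <- waveform_to_cam(reference_radial_series(), 20, 5, n_points = 720)
#' range(cam$radii_mm)
#' @export
waveform_to_cam <- function(x, base_radius_mm = 20, stroke_mm = 5,
                            n_points = 3600) {
  if (!(stroke_mm > 0) || !(base_radius_mm > stroke_mm)) {
    stop("cam geometry requires base_radius_mm > stroke_mm > 0", call. = FALSE)
  }
  from_series <- inherits(x, "fourier_series")
  if (from_series) {
    u <- evaluate_series(x, (seq_len(n_points) - 1) / n_points)
  } else if (inherits(x, "sampled_waveform")) {
    u <- resample_pulse(x, n_points)$values
  } else {
    stop("x must be a sampled_waveform or fourier_series", call. = FALSE)
  }
  rng <- range(u)
  if (diff(rng) <= 1e-12 * max(1, abs(rng[2]))) {
    # constant waveform: zero lift everywhere, a perfect circle at the level
    # of the constant (0 for a flat-line pulse)
    u <- rep(min(max(rng[1], 0), 1), n_points)
  } else if (abs(rng[1]) > 1e-9 || abs(rng[2] - 1) > 1e-9) {
    if (!from_series) {
      warning("input not normalized to [0, 1]; normalizing before cam synthesis")
    }
    u <- (u - rng[1]) / (rng[2] - rng[1])
  }
  foot <- which.min(u)
  u <- u[c(foot:n_points, seq_len(foot - 1))] # anchor angle 0 at the foot
  angles <- (seq_len(n_points) - 1) * 360 / n_points
  cam_profile(angles, base_radius_mm + stroke_mm * u, base_radius_mm,
              stroke_mm, checksum = fnv1a32(paste(sprintf("%.12g", u),
                                                  collapse = ",")))
}

#' Follower lift of a cam at given angles
#'
#' Knife-edge (point) follower kinematics: lift equals profile radius minus
#' base radius, with periodic linear interpolation between grid points. The
#' inverse of [waveform_to_cam()] up to interpolation error.
#'
#' @param profile A [cam_profile()].
#' @param angle_deg Numeric vector of angles in degrees (wrapped mod 360).
#' @return Follower lift in mm at each angle.
#' @export
cam_to_displacement <- function(profile, angle_deg) {
  stopifnot(inherits(profile, "cam_profile"))
  ang <- as.numeric(angle_deg) %% 360
  x <- c(profile$angles_deg, 360)
  y <- c(profile$radii_mm, profile$radii_mm[1])
  stats::approx(x, y, xout = ang, rule = 2)$y - profile$base_radius_mm
}

#' Export a cam profile as a machining point table
#'
#' Two-column delimited text (`angle_deg,radius_mm`, 6 decimal places) with a
#' commented header recording the geometry and the source-waveform checksum.
#' Suitable for CAM/CNC point import; convexity is not guaranteed and is
#' flagged in the header.
#'
#' @param profile A [cam_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_cam()]
#' @export
export_cam <- function(profile, path) {
  stopifnot(inherits(profile, "cam_profile"))
  header <- c(
    "# cam profile point table (polar; one pulse period per revolution)",
    sprintf("# base_radius_mm=%.9g", profile$base_radius_mm),
    sprintf("# stroke_mm=%.9g", profile$stroke_mm),
    sprintf("# n_points=%d", length(profile$angles_deg)),
    sprintf("# checksum=%s", if (is.null(profile$checksum)) "" else profile$checksum),
    "# note: convexity not guaranteed; check pressure angle before machining",
    "angle_deg,radius_mm"
  )
  rows <- sprintf("%.6f,%.6f", profile$angles_deg, profile$radii_mm)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a cam profile written by [export_cam()]
#'
#' @param path Path to the point table.
#' @return A [cam_profile()].
#' @export
read_cam <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s=", key), lines, value = TRUE)
    if (length(ln) == 0) return(NA_character_)
    sub(sprintf("^# %s=", key), "", ln[1])
  }
  base <- as.numeric(get_field("base_radius_mm"))
  stroke <- as.numeric(get_field("stroke_mm"))
  checksum <- get_field("checksum")
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  data_lines <- data_lines[!grepl("[A-Za-z]", data_lines)] # drop column header
  parts <- do.call(rbind, strsplit(data_lines, ","))
  cam_profile(as.numeric(parts[, 1]), as.numeric(parts[, 2]), base, stroke,
              checksum = if (is.na(checksum)) NULL else checksum)
}
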