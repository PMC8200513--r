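#' Gimballed-linac machine model
#'
#' Geometry constants of a gimbal-mounted linac of the Vero type: the beam
#' pans/tilts about a pivot upstream of isocenter, the gantry rotates about the
#' patient superior-inferior axis and the ring about the anterior-posterior
#' axis. Defaults describe the clinical machine: pivot 96 cm from isocenter,
#' pan/tilt travel of +/-2.4 degrees per axis, equivalently +/-4.2 cm reach in
#' the plane through isocenter perpendicular to the beam.
#'
#' @param pivot_cm Pivot-to-isocenter distance in cm.
#' @param gimbal_deg Pan/tilt travel limit per axis, degrees.
#' @param iso_plane_cm Reachable excursion in the isocenter plane, cm.
#' @return An object of class `machine_model`.
#' @examples
#' machine_model()
#' @export
machine_model <- function(pivot_cm = 96, gimbal_deg = 2.4, iso_plane_cm = 4.2) {
  stopifnot(is.numeric(pivot_cm), pivot_cm > 0,
            is.numeric(gimbal_deg), gimbal_deg > 0,
            is.numeric(iso_plane_cm), iso_plane_cm > 0)
  structure(
    list(pivot_cm = pivot_cm, gimbal_deg = gimbal_deg,
         iso_plane_cm = iso_plane_cm),
    class = "machine_model")
}

#' @export
print.machine_model <- function(x, ...) {
  cat("<machine_model> gimballed linac\n")
  cat(sprintf("  pivot-to-isocenter distance: %g cm\n", x$pivot_cm))
  cat(sprintf("  pan/tilt limit: +/-%g deg per axis (+/-%g cm at isocenter)\n",
              x$gimbal_deg, x$iso_plane_cm))
  invisible(x)
}

#' Normalize angles to [0, 360)
#'
#' @param x Angles in degrees.
#' @return Angles reduced modulo 360 into `[0, 360)`.
#' @examples
#' normalize_angle(c(-17, 360, 725.5))
#' @export
normalize_angle <- function(x) {
  out <- x %% 360
  # guard against 360 - eps rounding back up to exactly 360
  out[out >= 360] <- 0
  out
}

#' Smallest absolute difference between two angles
#'
#' @param a,b Angles in degrees.
#' @return Absolute angular separation in `[0, 180]`.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Construct a treatment plan table
#'
#' A plan is a tibble with one row per static beam. Angles are normalized to
#' `[0, 360)` on construction. The aperture is carried as a list-column of
#' beam's-eye-view (BEV) descriptors (see [aperture_circle()]); it travels
#' rigidly with the beam under the tracking transforms.
#'
#' @param label Beam labels (character).
#' @param iso_x,iso_y,iso_z Isocenter coordinates, cm, planning frame.
#' @param gantry,ring,collimator Beam angles in degrees.
#' @param weight Relative beam weights (monitor units), non-negative.
#' @param aperture Optional list of aperture descriptors, one per beam.
#' @return A tibble of class `beam_plan`.
#' @examples
#' beam_plan(label = "b1", iso_x = 0, iso_y = 0, iso_z = 0,
#'           gantry = 30, ring = 17)
#' @export
beam_plan <- function(label, iso_x, iso_y, iso_z, gantry, ring,
                      collimator = 0, weight = 1, aperture = NULL) {
  n <- length(gantry)
  plan <- tibble::tibble(
    label = as.character(label),
    iso_x = as.numeric(iso_x), iso_y = as.numeric(iso_y),
    iso_z = as.numeric(iso_z),
    gantry = normalize_angle(as.numeric(gantry)),
    ring = normalize_angle(as.numeric(ring)),
    collimator = normalize_angle(rep_len(as.numeric(collimator), n)),
    weight = rep_len(as.numeric(weight), n))
  if (!is.null(aperture)) {
    stopifnot(is.list(aperture), length(aperture) %in% c(1L, n))
    plan$aperture <- rep_len(aperture, n)
  }
  validate_plan(plan)
  class(plan) <- c("beam_plan", class(plan))
  plan
}

#' Circular BEV aperture
#'
#' @param radius_cm Field radius at the isocenter plane, cm.
#' @return An aperture descriptor usable in [beam_plan()].
#' @export
aperture_circle <- function(radius_cm) {
  stopifnot(is.numeric(radius_cm), radius_cm > 0, is.finite(radius_cm))
  structure(list(type = "circle", radius_cm = radius_cm),
            class = "bev_aperture")
}

validate_plan <- function(plan) {
  req <- c("label", "iso_x", "iso_y", "iso_z", "gantry", "ring",
           "collimator", "weight")
  missing <- setdiff(req, names(plan))
  if (length(missing) > 0L)
    stop("plan is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(plan) == 0L) stop("plan has no beams", call. = FALSE)
  num <- plan[c("iso_x", "iso_y", "iso_z", "gantry", "ring", "collimator",
                "weight")]
  if (!all(vapply(num, function(c) all(is.finite(c)), logical(1))))
    stop("plan contains non-finite numeric fields", call. = FALSE)
  if (any(plan$weight < 0)) stop("beam weights must be >= 0", call. = FALSE)
  invisible(plan)
}

as_beam_plan <- function(df) {
  validate_plan(df)
  if (!inherits(df, "beam_plan")) class(df) <- c("beam_plan", class(df))
  df
}

#' Fiducial-marker state on one respiratory phase
#'
#' @param positions Marker positions: a numeric vector of length 3 (single
#'   marker) or a matrix / data frame with columns x, y, z in cm.
#' @param phase Phase label, e.g. `"BH_exhale"`, `"0%"`, `"50%"`.
#' @return A tibble with columns `x`, `y`, `z` and attribute `phase`.
#' @examples
#' fiducial_state(c(1, 2, 3), phase = "0%")
#' @export
fiducial_state <- function(positions, phase = "") {
  if (is.numeric(positions) && is.null(dim(positions))) {
    stopifnot(length(positions) == 3L)
    positions <- matrix(positions, nrow = 1)
  }
  m <- as.matrix(as.data.frame(positions))
  if (ncol(m) != 3L) stop("fiducial positions need 3 columns (x, y, z)",
                          call. = FALSE)
  if (nrow(m) < 1L) stop("need at least one fiducial marker", call. = FALSE)
  if (!all(is.finite(m))) stop("fiducial positions must be finite",
                               call. = FALSE)
  out <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  attr(out, "phase") <- as.character(phase)
  out
}

fiducial_centroid <- function(fid) {
  fid <- fiducial_state(fid, phase = attr(fid, "phase") %||% "")
  c(x = mean(fid$x), y = mean(fid$y), z = mean(fid$z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
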