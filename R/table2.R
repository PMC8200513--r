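#' Worked phantom example: seven-beam sIMRT plan
#'
#' The machine's published worked example: a seven-beam step-and-shoot IMRT
#' plan optimized on a cylindrical phantom, whose target was moved 0.46 cm
#' left, 1.09 cm inferiorly and 0.99 cm posteriorly to simulate respiratory
#' motion. [table2_plan()] returns the original beams; [table2_fixture()]
#' additionally carries the published transformed angles and per-beam
#' isocenters (rounded to 0.1 degree / 0.01 cm as printed), the regression
#' surface for the rotation transform.
#'
#' @return `table2_plan()`: a `beam_plan` tibble of the 7 original beams.
#' @examples
#' table2_plan()
#' @export
table2_plan <- function() {
  beam_plan(
    label = paste0("beam", 1:7),
    iso_x = -0.11, iso_y = -87.84, iso_z = 28.01,
    gantry = c(192, 234, 270, 306, 342, 30, 150),
    ring = c(17, 343, 17, 343, 17, 17, 0),
    collimator = 0, weight = 1)
}

#' @rdname table2_plan
#' @return `table2_fixture()`: the plan columns plus published `new_iso_x/y/z`,
#'   `new_gantry`, `new_ring`, `new_collimator`.
#' @export
table2_fixture <- function() {
  dplyr::bind_cols(
    table2_plan(),
    tibble::tibble(
      new_iso_x = c(-0.74, -0.94, 0.13, -0.05, -0.24, -0.81, -0.04),
      new_iso_y = c(-86.79, -86.95, -87.05, -86.66, -86.93, -86.76, -86.85),
      new_iso_z = c(28.20, 28.72, 29.01, 28.59, 27.88, 28.60, 28.05),
      new_gantry = c(168.5, 126.5, 90.6, 54.4, 17.8, 30.7, 150.0),
      new_ring = c(194.5, 162.2, 196.5, 162.2, 195.3, 18.0, 1.2),
      new_collimator = c(182.5, 180.8, 180.0, 179.2, 178.3, 1.0, 358.8)))
}

#' @rdname table2_plan
#' @return `table2_displacement()`: the phantom target displacement mapped
#'   onto planning axes by the calibrated convention (cm).
#' @export
table2_displacement <- function() {
  displacement_from_clinical(left = 0.46, inferior = 1.09, posterior = 0.99)
}

#' Run the shipped worked example and compare against the published values
#'
#' Transforms the seven-beam phantom plan with the published displacement and
#' diffs every output (3 angles + 3 isocenter components per beam) against the
#' printed values.
#'
#' @param tol_angle Pass tolerance per angle, degrees.
#' @param tol_iso Pass tolerance per isocenter component, cm.
#' @return A list with `pass` (logical), `residuals` (per-beam tibble of
#'   signed residuals), `max_angle_resid`, `max_iso_resid`.
#' @examples
#' table2_check()$pass
#' @export
table2_check <- function(tol_angle = 1.0, tol_iso = 0.3) {
  fx <- table2_fixture()
  plan <- table2_plan()
  fid_ref <- fiducial_state(c(plan$iso_x[1], plan$iso_y[1], plan$iso_z[1]))
  fid_phase <- fiducial_state(fiducial_centroid(fid_ref) +
                                table2_displacement())
  tr <- rotate_plan(plan, fid_ref, fid_phase)
  resid <- tibble::tibble(
    label = plan$label,
    d_gantry = signed_angle_resid(tr$new_gantry, fx$new_gantry),
    d_ring = signed_angle_resid(tr$new_ring, fx$new_ring),
    d_collimator = signed_angle_resid(tr$new_collimator, fx$new_collimator),
    d_iso_x = tr$new_iso_x - fx$new_iso_x,
    d_iso_y = tr$new_iso_y - fx$new_iso_y,
    d_iso_z = tr$new_iso_z - fx$new_iso_z)
  max_a <- max(abs(resid$d_gantry), abs(resid$d_ring), abs(resid$d_collimator))
  max_i <- max(abs(resid$d_iso_x), abs(resid$d_iso_y), abs(resid$d_iso_z))
  list(pass = max_a <= tol_angle && max_i <= tol_iso,
       residuals = resid, max_angle_resid = max_a, max_iso_resid = max_i,
       transformed = tr)
}

signed_angle_resid <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Format a tracked plan as a worked-example style report
#'
#' One row per beam with original and transformed isocenter and angles,
#' rounded for side-by-side comparison (0.1 degree, 0.01 cm) the way the
#' published table is.
#'
#' @param tracked A `tracked_plan` from [rotate_plan()].
#' @return A tibble ready for [readr::write_csv()].
#' @export
report_table2 <- function(tracked) {
  stopifnot(all(c("new_gantry", "new_ring", "new_collimator") %in%
                  names(tracked)))
  tibble::tibble(
    beam = tracked$label,
    orig_iso_x = round(tracked$iso_x, 2),
    orig_iso_y = round(tracked$iso_y, 2),
    orig_iso_z = round(tracked$iso_z, 2),
    orig_gantry = round(tracked$gantry, 1),
    orig_ring = round(tracked$ring, 1),
    orig_collimator = round(tracked$collimator, 1),
    new_iso_x = round(tracked$new_iso_x, 2),
    new_iso_y = round(tracked$new_iso_y, 2),
    new_iso_z = round(tracked$new_iso_z, 2),
    new_gantry = round(tracked$new_gantry, 1),
    new_ring = round(tracked$new_ring, 1),
    new_collimator = round(tracked$new_collimator, 1))
}
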