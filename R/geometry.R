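#' Fiducial displacement between two respiratory phases
#'
#' The tracking transform is driven by the displacement of the implanted
#' fiducial markers between the reference phase and the target phase. Multiple
#' markers are reduced to their centroid before differencing; per-marker
#' pairing can be requested when both states list the markers in the same
#' order.
#'
#' @param fid_ref,fid_phase Fiducial states (see [fiducial_state()]).
#' @param paired If `TRUE`, difference markers one-to-one and average the
#'   per-marker displacements (requires equal marker counts).
#' @return Named numeric vector `c(x, y, z)` in cm:
#'   `centroid(fid_phase) - centroid(fid_ref)`.
#' @examples
#' fiducial_displacement(fiducial_state(c(0, 0, 0)),
#'                       fiducial_state(c(-0.46, 0.99, 1.09)))
#' @export
fiducial_displacement <- function(fid_ref, fid_phase, paired = FALSE) {
  fid_ref <- fiducial_state(fid_ref)
  fid_phase <- fiducial_state(fid_phase)
  if (paired && nrow(fid_ref) != nrow(fid_phase))
    stop(sprintf(
      "paired displacement needs equal marker counts (reference has %d, phase has %d)",
      nrow(fid_ref), nrow(fid_phase)), call. = FALSE)
  # mean of pairwise differences equals difference of centroids, so the paired
  # path only changes the error contract, not the value
  fiducial_centroid(fid_phase) - fiducial_centroid(fid_ref)
}

#' Map clinically named displacements onto planning-frame axes
#'
#' The planning frame used throughout the package was calibrated against the
#' machine's worked phantom example by exhaustively fitting all 48 signed axis
#' permutations (see [calibrate_axis_convention()]): patient left maps to
#' `-x`, posterior to `+y`, inferior to `+z`.
#'
#' @param left,inferior,posterior Displacement magnitudes in cm along the
#'   named clinical directions (negative values reverse the direction).
#' @return Named numeric vector `c(x, y, z)` in cm.
#' @examples
#' displacement_from_clinical(left = 0.46, inferior = 1.09, posterior = 0.99)
#' @export
displacement_from_clinical <- function(left = 0, inferior = 0, posterior = 0) {
  c(x = -left, y = posterior, z = inferior)
}

#' Unit direction from isocenter toward the gimbal pivot
#'
#' The gantry angle G and ring angle R act as polar and azimuthal coordinates
#' on the 96 cm sphere centred at isocenter:
#' `u(G, R) = (sin G cos(-R), sin G sin(-R), cos G)`.
#'
#' @param gantry,ring Angles in degrees (vectorized).
#' @return An n x 3 matrix of unit vectors.
#' @export
beam_direction <- function(gantry, ring) {
  g <- deg2rad(gantry)
  r <- deg2rad(-ring)
  cbind(x = sin(g) * cos(r), y = sin(g) * sin(r), z = cos(g))
}

#' Pivot point of each beam
#'
#' @param plan A beam plan (tibble, one row per beam).
#' @param machine A [machine_model()].
#' @return Tibble with columns `pivot_x`, `pivot_y`, `pivot_z` in cm.
#' @examples
#' pivot_point(beam_plan("b", 0, 0, 0, gantry = 90, ring = 0))
#' @export
pivot_point <- function(plan, machine = machine_model()) {
  plan <- as_beam_plan(plan)
  u <- beam_direction(plan$gantry, plan$ring)
  tibble::tibble(pivot_x = plan$iso_x + machine$pivot_cm * u[, 1],
                 pivot_y = plan$iso_y + machine$pivot_cm * u[, 2],
                 pivot_z = plan$iso_z + machine$pivot_cm * u[, 3])
}

#' Pivot-to-target vector for the displaced phase
#'
#' The vector from the displaced target back to the pan/tilt pivot, whose
#' direction defines the transformed beam axis and whose length encodes the
#' changed beam path. Two readings of the fiducial terms are available:
#'
#' * `"calibrated"` (default): `rho = pivot - displaced target
#'   = d*u(G1,R1) + fid1 - fid2` (with the original target at the plan
#'   isocenter and the displacement taken from the fiducial centroids). This
#'   reading reproduces the machine's worked phantom example to better than
#'   0.1 cm and is the one every downstream function uses.
#' * `"printed"`: the algebra with fiducial terms `+ 2*fid2 - iso - fid1`,
#'   retained for comparison; it does not reproduce the worked example (see
#'   the methods vignette) and should not be used for planning.
#'
#' @inheritParams pivot_point
#' @param fid_ref,fid_phase Fiducial states on the reference and target phase.
#' @param reading Which fiducial-term reading to evaluate.
#' @return Tibble with columns `rho_x`, `rho_y`, `rho_z`, `rho_norm` (cm).
#' @export
rho_vector <- function(plan, fid_ref, fid_phase,
                       machine = machine_model(),
                       reading = c("calibrated", "printed")) {
  plan <- as_beam_plan(plan)
  reading <- match.arg(reading)
  d <- machine$pivot_cm
  u <- beam_direction(plan$gantry, plan$ring)
  f1 <- fiducial_centroid(fid_ref)
  f2 <- fiducial_centroid(fid_phase)
  rho <- if (reading == "calibrated") {
    sweep(d * u, 2, f1 - f2, "+")
  } else {
    iso <- cbind(plan$iso_x, plan$iso_y, plan$iso_z)
    d * u + matrix(2 * f2, nrow(u), 3, byrow = TRUE) - iso -
      matrix(f1, nrow(u), 3, byrow = TRUE)
  }
  tibble::tibble(rho_x = rho[, 1], rho_y = rho[, 2], rho_z = rho[, 3],
                 rho_norm = sqrt(rowSums(rho^2)))
}

#' Transformed gantry angle
#'
#' Polar angle of the (displaced target -> pivot) vector on the pivot sphere,
#' computed with two-argument arctangent semantics: the numerator is the
#' non-negative transverse magnitude, so the result lies in `[0, 180]`, and
#' the quadrant follows the sign of `d*cos(G1) - dz`.
#'
#' @inheritParams pivot_point
#' @param delta_fid Fiducial displacement `c(x, y, z)` in cm.
#' @return Transformed gantry angles in degrees, one per beam.
#' @export
rotated_gantry <- function(plan, delta_fid, machine = machine_model()) {
  v <- displaced_axis(plan, delta_fid, machine)
  trans <- sqrt(v[, 1]^2 + v[, 2]^2)
  bad <- trans < 1e-12 & abs(v[, 3]) < 1e-12
  if (any(bad))
    stop("beam axis degenerate after displacement (target coincides with pivot) for beam(s): ",
         paste(as_beam_plan(plan)$label[bad], collapse = ", "), call. = FALSE)
  unname(normalize_angle(rad2deg(atan2(trans, v[, 3]))))
}

#' Transformed ring angle
#'
#' Azimuthal angle of the (displaced target -> pivot) vector, with the
#' quadrant resolved from the signs of both transverse components; reported in
#' `[0, 360)`. When the transformed gantry falls in `[0, 180]` for a beam
#' whose original gantry was in `(180, 360)`, the ring absorbs the hemisphere
#' flip (values jumping by about 180 degrees are expected).
#'
#' @inheritParams rotated_gantry
#' @return Transformed ring angles in degrees, one per beam.
#' @export
rotated_ring <- function(plan, delta_fid, machine = machine_model()) {
  v <- displaced_axis(plan, delta_fid, machine)
  trans <- sqrt(v[, 1]^2 + v[, 2]^2)
  if (any(trans < 1e-12))
    stop("ring angle undefined: beam axis along the polar axis with no transverse displacement for beam(s): ",
         paste(as_beam_plan(plan)$label[trans < 1e-12], collapse = ", "),
         call. = FALSE)
  unname(normalize_angle(-rad2deg(atan2(v[, 2], v[, 1]))))
}

# pivot minus displaced target, per beam (n x 3)
displaced_axis <- function(plan, delta_fid, machine) {
  plan <- as_beam_plan(plan)
  stopifnot(length(delta_fid) == 3L, all(is.finite(delta_fid)))
  u <- beam_direction(plan$gantry, plan$ring)
  sweep(machine$pivot_cm * u, 2, as.numeric(delta_fid), "-")
}

#' Transformed collimator angle
#'
#' The gimballed machine cannot rotate its collimator during delivery, but the
#' recomputed plan must rotate it to keep the beam's-eye view unchanged after
#' the gantry/ring change. Piecewise rule:
#' `C2 = (R2 - R1) mod 360` when `G2 > 270` or `G2 < 90`;
#' `C2 = -(R2 - R1) mod 360` when `90 < G2 < 270`;
#' `C2 = 0` when `G1 = 90`; `C2 = 180` when `G1 = 270`. The original-gantry
#' special cases take precedence. A transformed gantry landing exactly on 90
#' or 270 outside those special cases is assigned to the `-(R2 - R1)` branch
#' (continuity with the adjacent open interval).
#'
#' @param G1,R1 Original gantry and ring angles, degrees.
#' @param G2,R2 Transformed gantry and ring angles, degrees.
#' @return Collimator angles in `[0, 360)`, vectorized.
#' @export
rotated_collimator <- function(G1, R1, G2, R2) {
  n <- max(length(G1), length(R1), length(G2), length(R2))
  G1 <- rep_len(G1, n); R1 <- rep_len(R1, n)
  G2 <- rep_len(G2, n); R2 <- rep_len(R2, n)
  out <- numeric(n)
  special0 <- G1 == 90
  special180 <- G1 == 270
  pos <- !special0 & !special180 & (G2 > 270 | G2 < 90)
  neg <- !special0 & !special180 & !pos
  out[special0] <- 0
  out[special180] <- 180
  out[pos] <- normalize_angle(R2[pos] - R1[pos])
  out[neg] <- normalize_angle(-(R2[neg] - R1[neg]))
  out
}

#' Transformed per-beam isocenter
#'
#' The new isocenter sits on the transformed beam axis at the pivot distance
#' from the pivot: `new_iso = d*u(G1, R1) + fid1 - d * rho/|rho|`, an absolute
#' position (zero displacement returns the original isocenter exactly). Each
#' beam gets its own isocenter because the beam path length changes as the
#' beam pans and tilts.
#'
#' @inheritParams pivot_point
#' @param rho Tibble from [rho_vector()] (or any data frame with columns
#'   `rho_x`, `rho_y`, `rho_z`).
#' @param fid_ref Reference-phase fiducial state; its centroid anchors the
#'   original target (for plans whose fiducial centroid sits at isocenter this
#'   is the plan isocenter).
#' @return Tibble with columns `new_iso_x`, `new_iso_y`, `new_iso_z` (cm).
#' @export
new_isocenter <- function(plan, rho, fid_ref, machine = machine_model()) {
  plan <- as_beam_plan(plan)
  d <- machine$pivot_cm
  u <- beam_direction(plan$gantry, plan$ring)
  f1 <- fiducial_centroid(fid_ref)
  rmat <- cbind(rho$rho_x, rho$rho_y, rho$rho_z)
  rnorm <- sqrt(rowSums(rmat^2))
  if (any(rnorm <= 0))
    stop("rho vector has zero length; transformed isocenter undefined",
         call. = FALSE)
  base <- sweep(d * u, 2, f1, "+")
  niso <- base - d * rmat / rnorm
  tibble::tibble(new_iso_x = niso[, 1], new_iso_y = niso[, 2],
                 new_iso_z = niso[, 3])
}

#' Apply the rotation-method tracking transform to a whole plan
#'
#' Recreates, for every beam, the path the beam takes through the patient when
#' the gimbal pans/tilts to follow the fiducial displacement between two
#' respiratory phases: new gantry, ring and collimator angles plus a per-beam
#' isocenter. Apertures are carried over unchanged in BEV coordinates. Beams
#' whose equivalent pan/tilt excursion exceeds the machine limits are flagged
#' with warnings (in the `warnings` list-column), not errors.
#'
#' @inheritParams rho_vector
#' @return A tibble of class `tracked_plan`: the original plan columns plus
#'   `new_iso_x/y/z`, `new_gantry`, `new_ring`, `new_collimator`,
#'   `rho_norm`, `pan_deg`, `tilt_deg`, `inplane_cm` and `warnings`.
#'   Attributes `delta_fid` and `machine` record the transform inputs.
#' @examples
#' plan <- beam_plan("b1", -0.11, -87.84, 28.01, gantry = 30, ring = 17)
#' rotate_plan(plan,
#'             fid_ref = fiducial_state(c(-0.11, -87.84, 28.01)),
#'             fid_phase = fiducial_state(c(-0.57, -86.85, 29.10)))
#' @export
rotate_plan <- function(plan, fid_ref, fid_phase, machine = machine_model()) {
  plan <- as_beam_plan(plan)
  delta <- fiducial_displacement(fid_ref, fid_phase)
  if (sqrt(sum(delta^2)) < 1e-12) {
    # exact identity: skip the arctangent chart, which would otherwise
    # re-express beams with gantry in (180, 360) in the canonical
    # gantry-in-[0,180] representation (ring shifted by 180, collimator 180)
    res <- dplyr::bind_cols(
      plan,
      tibble::tibble(new_iso_x = plan$iso_x, new_iso_y = plan$iso_y,
                     new_iso_z = plan$iso_z, new_gantry = plan$gantry,
                     new_ring = plan$ring, new_collimator = rep(0, nrow(plan)),
                     rho_norm = rep(machine$pivot_cm, nrow(plan)),
                     pan_deg = 0, tilt_deg = 0, inplane_cm = 0,
                     warnings = rep(list(character(0)), nrow(plan))))
    attr(res, "delta_fid") <- delta
    attr(res, "machine") <- machine
    class(res) <- c("tracked_plan", class(res))
    return(res)
  }
  res <- tryCatch({
    rho <- rho_vector(plan, fid_ref, fid_phase, machine)
    G2 <- rotated_gantry(plan, delta, machine)
    R2 <- rotated_ring(plan, delta, machine)
    C2 <- rotated_collimator(plan$gantry, plan$ring, G2, R2)
    niso <- new_isocenter(plan, rho, fid_ref, machine)
    dplyr::bind_cols(plan, niso,
                     tibble::tibble(new_gantry = G2, new_ring = R2,
                                    new_collimator = C2,
                                    rho_norm = rho$rho_norm))
  }, error = function(e) {
    stop("rotation transform failed: ", conditionMessage(e), call. = FALSE)
  })
  exc <- gimbal_excursion(plan, delta, machine)
  res$pan_deg <- exc$pan_deg
  res$tilt_deg <- exc$tilt_deg
  res$inplane_cm <- exc$inplane_cm
  res$warnings <- gimbal_warnings(exc, machine)
  attr(res, "delta_fid") <- delta
  attr(res, "machine") <- machine
  class(res) <- c("tracked_plan", class(res))
  res
}

#' Apply the rotation-method transform to a single beam
#'
#' @param beam A one-row beam plan.
#' @inheritParams rotate_plan
#' @return A one-row `tracked_plan` tibble (see [rotate_plan()]).
#' @export
rotate_beam <- function(beam, fid_ref, fid_phase, machine = machine_model()) {
  beam <- as_beam_plan(beam)
  if (nrow(beam) != 1L) stop("rotate_beam() expects exactly one beam; use rotate_plan()",
                             call. = FALSE)
  rotate_plan(beam, fid_ref, fid_phase, machine)
}

#' Translation-method baseline
#'
#' Models tracking as a rigid translation: every beam isocenter is shifted by
#' the same fiducial displacement while gantry, ring and collimator angles are
#' unchanged. This is the simpler baseline the rotation method improves on.
#'
#' @inheritParams rotated_gantry
#' @return The plan with shifted isocenters (a `beam_plan` tibble).
#' @export
translate_plan <- function(plan, delta_fid) {
  plan <- as_beam_plan(plan)
  stopifnot(length(delta_fid) == 3L, all(is.finite(delta_fid)))
  plan$iso_x <- plan$iso_x + delta_fid[1]
  plan$iso_y <- plan$iso_y + delta_fid[2]
  plan$iso_z <- plan$iso_z + delta_fid[3]
  plan
}

#' Independent geometric construction of the tracked beam
#'
#' Validates the closed-form transform by direct 3-D construction: fix the
#' pivot `P` of the original beam, place the displaced target
#' `T = isocenter + delta_fid`, take the line `P -> T` as the new beam axis,
#' put the new isocenter on that line at the pivot distance from `P`, and
#' recover the gantry/ring angles by inverting the direction parameterization
#' `u(G, R)`. By construction the displaced target lies on the new axis and
#' the new isocenter is exactly the pivot distance from the pivot.
#'
#' @param beam A one-row beam plan.
#' @inheritParams rotated_gantry
#' @return A list with `gantry`, `ring` (degrees), `isocenter` (named numeric,
#'   cm), `axis_dist` (perpendicular distance of the displaced target from the
#'   new axis, cm) and `pivot`.
#' @export
geometric_oracle <- function(beam, delta_fid, machine = machine_model()) {
  beam <- as_beam_plan(beam)
  stopifnot(nrow(beam) == 1L, length(delta_fid) == 3L)
  piv <- as.numeric(pivot_point(beam, machine)[1, ])
  iso <- c(beam$iso_x, beam$iso_y, beam$iso_z)
  target <- iso + as.numeric(delta_fid)
  axis <- target - piv
  len <- sqrt(sum(axis^2))
  if (len == 0) stop("displaced target coincides with the pivot", call. = FALSE)
  dirv <- axis / len
  niso <- piv + machine$pivot_cm * dirv
  # invert u(G, R): the pivot-pointing direction is -dirv
  up <- -dirv
  gantry <- rad2deg(acos(max(-1, min(1, up[3]))))
  ring <- if (sqrt(up[1]^2 + up[2]^2) < 1e-15) beam$ring else
    normalize_angle(-rad2deg(atan2(up[2], up[1])))
  # perpendicular distance of the target from the line P + t*dirv
  w <- target - piv
  perp <- w - sum(w * dirv) * dirv
  list(gantry = gantry, ring = ring,
       isocenter = c(x = niso[1], y = niso[2], z = niso[3]),
       axis_dist = sqrt(sum(perp^2)),
       pivot = c(x = piv[1], y = piv[2], z = piv[3]))
}

# equivalent pan/tilt excursion of each beam for a rigid target displacement
gimbal_excursion <- function(plan, delta_fid, machine) {
  plan <- as_beam_plan(plan)
  u <- beam_direction(plan$gantry, plan$ring)
  g <- deg2rad(plan$gantry); r <- deg2rad(-plan$ring)
  e_theta <- cbind(cos(g) * cos(r), cos(g) * sin(r), -sin(g))
  e_phi <- cbind(-sin(r), cos(r), rep(0, length(g)))
  d <- as.numeric(delta_fid)
  along <- as.numeric(u %*% d)
  comp_t <- as.numeric(e_theta %*% d)
  comp_p <- as.numeric(e_phi %*% d)
  tibble::tibble(
    pan_deg = rad2deg(atan2(comp_p, machine$pivot_cm - along)),
    tilt_deg = rad2deg(atan2(comp_t, machine$pivot_cm - along)),
    inplane_cm = sqrt(comp_t^2 + comp_p^2))
}

gimbal_warnings <- function(exc, machine) {
  purrr::pmap(exc, function(pan_deg, tilt_deg, inplane_cm) {
    w <- character(0)
    if (abs(pan_deg) > machine$gimbal_deg)
      w <- c(w, sprintf("pan excursion %.2f deg exceeds the +/-%g deg gimbal limit",
                        pan_deg, machine$gimbal_deg))
    if (abs(tilt_deg) > machine$gimbal_deg)
      w <- c(w, sprintf("tilt excursion %.2f deg exceeds the +/-%g deg gimbal limit",
                        tilt_deg, machine$gimbal_deg))
    if (inplane_cm > machine$iso_plane_cm)
      w <- c(w, sprintf("in-plane excursion %.2f cm exceeds the +/-%g cm isocenter-plane limit",
                        inplane_cm, machine$iso_plane_cm))
    w
  })
}

#' Gimbal range-limit warnings for a tracked plan
#'
#' @param result A `tracked_plan` from [rotate_plan()].
#' @param machine A [machine_model()].
#' @return A list (one element per beam) of warning strings; empty when the
#'   excursion is within the pan/tilt and isocenter-plane limits.
#' @export
check_gimbal_limits <- function(result, machine = machine_model()) {
  stopifnot(all(c("pan_deg", "tilt_deg", "inplane_cm") %in% names(result)))
  gimbal_warnings(result[c("pan_deg", "tilt_deg", "inplane_cm")], machine)
}

#' Calibrate the clinical-direction axis convention
#'
#' The worked phantom example states its target displacement in clinical
#' directions (left / inferior / posterior) without naming the planning-frame
#' axes. This fit tries all 48 signed permutations of those directions onto
#' `(x, y, z)`, runs the rotation transform on the example's seven beams for
#' each candidate, and scores the summed squared residuals against the printed
#' outputs (3 angles + 3 isocenter components per beam). The winner is frozen
#' in [displacement_from_clinical()]; this function exists so the choice stays
#' reproducible and regression-tested.
#'
#' @param magnitudes Named displacements in cm,
#'   `c(left = ..., inferior = ..., posterior = ...)`.
#' @return A tibble of all 48 candidates sorted by score, with columns
#'   `delta_x`, `delta_y`, `delta_z`, `rss`, `max_angle_resid`,
#'   `max_iso_resid`.
#' @export
calibrate_axis_convention <- function(
    magnitudes = c(left = 0.46, inferior = 1.09, posterior = 0.99)) {
  fx <- table2_fixture()
  plan <- table2_plan()
  fid_ref <- fiducial_state(c(plan$iso_x[1], plan$iso_y[1], plan$iso_z[1]))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1)))
  cand <- purrr::map_dfr(seq_len(nrow(perms)), function(pi) {
    purrr::map_dfr(seq_len(nrow(signs)), function(si) {
      delta <- numeric(3)
      delta[perms[pi, ]] <- unname(magnitudes) * signs[si, ]
      fid_phase <- fiducial_state(fiducial_centroid(fid_ref) + delta)
      tr <- rotate_plan(plan, fid_ref, fid_phase)
      ang <- c(angle_diff(tr$new_gantry, fx$new_gantry),
               angle_diff(tr$new_ring, fx$new_ring),
               angle_diff(tr$new_collimator, fx$new_collimator))
      iso <- c(tr$new_iso_x - fx$new_iso_x, tr$new_iso_y - fx$new_iso_y,
               tr$new_iso_z - fx$new_iso_z)
      tibble::tibble(delta_x = delta[1], delta_y = delta[2],
                     delta_z = delta[3],
                     rss = sum(ang^2) + sum(iso^2),
                     max_angle_resid = max(ang), max_iso_resid = max(abs(iso)))
    })
  })
  dplyr::arrange(cand, .data$rss)
}
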