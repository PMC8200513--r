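#' Cylindrical phantom specification
#'
#' A water-equivalent cylindrical body (axis along z, the patient
#' superior-inferior direction) containing a cylindrical target and an
#' adjacent organ-at-risk cylinder, emulating the phantom used to exercise
#' tracking transforms: a target displaced 1-2 cm in one to three dimensions.
#'
#' @param body_radius_cm,body_length_cm Body cylinder dimensions, cm.
#' @param target_radius_cm,target_length_cm Target cylinder dimensions, cm.
#' @param target_center Target center, cm (must keep the target inside the
#'   body).
#' @param oar_gap_cm Gap between target surface and the OAR cylinder, cm.
#' @param spacing_cm Isotropic grid spacing, cm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(body_radius_cm = 10, body_length_cm = 20,
                         target_radius_cm = 2, target_length_cm = 4,
                         target_center = c(0, 0, 0), oar_gap_cm = 0.3,
                         spacing_cm = 0.2) {
  stopifnot(spacing_cm > 0, body_radius_cm > 0, target_radius_cm > 0)
  spec <- list(body_radius_cm = body_radius_cm,
               body_length_cm = body_length_cm,
               target_radius_cm = target_radius_cm,
               target_length_cm = target_length_cm,
               target_center = as.numeric(target_center),
               oar_gap_cm = oar_gap_cm, spacing_cm = spacing_cm)
  lat <- sqrt(sum(target_center[1:2]^2)) + target_radius_cm
  ax <- abs(target_center[3]) + target_length_cm / 2
  if (lat > body_radius_cm || ax > body_length_cm / 2)
    stop("target extends outside the phantom body", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

cylinder_mask <- function(centers, center, radius, length_) {
  r2 <- (centers[, 1] - center[1])^2 + (centers[, 2] - center[2])^2
  r2 <= radius^2 & abs(centers[, 3] - center[3]) <= length_ / 2
}

#' Build the cylindrical phantom on a reference grid
#'
#' @param spec A [phantom_spec()].
#' @param shift Rigid displacement of the anatomy (target, OAR, body,
#'   fiducials) within the fixed reference grid, cm. Used to realise other
#'   respiratory phases of the phantom.
#' @return A list of class `phantom` with `layout` (an empty [dose_grid()]
#'   giving origin/spacing/dims), masks `body`, `target`, `oar`
#'   ([roi_mask()]), `fiducials` (a [fiducial_state()]: three markers at
#'   fixed offsets around the target center), and the spec (with the applied
#'   shift recorded).
#' @export
make_phantom <- function(spec = phantom_spec(), shift = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"), length(shift) == 3L)
  sp <- spec$spacing_cm
  margin <- 1
  half_xy <- spec$body_radius_cm + margin
  half_z <- spec$body_length_cm / 2 + margin
  # even voxel counts: centers sit at half-voxel offsets, never exactly on
  # the cylinder boundaries, keeping voxelized volumes unbiased
  nx <- ny <- 2L * ceiling(half_xy / sp)
  nz <- 2L * ceiling(half_z / sp)
  origin <- c(-(nx - 1L) / 2 * sp, -(ny - 1L) / 2 * sp, -(nz - 1L) / 2 * sp)
  layout <- dose_grid(array(0, c(nx, ny, nz)), origin = origin,
                      spacing = rep(sp, 3))
  centers <- voxel_centers(layout)
  body_c <- as.numeric(shift)
  tgt_c <- spec$target_center + shift
  body <- cylinder_mask(centers, body_c, spec$body_radius_cm,
                        spec$body_length_cm)
  target <- cylinder_mask(centers, tgt_c, spec$target_radius_cm,
                          spec$target_length_cm)
  # OAR: a parallel cylinder abutting the target laterally (posterior side)
  oar_c <- tgt_c + c(0, spec$target_radius_cm + spec$oar_gap_cm +
                       spec$target_radius_cm / 2, 0)
  oar <- cylinder_mask(centers, oar_c, spec$target_radius_cm / 2,
                       spec$target_length_cm) & body
  dims <- c(nx, ny, nz)
  fid_offsets <- rbind(c(1.2, 0, 0.8), c(-1.0, 0.8, -0.6), c(0, -1.2, 0.5))
  structure(list(
    layout = layout,
    body = roi_mask(array(body, dims), origin, rep(sp, 3), "body"),
    target = roi_mask(array(target, dims), origin, rep(sp, 3), "target"),
    oar = roi_mask(array(oar, dims), origin, rep(sp, 3), "oar"),
    fiducials = fiducial_state(sweep(fid_offsets, 2, tgt_c, "+")),
    body_center = body_c, target_center = tgt_c, oar_center = oar_c,
    spec = spec, shift = as.numeric(shift)), class = "phantom")
}

#' Quasi-periodic breathing-trace specification
#'
#' The synthetic waveform is `a(t) = amplitude * cos^(2p)(pi t / period) +
#' noise`, peaking (maximum inhalation) at multiples of the period. The
#' asymmetry exponent `p >= 1` controls how much of each cycle is spent near
#' exhale: `p = 1` is a symmetric raised cosine (equal inhale/exhale time),
#' larger `p` sharpens the inhale peaks, which is the behaviour seen in real
#' respiratory traces.
#'
#' @param period_s Breathing period, s.
#' @param amplitude Peak amplitude, arbitrary units.
#' @param asymmetry Exponent `p`.
#' @param noise_sd Gaussian noise standard deviation, amplitude units.
#' @param duration_s Trace length, s (at least 3 periods).
#' @param sample_hz Sampling rate, Hz.
#' @param seed RNG seed for the noise.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(period_s = 4, amplitude = 1, asymmetry = 2,
                       noise_sd = 0.02, duration_s = 60, sample_hz = 25,
                       seed = 1L) {
  stopifnot(period_s > 0, duration_s >= 3 * period_s, asymmetry >= 1,
            noise_sd >= 0, sample_hz > 0)
  structure(list(period_s = period_s, amplitude = amplitude,
                 asymmetry = asymmetry, noise_sd = noise_sd,
                 duration_s = duration_s, sample_hz = sample_hz,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic breathing trace
#'
#' @param spec A [trace_spec()].
#' @return A [breathing_trace()] tibble. Deterministic for a fixed seed.
#' @examples
#' make_trace(trace_spec(asymmetry = 3, noise_sd = 0))
#' @export
make_trace <- function(spec = trace_spec()) {
  stopifnot(inherits(spec, "trace_spec"))
  t <- seq(0, spec$duration_s, by = 1 / spec$sample_hz)
  a <- spec$amplitude * cos(pi * t / spec$period_s)^(2 * spec$asymmetry)
  if (spec$noise_sd > 0)
    a <- a + with_seed(spec$seed, stats::rnorm(length(t), 0, spec$noise_sd))
  breathing_trace(t, a)
}

#' Ten-phase fiducial trajectory with rigid deformation fields
#'
#' Samples the noise-free breathing waveform at the phase centers of one
#' cycle (phase 0% centred at maximum inhalation, the ten bins covering equal
#' durations) and scales the peak fiducial displacement by the waveform
#' value, so phase 0% carries the full displacement and phase 50% (exhale,
#' the reference) is at rest. Each phase gets a rigid (constant-vector)
#' deformation field mapping reference coordinates into that phase when a
#' grid layout is supplied.
#'
#' @param peak_displacement Displacement of the fiducials at full inhale,
#'   `c(x, y, z)` cm.
#' @param spec A [trace_spec()] (waveform shape; noise ignored).
#' @param n_phases Number of respiratory phases.
#' @param layout Optional grid layout ([dose_grid()] or [roi_mask()]); when
#'   given, a `dvf` list-column of [deformation_field()]s is attached.
#' @param smooth_edge If `TRUE`, the fields taper smoothly to zero toward the
#'   lateral grid edge instead of being constant (exercises spatially varying
#'   interpolation); the fiducial displacements are unchanged.
#' @return A tibble with one row per phase: `phase` (label), `phase_frac`,
#'   `t_center_s`, `duration_s`, `dx`, `dy`, `dz` and optionally `dvf`.
#' @export
make_phase_series <- function(peak_displacement, spec = trace_spec(),
                              n_phases = 10, layout = NULL,
                              smooth_edge = FALSE) {
  stopifnot(length(peak_displacement) == 3L, n_phases >= 2L)
  machine <- machine_model()
  if (sqrt(sum(peak_displacement^2)) > machine$iso_plane_cm)
    warning(sprintf(
      "peak displacement %.2f cm exceeds the %.1f cm trackable range",
      sqrt(sum(peak_displacement^2)), machine$iso_plane_cm), call. = FALSE)
  k <- seq_len(n_phases) - 1L
  tc <- k * spec$period_s / n_phases
  s <- cos(pi * tc / spec$period_s)^(2 * spec$asymmetry)
  out <- tibble::tibble(
    phase = sprintf("%d%%", as.integer(round(100 * k / n_phases))),
    phase_frac = k / n_phases,
    t_center_s = tc,
    duration_s = spec$period_s / n_phases,
    dx = peak_displacement[1] * s,
    dy = peak_displacement[2] * s,
    dz = peak_displacement[3] * s)
  if (!is.null(layout)) {
    out$dvf <- purrr::pmap(out[c("dx", "dy", "dz")], function(dx, dy, dz)
      make_rigid_dvf(c(dx, dy, dz), layout, smooth_edge = smooth_edge))
  }
  out
}

#' Rigid (or edge-tapered) deformation field on a grid layout
#'
#' @param delta Displacement vector, cm (reference to phase).
#' @param layout A [dose_grid()] / [roi_mask()] defining the grid.
#' @param smooth_edge Taper the field with a raised-cosine window of the
#'   lateral radius so it vanishes at the grid edge.
#' @return A [deformation_field()].
#' @export
make_rigid_dvf <- function(delta, layout, smooth_edge = FALSE) {
  d <- grid_dims(layout)
  n <- prod(d)
  if (!smooth_edge) {
    u <- array(0, c(d, 3))
    u[, , , 1] <- delta[1]; u[, , , 2] <- delta[2]; u[, , , 3] <- delta[3]
  } else {
    centers <- voxel_centers(layout)
    rmax <- max(abs(c(layout$origin[1],
                      layout$origin[1] + (d[1] - 1) * layout$spacing[1])))
    r <- pmin(sqrt(centers[, 1]^2 + centers[, 2]^2) / rmax, 1)
    w <- cos(pi * r / 2)^2
    u <- array(c(delta[1] * w, delta[2] * w, delta[3] * w), c(d, 3))
  }
  deformation_field(u, origin = layout$origin, spacing = layout$spacing)
}

#' Project a point into a beam's-eye view
#'
#' Projects points through the beam source (placed on the beam axis at the
#' pivot distance upstream of the isocenter) onto the plane through the
#' isocenter perpendicular to the beam axis, expressed in collimator-rotated
#' BEV axes.
#'
#' @param beam A one-row beam plan (original angles/isocenter are used; pass a
#'   re-labelled tracked beam via [tracked_as_plan()] to project under the
#'   transformed geometry).
#' @param points Numeric vector of length 3 or an n x 3 matrix, cm.
#' @param machine A [machine_model()].
#' @return An n x 2 matrix of BEV coordinates (cm at the isocenter plane).
#' @export
bev_project <- function(beam, points, machine = machine_model()) {
  beam <- as_beam_plan(beam)
  stopifnot(nrow(beam) == 1L)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  stopifnot(ncol(points) == 3L)
  iso <- c(beam$iso_x, beam$iso_y, beam$iso_z)
  u <- as.numeric(beam_direction(beam$gantry, beam$ring))
  src <- iso + machine$pivot_cm * u
  g <- deg2rad(beam$gantry); r <- deg2rad(-beam$ring)
  e_theta <- c(cos(g) * cos(r), cos(g) * sin(r), -sin(g))
  e_phi <- c(-sin(r), cos(r), 0)
  cc <- deg2rad(beam$collimator)
  e1 <- cos(cc) * e_phi + sin(cc) * e_theta
  e2 <- -sin(cc) * e_phi + cos(cc) * e_theta
  sp <- sweep(points, 2, src, "-")          # source -> point
  denom <- as.numeric(sp %*% (-u))          # distance along beam axis
  if (any(denom <= 0))
    stop("point at or behind the beam source cannot be projected",
         call. = FALSE)
  scale <- machine$pivot_cm / denom
  q <- sp * scale                            # intersection with iso plane
  cbind(bev_x = as.numeric(q %*% e1), bev_y = as.numeric(q %*% e2))
}

#' Recast a tracked plan as a deliverable beam plan
#'
#' @param tracked A `tracked_plan` from [rotate_plan()].
#' @return A `beam_plan` whose angles and isocenters are the transformed ones.
#' @export
tracked_as_plan <- function(tracked) {
  plan <- beam_plan(label = tracked$label,
                    iso_x = tracked$new_iso_x, iso_y = tracked$new_iso_y,
                    iso_z = tracked$new_iso_z,
                    gantry = tracked$new_gantry, ring = tracked$new_ring,
                    collimator = tracked$new_collimator,
                    weight = tracked$weight,
                    aperture = if ("aperture" %in% names(tracked))
                      tracked$aperture else NULL)
  plan
}

#' Toy divergent-beam dose engine
#'
#' A deliberately simple photon-like model used only to demonstrate
#' rotation-vs-translation differences end to end: per beam, dose is
#' `weight * dose_scale * (pivot/d)^2 * exp(-mu * depth)` inside the
#' divergent cone projected from the source through the BEV aperture, zero
#' outside, summed over beams. `d` is the source-to-voxel distance and
#' `depth` the path length inside the phantom body from the entry point.
#' This is NOT a commissioned dose calculation; outputs are labelled "toy".
#'
#' @param plan A `beam_plan` (apertures required) or `tracked_plan` (its
#'   transformed geometry is used).
#' @param phantom A [make_phantom()] result (possibly shifted).
#' @param machine A [machine_model()].
#' @param mu Linear attenuation coefficient, 1/cm.
#' @param dose_scale cGy per unit beam weight at the isocenter distance.
#' @return A [dose_grid()] on the phantom layout (attribute `engine = "toy"`).
#' @export
toy_dose <- function(plan, phantom, machine = machine_model(), mu = 0.02,
                     dose_scale = 100) {
  if (inherits(plan, "tracked_plan")) plan <- tracked_as_plan(plan)
  plan <- as_beam_plan(plan)
  if (is.null(plan$aperture))
    stop("toy_dose needs beam apertures (see aperture_circle())", call. = FALSE)
  layout <- phantom$layout
  d <- grid_dims(layout)
  centers <- voxel_centers(layout)
  total <- numeric(nrow(centers))
  for (b in seq_len(nrow(plan))) {
    beam <- plan[b, ]
    ap <- plan$aperture[[b]]
    iso <- c(beam$iso_x, beam$iso_y, beam$iso_z)
    u <- as.numeric(beam_direction(beam$gantry, beam$ring))
    src <- iso + machine$pivot_cm * u
    sp <- sweep(centers, 2, src, "-")
    dist2 <- rowSums(sp^2)
    axial <- -(sp %*% u)                   # along-beam distance from source
    infield <- axial > 0
    bev <- matrix(Inf, nrow(centers), 2)
    bev[infield, ] <- bev_project(beam, centers[infield, , drop = FALSE],
                                  machine)
    inside <- infield & aperture_contains(ap, bev)
    depth <- body_depth(src, centers, sqrt(dist2), phantom)
    contrib <- beam$weight * dose_scale * (machine$pivot_cm^2 / dist2) *
      exp(-mu * depth)
    total <- total + ifelse(inside, contrib, 0)
  }
  out <- dose_grid(array(total, d), origin = layout$origin,
                   spacing = layout$spacing)
  attr(out, "engine") <- "toy"
  out
}

aperture_contains <- function(ap, bev) {
  stopifnot(inherits(ap, "bev_aperture"))
  sqrt(bev[, 1]^2 + bev[, 2]^2) <= ap$radius_cm
}

# path length inside the body cylinder from the entry point to each voxel
body_depth <- function(src, centers, dist, phantom) {
  spec <- phantom$spec
  bc <- phantom$body_center
  rb <- spec$body_radius_cm
  hl <- spec$body_length_cm / 2
  dirs <- sweep(centers, 2, src, "-") / dist
  # lateral quadratic: |(src + t*dir)_xy - bc_xy| = rb
  ox <- src[1] - bc[1]; oy <- src[2] - bc[2]
  a <- dirs[, 1]^2 + dirs[, 2]^2
  bq <- 2 * (ox * dirs[, 1] + oy * dirs[, 2])
  cq <- ox^2 + oy^2 - rb^2
  disc <- bq^2 - 4 * a * cq
  ok <- disc > 0 & a > 1e-12
  t_lat_in <- rep(Inf, length(a))
  t_lat_out <- rep(-Inf, length(a))
  sq <- sqrt(pmax(disc, 0))
  t_lat_in[ok] <- (-bq[ok] - sq[ok]) / (2 * a[ok])
  t_lat_out[ok] <- (-bq[ok] + sq[ok]) / (2 * a[ok])
  # axial slab |(src + t*dir)_z - bc_z| <= hl
  dz <- dirs[, 3]
  oz <- src[3] - bc[3]
  tz1 <- ifelse(abs(dz) > 1e-12, (-hl - oz) / dz, ifelse(abs(oz) <= hl, -Inf, Inf))
  tz2 <- ifelse(abs(dz) > 1e-12, (hl - oz) / dz, ifelse(abs(oz) <= hl, Inf, -Inf))
  t_z_in <- pmin(tz1, tz2)
  t_z_out <- pmax(tz1, tz2)
  t_in <- pmax(t_lat_in, t_z_in, 0)
  t_out <- pmin(t_lat_out, t_z_out)
  pmax(pmin(dist, t_out) - t_in, 0)
}
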