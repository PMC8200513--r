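#' Default configuration for the synthetic end-to-end demonstration
#'
#' One config drives the whole pipeline: cylindrical phantom, breathing
#' trace, ten-phase fiducial trajectory, toy doses per phase under the
#' rotation method, warps back to the exhale reference, two-phase and
#' ten-phase accumulation and an OAR constraint report. Defaults: a 2 cm
#' oblique peak displacement (1-2 cm per axis, the range the phantom
#' experiments exercise), a 4 s breathing period with asymmetry exponent 2,
#' and a 0.4 cm demo grid.
#'
#' @param seed Seed for the trace noise.
#' @return A nested list understood by [simulate_tracking()]; the same
#'   structure can be read from YAML (see the `simulate` CLI subcommand).
#' @export
demo_config <- function(seed = 1L) {
  list(
    phantom = list(spacing_cm = 0.4),
    trace = list(period_s = 4, amplitude = 1, asymmetry = 2,
                 noise_sd = 0.02, duration_s = 60, seed = seed),
    peak_displacement = c(1.2, 1.2, 1.0),
    n_phases = 10,
    plan = list(gantry = c(192, 234, 270, 306, 342, 30, 150),
                ring = c(17, 343, 17, 343, 17, 17, 0),
                aperture_margin_cm = 0.5),
    constraints = list(organ = "oar", limit_cGy = 1500),
    oob_warn = 1,
    smooth_edge = FALSE)
}

#' Run the synthetic tracking pipeline end to end
#'
#' Builds the phantom and its ten respiratory phases, derives breathing-trace
#' phase weights, applies the rotation method per phase, computes toy doses,
#' warps them back to the exhale reference with the per-phase rigid fields,
#' accumulates `Sum_2Phases` and `Sum_10Phases`, evaluates the OAR
#' constraint, and contrasts the rotation and translation methods on the
#' inhale phase.
#'
#' @param config A list as returned by [demo_config()] (or parsed from YAML).
#' @param out_dir Optional directory: when given, writes phantom and dose
#'   NRRDs, the plan JSON, trace CSV, weights JSON, the constraint report CSV
#'   and a manifest JSON.
#' @param quiet Suppress progress messages.
#' @return A list with `weights` ([phase_weights()]), `series` (phase table),
#'   `doses` (named list of accumulated [dose_grid()]s), `report` (constraint
#'   tibble across methods), `rot_trans_oar_diff` (max |rotation -
#'   translation| toy dose inside the inhale-phase OAR, cGy) and `plan`.
#' @export
simulate_tracking <- function(config = demo_config(), out_dir = NULL,
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  spec <- do.call(phantom_spec, config$phantom %||% list())
  tspec <- do.call(trace_spec, config$trace %||% list())
  machine <- machine_model()
  ref <- make_phantom(spec)

  say("phase weights from the synthetic breathing trace")
  trace <- make_trace(tspec)
  pw <- phase_weights(trace)

  n_phases <- config$n_phases %||% 10
  peak <- as.numeric(config$peak_displacement)
  series <- make_phase_series(peak, tspec, n_phases = n_phases,
                              layout = ref$layout,
                              smooth_edge = isTRUE(config$smooth_edge))

  pl <- config$plan
  plan <- beam_plan(
    label = sprintf("beam%d", seq_along(pl$gantry)),
    iso_x = ref$target_center[1], iso_y = ref$target_center[2],
    iso_z = ref$target_center[3],
    gantry = pl$gantry, ring = pl$ring, collimator = 0, weight = 1,
    aperture = list(aperture_circle(spec$target_radius_cm +
                                      (pl$aperture_margin_cm %||% 0.5))))

  say("toy dose per phase under the rotation method (%d phases)", n_phases)
  warped <- vector("list", n_phases)
  phase_doses <- vector("list", n_phases)
  for (k in seq_len(n_phases)) {
    delta <- c(series$dx[k], series$dy[k], series$dz[k])
    fid_phase <- fiducial_state(as.matrix(ref$fiducials[c("x", "y", "z")]) +
                                  matrix(delta, nrow(ref$fiducials), 3,
                                         byrow = TRUE),
                                phase = series$phase[k])
    tracked <- rotate_plan(plan, ref$fiducials, fid_phase, machine)
    ph <- make_phantom(spec, shift = delta)
    phase_doses[[k]] <- toy_dose(tracked, ph, machine)
    warped[[k]] <- warp_dose(phase_doses[[k]], series$dvf[[k]],
                             oob_warn = config$oob_warn %||% 1)
  }
  names(warped) <- names(phase_doses) <- series$phase

  i_in <- which(series$phase_frac == 0)
  i_ex <- which.min(abs(series$phase_frac - 0.5))
  doses <- list(
    Original_BH = toy_dose(plan, ref, machine),
    Sum_2Phases = accumulate_dose(list(warped[[i_ex]], warped[[i_in]]),
                                  c(pw$w_ex, pw$w_in)),
    Sum_10Phases = accumulate_dose(warped, rep(1 / n_phases, n_phases)))

  say("rotation vs translation contrast on the inhale phase")
  delta_in <- c(series$dx[i_in], series$dy[i_in], series$dz[i_in])
  inhale_ph <- make_phantom(spec, shift = delta_in)
  fid_in <- fiducial_state(as.matrix(ref$fiducials[c("x", "y", "z")]) +
                             matrix(delta_in, nrow(ref$fiducials), 3,
                                    byrow = TRUE), phase = "0%")
  rot_in <- toy_dose(rotate_plan(plan, ref$fiducials, fid_in, machine),
                     inhale_ph, machine)
  trans_in <- toy_dose(translate_plan(plan, delta_in), inhale_ph, machine)
  doses$Inhale_rot <- rot_in
  doses$Inhale_trans <- trans_in
  oar_diff <- max(abs(rot_in$values[inhale_ph$oar$values] -
                        trans_in$values[inhale_ph$oar$values]))

  constraints <- tibble::tibble(organ = config$constraints$organ,
                                limit_cGy = config$constraints$limit_cGy)
  masks_ref <- list(oar = ref$oar, target = ref$target)
  masks_in <- list(oar = inhale_ph$oar, target = inhale_ph$target)
  report <- dplyr::bind_rows(
    dplyr::mutate(evaluate_constraints(doses$Original_BH, masks_ref,
                                       constraints), method = "Original_BH"),
    dplyr::mutate(evaluate_constraints(doses$Inhale_trans, masks_in,
                                       constraints), method = "Inhale_trans"),
    dplyr::mutate(evaluate_constraints(doses$Inhale_rot, masks_in,
                                       constraints), method = "Inhale_rot"),
    dplyr::mutate(evaluate_constraints(doses$Sum_2Phases, masks_ref,
                                       constraints), method = "Sum_2Phases"),
    dplyr::mutate(evaluate_constraints(doses$Sum_10Phases, masks_ref,
                                       constraints), method = "Sum_10Phases"))
  report <- dplyr::relocate(report, "method")

  result <- list(weights = pw, series = series, plan = plan, doses = doses,
                 report = report, rot_trans_oar_diff = oar_diff,
                 phantom = ref, inhale_phantom = inhale_ph, config = config)
  if (!is.null(out_dir)) write_simulation(result, out_dir)
  result
}

write_simulation <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_plan(result$plan, p("plan.json"))
  write_trace(result$weights$trace, p("trace.csv"))
  jsonlite::write_json(glance(result$weights), p("weights.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(result$doses))
    write_nrrd(result$doses[[nm]], p(sprintf("dose_%s.nrrd", nm)))
  write_nrrd(result$phantom$target, p("mask_target.nrrd"))
  write_nrrd(result$phantom$oar, p("mask_oar.nrrd"))
  for (k in seq_len(nrow(result$series)))
    write_nrrd(result$series$dvf[[k]],
               p(sprintf("dvf_phase_%02d.nrrd", k - 1L)))
  readr::write_csv(result$report, p("report.csv"))
  jsonlite::write_json(
    list(files = list.files(out_dir),
         rot_trans_oar_diff_cGy = result$rot_trans_oar_diff,
         engine = "toy"),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
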