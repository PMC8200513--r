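test_that("pivot point follows the gantry/ring parameterization", {
  m <- machine_model()
  p1 <- pivot_point(beam_plan("a", 0, 0, 0, gantry = 0, ring = 0), m)
  expect_equal(as.numeric(p1), c(0, 0, 96), tolerance = 1e-12)
  p2 <- pivot_point(beam_plan("a", 0, 0, 0, gantry = 90, ring = 0), m)
  expect_equal(as.numeric(p2), c(96, 0, 0), tolerance = 1e-9)
  p3 <- pivot_point(beam_plan("a", -0.11, -87.84, 28.01,
                              gantry = 150, ring = 0), m)
  expect_equal(as.numeric(p3), c(47.89, -87.84, -55.1284), tolerance = 1e-4)
})

test_that("fiducial displacement is the centroid difference", {
  f0 <- fiducial_state(c(1, 2, 3))
  expect_equal(unname(fiducial_displacement(f0, f0)), c(0, 0, 0))
  # the worked example's displacement under the calibrated axis convention
  f1 <- fiducial_state(c(1 - 0.46, 2 + 0.99, 3 + 1.09))
  expect_equal(unname(fiducial_displacement(f0, f1)), c(-0.46, 0.99, 1.09),
               tolerance = 1e-12)
  # two markers whose centroids differ by (0.5, 0, 0)
  a <- fiducial_state(rbind(c(0, 0, 0), c(2, 1, 1)))
  b <- fiducial_state(rbind(c(0.2, 0, 0), c(2.8, 1, 1)))
  expect_equal(unname(fiducial_displacement(a, b)), c(0.5, 0, 0),
               tolerance = 1e-12)
  expect_error(fiducial_displacement(a, f0, paired = TRUE), "2.*1")
})

fiducial_centroid2 <- function(f) c(mean(f$x), mean(f$y), mean(f$z))

test_that("rho vector reduces to the pivot radius with no displacement", {
  plan <- random_plan(5)
  iso <- fiducial_state(c(plan$iso_x[1], plan$iso_y[1], plan$iso_z[1]))
  r <- rho_vector(plan, iso, iso)
  expect_equal(r$rho_norm, rep(96, 5), tolerance = 1e-9)
  # bounded displacement keeps |rho| within the geometric band
  withr::with_seed(42, {
    for (i in 1:20) {
      d <- stats::runif(3, -1, 1)
      d <- d / sqrt(sum(d^2)) * stats::runif(1, 0, 2)
      fid2 <- fiducial_state(fiducial_centroid2(iso) + d)
      rn <- rho_vector(plan, iso, fid2)$rho_norm
      expect_true(all(rn >= 92 & rn <= 100))
    }
  })
})

test_that("gantry/ring transforms are identities at zero displacement", {
  plan <- beam_plan("a", 0, 0, 0, gantry = 30, ring = 17)
  expect_equal(rotated_gantry(plan, c(0, 0, 0)), 30, tolerance = 1e-9)
  expect_equal(rotated_ring(plan, c(0, 0, 0)), 17, tolerance = 1e-9)
  # polar-axis degeneracy: no transverse component, ring undefined
  polar <- beam_plan("p", 0, 0, 0, gantry = 0, ring = 0)
  expect_error(rotated_ring(polar, c(0, 0, 0.5)), "polar")
})

test_that("collimator branch rule reproduces the printed cases", {
  # first branch (G2 < 90): beam 6 of the worked example
  expect_equal(rotated_collimator(30, 17, 30.7, 18.0), 1.0, tolerance = 1e-9)
  # second branch with mod-360 wrap: beam 7
  expect_equal(rotated_collimator(150, 0, 150.0, 1.2), 358.8,
               tolerance = 1e-9)
  # second branch: beam 1, -(194.5 - 17) mod 360
  expect_equal(rotated_collimator(192, 17, 168.5, 194.5), 182.5,
               tolerance = 1e-9)
  # first branch landing negative before the wrap: beam 4
  expect_equal(rotated_collimator(306, 343, 54.4, 162.2), 179.2,
               tolerance = 1e-9)
  # original-gantry special cases take precedence
  expect_equal(rotated_collimator(90, 10, 120, 40), 0)
  expect_equal(rotated_collimator(270, 10, 120, 40), 180)
  # zero displacement: R2 = R1, any branch gives 0
  expect_equal(rotated_collimator(30, 17, 30, 17), 0)
})

test_that("zero displacement reproduces every beam exactly", {
  plan <- random_plan(10, seed = 3)
  iso1 <- fiducial_state(c(plan$iso_x[1], plan$iso_y[1], plan$iso_z[1]))
  tr <- rotate_plan(plan, iso1, iso1)
  expect_equal(angle_diff(tr$new_gantry, plan$gantry), rep(0, 10),
               tolerance = 1e-9)
  expect_equal(angle_diff(tr$new_ring, plan$ring), rep(0, 10),
               tolerance = 1e-9)
  expect_equal(angle_diff(tr$new_collimator, 0), rep(0, 10),
               tolerance = 1e-9)
  # isocenters come back exactly (up to strict floating cancellation)
  expect_equal(tr$new_iso_x, plan$iso_x, tolerance = 1e-12)
  expect_equal(tr$new_iso_y, plan$iso_y, tolerance = 1e-12)
  expect_equal(tr$new_iso_z, plan$iso_z, tolerance = 1e-12)
})

test_that("the seven-beam worked example is reproduced within tolerance", {
  chk <- table2_check(tol_angle = 1.0, tol_iso = 0.3)
  expect_true(chk$pass)
  # the calibrated frame does much better than the contract tolerance
  expect_lt(chk$max_angle_resid, 0.5)
  expect_lt(chk$max_iso_resid, 0.15)
  # each beam gets its own isocenter
  tr <- chk$transformed
  isos <- paste(round(tr$new_iso_x, 4), round(tr$new_iso_y, 4),
                round(tr$new_iso_z, 4))
  expect_equal(length(unique(isos)), 7L)
})

test_that("axis-convention calibration is frozen at its fitted optimum", {
  cal <- calibrate_axis_convention()
  expect_equal(c(cal$delta_x[1], cal$delta_y[1], cal$delta_z[1]),
               unname(table2_displacement()))
  # the winner is decisively better than the runner-up
  expect_lt(cal$rss[1], cal$rss[2] / 2)
})

test_that("closed-form transform agrees with the geometric construction", {
  m <- machine_model()
  withr::with_seed(11, {
    plans <- random_plan(50, seed = 11)
    for (i in seq_len(nrow(plans))) {
      beam <- plans[i, ]
      d <- stats::runif(3, -1, 1)
      d <- d / sqrt(sum(d^2)) * stats::runif(1, 0.05, 2)
      iso <- fiducial_state(c(beam$iso_x, beam$iso_y, beam$iso_z))
      fid2 <- fiducial_state(c(beam$iso_x, beam$iso_y, beam$iso_z) + d)
      tr <- rotate_beam(beam, iso, fid2, m)
      or <- geometric_oracle(beam, d, m)
      expect_lt(angle_diff(tr$new_gantry, or$gantry), 1)
      expect_lt(angle_diff(tr$new_ring, or$ring), 1)
      expect_lt(max(abs(c(tr$new_iso_x, tr$new_iso_y, tr$new_iso_z) -
                          or$isocenter)), 0.3)
      # the oracle's axis passes through the displaced target
      expect_lt(or$axis_dist, 1e-9)
      # pivot-distance conservation for the transformed beam
      newb <- beam_plan("n", tr$new_iso_x, tr$new_iso_y, tr$new_iso_z,
                        tr$new_gantry, tr$new_ring)
      pv <- as.numeric(pivot_point(newb, m))
      old_pv <- as.numeric(pivot_point(beam, m))
      expect_equal(sqrt(sum((pv - c(tr$new_iso_x, tr$new_iso_y,
                                    tr$new_iso_z))^2)), 96,
                   tolerance = 1e-6)
      # the transformed beam pivots about the same point
      expect_lt(max(abs(pv - old_pv)), 1e-6)
    }
  })
})

test_that("displacement then its negation round-trips the plan", {
  plan <- table2_plan()
  d <- c(0.8, -0.6, 1.0)
  iso <- fiducial_state(c(plan$iso_x[1], plan$iso_y[1], plan$iso_z[1]))
  fid2 <- fiducial_state(c(plan$iso_x[1], plan$iso_y[1], plan$iso_z[1]) + d)
  fwd <- rotate_plan(plan, iso, fid2)
  plan2 <- tracked_as_plan(fwd)
  back <- rotate_plan(plan2, fid2, iso)
  # the recovered angles may land in the canonical hemisphere chart
  # (gantry in [0, 180] with the ring absorbing the flip), so compare the
  # physical beam directions: 1 deg of axis error ~ 0.0175 on unit vectors
  u_back <- beam_direction(back$new_gantry, back$new_ring)
  u_orig <- beam_direction(plan$gantry, plan$ring)
  expect_lt(max(abs(u_back - u_orig)), 0.02)
})

test_that("translation baseline is an exact group action", {
  plan <- table2_plan()
  d1 <- c(0.46, 0.99, -1.09); d2 <- c(-1, 0.5, 2)
  p12 <- translate_plan(translate_plan(plan, d1), d2)
  p_sum <- translate_plan(plan, d1 + d2)
  expect_equal(p12$iso_x, p_sum$iso_x, tolerance = 1e-12)
  expect_equal(p12$iso_y, p_sum$iso_y, tolerance = 1e-12)
  expect_equal(p12$iso_z, p_sum$iso_z, tolerance = 1e-12)
  expect_identical(p12$gantry, plan$gantry)
  back <- translate_plan(translate_plan(plan, d1), -d1)
  expect_equal(back$iso_x, plan$iso_x)
  # all beams shift by the same amount
  expect_equal(unique(round(translate_plan(plan, d1)$iso_x - plan$iso_x, 12)),
               d1[1])
})

test_that("gimbal range limits produce warnings, not errors", {
  m <- machine_model()
  plan <- beam_plan("a", 0, 0, 0, gantry = 90, ring = 0)
  iso <- fiducial_state(c(0, 0, 0))
  # 1 cm in-plane: fine
  ok <- rotate_plan(plan, iso, fiducial_state(c(0, 1, 0)), m)
  expect_length(ok$warnings[[1]], 0)
  # 5 cm in-plane: beyond the 4.2 cm reach
  bad <- rotate_plan(plan, iso, fiducial_state(c(0, 5, 0)), m)
  expect_true(any(grepl("4.2", bad$warnings[[1]], fixed = TRUE)))
  expect_identical(check_gimbal_limits(bad, m), bad$warnings)
  # the angular and in-plane limits are consistent: 4.2 cm ~ 2.5 deg
  expect_equal(atan2(4.2, 96) * 180 / pi, 2.505, tolerance = 1e-3)
  expect_true(any(grepl("deg", bad$warnings[[1]])))
})
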