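test_that("warping with a zero field is an exact pass-through", {
  set.seed(5)
  d <- dose_grid(array(stats::runif(8 * 7 * 6, 0, 500), c(8, 7, 6)),
                 origin = c(-1, 0, 2), spacing = c(0.5, 0.4, 0.3))
  dvf <- make_rigid_dvf(c(0, 0, 0), d)
  w <- warp_dose(d, dvf)
  expect_equal(w$values, d$values, tolerance = 1e-12)
  expect_equal(attr(w, "oob_fraction"), 0)
})

test_that("a rigid field undoes a rigid translation away from borders", {
  set.seed(6)
  base <- array(stats::runif(20^3, 0, 100), c(20, 20, 20))
  ref <- dose_grid(base, spacing = c(0.5, 0.5, 0.5))
  # phase dose is the reference shifted by -1 cm in x (2 voxels)
  shifted <- dose_grid(base[c(3:20, 20, 20), , ], spacing = c(0.5, 0.5, 0.5))
  w <- suppressWarnings(warp_dose(shifted, make_rigid_dvf(c(1, 0, 0), ref)))
  expect_lt(max(abs(w$values[1:14, , ] - base[5:18, , ])), 1e-6)
})

test_that("interpolating a constant dose returns the constant", {
  d <- uniform_grid(250, dims = c(10, 10, 10), spacing = c(0.3, 0.3, 0.3))
  u <- array(stats::runif(10^3 * 3, -0.2, 0.2), c(10, 10, 10, 3))
  dvf <- deformation_field(u, spacing = c(0.3, 0.3, 0.3))
  w <- suppressWarnings(warp_dose(d, dvf))
  inb <- w$values[w$values > 0]
  expect_equal(inb, rep(250, length(inb)), tolerance = 1e-12)
})

test_that("warping is linear in the dose", {
  set.seed(7)
  dims <- c(9, 9, 9)
  d1 <- dose_grid(array(stats::runif(prod(dims), 0, 10), dims))
  d2 <- dose_grid(array(stats::runif(prod(dims), 0, 10), dims))
  u <- array(stats::runif(prod(dims) * 3, -0.4, 0.4), c(dims, 3))
  dvf <- deformation_field(u)
  lhs <- suppressWarnings(
    warp_dose(dose_grid(2 * d1$values + 3 * d2$values), dvf))
  rhs1 <- suppressWarnings(warp_dose(d1, dvf))
  rhs2 <- suppressWarnings(warp_dose(d2, dvf))
  expect_equal(lhs$values, 2 * rhs1$values + 3 * rhs2$values,
               tolerance = 1e-9)
})

test_that("incongruent grids are refused with both layouts named", {
  a <- uniform_grid(1, dims = c(4, 4, 4))
  b <- uniform_grid(1, dims = c(5, 4, 4))
  expect_error(accumulate_dose(list(a, b), c(0.5, 0.5)), "not congruent")
  dvf <- make_rigid_dvf(c(0, 0, 0), a)
  expect_error(warp_dose(b, dvf, reference = b), "not congruent")
})

test_that("weighted accumulation is exact voxelwise arithmetic", {
  s <- accumulate_dose(list(uniform_grid(100), uniform_grid(200)),
                       c(0.7, 0.3))
  expect_equal(unique(as.numeric(s$values)), 130)
  ten <- accumulate_dose(rep(list(uniform_grid(42)), 10), rep(0.1, 10))
  expect_equal(unique(as.numeric(ten$values)), 42)
  # patient-style exhale/inhale weighting
  two <- accumulate_dose(list(uniform_grid(1000), uniform_grid(2000)),
                         c(0.72, 0.28))
  expect_equal(unique(as.numeric(two$values)), 0.72 * 1000 + 0.28 * 2000)
  expect_error(accumulate_dose(list(uniform_grid(1), uniform_grid(2)),
                               c(0.7, 0.4)), "sum to 1")
})

test_that("dose-at-volume matches the descending-sort oracle", {
  # uniform dose: any volume returns the uniform value
  expect_equal(dose_at_volume(uniform_grid(1000, c(10, 10, 10),
                                           spacing = c(0.1, 0.1, 0.1)),
                              full_mask(c(10, 10, 10),
                                        spacing = c(0.1, 0.1, 0.1)), 0.03),
               1000)
  # 100 voxels of 0.001 cc, doses 1..100: top 0.03 cc spans 30 voxels
  d <- dose_grid(array(1:100, c(100, 1, 1)), spacing = c(0.1, 0.1, 0.1))
  m <- full_mask(c(100, 1, 1), spacing = c(0.1, 0.1, 0.1))
  expect_equal(dose_at_volume(d, m, 0.03), 71)
  # vanishing volume tends to the maximum voxel dose
  expect_equal(dose_at_volume(d, m, 1e-9), 100)
  # randomized agreement with the independent brute-force oracle
  withr::with_seed(13, {
    for (i in 1:50) {
      dims <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1))
      sp <- stats::runif(1, 0.05, 0.2)
      vals <- array(stats::rgamma(prod(dims), 2, 0.01), dims)
      keep <- array(stats::runif(prod(dims)) < 0.7, dims)
      keep[1, 1, 1] <- TRUE
      dg <- dose_grid(vals, spacing = rep(sp, 3))
      mk <- roi_mask(keep, spacing = rep(sp, 3))
      v <- stats::runif(1, 0.2, 0.9) * sum(keep) * sp^3
      expect_equal(dose_at_volume(dg, mk, v),
                   oracle_dose_at_volume(vals[keep], sp^3, v),
                   tolerance = 1e-9)
    }
  })
  # error when the mask cannot hold the metric volume
  tiny <- roi_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)),
                   spacing = c(0.1, 0.1, 0.1))
  expect_error(dose_at_volume(uniform_grid(1, c(2, 2, 2),
                                           spacing = c(0.1, 0.1, 0.1)),
                              tiny, 0.03), "smaller than")
})

test_that("the cumulative DVH is monotone and anchored at full volume", {
  set.seed(8)
  d <- dose_grid(array(stats::rgamma(6^3, 2, 0.01), c(6, 6, 6)),
                 spacing = c(0.2, 0.2, 0.2))
  m <- full_mask(c(6, 6, 6), spacing = c(0.2, 0.2, 0.2))
  tab <- dvh(d, m)
  expect_equal(tab$volume_cc[1], sum(m$values) * 0.2^3)
  expect_true(all(diff(tab$volume_cc) <= 0))
  expect_true(all(diff(tab$dose_cGy) > 0))
  # D at larger volumes is monotone nonincreasing
  vols <- c(0.05, 0.2, 0.5, 1)
  ds <- vapply(vols, function(v) dose_at_volume(d, m, v), numeric(1))
  expect_true(all(diff(ds) <= 0))
  expect_lte(max(ds), max(d$values[m$values]))
  expect_s3_class(autoplot(tab), "ggplot")
})

test_that("constraint evaluation flags exceedances with margins", {
  g <- uniform_grid(3000, c(5, 5, 5), spacing = c(0.2, 0.2, 0.2))
  m <- list(duodenum = full_mask(c(5, 5, 5), spacing = c(0.2, 0.2, 0.2),
                                 name = "duodenum"))
  lim <- tibble::tibble(organ = "duodenum", limit_cGy = 3200)
  rep1 <- evaluate_constraints(g, m, lim)
  expect_false(rep1$exceeded)
  expect_equal(rep1$margin_cGy, 200)
  rep2 <- evaluate_constraints(uniform_grid(3300, c(5, 5, 5),
                                            spacing = c(0.2, 0.2, 0.2)),
                               m, lim)
  expect_true(rep2$exceeded)
  expect_equal(nrow(evaluate_constraints(g, m, lim[0, ])), 0L)
  expect_error(evaluate_constraints(g, m,
                                    tibble::tibble(organ = "cord",
                                                   limit_cGy = 2000)),
               "cord")
})

test_that("scenario dispatch honours each method's arity and weights", {
  g <- uniform_grid(100)
  expect_identical(run_method("Original_BH", list(g)), g)
  expect_identical(run_method("Inhale_rot", list(g)), g)
  expect_error(run_method("Sum_2Phases", list(g)), "exactly 2")
  expect_error(run_method("Sum_10Phases", rep(list(g), 3)), "exactly 10")
  # degenerate two-phase weight returns the exhale dose alone
  gex <- uniform_grid(100); gin <- uniform_grid(900)
  s <- run_method("Sum_2Phases", list(gex, gin), weights = c(1, 0))
  expect_equal(s$values, gex$values)
  s10 <- run_method("Sum_10Phases", rep(list(g), 10),
                    dvfs = rep(list(make_rigid_dvf(c(0, 0, 0), g)), 10))
  expect_equal(s10$values, g$values, tolerance = 1e-12)
})

test_that("accumulation is convex: bounded by the per-phase extremes", {
  set.seed(9)
  dims <- c(7, 7, 7)
  doses <- lapply(1:4, function(i)
    dose_grid(array(stats::runif(prod(dims), 0, 100), dims),
              spacing = c(0.15, 0.15, 0.15)))
  w <- c(0.4, 0.3, 0.2, 0.1)
  acc <- accumulate_dose(doses, w)
  lo <- pmin(doses[[1]]$values, doses[[2]]$values, doses[[3]]$values,
             doses[[4]]$values)
  hi <- pmax(doses[[1]]$values, doses[[2]]$values, doses[[3]]$values,
             doses[[4]]$values)
  expect_true(all(acc$values >= lo - 1e-12 & acc$values <= hi + 1e-12))
  m <- full_mask(dims, spacing = c(0.15, 0.15, 0.15))
  d_acc <- dose_at_volume(acc, m, 0.03)
  d_phases <- vapply(doses, function(d) dose_at_volume(d, m, 0.03),
                     numeric(1))
  expect_lte(d_acc, max(d_phases))
})
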