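#' Regular 3-D dose grid
#'
#' A voxelized dose distribution on a regular axis-aligned grid. `origin` is
#' the coordinate of the first voxel *center*; voxel `i` (1-based) is centred
#' at `origin + (i - 1) * spacing` along each axis.
#'
#' @param values 3-D numeric array, dose in cGy, non-negative and finite.
#' @param origin Length-3 numeric, cm.
#' @param spacing Length-3 numeric, cm per voxel, all positive.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(origin) == 3L, length(spacing) == 3L,
            all(is.finite(origin)), all(spacing > 0))
  if (!all(is.finite(values)) || any(values < 0))
    stop("dose values must be finite and >= 0", call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing (%g, %g, %g) cm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) cm; dose range [%g, %g] cGy\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  oob <- attr(x, "oob_fraction")
  if (!is.null(oob)) cat(sprintf("  out-of-bounds fraction: %.4f\n", oob))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A voxel belongs to the ROI if its center is inside the structure (no
#' partial-volume weighting); the ROI volume is therefore
#' `sum(mask) * prod(spacing)`.
#'
#' @param values 3-D logical (or 0/1) array on the reference grid layout.
#' @param origin,spacing Grid layout, as in [dose_grid()].
#' @param name Structure name.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                     name = "ROI") {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  values <- array(as.logical(values), dim = dim(values))
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), name = name),
            class = "roi_mask")
}

#' Per-voxel deformation vector field
#'
#' Maps a reference-frame point `x` to its corresponding point `x + u(x)` in
#' the phase image (pull-back convention, `reference_to_phase`): warping needs
#' one resampling and no field inversion.
#'
#' @param u 4-D numeric array `dims x 3`, displacement in cm.
#' @param origin,spacing Grid layout of the reference frame.
#' @return An object of class `deformation_field` with attribute
#'   `direction = "reference_to_phase"`.
#' @export
deformation_field <- function(u, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  stopifnot(is.array(u), length(dim(u)) == 4L, dim(u)[4] == 3L,
            all(is.finite(u)))
  structure(list(u = u, origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 direction = "reference_to_phase"),
            class = "deformation_field")
}

grid_dims <- function(g) dim(if (inherits(g, "deformation_field")) g$u else g$values)[1:3]

congruent_grids <- function(a, b, tol = 1e-6) {
  all(grid_dims(a) == grid_dims(b)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

describe_layout <- function(g) {
  d <- grid_dims(g)
  sprintf("[%s] voxels, origin (%s) cm, spacing (%s) cm",
          paste(d, collapse = " x "),
          paste(signif(g$origin, 6), collapse = ", "),
          paste(signif(g$spacing, 6), collapse = ", "))
}

require_congruent <- function(a, b, what_a, what_b, tol = 1e-6) {
  if (!congruent_grids(a, b, tol))
    stop(sprintf("%s %s is not congruent with %s %s; explicit resampling required",
                 what_a, describe_layout(a), what_b, describe_layout(b)),
         call. = FALSE)
}

# vectorised trilinear sampling of a 3-D array at world coordinates (N x 3);
# points beyond the voxel-center extent return `fill` and are flagged
trilinear_sample <- function(grid, coords, fill = 0) {
  d <- dim(grid$values)
  ci <- sweep(sweep(coords, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  eps <- 1e-9 * matrix(d, nrow(ci), 3, byrow = TRUE)
  oob <- ci[, 1] < 1 - eps[, 1] | ci[, 1] > d[1] + eps[, 1] |
    ci[, 2] < 1 - eps[, 2] | ci[, 2] > d[2] + eps[, 2] |
    ci[, 3] < 1 - eps[, 3] | ci[, 3] > d[3] + eps[, 3]
  dmat <- matrix(d, nrow(ci), 3, byrow = TRUE)
  i0 <- pmin(pmax(floor(ci), 1), pmax(dmat - 1, 1))
  fr <- pmin(pmax(ci - i0, 0), 1)
  v <- grid$values
  gather <- function(ox, oy, oz)
    v[cbind(pmin(i0[, 1] + ox, d[1]), pmin(i0[, 2] + oy, d[2]),
            pmin(i0[, 3] + oz, d[3]))]
  w000 <- (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3])
  w100 <- fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3])
  w010 <- (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3])
  w110 <- fr[, 1] * fr[, 2] * (1 - fr[, 3])
  w001 <- (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3]
  w101 <- fr[, 1] * (1 - fr[, 2]) * fr[, 3]
  w011 <- (1 - fr[, 1]) * fr[, 2] * fr[, 3]
  w111 <- fr[, 1] * fr[, 2] * fr[, 3]
  out <- w000 * gather(0, 0, 0) + w100 * gather(1, 0, 0) +
    w010 * gather(0, 1, 0) + w110 * gather(1, 1, 0) +
    w001 * gather(0, 0, 1) + w101 * gather(1, 0, 1) +
    w011 * gather(0, 1, 1) + w111 * gather(1, 1, 1)
  out[oob] <- fill
  list(values = out, oob = oob)
}

voxel_centers <- function(g) {
  d <- grid_dims(g)
  xs <- g$origin[1] + (seq_len(d[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(d[2]) - 1) * g$spacing[2]
  zs <- g$origin[3] + (seq_len(d[3]) - 1) * g$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Warp a per-phase dose grid onto the reference anatomy
#'
#' For every reference voxel center `x`, the warped dose is the trilinear
#' sample of the phase dose at `x + u(x)`. Samples falling outside the phase
#' grid score 0 cGy; their fraction is recorded in the `oob_fraction`
#' attribute of the result and a warning is raised when it exceeds
#' `oob_warn` (silent zeros could fake organ sparing).
#'
#' @param phase_dose [dose_grid()] computed on the phase anatomy.
#' @param dvf [deformation_field()] on the reference layout
#'   (`reference_to_phase` convention).
#' @param reference Optional [dose_grid()] or layout the dvf must be congruent
#'   with; defaults to the dvf's own layout.
#' @param oob_warn Warning threshold on the out-of-bounds fraction.
#' @return A [dose_grid()] on the reference layout with attribute
#'   `oob_fraction`.
#' @export
warp_dose <- function(phase_dose, dvf, reference = NULL, oob_warn = 0.01) {
  stopifnot(inherits(phase_dose, "dose_grid"),
            inherits(dvf, "deformation_field"))
  if (!is.null(reference))
    require_congruent(dvf, reference, "deformation field", "reference grid")
  d <- grid_dims(dvf)
  centers <- voxel_centers(dvf)
  u <- matrix(dvf$u, ncol = 3L)
  smp <- trilinear_sample(phase_dose, centers + u, fill = 0)
  vals <- array(pmax(smp$values, 0), dim = d)
  oob <- mean(smp$oob)
  out <- dose_grid(vals, origin = dvf$origin, spacing = dvf$spacing)
  attr(out, "oob_fraction") <- oob
  if (oob > oob_warn)
    warning(sprintf("%.1f%% of reference voxels sampled outside the phase dose grid (scored 0 cGy)",
                    100 * oob), call. = FALSE)
  out
}

#' Weighted voxelwise accumulation of dose grids
#'
#' @param doses List of congruent [dose_grid()] objects (already on the
#'   reference anatomy).
#' @param weights Numeric weights summing to 1 (within 1e-9).
#' @return A [dose_grid()]: `sum_i w_i * D_i`.
#' @examples
#' g <- function(v) dose_grid(array(v, c(2, 2, 2)))
#' accumulate_dose(list(g(100), g(200)), c(0.7, 0.3))
#' @export
accumulate_dose <- function(doses, weights) {
  stopifnot(is.list(doses), length(doses) >= 1L,
            length(weights) == length(doses))
  if (abs(sum(weights) - 1) > 1e-9)
    stop(sprintf("weights must sum to 1 (got %.12g)", sum(weights)),
         call. = FALSE)
  ref <- doses[[1]]
  for (i in seq_along(doses)) {
    stopifnot(inherits(doses[[i]], "dose_grid"))
    require_congruent(doses[[i]], ref, sprintf("dose grid %d", i),
                      "dose grid 1")
  }
  acc <- weights[1] * doses[[1]]$values
  for (i in seq_along(doses)[-1]) acc <- acc + weights[i] * doses[[i]]$values
  dose_grid(pmax(acc, 0), origin = ref$origin, spacing = ref$spacing)
}

#' Near-maximum dose to a fixed volume (DVH metric)
#'
#' `dose_at_volume(dose, mask, v)` is the largest dose `D` such that at least
#' `v` cm^3 of the structure receives `>= D` (the `D0.03cc` "maximum dose"
#' metric by default). Voxel doses inside the mask are sorted descending and
#' the cutoff is located with partial-voxel linear interpolation, so voxels
#' tied at the cutoff contribute pro-rata; as `volume_cc -> 0` the metric
#' tends to the maximum voxel dose.
#'
#' @param dose A [dose_grid()].
#' @param mask An [roi_mask()] congruent with `dose`.
#' @param volume_cc Metric volume in cm^3.
#' @return Dose in cGy.
#' @export
dose_at_volume <- function(dose, mask, volume_cc = 0.03) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "roi_mask"),
            volume_cc >= 0)
  require_congruent(mask, dose, sprintf("mask '%s'", mask$name), "dose grid")
  vox <- prod(mask$spacing)
  d <- sort(dose$values[mask$values], decreasing = TRUE)
  n <- length(d)
  total <- n * vox
  if (n == 0L) stop(sprintf("mask '%s' is empty", mask$name), call. = FALSE)
  if (total < volume_cc)
    stop(sprintf("mask '%s' volume %.4g cc is smaller than the metric volume %.4g cc",
                 mask$name, total, volume_cc), call. = FALSE)
  if (volume_cc <= vox) return(d[1])
  stats::approx(x = seq_len(n) * vox, y = d, xout = volume_cc,
                rule = 2)$y
}

#' Cumulative dose-volume histogram
#'
#' @inheritParams dose_at_volume
#' @param breaks Number of dose levels (spanning 0 to the mask maximum).
#' @return Tibble with `dose_cGy`, `volume_cc`, `volume_pct`: the structure
#'   volume receiving at least each dose level. Starts at the full mask
#'   volume at 0 cGy and is monotone nonincreasing.
#' @export
dvh <- function(dose, mask, breaks = 256) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "roi_mask"))
  require_congruent(mask, dose, sprintf("mask '%s'", mask$name), "dose grid")
  vox <- prod(mask$spacing)
  d <- dose$values[mask$values]
  lev <- seq(0, max(d), length.out = breaks)
  vol <- vapply(lev, function(x) sum(d >= x) * vox, numeric(1))
  out <- tibble::tibble(organ = mask$name, dose_cGy = lev, volume_cc = vol,
                        volume_pct = 100 * vol / (length(d) * vox))
  class(out) <- c("dvh_table", class(out))
  out
}

#' @rdname dvh
#' @param object A `dvh_table`.
#' @param ... Unused.
#' @method autoplot dvh_table
#' @export
autoplot.dvh_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_cGy,
                                       y = .data$volume_pct,
                                       colour = .data$organ)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "dose (cGy)", y = "volume (%)",
                  title = "cumulative DVH") +
    ggplot2::theme_minimal()
}

#' Evaluate organ-at-risk dose constraints
#'
#' @param dose Accumulated [dose_grid()] on the reference anatomy.
#' @param masks Named list of [roi_mask()] objects; names must cover every
#'   organ in `constraints`.
#' @param constraints Data frame with columns `organ` and `limit_cGy`.
#' @param volume_cc Metric volume for the near-maximum dose (default
#'   D0.03cc).
#' @return Tibble with one row per constraint: `organ`, `limit_cGy`,
#'   `dose_cGy`, `margin_cGy` (limit minus dose), `exceeded`.
#' @export
evaluate_constraints <- function(dose, masks, constraints,
                                 volume_cc = 0.03) {
  stopifnot(is.data.frame(constraints))
  if (nrow(constraints) == 0L)
    return(tibble::tibble(organ = character(), limit_cGy = numeric(),
                          dose_cGy = numeric(), margin_cGy = numeric(),
                          exceeded = logical()))
  stopifnot(all(c("organ", "limit_cGy") %in% names(constraints)),
            all(constraints$limit_cGy > 0))
  nm <- if (is.null(names(masks)))
    vapply(masks, function(m) m$name, character(1)) else names(masks)
  missing <- setdiff(constraints$organ, nm)
  if (length(missing) > 0L)
    stop("no mask supplied for organ(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  names(masks) <- nm
  purrr::map_dfr(seq_len(nrow(constraints)), function(i) {
    organ <- constraints$organ[i]
    dmax <- dose_at_volume(dose, masks[[organ]], volume_cc)
    tibble::tibble(organ = organ, limit_cGy = constraints$limit_cGy[i],
                   dose_cGy = dmax,
                   margin_cGy = constraints$limit_cGy[i] - dmax,
                   exceeded = dmax > constraints$limit_cGy[i])
  })
}

#' Dispatch one of the standard dose re-calculation scenarios
#'
#' The five scenarios compared in the workflow: `Original_BH` (the plan as
#' optimized on the breath-hold exhale CT), `Inhale_trans` / `Inhale_rot`
#' (single re-calculation on the inhale phase via the translation / rotation
#' method), `Sum_2Phases` (inhale + exhale doses warped to the reference and
#' summed with breathing-trace weights) and `Sum_10Phases` (all ten phase
#' doses warped and summed with equal weights 0.1, which inherently models
#' the phase weighting).
#'
#' @param method One of `"Original_BH"`, `"Inhale_trans"`, `"Inhale_rot"`,
#'   `"Sum_2Phases"`, `"Sum_10Phases"`.
#' @param doses List of [dose_grid()] per phase (length 1, 2 or 10 according
#'   to the method).
#' @param dvfs List of [deformation_field()] aligned with `doses`; `NULL`
#'   entries (or `NULL` overall) mean identity.
#' @param weights For `Sum_2Phases`: numeric `c(w_ex, w_in)` aligned with
#'   `doses`, or a [phase_weights()] object with `doses` ordered
#'   (exhale, inhale).
#' @return The accumulated [dose_grid()].
#' @export
run_method <- function(method = c("Original_BH", "Inhale_trans", "Inhale_rot",
                                  "Sum_2Phases", "Sum_10Phases"),
                       doses, dvfs = NULL, weights = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(doses))
  n_req <- switch(method, Original_BH = 1L, Inhale_trans = 1L,
                  Inhale_rot = 1L, Sum_2Phases = 2L, Sum_10Phases = 10L)
  if (length(doses) != n_req)
    stop(sprintf("%s needs exactly %d dose grid(s), got %d",
                 method, n_req, length(doses)), call. = FALSE)
  if (n_req == 1L) return(doses[[1]])
  if (method == "Sum_10Phases") {
    weights <- rep(0.1, 10)
  } else {
    if (inherits(weights, "phase_weights"))
      weights <- c(weights$w_ex, weights$w_in)
    if (is.null(weights) || length(weights) != 2L)
      stop("Sum_2Phases needs weights c(w_ex, w_in) or a phase_weights object",
           call. = FALSE)
  }
  warped <- purrr::map2(doses, seq_along(doses), function(d, i) {
    f <- if (is.null(dvfs)) NULL else dvfs[[i]]
    if (is.null(f)) d else warp_dose(d, f)
  })
  accumulate_dose(warped, weights)
}
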