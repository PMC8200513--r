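# shared fixtures and small independent oracles

# a random beam plan with gantry/ring spread over the sphere
random_plan <- function(n, seed = 1) {
  withr::with_seed(seed, {
    beam_plan(label = sprintf("b%d", seq_len(n)),
              iso_x = stats::runif(n, -5, 5),
              iso_y = stats::runif(n, -90, -80),
              iso_z = stats::runif(n, 20, 35),
              gantry = stats::runif(n, 5, 355),
              ring = stats::runif(n, 0, 360))
  })
}

# brute-force dose-at-volume oracle: walk voxels in descending dose,
# accumulating volume; linear interpolation between successive voxel doses
oracle_dose_at_volume <- function(dose_vals, voxel_cc, volume_cc) {
  d <- sort(dose_vals, decreasing = TRUE)
  if (volume_cc <= voxel_cc) return(d[1])
  cum <- 0
  for (i in seq_along(d)) {
    cum <- cum + voxel_cc
    if (cum >= volume_cc) {
      if (cum == volume_cc || i == 1) {
        lo <- d[i]
        hi <- if (i == 1) d[1] else d[i - 1]
        frac <- (cum - volume_cc) / voxel_cc
        return(lo + frac * (hi - lo))
      }
      frac <- (cum - volume_cc) / voxel_cc
      return(d[i] + frac * (d[i - 1] - d[i]))
    }
  }
  stop("volume larger than mask")
}

# quadrature oracle for the cos^(2p) waveform: fraction of one period spent
# above the halfway amplitude, by dense sampling
oracle_frac_above_half <- function(p, n = 1e6) {
  t <- seq(0, 1, length.out = n)
  a <- cos(pi * t)^(2 * p)
  mean(a > 0.5)
}

uniform_grid <- function(value, dims = c(4, 4, 4), spacing = c(1, 1, 1)) {
  dose_grid(array(value, dims), spacing = spacing)
}

full_mask <- function(dims = c(4, 4, 4), spacing = c(1, 1, 1), name = "m") {
  roi_mask(array(TRUE, dims), spacing = spacing, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
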