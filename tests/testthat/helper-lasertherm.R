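# Shared fixtures: a reference thermal profile, noiseless and noisy scenes,
# and small independent oracles used across tests.

ref_profile <- function() thermal_profile(slope = 4, half_distance = 11, ambient = 20)

noiseless_scene <- function(...) {
  scene_spec(shot_noise = FALSE, read_noise_sd = 0, ...)
}

# Independent polyline-length oracle: explicit loop over consecutive pairs.
brute_polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  total <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d <- pts[i + 1, ] - pts[i, ]
    total <- total + sqrt(d[1]^2 + d[2]^2 + d[3]^2)
  }
  total
}

# Random proper rotation matrix (QR of a Gaussian matrix, det corrected).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Binary erosion of a logical mask by k 4-neighbourhood steps; used to step
# away from mask edges where block downsampling mixes cell and background.
erode_mask <- function(m, k) {
  for (i in seq_len(k)) {
    n <- nrow(m); c <- ncol(m)
    m <- m &
      rbind(FALSE, m[-n, , drop = FALSE]) & rbind(m[-1, , drop = FALSE], FALSE) &
      cbind(FALSE, m[, -c, drop = FALSE]) & cbind(m[, -1, drop = FALSE], FALSE)
  }
  m
}
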