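# Shared fixtures and independent oracles, built in code.

# a dihedral series with uniform 0.1-ns spacing from bare angles
series_from_angles <- function(angles, dt = 0.1, ...) {
  dihedral_series((seq_along(angles) - 1) * dt, angles, ...)
}

# density from per-bin counts: angles repeated at bin centres, so heights
# are exactly counts / (n * binwidth)
density_from_counts <- function(counts, binwidth = 45, window_start = 0) {
  centers <- window_start + (seq_along(counts) - 0.5) * binwidth
  angles <- rep(centers, counts)
  make_density(stack_angles(series_from_angles(angles),
                            window_start = window_start), binwidth)
}

# analytic von Mises density (per degree) at angles theta (degrees)
vm_density_deg <- function(theta, mu, sigma) {
  kappa <- 1 / (sigma * pi / 180)^2
  t_r <- theta * pi / 180
  m_r <- mu * pi / 180
  exp(kappa * cos(t_r - m_r)) / (2 * pi * besselI(kappa, 0, expon.scaled = FALSE)) *
    pi / 180
}

# brute-force violation counter: enumerate maximal non-native runs by hand
brute_force_violations <- function(labels, times, native, min_dwell) {
  dt <- if (length(times) > 1) median(diff(times)) else 0
  count <- 0L
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] != native) {
      j <- i
      while (j < n && labels[j + 1L] != native) j <- j + 1L
      if (times[j] - times[i] + dt >= min_dwell - 1e-9) count <- count + 1L
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

# map state labels onto representative angles so classify_states() recovers
# them exactly (centres of the default windows, plus a far-away "other")
angles_for_labels <- function(labels) {
  c(in_site = 190, out_site = 285, other = 60)[labels]
}
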