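# Shared fixtures, all generated in code.
#
# Two instrument scales are used: the full default emulation grid (11 q,
# 0.4 ueV steps) for statistically demanding studies, and a reduced "study"
# grid (6 q, 1.0 ueV steps, single-Gaussian resolution) where a fit per
# second matters more than ultimate precision.

study_instrument <- function() {
  default_instrument(q_values = seq(0.4, 1.9, by = 0.3), omega_step = 1.0,
                     n_components = 1L)
}

fine_instrument <- function() {
  default_instrument(n_components = 1L)
}

study_solvent <- function(inst = study_instrument()) {
  solvent_table(inst$q_values)
}

two_pop_truth <- function(solvent, ...) {
  ground_truth("two_population", D_dil = 5, D_dense = 1, r = 0.5,
               solvent = solvent, ...)
}

single_truth <- function(solvent, D = 2.5, ...) {
  ground_truth("single", D = D, solvent = solvent, ...)
}

quick_control <- function(n_starts = 1L, maxiter = 150L) {
  fit_control(n_starts = n_starts, maxiter = maxiter, seed = 42L)
}

# full multi-start control for tests that must reach the global optimum
robust_control <- function() fit_control()

# independent fwhm measurement: dense-grid scan plus linear interpolation of
# the half-maximum crossings (no bisection, unlike composite_fwhm())
scan_fwhm <- function(components, span = 25, step = 1e-3) {
  w <- seq(-span, span, by = step)
  f <- numeric(length(w))
  for (j in seq_len(nrow(components))) {
    f <- f + components$amplitude[j] *
      dnorm(w, components$center[j], components$sigma[j])
  }
  half <- max(f) / 2
  above <- which(f >= half)
  i1 <- min(above); i2 <- max(above)
  interp_cross <- function(ia, ib) {
    w[ia] + (half - f[ia]) * (w[ib] - w[ia]) / (f[ib] - f[ia])
  }
  interp_cross(i2, i2 + 1L) - interp_cross(i1, i1 - 1L)
}

# trapezoid integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
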