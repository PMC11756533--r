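# Hard-sphere short-time hydrodynamics: translational and rotational
# self-diffusion reduced by crowding, combined into the apparent diffusion
# coefficient seen by an incoherent quasi-elastic experiment.

#' Hard-sphere short-time diffusion model
#'
#' Polynomial crowding corrections `f_t(phi)` and `f_r(phi)` for the
#' translational and rotational short-time self-diffusion of colloidal hard
#' spheres, together with the sphere radius and dilute-limit coefficients
#' used to compose the apparent diffusion.  The default polynomials are the
#' standard short-time virial forms
#' `f_t = 1 - 1.8315 phi (1 + 0.12007 phi - 0.65074 phi^2)` and
#' `f_r = 1 - 0.631 phi - 0.726 phi^2`; both are configuration values, not
#' hard-coded truths.
#'
#' @param ft_coeffs,fr_coeffs Polynomial coefficients (constant term first).
#' @param radius Sphere radius (A); 30 A is the scale of a serum albumin.
#' @param l_max Truncation order of the rotational series (>= 10).
#' @param D_t0 Dilute-limit translational diffusion coefficient (A^2/ns).
#' @param D_r0 Dilute-limit rotational diffusion coefficient (1/ns); the
#'   default is the Stokes-consistent `3 D_t0 / (4 radius^2)`.
#' @return Object of class `qens_hard_sphere`.
#' @export
hard_sphere_model <- function(ft_coeffs = c(1, -1.8315, -1.8315 * 0.12007,
                                            1.8315 * 0.65074),
                              fr_coeffs = c(1, -0.631, -0.726),
                              radius = 30, l_max = 60L,
                              D_t0 = 6, D_r0 = NULL) {
  check_positive(radius, "radius")
  check_positive(D_t0, "D_t0")
  if (l_max < 10) abort_invalid("`l_max` must be >= 10")
  if (is.null(D_r0)) D_r0 <- 3 * D_t0 / (4 * radius^2)
  check_nonnegative(D_r0, "D_r0")
  m <- structure(list(ft_coeffs = ft_coeffs, fr_coeffs = fr_coeffs,
                      radius = radius, l_max = as.integer(l_max),
                      D_t0 = D_t0, D_r0 = D_r0),
                 class = "qens_hard_sphere")
  # dilute limit and monotonicity sanity checks
  if (abs(.polyval(ft_coeffs, 0) - 1) > 1e-12 ||
      abs(.polyval(fr_coeffs, 0) - 1) > 1e-12) {
    abort_invalid("f_t(0) and f_r(0) must equal 1")
  }
  grid <- seq(0, 0.5, by = 0.01)
  if (any(diff(.polyval(ft_coeffs, grid)) >= 0) ||
      any(diff(.polyval(fr_coeffs, grid)) >= 0)) {
    abort_invalid("f_t and f_r must be strictly decreasing on [0, 0.5]")
  }
  m
}

#' @export
print.qens_hard_sphere <- function(x, ...) {
  cat(sprintf("<qens_hard_sphere> R = %g A, D_t0 = %g A^2/ns, D_r0 = %g 1/ns, l_max = %d\n",
              x$radius, x$D_t0, x$D_r0, x$l_max))
  invisible(x)
}

.polyval <- function(coeffs, x) {
  out <- 0
  for (c_k in rev(coeffs)) out <- out * x + c_k
  out
}

.check_phi_range <- function(phi) {
  if (!is.numeric(phi) || any(!is.finite(phi)) || any(phi < 0) ||
      any(phi >= 0.55)) {
    abort_invalid("`phi` must lie in [0, 0.55)")
  }
}

#' Translational crowding factor f_t(phi)
#'
#' @param phi Volume fraction in `[0, 0.55)`.
#' @param model A [hard_sphere_model()].
#' @return Fraction `D_t(phi)/D_t(0)`.
#' @export
ft <- function(phi, model = hard_sphere_model()) {
  .check_phi_range(phi)
  .polyval(model$ft_coeffs, phi)
}

#' Rotational crowding factor f_r(phi)
#'
#' @inheritParams ft
#' @return Fraction `D_r(phi)/D_r(0)`.
#' @export
fr <- function(phi, model = hard_sphere_model()) {
  .check_phi_range(phi)
  .polyval(model$fr_coeffs, phi)
}

# rotational form-factor weights B_l(qR) = (2l+1) j_l(qR)^2, truncated when
# their cumulative sum reaches 1 - 1e-6 (spherical-Bessel completeness)
bessel_weights <- function(qR, l_max) {
  if (qR < 1e-4) return(c(1))  # monomer form-factor limit: B_0 -> 1
  l <- 0:l_max
  jl <- sqrt(pi / (2 * qR)) * vapply(l, function(ll)
    besselJ(qR, ll + 0.5), numeric(1))
  B <- (2 * l + 1) * jl^2
  cs <- cumsum(B)
  ltrunc <- which(cs >= 1 - 1e-6)
  if (length(ltrunc) == 0) {
    rlang::abort(sprintf("B_l series not converged at l_max = %d (qR = %g)",
                         l_max, qR),
                 class = "qens_numeric_error")
  }
  B[seq_len(ltrunc[1])]
}

#' Apparent short-time diffusion from translation and rotation
#'
#' For a sphere of radius `R` with translational diffusion `D_t` and
#' rotational diffusion `D_r`, the incoherent scattering function is the
#' series `S(q, omega) = sum_l B_l(qR) L(omega; hbar (D_t q^2 + l (l+1)
#' D_r))` with `B_l = (2l+1) j_l(qR)^2`.  The apparent diffusion coefficient
#' is obtained numerically: the half-width at half-maximum of the composite
#' line found by bisection, divided by `hbar q^2`.
#'
#' @param D_t Translational diffusion coefficient (A^2/ns).
#' @param D_r Rotational diffusion coefficient (1/ns).
#' @param q Momentum transfer (1/A).
#' @param R Sphere radius (A).
#' @param l_max Series truncation bound.
#' @return Apparent diffusion coefficient (A^2/ns).
#' @export
apparent_diffusion <- function(D_t, D_r, q = 1.0, R = 30, l_max = 60L) {
  check_nonnegative(D_t, "D_t")
  check_nonnegative(D_r, "D_r")
  check_positive(q, "q")
  check_nonnegative(R, "R")
  B <- bessel_weights(q * R, l_max)
  l <- seq_along(B) - 1
  gam <- .hbar() * (D_t * q^2 + l * (l + 1) * D_r)
  if (all(gam == 0)) return(0)
  if (gam[1] == 0 && length(gam) > 1) gam[1] <- 1e-12 * max(gam)
  s_of <- function(w) sum(B * (gam / pi) / (gam^2 + w^2))
  s0 <- s_of(0)
  upper <- max(gam) * 4
  while (s_of(upper) > s0 / 2 && upper < max(gam) * 1e6) upper <- upper * 4
  root <- tryCatch(
    stats::uniroot(function(w) s_of(w) - s0 / 2, c(0, upper),
                   tol = 1e-12 * max(gam)),
    error = function(e) rlang::abort(
      sprintf("half-width bisection failed: %s", conditionMessage(e)),
      class = "qens_numeric_error"))
  root$root / (.hbar() * q^2)
}

#' Predicted dense/dilute apparent-diffusion ratio
#'
#' Composes the crowding factors and the apparent-diffusion reduction into
#' the hard-sphere monomer prediction `f(phi_dense) / f(phi_dilute)`, where
#' `f(phi) = D_app(D_t0 f_t(phi), D_r0 f_r(phi)) / D_app(D_t0, D_r0)`.  Any
#' dilute-limit temperature dependence cancels in this ratio.  A
#' non-convergent half-width search at either volume fraction yields a
#' flagged missing value rather than an error, mirroring the practice of
#' plotting the prediction only where the root finding converges.
#'
#' @param phi_dense,phi_dilute Volume fractions in `[0, 0.55)`.
#' @param model A [hard_sphere_model()].
#' @param q_ref Reference momentum transfer (1/A) at which the apparent
#'   diffusion is evaluated.
#' @return Ratio in `(0, 1]` when `phi_dense > phi_dilute`; `NA` with
#'   attribute `converged = FALSE` on numerical failure.
#' @export
predicted_ratio <- function(phi_dense, phi_dilute,
                            model = hard_sphere_model(), q_ref = 1.0) {
  .check_phi_range(c(phi_dense, phi_dilute))
  f_of <- function(phi) {
    apparent_diffusion(model$D_t0 * ft(phi, model),
                       model$D_r0 * fr(phi, model),
                       q = q_ref, R = model$radius, l_max = model$l_max) /
      apparent_diffusion(model$D_t0, model$D_r0,
                         q = q_ref, R = model$radius, l_max = model$l_max)
  }
  tryCatch(f_of(phi_dense) / f_of(phi_dilute),
           qens_numeric_error = function(e) {
             structure(NA_real_, converged = FALSE)
           })
}
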