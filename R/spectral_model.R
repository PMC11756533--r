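#' Unit-area Lorentzian density
#'
#' The building block of all quasi-elastic line shapes: a diffusing particle
#' contributes `(1/pi) * gamma / (gamma^2 + omega^2)` to the dynamic structure
#' factor, where `gamma` is the half width at half maximum (HWHM).
#'
#' @param omega Energy transfer values (ueV).
#' @param gamma HWHM (ueV), strictly positive.
#' @return Density values (1/ueV) integrating to one over the real line.
#' @examples
#' lorentzian(0, 1)      # peak value 1/pi
#' lorentzian(1, 1)      # half maximum at omega = gamma
#' @export
lorentzian <- function(omega, gamma) {
  check_positive(gamma, "gamma")
  (gamma / pi) / (gamma^2 + omega^2)
}

#' Center-of-mass Fickian line width
#'
#' Fickian diffusion of the protein (or protein cluster) center of mass gives
#' a Lorentzian of HWHM `gamma = hbar * D * q^2`.
#'
#' @param D Diffusion coefficient (A^2/ns), non-negative.
#' @param q Momentum transfer (1/A), positive.
#' @return HWHM in ueV.
#' @examples
#' com_width(5, 1)  # 0.6582119 * 5
#' @export
com_width <- function(D, q) {
  check_nonnegative(D, "D")
  check_positive(q, "q")
  .hbar() * D * q^2
}

#' Jump-diffusion internal line width
#'
#' Internal (backbone / side-chain) motions follow a jump-diffusion law: the
#' width grows Fickian at small `q` and saturates at `hbar / tau` at large
#' `q`, with `tau` the residence time:
#' `lambda = hbar * D * q^2 / (1 + D * q^2 * tau)`.
#'
#' @param D_i Internal diffusion coefficient (A^2/ns), non-negative.
#' @param tau_i Residence time (ns), non-negative.
#' @param q Momentum transfer (1/A).
#' @return HWHM in ueV.
#' @export
internal_width <- function(D_i, tau_i, q) {
  check_nonnegative(D_i, "D_i")
  check_nonnegative(tau_i, "tau_i")
  check_positive(q, "q")
  .hbar() * D_i * q^2 / (1 + D_i * q^2 * tau_i)
}

#' Internal-dynamics spectral component convolved with one COM width
#'
#' Two coupled internal Lorentzians riding on a center-of-mass line of HWHM
#' `com_gamma`; the analytic convolution of Lorentzians adds their widths, so
#' the mixture is `alpha * L(gamma + lambda1) + (1 - alpha) * L(gamma +
#' lambda2)`, with unit area.
#'
#' @param q Momentum transfer (1/A).
#' @param omega Energy transfer grid (ueV).
#' @param com_gamma COM HWHM (ueV), non-negative.
#' @param internal List with fields `D1`, `D2` (A^2/ns), `tau1`, `tau2` (ns)
#'   and `alpha` (backbone weight in `[0, 1]`; scalar or function of q).
#' @return Unit-area density on `omega` (1/ueV).
#' @export
internal_component <- function(q, omega, com_gamma, internal) {
  check_nonnegative(com_gamma, "com_gamma")
  alpha <- value_at_q(internal$alpha, q, "alpha")
  check_fraction(alpha, "alpha")
  l1 <- internal_width(internal$D1, internal$tau1, q)
  l2 <- internal_width(internal$D2, internal$tau2, q)
  alpha * lorentzian(omega, com_gamma + l1) +
    (1 - alpha) * lorentzian(omega, com_gamma + l2)
}

#' Faddeeva function w(z)
#'
#' Scaled complex complementary error function
#' `w(z) = exp(-z^2) * erfc(-i z)` for `Im(z) >= 0`, the analytic core of the
#' Voigt profile.  Evaluated by a 40-term Weideman rational approximation,
#' switching to a continued fraction far from the origin.
#'
#' @param z Complex vector with non-negative imaginary parts.
#' @return Complex vector `w(z)`.
#' @export
faddeeva_w <- function(z) {
  .faddeeva_w_cpp(as.complex(z))
}

#' Voigt profile
#'
#' Unit-area convolution of a Lorentzian (HWHM `gamma`) with a Gaussian
#' (s.d. `sigma`): `V(x) = Re[w((x + i gamma) / (sigma sqrt(2)))] /
#' (sigma sqrt(2 pi))`.  This is the line shape of a resolution-broadened
#' diffusive line.
#'
#' @param x Abscissa values (ueV).
#' @param sigma Gaussian standard deviation (ueV), positive.
#' @param gamma Lorentzian HWHM (ueV), non-negative.  `gamma = 0` returns the
#'   pure Gaussian.
#' @return Density values (1/ueV).
#' @export
voigt_profile <- function(x, sigma, gamma) {
  check_positive(sigma, "sigma")
  check_nonnegative(gamma, "gamma")
  .voigt_cpp(as.numeric(x), sigma, gamma)
}

# Gaussian density
.gauss <- function(x, mu, sigma) {
  exp(-0.5 * ((x - mu) / sigma)^2) / (sigma * sqrt(2 * pi))
}

#' Resolution model: per-q sums of non-centered Gaussians
#'
#' The instrument resolution function `R(q, omega)` is represented
#' analytically as an area-normalized sum of Gaussian components, generally
#' off-center, one component list per momentum transfer.
#'
#' @param q_values Momentum transfers (1/A), strictly increasing, positive.
#' @param components List (one element per q) of data frames with columns
#'   `amplitude` (non-negative, summing to 1 per q), `center` (ueV) and
#'   `sigma` (ueV, positive).
#' @return Object of class `qens_resolution`.
#' @export
resolution_model <- function(q_values, components) {
  check_positive(q_values, "q_values")
  if (is.unsorted(q_values, strictly = TRUE)) {
    abort_invalid("`q_values` must be strictly increasing")
  }
  if (length(components) != length(q_values)) {
    abort_invalid("`components` must have one element per q")
  }
  components <- lapply(components, function(cmp) {
    cmp <- as.data.frame(cmp)
    stopifnot(all(c("amplitude", "center", "sigma") %in% names(cmp)))
    check_nonnegative(cmp$amplitude, "amplitude")
    check_positive(cmp$sigma, "sigma")
    tot <- sum(cmp$amplitude)
    if (abs(tot - 1) > 1e-6) {
      abort_invalid("per-q resolution amplitudes must sum to 1")
    }
    cmp$amplitude <- cmp$amplitude / tot
    cmp
  })
  structure(list(q = as.numeric(q_values), components = components),
            class = "qens_resolution")
}

#' @export
print.qens_resolution <- function(x, ...) {
  nc <- vapply(x$components, nrow, integer(1))
  cat(sprintf("<qens_resolution> %d q values in [%.3g, %.3g] 1/A, %s Gaussian component(s) per q\n",
              length(x$q), min(x$q), max(x$q),
              if (length(unique(nc)) == 1L) nc[1] else paste(range(nc), collapse = "-")))
  invisible(x)
}

#' Resolution components at a given q
#'
#' @param resolution A [resolution_model()] object.
#' @param q Momentum transfer (1/A); must match one of the tabulated values.
#' @return Data frame of Gaussian components.
#' @export
resolution_at <- function(resolution, q) {
  i <- which(abs(resolution$q - q) < 1e-8)
  if (length(i) != 1L) {
    abort_invalid(sprintf("resolution model does not cover q = %g", q),
                  class = "qens_config_error")
  }
  resolution$components[[i]]
}

#' Resolution profile R(q, omega)
#'
#' @inheritParams resolution_at
#' @param omega Energy transfer grid (ueV).
#' @return Area-normalized density (1/ueV).
#' @export
resolution_profile <- function(resolution, q, omega) {
  cmp <- resolution_at(resolution, q)
  out <- numeric(length(omega))
  for (j in seq_len(nrow(cmp))) {
    out <- out + cmp$amplitude[j] * .gauss(omega, cmp$center[j], cmp$sigma[j])
  }
  out
}

# A model component list is a list of elements
#   list(kind = "lorentzian", weight = w, gamma = g)   quasi-elastic line
#   list(kind = "elastic",    weight = w)               delta at omega = 0
# Weights carry the full amplitude; every line shape underneath is unit-area.

#' Analytic convolution of model components with the resolution function
#'
#' Each Lorentzian component becomes a sum of shifted Voigt profiles (one per
#' Gaussian resolution component); each elastic delta becomes the resolution
#' profile itself.  Linearity and area are preserved exactly because the
#' resolution is area-normalized.
#'
#' @param model_components List of components, see Details.
#' @param resolution A [resolution_model()] object.
#' @param q Momentum transfer (1/A) at which the resolution is taken.
#' @param omega Energy transfer grid (ueV).
#' @details A component is a list with fields `kind` (`"lorentzian"` or
#'   `"elastic"`), `weight` (amplitude) and, for Lorentzians, `gamma` (HWHM,
#'   ueV).  A Lorentzian with `gamma = 0` is treated as elastic.
#' @return Intensity on the `omega` grid.
#' @export
convolve_resolution <- function(model_components, resolution, q, omega) {
  cmp <- resolution_at(resolution, q)
  out <- numeric(length(omega))
  for (mc in model_components) {
    w <- mc$weight
    if (w == 0) next
    if (identical(mc$kind, "elastic") || mc$gamma <= 0) {
      for (j in seq_len(nrow(cmp))) {
        out <- out + w * cmp$amplitude[j] *
          .gauss(omega, cmp$center[j], cmp$sigma[j])
      }
    } else {
      for (j in seq_len(nrow(cmp))) {
        out <- out + w * cmp$amplitude[j] *
          .voigt_cpp(omega - cmp$center[j], cmp$sigma[j], mc$gamma)
      }
    }
  }
  out
}

#' Brute-force numerical convolution (quadrature fallback)
#'
#' Trapezoid-quadrature convolution of the unconvolved model with the
#' resolution profile on a padded fine grid.  Retained as the independent
#' cross-check of the analytic Voigt evaluation in [convolve_resolution()];
#' orders of magnitude slower, never used in fits.
#'
#' @inheritParams convolve_resolution
#' @param pad Padding (ueV) added on both sides of the `omega` range for the
#'   quadrature variable, so that truncated Lorentzian tails are negligible.
#' @param step Quadrature step (ueV).
#' @return Intensity on the `omega` grid.
#' @export
convolve_numeric <- function(model_components, resolution, q, omega,
                             pad = 400, step = 0.02) {
  cmp <- resolution_at(resolution, q)
  u <- seq(min(omega) - pad, max(omega) + pad, by = step)
  # unconvolved quasi-elastic part sampled on u
  f <- numeric(length(u))
  out <- numeric(length(omega))
  for (mc in model_components) {
    if (mc$weight == 0) next
    if (identical(mc$kind, "elastic") || mc$gamma <= 0) {
      # delta convolves to the resolution profile exactly; no quadrature needed
      for (j in seq_len(nrow(cmp))) {
        out <- out + mc$weight * cmp$amplitude[j] *
          .gauss(omega, cmp$center[j], cmp$sigma[j])
      }
    } else {
      f <- f + mc$weight * lorentzian(u, mc$gamma)
    }
  }
  if (any(f != 0)) {
    # out(omega_i) += int f(u) R(omega_i - u) du, trapezoid in u, chunked to
    # bound memory
    wts <- rep(step, length(u)); wts[c(1, length(u))] <- step / 2
    fw <- f * wts
    chunk <- 64L
    for (i0 in seq(1L, length(omega), by = chunk)) {
      ii <- i0:min(i0 + chunk - 1L, length(omega))
      dm <- outer(omega[ii], u, "-")
      rv <- numeric(length(dm))
      dim(rv) <- dim(dm)
      for (j in seq_len(nrow(cmp))) {
        rv <- rv + cmp$amplitude[j] * .gauss(dm, cmp$center[j], cmp$sigma[j])
      }
      out[ii] <- out[ii] + as.numeric(rv %*% fw)
    }
  }
  out
}

# Build the component list of the measured model at one q.
# params is ground-truth shaped (see ground_truth()); solvent_row is a list
# with beta and gamma for this q; per-q fields of params may be scalars or
# functions of q.
model_components_at_q <- function(q, params, solvent_row) {
  beta <- value_at_q(params$beta, q, "beta")
  A0 <- value_at_q(params$A0, q, "A0")
  eres <- if (is.null(params$elastic_residual)) 0 else
    value_at_q(params$elastic_residual, q, "elastic_residual")
  check_nonnegative(beta, "beta")
  check_nonnegative(A0, "A0")
  alpha <- value_at_q(params$internal$alpha, q, "alpha")
  check_fraction(alpha, "alpha")
  l1 <- internal_width(params$internal$D1, params$internal$tau1, q)
  l2 <- internal_width(params$internal$D2, params$internal$tau2, q)

  if (identical(params$model_tag, "two_population")) {
    pops <- list(list(w = params$r, gamma = com_width(params$D_dil, q)),
                 list(w = 1 - params$r, gamma = com_width(params$D_dense, q)))
  } else {
    pops <- list(list(w = 1, gamma = com_width(params$D, q)))
  }
  out <- list()
  for (p in pops) {
    out <- c(out, list(
      list(kind = "lorentzian", weight = beta * p$w, gamma = p$gamma),
      list(kind = "lorentzian", weight = beta * p$w * alpha, gamma = p$gamma + l1),
      list(kind = "lorentzian", weight = beta * p$w * (1 - alpha), gamma = p$gamma + l2)
    ))
  }
  out <- c(out, list(list(kind = "elastic", weight = A0 + eres)))
  if (!is.null(solvent_row) && solvent_row$beta > 0) {
    out <- c(out, list(list(kind = "lorentzian", weight = solvent_row$beta,
                            gamma = solvent_row$gamma)))
  }
  out
}

#' Evaluate the full measured QENS model at one q
#'
#' Assembles the measured dynamic structure factor: protein center-of-mass
#' Lorentzian(s) (one population, or dilute/dense populations connected by the
#' intensity ratio `r`), the internal-dynamics mixture convolved with each COM
#' width at the same ratio, an elastic line, and the fixed solvent Lorentzian
#' - everything convolved analytically with the resolution function.
#'
#' With `model_tag = "single"` the two-population form reduces exactly to the
#' single-population model; when the ratio r equals 1 the two-population evaluation is
#' identical to a single population at `D_dil`.
#'
#' @param q Momentum transfer (1/A).
#' @param omega Energy transfer grid (ueV).
#' @param params Ground-truth-shaped parameter list, see [ground_truth()].
#' @param resolution A [resolution_model()] object covering `q`.
#' @param solvent Solvent table: data frame with columns `q`, `beta`, `gamma`
#'   (fixed from a pure-solvent measurement), or `NULL` for no solvent term.
#' @return Intensity on the `omega` grid.
#' @export
eval_model <- function(q, omega, params, resolution, solvent = NULL) {
  params <- validate_ground_truth(params)
  srow <- solvent_row_at(solvent, q)
  mc <- model_components_at_q(q, params, srow)
  convolve_resolution(mc, resolution, q, omega)
}

# look up solvent (beta, gamma) at q; NULL table -> no solvent term
solvent_row_at <- function(solvent, q) {
  if (is.null(solvent)) return(list(beta = 0, gamma = 1))
  i <- which(abs(solvent$q - q) < 1e-8)
  if (length(i) != 1L) {
    abort_invalid(sprintf("solvent table does not cover q = %g", q),
                  class = "qens_config_error")
  }
  list(beta = solvent$beta[i], gamma = solvent$gamma[i])
}
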