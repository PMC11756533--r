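# Quantitative interpretation layer: unit conversions of the sample
# preparation and spectrometer bookkeeping, normalized diffusion ratios, the
# dense/dilute factorization test, the salt master curve, Flory-Stockmayer
# cluster statistics and the lever rule.

#' Dry protein volume fraction from concentration
#'
#' `phi = c_p * nu_p / (1000 + c_p * nu_p)` for `c_p` in mg/mL and the
#' protein specific volume `nu_p` in mL/g (so `c_p * nu_p` is in mL of
#' protein per liter of solvent).
#'
#' @param c_p Protein concentration (mg/mL), non-negative.
#' @param nu_p Protein specific volume (mL/g), positive; 0.735 mL/g for
#'   serum albumin.
#' @return Volume fraction in `[0, 1)`.
#' @examples
#' phi_from_cp(240, 0.735)  # 0.15
#' @export
phi_from_cp <- function(c_p, nu_p = 0.735) {
  check_nonnegative(c_p, "c_p")
  check_positive(nu_p, "nu_p")
  c_p * nu_p / (1000 + c_p * nu_p)
}

#' Protein concentration from volume fraction
#'
#' Exact inverse of [phi_from_cp()].
#'
#' @param phi Volume fraction in `[0, 1)`.
#' @param nu_p Protein specific volume (mL/g).
#' @return Concentration (mg/mL).
#' @export
cp_from_phi <- function(phi, nu_p = 0.735) {
  check_fraction(phi, "phi")
  check_positive(nu_p, "nu_p")
  1000 * phi / (nu_p * (1 - phi))
}

#' Number of salt ions per protein
#'
#' `c_s / (1000 c_p / M)`: the molar salt concentration divided by the molar
#' protein concentration, reported to one decimal by convention.
#'
#' @param c_s Salt concentration (mM).
#' @param c_p Protein concentration (mg/mL), positive.
#' @param molar_mass Protein molar mass (g/mol); 66430 g/mol for BSA.
#' @param digits Decimals for the reporting convention; `NULL` for the raw
#'   value.
#' @return Salt ions per protein molecule.
#' @examples
#' salt_per_protein(27, 240)  # 7.5
#' @export
salt_per_protein <- function(c_s, c_p, molar_mass = 66430, digits = 1) {
  check_nonnegative(c_s, "c_s")
  check_positive(c_p, "c_p")
  check_positive(molar_mass, "molar_mass")
  x <- c_s / (1000 * c_p / molar_mass)
  if (is.null(digits)) x else round(x, digits)
}

#' Reduced diffusion coefficient
#'
#' Normalization to the salt-free reference at the same temperature,
#' `D / D(c_s/c_p = 0, T)`.
#'
#' @param D Diffusion coefficient (A^2/ns), non-negative.
#' @param D_ref_salt_free Salt-free reference (A^2/ns), positive.
#' @return Dimensionless reduced diffusion.
#' @export
reduced_D <- function(D, D_ref_salt_free) {
  check_nonnegative(D, "D")
  check_positive(D_ref_salt_free, "D_ref_salt_free")
  D / D_ref_salt_free
}

#' Salt master curve g(c_s/c_p)
#'
#' Monotone-decreasing slowing-down of the short-time self-diffusion with
#' the number of salt ions per protein, parametrized as
#' `g(x) = g_inf + (1 - g_inf) exp(-x / x0)` with `g(0) = 1` and a plateau
#' `g_inf` (0.4 in the percolation limit) at large `x`.
#'
#' @param x Salt ions per protein, non-negative.
#' @param g_inf Plateau level in `(0, 1]`.
#' @param x0 Decay scale (salt ions per protein), positive.
#' @return Values in `(0, 1]`.
#' @export
master_curve <- function(x, g_inf = 0.4, x0 = 3) {
  check_nonnegative(x, "x")
  check_positive(x0, "x0")
  check_fraction(g_inf, "g_inf")
  g_inf + (1 - g_inf) * exp(-x / x0)
}

#' Factorization test of dense/dilute diffusion ratios
#'
#' The central hypothesis under test: at constant temperature the COM
#' diffusion factorizes into a dilute-limit coefficient, a crowding factor
#' `f(phi)` and a salt master curve `g(c_s/c_p)`; if the cluster statistics
#' (`g`) are identical in the coexisting phases, the fitted ratio
#' `D_dense / D_dil` must equal the hard-sphere prediction
#' `f(phi_dense) / f(phi_dilute)`.
#'
#' @param fit_ratio Fitted `D_dense / D_dil` from a two-population fit.
#' @param phi_dense,phi_dilute Volume fractions of the coexisting phases.
#' @param model A [hard_sphere_model()].
#' @param tolerance Relative tolerance for the pass/fail flag.
#' @param q_ref Reference momentum transfer (1/A) for the prediction.
#' @return List of class `qens_factorization` with `fitted`, `predicted`,
#'   `difference`, `rel_difference`, `tolerance`, `pass` and `comparable`
#'   (FALSE when the hard-sphere root finding failed).
#' @export
factorization_test <- function(fit_ratio, phi_dense, phi_dilute,
                               model = hard_sphere_model(),
                               tolerance = 0.05, q_ref = 1.0) {
  if (!is.finite(fit_ratio)) abort_invalid("`fit_ratio` must be finite")
  pred <- predicted_ratio(phi_dense, phi_dilute, model, q_ref)
  comparable <- is.finite(pred)
  diff <- if (comparable) fit_ratio - pred else NA_real_
  rel <- if (comparable) abs(diff) / pred else NA_real_
  structure(list(fitted = fit_ratio, predicted = as.numeric(pred),
                 difference = diff, rel_difference = rel,
                 tolerance = tolerance,
                 pass = comparable && rel <= tolerance,
                 comparable = comparable),
            class = "qens_factorization")
}

#' @export
print.qens_factorization <- function(x, ...) {
  if (!x$comparable) {
    cat("<qens_factorization> incomparable (hard-sphere prediction did not converge)\n")
  } else {
    cat(sprintf("<qens_factorization> fitted %.3f vs predicted %.3f (rel. diff %.1f%%): %s at %.0f%% tolerance\n",
                x$fitted, x$predicted, 100 * x$rel_difference,
                if (x$pass) "consistent" else "violated", 100 * x$tolerance))
  }
  invisible(x)
}

#' Flory-Stockmayer cluster size distribution
#'
#' Classical cluster statistics for particles with `f` bonding sites and
#' bond probability `p`: the number of n-mers per monomer is
#' `rho_n / rho = f ((f-1) n)! / (n! ((f-2) n + 2)!) p^(n-1)
#' (1-p)^((f-2) n + 2)`, with percolation threshold `p_c = 1 / (f - 1)`.
#' Below `p_c` the weight fractions `n rho_n / rho` sum to one (all mass in
#' finite clusters); above `p_c` the deficit is the gel fraction.
#'
#' @param f Functionality (number of bonding sites), integer >= 2.
#' @param p Bond probability in `[0, 1]`.
#' @param n_max Largest cluster size retained; `NULL` chooses adaptively so
#'   that the truncated sol mass below `p_c` is converged to 1e-10.
#' @return Object of class `qens_clusters` with `n`, `rho_n_over_rho`,
#'   number and weight fractions, and `p_c`.
#' @examples
#' flory_stockmayer(3, 0.3)$p_c  # 0.5
#' @export
flory_stockmayer <- function(f, p, n_max = NULL) {
  if (!is.numeric(f) || f < 2 || f != round(f)) {
    abort_invalid("`f` must be an integer >= 2")
  }
  check_fraction(p, "p")
  f <- as.integer(f)
  p_c <- 1 / (f - 1)
  weight_tail_tol <- 1e-10
  nmax <- if (is.null(n_max)) 256L else as.integer(n_max)
  repeat {
    n <- seq_len(nmax)
    if (p == 0) {
      rho <- c(1, numeric(nmax - 1L))
    } else if (p == 1 && f == 2) {
      rho <- numeric(nmax)  # a single infinite chain: no finite clusters
    } else {
      lg <- log(f) + lgamma((f - 1) * n + 1) - lgamma(n + 1) -
        lgamma((f - 2) * n + 2 + 1) + (n - 1) * log(p) +
        ((f - 2) * n + 2) * log1p(-p)
      rho <- exp(lg)
    }
    mass <- sum(n * rho)
    if (!is.null(n_max)) break
    tail_ok <- nmax >= 2 && n[nmax] * rho[nmax] <
      weight_tail_tol * max(mass, 1e-300) / nmax
    if (p > 0.98 * p_c || tail_ok || nmax >= 2^20) break
    nmax <- nmax * 4L
  }
  structure(list(f = f, p = p, p_c = p_c, n = n,
                 rho_n_over_rho = rho,
                 number_fraction = if (sum(rho) > 0) rho / sum(rho) else rho,
                 weight_fraction = n * rho,
                 sol_mass = mass),
            class = "qens_clusters")
}

#' @export
print.qens_clusters <- function(x, ...) {
  cat(sprintf("<qens_clusters> f = %d, p = %.3f (p_c = %.3f), n up to %d, sol mass %.6f\n",
              x$f, x$p, x$p_c, max(x$n), x$sol_mass))
  invisible(x)
}

#' Lever rule
#'
#' Mass conservation over the two coexisting phases:
#' `c_total = (c_dense - c_dilute) V* + c_dilute`, solved for the dense-phase
#' volume fraction `V*`.
#'
#' @param c_total,c_dense,c_dilute Concentrations (any common unit), with
#'   `c_total` between `c_dilute` and `c_dense`.
#' @return `V*` in `[0, 1]`.
#' @examples
#' lever_rule(240, 400, 80)  # 0.5
#' @export
lever_rule <- function(c_total, c_dense, c_dilute) {
  if (c_dense == c_dilute) {
    abort_invalid("`c_dense` and `c_dilute` must differ",
                  class = "qens_invalid_composition")
  }
  lo <- min(c_dense, c_dilute); hi <- max(c_dense, c_dilute)
  if (c_total < lo || c_total > hi) {
    abort_invalid("`c_total` must lie between `c_dilute` and `c_dense`",
                  class = "qens_invalid_composition")
  }
  (c_total - c_dilute) / (c_dense - c_dilute)
}

#' Energy-time conversion
#'
#' Observation time associated with an energy transfer, `tau = h / E`: the
#' +/-100 ueV window of a backscattering spectrometer with 3.5 ueV
#' resolution translates to times between about 41 ps and 1.2 ns.
#'
#' @param E Energy (ueV), positive.
#' @return Time (ns).
#' @examples
#' energy_to_time(100)  # ~0.041 ns
#' @export
energy_to_time <- function(E) {
  check_positive(E, "E")
  .planck_h() / E
}

#' Inverse of [energy_to_time()]
#' @param tau Time (ns), positive.
#' @return Energy (ueV).
#' @export
time_to_energy <- function(tau) {
  check_positive(tau, "tau")
  .planck_h() / tau
}

#' Relative centrifugal force
#'
#' `RCF = 1.118e-5 * r_cm * rpm^2` in multiples of g.
#'
#' @param rpm Rotor speed (revolutions per minute), non-negative.
#' @param rotor_radius_cm Rotor radius (cm), positive.
#' @return Relative centrifugal force in multiples of g.
#' @examples
#' centrifugal_force(3900, 18.9)  # ~3214 g
#' @export
centrifugal_force <- function(rpm, rotor_radius_cm) {
  check_nonnegative(rpm, "rpm")
  check_positive(rotor_radius_cm, "rotor_radius_cm")
  1.118e-5 * rotor_radius_cm * rpm^2
}

#' Turbidity index from UV-vis absorbance
#'
#' Normalizes a temperature- and wavelength-resolved absorbance table to a
#' reference spectrum (salt-free solution at the lowest set temperature) and
#' averages over a wavelength window, yielding one turbidity index per
#' temperature.
#'
#' @param absorbance Data frame with columns `T` (K), `lambda` (nm), `A`.
#' @param reference Data frame with columns `lambda`, `A` covering the
#'   wavelength window.
#' @param lambda_range Averaging window (nm), default 500-700 nm.
#' @return Data frame with columns `T` and `turbidity_index`, ordered by `T`.
#' @export
uvvis_normalize <- function(absorbance, reference,
                            lambda_range = c(500, 700)) {
  keep <- absorbance$lambda > lambda_range[1] &
    absorbance$lambda < lambda_range[2]
  if (!any(keep)) {
    abort_invalid("no wavelengths inside `lambda_range`",
                  class = "qens_invalid_input")
  }
  ab <- absorbance[keep, , drop = FALSE]
  ref <- reference$A[match(ab$lambda, reference$lambda)]
  if (any(is.na(ref))) {
    abort_invalid("reference does not cover the wavelength window",
                  class = "qens_invalid_input")
  }
  ratio <- ab$A / ref
  Ts <- sort(unique(ab$T))
  data.frame(T = Ts,
             turbidity_index = vapply(Ts, function(tt)
               mean(ratio[ab$T == tt]), numeric(1)))
}
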