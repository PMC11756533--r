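# Seeded generators for synthetic backscattering spectra and mock
# phase-separation compositions.  These define the reference conditions under
# which the fitting and analysis layers are exercised: a +/-100 ueV window,
# ~3.5 ueV fwhm resolution and q between 0.4 and 1.9 1/A, i.e. the regime of
# a cold-neutron backscattering spectrometer.

# evaluate code with a local, restorable RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Instrument configuration
#'
#' Energy-transfer grid, momentum transfers and resolution model of the
#' (emulated) backscattering spectrometer.
#'
#' @param omega_grid Strictly increasing energy transfers (ueV).
#' @param q_values Strictly increasing, positive momentum transfers (1/A).
#' @param resolution A [resolution_model()] covering `q_values`.
#' @param omega_window Length-2 window (ueV) containing `omega_grid`.
#' @return Object of class `qens_instrument`.
#' @export
instrument_config <- function(omega_grid, q_values, resolution,
                              omega_window = range(omega_grid)) {
  if (is.unsorted(omega_grid, strictly = TRUE)) {
    abort_invalid("`omega_grid` must be strictly increasing")
  }
  check_positive(q_values, "q_values")
  if (is.unsorted(q_values, strictly = TRUE)) {
    abort_invalid("`q_values` must be strictly increasing")
  }
  if (omega_window[1] > min(omega_grid) || omega_window[2] < max(omega_grid)) {
    abort_invalid("`omega_window` must cover `omega_grid`")
  }
  for (q in q_values) resolution_at(resolution, q)  # must cover all q
  structure(list(omega_grid = as.numeric(omega_grid),
                 q_values = as.numeric(q_values),
                 resolution = resolution,
                 omega_window = as.numeric(omega_window)),
            class = "qens_instrument")
}

#' @export
print.qens_instrument <- function(x, ...) {
  cat(sprintf("<qens_instrument> omega in [%g, %g] ueV (%d channels), %d q values in [%g, %g] 1/A\n",
              min(x$omega_grid), max(x$omega_grid), length(x$omega_grid),
              length(x$q_values), min(x$q_values), max(x$q_values)))
  invisible(x)
}

#' Generate a multi-Gaussian resolution model
#'
#' Draws, per q, `n_components` area-normalized non-centered Gaussian
#' components and rescales centers and widths so that the composite profile
#' has the requested full width at half maximum (measured numerically, so the
#' match is exact up to root-finding tolerance).
#'
#' @param q_values Momentum transfers (1/A).
#' @param fwhm Target composite fwhm (ueV), positive; 3.5 ueV emulates a
#'   Si(111) backscattering spectrometer.
#' @param n_components Number of Gaussian components per q (>= 1).
#' @param seed Integer seed for the component draws (`NULL` for the current
#'   RNG state).
#' @return A [resolution_model()] object.
#' @examples
#' res <- make_resolution(c(0.4, 1.0), fwhm = 3.5, n_components = 3, seed = 1)
#' @export
make_resolution <- function(q_values, fwhm = 3.5, n_components = 1L,
                            seed = NULL) {
  check_positive(fwhm, "fwhm")
  if (n_components < 1) abort_invalid("`n_components` must be >= 1")
  sigma0 <- fwhm / (2 * sqrt(2 * log(2)))
  comps <- with_seed(seed, lapply(q_values, function(q) {
    if (n_components == 1L) {
      return(data.frame(amplitude = 1, center = 0, sigma = sigma0))
    }
    amp <- rexp(n_components)
    amp <- amp / sum(amp)
    cen <- runif(n_components, -0.3, 0.3) * fwhm
    sig <- sigma0 * runif(n_components, 0.6, 1.4)
    cmp <- data.frame(amplitude = amp, center = cen, sigma = sig)
    s <- fwhm / composite_fwhm(cmp)
    cmp$center <- cmp$center * s
    cmp$sigma <- cmp$sigma * s
    cmp
  }))
  resolution_model(q_values, comps)
}

#' Numerically measured fwhm of a multi-Gaussian profile
#'
#' Locates the profile maximum and the two half-maximum crossings by
#' root bisection.
#'
#' @param components Data frame with `amplitude`, `center`, `sigma` columns.
#' @return Full width at half maximum (ueV).
#' @export
composite_fwhm <- function(components) {
  f <- function(w) {
    out <- 0
    for (j in seq_len(nrow(components))) {
      out <- out + components$amplitude[j] *
        .gauss(w, components$center[j], components$sigma[j])
    }
    out
  }
  span <- max(abs(components$center)) + 10 * max(components$sigma)
  opt <- stats::optimize(f, c(-span, span), maximum = TRUE, tol = 1e-10)
  half <- opt$objective / 2
  left <- stats::uniroot(function(w) f(w) - half, c(-span, opt$maximum),
                         tol = 1e-10)$root
  right <- stats::uniroot(function(w) f(w) - half, c(opt$maximum, span),
                          tol = 1e-10)$root
  right - left
}

#' Default emulated instrument
#'
#' Energy window -100..+100 ueV in 0.4 ueV steps, q from 0.4 to 1.9 1/A in
#' 0.15 1/A steps and a 3.5 ueV fwhm resolution.
#'
#' @param q_values,omega_step,fwhm,n_components,seed Overrides of the
#'   defaults.
#' @return A `qens_instrument`.
#' @export
default_instrument <- function(q_values = seq(0.4, 1.9, by = 0.15),
                               omega_step = 0.4, fwhm = 3.5,
                               n_components = 3L, seed = 1L) {
  omega <- seq(-100, 100, by = omega_step)
  res <- make_resolution(q_values, fwhm = fwhm, n_components = n_components,
                         seed = seed)
  instrument_config(omega, q_values, res)
}

#' Ground truth for a synthetic spectrum set
#'
#' Collects every generating parameter of the measured model: the
#' center-of-mass diffusion (one population `D`, or `D_dil`/`D_dense`
#' connected by the intensity ratio `r`), internal jump-diffusion parameters,
#' per-q amplitudes and the fixed solvent term.
#'
#' @param model_tag `"single"` or `"two_population"`.
#' @param D COM diffusion coefficient (A^2/ns), single-population mode.
#' @param D_dil,D_dense Dilute/dense-population COM diffusion coefficients
#'   (A^2/ns), with `D_dense < D_dil`.
#' @param r Intensity ratio of the dilute population, in `[0, 1]`.
#' @param internal List with `D1`, `D2` (A^2/ns), `tau1`, `tau2` (ns),
#'   `alpha` (backbone weight; scalar or function of q).
#' @param A0 Elastic amplitude (EISF plus residual container line); scalar or
#'   function of q.
#' @param beta Protein amplitude scale; scalar or function of q.
#' @param elastic_residual Extra elastic amplitude for residual container
#'   scattering.
#' @param solvent Solvent table (data frame `q`, `beta`, `gamma`) or `NULL`.
#' @return Validated list of class `qens_truth`.
#' @export
ground_truth <- function(model_tag = c("single", "two_population"),
                         D = 2.5, D_dil = 5, D_dense = 1, r = 0.5,
                         internal = list(D1 = 5, tau1 = 0.1,
                                         D2 = 30, tau2 = 0.01, alpha = 0.4),
                         A0 = 0.05, beta = 0.8, elastic_residual = 0.01,
                         solvent = NULL) {
  model_tag <- match.arg(model_tag)
  out <- structure(list(model_tag = model_tag, D = D, D_dil = D_dil,
                        D_dense = D_dense, r = r, internal = internal,
                        A0 = A0, beta = beta,
                        elastic_residual = elastic_residual,
                        solvent = solvent),
                   class = "qens_truth")
  validate_ground_truth(out)
}

#' Validate a ground-truth parameter list
#'
#' @param params Ground-truth-shaped list.
#' @return The validated list, invisibly unchanged.
#' @export
validate_ground_truth <- function(params) {
  if (identical(params$model_tag, "two_population")) {
    check_nonnegative(params$D_dil, "D_dil")
    check_nonnegative(params$D_dense, "D_dense")
    check_fraction(params$r, "r")
    if (params$D_dense >= params$D_dil) {
      abort_invalid("two-population mode requires D_dense < D_dil")
    }
  } else {
    check_nonnegative(params$D, "D")
  }
  check_nonnegative(params$internal$D1, "internal$D1")
  check_nonnegative(params$internal$D2, "internal$D2")
  check_nonnegative(params$internal$tau1, "internal$tau1")
  check_nonnegative(params$internal$tau2, "internal$tau2")
  if (is.numeric(params$internal$alpha)) {
    check_fraction(params$internal$alpha, "internal$alpha")
  }
  if (is.numeric(params$A0)) check_fraction(params$A0, "A0")
  if (is.numeric(params$beta)) check_nonnegative(params$beta, "beta")
  params
}

#' Solvent (D2O) model table
#'
#' Fixed solvent contribution: amplitude scaled by the volume not excluded by
#' protein, `beta0 * (1 - phi)`, and a jump-diffusion width for heavy water.
#'
#' @param q_values Momentum transfers (1/A).
#' @param phi Protein dry volume fraction.
#' @param beta0 Solvent amplitude at `phi = 0`.
#' @param D_solv Solvent diffusion coefficient (A^2/ns).
#' @param tau_solv Solvent residence time (ns).
#' @return Data frame with columns `q`, `beta`, `gamma`.
#' @export
solvent_table <- function(q_values, phi = 0.15, beta0 = 0.2,
                          D_solv = 130, tau_solv = 0.004) {
  check_fraction(phi, "phi")
  data.frame(q = q_values,
             beta = beta0 * (1 - phi),
             gamma = vapply(q_values, function(q)
               internal_width(D_solv, tau_solv, q), numeric(1)))
}

#' Simulate a set of QENS spectra
#'
#' Evaluates the noiseless measured model on the instrument grid and adds
#' Gaussian counting noise with variance proportional to the model (the
#' counting-statistics surrogate), normalized per q so that the peak channel
#' collects `counts_scale` expected counts: `var = model * max(model) /
#' counts_scale`.  Per-point errors are set to the noise standard deviation
#' (the structure of reduced backscattering data, which carry per-point
#' Gaussian errors).
#'
#' @param config A `qens_instrument`.
#' @param truth A [ground_truth()] object (its `solvent` field supplies the
#'   solvent table; if `NULL`, a default [solvent_table()] is used).
#' @param counts_scale Expected counts at unit model intensity; larger means
#'   less noise.  `Inf` gives the noiseless model.
#' @param seed Integer seed recorded in the metadata.
#' @param add_noise Set `FALSE` for the noiseless model with finite errors.
#' @param metadata Named list of sample descriptors (`c_p`, `c_s`, `T`,
#'   `phi`, ...) stored with each spectrum.
#' @return List of class `qens_spectra`; one `qens_spectrum` per q, each with
#'   fields `q`, `omega`, `intensity`, `error`, `metadata`.
#' @export
simulate_spectrum <- function(config, truth, counts_scale = 1e4, seed = 1L,
                              add_noise = TRUE, metadata = list()) {
  if (!is.numeric(counts_scale) || is.na(counts_scale) || counts_scale <= 0) {
    abort_invalid("`counts_scale` must be > 0")
  }
  truth <- validate_ground_truth(truth)
  solvent <- truth$solvent
  if (is.null(solvent)) {
    solvent <- solvent_table(config$q_values,
                             phi = metadata$phi %||% 0.15)
  }
  md <- modifyList(list(seed = seed, counts_scale = counts_scale,
                        model_tag = truth$model_tag), metadata)
  spectra <- with_seed(seed, lapply(config$q_values, function(q) {
    model <- eval_model(q, config$omega_grid, truth, config$resolution,
                        solvent)
    sdv <- if (is.finite(counts_scale)) {
      sqrt(model * max(model) / counts_scale)
    } else numeric(length(model))
    intensity <- model
    if (add_noise && any(sdv > 0)) {
      intensity <- intensity + rnorm(length(model), sd = sdv)
    }
    structure(list(q = q, omega = config$omega_grid, intensity = intensity,
                   error = pmax(sdv, 1e-12), metadata = md),
              class = "qens_spectrum")
  }))
  structure(spectra, class = "qens_spectra",
            solvent = solvent, truth = truth)
}

#' @export
print.qens_spectra <- function(x, ...) {
  qs <- vapply(x, function(s) s$q, numeric(1))
  cat(sprintf("<qens_spectra> %d spectra, q in [%g, %g] 1/A, %d channels each\n",
              length(x), min(qs), max(qs), length(x[[1]]$omega)))
  invisible(x)
}

#' Mock liquid-liquid coexistence diagram
#'
#' Ellipse-shaped binodal in the (salt, protein) concentration plane with tie
#' lines at constant salt concentration, plus the salt master curve `g`.  The
#' real binodal of a protein/multivalent-salt system is only known
#' schematically, so the generator uses this self-consistent geometry.
#'
#' @param center_cs,width_cs Center and half-width of the binodal in salt
#'   concentration (mM).
#' @param center_cp,width_cp Center and half-width in protein concentration
#'   (mg/mL).
#' @param g_inf Master-curve plateau in the percolation limit.
#' @param g_x0 Master-curve decay scale in salt ions per protein.
#' @return Object of class `qens_phase_diagram` with a `g` function and
#'   binodal helpers.
#' @export
phase_diagram_mock <- function(center_cs = 27.5, width_cs = 7.5,
                               center_cp = 240, width_cp = 200,
                               g_inf = 0.4, g_x0 = 3) {
  structure(list(center_cs = center_cs, width_cs = width_cs,
                 center_cp = center_cp, width_cp = width_cp,
                 g_inf = g_inf, g_x0 = g_x0),
            class = "qens_phase_diagram")
}

# protein-concentration branches of the binodal at salt concentration c_s;
# NULL when c_s lies outside the salt extent of the coexistence region
binodal_branches <- function(diagram, c_s) {
  u <- (c_s - diagram$center_cs) / diagram$width_cs
  if (abs(u) >= 1) return(NULL)
  h <- diagram$width_cp * sqrt(1 - u^2)
  c(dilute = diagram$center_cp - h, dense = diagram$center_cp + h)
}

#' Phase composition
#'
#' @param c_p Protein concentration (mg/mL).
#' @param c_s Salt concentration (mM).
#' @param T Temperature (K).
#' @param nu_p Protein specific volume (mL/g), used to derive the volume
#'   fraction.
#' @param phase_label One of `"total"`, `"dense"`, `"dilute"`.
#' @return Object of class `qens_composition` with derived `phi`.
#' @export
phase_composition <- function(c_p, c_s, T = 298, nu_p = 0.735,
                              phase_label = c("total", "dense", "dilute")) {
  check_nonnegative(c_p, "c_p")
  check_nonnegative(c_s, "c_s")
  phase_label <- match.arg(phase_label)
  structure(list(c_p = c_p, c_s = c_s, T = T, nu_p = nu_p,
                 phi = phi_from_cp(c_p, nu_p), phase_label = phase_label),
            class = "qens_composition")
}

#' @export
print.qens_composition <- function(x, ...) {
  cat(sprintf("<qens_composition> %s: c_p = %g mg/mL, c_s = %g mM, phi = %.3f, T = %g K\n",
              x$phase_label, x$c_p, x$c_s, x$phi, x$T))
  invisible(x)
}

#' Split a total composition into coexisting dense and dilute phases
#'
#' For a total composition inside the binodal, places the dense and dilute
#' phases on the coexistence boundary (at the same salt concentration, the
#' mock tie-line rule) and returns the dense-phase volume fraction `V*` such
#' that the lever rule `c_total = (c_dense - c_dilute) V* + c_dilute` holds
#' exactly for both protein and salt.
#'
#' @param total A [phase_composition()].
#' @param diagram A [phase_diagram_mock()].
#' @return List with `dense`, `dilute` (compositions), `V_dense_star`, and a
#'   logical `split`; a composition outside the binodal is returned unchanged
#'   with `V_dense_star = 0` and `split = FALSE`.
#' @export
split_composition <- function(total, diagram) {
  br <- binodal_branches(diagram, total$c_s)
  inside <- !is.null(br) && total$c_p >= br["dilute"] && total$c_p <= br["dense"]
  if (!inside) {
    return(list(dense = total, dilute = total, V_dense_star = 0,
                split = FALSE))
  }
  dense <- phase_composition(unname(br["dense"]), total$c_s, total$T,
                             total$nu_p, "dense")
  dilute <- phase_composition(unname(br["dilute"]), total$c_s, total$T,
                              total$nu_p, "dilute")
  vstar <- lever_rule(total$c_p, dense$c_p, dilute$c_p)
  list(dense = dense, dilute = dilute, V_dense_star = vstar, split = TRUE)
}

#' Synthetic temperature-dependent turbidity table
#'
#' Emulates UV-vis absorbance spectra with a sigmoidal turbidity onset in
#' temperature, for testing the turbidity normalization: the absorbance at
#' each wavelength is the reference spectrum scaled by
#' `1 + amp / (1 + exp(-(T - T_mid)/width))` plus Gaussian noise.
#'
#' @param T_values Temperatures (K).
#' @param lambda_values Wavelengths (nm).
#' @param T_mid Transition midpoint (K).
#' @param width Transition width (K).
#' @param amp Turbidity amplitude relative to the reference.
#' @param noise Relative noise level.
#' @param seed Integer seed.
#' @return List with `absorbance` (data frame `T`, `lambda`, `A`) and
#'   `reference` (data frame `lambda`, `A`).
#' @export
simulate_turbidity <- function(T_values = seq(278, 318, by = 2.5),
                               lambda_values = seq(450, 750, by = 10),
                               T_mid = 300, width = 1.5, amp = 4,
                               noise = 0.01, seed = 1L) {
  ref <- data.frame(lambda = lambda_values,
                    A = 0.08 + 0.04 * exp(-(lambda_values - 450) / 150))
  ab <- with_seed(seed, {
    grid <- expand.grid(T = T_values, lambda = lambda_values)
    base <- ref$A[match(grid$lambda, ref$lambda)]
    scale <- 1 + amp / (1 + exp(-(grid$T - T_mid) / width))
    grid$A <- base * scale * (1 + rnorm(nrow(grid), sd = noise))
    grid
  })
  list(absorbance = ab, reference = ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
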