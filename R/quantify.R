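#' Decompose an amplitude spectrum onto candidate difference spectra
#'
#' Assigns a decay-associated amplitude spectrum to photochemical species by
#' least squares: each candidate radical-pair difference spectrum (optionally
#' together with a hydrated-electron term) is fitted to the per-wavelength
#' amplitudes, singleton candidates are ranked by residual RMSD, and joint
#' coefficients for the full candidate set are reported. Coefficients are on
#' the concentration-times-path scale (M cm) when amplitudes are absorbance
#' units and candidates are difference molar absorptivities.
#'
#' Amplitude spectra are signed, so coefficients are unconstrained by
#' default; `nonneg = TRUE` restricts them to be non-negative (sensible when
#' all candidates are oriented as formed-minus-depleted of the same
#' photoreaction).
#'
#' @param amplitudes data frame with columns `wavelength_nm` and `amplitude`
#'   (e.g. from [amplitude_spectrum()]), at least two wavelengths.
#' @param candidates named list of `difference_spectrum` (or
#'   `spectrum_table`) objects, evaluable at all amplitude wavelengths.
#' @param include_eaq logical: add a hydrated-electron component to every
#'   candidate model and the joint fit.
#' @param registry species registry supplying the `e_aq` spectrum when
#'   `include_eaq`.
#' @param nonneg logical: constrain coefficients to be `>= 0`
#'   (nonnegative least squares).
#' @return Object of class `amp_decomposition`: `ranking` (data frame of
#'   singleton candidates sorted by RMSD, with coefficients),
#'   `best_candidate`, joint `coefficients`, `joint_rmsd`,
#'   `conditioning_warning` flag.
#' @export
decompose_amplitudes <- function(amplitudes, candidates, include_eaq = FALSE,
                                 registry = spectra_registry(), nonneg = FALSE) {
  amplitudes <- as.data.frame(amplitudes)
  stopifnot(all(c("wavelength_nm", "amplitude") %in% names(amplitudes)))
  if (nrow(amplitudes) < 2L) stop("need at least two wavelengths")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be a named list")
  wl <- amplitudes$wavelength_nm
  y <- amplitudes$amplitude
  X <- vapply(candidates, function(cs) eval_spectrum(cs, wl), numeric(length(wl)))
  X <- matrix(X, nrow = length(wl),
              dimnames = list(NULL, names(candidates)))
  eaq_col <- if (include_eaq) eval_spectrum(registry$e_aq, wl) else NULL

  fit_one <- function(Xi) {
    if (nonneg) {
      nn <- pracma::lsqnonneg(Xi, y)
      cf <- nn$x
      res <- y - Xi %*% cf
    } else {
      f <- stats::lm.fit(Xi, y)
      cf <- f$coefficients; cf[is.na(cf)] <- 0
      res <- f$residuals
    }
    list(coef = as.numeric(cf), rmsd = sqrt(mean(res^2)))
  }

  rank_rows <- lapply(names(candidates), function(nm) {
    Xi <- cbind(X[, nm], eaq_col)
    f <- fit_one(Xi)
    data.frame(candidate = nm, coefficient = f$coef[1],
               eaq_coefficient = if (include_eaq) f$coef[2] else NA_real_,
               rmsd = f$rmsd, stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, rank_rows)
  ranking <- ranking[order(ranking$rmsd), ]
  rownames(ranking) <- NULL

  Xj <- cbind(X, if (include_eaq) matrix(eaq_col, dimnames = list(NULL, "e_aq")))
  cond_warn <- FALSE
  if (ncol(Xj) > 1L && (ncol(Xj) > nrow(Xj) || kappa(Xj) > 1e8)) {
    cond_warn <- TRUE
    warning("candidate spectra are nearly collinear at these wavelengths")
  }
  joint <- fit_one(Xj)
  structure(list(ranking = ranking, best_candidate = ranking$candidate[1],
                 coefficients = stats::setNames(joint$coef, colnames(Xj)),
                 joint_rmsd = joint$rmsd, include_eaq = include_eaq,
                 nonneg = nonneg, conditioning_warning = cond_warn,
                 wavelengths = wl, amplitudes = y, design = Xj),
            class = "amp_decomposition")
}

#' @export
print.amp_decomposition <- function(x, ...) {
  cat("<amp_decomposition> singleton candidate ranking (best first):\n")
  print(x$ranking, row.names = FALSE)
  cat(sprintf("\nbest candidate: %s\njoint coefficients:\n", x$best_candidate))
  print(x$coefficients)
  cat(sprintf("joint RMSD %.4g%s\n", x$joint_rmsd,
              if (x$conditioning_warning) "  [ill-conditioned design]" else ""))
  invisible(x)
}

#' Inputs for relative actinometric quantum-yield determination
#'
#' Collects all quantities of the relative actinometry calculation against a
#' reference photoreaction of known quantum yield (canonically the
#' metal-to-ligand charge-transfer triplet formation of tris(bipyridine)
#' ruthenium(II), with unit yield): signal amplitudes at the probe
#' wavelength, difference molar absorptivities of the photoproducts, ground
#' state molar absorptivities at the excitation wavelength, concentrations,
#' the excitation path length and the reference yield.
#'
#' @param dA_sample,dA_ref signal amplitudes (absorbance units) of sample and
#'   reference at the probe wavelength.
#' @param delta_eps_sample,delta_eps_ref photoproduct-minus-ground difference
#'   molar absorptivities at the probe wavelength (M^-1 cm^-1, nonzero).
#' @param eps_exc_sample,eps_exc_ref ground-state molar absorptivities at the
#'   excitation wavelength (M^-1 cm^-1, > 0).
#' @param c_sample,c_ref concentrations (M, > 0).
#' @param d excitation path length (cm, > 0); default 0.2.
#' @param phi_ref reference quantum yield; default 1.
#' @return Object of class `actinometry_input`.
#' @export
actinometry_input <- function(dA_sample, dA_ref, delta_eps_sample,
                              delta_eps_ref = -11000,
                              eps_exc_sample, eps_exc_ref = 10128,
                              c_sample, c_ref = 27.4e-6, d = 0.2,
                              phi_ref = 1) {
  vals <- list(dA_sample = dA_sample, dA_ref = dA_ref,
               delta_eps_sample = delta_eps_sample,
               delta_eps_ref = delta_eps_ref,
               eps_exc_sample = eps_exc_sample, eps_exc_ref = eps_exc_ref,
               c_sample = c_sample, c_ref = c_ref, d = d, phi_ref = phi_ref)
  if (any(!vapply(vals, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), TRUE)))
    stop("all actinometry inputs must be finite scalars")
  if (delta_eps_sample == 0 || delta_eps_ref == 0)
    stop("difference molar absorptivities must be nonzero")
  if (any(c(eps_exc_sample, eps_exc_ref, c_sample, c_ref, d, phi_ref) <= 0))
    stop("molar absorptivities, concentrations, path and phi_ref must be positive")
  structure(vals, class = "actinometry_input")
}

#' Fraction of excitation light absorbed by a sample
#'
#' `1 - 10^(-eps * c * d)`, the decadic absorbed fraction of a beam crossing
#' path `d` through concentration `c` of a species with molar absorptivity
#' `eps` at the excitation wavelength.
#'
#' @param eps molar absorptivity (M^-1 cm^-1, >= 0).
#' @param c concentration (M, >= 0).
#' @param d path length (cm, >= 0).
#' @return Absorbed fraction in `[0, 1)`.
#' @examples
#' absorbed_fraction(10128, 27.4e-6, 0.2)  # ~0.12 for the Ru reference
#' @export
absorbed_fraction <- function(eps, c, d) {
  if (any(c(eps, c, d) < 0)) stop("eps, c and d must be non-negative")
  1 - 10^(-eps * c * d)
}

#' Relative actinometric quantum yield
#'
#' The quantum yield of the sample photoreaction relative to the reference:
#' \deqn{\Phi = \Phi_{ref}\,
#'   \frac{\Delta A_s / (\Delta\epsilon_s\, f_s)}
#'        {\Delta A_{ref} / (\Delta\epsilon_{ref}\, f_{ref})},\qquad
#'   f = 1 - 10^{-\epsilon_{exc} c d}}
#' where the absorbed fractions `f` account for the different portions of the
#' excitation pulse absorbed by sample and reference measured under identical
#' geometry (the probe path is common and cancels; only the excitation path
#' `d` enters). Matching signs of `dA` and `delta_eps` give a positive yield.
#' A result outside `[0, 1.05]` triggers a plausibility warning and is
#' flagged.
#'
#' @param inp an [actinometry_input()].
#' @return Object of class `quantum_yield`: list with `phi`, the absorbed
#'   fractions `f_sample` and `f_ref`, the per-arm reduced amplitudes, and a
#'   `plausible` flag.
#' @examples
#' wt <- actinometry_input(dA_sample = -0.023, dA_ref = -0.097,
#'                         delta_eps_sample = -3525,
#'                         eps_exc_sample = 9460, c_sample = 40e-6)
#' quantum_yield(wt)  # ~0.555
#' @export
quantum_yield <- function(inp) {
  stopifnot(inherits(inp, "actinometry_input"))
  f_s <- absorbed_fraction(inp$eps_exc_sample, inp$c_sample, inp$d)
  f_r <- absorbed_fraction(inp$eps_exc_ref, inp$c_ref, inp$d)
  num <- inp$dA_sample / (inp$delta_eps_sample * f_s)
  den <- inp$dA_ref / (inp$delta_eps_ref * f_r)
  phi <- inp$phi_ref * num / den
  plausible <- phi >= 0 && phi <= 1.05
  if (!plausible)
    warning(sprintf("quantum yield %.3g outside [0, 1.05]; check signs and inputs", phi))
  structure(list(phi = phi, f_sample = f_s, f_ref = f_r,
                 reduced_sample = num, reduced_ref = den,
                 plausible = plausible, input = inp),
            class = "quantum_yield")
}

#' @export
print.quantum_yield <- function(x, ...) {
  cat(sprintf("quantum yield Phi = %.4g (%.1f%%)%s\n", x$phi, 100 * x$phi,
              if (!x$plausible) "  [IMPLAUSIBLE]" else ""))
  cat(sprintf("  absorbed fraction: sample %.4g, reference %.4g\n",
              x$f_sample, x$f_ref))
  invisible(x)
}
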