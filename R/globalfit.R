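#' Global multiexponential fit with shared time constants
#'
#' Fits all wavelengths of a trace set simultaneously with a sum of one or two
#' exponential decays sharing their time constants across wavelengths, with
#' per-wavelength amplitudes and (optionally) offsets, by unweighted
#' Levenberg-Marquardt least squares. The nonlinear search runs over the
#' logarithms of the time constants only; for any trial set of time constants
#' the amplitudes and offsets are solved exactly by linear least squares
#' (variable projection), which makes the fit fast and insensitive to
#' amplitude starting values.
#'
#' When `irf_fwhm` is supplied the model basis is the analytic
#' Gaussian-convolved exponential of [irf_exp()] (and the offset basis the
#' convolved step); otherwise sharp exponentials are used and, if the trace
#' set carries an instrument-response width, points earlier than
#' `1.5 * irf_fwhm` are excluded from the fit (amplitudes then refer to the
#' extrapolation of the post-response decay to `t = 0`).
#'
#' Initialization uses a deterministic multi-start: time-constant starting
#' values are drawn from a log-spaced grid spanning the fitted time window
#' (with a small seeded jitter), the best of `n_starts` converged runs is
#' kept, and components are reported sorted by ascending time constant (ties
#' broken by amplitude norm). Non-convergence is reported in the `converged`
#' flag, never raised. Near-constant data yield a flagged zero-component
#' fallback (offsets only).
#'
#' @param traces a `trace_set` (see [generate_dataset()] or
#'   [read_trace_tsv()]), or a list with elements `times`, `dA` (matrix,
#'   time x wavelength) and `wavelengths`.
#' @param n_components 1 or 2 exponential components.
#' @param allow_offset logical: per-wavelength constant offsets (residual
#'   absorbance of longer-lived species).
#' @param irf_fwhm Gaussian IRF FWHM in seconds for a convolved fit, or
#'   `NULL` for sharp exponentials.
#' @param seed integer seed for the multi-start jitter (deterministic given
#'   data and seed).
#' @param n_starts number of starting points.
#' @param fit_window optional `c(tmin, tmax)` restricting the fitted time
#'   range (seconds).
#' @param weights optional per-point weight matrix (same shape as `dA`);
#'   default unweighted, as is conventional for such fits.
#' @return Object of class `global_fit` with fields `time_constants` (s,
#'   ascending), `amplitudes` (wavelength x component), `offsets`,
#'   `residual_rmsd`, `std_errors` (per time constant), `amplitude_se`,
#'   `converged`, `iterations`, `n_components`, plus the fitted data and
#'   model description. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' sc <- preset_scheme("WT")
#' st <- instrument_setup("ms_s", wavelengths = c(450, 540),
#'                        time_grid = 10^seq(-4.3, -2, length.out = 120))
#' ts <- generate_dataset(sc, st)
#' fit <- fit_global(ts, n_components = 2)
#' coef(fit)
#' @export
fit_global <- function(traces, n_components = 1L, allow_offset = TRUE,
                       irf_fwhm = NULL, seed = 1L, n_starts = 5L,
                       fit_window = NULL, weights = NULL) {
  d <- as_fit_data(traces)
  n_components <- as.integer(n_components)
  if (!n_components %in% c(1L, 2L))
    stop("n_components must be 1 or 2")
  keep <- rep(TRUE, length(d$times))
  if (!is.null(fit_window))
    keep <- keep & d$times >= fit_window[1] & d$times <= fit_window[2]
  if (is.null(irf_fwhm) && !is.null(d$setup_irf) && d$setup_irf > 0)
    keep <- keep & d$times >= 1.5 * d$setup_irf
  t <- d$times[keep]
  # fit in canonical (ascending-wavelength) column order so results do not
  # depend on the order traces are supplied in; report in the input order
  ord <- order(d$wavelengths)
  inv_ord <- order(ord)
  Y <- d$dA[keep, ord, drop = FALSE]
  n_lambda <- ncol(Y)
  n_par <- n_components + n_components * n_lambda + allow_offset * n_lambda
  if (length(t) * n_lambda < 2 * n_par)
    stop("need at least two data points per free parameter")
  w <- if (is.null(weights)) NULL else sqrt(weights[keep, , drop = FALSE])

  # degenerate (constant-trace) data: flagged offsets-only fallback
  y_scale <- max(abs(sweep(Y, 2, colMeans(Y))))
  if (y_scale < 1e-12 * max(abs(Y), 1e-300)) {
    return(new_global_fit(
      tau = numeric(0), A = matrix(0, n_lambda, 0),
      offs = colMeans(Y)[inv_ord], rmsd = y_scale,
      se = numeric(0), ase = NULL, conv = FALSE, iter = 0L,
      n_components = 0L, t = t, Y = Y[, inv_ord, drop = FALSE], d = d,
      irf_fwhm = irf_fwhm, allow_offset = TRUE, degenerate = TRUE))
  }

  basis <- function(log_tau) {
    tau <- exp(log_tau)                       # columns in the order passed
    cols <- if (is.null(irf_fwhm)) {
      vapply(tau, function(tt) exp(-t / tt), numeric(length(t)))
    } else {
      vapply(tau, function(tt) irf_exp(t, 1 / tt, irf_fwhm), numeric(length(t)))
    }
    if (allow_offset) {
      off <- if (is.null(irf_fwhm)) rep(1, length(t)) else irf_exp(t, 0, irf_fwhm)
      cols <- cbind(cols, off)
    }
    cols
  }
  proj_resid <- function(log_tau) {
    B <- basis(log_tau)
    if (is.null(w)) {
      fit <- stats::lm.fit(B, Y)
      as.numeric(fit$residuals)
    } else {
      as.numeric(vapply(seq_len(n_lambda), function(j)
        stats::lm.wfit(B, Y[, j], w[, j]^2)$residuals, numeric(length(t))))
    }
  }
  solve_linear <- function(log_tau) {
    B <- basis(log_tau)
    cf <- stats::lm.fit(B, Y)$coefficients
    cf[is.na(cf)] <- 0
    cf <- matrix(cf, ncol = n_lambda)
    list(B = B, coef = cf)
  }

  # deterministic multi-start over a log-spaced grid of the time window
  t_pos <- t[t > 0]
  lo <- log(max(min(t_pos), min(diff(sort(unique(t))))))
  hi <- log(max(t) )
  starts <- start_grid(n_components, lo, hi, n_starts, seed)
  lower <- rep(lo - log(50), n_components)
  upper <- rep(hi + log(50), n_components)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- try(minpack.lm::nls.lm(
      par = starts[s, ], fn = proj_resid, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-14, ptol = 1e-14)), silent = TRUE)
    if (inherits(res, "try-error")) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-300 ||
        (rss < best$rss * (1 + 1e-12) && res$info %in% 1:4 && !best$ok))
      best <- list(fit = res, rss = rss, ok = res$info %in% 1:4)
  }
  if (is.null(best))
    stop("all Levenberg-Marquardt starts failed")
  log_tau <- sort(as.numeric(best$fit$par))
  lin <- solve_linear(log_tau)
  tau <- exp(log_tau)
  A <- t(lin$coef[seq_len(n_components), , drop = FALSE])  # wavelength x comp
  offs <- if (allow_offset) lin$coef[n_components + 1L, ] else rep(0, n_lambda)
  resid <- Y - lin$B %*% lin$coef
  rmsd <- sqrt(mean(resid^2))

  # standard errors: Jacobian of the projected residual in log tau
  se <- rep(NA_real_, n_components)
  dof <- length(Y) - n_par
  if (dof > 0 && rmsd > 0) {
    J <- num_jacobian(proj_resid, log_tau)
    JtJ <- crossprod(J)
    if (rcond(JtJ) > 1e-14) {
      s2 <- sum(resid^2) / dof
      se_log <- sqrt(diag(solve(JtJ)) * s2)
      se <- tau * se_log                      # delta method
    }
  }
  ase <- amplitude_se(lin$B, resid, n_lambda)

  new_global_fit(tau = tau, A = A[inv_ord, , drop = FALSE],
                 offs = offs[inv_ord],
                 rmsd = rmsd, se = se,
                 ase = if (is.null(ase)) NULL else ase[, inv_ord, drop = FALSE],
                 conv = best$fit$info %in% 1:4,
                 iter = best$fit$niter, n_components = n_components,
                 t = t, Y = Y[, inv_ord, drop = FALSE], d = d,
                 irf_fwhm = irf_fwhm,
                 allow_offset = allow_offset, degenerate = FALSE)
}

start_grid <- function(k, lo, hi, n_starts, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  span <- hi - lo
  qs <- if (k == 1) cbind(seq(0.15, 0.85, length.out = n_starts))
        else cbind(seq(0.1, 0.5, length.out = n_starts),
                   seq(0.55, 0.95, length.out = n_starts))
  starts <- lo + qs * span
  starts + matrix(stats::runif(length(starts), -0.05, 0.05) * span,
                  nrow = n_starts)
}

num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xj <- x; xj[j] <- xj[j] + eps
    J[, j] <- (f(xj) - f0) / eps
  }
  J
}

amplitude_se <- function(B, resid, n_lambda) {
  dof <- nrow(B) - ncol(B)
  if (dof <= 0) return(NULL)
  XtXi <- tryCatch(solve(crossprod(B)), error = function(e) NULL)
  if (is.null(XtXi)) return(NULL)
  s2 <- colSums(resid^2) / dof
  sqrt(outer(diag(XtXi), s2))                 # coef x wavelength
}

as_fit_data <- function(traces) {
  if (inherits(traces, "trace_set"))
    return(list(times = traces$times, dA = traces$dA,
                wavelengths = traces$wavelengths,
                setup_irf = if (isTRUE(traces$convolved)) 0 else traces$setup$irf_fwhm))
  if (is.list(traces) && all(c("times", "dA") %in% names(traces))) {
    dA <- as.matrix(traces$dA)
    return(list(times = traces$times, dA = dA,
                wavelengths = traces$wavelengths %||% seq_len(ncol(dA)),
                setup_irf = traces$setup_irf %||% NULL))
  }
  stop("traces must be a trace_set or a list with times and dA")
}

new_global_fit <- function(tau, A, offs, rmsd, se, ase, conv, iter,
                           n_components, t, Y, d, irf_fwhm, allow_offset,
                           degenerate) {
  if (length(tau) > 1L) {
    # ascending tau; deterministic tie-break by amplitude norm
    ord <- order(tau, -sqrt(colSums(A^2)))
    tau <- tau[ord]; A <- A[, ord, drop = FALSE]; se <- se[ord]
  }
  rownames(A) <- d$wavelengths
  structure(list(
    n_components = n_components, time_constants = as.numeric(tau),
    amplitudes = A, offsets = stats::setNames(as.numeric(offs), d$wavelengths),
    residual_rmsd = rmsd, std_errors = as.numeric(se), amplitude_se = ase,
    converged = conv, iterations = iter, degenerate = degenerate,
    wavelengths = d$wavelengths, times = t, data = Y,
    irf_fwhm = irf_fwhm, allow_offset = allow_offset),
    class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit> %d component(s), %d wavelengths, %d points%s\n",
              x$n_components, length(x$wavelengths), length(x$times),
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  if (x$degenerate) cat("  degenerate data: offsets-only fallback\n")
  for (i in seq_along(x$time_constants))
    cat(sprintf("  tau_%d = %s (se %s)\n", i, format_time(x$time_constants[i]),
                if (is.na(x$std_errors[i])) "n/a" else format_time(x$std_errors[i])))
  cat(sprintf("  residual RMSD = %.4g\n", x$residual_rmsd))
  invisible(x)
}

#' @export
summary.global_fit <- function(object, ...) {
  comp <- data.frame(
    component = seq_along(object$time_constants),
    tau_s = object$time_constants, se_s = object$std_errors)
  amp <- data.frame(wavelength_nm = object$wavelengths,
                    object$amplitudes, offset = object$offsets,
                    check.names = FALSE)
  out <- list(components = comp, amplitudes = amp,
              residual_rmsd = object$residual_rmsd,
              converged = object$converged, iterations = object$iterations)
  class(out) <- "summary.global_fit"
  out
}

#' @export
print.summary.global_fit <- function(x, ...) {
  cat("Shared time constants:\n"); print(x$components, row.names = FALSE)
  cat("\nPer-wavelength amplitudes:\n"); print(x$amplitudes, row.names = FALSE)
  cat(sprintf("\nresidual RMSD %.4g; converged: %s (%d iterations)\n",
              x$residual_rmsd, x$converged, x$iterations))
  invisible(x)
}

#' @export
coef.global_fit <- function(object, ...) {
  tau <- stats::setNames(object$time_constants,
                         paste0("tau", seq_along(object$time_constants)))
  amps <- as.numeric(object$amplitudes)
  if (length(amps) > 0L)
    names(amps) <- as.character(outer(object$wavelengths,
                                      seq_len(object$n_components),
                                      function(w, k) sprintf("A%d_%gnm", k, w)))
  c(tau, amps)
}

model_matrix_gf <- function(object, times) {
  cols <- lapply(object$time_constants, function(tau) {
    if (is.null(object$irf_fwhm)) exp(-times / tau)
    else irf_exp(times, 1 / tau, object$irf_fwhm)
  })
  B <- do.call(cbind, c(cols, list(
    if (is.null(object$irf_fwhm)) rep(1, length(times))
    else irf_exp(times, 0, object$irf_fwhm))))
  B
}

#' @export
predict.global_fit <- function(object, times = object$times, ...) {
  B <- model_matrix_gf(object, times)
  cf <- rbind(t(object$amplitudes), object$offsets)
  out <- B %*% cf
  colnames(out) <- paste0("dA_", object$wavelengths, "nm")
  out
}

#' @export
fitted.global_fit <- function(object, ...) predict(object)

#' @export
residuals.global_fit <- function(object, ...) object$data - predict(object)

#' @export
plot.global_fit <- function(x, log = "x", ...) {
  graphics::matplot(x$times, x$data, pch = 1, cex = 0.4, log = log,
                    xlab = "time (s)", ylab = expression(Delta * A), ...)
  graphics::matlines(x$times, fitted(x), lty = 1)
  invisible(x)
}

#' Compare two nested global fits of the same data
#'
#' Reports the residual-RMSD ratio of two fits of identical data and a
#' verdict: the improvement from the larger model is called `"marginal"` when
#' the RMSD improves by less than `threshold` (default 5\%), `"substantial"`
#' otherwise. Also reports the improvement per added parameter.
#'
#' @param fit1,fit2 `global_fit` objects on identical data (any order; the
#'   one with more parameters is treated as the larger model).
#' @param threshold relative RMSD improvement below which the verdict is
#'   `"marginal"`.
#' @return List with `rmsd_ratio` (larger model / smaller model),
#'   `improvement`, `improvement_per_parameter`, `added_parameters`,
#'   `verdict`.
#' @export
compare_models <- function(fit1, fit2, threshold = 0.05) {
  stopifnot(inherits(fit1, "global_fit"), inherits(fit2, "global_fit"))
  if (!isTRUE(all.equal(dim(fit1$data), dim(fit2$data))) ||
      !isTRUE(all.equal(fit1$data, fit2$data)))
    stop("fits must be on identical data")
  npar <- function(f) f$n_components * (1 + length(f$wavelengths)) +
    f$allow_offset * length(f$wavelengths)
  if (npar(fit2) < npar(fit1)) { tmp <- fit1; fit1 <- fit2; fit2 <- tmp }
  ratio <- fit2$residual_rmsd / fit1$residual_rmsd
  improvement <- 1 - ratio
  added <- max(npar(fit2) - npar(fit1), 1L)
  list(rmsd_ratio = ratio, improvement = improvement,
       improvement_per_parameter = improvement / added,
       added_parameters = added,
       verdict = if (improvement < threshold) "marginal" else "substantial")
}

#' Amplitude spectrum (decay-associated spectrum) of a global fit
#'
#' Per-wavelength amplitudes of one fitted component, or the summed
#' amplitudes of all components extrapolated to `t = 0` (`component =
#' "t0"`). Offsets are never included in the `t = 0` extrapolation: they
#' represent species outliving the fitted window, not the initial
#' photoproduct.
#'
#' @param fit a converged `global_fit`.
#' @param component component index (1-based, ascending time constants) or
#'   `"t0"`.
#' @return Data frame with columns `wavelength_nm` and `amplitude`.
#' @export
amplitude_spectrum <- function(fit, component = "t0") {
  stopifnot(inherits(fit, "global_fit"))
  if (!fit$converged)
    warning("amplitude spectrum of a non-converged fit")
  if (identical(component, "t0")) {
    amp <- rowSums(fit$amplitudes)
  } else {
    component <- as.integer(component)
    if (component < 1L || component > fit$n_components)
      stop("component index out of range")
    amp <- fit$amplitudes[, component]
  }
  data.frame(wavelength_nm = fit$wavelengths, amplitude = as.numeric(amp))
}
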