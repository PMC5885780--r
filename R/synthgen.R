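#' Instrument setup for synthetic flash-photolysis traces
#'
#' Describes one of the three measurement regimes used in flash-induced
#' absorption experiments on flavoproteins, with per-regime defaults:
#' \describe{
#'   \item{`ps_ns`}{200 ps FWHM Gaussian instrument response, log-spaced time
#'     grid 10 ps to 20 ns, 355 nm excitation.}
#'   \item{`ns_us`}{5 ns response, grid 10 ns to 100 us, 470 nm excitation.}
#'   \item{`ms_s`}{30 us response, grid 10 us to 10 s, 470 nm excitation.}
#' }
#'
#' @param regime one of `"ps_ns"`, `"ns_us"`, `"ms_s"`.
#' @param wavelengths monitoring wavelengths in nm.
#' @param irf_fwhm instrument response FWHM in seconds (`NULL` for the regime
#'   default).
#' @param time_grid time grid in seconds, strictly increasing (`NULL` for the
#'   regime default, log-spaced).
#' @param n_times number of points in the default log-spaced grid.
#' @param noise_sigma additive Gaussian noise standard deviation in
#'   absorbance units. May be given as an absolute value, or computed from a
#'   relative level by [generate_dataset()]'s `noise_relative` argument.
#' @param excitation_nm excitation wavelength (metadata).
#' @param seed integer seed controlling the noise stream.
#' @param t_max optional override of the default grid end (seconds).
#' @return Object of class `instrument_setup`.
#' @export
instrument_setup <- function(regime = c("ps_ns", "ns_us", "ms_s"),
                             wavelengths = c(408, 457, 540, 562, 594),
                             irf_fwhm = NULL, time_grid = NULL, n_times = 300L,
                             noise_sigma = 0, excitation_nm = NULL,
                             seed = 1L, t_max = NULL) {
  regime <- match.arg(regime)
  defaults <- list(
    ps_ns = list(irf = 200e-12, t0 = 1e-11, t1 = 2e-8,  exc = 355),
    ns_us = list(irf = 5e-9,    t0 = 1e-8,  t1 = 1e-4,  exc = 470),
    ms_s  = list(irf = 30e-6,   t0 = 1e-5,  t1 = 10,    exc = 470))[[regime]]
  if (is.null(irf_fwhm)) irf_fwhm <- defaults$irf
  if (is.null(excitation_nm)) excitation_nm <- defaults$exc
  if (is.null(time_grid)) {
    t1 <- if (is.null(t_max)) defaults$t1 else t_max
    time_grid <- 10^seq(log10(defaults$t0), log10(t1), length.out = n_times)
  }
  if (any(diff(time_grid) <= 0)) stop("time grid must be strictly increasing")
  if (irf_fwhm < 0 || noise_sigma < 0)
    stop("irf_fwhm and noise_sigma must be non-negative")
  structure(list(regime = regime, wavelengths = as.numeric(wavelengths),
                 irf_fwhm = irf_fwhm, time_grid = as.numeric(time_grid),
                 noise_sigma = noise_sigma, excitation_nm = excitation_nm,
                 seed = as.integer(seed)),
            class = "instrument_setup")
}

#' @export
print.instrument_setup <- function(x, ...) {
  cat(sprintf("<instrument_setup> %s: IRF %s, %d x %d grid (%s..%s), sigma = %g, seed %d\n",
              x$regime, format_time(x$irf_fwhm), length(x$time_grid),
              length(x$wavelengths), format_time(min(x$time_grid)),
              format_time(max(x$time_grid)), x$noise_sigma, x$seed))
  invisible(x)
}

#' Gaussian-convolved exponential decay
#'
#' Analytic convolution of `H(t) exp(-k t)` with a unit-area Gaussian of the
#' given FWHM (the exponential-times-complementary-error-function model used
#' for instrument-response convolution in transient absorption fitting):
#' \deqn{f(t) = \tfrac12 e^{(k\sigma)^2/2 - k t}\,
#'       \mathrm{erfc}\!\left(\frac{k\sigma - t/\sigma}{\sqrt 2}\right)}
#' with `sigma = fwhm / (2 sqrt(2 log 2))`. Evaluated in a numerically stable
#' form via the scaled complementary error function. `fwhm = 0` returns the
#' sharp exponential exactly; `rate = 0` gives the convolved step.
#'
#' @param times numeric times (s); may include negative values.
#' @param rate decay rate constant (s^-1, >= 0).
#' @param fwhm Gaussian IRF full width at half maximum (s, >= 0).
#' @return Numeric vector of model values.
#' @export
irf_exp <- function(times, rate, fwhm) {
  if (fwhm < 0 || rate < 0) stop("rate and fwhm must be non-negative")
  if (fwhm == 0) return(ifelse(times < 0, 0, exp(-rate * times)))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (rate == 0) return(0.5 * pracma::erfc(-times / (sigma * sqrt(2))))
  a <- (rate * sigma - times / sigma) / sqrt(2)
  out <- numeric(length(times))
  pos <- a >= 0
  # e^{a^2} erfc(a) = erfcx(a); a^2 = (k sigma)^2/2 - k t + t^2/(2 sigma^2)
  out[pos] <- 0.5 * erfcx_stable(a[pos]) * exp(-times[pos]^2 / (2 * sigma^2))
  out[!pos] <- 0.5 * exp((rate * sigma)^2 / 2 - rate * times[!pos]) *
    pracma::erfc(a[!pos])
  out
}

#' Absorbance change of a trajectory at one wavelength
#'
#' Beer-Lambert composition: each state contributes its population times the
#' difference molar absorptivity of its species relative to the scheme's
#' ground state, times the photoproduct concentration and probe path length:
#' `dA(t) = sum_states p(t) * Delta_eps_state(lambda) * c * d`.
#'
#' @param traj a `population_trajectory` from [propagate()].
#' @param scheme the `kinetic_scheme` that produced it (supplies the
#'   state-to-species map and the ground state).
#' @param registry species spectra, see [spectra_registry()].
#' @param pair_concentration photoproduct (radical-pair) concentration in M
#'   corresponding to unit initial population.
#' @param path probe path length in cm.
#' @param wavelength_nm monitoring wavelength (nm).
#' @return Numeric vector of absorbance changes, one per trajectory time.
#' @export
trace_from_trajectory <- function(traj, scheme, registry, pair_concentration,
                                  path = 1, wavelength_nm) {
  stopifnot(inherits(traj, "population_trajectory"))
  if (pair_concentration <= 0) stop("pair_concentration must be positive")
  de <- state_delta_eps(scheme, registry, wavelength_nm)
  drop(traj$populations %*% de) * pair_concentration * path
}

# difference molar absorptivity of every state vs the ground state
state_delta_eps <- function(scheme, registry, wavelength_nm) {
  eps_of <- function(spp) {
    missing <- setdiff(spp, names(registry))
    if (length(missing) > 0L)
      stop("species missing from registry: ", paste(missing, collapse = ", "))
    sum(vapply(spp, function(s) eval_spectrum(registry[[s]], wavelength_nm), 0))
  }
  ground_eps <- eps_of(scheme$species[[scheme$ground]])
  vapply(scheme$states, function(st) eps_of(scheme$species[[st]]) - ground_eps, 0)
}

#' Generate a synthetic multi-wavelength trace set from a kinetic scheme
#'
#' Composes [propagate()] (via the scheme's multiexponential components),
#' Beer-Lambert conversion to absorbance changes, analytic Gaussian
#' instrument-response convolution of every kinetic component
#' (see [irf_exp()]), an optional hydrated-electron artifact, and seeded
#' i.i.d. additive Gaussian noise. Deterministic given the setup seed.
#'
#' @param scheme a `kinetic_scheme`.
#' @param setup an [instrument_setup()].
#' @param registry species spectra; default [spectra_registry()].
#' @param pair_concentration photoproduct concentration (M) for unit initial
#'   population; default 6.5e-6.
#' @param path probe path length (cm); default 1.
#' @param noise_relative if not `NULL`, overrides `setup$noise_sigma` with
#'   `noise_relative * max(abs(noiseless model))`.
#' @param convolve_irf logical: apply the IRF convolution (default `TRUE` in
#'   the `ps_ns` regime, `FALSE` otherwise, matching how such data are
#'   usually fitted post-response).
#' @param eaq_fraction hydrated-electron artifact amplitude as a fraction of
#'   the radical-pair concentration (0 disables; see
#'   [add_electron_artifact()]).
#' @param tau_eaq hydrated-electron lifetime (s).
#' @return Object of class `trace_set`: `times`, matrix `dA`
#'   (time x wavelength), `wavelengths`, the `setup`, and provenance fields
#'   (`scheme_id`, `pair_concentration`, `path`, `seed`, `noise_sigma`)
#'   sufficient to regenerate the data bit-identically.
#' @export
generate_dataset <- function(scheme, setup, registry = spectra_registry(),
                             pair_concentration = 6.5e-6, path = 1,
                             noise_relative = NULL,
                             convolve_irf = setup$regime == "ps_ns",
                             eaq_fraction = 0, tau_eaq = 1e-6) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(setup, "instrument_setup"))
  times <- setup$time_grid
  fwhm <- if (convolve_irf) setup$irf_fwhm else 0
  cmp <- exp_components(scheme)
  if (is.null(cmp)) {
    if (fwhm > 0)
      stop("analytic IRF convolution needs a diagonalizable rate matrix")
    P <- propagate(scheme, times)$populations
    B <- NULL
  } else {
    B <- vapply(cmp$rates, function(k) irf_exp(times, k, fwhm), numeric(length(times)))
    P <- B %*% t(cmp$C)                       # time x state, IRF-convolved
  }
  DE <- vapply(setup$wavelengths, function(wl)
    state_delta_eps(scheme, registry, wl), numeric(length(scheme$states)))
  M <- (P %*% DE) * pair_concentration * path # time x wavelength
  colnames(M) <- paste0("dA_", setup$wavelengths, "nm")
  ts <- structure(list(times = times, dA = M, wavelengths = setup$wavelengths,
                       setup = setup, scheme_id = scheme$id,
                       pair_concentration = pair_concentration, path = path,
                       seed = setup$seed, noise_sigma = 0,
                       eaq_fraction = 0, tau_eaq = tau_eaq,
                       convolved = fwhm > 0),
                  class = "trace_set")
  if (eaq_fraction > 0)
    ts <- add_electron_artifact(ts, eaq_fraction, tau_eaq, registry = registry)
  sigma <- if (!is.null(noise_relative)) noise_relative * max(abs(ts$dA))
           else setup$noise_sigma
  if (sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(setup$seed)
    ts$dA <- ts$dA + matrix(stats::rnorm(length(ts$dA), sd = sigma),
                            nrow = nrow(ts$dA))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    ts$noise_sigma <- sigma
  }
  ts
}

#' Add a hydrated-electron artifact to a trace set
#'
#' Upon UV excitation a second photon can ionize the freshly formed flavin
#' anion radical, producing hydrated electrons that absorb broadly around
#' 720 nm and decay fast. The artifact is modelled as an additional component
#' with concentration `fraction * pair_concentration`, the hydrated-electron
#' spectrum, and a single-exponential decay `tau_eaq` (IRF-convolved when the
#' trace set is). The `fraction` convention (fraction of the radical-pair
#' concentration) can be sidestepped by passing an absolute concentration via
#' `fraction * pair_concentration` of your choosing.
#'
#' On millisecond-and-slower grids the artifact has decayed below any
#' practical detection level, so such traces are unaffected regardless of
#' `fraction`.
#'
#' @param ts a `trace_set` (noiseless; add noise afterwards or use
#'   [generate_dataset()]'s `eaq_fraction`).
#' @param fraction hydrated-electron concentration as a fraction of the
#'   radical-pair concentration, in `[0, 1)`.
#' @param tau_eaq hydrated-electron lifetime (s).
#' @param registry species spectra containing `e_aq`.
#' @return The trace set with the artifact added.
#' @export
add_electron_artifact <- function(ts, fraction, tau_eaq = 1e-6,
                                  registry = spectra_registry()) {
  stopifnot(inherits(ts, "trace_set"))
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (fraction == 0) return(ts)
  # hydrated electrons never survive into the millisecond regime
  if (identical(ts$setup$regime, "ms_s")) return(ts)
  fwhm <- if (isTRUE(ts$convolved)) ts$setup$irf_fwhm else 0
  decay <- irf_exp(ts$times, 1 / tau_eaq, fwhm)
  eps <- vapply(ts$wavelengths, function(wl)
    eval_spectrum(registry$e_aq, wl), 0)
  ts$dA <- ts$dA + (decay %o% eps) * fraction * ts$pair_concentration * ts$path
  ts$eaq_fraction <- fraction
  ts$tau_eaq <- tau_eaq
  ts
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %s (%s): %d times x %d wavelengths (%s), sigma = %.3g%s\n",
              x$scheme_id, x$setup$regime, nrow(x$dA), ncol(x$dA),
              paste(x$wavelengths, collapse = "/"), x$noise_sigma,
              if (x$eaq_fraction > 0)
                sprintf(", e_aq %g%%", 100 * x$eaq_fraction) else ""))
  invisible(x)
}

#' @export
plot.trace_set <- function(x, log = "x", ...) {
  graphics::matplot(x$times, x$dA, type = "l", lty = 1, log = log,
                    xlab = "time (s)", ylab = expression(Delta * A), ...)
  graphics::legend("topright", legend = paste0(x$wavelengths, " nm"),
                   col = seq_along(x$wavelengths), lty = 1, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  data.frame(time_s = x$times, x$dA, check.names = FALSE)
}

#' Simulate flash-photolysis data from a kinetic scheme
#'
#' `simulate()` method wrapping [generate_dataset()]: draws `nsim` trace sets
#' whose noise streams are seeded deterministically from `seed`
#' (`seed + 0:(nsim-1)`).
#'
#' @param object a `kinetic_scheme`.
#' @param nsim number of replicate trace sets.
#' @param seed integer base seed; overrides the setup seed.
#' @param setup an [instrument_setup()].
#' @param ... passed to [generate_dataset()].
#' @return A `trace_set` (`nsim = 1`) or a list of them.
#' @export
simulate.kinetic_scheme <- function(object, nsim = 1, seed = 1L,
                                    setup = instrument_setup(), ...) {
  out <- lapply(seq_len(nsim) - 1L, function(i) {
    setup$seed <- as.integer(seed + i)
    generate_dataset(object, setup, ...)
  })
  if (nsim == 1) out[[1]] else out
}

#' Read / write a trace set as tab-separated text
#'
#' Column 1 is `time_s`, then one `dA_<wavelength>nm` column per wavelength.
#' `#`-prefixed header lines carry the regime, IRF, seed, scheme id, noise
#' sigma, concentration and path; unrecognized comment lines are preserved on
#' a round trip. Writing, reading and re-writing reproduces the file
#' byte-for-byte.
#'
#' @param ts a `trace_set`.
#' @param path file path.
#' @return `read_trace_tsv` returns a `trace_set`; `write_trace_tsv` returns
#'   `path` invisibly.
#' @export
write_trace_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  hdr <- c(sprintf("# scheme: %s", ts$scheme_id),
           sprintf("# regime: %s", ts$setup$regime),
           sprintf("# irf_fwhm_s: %s", num_txt(ts$setup$irf_fwhm)),
           sprintf("# convolved: %s", if (isTRUE(ts$convolved)) "yes" else "no"),
           sprintf("# seed: %d", ts$seed),
           sprintf("# noise_sigma: %s", num_txt(ts$noise_sigma)),
           sprintf("# pair_concentration_M: %s", num_txt(ts$pair_concentration)),
           sprintf("# path_cm: %s", num_txt(ts$path)),
           sprintf("# eaq_fraction: %s", num_txt(ts$eaq_fraction)),
           sprintf("# excitation_nm: %s", num_txt(ts$setup$excitation_nm)),
           ts$extra_comments)
  body <- paste(num_txt(ts$times),
                apply(ts$dA, 1L, function(r) paste(num_txt(r), collapse = "\t")),
                sep = "\t")
  writeLines(c(hdr, paste(c("time_s", colnames(ts$dA)), collapse = "\t"), body),
             path)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  if (!file.exists(path)) stop("trace TSV not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  meta <- list(); extras <- character(0)
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^# ([a-zA-Z_]+): (.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3] else extras <- c(extras, ln)
  }
  body <- lines[!is_comment]
  header <- strsplit(body[1], "\t")[[1]]
  if (header[1] != "time_s")
    stop("trace TSV must start with a time_s column: ", path)
  wl_cols <- header[-1]
  if (!all(grepl("^dA_[0-9.]+nm$", wl_cols)))
    stop("trace columns must be named dA_<wavelength>nm: ", path)
  wavelengths <- as.numeric(sub("^dA_([0-9.]+)nm$", "\\1", wl_cols))
  rows <- strsplit(body[-1], "\t")
  bad <- which(lengths(rows) != length(header))
  if (length(bad) > 0L)
    stop(sprintf("malformed row at line %d of %s",
                 which(!is_comment)[1 + bad[1]], path))
  vals <- matrix(as.numeric(unlist(rows)), ncol = length(header), byrow = TRUE)
  if (any(!is.finite(vals)))
    stop("non-numeric values in trace TSV: ", path)
  setup <- instrument_setup(
    regime = meta$regime %||% "ns_us", wavelengths = wavelengths,
    irf_fwhm = as.numeric(meta$irf_fwhm_s %||% 0), time_grid = vals[, 1],
    noise_sigma = as.numeric(meta$noise_sigma %||% 0),
    excitation_nm = as.numeric(meta$excitation_nm %||% 470),
    seed = as.integer(meta$seed %||% 1))
  dA <- vals[, -1, drop = FALSE]
  colnames(dA) <- wl_cols
  structure(list(times = vals[, 1], dA = dA, wavelengths = wavelengths,
                 setup = setup, scheme_id = meta$scheme %||% "unknown",
                 pair_concentration = as.numeric(meta$pair_concentration_M %||% NA),
                 path = as.numeric(meta$path_cm %||% 1),
                 seed = as.integer(meta$seed %||% 1),
                 noise_sigma = as.numeric(meta$noise_sigma %||% 0),
                 eaq_fraction = as.numeric(meta$eaq_fraction %||% 0),
                 tau_eaq = 1e-6,
                 convolved = identical(meta$convolved, "yes"),
                 extra_comments = if (length(extras)) extras else NULL),
            class = "trace_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scaled complementary error function, safe for large arguments
# (exp(x^2) * erfc(x) overflows numerically above x ~ 26; use the
# asymptotic series 1/(x sqrt(pi)) * (1 - 1/(2x^2) + 3/(4x^4) - 15/(8x^6))
# there, accurate to ~1e-11 relative at the switch point)
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  small <- x <= 25
  out[small] <- pracma::erfcx(x[small])
  xl <- x[!small]
  out[!small] <- (1 - 1 / (2 * xl^2) + 3 / (4 * xl^4) - 15 / (8 * xl^6)) /
    (xl * sqrt(pi))
  out
}
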