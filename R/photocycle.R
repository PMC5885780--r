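#' First-order kinetic scheme of a photocycle
#'
#' A `kinetic_scheme` is a continuous-time first-order reaction network: named
#' states (each mapped to the set of spectroscopic species present in it),
#' first-order transitions with strictly positive rate constants, and an
#' initial population vector. Populations evolve as `dp/dt = K p` with the
#' usual rate matrix (off-diagonal `K[j,i] = k(i->j)`, column sums zero), so
#' total population is conserved. At least one state must be absorbing (no
#' outgoing transitions), representing recovered ground state or a stable
#' photoproduct.
#'
#' @param states character vector of state names (ordered).
#' @param species named list mapping each state name to a character vector of
#'   species labels present in that state (labels as in [spectra_registry()]).
#' @param transitions data frame with columns `from`, `to`, `rate` (s^-1, > 0)
#'   or `tau` (s, converted to `rate = 1/tau`).
#' @param initial named (or ordered) numeric vector of initial populations,
#'   summing to 1.
#' @param ground name of the ground/reference state used as the Beer-Lambert
#'   baseline when traces are synthesized; defaults to the last absorbing
#'   state.
#' @param id optional scheme identifier string.
#' @return Object of class `kinetic_scheme`.
#' @seealso [preset_scheme()], [propagate()]
#' @export
kinetic_scheme <- function(states, species, transitions, initial,
                           ground = NULL, id = "scheme") {
  stopifnot(is.character(states), length(states) >= 1L, !anyDuplicated(states))
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (!("rate" %in% names(transitions))) {
    if (!("tau" %in% names(transitions))) stop("transitions need a rate or tau column")
    transitions$rate <- 1 / transitions$tau
  }
  transitions <- transitions[c("from", "to", "rate")]
  if (nrow(transitions) > 0L) {
    if (!all(transitions$from %in% states) || !all(transitions$to %in% states))
      stop("transition endpoints must be declared states")
    if (any(!is.finite(transitions$rate)) || any(transitions$rate <= 0))
      stop("all rate constants must be finite and strictly positive")
  }
  if (is.null(names(initial))) names(initial) <- states[seq_along(initial)]
  p0 <- stats::setNames(rep(0, length(states)), states)
  p0[names(initial)] <- initial
  if (abs(sum(p0) - 1) > 1e-12)
    stop("initial populations must sum to 1")
  has_exit <- states %in% transitions$from
  if (all(has_exit))
    stop("scheme needs at least one absorbing state (no outgoing transitions)")
  if (is.null(ground)) ground <- states[!has_exit][sum(!has_exit)]
  stopifnot(ground %in% states)
  missing_sp <- setdiff(states, names(species))
  if (length(missing_sp) > 0L)
    stop("species mapping missing for states: ", paste(missing_sp, collapse = ", "))
  structure(list(states = states, species = species[states],
                 transitions = transitions, initial = p0,
                 ground = ground, id = id),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %s: %d states, %d transitions (ground: %s)\n",
              x$id, length(x$states), nrow(x$transitions), x$ground))
  for (i in seq_len(nrow(x$transitions)))
    cat(sprintf("  %s -> %s : tau = %s\n", x$transitions$from[i],
                x$transitions$to[i], format_time(1 / x$transitions$rate[i])))
  ip <- x$initial[x$initial > 0]
  cat("initial:", paste(sprintf("%s = %g", names(ip), ip), collapse = ", "), "\n")
  invisible(x)
}

#' Rate matrix of a kinetic scheme
#'
#' @param scheme a `kinetic_scheme`.
#' @return Square matrix `K` with `K[j,i]` the rate from state i to state j
#'   and column sums zero.
#' @export
rate_matrix <- function(scheme) {
  n <- length(scheme$states)
  K <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    K[tr$to[i], tr$from[i]] <- K[tr$to[i], tr$from[i]] + tr$rate[i]
    K[tr$from[i], tr$from[i]] <- K[tr$from[i], tr$from[i]] - tr$rate[i]
  }
  K
}

#' Multiexponential components of a scheme's population dynamics
#'
#' Eigendecomposition of the rate matrix: every state population is
#' `p_i(t) = sum_j C[i,j] exp(-rates[j] t)`. Returns `NULL` when the
#' eigenvector matrix is too ill-conditioned (numerically defective rate
#' matrix); callers then fall back to a scaled-squaring matrix exponential.
#'
#' @param scheme a `kinetic_scheme`.
#' @return List with `rates` (decay rates, s^-1, >= 0) and coefficient matrix
#'   `C` (states x modes), or `NULL`.
#' @keywords internal
#' @export
exp_components <- function(scheme) {
  K <- rate_matrix(scheme)
  e <- eigen(K)
  if (max(abs(Im(e$values))) > 1e-8 * max(abs(Re(e$values)), 1))
    return(NULL)
  V <- Re(e$vectors)
  if (rcond(V) < 1e-10) return(NULL)
  lam <- Re(e$values)
  c0 <- solve(V, scheme$initial)
  C <- V * rep(c0, each = nrow(V))
  rates <- -lam
  rates[abs(rates) < 1e-12 * max(abs(rates), 1)] <- 0
  if (any(rates < 0)) return(NULL)
  list(rates = rates, C = C)
}

#' Propagate state populations of a kinetic scheme
#'
#' Exact solution of `dp/dt = K p`, via eigendecomposition of the rate matrix
#' when it is well-conditioned, otherwise via the scaled-squaring matrix
#' exponential (`Matrix::expm`) per time point. Deterministic.
#'
#' @param scheme a `kinetic_scheme`.
#' @param times numeric vector of times in seconds, all `>= 0`.
#' @return Object of class `population_trajectory`: list with `times` and a
#'   `populations` matrix (time x state). Total population is conserved.
#' @export
propagate <- function(scheme, times) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  cmp <- exp_components(scheme)
  if (!is.null(cmp)) {
    E <- exp(-outer(times, cmp$rates))           # time x mode
    P <- E %*% t(cmp$C)                          # time x state
  } else {
    K <- rate_matrix(scheme)
    P <- t(vapply(times, function(t)
      as.numeric(Matrix::expm(K * t) %*% scheme$initial),
      numeric(length(scheme$states))))
  }
  P[P < 0 & P > -1e-9] <- 0
  colnames(P) <- scheme$states
  structure(list(times = times, populations = P, scheme_id = scheme$id),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("<population_trajectory> %s: %d times (%s to %s), states: %s\n",
              x$scheme_id, length(x$times), format_time(min(x$times)),
              format_time(max(x$times)),
              paste(colnames(x$populations), collapse = ", ")))
  invisible(x)
}

#' @export
plot.population_trajectory <- function(x, log = "x", ...) {
  tt <- x$times
  if (grepl("x", log) && any(tt <= 0)) tt <- pmax(tt, min(tt[tt > 0]) / 10)
  graphics::matplot(tt, x$populations, type = "l", lty = 1, log = log,
                    xlab = "time (s)", ylab = "population", ...)
  graphics::legend("right", legend = colnames(x$populations),
                   col = seq_len(ncol(x$populations)), lty = 1, bty = "n")
  invisible(x)
}

#' Branching fraction of one first-order channel among parallel channels
#'
#' For a state with several parallel first-order exits, the probability of
#' leaving through a given channel is `k_target / sum(k_all)`.
#'
#' @param k_target rate constant (s^-1) of the channel of interest; must be an
#'   element of `k_all`.
#' @param k_all numeric vector of all parallel rate constants (s^-1, > 0).
#' @return Branching fraction in (0, 1].
#' @examples
#' branching_fraction(1 / 0.4118e-9, c(1 / 0.4118e-9, 1 / 2.3333e-9))  # ~0.85
#' @export
branching_fraction <- function(k_target, k_all) {
  if (length(k_all) == 0L) stop("k_all must be non-empty")
  if (any(!is.finite(k_all)) || any(k_all <= 0))
    stop("all rate constants must be finite and positive")
  if (!any(abs(k_all - k_target) <= 1e-12 * k_target))
    stop("k_target must be one of k_all")
  k_target / sum(k_all)
}

#' Intrinsic time constant from an observed one and its branching fraction
#'
#' Under direct competition of parallel first-order channels the observed
#' decay time is `tau_obs = 1/sum(k)`; the intrinsic time constant of the
#' channel with branching fraction `phi` is `tau_obs / phi`.
#'
#' @param tau_observed observed decay time constant (s).
#' @param branch_fraction branching fraction of the channel, in (0, 1].
#' @return Intrinsic time constant (s).
#' @examples
#' observed_to_intrinsic(350e-12, 0.85)  # ~0.41 ns deprotonation
#' observed_to_intrinsic(350e-12, 0.15)  # ~2.3 ns recombination
#' @export
observed_to_intrinsic <- function(tau_observed, branch_fraction) {
  if (!is.numeric(branch_fraction) || branch_fraction <= 0 || branch_fraction > 1)
    stop("branch_fraction must lie in (0, 1]")
  if (tau_observed <= 0) stop("tau_observed must be positive")
  tau_observed / branch_fraction
}

#' Observed decay time of parallel first-order channels
#'
#' `1 / sum(1/tau_i)` for intrinsic channel time constants `tau_i`.
#'
#' @param taus numeric vector of intrinsic time constants (s, > 0).
#' @return Observed (combined) time constant (s).
#' @examples
#' parallel_observed_tau(c(300e-6, 1e-3)) * 1e6  # 230.8 us
#' @export
parallel_observed_tau <- function(taus) {
  if (length(taus) == 0L) stop("taus must be non-empty")
  if (any(!is.finite(taus)) || any(taus <= 0)) stop("all taus must be positive")
  1 / sum(1 / taus)
}

#' Quantum yield of a sequential cascade
#'
#' The end-to-end quantum yield of a cascade of branching steps is the product
#' of the per-stage fractions.
#'
#' @param stage_fractions numeric vector of per-stage yields, each in (0, 1].
#' @return Product of the fractions.
#' @examples
#' cascade_yield(c(0.65, 0.85))  # ~0.55 end yield
#' @export
cascade_yield <- function(stage_fractions) {
  if (length(stage_fractions) == 0L) stop("stage_fractions must be non-empty")
  if (any(stage_fractions <= 0) || any(stage_fractions > 1))
    stop("stage fractions must lie in (0, 1]")
  prod(stage_fractions)
}

#' Initial-stage yield implied by an end yield and downstream fractions
#'
#' Inverse form of [cascade_yield()]: divides an end-to-end yield by the
#' product of the known downstream branching fractions.
#'
#' @param end_yield end-to-end quantum yield, in (0, 1].
#' @param downstream_fractions downstream per-stage fractions, each in (0, 1].
#' @return Implied yield of the initial stage.
#' @examples
#' invert_cascade_yield(0.554, 0.85)  # ~0.65 initial-pair yield
#' @export
invert_cascade_yield <- function(end_yield, downstream_fractions) {
  if (end_yield <= 0 || end_yield > 1) stop("end_yield must lie in (0, 1]")
  y <- end_yield / cascade_yield(downstream_fractions)
  if (y > 1 + 1e-9)
    warning("implied initial yield exceeds 1; inputs are inconsistent")
  y
}

#' Kinetic isotope effect from protiated and deuterated time constants
#'
#' `KIE = k_H / k_D = tau_D / tau_H`. Values below 1 are flagged as inverse.
#'
#' @param tau_H time constant in H2O (s).
#' @param tau_D time constant in D2O (s).
#' @return Numeric KIE with attributes `rounded_2sf` and `inverse`.
#' @examples
#' kie(350e-12, 800e-12)  # ~2.3
#' @export
kie <- function(tau_H, tau_D) {
  if (tau_H <= 0 || tau_D <= 0) stop("time constants must be positive")
  v <- tau_D / tau_H
  structure(v, rounded_2sf = signif(v, 2), inverse = v < 1, class = "kie")
}

#' @export
print.kie <- function(x, ...) {
  cat(sprintf("KIE (k_H/k_D) = %.4g  [2 s.f.: %g]%s\n", unclass(x),
              attr(x, "rounded_2sf"),
              if (attr(x, "inverse")) "  (inverse isotope effect)" else ""))
  invisible(x)
}

# --- preset photocycle schemes -----------------------------------------------

# Default time constants (seconds). Observed values enter as such; intrinsic
# pair-state constants are stored so that the observed fast phase and its
# branching ratio are reproduced: 1/(1/0.41176 ns + 1/2.3333 ns) = 350 ps with
# an 85:15 deprotonation:recombination split.
preset_defaults <- function() {
  list(
    tau_formation = 5e-12,    # lumped sub-resolution hopping along the Trp triad;
                              # fast enough that the pair is fully formed within
                              # the 200 ps instrument response, as observed
                              # (the fast phase then fits monoexponentially)
    pair_yield    = 0.65,     # quantum yield of the primary flavin/TrpH pair
    tau_dep       = 350e-12 / 0.85,   # intrinsic TrpH+ deprotonation, ~0.41 ns
    tau_rec1      = 350e-12 / 0.15,   # intrinsic pair recombination, ~2.33 ns
    tau_rec2      = 300e-6,   # effective flavin/Trp recombination
    tau_tyr_ox    = 1e-3,     # effective Tyr oxidation by the Trp radical
    tau_rec3      = 1.1e-3,   # flavin/Tyr pair recombination
    tau_dep_D2O   = 800e-12,  # observed fast phase in D2O
    tau_obs_E387Q = 500e-12,  # observed fast phase in the E387Q mutant
    tau_rec_W388F = 1.2e-9,   # pair recombination in W388F
    tau_side_et   = 15e-9,    # side electron transfer from Tyr (10-20 ns window)
    pair_yield_W388F = 0.55,
    tau_rec3_W388F   = 2.7e-3,
    tau_rec_Y345F    = 250e-6,  # observed monoexponential decay in Y345F
    k_scav        = 1e5,      # cysteine scavenging, M^-1 s^-1 (free parameter)
    fast_fraction = 0.15,     # subpopulation with fast flavin protonation
    tau_prot_slow = 630e-3,
    tau_prot_fast = 2.2e-3
  )
}

#' Preset photocycle schemes for the wild type and mutants
#'
#' Fully populated [kinetic_scheme()]s encoding the photocycle of the class II
#' photolyase studied here, with the directly observed or branching-derived
#' time constants as defaults and every rate overridable.
#'
#' Variants:
#' \describe{
#'   \item{`WT`}{excited flavin -> flavin-anion/TrpH+ pair (65\% yield, lumped
#'     sub-resolution formation) -> deprotonation (intrinsic ~0.41 ns, 85\%)
#'     in competition with recombination (~2.33 ns, 15\%); the
#'     flavin-anion/Trp pair recombines (effective 300 us) in competition with
#'     Tyr oxidation (effective 1 ms); the flavin-anion/Tyr pair recombines in
#'     1.1 ms.}
#'   \item{`WT_D2O`}{as WT with the deprotonation slowed so the observed fast
#'     phase is 800 ps (recombination unchanged).}
#'   \item{`E387Q`}{as WT with deprotonation adjusted so the observed fast
#'     phase is 500 ps.}
#'   \item{`W388F`}{excited flavin -> flavin-anion/TrpH+ pair (55\% yield) ->
#'     recombination (1.2 ns) in competition with slow side electron transfer
#'     from a tyrosine (default 15 ns within the stated 10-20 ns window);
#'     the resulting flavin-anion/Tyr pair recombines in 2.7 ms.}
#'   \item{`Y345F`}{as WT without the Tyr branch; the flavin-anion/Trp pair
#'     recombines with the observed 250 us.}
#'   \item{`WT_cysteine`}{WT plus scavenging of the Trp/Tyr radicals by
#'     cysteine (rate `k_scav * cysteine_M`), leaving an isolated flavin anion
#'     radical that is protonated to the neutral radical; a static 15\%
#'     subpopulation (second set of initial states) protonates fast (2.2 ms),
#'     the rest slow (630 ms). With `cysteine_M = 0` the WT scheme is
#'     returned, so trajectories are identical to WT.}
#' }
#'
#' @param variant one of `"WT"`, `"WT_D2O"`, `"E387Q"`, `"W388F"`, `"Y345F"`,
#'   `"WT_cysteine"`.
#' @param cysteine_M cysteine concentration in M (used by `WT_cysteine`;
#'   default 0.3).
#' @param ... named overrides of the default parameters (see
#'   `photokin:::preset_defaults()` for names), e.g. `tau_side_et = 10e-9`.
#' @return A `kinetic_scheme` with attribute `"generating_taus"` listing the
#'   observable time constants the scheme implies (used by pipeline
#'   summaries).
#' @export
preset_scheme <- function(variant = c("WT", "WT_D2O", "E387Q", "W388F",
                                      "Y345F", "WT_cysteine"),
                          cysteine_M = 0.3, ...) {
  variant <- match.arg(variant)
  par <- utils::modifyList(preset_defaults(), list(...))
  sp <- list(excited = "FAD_ox",
             pair_TrpH = c("FAD_radanion", "TrpH_cat"),
             pair_Trp  = c("FAD_radanion", "Trp_rad"),
             pair_Tyr  = c("FAD_radanion", "Tyr_rad"),
             ground = "FAD_ox")
  k_form <- 1 / par$tau_formation
  wt_like <- function(tau_dep, tau_rec1, tau_rec2, tau_tyr_ox, tau_rec3, id) {
    sc <- kinetic_scheme(
      states = c("excited", "pair_TrpH", "pair_Trp", "pair_Tyr", "ground"),
      species = sp,
      transitions = data.frame(
        from = c("excited", "excited", "pair_TrpH", "pair_TrpH",
                 "pair_Trp", "pair_Trp", "pair_Tyr"),
        to   = c("pair_TrpH", "ground", "pair_Trp", "ground",
                 "ground", "pair_Tyr", "ground"),
        rate = c(par$pair_yield * k_form, (1 - par$pair_yield) * k_form,
                 1 / tau_dep, 1 / tau_rec1,
                 1 / tau_rec2, 1 / tau_tyr_ox, 1 / tau_rec3)),
      initial = c(excited = 1), ground = "ground", id = id)
    attr(sc, "generating_taus") <- c(
      fast_ps = 1 / (1 / tau_dep + 1 / tau_rec1),
      recomb_fast = 1 / (1 / tau_rec2 + 1 / tau_tyr_ox),
      recomb_slow = tau_rec3)
    sc
  }
  if (variant == "WT")
    return(wt_like(par$tau_dep, par$tau_rec1, par$tau_rec2,
                   par$tau_tyr_ox, par$tau_rec3, "WT"))
  if (variant == "WT_D2O") {
    k_dep_D <- 1 / par$tau_dep_D2O - 1 / par$tau_rec1
    if (k_dep_D <= 0) stop("D2O observed phase slower than the recombination limit")
    return(wt_like(1 / k_dep_D, par$tau_rec1, par$tau_rec2,
                   par$tau_tyr_ox, par$tau_rec3, "WT_D2O"))
  }
  if (variant == "E387Q") {
    k_dep <- 1 / par$tau_obs_E387Q - 1 / par$tau_rec1
    if (k_dep <= 0) stop("E387Q observed phase slower than the recombination limit")
    return(wt_like(1 / k_dep, par$tau_rec1, par$tau_rec2,
                   par$tau_tyr_ox, par$tau_rec3, "E387Q"))
  }
  if (variant == "W388F") {
    sc <- kinetic_scheme(
      states = c("excited", "pair_TrpH", "pair_Tyr", "ground"),
      species = sp[c("excited", "pair_TrpH", "pair_Tyr", "ground")],
      transitions = data.frame(
        from = c("excited", "excited", "pair_TrpH", "pair_TrpH", "pair_Tyr"),
        to   = c("pair_TrpH", "ground", "ground", "pair_Tyr", "ground"),
        rate = c(par$pair_yield_W388F * k_form,
                 (1 - par$pair_yield_W388F) * k_form,
                 1 / par$tau_rec_W388F, 1 / par$tau_side_et,
                 1 / par$tau_rec3_W388F)),
      initial = c(excited = 1), ground = "ground", id = "W388F")
    attr(sc, "generating_taus") <- c(
      fast_ps = 1 / (1 / par$tau_rec_W388F + 1 / par$tau_side_et),
      recomb_slow = par$tau_rec3_W388F,
      tyr_pair_yield = par$pair_yield_W388F *
        branching_fraction(1 / par$tau_side_et,
                           c(1 / par$tau_rec_W388F, 1 / par$tau_side_et)))
    return(sc)
  }
  if (variant == "Y345F") {
    sc <- kinetic_scheme(
      states = c("excited", "pair_TrpH", "pair_Trp", "ground"),
      species = sp[c("excited", "pair_TrpH", "pair_Trp", "ground")],
      transitions = data.frame(
        from = c("excited", "excited", "pair_TrpH", "pair_TrpH", "pair_Trp"),
        to   = c("pair_TrpH", "ground", "pair_Trp", "ground", "ground"),
        rate = c(par$pair_yield * k_form, (1 - par$pair_yield) * k_form,
                 1 / par$tau_dep, 1 / par$tau_rec1, 1 / par$tau_rec_Y345F)),
      initial = c(excited = 1), ground = "ground", id = "Y345F")
    attr(sc, "generating_taus") <- c(
      fast_ps = 1 / (1 / par$tau_dep + 1 / par$tau_rec1),
      recomb = par$tau_rec_Y345F)
    return(sc)
  }
  # WT_cysteine: two static subpopulations (slow / fast flavin protonation)
  if (cysteine_M < 0) stop("cysteine_M must be non-negative")
  if (cysteine_M == 0) {
    sc <- wt_like(par$tau_dep, par$tau_rec1, par$tau_rec2,
                  par$tau_tyr_ox, par$tau_rec3, "WT_cysteine")
    return(sc)
  }
  k_sc <- par$k_scav * cysteine_M
  pools <- list(s = list(w = 1 - par$fast_fraction, tau_prot = par$tau_prot_slow),
                f = list(w = par$fast_fraction, tau_prot = par$tau_prot_fast))
  states <- "ground"; species2 <- list(ground = "FAD_ox")
  tr <- NULL; init <- c()
  for (nm in names(pools)) {
    pl <- pools[[nm]]
    st <- paste0(c("excited", "pair_TrpH", "pair_Trp", "pair_Tyr",
                   "radical", "FADH"), "_", nm)
    states <- c(states, st)
    species2[st] <- list("FAD_ox", c("FAD_radanion", "TrpH_cat"),
                         c("FAD_radanion", "Trp_rad"),
                         c("FAD_radanion", "Tyr_rad"),
                         "FAD_radanion", "FADH_rad")
    tr <- rbind(tr, data.frame(
      from = c(st[1], st[1], st[2], st[2], st[3], st[3], st[4],
               st[3], st[4], st[5]),
      to   = c(st[2], "ground", st[3], "ground", "ground", st[4], "ground",
               st[5], st[5], st[6]),
      rate = c(par$pair_yield * k_form, (1 - par$pair_yield) * k_form,
               1 / par$tau_dep, 1 / par$tau_rec1,
               1 / par$tau_rec2, 1 / par$tau_tyr_ox, 1 / par$tau_rec3,
               k_sc, k_sc, 1 / pl$tau_prot)))
    init[st[1]] <- pl$w
  }
  sc <- kinetic_scheme(states, species2, tr, init, ground = "ground",
                       id = sprintf("WT_cysteine_%gM", cysteine_M))
  attr(sc, "generating_taus") <- c(
    fast_ps = 1 / (1 / par$tau_dep + 1 / par$tau_rec1),
    tau_scav = 1 / k_sc,
    prot_slow = par$tau_prot_slow, prot_fast = par$tau_prot_fast)
  sc
}

# --- time-unit helpers and scheme config serialization -----------------------

time_units <- c(ps = 1e-12, ns = 1e-9, us = 1e-6, ms = 1e-3, s = 1)

#' Parse and format times with ps/ns/us/ms/s units
#'
#' `parse_time("350ps")` gives `3.5e-10`; `format_time(3.5e-10)` gives
#' `"350ps"`. `"µs"` is accepted as a synonym of `"us"`.
#'
#' @param x character vector like `"350ps"`, `"1.1ms"` (`parse_time`) or
#'   numeric seconds (`format_time`).
#' @return Numeric seconds, or a character rendering.
#' @export
parse_time <- function(x) {
  x <- gsub("µ|μ", "u", trimws(x))  # micro sign or Greek mu
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*(ps|ns|us|ms|s)$", x))
  vapply(m, function(p) {
    if (length(p) != 3L) stop("cannot parse time value: ", paste(p, collapse = ""))
    as.numeric(p[2]) * time_units[[p[3]]]
  }, 0)
}

#' @rdname parse_time
#' @param digits significant digits used by `format_time`.
#' @export
format_time <- function(x, digits = 6) {
  vapply(x, function(v) {
    if (v == 0) return("0s")
    u <- names(time_units)[max(1, findInterval(abs(v), time_units * 0.9999))]
    paste0(trimws(formatC(v / time_units[[u]], digits = digits, format = "g")), u)
  }, "")
}

#' Read / write a kinetic scheme as structured text
#'
#' Key-value lines: `id:`, `ground:`, one `state <name> : species = A + B` per
#' state, one `init <name> = <p>` per populated state, and one
#' `<from> -> <to> : tau = <value><unit>` per transition (units ps/ns/us/ms/s).
#' The round trip `read(write(x))` reproduces the scheme losslessly (rates to
#' full double precision via the canonical number rendering).
#'
#' @param scheme a `kinetic_scheme`.
#' @param path file path.
#' @return `read_scheme_config` returns a `kinetic_scheme`;
#'   `write_scheme_config` returns `path` invisibly.
#' @export
write_scheme_config <- function(scheme, path) {
  lines <- c(sprintf("id: %s", scheme$id), sprintf("ground: %s", scheme$ground))
  for (st in scheme$states)
    lines <- c(lines, sprintf("state %s : species = %s", st,
                              paste(scheme$species[[st]], collapse = " + ")))
  ip <- scheme$initial[scheme$initial != 0]
  lines <- c(lines, sprintf("init %s = %s", names(ip), num_txt(ip)))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    tau <- 1 / tr$rate[i]
    u <- names(time_units)[max(1, findInterval(tau, time_units * 0.9999))]
    lines <- c(lines, sprintf("%s -> %s : tau = %s%s", tr$from[i], tr$to[i],
                              num_txt(tau / time_units[[u]]), u))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scheme_config
#' @export
read_scheme_config <- function(path) {
  if (!file.exists(path)) stop("scheme config not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  id <- sub("^id: ", "", grep("^id: ", lines, value = TRUE)[1])
  ground <- sub("^ground: ", "", grep("^ground: ", lines, value = TRUE)[1])
  st_lines <- grep("^state ", lines, value = TRUE)
  m <- regmatches(st_lines, regexec("^state (\\S+) : species = (.*)$", st_lines))
  states <- vapply(m, `[`, "", 2L)
  species <- stats::setNames(lapply(m, function(p)
    trimws(strsplit(p[3], "\\+")[[1]])), states)
  in_lines <- grep("^init ", lines, value = TRUE)
  m <- regmatches(in_lines, regexec("^init (\\S+) = (\\S+)$", in_lines))
  initial <- stats::setNames(vapply(m, function(p) as.numeric(p[3]), 0),
                             vapply(m, `[`, "", 2L))
  tr_lines <- grep("->", lines, value = TRUE, fixed = TRUE)
  m <- regmatches(tr_lines, regexec("^(\\S+) -> (\\S+) : tau = (\\S+)$", tr_lines))
  transitions <- data.frame(
    from = vapply(m, `[`, "", 2L), to = vapply(m, `[`, "", 3L),
    tau = parse_time(vapply(m, `[`, "", 4L)), stringsAsFactors = FALSE)
  kinetic_scheme(states, species, transitions, initial, ground = ground, id = id)
}
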