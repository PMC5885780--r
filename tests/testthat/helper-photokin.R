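# shared fixtures, built in code

the_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- spectra_registry()
    reg
  }
})

pair_candidates <- function(reg = the_registry()) {
  list(
    "FAD_radanion+TrpH_cat" =
      difference_spectrum(c("FAD_radanion", "TrpH_cat"), "FAD_ox", reg),
    "FAD_radanion+Trp_rad" =
      difference_spectrum(c("FAD_radanion", "Trp_rad"), "FAD_ox", reg),
    "FAD_radanion+Tyr_rad" =
      difference_spectrum(c("FAD_radanion", "Tyr_rad"), "FAD_ox", reg))
}

# a minimal two-state decay A -> B, tau given
two_state <- function(tau = 1, species_A = "FAD_radanion",
                      species_B = "FAD_ox") {
  kinetic_scheme(
    states = c("A", "B"),
    species = list(A = species_A, B = species_B),
    transitions = data.frame(from = "A", to = "B", rate = 1 / tau),
    initial = c(A = 1), ground = "B", id = "two_state")
}

# radical pair with two parallel exits (deprotonation vs recombination)
pair_branching <- function(tau_dep = 350e-12 / 0.85,
                           tau_rec = 350e-12 / 0.15) {
  kinetic_scheme(
    states = c("pair", "product", "ground"),
    species = list(pair = c("FAD_radanion", "TrpH_cat"),
                   product = c("FAD_radanion", "Trp_rad"),
                   ground = "FAD_ox"),
    transitions = data.frame(from = c("pair", "pair"),
                             to = c("product", "ground"),
                             rate = c(1 / tau_dep, 1 / tau_rec)),
    initial = c(pair = 1), ground = "ground", id = "pair_branching")
}

ms_setup_wt <- function(seed = 7L, wavelengths = c(408, 450, 540, 562)) {
  instrument_setup("ms_s", wavelengths = wavelengths,
                   time_grid = 10^seq(log10(5e-5), log10(2e-2),
                                      length.out = 300),
                   seed = seed)
}

all_presets <- function() {
  list(WT = preset_scheme("WT"),
       WT_D2O = preset_scheme("WT_D2O"),
       E387Q = preset_scheme("E387Q"),
       W388F = preset_scheme("W388F"),
       Y345F = preset_scheme("Y345F"),
       WT_cys = preset_scheme("WT_cysteine", cysteine_M = 0.3))
}
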