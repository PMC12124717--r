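# Embedded element tables. Covalent radii follow the Cordero single-bond
# compilation (high-spin values for Mn/Fe/Co); masses are standard atomic
# weights; the UFF table carries the nonbonded vdW distance x (Å, position of
# the LJ minimum) and well depth D (kcal/mol) for the metals this package
# parametrizes. All lookups are by element symbol, case-sensitive.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm")

.atomic_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 98.0, 101.07, 102.906, 106.42, 107.868, 112.414, 114.818, 118.710,
  121.760, 127.60, 126.904, 131.293, 132.905, 137.327, 138.905, 140.116, 140.908, 144.242,
  145.0, 150.36, 151.964, 157.25, 158.925, 162.500, 164.930, 167.259, 168.934, 173.045,
  174.967, 178.49, 180.948, 183.84, 186.207, 190.23, 192.217, 195.084, 196.967, 200.592,
  204.38, 207.2, 208.980, 209.0, 210.0, 222.0, 223.0, 226.0, 227.0, 232.038,
  231.036, 238.029, 237.0, 244.0, 243.0, 247.0)

.covalent_radii <- c(
  0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
  1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
  1.70, 1.60, 1.53, 1.39, 1.61, 1.52, 1.50, 1.24, 1.32, 1.22,
  1.22, 1.20, 1.19, 1.20, 1.20, 1.16, 2.20, 1.95, 1.90, 1.75,
  1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44, 1.42, 1.39,
  1.39, 1.38, 1.39, 1.40, 2.44, 2.15, 2.07, 2.04, 2.03, 2.01,
  1.99, 1.98, 1.98, 1.96, 1.94, 1.92, 1.92, 1.89, 1.90, 1.87,
  1.87, 1.75, 1.70, 1.62, 1.51, 1.44, 1.41, 1.36, 1.36, 1.32,
  1.45, 1.46, 1.48, 1.40, 1.50, 1.50, 2.60, 2.21, 2.15, 2.06,
  2.00, 1.96, 1.90, 1.87, 1.80, 1.69)

# Alkali, alkaline-earth, transition and post-transition metals,
# lanthanides and actinides. Metalloids (B, Si, Ge, As, Sb, Te) excluded.
.metal_elements <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Cs", "Ba",
  "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
  "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
  "Po", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm")

# UFF nonbonded parameters for metals: x = vdW distance at the energy
# minimum (Å), d = well depth (kcal/mol).
.uff_metal_lj <- local({
  tab <- matrix(c(
    2.451, 0.025,  # Li
    2.745, 0.085,  # Be
    2.983, 0.030,  # Na
    3.021, 0.111,  # Mg
    4.499, 0.505,  # Al
    3.812, 0.035,  # K
    3.399, 0.238,  # Ca
    3.295, 0.019,  # Sc
    3.175, 0.017,  # Ti
    3.144, 0.016,  # V
    3.023, 0.015,  # Cr
    2.961, 0.013,  # Mn
    2.912, 0.013,  # Fe
    2.872, 0.014,  # Co
    2.834, 0.015,  # Ni
    3.495, 0.005,  # Cu
    2.763, 0.124,  # Zn
    4.383, 0.415,  # Ga
    4.114, 0.040,  # Rb
    3.641, 0.235,  # Sr
    3.345, 0.072,  # Y
    3.124, 0.069,  # Zr
    3.165, 0.059,  # Nb
    3.052, 0.056,  # Mo
    2.998, 0.048,  # Tc
    2.963, 0.056,  # Ru
    2.929, 0.053,  # Rh
    2.899, 0.048,  # Pd
    3.148, 0.036,  # Ag
    2.848, 0.228,  # Cd
    4.463, 0.599,  # In
    4.392, 0.567,  # Sn
    4.517, 0.045,  # Cs
    3.703, 0.364,  # Ba
    3.522, 0.017,  # La
    3.556, 0.013,  # Ce
    3.535, 0.010,  # Nd
    3.487, 0.008,  # Eu
    3.368, 0.009,  # Gd
    3.451, 0.007,  # Tb
    3.428, 0.007,  # Dy
    3.409, 0.007,  # Ho
    3.391, 0.007,  # Er
    3.374, 0.006,  # Tm
    3.355, 0.228,  # Yb
    3.640, 0.041,  # Lu
    3.141, 0.072,  # Hf
    3.170, 0.081,  # Ta
    3.069, 0.067,  # W
    2.954, 0.066,  # Re
    3.120, 0.037,  # Os
    2.840, 0.073,  # Ir
    2.754, 0.080,  # Pt
    3.293, 0.039,  # Au
    2.705, 0.385,  # Hg
    4.347, 0.680,  # Tl
    4.297, 0.663,  # Pb
    4.370, 0.518,  # Bi
    3.395, 0.026,  # Th
    3.395, 0.022), # U
    ncol = 2, byrow = TRUE)
  rownames(tab) <- c(
    "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
    "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo",
    "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Cs", "Ba", "La", "Ce",
    "Nd", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta",
    "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Th", "U")
  colnames(tab) <- c("x", "d")
  tab
})

# Element-level Lennard-Jones fallback for organic atoms whose type has no
# NONBON entry in the database (GAFF-like values; R_min/2 in Å, eps kcal/mol).
.organic_lj_fallback <- local({
  tab <- matrix(c(
    1.4870, 0.0157,  # H
    1.9080, 0.0860,  # C
    1.8240, 0.1700,  # N
    1.6612, 0.2100,  # O
    1.7500, 0.0610,  # F
    2.1000, 0.2000,  # P
    2.0000, 0.2500,  # S
    1.9480, 0.2650,  # Cl
    2.2200, 0.3200,  # Br
    2.3500, 0.4240,  # I
    1.1100, 0.0570,  # B
    2.1475, 0.4000), # Si
    ncol = 2, byrow = TRUE)
  rownames(tab) <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
                     "B", "Si")
  colnames(tab) <- c("rmin_half", "eps")
  tab
})

#' Element property lookups
#'
#' Small helpers over the embedded element tables: atomic number, standard
#' atomic weight, single-bond covalent radius (Å) and metal classification.
#'
#' @param symbol Character vector of element symbols (case-sensitive,
#'   e.g. `"Ru"`).
#' @return `element_number()` returns integer atomic numbers;
#'   `element_mass()` and `covalent_radius()` numeric vectors;
#'   `is_metal_element()` a logical vector.
#' @examples
#' element_number("Ru")
#' covalent_radius(c("Ru", "N"))
#' is_metal_element(c("C", "Fe"))
#' @export
element_number <- function(symbol) {
  idx <- match(symbol, .element_symbols)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' @rdname element_number
#' @export
element_mass <- function(symbol) {
  .atomic_masses[element_number(symbol)]
}

#' @rdname element_number
#' @export
covalent_radius <- function(symbol) {
  .covalent_radii[element_number(symbol)]
}

#' @rdname element_number
#' @export
is_metal_element <- function(symbol) {
  element_number(symbol) # validates
  symbol %in% .metal_elements
}
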