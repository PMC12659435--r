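#' @keywords internal
#' Element tables for the restricted small-molecule chemistry supported by
#' the package: C, N, H, O, P, S, Cl, Br, F, I and B.

# monoisotopic masses of the most abundant isotope (Da)
.MONO_MASS <- c(
  H  = 1.00782503207,
  B  = 11.0093054,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473
)

# mass of a proton; used for [M-H]- adduct arithmetic
.PROTON_MASS <- 1.007276

# allowed heavy elements (hydrogen handled implicitly)
.ALLOWED_ELEMENTS <- c("C", "N", "H", "O", "P", "S", "Cl", "Br", "F", "I", "B")

# default valence ladders used to fill implicit hydrogens
.VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

# elements that may be written lowercase (aromatic) in SMILES
.AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")
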