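# Monoisotopic mass constants used throughout the package.
# Residue masses are the standard IUPAC monoisotopic values to six decimals.

#' Monoisotopic mass constants
#'
#' Returns the set of mass constants used by all peptide arithmetic in the
#' package: monoisotopic residue masses for the 20 canonical amino acids,
#' the masses of water and a proton, the formaldehyde linker mass and any
#' fixed modifications.
#'
#' The formaldehyde cross-link is a methylene bridge: the net addition to a
#' linked peptide pair is CH2O minus H2O, i.e. exactly 12 Da (monoisotopic
#' carbon). A doubly bridged pair carries +24 Da.
#'
#' @param fixed_mods Named numeric vector of fixed modification masses keyed
#'   by residue letter. Default is carbamidomethylation of cysteine
#'   (+57.021464 Da), the standard alkylation adduct from chloroacetamide
#'   sample preparation. Use `c()` to disable all fixed modifications.
#' @return A list with components `residue_monoisotopic` (named numeric,
#'   Da), `water`, `proton`, `co` (carbon monoxide, for a-ions),
#'   `linker_single`, `linker_double` (Da) and `fixed_mods`.
#' @examples
#' const <- mass_constants()
#' const$linker_single  # 12
#' @export
mass_constants <- function(fixed_mods = c(C = 57.021464)) {
  residues <- c(
    G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
    V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
  linker <- 12.0  # monoisotopic CH2O - H2O = 12C exactly
  if (length(fixed_mods) && (is.null(names(fixed_mods)) ||
        !all(names(fixed_mods) %in% names(residues))))
    stop("fixed_mods must be named by canonical residue letters")
  list(
    residue_monoisotopic = residues,
    water  = 18.010565,
    proton =  1.007276,
    co     = 27.994915,
    linker_single = linker,
    linker_double = 2 * linker,
    fixed_mods = fixed_mods
  )
}

#' Formaldehyde linker mass computed from elemental monoisotopic masses
#'
#' Computes the net mass added per methylene bridge from first principles:
#' monoisotopic CH2O (formaldehyde) minus H2O (the water lost on
#' condensation), i.e. 12C + 2(1H) + 16O - 2(1H) - 16O.
#'
#' @param n_links Number of bridges (1 or 2).
#' @return Mass in Da (12 for one bridge, 24 for two).
#' @export
linker_mass <- function(n_links = 1L) {
  stopifnot(n_links >= 1)
  h <- 1.0078250319
  o <- 15.9949146221
  c12 <- 12.0
  n_links * ((c12 + 2 * h + o) - (2 * h + o))
}
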