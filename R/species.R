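# Species/redox data model and spin diagnostics.
#
# The study system: 12 iron coordination complexes mimicking protein
# coordination shells (water plus one amino-acid-side-chain ligand), each in
# the Fe(II) and Fe(III) oxidation states.  The quantity of interest is the
# electronic component of the reduction energy at 0 K,
# dE_elec = E(Fe II complex) - E(Fe III complex).

#' Canonical complex labels and ligand groups
#'
#' The 12 model complexes, in canonical report order: the all-water series
#' (group A, coordination numbers 1, 2, 4, 6), the tetrahedral one-side-chain
#' series (group B) and the octahedral one-side-chain series (group C).
#' Ligand abbreviations: CH3O- methoxide (serine), CH3S- methanethiolate
#' (cysteine), NH2CH3 methylamine (lysine), HCOO- formate
#' (aspartate/glutamate).
#'
#' @return `iron_complexes()` returns a data frame with columns `complex_id`,
#'   `group` (A/B/C) and `ligand_charge_sum`; `complex_groups()` returns a
#'   named list of the three 4-complex groups.
#' @export
iron_complexes <- function() {
  data.frame(
    complex_id = c(
      "Fe(H2O)", "Fe(H2O)2", "Fe(H2O)4", "Fe(H2O)6",
      "Fe(H2O)3(CH3O-)", "Fe(H2O)3(CH3S-)", "Fe(H2O)3(NH2CH3)",
      "Fe(H2O)3(HCOO-)",
      "Fe(H2O)5(CH3O-)", "Fe(H2O)5(CH3S-)", "Fe(H2O)5(NH2CH3)",
      "Fe(H2O)5(HCOO-)"
    ),
    group = rep(c("A", "B", "C"), each = 4L),
    ligand_charge_sum = c(0L, 0L, 0L, 0L,
                          -1L, -1L, 0L, -1L,
                          -1L, -1L, 0L, -1L),
    stringsAsFactors = FALSE
  )
}

#' @rdname iron_complexes
#' @export
complex_groups <- function() {
  ic <- iron_complexes()
  split(ic$complex_id, ic$group)
}

#' One complex in one oxidation/spin state
#'
#' @param complex_id complex label (free text; the 12 canonical labels are in
#'   [iron_complexes()]).
#' @param oxidation_state `"II"` or `"III"`.
#' @param spin_multiplicity 2S+1; the states considered are quintet (5) or
#'   singlet (1) for Fe(II), sextet (6) or doublet (2) for Fe(III).
#' @param ligand_charge_sum summed formal charge of the ligands.
#' @return A `species_state` list with the fields above plus `total_charge`
#'   (= metal charge + ligand charge sum).
#' @export
species_state <- function(complex_id, oxidation_state,
                          spin_multiplicity = if (oxidation_state == "II") 5L else 6L,
                          ligand_charge_sum = 0L) {
  oxidation_state <- match.arg(oxidation_state, c("II", "III"))
  allowed <- if (oxidation_state == "II") c(1L, 5L) else c(2L, 6L)
  if (!spin_multiplicity %in% allowed) {
    stop("spin multiplicity ", spin_multiplicity, " not considered for Fe(",
         oxidation_state, "); allowed: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  metal_charge <- if (oxidation_state == "II") 2L else 3L
  structure(
    list(complex_id = as.character(complex_id),
         oxidation_state = oxidation_state,
         spin_multiplicity = as.integer(spin_multiplicity),
         ligand_charge_sum = as.integer(ligand_charge_sum),
         total_charge = metal_charge + as.integer(ligand_charge_sum)),
    class = "species_state"
  )
}

#' An oxidized/reduced pair of the same complex
#'
#' @param oxidized,reduced [species_state()] objects sharing `complex_id`,
#'   with charges differing by one electron.
#' @return A `redox_couple` list.
#' @export
redox_couple <- function(oxidized, reduced) {
  stopifnot(inherits(oxidized, "species_state"),
            inherits(reduced, "species_state"))
  if (oxidized$complex_id != reduced$complex_id) {
    stop("oxidized and reduced species must share a complex_id", call. = FALSE)
  }
  if (oxidized$total_charge - reduced$total_charge != 1L) {
    stop("charge(oxidized) - charge(reduced) must be 1", call. = FALSE)
  }
  structure(list(oxidized = oxidized, reduced = reduced,
                 complex_id = oxidized$complex_id),
            class = "redox_couple")
}

#' Expected spin-squared value for a pure spin state
#'
#' For multiplicity 2S+1 a pure spin state has <S^2> = S(S+1): 6.0 for a
#' quintet (high-spin Fe II) and 8.75 for a sextet (high-spin Fe III).
#'
#' @param multiplicity positive integer 2S+1.
#' @return S(S+1) as a numeric.
#' @examples
#' expected_s2(5) # 6
#' expected_s2(6) # 8.75
#' @export
expected_s2 <- function(multiplicity) {
  if (!is.numeric(multiplicity) || any(multiplicity < 1) ||
      any(multiplicity != as.integer(multiplicity))) {
    stop("`multiplicity` must be a positive integer (2S+1)", call. = FALSE)
  }
  s <- (multiplicity - 1) / 2
  s * (s + 1)
}

#' Flag a spin-contaminated wavefunction
#'
#' Compares an observed <S^2> against the pure-state expectation.  The default
#' tolerance 0.05 passes the pre-annihilation deviations typical of
#' high-spin iron complexes (~0.01) while flagging genuinely contaminated
#' wavefunctions.
#'
#' @param observed_s2 observed <S^2>.
#' @param multiplicity nominal 2S+1.
#' @param tol positive tolerance on |observed - expected|.
#' @return `TRUE` if contaminated (deviation exceeds `tol`).
#' @export
contamination_flag <- function(observed_s2, multiplicity, tol = 0.05) {
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  abs(observed_s2 - expected_s2(multiplicity)) > tol
}

#' Pick the ground spin state from candidate energies
#'
#' Returns the multiplicity whose energy is lowest.  Exact ties are broken
#' toward the larger multiplicity (high-spin), the ground state found for all
#' the iron complexes considered here.
#'
#' @param candidates named numeric vector or named list of [quantity()]
#'   energies; names are multiplicities.
#' @return The ground-state multiplicity as an integer.
#' @export
select_ground_multiplicity <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidate spin states", call. = FALSE)
  mult <- as.integer(names(candidates))
  if (anyNA(mult)) stop("candidate names must be multiplicities", call. = FALSE)
  if (is.list(candidates)) {
    units <- vapply(candidates, qty_unit, character(1))
    if (length(unique(units)) > 1L) {
      stop("candidate energies must share a unit", call. = FALSE)
    }
    e <- vapply(candidates, qty_value, numeric(1))
  } else {
    e <- as.numeric(candidates)
  }
  best <- which(e == min(e))
  mult[best][which.max(mult[best])]
}

#' Electronic reduction energy of a redox couple
#'
#' dE_elec = E(reduced) - E(oxidized): the electronic component of the
#' reduction energy at 0 K.  For gas-phase cationic iron complexes this is
#' large and negative (electron attachment to a cation is strongly
#' favourable).
#'
#' @param e_reduced,e_oxidized [quantity()] energies in the same unit.
#' @return A `quantity`: `e_reduced - e_oxidized`.
#' @export
delta_e_redox <- function(e_reduced, e_oxidized) {
  if (!is_quantity(e_reduced) || !is_quantity(e_oxidized)) {
    stop("energies must be quantities", call. = FALSE)
  }
  e_reduced - e_oxidized
}
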