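#' Enumerate the assignable atoms of a protein
#'
#' Expands a sequence into its full complement of assignable
#' \eqn{^1}H/\eqn{^{13}}C/\eqn{^{15}}N atoms using the standard residue
#' topology. Prolines carry no amide proton; the chain-initial residue
#' carries no assignable amide proton either (N-terminal ammonium).
#'
#' @param sequence Sequence tibble from [protein_sequence()].
#' @param nterm Is the first row of `sequence` a true chain terminus? By
#'   default this is inferred from the numbering: a sequence starting at
#'   residue number 1 is treated as the chain start, anything else as an
#'   internal fragment (whose first residue keeps its HN).
#' @return Tibble (one row per atom) with columns `residue_number`,
#'   `residue_type`, `atom_name`, `nucleus`, `element`, `parent`,
#'   `hybrid`, `aliphatic`.
#' @export
#' @examples
#' enumerate_atoms(protein_sequence("APA"))
enumerate_atoms <- function(sequence,
                            nterm = sequence$residue_number[1] == 1L) {
  check_sequence(sequence)
  topo <- residue_topology()
  atoms <- dplyr::inner_join(sequence, topo, by = "residue_type",
                             relationship = "many-to-many")
  atoms <- dplyr::filter(atoms, .data$assignable)
  if (isTRUE(nterm)) {
    atoms <- dplyr::filter(atoms,
      !(.data$residue_number == sequence$residue_number[1] &
          .data$atom_name == "HN"))
  }
  dplyr::select(atoms, "residue_number", "residue_type", "atom_name",
                "nucleus", "element", "parent", "hybrid", "aliphatic")
}

# Stable atom key "residue_number:atom_name" used for indexing.
atom_key <- function(residue_number, atom_name) {
  paste0(residue_number, ":", atom_name)
}
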