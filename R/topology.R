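#' @importFrom rlang .data
#' @import tibble
NULL

# Three-letter codes of the 20 standard amino acids, with one-letter lookup.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.pkg_cache <- new.env(parent = emptyenv())

# Side-chain topology, one row per atom: name, parent, hybridisation.
# Hydroxyl/sulfhydryl and ammonium/guanidinium protons are not part of the
# assignable complement and are omitted entirely (neutral-pH convention);
# HIS is enumerated as the neutral N-delta-H tautomer.
.sidechain_defs <- list(
  ALA = c("CB CA sp3", "HB1 CB -", "HB2 CB -", "HB3 CB -"),
  ARG = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp3", "HG2 CG -",
          "HG3 CG -", "CD CG sp3", "HD2 CD -", "HD3 CD -", "NE CD sp2",
          "HE NE -", "CZ NE sp2", "NH1 CZ sp2", "NH2 CZ sp2"),
  ASN = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp2", "OD1 CG -",
          "ND2 CG sp2", "HD21 ND2 -", "HD22 ND2 -"),
  ASP = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp2", "OD1 CG -",
          "OD2 CG -"),
  CYS = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "SG CB sp3"),
  GLN = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp3", "HG2 CG -",
          "HG3 CG -", "CD CG sp2", "OE1 CD -", "NE2 CD sp2", "HE21 NE2 -",
          "HE22 NE2 -"),
  GLU = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp3", "HG2 CG -",
          "HG3 CG -", "CD CG sp2", "OE1 CD -", "OE2 CD -"),
  GLY = character(0),
  HIS = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp2", "ND1 CG sp2",
          "HD1 ND1 -", "CE1 ND1 sp2", "HE1 CE1 -", "NE2 CE1 sp2",
          "CD2 NE2 sp2", "HD2 CD2 -"),
  ILE = c("CB CA sp3", "HB CB -", "CG1 CB sp3", "HG12 CG1 -", "HG13 CG1 -",
          "CD1 CG1 sp3", "HD11 CD1 -", "HD12 CD1 -", "HD13 CD1 -",
          "CG2 CB sp3", "HG21 CG2 -", "HG22 CG2 -", "HG23 CG2 -"),
  LEU = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp3", "HG CG -",
          "CD1 CG sp3", "HD11 CD1 -", "HD12 CD1 -", "HD13 CD1 -",
          "CD2 CG sp3", "HD21 CD2 -", "HD22 CD2 -", "HD23 CD2 -"),
  LYS = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp3", "HG2 CG -",
          "HG3 CG -", "CD CG sp3", "HD2 CD -", "HD3 CD -", "CE CD sp3",
          "HE2 CE -", "HE3 CE -", "NZ CE sp3"),
  MET = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp3", "HG2 CG -",
          "HG3 CG -", "SD CG sp3", "CE SD sp3", "HE1 CE -", "HE2 CE -",
          "HE3 CE -"),
  PHE = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp2", "CD1 CG sp2",
          "HD1 CD1 -", "CE1 CD1 sp2", "HE1 CE1 -", "CZ CE1 sp2", "HZ CZ -",
          "CD2 CG sp2", "HD2 CD2 -", "CE2 CD2 sp2", "HE2 CE2 -"),
  PRO = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp3", "HG2 CG -",
          "HG3 CG -", "CD CG sp3", "HD2 CD -", "HD3 CD -"),
  SER = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "OG CB sp3"),
  THR = c("CB CA sp3", "HB CB -", "OG1 CB sp3", "CG2 CB sp3", "HG21 CG2 -",
          "HG22 CG2 -", "HG23 CG2 -"),
  TRP = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp2", "CD1 CG sp2",
          "HD1 CD1 -", "NE1 CD1 sp2", "HE1 NE1 -", "CD2 CG sp2",
          "CE2 CD2 sp2", "CE3 CD2 sp2", "HE3 CE3 -", "CZ2 CE2 sp2",
          "HZ2 CZ2 -", "CZ3 CE3 sp2", "HZ3 CZ3 -", "CH2 CZ2 sp2",
          "HH2 CH2 -"),
  TYR = c("CB CA sp3", "HB2 CB -", "HB3 CB -", "CG CB sp2", "CD1 CG sp2",
          "HD1 CD1 -", "CE1 CD1 sp2", "HE1 CE1 -", "CZ CE1 sp2", "OH CZ -",
          "CD2 CG sp2", "HD2 CD2 -", "CE2 CD2 sp2", "HE2 CE2 -"),
  VAL = c("CB CA sp3", "HB CB -", "CG1 CB sp3", "HG11 CG1 -", "HG12 CG1 -",
          "HG13 CG1 -", "CG2 CB sp3", "HG21 CG2 -", "HG22 CG2 -",
          "HG23 CG2 -")
)

# 15N nuclei kept out of the assignable set (quaternary-amine / guanidinium).
.unassignable_atoms <- tibble::tribble(
  ~residue_type, ~atom_name,
  "ARG", "NH1",
  "ARG", "NH2",
  "LYS", "NZ"
)

#' Per-residue atom topology of the 20 standard amino acids
#'
#' Returns the covalent topology used throughout the package: one row per
#' atom of each residue type, with its element, parent atom (covalent bond
#' towards the backbone), hybridisation and whether it belongs to the
#' assignable \eqn{^1}H/\eqn{^{13}}C/\eqn{^{15}}N complement.
#'
#' The backbone complement is N, HN, CA, HA, C, O (glycine: HA2/HA3, no CB;
#' proline: no HN). Stereo protons are enumerated individually (HB2/HB3);
#' no pseudo-atom collapsing is performed. Hydroxyl, sulfhydryl, ammonium
#' and guanidinium protons are excluded.
#'
#' @return A tibble with columns `residue_type`, `atom_name`, `element`,
#'   `parent`, `hybrid`, `nucleus` (`1H`/`13C`/`15N` or `NA` for O/S),
#'   `assignable` (logical), `aliphatic` (logical; sp3 carbon).
#' @export
#' @examples
#' residue_topology() |> dplyr::filter(residue_type == "ALA")
residue_topology <- function() {
  if (!is.null(.pkg_cache$topology)) return(.pkg_cache$topology)
  backbone <- function(res) {
    rows <- list(
      c("N", "-", "sp2"),
      c("HN", "N", "-"),
      c("CA", "N", "sp3"),
      c("HA", "CA", "-"),
      c("C", "CA", "sp2"),
      c("O", "C", "-")
    )
    if (res == "GLY") {
      rows <- list(c("N", "-", "sp2"), c("HN", "N", "-"), c("CA", "N", "sp3"),
                   c("HA2", "CA", "-"), c("HA3", "CA", "-"), c("C", "CA", "sp2"),
                   c("O", "C", "-"))
    }
    if (res == "PRO") rows <- rows[!vapply(rows, function(r) r[1] == "HN", TRUE)]
    rows
  }
  all <- purrr::map_dfr(AA3, function(res) {
    sc <- strsplit(.sidechain_defs[[res]], "[ ]+")
    rows <- c(backbone(res), sc)
    tibble::tibble(
      residue_type = res,
      atom_name = vapply(rows, `[`, "", 1),
      parent = vapply(rows, `[`, "", 2),
      hybrid = vapply(rows, `[`, "", 3)
    )
  })
  all$parent[all$parent == "-"] <- NA_character_
  all$hybrid[all$hybrid == "-"] <- NA_character_
  all$element <- substr(all$atom_name, 1, 1)
  all$element[all$atom_name == "SD"] <- "S"
  all$element[all$atom_name == "SG"] <- "S"
  all$nucleus <- unname(c(H = "1H", C = "13C", N = "15N",
                          O = NA, S = NA)[all$element])
  excl <- paste(.unassignable_atoms$residue_type, .unassignable_atoms$atom_name)
  all$assignable <- !is.na(all$nucleus) &
    !(paste(all$residue_type, all$atom_name) %in% excl)
  all$aliphatic <- all$element == "C" & !is.na(all$hybrid) & all$hybrid == "sp3"
  .pkg_cache$topology <- all
  all
}

# Alias table for atom-name normalization across PDB/BMRB/CYANA dialects.
.atom_aliases <- c(
  "H" = "HN", "C'" = "C", "CO" = "C",
  "HA1" = "HA2", "1HA" = "HA2", "2HA" = "HA3",
  "HN1" = "HN", "HT1" = "HN"
)

#' Normalize an atom name to the package's canonical convention
#'
#' Maps common dialect variants (`H` for the amide proton, `C'`/`CO` for the
#' backbone carbonyl, `HA1` for glycine `HA2`, ...) onto the canonical names
#' used by [residue_topology()].
#'
#' @param atom_name Character vector of atom names.
#' @return Character vector of canonical names.
#' @export
normalize_atom_name <- function(atom_name) {
  hit <- unname(.atom_aliases[atom_name])
  ifelse(is.na(hit), atom_name, hit)
}

# Nucleus for a canonical atom name (vectorised, residue-independent).
nucleus_of <- function(atom_name) {
  el <- substr(atom_name, 1, 1)
  out <- c(H = "1H", C = "13C", N = "15N")[el]
  unname(out)
}

#' Magnetic equivalence groups of an atom set
#'
#' Returns a grouping key: atoms that share one resonance are given the
#' same key — the three protons of a methyl rotor, and the symmetry-pair
#' protons and carbons of fast-flipping PHE/TYR rings (HD1/HD2, HE1/HE2,
#' CD1/CD2, CE1/CE2). All other atoms are their own group.
#'
#' @param atom_set Atom tibble from [enumerate_atoms()].
#' @return Character vector of group keys, parallel to `atom_set` rows.
#' @export
equivalence_groups <- function(atom_set) {
  key <- atom_key(atom_set$residue_number, atom_set$atom_name)
  topo <- residue_topology()
  info <- dplyr::left_join(
    atom_set[, c("residue_type", "atom_name")],
    topo[, c("residue_type", "atom_name", "element", "parent")],
    by = c("residue_type", "atom_name"))
  # methyl protons: H whose parent carbon carries three H children
  hcount <- topo[topo$element == "H" & !is.na(topo$parent), ]
  n_h <- tapply(hcount$atom_name,
                paste(hcount$residue_type, hcount$parent), length)
  is_h <- info$element == "H" & !is.na(info$parent)
  pk <- paste(info$residue_type, info$parent)
  methyl <- is_h & !is.na(n_h[pk]) & n_h[pk] == 3
  key[methyl] <- atom_key(atom_set$residue_number[methyl],
                          paste0("Q", info$parent[methyl]))
  # fast-flipping aromatic rings: PHE/TYR symmetric pairs
  ring <- atom_set$residue_type %in% c("PHE", "TYR") &
    atom_set$atom_name %in% c("HD1", "HD2", "HE1", "HE2",
                              "CD1", "CD2", "CE1", "CE2")
  key[ring] <- atom_key(atom_set$residue_number[ring],
                        paste0(substr(atom_set$atom_name[ring], 1, 2), "*"))
  key
}
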