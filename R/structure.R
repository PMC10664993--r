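# Structure bundles: multi-conformer coordinate tables, inter-atomic
# distances, expected NOESY generation by the all-conformer distance rule,
# backbone RMSD, and PDB I/O.

#' Assemble a structure bundle from a coordinate table
#'
#' @param coords Tibble with columns `conformer`, `residue_number`,
#'   `residue_type`, `atom_name`, `x`, `y`, `z` (an `element` column is
#'   added if missing).
#' @param label Provenance tag: `experimental`, `predicted`, `random` or
#'   `decoy`. Metadata only; nothing downstream branches on it.
#' @return Structure-bundle tibble.
#' @export
structure_bundle <- function(coords, label = "experimental") {
  stopifnot(all(c("conformer", "residue_number", "atom_name",
                  "x", "y", "z") %in% names(coords)))
  if (nrow(coords) == 0) stop("empty bundle", call. = FALSE)
  coords$atom_name <- normalize_atom_name(coords$atom_name)
  if (!"element" %in% names(coords)) {
    coords$element <- ifelse(coords$atom_name %in% c("SD", "SG"), "S",
                             substr(coords$atom_name, 1, 1))
  }
  keysets <- tapply(atom_key(coords$residue_number, coords$atom_name),
                    coords$conformer, function(k) paste(sort(k), collapse = "|"))
  if (length(unique(keysets)) != 1) {
    stop("all conformers must share the same atom key set", call. = FALSE)
  }
  attr(coords, "label") <- label
  coords
}

# Coordinates of requested atom keys, one 3-column matrix per conformer,
# rows in key order. Errors name the missing atom and conformer.
bundle_xyz <- function(bundle, keys) {
  confs <- sort(unique(bundle$conformer))
  lapply(confs, function(cf) {
    sub <- bundle[bundle$conformer == cf, ]
    idx <- match(keys, atom_key(sub$residue_number, sub$atom_name))
    if (anyNA(idx)) {
      stop(sprintf("atom %s missing from conformer %d",
                   keys[which(is.na(idx))[1]], cf), call. = FALSE)
    }
    cbind(sub$x[idx], sub$y[idx], sub$z[idx])
  })
}

#' Maximal inter-atomic distance over the conformers of a bundle
#'
#' @param bundle Structure-bundle tibble.
#' @param a,b Atoms, given either as `"residue:atom"` key strings (e.g.
#'   `"5:HN"`) or as one-row tibbles with `residue_number` and `atom_name`.
#' @return Distance in Angstrom (max over conformers).
#' @export
max_distance <- function(bundle, a, b) {
  key_of <- function(x) {
    if (is.character(x)) x else atom_key(x$residue_number, x$atom_name)
  }
  xyz <- bundle_xyz(bundle, c(key_of(a), key_of(b)))
  max(vapply(xyz, function(m) sqrt(sum((m[1, ] - m[2, ])^2)), 0))
}

# Step function mapping a maximal distance to the tiered observation
# probability (0.9 below 4 A, then 0.8/0.7/0.6/0.5 in 0.5 A steps up to 6).
noesy_probability <- function(d_max) {
  p <- c(0.9, 0.8, 0.7, 0.6, 0.5)[findInterval(d_max, c(4, 4.5, 5, 5.5)) + 1]
  p[d_max >= 6] <- NA_real_
  p
}

#' Back-calculate expected NOESY cross peaks from a structure bundle
#'
#' Emits an expected cross peak for every proton pair whose distance is
#' below 6.0 Angstrom in all conformers of the bundle, with observation
#' probability 0.9 if the maximal distance is below 4 Angstrom, then 0.8,
#' 0.7, 0.6 and 0.5 in 0.5-Angstrom steps up to 6. For the 15N-edited
#' NOESY the detected proton is nitrogen-bound and the peak is
#' (H_x, N_i, HN_i); for the 13C-edited NOESY it is carbon-bound and the
#' peak is (H_x, C_j, H_j). Diagonal peaks (H_x equal to the detected
#' proton) are excluded; symmetric partners are both emitted unless
#' `collapse_symmetric`.
#'
#' @param bundle Structure-bundle tibble covering the protons of
#'   `atom_set` (missing protons are reported and their peaks skipped).
#' @param atom_set Atom tibble from [enumerate_atoms()].
#' @param spectrum NOESY spectrum name or definition row.
#' @param collapse_symmetric Emit only one of each symmetric pair.
#' @return Expected-peak tibble (`res1`/`atom1` = H_x, `res2`/`atom2` =
#'   edited heteroatom, `res3`/`atom3` = detected proton) with
#'   `probability` and `origin` in `noesy-short`/`noesy-medium`/`noesy-long`.
#' @export
expected_noesy <- function(bundle, atom_set, spectrum,
                           collapse_symmetric = FALSE) {
  sdef <- if (is.character(spectrum)) spectrum_definition(spectrum) else spectrum
  if (sdef$kind != "NOESY") stop("expected_noesy requires a NOESY spectrum",
                                 call. = FALSE)
  if (is.null(bundle) || nrow(bundle) == 0) stop("empty bundle", call. = FALSE)
  protons <- atom_set[atom_set$element == "H", ]
  pkey <- atom_key(protons$residue_number, protons$atom_name)
  bkey <- unique(atom_key(bundle$residue_number, bundle$atom_name))
  missing <- !pkey %in% bkey
  if (any(missing)) {
    warning(sprintf("%d protons missing from bundle; their peaks skipped",
                    sum(missing)), call. = FALSE)
    protons <- protons[!missing, ]
    pkey <- pkey[!missing]
  }
  if (nrow(protons) == 0) return(empty_expected())
  xyz <- bundle_xyz(bundle, pkey)
  dmax <- NULL
  for (m in xyz) {
    d <- as.matrix(stats::dist(m))
    dmax <- if (is.null(dmax)) d else pmax(dmax, d)
  }
  # detected protons: bound to N (15N-edited) or C (13C-edited)
  parent_el <- substr(protons$parent, 1, 1)
  det <- if (sdef$template == "N15NOESY") parent_el == "N" else parent_el == "C"
  det_idx <- which(det)
  if (length(det_idx) == 0) return(empty_expected())
  pair <- which(dmax[, det_idx, drop = FALSE] < 6.0, arr.ind = TRUE)
  hi <- pair[, 1]; di <- det_idx[pair[, 2]]
  keep <- hi != di
  hi <- hi[keep]; di <- di[keep]
  if (collapse_symmetric) {
    both_det <- det[hi]
    drop <- both_det & hi > di
    hi <- hi[!drop]; di <- di[!drop]
  }
  if (length(hi) == 0) return(empty_expected())
  d <- dmax[cbind(hi, di)]
  p <- noesy_probability(d)
  tibble::tibble(
    spectrum = sdef$name,
    res1 = protons$residue_number[hi], atom1 = protons$atom_name[hi],
    res2 = protons$residue_number[di], atom2 = protons$parent[di],
    res3 = protons$residue_number[di], atom3 = protons$atom_name[di],
    probability = p,
    origin = c("noesy-short", "noesy-medium", "noesy-medium", "noesy-long",
               "noesy-long")[match(p, c(0.9, 0.8, 0.7, 0.6, 0.5))]
  )
}

empty_expected <- function() {
  tibble::tibble(spectrum = character(), res1 = integer(), atom1 = character(),
                 res2 = integer(), atom2 = character(), res3 = integer(),
                 atom3 = character(), probability = numeric(),
                 origin = character())
}

#' Random-structure fallback bundle
#'
#' When no structure is supplied, expected NOESY peaks are generated from
#' a bundle of random conformers (correct covalent geometry, random
#' torsions). Only short-range contacts survive the all-conformer distance
#' criterion, so the NOESY expectation degrades gracefully to
#' sequence-local peaks.
#'
#' @param sequence Sequence tibble.
#' @param n_conformers Number of random conformers (>= 2; default 20).
#' @param seed Integer seed.
#' @return Structure-bundle tibble with label `random`.
#' @export
fallback_bundle <- function(sequence, n_conformers = 20, seed = 1) {
  if (n_conformers < 2) {
    stop("fallback bundle needs at least 2 conformers", call. = FALSE)
  }
  build_structure(sequence, mode = "random", n_conformers = n_conformers,
                  seed = seed)
}

#' Backbone RMSD between two bundles after Kabsch superposition
#'
#' Compares the first conformer of each bundle (or the mean over all
#' conformer pairs) on the common backbone N, CA, C atoms, after
#' least-squares rigid-body superposition.
#'
#' @param bundle_a,bundle_b Structure-bundle tibbles.
#' @param residue_range Optional integer vector of residue numbers.
#' @param all_pairs Average over all conformer pairs instead of comparing
#'   first conformers.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(bundle_a, bundle_b, residue_range = NULL,
                          all_pairs = FALSE) {
  pick <- function(b) {
    sub <- b[b$atom_name %in% c("N", "CA", "C"), ]
    if (!is.null(residue_range)) sub <- sub[sub$residue_number %in% residue_range, ]
    sub
  }
  a <- pick(bundle_a); b <- pick(bundle_b)
  keys <- intersect(unique(atom_key(a$residue_number, a$atom_name)),
                    unique(atom_key(b$residue_number, b$atom_name)))
  if (length(keys) == 0) stop("no common backbone atoms", call. = FALSE)
  xa <- bundle_xyz(a, keys); xb <- bundle_xyz(b, keys)
  one <- function(ma, mb) {
    bio3d::rmsd(as.vector(t(ma)), as.vector(t(mb)), fit = TRUE)
  }
  if (!all_pairs) return(one(xa[[1]], xb[[1]]))
  mean(vapply(xa, function(ma) mean(vapply(xb, function(mb) one(ma, mb), 0)), 0))
}

#' Write a structure bundle as a multi-MODEL PDB file
#'
#' @param bundle Structure-bundle tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle_pdb <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in sort(unique(bundle$conformer))) {
    sub <- bundle[bundle$conformer == cf, ]
    writeLines(sprintf("MODEL     %4d", cf), con)
    nm <- ifelse(sub$atom_name == "HN", "H", sub$atom_name)
    pad <- ifelse(nchar(nm) >= 4, nm, sprintf(" %-3s", nm))
    writeLines(sprintf("ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(sub)), pad, sub$residue_type,
                       sub$residue_number, sub$x, sub$y, sub$z, sub$element),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a structure bundle from a (multi-MODEL) PDB file
#'
#' Uses the bio3d reader; MODEL records become conformers. Atom names are
#' normalized to the package convention (`H` becomes `HN`, digit-first
#' proton names are rewritten). If the file lacks protons they can be
#' reconstructed with [add_protons()].
#'
#' @param path PDB file path.
#' @param label Provenance tag for the bundle.
#' @return Structure-bundle tibble.
#' @export
read_bundle_pdb <- function(path, label = "experimental") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nm <- at$elety
  swap <- grepl("^[0-9]", nm)   # 1HB -> HB1
  nm[swap] <- paste0(substring(nm[swap], 2), substring(nm[swap], 1, 1))
  nm <- normalize_atom_name(nm)
  nmodel <- nrow(pdb$xyz)
  out <- dplyr::bind_rows(lapply(seq_len(nmodel), function(k) {
    m <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    tibble::tibble(conformer = k, residue_number = at$resno,
                   residue_type = at$resid, atom_name = nm,
                   x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  out <- out[out$residue_type %in% AA3, ]
  structure_bundle(out, label = label)
}

#' Reconstruct missing protons from heavy-atom geometry
#'
#' Adds any topology protons absent from the bundle at idealized
#' positions: sp3/sp2 centers are completed from the directions of the
#' placed substituents, methyl and amide protons from torsion-slot
#' placement over the residue topology tree.
#'
#' @param bundle Structure-bundle tibble (heavy atoms at least).
#' @param sequence Sequence tibble matching the bundle numbering.
#' @return Structure-bundle tibble including all protons.
#' @export
add_protons <- function(bundle, sequence) {
  topo <- residue_topology()
  full <- dplyr::inner_join(sequence, topo, by = "residue_type",
                            relationship = "many-to-many")
  full <- full[full$residue_type != "PRO" | full$atom_name != "HN", ]
  out <- lapply(sort(unique(bundle$conformer)), function(cf) {
    sub <- bundle[bundle$conformer == cf, ]
    have <- atom_key(sub$residue_number, sub$atom_name)
    coords <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(sub))) {
      assign(atom_key(sub$residue_number[k], sub$atom_name[k]),
             c(sub$x[k], sub$y[k], sub$z[k]), coords)
    }
    getc <- function(res, atom) {
      k <- atom_key(res, atom)
      if (exists(k, coords)) get(k, coords) else NULL
    }
    miss <- full[!atom_key(full$residue_number, full$atom_name) %in% have &
                   full$element == "H", ]
    new_rows <- list()
    for (k in seq_len(nrow(miss))) {
      res <- miss$residue_number[k]; atom <- miss$atom_name[k]
      rt <- miss$residue_type[k]; parent <- miss$parent[k]
      P <- getc(res, parent)
      if (is.null(P)) next
      pos <- NULL
      if (atom == "HN") {
        Cp <- getc(res - 1, "C"); N <- P; CAp <- getc(res - 1, "CA")
        CA <- getc(res, "CA")
        if (!is.null(Cp) && !is.null(CAp)) {
          pos <- nerf_place(CAp, Cp, N, 1.00, 119.5, 0)
        } else if (!is.null(CA)) {
          pos <- P + 1.0 * unit3(P - CA + c(0, 0, 0.3))
        }
      } else {
        # neighbours of the parent (its own parent plus placed children)
        tsub <- topo[topo$residue_type == rt, ]
        gp <- tsub$parent[tsub$atom_name == parent]
        kids <- tsub$atom_name[!is.na(tsub$parent) & tsub$parent == parent]
        nb <- c(if (!is.na(gp)) gp, kids[kids != atom])
        nbpos <- Filter(Negate(is.null), lapply(nb, function(a) getc(res, a)))
        nmiss <- sum(vapply(kids, function(a) is.null(getc(res, a)), TRUE))
        if (length(nbpos) >= 2 && nmiss == 1) {
          dirs <- vapply(nbpos, function(q) unit3(q - P), numeric(3))
          pos <- P + 1.09 * unit3(-rowSums(dirs))
        } else if (!is.na(gp)) {
          G <- getc(res, gp)
          g2 <- tsub$parent[tsub$atom_name == gp]
          G2 <- if (!is.na(g2)) getc(res, g2) else getc(res - 1, "C")
          if (gp == "CA") G2 <- getc(res, "N")
          if (!is.null(G) && !is.null(G2)) {
            slot <- match(atom, kids[vapply(kids, function(a)
              is.null(getc(res, a)), TRUE)])
            offs <- c(180, 60, -60)
            pos <- nerf_place(G2, G, P, 1.09, 109.5, offs[min(slot, 3)])
          }
        }
      }
      if (!is.null(pos)) {
        assign(atom_key(res, atom), pos, coords)
        new_rows[[length(new_rows) + 1]] <- tibble::tibble(
          conformer = cf, residue_number = res, residue_type = rt,
          atom_name = atom, element = "H",
          x = pos[1], y = pos[2], z = pos[3])
      }
    }
    dplyr::bind_rows(c(list(sub), new_rows))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "label") <- attr(bundle, "label")
  res
}
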