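# Ideal-geometry construction of protein conformers from torsion angles
# (natural extension reference frame placement over the residue topology
# tree). Used by the synthetic benchmark generator and the random-bundle
# fallback; bond lengths and angles are standard idealized values.

.deg <- pi / 180

.bond_length <- function(e1, e2) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  switch(key, "C-C" = 1.52, "C-N" = 1.46, "C-O" = 1.40, "C-S" = 1.81,
         "C-H" = 1.09, "H-N" = 1.00, "H-S" = 1.34, "N-N" = 1.35, 1.5)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v * v))

# Place atom D given positions A, B, C, bond length C-D, angle B-C-D (deg)
# and dihedral A-B-C-D (deg).
nerf_place <- function(A, B, C, r, theta, tau) {
  th <- theta * .deg; ta <- tau * .deg
  d2 <- c(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  M <- cbind(bc, cross3(n, bc), n)
  C + as.vector(M %*% d2)
}

# Dihedral angle (degrees) of four points.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) / .deg
}

# Ordered side-chain placement plan for one residue type: heavy centers
# with their children (heavy first, then H), torsion-slot offsets and
# whether the bond to the parent is rotatable.
sidechain_plan <- function(residue_type) {
  key <- paste0("plan:", residue_type)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  topo <- residue_topology()
  topo <- topo[topo$residue_type == residue_type, ]
  centers <- list()
  for (p in topo$atom_name[topo$element != "H" & !is.na(topo$parent)]) {
    kids <- topo$atom_name[!is.na(topo$parent) & topo$parent == p]
    if (length(kids) == 0 || p %in% c("CA", "C")) next
    kids <- kids[order(topo$element[match(kids, topo$atom_name)] == "H")]
    g <- topo$parent[topo$atom_name == p]
    hyb_p <- topo$hybrid[topo$atom_name == p]
    hyb_g <- topo$hybrid[topo$atom_name == g]
    rot <- isTRUE(hyb_p == "sp3") || isTRUE(hyb_g == "sp3")
    off <- if (isTRUE(hyb_p == "sp2")) c(0, 180, 90) else c(0, 120, -120)
    centers[[p]] <- list(parent = g, children = kids, rotatable = rot,
                         sp2 = isTRUE(hyb_p == "sp2"),
                         offsets = off[seq_along(kids)],
                         angle = if (isTRUE(hyb_p == "sp2")) 120 else 109.5)
    if (p == "N") centers[[p]] <- NULL   # proline ring HN handled elsewhere
  }
  .pkg_cache[[key]] <- centers
  centers
}

# Names of the torsion parameters of a sequence (phi/psi per residue plus
# one chi per rotatable side-chain bond).
torsion_names <- function(sequence) {
  unlist(lapply(seq_len(nrow(sequence)), function(i) {
    res <- sequence$residue_number[i]
    plan <- sidechain_plan(sequence$residue_type[i])
    chis <- names(plan)[vapply(plan, function(p) p$rotatable, TRUE)]
    c(paste0("phi:", res), paste0("psi:", res),
      if (length(chis)) paste0("chi:", res, ":", chis))
  }))
}

# Standard torsion values per mode; chi angles staggered anti.
standard_torsions <- function(sequence, mode = c("helix", "extended", "random")) {
  mode <- match.arg(mode)
  nm <- torsion_names(sequence)
  val <- vapply(nm, function(n) {
    kind <- strsplit(n, ":")[[1]][1]
    switch(mode,
      helix = switch(kind, phi = -57, psi = -47, 180),
      extended = switch(kind, phi = -120, psi = 130, 180),
      random = stats::runif(1, -180, 180))
  }, 0)
  stats::setNames(val, nm)
}

# Build one conformer from a named torsion vector. Returns a tibble with
# every topology atom (including O/S and protons) and coordinates in Angstrom.
build_conformer <- function(sequence, torsions) {
  topo <- residue_topology()
  n <- nrow(sequence)
  coords <- new.env(parent = emptyenv())
  setc <- function(res, atom, xyz) assign(atom_key(res, atom), xyz, coords)
  getc <- function(res, atom) get(atom_key(res, atom), coords)
  tor <- function(name, default = 180) {
    v <- torsions[name]
    if (is.na(v)) default else unname(v)
  }
  rn <- sequence$residue_number
  # residue 1 backbone with a virtual preceding carbonyl for references
  setc(rn[1], "N", c(0, 0, 0))
  C0 <- 1.329 * c(cos(121.7 * .deg), sin(121.7 * .deg), 0)
  setc(rn[1], "CA", c(1.458, 0, 0))
  setc(rn[1], "C", nerf_place(C0, getc(rn[1], "N"), getc(rn[1], "CA"),
                              1.525, 111.0, tor(paste0("phi:", rn[1]), -120)))
  prevC_of <- function(i) if (i == 1) C0 else getc(rn[i - 1], "C")
  for (i in seq_len(n)) {
    res <- rn[i]; rt <- sequence$residue_type[i]
    N <- getc(res, "N"); CA <- getc(res, "CA"); C <- getc(res, "C")
    phi <- tor(paste0("phi:", res), -120); psi <- tor(paste0("psi:", res), 130)
    # amide proton (trans to the preceding CA across the peptide bond)
    if (rt != "PRO") {
      Aref <- if (i == 1) CA else getc(rn[i - 1], "CA")
      setc(res, "HN", nerf_place(Aref, prevC_of(i), N, 1.00, 119.5,
                                 if (i == 1) 180 else 0))
    }
    # carbonyl O and the next residue's backbone
    if (i < n) {
      Nn <- nerf_place(N, CA, C, 1.329, 116.2, psi)
      setc(rn[i + 1], "N", Nn)
      setc(rn[i + 1], "CA", nerf_place(CA, C, Nn, 1.458, 121.7, 180))
      setc(rn[i + 1], "C", nerf_place(C, Nn, getc(rn[i + 1], "CA"), 1.525,
                                      111.0, tor(paste0("phi:", rn[i + 1]), -120)))
    }
    setc(res, "O", nerf_place(N, CA, C, 1.23, 120.5, psi + 180))
    # CA substituents referenced to phi
    if (rt == "GLY") {
      setc(res, "HA2", nerf_place(prevC_of(i), N, CA, 1.09, 109.5, phi - 121))
      setc(res, "HA3", nerf_place(prevC_of(i), N, CA, 1.09, 109.5, phi + 121))
    } else {
      setc(res, "CB", nerf_place(prevC_of(i), N, CA, 1.52, 110.5, phi - 122.5))
      setc(res, "HA", nerf_place(prevC_of(i), N, CA, 1.09, 108.0, phi + 118.5))
    }
    # side chain beyond CB over the topology tree
    plan <- sidechain_plan(rt)
    for (p in names(plan)) {
      pl <- plan[[p]]
      g <- pl$parent
      g2 <- topo$parent[topo$residue_type == rt & topo$atom_name == g]
      P <- getc(res, p); G <- getc(res, g)
      G2 <- if (is.na(g2)) prevC_of(i) else if (g2 == "N" && g == "CA") N else getc(res, g2)
      if (g == "CA") G2 <- N
      base <- if (pl$rotatable) tor(paste0("chi:", res, ":", p), 180) else 180
      for (k in seq_along(pl$children)) {
        kid <- pl$children[k]
        el <- substr(kid, 1, 1)
        el <- if (kid %in% c("SD", "SG")) "S" else el
        pe <- topo$element[topo$residue_type == rt & topo$atom_name == p]
        r <- .bond_length(pe, el)
        setc(res, kid, nerf_place(G2, G, P, r, pl$angle, base + pl$offsets[k]))
      }
    }
  }
  rows <- dplyr::inner_join(sequence, topo, by = "residue_type",
                            relationship = "many-to-many")
  rows <- rows[rows$residue_type != "PRO" | rows$atom_name != "HN", ]
  xyz <- t(vapply(seq_len(nrow(rows)),
                  function(k) getc(rows$residue_number[k], rows$atom_name[k]),
                  numeric(3)))
  tibble::tibble(residue_number = rows$residue_number,
                 residue_type = rows$residue_type,
                 atom_name = rows$atom_name, element = rows$element,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# Repulsion-only clash score between residues more than one apart:
# sum over heavy-atom pairs closer than `cutoff` of (cutoff - d)^2.
clash_score <- function(conf, cutoff = 2.4) {
  heavy <- conf[conf$element != "H", ]
  xyz <- cbind(heavy$x, heavy$y, heavy$z)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(heavy$residue_number, heavy$residue_number, "-"))
  bad <- d < cutoff & sep > 1
  sum((cutoff - d[bad])^2) / 2
}

#' Build a synthetic structure bundle from ideal geometry
#'
#' Constructs `n_conformers` conformers of the sequence from idealized
#' covalent geometry with backbone torsions set by `mode` (`helix`
#' \eqn{\phi=-57^\circ,\psi=-47^\circ}; `extended`; or `random` torsions,
#' independently drawn per conformer). In helix/extended mode conformers
#' differ by small Gaussian torsion noise; in random mode, clashes are
#' relieved by a short stochastic torsion-space descent on a
#' repulsion-only score. All protons are present.
#'
#' @param sequence Sequence tibble.
#' @param mode `"helix"`, `"extended"` or `"random"`.
#' @param n_conformers Number of conformers (default 5).
#' @param seed Integer seed; the build is a pure function of its inputs.
#' @param torsion_noise_sd Per-conformer torsion noise, degrees (default 4).
#' @return A structure-bundle tibble (`conformer`, `residue_number`,
#'   `residue_type`, `atom_name`, `element`, `x`, `y`, `z`) with
#'   attributes `label` and `torsions` (per-conformer named vectors).
#' @export
build_structure <- function(sequence, mode = c("helix", "extended", "random"),
                            n_conformers = 5, seed = 1,
                            torsion_noise_sd = 4) {
  mode <- match.arg(mode)
  check_sequence(sequence)
  confs <- withr::with_seed(seed, {
    base <- standard_torsions(sequence, if (mode == "random") "extended" else mode)
    lapply(seq_len(n_conformers), function(k) {
      tors <- if (mode == "random") {
        standard_torsions(sequence, "random")
      } else {
        base + stats::rnorm(length(base), 0, torsion_noise_sd)
      }
      conf <- build_conformer(sequence, tors)
      if (mode == "random") {
        cs <- clash_score(conf)
        it <- 0
        while (cs > 0 && it < 20) {
          it <- it + 1
          res_i <- sample(nrow(sequence), 1)
          cand <- tors
          idx <- grep(paste0(":", sequence$residue_number[res_i], "(:|$)"),
                      names(tors))
          cand[idx] <- stats::runif(length(idx), -180, 180)
          conf2 <- build_conformer(sequence, cand)
          cs2 <- clash_score(conf2)
          if (cs2 < cs) { conf <- conf2; tors <- cand; cs <- cs2 }
        }
      }
      list(conf = conf, tors = tors)
    })
  })
  out <- dplyr::bind_rows(lapply(seq_along(confs), function(k) {
    dplyr::mutate(confs[[k]]$conf, conformer = k, .before = 1)
  }))
  attr(out, "label") <- if (mode == "random") "random" else "predicted"
  attr(out, "torsions") <- lapply(confs, `[[`, "tors")
  out
}
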