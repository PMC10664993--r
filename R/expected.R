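# Through-bond expected peak generation from magnetization-transfer
# pathway templates instantiated at every residue.

# Pairwise bond-count distances between atoms of one residue type over the
# covalent (parent) tree; used to grade TOCSY relay pathways.
residue_bond_distance <- function(residue_type) {
  key <- paste0("bonddist:", residue_type)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  topo <- residue_topology()
  topo <- topo[topo$residue_type == residue_type, ]
  n <- nrow(topo)
  adj <- matrix(FALSE, n, n, dimnames = list(topo$atom_name, topo$atom_name))
  for (i in seq_len(n)) {
    p <- topo$parent[i]
    if (!is.na(p) && p %in% topo$atom_name) {
      adj[i, p] <- TRUE
      adj[p, topo$atom_name[i]] <- TRUE
    }
  }
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  frontier <- diag(n) > 0
  step <- 0
  while (any(is.infinite(d)) && step < n) {
    step <- step + 1
    reach <- (frontier %*% adj) > 0
    newly <- reach & is.infinite(d)
    d[newly] <- step
    frontier <- reach
  }
  .pkg_cache[[key]] <- d
  d
}

#' Back-calculate expected through-bond cross peaks
#'
#' Instantiates the spectrum's magnetization-transfer pathway template at
#' every residue where all constituent atoms exist. Prolines and the chain
#' start contribute no amide-rooted peaks. Observation probabilities come
#' from the spectrum library: `p_strong` for one-bond/strong pathways,
#' `p_weak` for sequential and long TOCSY relay pathways.
#'
#' @param spectrum Spectrum name or one-row definition from
#'   [spectrum_definition()]; must be a through-bond experiment.
#' @param atom_set Atom tibble from [enumerate_atoms()].
#' @return Expected-peak tibble: `spectrum`, `res1`/`atom1` ...
#'   `res3`/`atom3` (third dimension `NA` for 2D spectra), `probability`,
#'   `origin = "through-bond"`.
#' @export
#' @examples
#' expected_peaks_throughbond("HNCA", enumerate_atoms(protein_sequence("AAA")))
expected_peaks_throughbond <- function(spectrum, atom_set) {
  sdef <- if (is.character(spectrum)) spectrum_definition(spectrum) else spectrum
  if (sdef$kind != "through-bond") {
    stop("expected_peaks_throughbond requires a through-bond spectrum",
         call. = FALSE)
  }
  have <- atom_key(atom_set$residue_number, atom_set$atom_name)
  has <- function(res, atom) atom_key(res, atom) %in% have
  restype <- stats::setNames(atom_set$residue_type, atom_set$residue_number)
  residues <- sort(unique(atom_set$residue_number))
  ps <- sdef$p_strong; pw <- sdef$p_weak

  rows <- list()
  emit <- function(r1, a1, r2, a2, r3 = NA, a3 = NA, p) {
    rows[[length(rows) + 1]] <<- list(r1, a1, r2, a2, r3, a3, p)
  }
  # protons bound to carbon, per residue
  h_on_c <- function(res) {
    sub <- atom_set[atom_set$residue_number == res & atom_set$element == "H", ]
    sub[!is.na(sub$parent) & substr(sub$parent, 1, 1) == "C", ]
  }
  aliph_c <- function(res) {
    sub <- atom_set[atom_set$residue_number == res & atom_set$aliphatic, ]
    sub$atom_name
  }
  tmpl <- sdef$template
  for (i in residues) {
    amide <- has(i, "HN") && has(i, "N")
    prev <- i - 1L
    prev_ok <- prev %in% residues
    if (tmpl == "N15HSQC" && amide) emit(i, "HN", i, "N", p = ps)
    if (tmpl == "C13HSQC") {
      h <- h_on_c(i)
      for (k in seq_len(nrow(h))) emit(i, h$atom_name[k], i, h$parent[k], p = ps)
    }
    if (tmpl == "HNCA" && amide) {
      if (has(i, "CA")) emit(i, "HN", i, "N", i, "CA", p = ps)
      if (prev_ok && has(prev, "CA")) emit(i, "HN", i, "N", prev, "CA", p = pw)
    }
    if (tmpl == "HNcoCA" && amide && prev_ok && has(prev, "CA"))
      emit(i, "HN", i, "N", prev, "CA", p = ps)
    if (tmpl == "HNCO" && amide && prev_ok && has(prev, "C"))
      emit(i, "HN", i, "N", prev, "C", p = ps)
    if (tmpl == "HNcaCO" && amide) {
      if (has(i, "C")) emit(i, "HN", i, "N", i, "C", p = ps)
      if (prev_ok && has(prev, "C")) emit(i, "HN", i, "N", prev, "C", p = pw)
    }
    if (tmpl == "CBCANH" && amide) {
      for (a in c("CA", "CB")) {
        if (has(i, a)) emit(i, "HN", i, "N", i, a, p = ps)
        if (prev_ok && has(prev, a)) emit(i, "HN", i, "N", prev, a, p = pw)
      }
    }
    if (tmpl == "CBCAcoNH" && amide && prev_ok) {
      for (a in c("CA", "CB")) if (has(prev, a))
        emit(i, "HN", i, "N", prev, a, p = ps)
    }
    if (tmpl == "HBHAcoNH" && amide && prev_ok) {
      hh <- h_on_c(prev)
      hh <- hh[grepl("^HA|^HB", hh$atom_name), ]
      for (k in seq_len(nrow(hh))) emit(i, "HN", i, "N", prev, hh$atom_name[k], p = ps)
    }
    if (tmpl == "hCcoNH" && amide && prev_ok) {
      bd <- residue_bond_distance(restype[[as.character(prev)]])
      for (a in aliph_c(prev)) {
        p <- if (a %in% c("CA", "CB")) ps else pw
        emit(i, "HN", i, "N", prev, a, p = p)
      }
    }
    if (tmpl %in% c("HCCHTOCSY", "CCHTOCSY")) {
      bd <- residue_bond_distance(restype[[as.character(i)]])
      h <- h_on_c(i)
      h <- h[h$parent %in% aliph_c(i), ]
      if (tmpl == "HCCHTOCSY" && nrow(h) > 1) {
        for (a in seq_len(nrow(h))) for (b in seq_len(nrow(h))) {
          if (a == b) next
          p <- if (bd[h$parent[a], h$parent[b]] <= 1) ps else pw
          emit(i, h$atom_name[a], i, h$parent[a], i, h$atom_name[b], p = p)
        }
      }
      if (tmpl == "CCHTOCSY") {
        cs <- aliph_c(i)
        for (ca in seq_len(nrow(h))) for (cb in cs) {
          if (cb == h$parent[ca]) next
          p <- if (bd[cb, h$parent[ca]] <= 1) ps else pw
          emit(i, cb, i, h$parent[ca], i, h$atom_name[ca], p = p)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(spectrum = character(), res1 = integer(),
                          atom1 = character(), res2 = integer(),
                          atom2 = character(), res3 = integer(),
                          atom3 = character(), probability = numeric(),
                          origin = character()))
  }
  tibble::tibble(
    spectrum = sdef$name,
    res1 = as.integer(vapply(rows, function(r) r[[1]], 0)),
    atom1 = vapply(rows, function(r) r[[2]], ""),
    res2 = as.integer(vapply(rows, function(r) r[[3]], 0)),
    atom2 = vapply(rows, function(r) r[[4]], ""),
    res3 = vapply(rows, function(r) as.integer(r[[5]]), NA_integer_),
    atom3 = vapply(rows, function(r) as.character(r[[6]]), NA_character_),
    probability = vapply(rows, function(r) r[[7]], 0),
    origin = "through-bond"
  )
}
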