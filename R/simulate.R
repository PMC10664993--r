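# Ground-truthed synthetic assignment problems: shift truths drawn from
# the priors, peak lists with positional jitter, detection losses and
# artifact peaks, decoy bundles at controlled backbone RMSD, and
# multi-domain concatenation.

#' Noise model for simulated peak lists
#'
#' @param position_jitter Positional jitter SD, as a fraction of the
#'   dimension tolerance (default 1/3).
#' @param detection Use each expected peak's observation probability as a
#'   Bernoulli detection probability (default TRUE).
#' @param artifact_rate Expected artifact peaks per true expected peak
#'   (default 0.1).
#' @param true_score_shape,artifact_score_shape Beta parameters
#'   `c(alpha, beta)` of the confidence-score laws for true and artifact
#'   peaks (defaults Beta(8,2) and Beta(2,8), ordering most true peaks
#'   above the NOESY 0.1 threshold while exercising the top-K filter).
#' @param seed Integer seed.
#' @return Named list.
#' @export
noise_model <- function(position_jitter = 1 / 3, detection = TRUE,
                        artifact_rate = 0.1, true_score_shape = c(8, 2),
                        artifact_score_shape = c(2, 8), seed = 1) {
  stopifnot(position_jitter >= 0, artifact_rate >= 0)
  list(position_jitter = position_jitter, detection = detection,
       artifact_rate = artifact_rate, true_score_shape = true_score_shape,
       artifact_score_shape = artifact_score_shape, seed = seed)
}

#' Draw true chemical shifts from the priors
#'
#' One value per atom from its Gaussian prior, truncated at 3 SD.
#'
#' @param priors Prior tibble.
#' @param seed Integer seed.
#' @return Tibble `residue_number`, `residue_type`, `atom_name`,
#'   `nucleus`, `shift`.
#' @export
sample_true_shifts <- function(priors, seed = 1) {
  withr::with_seed(seed, {
    u <- stats::runif(nrow(priors), stats::pnorm(-3), stats::pnorm(3))
    val <- priors$mean + priors$sd * stats::qnorm(u)
  })
  # magnetically equivalent atoms (methyl rotors, fast-flipping aromatic
  # ring pairs) share one resonance: collapse their draws to the group's
  # first value
  grp <- equivalence_groups(priors)
  val <- val[match(grp, grp)]
  tibble::tibble(residue_number = priors$residue_number,
                 residue_type = priors$residue_type,
                 atom_name = priors$atom_name, nucleus = priors$nucleus,
                 shift = val)
}

#' Simulate observed peak lists from expected peaks and true shifts
#'
#' Each expected peak is detected with its observation probability (or
#' always, when detection is off) at positions equal to the true shifts
#' plus Gaussian jitter; artifact peaks (count Binomial(n_expected,
#' artifact_rate) per spectrum) are placed uniformly over the occupied
#' ppm box of the true peaks with low confidence scores. The ground-truth
#' mapping is attached as attribute `truth_mapping`.
#'
#' @param expected Expected-peak tibble (may span several spectra).
#' @param truth True-shift tibble from [sample_true_shifts()].
#' @param noise Noise model from [noise_model()].
#' @return Observed-peak tibble (`spectrum`, `id`, `w1`..`w3`,
#'   `intensity`, `confidence`); ids unique within each spectrum.
#' @export
simulate_peak_lists <- function(expected, truth, noise = noise_model()) {
  tkey <- atom_key(truth$residue_number, truth$atom_name)
  lookup <- function(res, atom) {
    out <- truth$shift[match(atom_key(res, atom), tkey)]
    if (anyNA(out[!is.na(atom)])) stop("truth does not cover all atoms",
                                       call. = FALSE)
    out
  }
  w1t <- lookup(expected$res1, expected$atom1)
  w2t <- lookup(expected$res2, expected$atom2)
  w3t <- ifelse(is.na(expected$atom3), NA, lookup(expected$res3, expected$atom3))
  withr::with_seed(noise$seed, {
    out <- lapply(unique(expected$spectrum), function(sp) {
      rows <- which(expected$spectrum == sp)
      dims <- spectrum_definition(sp)$dims[[1]]
      tolv <- dims$tolerance
      det <- if (isTRUE(noise$detection)) {
        stats::runif(length(rows)) < expected$probability[rows]
      } else rep(TRUE, length(rows))
      tr <- rows[det]
      pos <- cbind(w1t[tr], w2t[tr], if (nrow(dims) >= 3) w3t[tr] else NULL)
      if (noise$position_jitter > 0 && length(tr) > 0) {
        for (d in seq_len(ncol(pos))) {
          pos[, d] <- pos[, d] + stats::rnorm(length(tr), 0,
                                              noise$position_jitter * tolv[d])
        }
      }
      n_art <- stats::rbinom(1, length(rows), min(noise$artifact_rate, 1))
      apos <- NULL
      if (n_art > 0 && length(tr) > 1) {
        apos <- vapply(seq_len(ncol(pos)), function(d) {
          stats::runif(n_art, min(pos[, d]), max(pos[, d]))
        }, numeric(n_art))
        if (n_art == 1) apos <- matrix(apos, 1)
      } else n_art <- 0L
      n_true <- length(tr)
      conf <- c(stats::rbeta(n_true, noise$true_score_shape[1],
                             noise$true_score_shape[2]),
                stats::rbeta(n_art, noise$artifact_score_shape[1],
                             noise$artifact_score_shape[2]))
      allpos <- rbind(pos, apos)
      pk <- tibble::tibble(spectrum = sp,
                           id = seq_len(n_true + n_art))
      for (d in seq_len(nrow(dims))) pk[[paste0("w", d)]] <-
        if (d <= ncol(allpos)) allpos[, d] else NA_real_
      pk$intensity <- stats::rlnorm(n_true + n_art, 0, 0.5)
      pk$confidence <- conf
      attr(pk, "truth_rows") <- tibble::tibble(expected_row = tr,
                                               obs_id = seq_len(n_true))
      pk
    })
  })
  truth_mapping <- dplyr::bind_rows(lapply(out, function(pk) {
    tm <- attr(pk, "truth_rows")
    tm$spectrum <- pk$spectrum[1] %||% NA_character_
    tm
  }))
  res <- dplyr::bind_rows(out)
  attr(res, "truth_mapping") <- truth_mapping
  res
}

#' Perturb a bundle to a target backbone RMSD (decoy generation)
#'
#' Applies Gaussian torsion-space perturbation to the first conformer of
#' `bundle`, with the magnitude found by bisection so that the backbone
#' RMSD to the original lies within 10% of `target_rmsd`. Emits a triplet
#' of decoy conformers with pairwise backbone RMSD below 1 Angstrom.
#'
#' @param bundle Structure bundle built by [build_structure()] (its
#'   torsion attribute is used; for coordinate-only bundles backbone
#'   torsions are re-derived and side chains rebuilt at standard rotamers).
#' @param target_rmsd Target backbone RMSD in Angstrom (>= 0).
#' @param seed Integer seed.
#' @param n_decoys Conformers in the decoy bundle (default 3).
#' @return Structure bundle with label `decoy`.
#' @export
perturb_to_rmsd <- function(bundle, target_rmsd, seed = 1, n_decoys = 3) {
  stopifnot(target_rmsd >= 0)
  seq_tbl <- dplyr::distinct(bundle[bundle$conformer == min(bundle$conformer), ],
                             .data$residue_number, .data$residue_type)
  tors <- attr(bundle, "torsions")
  base <- if (!is.null(tors)) tors[[1]] else derive_torsions(bundle, seq_tbl)
  if (target_rmsd == 0) {
    out <- dplyr::bind_rows(lapply(seq_len(n_decoys), function(k) {
      dplyr::mutate(build_conformer(seq_tbl, base), conformer = k, .before = 1)
    }))
    attr(out, "label") <- "decoy"
    attr(out, "torsions") <- rep(list(base), n_decoys)
    return(out)
  }
  ref <- dplyr::mutate(build_conformer(seq_tbl, base), conformer = 1, .before = 1)
  withr::with_seed(seed, {
    direction <- stats::rnorm(length(base))
    names(direction) <- names(base)
    rmsd_at <- function(eps) {
      cand <- base + eps * direction
      conf <- dplyr::mutate(build_conformer(seq_tbl, cand), conformer = 1,
                            .before = 1)
      list(r = backbone_rmsd(ref, conf), tors = cand)
    }
    lo <- 0; hi <- 2
    while (rmsd_at(hi)$r < target_rmsd && hi < 512) hi <- hi * 2
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      r <- rmsd_at(mid)$r
      if (abs(r - target_rmsd) <= 0.1 * target_rmsd) break
      if (r < target_rmsd) lo <- mid else hi <- mid
    }
    main <- rmsd_at(mid)
    # sibling decoys: small extra perturbations, pairwise RMSD < 1 A
    sib_eps <- 0.02
    decoys <- list(main$tors)
    for (k in seq_len(n_decoys - 1)) {
      repeat {
        cand <- main$tors + sib_eps * stats::rnorm(length(base))
        confs <- lapply(c(decoys, list(cand)), function(tv) {
          dplyr::mutate(build_conformer(seq_tbl, tv), conformer = 1, .before = 1)
        })
        ok <- all(vapply(seq_along(decoys), function(j) {
          backbone_rmsd(confs[[j]], confs[[length(confs)]]) < 0.9
        }, TRUE))
        if (ok) { decoys[[length(decoys) + 1]] <- cand; break }
        sib_eps <- sib_eps / 2
      }
    }
  })
  out <- dplyr::bind_rows(lapply(seq_along(decoys), function(k) {
    dplyr::mutate(build_conformer(seq_tbl, decoys[[k]]), conformer = k,
                  .before = 1)
  }))
  attr(out, "label") <- "decoy"
  attr(out, "torsions") <- decoys
  out
}

# Re-derive backbone torsions from coordinates (side chains fall back to
# standard anti rotamers).
derive_torsions <- function(bundle, seq_tbl) {
  sub <- bundle[bundle$conformer == min(bundle$conformer), ]
  getc <- function(res, atom) {
    i <- which(sub$residue_number == res & sub$atom_name == atom)
    if (length(i) == 0) NULL else c(sub$x[i[1]], sub$y[i[1]], sub$z[i[1]])
  }
  tors <- standard_torsions(seq_tbl, "extended")
  for (i in seq_len(nrow(seq_tbl))) {
    res <- seq_tbl$residue_number[i]
    N <- getc(res, "N"); CA <- getc(res, "CA"); C <- getc(res, "C")
    Cp <- getc(res - 1, "C"); Nn <- getc(res + 1, "N")
    if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C)) {
      tors[paste0("phi:", res)] <- dihedral4(Cp, N, CA, C)
    }
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nn)) {
      tors[paste0("psi:", res)] <- dihedral4(N, CA, C, Nn)
    }
  }
  tors
}

#' Concatenate domains into one multi-domain problem
#'
#' Joins the domain sequences with 10-glycine linkers, renumbers residues
#' contiguously, merges per-spectrum peak lists (ids re-keyed), shifts
#' truths and bundles. Linker residues carry priors but no observed
#' peaks; domain bundles are placed rigidly along the linker direction
#' with extended linker geometry and no global packing.
#'
#' @param domains List of domain problems; each a list with elements
#'   `sequence`, and optionally `bundle`, `truth`, `peaks`.
#' @param linker_length Glycines between consecutive domains (default 10).
#' @return List with the combined `sequence`, `bundle`, `truth`, `peaks`.
#' @export
concatenate_domains <- function(domains, linker_length = 10) {
  if (length(domains) < 2) stop("need at least two domains", call. = FALSE)
  gap <- 0L
  seqs <- list(); truths <- list(); peaks <- list(); bundles <- list()
  offset <- 0L
  x_off <- 0
  for (di in seq_along(domains)) {
    d <- domains[[di]]
    n <- nrow(d$sequence)
    shift_n <- offset + 1L - d$sequence$residue_number[1]
    sq <- dplyr::mutate(d$sequence, residue_number = .data$residue_number + shift_n)
    seqs[[length(seqs) + 1]] <- sq
    if (!is.null(d$truth)) {
      truths[[length(truths) + 1]] <-
        dplyr::mutate(d$truth, residue_number = .data$residue_number + shift_n)
    }
    if (!is.null(d$peaks)) {
      pk <- d$peaks
      pk$id <- pk$id + 100000L * (di - 1L)
      peaks[[length(peaks) + 1]] <- pk
    }
    if (!is.null(d$bundle)) {
      b <- dplyr::mutate(d$bundle,
                         residue_number = .data$residue_number + shift_n)
      b$x <- b$x - min(b$x) + x_off
      x_off <- max(b$x) + 3.5 * (linker_length + 1)
      bundles[[length(bundles) + 1]] <- b
    }
    offset <- offset + n
    if (di < length(domains)) {
      linker <- protein_sequence(rep("GLY", linker_length),
                                 first_residue_number = offset + 1L)
      seqs[[length(seqs) + 1]] <- linker
      if (length(bundles) > 0) {
        lb <- build_structure(linker, "extended", n_conformers = 1,
                              seed = 1000 + di)
        lb$x <- lb$x - min(lb$x) + max(bundles[[length(bundles)]]$x) + 1.5
        lb$conformer <- 1L
        bundles[[length(bundles) + 1]] <- lb
      }
      offset <- offset + linker_length
    }
  }
  sequence <- dplyr::bind_rows(seqs)
  if (anyDuplicated(sequence$residue_number) > 0) {
    stop("internal error: overlapping residue numbers after renumbering",
         call. = FALSE)
  }
  bundle <- NULL
  if (length(bundles) > 0) {
    # replicate to a common conformer count using each domain's first conformer
    bundle <- dplyr::bind_rows(lapply(bundles, function(b) {
      b[b$conformer == min(b$conformer), ]
    }))
    bundle$conformer <- 1L
    attr(bundle, "label") <- "predicted"
  }
  list(sequence = sequence,
       bundle = bundle,
       truth = if (length(truths) > 0) dplyr::bind_rows(truths) else NULL,
       peaks = if (length(peaks) > 0) dplyr::bind_rows(peaks) else NULL)
}
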