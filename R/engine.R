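# The peak-mapping engine: maps expected cross peaks onto observed peaks
# by evolutionary search with residue-block (spin-system) proposals and
# local refinement, under Gaussian shift priors. Atom shifts are a
# deterministic function of the mapping (the tolerance-weighted mean of
# all mapped peak positions attributed to the atom), so the search space
# is the discrete space of peak mappings.

#' Engine parameters
#'
#' @param population_size Genomes per generation (50).
#' @param generations Maximum generations (200).
#' @param mutation_rate Per-residue-block mutation probability (0.05).
#' @param tournament_size Tournament selection size (3).
#' @param lambda Penalty per unit probability of an unmapped expected
#'   peak (0.2).
#' @param beta Weight of the Gaussian prior reward per assigned atom (0.5).
#' @param k Hard search-range half-width in prior SDs: an observed peak is
#'   a candidate for an expected peak only if every dimension lies within
#'   tolerance + k*sd of the dimension atom's prior (3).
#' @param seed Integer seed; runs are deterministic given the seed.
#' @param stall Early-stop after this many generations without
#'   improvement (25).
#' @param local_iters Iterations of the local mapping/shift refinement (10).
#' @return Named list of parameters.
#' @export
engine_params <- function(population_size = 50, generations = 200,
                          mutation_rate = 0.05, tournament_size = 3,
                          lambda = 0.2, beta = 0.5, k = 3, seed = 1,
                          stall = 25, local_iters = 10) {
  p <- list(population_size = population_size, generations = generations,
            mutation_rate = mutation_rate, tournament_size = tournament_size,
            lambda = lambda, beta = beta, k = k, seed = seed, stall = stall,
            local_iters = local_iters)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x >= 0, TRUE)),
            p$population_size >= 2, p$tournament_size >= 1)
  p
}

# Precompute the flattened mapping problem: atom indices, per-peak
# candidate observed peaks (within tolerance + k*sd of the priors in every
# dimension) and the arrays used by the evaluator.
build_problem <- function(expected, observed, priors, params,
                          library = spectrum_library()) {
  stopifnot(nrow(expected) > 0)
  akey <- atom_key(priors$residue_number, priors$atom_name)
  mu <- priors$mean; sd <- priors$sd
  aidx <- function(res, atom) match(atom_key(res, atom), akey)

  E <- nrow(expected)
  ai <- cbind(aidx(expected$res1, expected$atom1),
              aidx(expected$res2, expected$atom2),
              ifelse(is.na(expected$atom3), NA,
                     aidx(expected$res3, expected$atom3)))
  used <- which(!is.na(cbind(expected$atom1, expected$atom2, expected$atom3)) &
                  is.na(ai), arr.ind = TRUE)
  if (nrow(used) > 0) {
    e <- used[1, 1]; d <- used[1, 2]
    stop(sprintf("expected peak %d references atom %s %s without a prior",
                 e, expected[[paste0("res", d)]][e],
                 expected[[paste0("atom", d)]][e]), call. = FALSE)
  }
  tol <- matrix(NA_real_, E, 3)
  for (sp in unique(expected$spectrum)) {
    dims <- spectrum_definition(sp, library)$dims[[1]]
    rows <- expected$spectrum == sp
    for (d in seq_len(nrow(dims))) tol[rows, d] <- dims$tolerance[d]
  }
  kw <- 1 / (2 * (tol / 2)^2)     # Gaussian kernel weights per (peak, dim)
  wmean <- 1 / tol^2              # tolerance weights for the shift mean

  # candidate generation per spectrum
  ce <- integer(0); cobs <- integer(0)
  cpos <- matrix(numeric(0), 0, 3)
  if (!is.null(observed) && nrow(observed) > 0) {
    for (sp in unique(expected$spectrum)) {
      oe <- which(expected$spectrum == sp)
      oo <- which(observed$spectrum == sp)
      if (length(oo) == 0) next
      ok <- matrix(TRUE, length(oe), length(oo))
      for (d in 1:3) {
        a <- ai[oe, d]
        has <- !is.na(a)
        if (!any(has)) next
        w <- observed[[paste0("w", d)]][oo]
        lim <- tol[oe, d] + params$k * sd[a]
        dd <- abs(outer(mu[a], w, "-")) <= matrix(lim, length(oe), length(oo))
        dd[is.na(dd)] <- TRUE
        ok[has, ] <- ok[has, , drop = FALSE] & dd[has, , drop = FALSE]
      }
      hit <- which(ok, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        ce <- c(ce, oe[hit[, 1]])
        cobs <- c(cobs, oo[hit[, 2]])
        pm <- cbind(observed$w1[oo[hit[, 2]]],
                    if ("w2" %in% names(observed)) observed$w2[oo[hit[, 2]]] else NA,
                    if ("w3" %in% names(observed)) observed$w3[oo[hit[, 2]]] else NA)
        cpos <- rbind(cpos, pm)
      }
    }
  }
  ord <- order(ce)
  ce <- ce[ord]; cobs <- cobs[ord]
  cpos <- cpos[ord, , drop = FALSE]
  nc <- length(ce)
  cand_of <- split(seq_len(nc), factor(ce, levels = seq_len(E)))
  cand_x <- lapply(seq_len(E), function(e) {
    cpos[cand_of[[e]], , drop = FALSE]
  })

  # long-format arrays over (candidate row, valid dimension)
  lf_cr <- integer(0); lf_a <- integer(0); lf_x <- numeric(0)
  lf_w <- numeric(0); lf_kw <- numeric(0); lf_tol <- numeric(0)
  for (d in 1:3) {
    a <- ai[ce, d]
    has <- which(!is.na(a))
    lf_cr <- c(lf_cr, has)
    lf_a <- c(lf_a, a[has])
    lf_x <- c(lf_x, cpos[has, d])
    lf_w <- c(lf_w, wmean[ce[has], d])
    lf_kw <- c(lf_kw, kw[ce[has], d])
    lf_tol <- c(lf_tol, tol[ce[has], d])
  }
  o2 <- order(lf_cr)
  lf_cr <- lf_cr[o2]; lf_a <- lf_a[o2]; lf_x <- lf_x[o2]
  lf_w <- lf_w[o2]; lf_kw <- lf_kw[o2]; lf_tol <- lf_tol[o2]
  lf_rows_by_cr <- split(seq_along(lf_cr), factor(lf_cr, levels = seq_len(nc)))
  lf_cnt <- tabulate(lf_cr, nbins = nc)
  lf_end <- cumsum(lf_cnt)
  lf_start <- lf_end - lf_cnt + 1L

  # proposal units: per residue, an amide-rooted unit (peaks touching the
  # residue's HN/N) and an aliphatic unit (all other peaks, keyed by the
  # heteroatom dimension's residue), interleaved along the sequence so
  # that segment windows span the aliphatic(i) <-> amide(i+1) chain links.
  amide_touch <- (expected$atom1 %in% c("HN", "N")) * expected$res1
  amide_touch <- pmax(amide_touch,
                      (expected$atom2 %in% c("HN", "N")) * expected$res2,
                      ifelse(!is.na(expected$atom3) &
                               expected$atom3 %in% c("HN", "N"),
                             expected$res3, 0L))
  unit_key <- ifelse(amide_touch > 0, 2 * amide_touch, 2 * expected$res2 + 1)
  blocks <- split(seq_len(E), unit_key)
  ai_long <- data.frame(a = as.vector(ai), e = rep(seq_len(E), 3))
  ai_long <- ai_long[!is.na(ai_long$a), ]
  peaks_by_atom <- split(ai_long$e, factor(ai_long$a, levels = seq_along(akey)))

  list(E = E, n_atoms = length(akey), mu = mu, sd = sd, akey = akey,
       p_e = expected$probability, totalP = sum(expected$probability),
       ai = ai, tol = tol, kw = kw,
       ce = ce, cobs = cobs, cpos = cpos, nc = nc,
       cand_of = cand_of, cand_x = cand_x,
       lf_cr = lf_cr, lf_a = lf_a, lf_x = lf_x, lf_w = lf_w, lf_kw = lf_kw,
       lf_tol = lf_tol, lf_rows_by_cr = lf_rows_by_cr,
       lf_start = lf_start, lf_end = lf_end,
       blocks = blocks, block_res = as.integer(names(blocks)) %/% 2L,
       peaks_by_atom = peaks_by_atom,
       tb = expected$origin == "through-bond",
       params = params, expected = expected, observed = observed)
}

# Evaluate a genome: derive atom shifts (tolerance-weighted means, clipped
# to the 3-sd prior range), repair tolerance violations by unmapping, and
# return the score with the repaired genome and shifts.
eval_genome <- function(pr, g, repair = TRUE) {
  lam <- pr$params$lambda; beta <- pr$params$beta
  repeat {
    sel <- which(g > 0)
    if (length(sel) == 0) {
      return(list(score = -lam * pr$totalP, g = g,
                  shifts = rep(NA_real_, pr$n_atoms), feasible = TRUE))
    }
    cr <- g[sel]
    use <- unlist(pr$lf_rows_by_cr[cr], use.names = FALSE)
    crv <- pr$lf_cr[use]; av <- pr$lf_a[use]; xv <- pr$lf_x[use]
    wv <- pr$lf_w[use]; kwv <- pr$lf_kw[use]; tolv <- pr$lf_tol[use]
    # tolerance-weighted means per atom (order + cumsum boundaries)
    o <- order(av)
    avs <- av[o]
    b <- c(which(diff(avs) != 0L), length(avs))
    csn <- cumsum((wv * xv)[o]); csd <- cumsum(wv[o])
    left <- c(0, csn[b[-length(b)]]); leftd <- c(0, csd[b[-length(b)]])
    aset <- avs[b]
    sh <- (csn[b] - left) / (csd[b] - leftd)
    sh <- pmin(pmax(sh, pr$mu[aset] - 3 * pr$sd[aset]),
               pr$mu[aset] + 3 * pr$sd[aset])
    shift <- rep(NA_real_, pr$n_atoms)
    shift[aset] <- sh
    dv <- abs(xv - shift[av])
    viol <- dv > tolv + 1e-9
    if (any(viol) && repair) {
      bad_rows <- unique(crv[viol])
      g[match(bad_rows, g)] <- 0L
      next
    }
    # kernel exponent sums per mapped candidate row (contiguous groups)
    bc <- c(which(diff(crv) != 0L), length(crv))
    csk <- cumsum(dv^2 * kwv)
    ksums <- csk[bc] - c(0, csk[bc[-length(bc)]])
    pmap <- pr$p_e[pr$ce[crv[bc]]]
    mapped_term <- sum(pmap * exp(-ksums))
    unmapped_term <- lam * (pr$totalP - sum(pr$p_e[pr$ce[cr]]))
    prior_term <- beta * sum(exp(-(shift[aset] - pr$mu[aset])^2 /
                                   (2 * pr$sd[aset]^2)))
    return(list(score = mapped_term - unmapped_term + prior_term, g = g,
                shifts = shift, feasible = !any(viol)))
  }
}

# Squared-deviation sums (kernel exponents) of every candidate of peak e
# against a full-length shift surrogate vector.
peak_ks <- function(pr, e, s_at) {
  xm <- pr$cand_x[[e]]
  if (nrow(xm) == 0) return(numeric(0))
  ks <- numeric(nrow(xm))
  for (d in 1:3) {
    a <- pr$ai[e, d]
    if (is.na(a)) next
    ks <- ks + pr$kw[e, d] * (xm[, d] - s_at[a])^2
  }
  ks
}

# One full pass mapping every peak to its deviation-best candidate given
# the current shifts (prior means where unassigned), then re-deriving
# shifts; repeated up to `niter` times, keeping the best repaired
# solution. Ranking uses the squared-deviation sums directly so that the
# ordering survives kernel underflow far from the optimum.
local_refine <- function(pr, g, niter = pr$params$local_iters) {
  best <- eval_genome(pr, g)
  if (pr$nc == 0) return(best)
  cur <- best
  for (it in seq_len(niter)) {
    s_at <- ifelse(is.na(cur$shifts), pr$mu, cur$shifts)
    cs <- c(0, cumsum(pr$lf_kw * (pr$lf_x - s_at[pr$lf_a])^2))
    kv <- cs[pr$lf_end + 1L] - cs[pr$lf_start]
    o <- order(pr$ce, kv)
    first <- o[!duplicated(pr$ce[o])]
    g2 <- integer(pr$E)
    g2[pr$ce[first]] <- first
    cur <- eval_genome(pr, g2)
    if (cur$score > best$score) best <- cur
    else if (it > 2) break
  }
  best
}

# Coherent proposal for a run of consecutive residue blocks. Within each
# block, peaks are processed most-constrained-first; the first peak of
# the first block is the segment root, whose candidate is forced
# (`root_pick`), sampled tempered by prior agreement, or greedy. Chosen
# peak positions fix tentative shifts that propagate through the
# segment. Atoms owned by the segment (touched by no mapped peak outside
# it) are scored against their priors with prior weights, so sequential
# and prior evidence can steer the anchor; atoms constrained from
# outside keep full kernel weights against the current shifts.
propose_segment <- function(pr, g, shifts, block_list, root_pick = NULL,
                            sample_root = TRUE, max_noesy = 150) {
  seg <- unlist(block_list, use.names = FALSE)
  outside <- setdiff(which(g > 0), seg)
  ref <- ifelse(is.na(shifts), pr$mu, shifts)
  free <- rep(TRUE, pr$n_atoms)
  if (length(outside) > 0) {
    ext <- pr$ai[outside, , drop = FALSE]
    ext <- unique(ext[!is.na(ext)])
    free[ext[!is.na(shifts[ext])]] <- FALSE
  }
  ref[free] <- pr$mu[free]
  pw <- 1 / (2 * pr$sd^2)            # prior weights for free atoms
  # soft exclusivity: observed peaks already chosen (outside the segment
  # or earlier within it) are discouraged during construction, steering
  # the greedy proposal toward a one-to-one matching; the score itself
  # still allows overlap.
  used <- rep(FALSE, max(1, nrow(pr$observed) %||% 0, max(pr$cobs, 0)))
  if (length(outside) > 0) used[pr$cobs[g[outside]]] <- TRUE
  seg_ks <- function(e) {
    xm <- pr$cand_x[[e]]
    ks <- numeric(nrow(xm))
    for (d in 1:3) {
      a <- pr$ai[e, d]
      if (is.na(a)) next
      w <- if (free[a]) pw[a] else pr$kw[e, d]
      ks <- ks + w * (xm[, d] - ref[a])^2
    }
    ks + 8 * used[pr$cobs[pr$cand_of[[e]]]]
  }
  first <- TRUE
  tent_set <- rep(FALSE, pr$n_atoms)
  # incremental constraint counts: ncon_all[e] = number of dimensions of
  # peak e whose atom already has a tentative shift
  ncon_all <- integer(pr$E)
  bump <- function(a) {
    hit <- pr$peaks_by_atom[[a]]
    if (length(hit) > 0) ncon_all[hit] <<- ncon_all[hit] + 1L
  }
  for (peaks in block_list) {
    ncand <- vapply(pr$cand_of[peaks], length, 0L)
    # bound per-block work: through-bond peaks (anchor-defining) are
    # always re-proposed; of the numerous NOESY leaf peaks only the
    # `max_noesy` most constrained are, the surplus being unmapped so
    # stale choices cannot poison the new shifts (local refinement
    # re-maps them against the accepted anchors).
    remaining <- peaks
    noesy <- !pr$tb[remaining]
    if (sum(noesy) > max_noesy) {
      ord0 <- order(!pr$tb[remaining], -ncon_all[remaining], ncand)
      keep <- ord0[seq_len(sum(pr$tb[remaining]) + max_noesy)]
      g[remaining[-keep]] <- 0L
      remaining <- remaining[keep]
      ncand <- ncand[keep]
    }
    # dynamic constraint ordering: always process the peak with the most
    # tentatively fixed dimensions next, so information propagates
    # through the spin-system network as it is built.
    while (length(remaining) > 0) {
      nc_r <- ncon_all[remaining]
      top <- nc_r == max(nc_r)
      jj <- which(top)[which.min(ncand[top])]
      e <- remaining[jj]
      remaining <- remaining[-jj]; ncand <- ncand[-jj]
      cl <- pr$cand_of[[e]]
      if (length(cl) == 0) { g[e] <- 0L; next }
      ks <- seg_ks(e)
      if (first) {
        if (!is.null(root_pick)) {
          pick <- root_pick
        } else if (sample_root && length(cl) > 1) {
          wts <- exp(-(ks - min(ks)) / 8)
          pick <- sample.int(length(cl), 1, prob = wts)
        } else {
          pick <- which.min(ks)
        }
        first <- FALSE
      } else {
        pick <- which.min(ks)
      }
      g[e] <- cl[pick]
      used[pr$cobs[cl[pick]]] <- TRUE
      for (d in 1:3) {
        a <- pr$ai[e, d]
        if (!is.na(a) && !tent_set[a]) {
          ref[a] <- pr$cand_x[[e]][pick, d]
          tent_set[a] <- TRUE
          free[a] <- FALSE
          bump(a)
        }
      }
    }
  }
  g
}

# Joint two-peak polish for tiny instances: try every candidate
# combination for each pair of peaks with full evaluation, interleaved
# with the single-peak polish, until no sweep improves.
pair_polish <- function(pr, sol, max_sweeps = 4) {
  best <- sol
  if (pr$E > 12) return(best)
  for (sw in seq_len(max_sweeps)) {
    improved <- FALSE
    for (e1 in seq_len(pr$E - 1)) {
      for (e2 in seq((e1 + 1), pr$E)) {
        for (c1 in c(0L, pr$cand_of[[e1]])) {
          for (c2 in c(0L, pr$cand_of[[e2]])) {
            if (best$g[e1] == c1 && best$g[e2] == c2) next
            g <- best$g; g[e1] <- c1; g[e2] <- c2
            ev <- eval_genome(pr, g)
            if (ev$score > best$score + 1e-12) {
              best <- ev
              improved <- TRUE
            }
          }
        }
      }
    }
    if (!improved) break
  }
  best
}

# Anchor-swap sweep: for pairs of same-kind units, re-propose each unit
# rooted at the other's current anchor observed peak and keep the best
# full evaluation. Fixes pairwise-swapped spin systems that windowed
# moves cannot reach (the units need not be adjacent).
swap_icm <- function(pr, sol, max_units = 80) {
  nb <- length(pr$blocks)
  if (nb > max_units) return(sol)
  best <- sol
  kind <- as.integer(names(pr$blocks)) %% 2L
  roots <- vapply(pr$blocks, function(pk) block_root(pr, pk), 0L)
  it <- 0
  repeat {
    it <- it + 1
    improved <- FALSE
    cur_obs <- ifelse(is.na(roots) | best$g[roots] == 0L, NA_integer_,
                      pr$cobs[best$g[roots]])
    for (i in seq_len(nb - 1)) {
      if (is.na(roots[i])) next
      if (pr$E > 2000 && kind[i] != 0L) next
      for (j in seq((i + 1), nb)) {
        if (is.na(roots[j]) || kind[i] != kind[j]) next
        oi <- cur_obs[i]; oj <- cur_obs[j]
        if (is.na(oi) && is.na(oj)) next
        if (identical(oi, oj)) next
        pick_i <- if (is.na(oj)) NULL else
          match(oj, pr$cobs[pr$cand_of[[roots[i]]]])
        pick_j <- if (is.na(oi)) NULL else
          match(oi, pr$cobs[pr$cand_of[[roots[j]]]])
        if ((!is.null(pick_i) && is.na(pick_i)) ||
            (!is.null(pick_j) && is.na(pick_j))) next
        g <- best$g
        bl_i <- pr$blocks[[i]]; bl_j <- pr$blocks[[j]]
        bl_i <- c(roots[i], setdiff(bl_i, roots[i]))
        bl_j <- c(roots[j], setdiff(bl_j, roots[j]))
        if (!is.null(pick_i)) {
          g <- propose_segment(pr, g, best$shifts, list(bl_i),
                               root_pick = pick_i)
        } else g[bl_i] <- 0L
        if (!is.null(pick_j)) {
          g <- propose_segment(pr, g, best$shifts, list(bl_j),
                               root_pick = pick_j)
        } else g[bl_j] <- 0L
        ev <- eval_genome(pr, g)
        if (ev$score > best$score + 1e-12) {
          best <- ev
          improved <- TRUE
          cur_obs <- ifelse(is.na(roots) | best$g[roots] == 0L, NA_integer_,
                            pr$cobs[best$g[roots]])
        }
      }
    }
    if (!improved || it >= 3) break
  }
  best
}

# Exhaustive per-peak polish for small instances: cycle through peaks,
# trying every candidate (and unmapped) with full evaluation, until a
# sweep yields no improvement.
peak_polish <- function(pr, sol, max_sweeps = 6) {
  best <- sol
  for (sw in seq_len(max_sweeps)) {
    improved <- FALSE
    for (e in sample(seq_len(pr$E))) {
      for (ch in c(0L, pr$cand_of[[e]])) {
        if (best$g[e] == ch) next
        g <- best$g; g[e] <- ch
        ev <- eval_genome(pr, g)
        if (ev$score > best$score + 1e-12) {
          best <- ev
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}

# Root peak of a block: fewest (nonzero) candidates.
block_root <- function(pr, peaks) {
  ncand <- vapply(pr$cand_of[peaks], length, 0L)
  if (all(ncand == 0)) return(NA_integer_)
  peaks[ncand > 0][which.min(ncand[ncand > 0])]
}

# Iterated conditional modes over residue segments: for windows of
# consecutive blocks (lengths in `lens`), try each root-anchor candidate
# of the window's first block (capped at `max_anchors`, nearest by
# current deviation), re-propose the whole window coherently, and keep
# the best full evaluation. Escapes chain-swapped spin-system
# permutations that single-block moves cannot fix.
segment_icm <- function(pr, sol, lens = NULL, max_anchors = NULL,
                        sweeps = 2) {
  best <- sol
  nb <- length(pr$blocks)
  big <- pr$E > 800
  if (is.null(lens)) lens <- if (big) c(1, 2) else c(1, 3)
  if (is.null(max_anchors)) max_anchors <- if (big) 32 else 16
  for (sw in seq_len(sweeps)) {
    improved <- FALSE
    for (len in lens) {
      for (st in sample(seq_len(max(nb - len + 1, 1)))) {
        bl <- pr$blocks[st:min(st + len - 1, nb)]
        root <- block_root(pr, bl[[1]])
        if (is.na(root)) next
        nanch <- length(pr$cand_of[[root]])
        anchors <- seq_len(nanch)
        if (nanch > max_anchors) {
          s_at <- ifelse(is.na(best$shifts), pr$mu, best$shifts)
          anchors <- order(peak_ks(pr, root, s_at))[seq_len(max_anchors)]
        }
        bl[[1]] <- c(root, setdiff(bl[[1]], root))
        local_best <- best
        for (ap in anchors) {
          g <- propose_segment(pr, best$g, best$shifts, bl, root_pick = ap)
          ev <- eval_genome(pr, g)
          if (ev$score > local_best$score + 1e-12) local_best <- ev
        }
        if (len == 1) {
          g0 <- best$g; g0[bl[[1]]] <- 0L    # block-unmapped alternative
          ev0 <- eval_genome(pr, g0)
          if (ev0$score > local_best$score + 1e-12) local_best <- ev0
        }
        if (local_best$score > best$score + 1e-12) {
          best <- local_best
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}

# A coherent random genome: every block proposed from prior means.
coherent_genome <- function(pr) {
  g <- integer(pr$E)
  none <- rep(NA_real_, pr$n_atoms)
  for (b in sample(seq_along(pr$blocks))) {
    g <- propose_segment(pr, g, none, pr$blocks[b])
  }
  g
}

#' Map expected peaks onto observed peaks (one optimization run)
#'
#' Runs the evolutionary optimization: genomes are per-peak candidate
#' choices organized in residue blocks; crossover cuts at a residue
#' boundary, mutation re-proposes whole blocks as coherent spin-system
#' hypotheses, selection is by tournament, and the elite is polished by
#' local mapping/shift refinement. Atom shifts are the tolerance-weighted
#' mean of the mapped peak positions attributed to the atom; every mapped
#' peak deviates from its observed position by at most the dimension
#' tolerance, and every assigned shift lies within 3 SD of its prior. The
#' returned score is never below that of the empty mapping.
#'
#' @param expected Expected-peak tibble (through-bond and/or NOESY rows).
#' @param observed Observed-peak tibble (`spectrum`, `id`, `w1`..`w3`,
#'   `confidence`), already filtered with [select_observed_peaks()].
#' @param priors Prior tibble from [statistical_priors()] or
#'   [predicted_priors()].
#' @param params Engine parameters from [engine_params()].
#' @return A `shift_mapping` object: list with `shifts` (tibble
#'   `residue_number`, `atom_name`, `nucleus`, `shift`, `n_peaks`),
#'   `mapping` (tibble `expected_row`, `spectrum`, `obs_id`), `score`,
#'   `n_mapped`, `n_expected`.
#' @export
run_single <- function(expected, observed, priors, params = engine_params()) {
  if (nrow(expected) == 0) stop("no expected peaks", call. = FALSE)
  pr <- build_problem(expected, observed, priors, params)
  sol <- withr::with_seed(params$seed, run_search(pr))
  as_shift_mapping(pr, sol)
}

run_search <- function(pr) {
  params <- pr$params
  best <- local_refine(pr, integer(pr$E))
  empty <- eval_genome(pr, integer(pr$E))
  if (empty$score > best$score) best <- empty
  if (pr$nc == 0 || params$generations == 0) return(best)
  np <- params$population_size
  pop <- vector("list", np)
  pop[[1]] <- best
  pop[[2]] <- empty
  if (np >= 3) for (i in 3:np) pop[[i]] <- eval_genome(pr, coherent_genome(pr))
  fit <- vapply(pop, `[[`, 0, "score")
  if (max(fit) > best$score) best <- pop[[which.max(fit)]]
  blocks_res <- pr$block_res
  nb <- length(pr$blocks)
  block_of_peak <- integer(pr$E)
  for (b in seq_len(nb)) block_of_peak[pr$blocks[[b]]] <- b
  stall <- 0
  for (gen in seq_len(params$generations)) {
    newpop <- vector("list", np)
    newpop[[1]] <- best
    for (i in 2:np) {
      pick <- function() {
        cand <- sample.int(np, min(params$tournament_size, np))
        pop[[cand[which.max(fit[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      cut <- blocks_res[sample.int(nb, 1)]
      take1 <- blocks_res[block_of_peak] < cut
      g <- ifelse(take1, p1$g, p2$g)
      mut <- which(stats::runif(nb) < params$mutation_rate)
      for (b in mut) {
        len <- sample(1:3, 1)
        g <- propose_segment(pr, g, p1$shifts,
                             pr$blocks[b:min(b + len - 1, nb)])
      }
      newpop[[i]] <- eval_genome(pr, g)
    }
    fi <- vapply(newpop, `[[`, 0, "score")
    bi <- which.max(fi)
    if (pr$E <= 800 || gen %% 3 == 0) {
      ref <- local_refine(pr, newpop[[bi]]$g, niter = 2)
      if (ref$score > newpop[[bi]]$score) newpop[[bi]] <- ref
    }
    pop <- newpop
    fit <- vapply(pop, `[[`, 0, "score")
    if (max(fit) > best$score + 1e-12) {
      best <- pop[[which.max(fit)]]
      stall <- 0
    } else stall <- stall + 1
    if (gen %% 10 == 0 || stall >= params$stall) {
      ref <- segment_icm(pr, best, sweeps = 1)
      if (ref$score > best$score + 1e-12) {
        best <- ref
        pop[[1]] <- best
        fit[1] <- best$score
        stall <- 0
      }
    }
    if (stall >= params$stall) break
  }
  best <- segment_icm(pr, best)
  repeat {
    sw <- swap_icm(pr, best)
    if (sw$score <= best$score + 1e-12) break
    best <- segment_icm(pr, sw, sweeps = 1)
    if (best$score < sw$score) best <- sw
  }
  best <- local_refine(pr, best$g)
  if (pr$nc <= 400) best <- peak_polish(pr, best)
  if (pr$E <= 12 && pr$nc <= 120) {
    best <- pair_polish(pr, best)
    # small instances afford independent restarts, fully polished
    for (r in seq_len(8)) {
      cand <- eval_genome(pr, coherent_genome(pr))
      cand <- local_refine(pr, cand$g)
      cand <- peak_polish(pr, cand)
      cand <- pair_polish(pr, cand)
      if (cand$score > best$score + 1e-12) best <- cand
    }
  }
  best
}

as_shift_mapping <- function(pr, sol) {
  sel <- which(sol$g > 0)
  mapping <- tibble::tibble(
    expected_row = sel,
    spectrum = pr$expected$spectrum[sel],
    obs_id = if (length(sel) > 0) pr$observed$id[pr$cobs[sol$g[sel]]] else integer(0)
  )
  aset <- which(!is.na(sol$shifts))
  parts <- strsplit(pr$akey[aset], ":", fixed = TRUE)
  npk <- integer(length(aset))
  if (length(sel) > 0) {
    use <- unlist(pr$lf_rows_by_cr[sol$g[sel]], use.names = FALSE)
    cnt <- table(factor(pr$lf_a[use], levels = aset))
    npk <- as.integer(cnt)
  }
  shifts <- tibble::tibble(
    residue_number = as.integer(vapply(parts, `[`, "", 1)),
    atom_name = vapply(parts, `[`, "", 2),
    shift = sol$shifts[aset],
    n_peaks = npk
  )
  shifts$nucleus <- nucleus_of(shifts$atom_name)
  out <- list(shifts = shifts, mapping = mapping, score = sol$score,
              n_mapped = length(sel), n_expected = pr$E)
  class(out) <- "shift_mapping"
  out
}

#' @export
print.shift_mapping <- function(x, ...) {
  cat(sprintf("<shift_mapping> %d/%d expected peaks mapped, %d atoms assigned, score %.3f\n",
              x$n_mapped, x$n_expected, nrow(x$shifts), x$score))
  invisible(x)
}

#' Score a mapping solution
#'
#' Evaluates the objective: the sum over mapped expected peaks of
#' probability times a Gaussian positional kernel (SD = tolerance/2 per
#' dimension), minus `lambda` times the probability mass of unmapped
#' peaks, plus `beta` times a Gaussian prior kernel per assigned atom.
#' Errors if a mapped peak violates a dimension tolerance.
#'
#' @param solution A `shift_mapping` object (or a tibble like its
#'   `mapping` element).
#' @inheritParams run_single
#' @return The numeric score.
#' @export
score_mapping <- function(solution, expected, observed, priors,
                          params = engine_params()) {
  pr <- build_problem(expected, observed, priors, params)
  mp <- if (inherits(solution, "shift_mapping")) solution$mapping else solution
  g <- integer(pr$E)
  for (k in seq_len(nrow(mp))) {
    e <- mp$expected_row[k]
    orow <- which(pr$observed$id == mp$obs_id[k] &
                    pr$observed$spectrum == mp$spectrum[k])
    hit <- pr$cand_of[[e]][pr$cobs[pr$cand_of[[e]]] %in% orow]
    if (length(hit) == 0) stop("mapped peak outside the candidate range",
                               call. = FALSE)
    g[e] <- hit[1]
  }
  ev <- eval_genome(pr, g, repair = FALSE)
  if (!ev$feasible) stop("mapping violates a dimension tolerance", call. = FALSE)
  ev$score
}

#' Exhaustive mapping search (test oracle)
#'
#' Enumerates every feasible mapping (each expected peak to one of its
#' candidate observed peaks or to nothing) and returns the global optimum
#' of the score. Intended as an independent oracle for small instances.
#'
#' @inheritParams run_single
#' @param max_states Enumeration cap; instances with more mapping
#'   combinations raise an error (default 1e6).
#' @return A `shift_mapping` object at the global optimum.
#' @export
exhaustive_search <- function(expected, observed, priors,
                              params = engine_params(), max_states = 1e6) {
  pr <- build_problem(expected, observed, priors, params)
  sizes <- vapply(pr$cand_of, length, 0L) + 1
  if (prod(sizes) > max_states) {
    stop(sprintf("instance too large for exhaustive search (%g states)",
                 prod(sizes)), call. = FALSE)
  }
  counter <- integer(pr$E)
  best <- eval_genome(pr, integer(pr$E))
  repeat {
    g <- integer(pr$E)
    nz <- counter > 0
    g[nz] <- vapply(which(nz), function(e) pr$cand_of[[e]][counter[e]], 0L)
    ev <- eval_genome(pr, g, repair = FALSE)
    if (ev$feasible && ev$score > best$score) best <- ev
    e <- 1
    while (e <= pr$E) {
      counter[e] <- counter[e] + 1
      if (counter[e] < sizes[e]) break
      counter[e] <- 0L
      e <- e + 1
    }
    if (e > pr$E) break
  }
  as_shift_mapping(pr, best)
}
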