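# Multi-run consensus: combine R independent mapping runs into per-atom
# consensus shifts with strong/weak reliability classes, and estimate
# accuracy from the strong fraction.

.consensus_tol <- c("1H" = 0.03, "13C" = 0.4, "15N" = 0.4)

#' Combine independent runs into a consensus assignment
#'
#' For each atom, collects the shift values found across the runs and
#' finds the window of width twice the nucleus tolerance containing the
#' most values (windows are anchored at observed values, which is
#' sufficient for an exact mode search; ties resolved toward the window
#' with the smallest member median). The consensus shift is the mean of
#' the in-window values; support is the in-window fraction of the values
#' found. An atom is classified strong when its support is at least 0.8
#' (and, guarding against sparsely found atoms, it was found in at least
#' half the runs); otherwise weak; atoms never assigned are unassigned.
#'
#' @param solutions List of `shift_mapping` objects (R >= 2; 20 runs by
#'   convention).
#' @param tolerances Named vector of per-nucleus window half-widths
#'   (defaults 0.03 ppm for 1H, 0.4 ppm for 13C/15N).
#' @param atom_set Optional atom tibble; unassigned atoms appear in the
#'   output with class `unassigned`.
#' @param support_denominator `"found"` (default: runs in which the atom
#'   was assigned) or `"total"` (all R runs).
#' @param min_found_fraction Atoms found in fewer than this fraction of
#'   runs are demoted to weak (default 0.5).
#' @return `consensus_assignment` tibble: `residue_number`, `atom_name`,
#'   `nucleus`, `shift`, `support`, `n_runs_found`, `class`.
#' @export
consensus <- function(solutions, tolerances = .consensus_tol,
                      atom_set = NULL, support_denominator = c("found", "total"),
                      min_found_fraction = 0.5) {
  support_denominator <- match.arg(support_denominator)
  R <- length(solutions)
  if (R < 2) stop("consensus requires at least 2 runs", call. = FALSE)
  all_sh <- dplyr::bind_rows(lapply(solutions, function(s) {
    if (inherits(s, "shift_mapping")) s$shifts else s
  }))
  grp <- dplyr::group_by(all_sh, .data$residue_number, .data$atom_name)
  out <- dplyr::summarise(grp, nucleus = .data$nucleus[1], values = list(.data$shift),
                          .groups = "drop")
  res <- purrr::pmap_dfr(out, function(residue_number, atom_name, nucleus, values) {
    tol <- tolerances[[nucleus]]
    v <- values[!is.na(values)]
    nfound <- length(v)
    counts <- vapply(v, function(c0) sum(abs(v - c0) <= tol), 0L)
    cmax <- max(counts)
    cand <- which(counts == cmax)
    if (length(cand) > 1) {
      meds <- vapply(cand, function(i) stats::median(v[abs(v - v[i]) <= tol]), 0)
      cand <- cand[which.min(meds)]
    } else cand <- cand[1]
    inw <- abs(v - v[cand]) <= tol
    denom <- if (support_denominator == "found") nfound else R
    support <- sum(inw) / denom
    tibble::tibble(residue_number = residue_number, atom_name = atom_name,
                   nucleus = nucleus, shift = mean(v[inw]), support = support,
                   n_runs_found = nfound)
  })
  res$class <- ifelse(res$support >= 0.8 &
                        res$n_runs_found >= min_found_fraction * R,
                      "strong", "weak")
  if (!is.null(atom_set)) {
    full <- dplyr::select(atom_set, "residue_number", "atom_name", "nucleus")
    res <- dplyr::left_join(full, res,
                            by = c("residue_number", "atom_name", "nucleus"))
    res$class[is.na(res$shift)] <- "unassigned"
  }
  class(res) <- c("consensus_assignment", class(res))
  res
}

#' Estimate assignment accuracy from the strong fraction
#'
#' Evaluates the empirical linear relationships between the percentage S
#' of strong assignments and the expected accuracy: overall
#' A = 0.89 S + 7.88 (percent) and, for the strong assignments alone,
#' A_strong = 0.45 S + 51.49 (percent).
#'
#' @param S Percentage of strong assignments, in \[0, 100\].
#' @return Tibble with `S`, `A`, `A_strong` (all percent).
#' @export
#' @examples
#' estimate_accuracy(80)
estimate_accuracy <- function(S) {
  if (any(S < 0 | S > 100)) stop("S must be within [0, 100]", call. = FALSE)
  tibble::tibble(S = S, A = 0.89 * S + 7.88, A_strong = 0.45 * S + 51.49)
}
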