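# Evaluation of a consensus assignment against a reference shift list
# with per-nucleus tolerances.

.eval_tol <- c("1H" = 0.03, "13C" = 0.4, "15N" = 0.4)

# Stereo partner of an atom name (HB2 <-> HB3, CD1 <-> CD2 with their
# protons, ...); NA when the atom has no stereo partner.
stereo_partner <- function(atom_name, residue_type) {
  out <- rep(NA_character_, length(atom_name))
  m23 <- grepl("^H.*2$", atom_name) & !grepl("^H.*[12]2$", atom_name)
  out[m23] <- sub("2$", "3", atom_name[m23])
  m32 <- grepl("^H.*3$", atom_name) & !grepl("^H.*[12]3$", atom_name)
  out[m32] <- sub("3$", "2", atom_name[m32])
  # side-chain amide NH2 protons (E/Z assignment frequently arbitrary)
  nh21 <- grepl("^H[DE]21$", atom_name)
  out[nh21] <- sub("21$", "22", atom_name[nh21])
  nh22 <- grepl("^H[DE]22$", atom_name)
  out[nh22] <- sub("22$", "21", atom_name[nh22])
  # isopropyl / methyl-pair swaps (VAL, LEU) and their protons
  pair12 <- residue_type %in% c("VAL", "LEU") &
    grepl("^[HC][GD].*1", atom_name)
  out[pair12] <- sub("1", "2", atom_name[pair12])
  pair21 <- residue_type %in% c("VAL", "LEU") & grepl("^[HC][GD].*2", atom_name)
  out[pair21] <- sub("2", "1", atom_name[pair21])
  # glycine HA2/HA3 already covered by the generic 2/3 rule
  out[out == atom_name] <- NA
  out
}

#' Compare a consensus assignment with a reference shift list
#'
#' An assigned atom with a reference value is correct when the absolute
#' deviation is within the nucleus tolerance (0.03 ppm for 1H, 0.4 ppm
#' for 13C/15N). Stereo pairs swapped relative to the reference (e.g.
#' HB2/HB3) count as correct when both match the swapped partner
#' (disable with `stereo_leniency = FALSE`). Metrics: `correct_strong` =
#' correct strong / strong with reference; `correct_weak` analogous;
#' `correct_all` = correct assigned / assigned with reference; `strong` =
#' strong with reference / assigned with reference; `completeness_strong`
#' = correct strong / atoms with reference. Empty denominators yield NA.
#'
#' @param assignment `consensus_assignment` tibble (or any tibble with
#'   `residue_number`, `atom_name`, `nucleus`, `shift` and optionally
#'   `class`).
#' @param reference Reference shift tibble (`residue_number`,
#'   `atom_name`, `shift`).
#' @param tolerances Named per-nucleus tolerance vector.
#' @param stereo_leniency Accept swapped stereo pairs (default TRUE).
#' @return `eval_report` object: list with `metrics` (one-row tibble),
#'   `per_atom_type` tibble and the joined `detail` tibble.
#' @export
compare_assignment <- function(assignment, reference, tolerances = .eval_tol,
                               stereo_leniency = TRUE) {
  if (is.null(reference) || nrow(reference) == 0) {
    stop("reference shift list is empty", call. = FALSE)
  }
  asg <- assignment[!is.na(assignment$shift), ]
  if (!"class" %in% names(asg)) asg$class <- "strong"
  if (!"residue_type" %in% names(asg)) {
    asg$residue_type <- NA_character_
  }
  rkey <- atom_key(reference$residue_number,
                   normalize_atom_name(reference$atom_name))
  nuc <- asg$nucleus
  if (any(!nuc %in% names(tolerances))) {
    stop("no tolerance entry for nucleus ",
         setdiff(nuc, names(tolerances))[1], call. = FALSE)
  }
  tol <- unname(tolerances[nuc])
  ref_val <- reference$shift[match(atom_key(asg$residue_number, asg$atom_name),
                                   rkey)]
  ok <- abs(asg$shift - ref_val) <= tol + 1e-12
  if (stereo_leniency) {
    sp <- stereo_partner(asg$atom_name, asg$residue_type)
    ref_sw <- reference$shift[match(atom_key(asg$residue_number, sp), rkey)]
    ok_sw <- abs(asg$shift - ref_sw) <= tol + 1e-12
    ok <- ok | (!is.na(ok_sw) & ok_sw)
  }
  detail <- dplyr::mutate(asg, reference = ref_val, correct = ok)
  with_ref <- detail[!is.na(detail$correct), ]
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  s <- with_ref$class == "strong"
  n_ref_total <- length(unique(rkey))
  metrics <- tibble::tibble(
    correct_strong = pct(sum(with_ref$correct[s]), sum(s)),
    completeness_strong = pct(sum(with_ref$correct[s]), n_ref_total),
    strong = pct(sum(s), nrow(with_ref)),
    correct_weak = pct(sum(with_ref$correct[!s]), sum(!s)),
    correct_all = pct(sum(with_ref$correct), nrow(with_ref))
  )
  pat <- dplyr::group_by(with_ref, .data$nucleus)
  per_atom_type <- dplyr::summarise(pat, n = dplyr::n(),
                                    correct = 100 * mean(.data$correct),
                                    .groups = "drop")
  out <- list(metrics = metrics, per_atom_type = per_atom_type,
              detail = detail)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat("Assignment evaluation (percent):\n")
  cat(sprintf("  Correct (strong) %6.2f  Completeness (strong) %6.2f  Strong %6.2f\n",
              m$correct_strong, m$completeness_strong, m$strong))
  cat(sprintf("  Correct (weak)   %6.2f  Correct (all)        %6.2f\n",
              m$correct_weak, m$correct_all))
  invisible(x)
}

#' Backbone amide (HN, N) pair accuracy
#'
#' Fraction of residues whose amide 1H and 15N are both assigned, both
#' have reference values, and both deviate within their tolerances
#' (0.03 and 0.4 ppm). A residue's amide is correct only as a pair.
#'
#' @inheritParams compare_assignment
#' @return Percentage of correct amide pairs, or NA when no pair is
#'   assessable.
#' @export
hn_accuracy <- function(assignment, reference, tolerances = .eval_tol) {
  asg <- assignment[!is.na(assignment$shift) &
                      assignment$atom_name %in% c("HN", "N"), ]
  rkey <- atom_key(reference$residue_number,
                   normalize_atom_name(reference$atom_name))
  asg$reference <- reference$shift[match(atom_key(asg$residue_number,
                                                  asg$atom_name), rkey)]
  asg <- asg[!is.na(asg$reference), ]
  wide <- tidyr::pivot_wider(asg[, c("residue_number", "atom_name", "shift",
                                     "reference")],
                             names_from = "atom_name",
                             values_from = c("shift", "reference"))
  if (!all(c("shift_HN", "shift_N") %in% names(wide))) return(NA_real_)
  wide <- wide[!is.na(wide$shift_HN) & !is.na(wide$shift_N), ]
  if (nrow(wide) == 0) return(NA_real_)
  ok <- abs(wide$shift_HN - wide$reference_HN) <= tolerances[["1H"]] + 1e-12 &
    abs(wide$shift_N - wide$reference_N) <= tolerances[["15N"]] + 1e-12
  100 * mean(ok)
}
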