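#' Default chemical-shift statistics table
#'
#' A per-(residue type, atom) table of mean and standard deviation of
#' protein chemical shifts, patterned on database-wide statistics. Backbone
#' and CB values are tabulated per residue type; side-chain values follow
#' atom-class rules (methyls, methylenes, aromatics, side-chain amides).
#' The values are bundled package data intended as realistic Gaussian
#' priors, not as a database snapshot.
#'
#' @return Tibble with columns `residue_type`, `atom_name`, `mean`, `sd`
#'   covering every assignable atom of every standard residue.
#' @export
default_shift_statistics <- function() {
  if (!is.null(.pkg_cache$shift_stats)) return(.pkg_cache$shift_stats)
  topo <- dplyr::filter(residue_topology(), .data$assignable)

  ca <- c(ALA = 53.1, ARG = 56.8, ASN = 53.5, ASP = 54.7, CYS = 58.3,
          GLN = 56.6, GLU = 57.3, GLY = 45.4, HIS = 56.5, ILE = 61.6,
          LEU = 55.6, LYS = 56.9, MET = 56.1, PHE = 58.1, PRO = 63.3,
          SER = 58.7, THR = 62.2, TRP = 57.7, TYR = 58.1, VAL = 62.5)
  cb <- c(ALA = 19.0, ARG = 30.7, ASN = 38.7, ASP = 40.9, CYS = 28.0,
          GLN = 29.2, GLU = 30.0, HIS = 30.2, ILE = 38.6, LEU = 42.3,
          LYS = 32.8, MET = 33.0, PHE = 39.9, PRO = 31.8, SER = 63.8,
          THR = 69.7, TRP = 29.9, TYR = 39.3, VAL = 32.7)
  n15 <- c(GLY = 109.7, PRO = 134.0, ALA = 123.2, VAL = 121.1, ILE = 121.5,
           THR = 115.5, SER = 116.3)

  parent_of <- stats::setNames(residue_topology()$hybrid,
    paste(residue_topology()$residue_type, residue_topology()$atom_name))

  rule_row <- function(res, atom, element, parent, hybrid, aliphatic) {
    p_hyb <- parent_of[paste(res, parent)]
    methyl_h <- element == "H" && grepl("^H[BGDEZ].?[123]$", atom) &&
      atom %in% c("HB1","HB2","HB3","HG11","HG12","HG13","HG21","HG22","HG23",
                  "HD11","HD12","HD13","HD21","HD22","HD23","HE1","HE2","HE3") &&
      res %in% c("ALA","VAL","LEU","ILE","THR","MET") &&
      !(res == "ILE" && atom %in% c("HG12","HG13"))
    if (atom == "CA") return(c(ca[[res]], 2.0))
    if (atom == "CB") return(c(cb[[res]], 1.8))
    if (atom == "C") return(c(176.3, 2.0))
    if (atom == "N") return(c(if (res %in% names(n15)) n15[[res]] else 120.0, 4.0))
    if (atom == "HN") return(c(8.3, 0.65))
    if (atom %in% c("HA", "HA2", "HA3"))
      return(c(if (res == "GLY") 3.96 else 4.45, 0.45))
    if (element == "H") {
      if (!is.na(p_hyb) && p_hyb == "sp2" && substr(parent, 1, 1) == "N") {
        if (res == "TRP" && atom == "HE1") return(c(10.1, 0.55))
        if (res == "HIS" && atom == "HD1") return(c(9.5, 1.5))
        if (res == "ARG" && atom == "HE") return(c(7.3, 0.6))
        return(c(7.3, 0.5))                      # ASN/GLN side-chain amide
      }
      if (!is.na(p_hyb) && p_hyb == "sp2") return(c(7.1, 0.5))  # aromatic
      if (methyl_h) return(c(0.95, 0.35))
      if (res %in% c("SER", "THR") && atom %in% c("HB", "HB2", "HB3"))
        return(c(3.95, 0.3))
      if (grepl("^HB", atom)) return(c(1.95, 0.5))
      if (grepl("^HG", atom)) return(c(1.45, 0.5))
      if (grepl("^HD", atom)) return(c(1.75, 0.7))
      return(c(2.6, 0.7))
    }
    if (element == "C") {
      if (!is.na(hybrid) && hybrid == "sp2") {
        if (res %in% c("ASN", "ASP") && atom == "CG") return(c(176.5, 1.8))
        if (res %in% c("GLN", "GLU") && atom == "CD") return(c(178.5, 1.8))
        if (res == "ARG" && atom == "CZ") return(c(159.5, 1.5))
        return(c(127.0, 7.0))                    # aromatic ring carbon
      }
      if (res == "ILE" && atom == "CD1") return(c(13.5, 1.8))
      if (res == "THR" && atom == "CG2") return(c(21.5, 1.2))
      if (res %in% c("VAL", "LEU") && grepl("^C[GD][12]$", atom))
        return(c(22.5, 2.0))
      if (res == "ILE" && atom == "CG2") return(c(17.5, 1.5))
      if (res == "ALA") return(c(19.0, 1.8))
      if (res == "MET" && atom == "CE") return(c(17.0, 1.5))
      if (grepl("^CG", atom)) return(c(27.5, 2.5))
      if (grepl("^CD", atom)) return(c(32.0, 6.0))
      if (grepl("^CE", atom)) return(c(38.0, 5.0))
      return(c(30.0, 5.0))
    }
    # side-chain nitrogens
    if (res == "ASN" && atom == "ND2") return(c(112.8, 2.2))
    if (res == "GLN" && atom == "NE2") return(c(111.9, 1.9))
    if (res == "ARG" && atom == "NE") return(c(84.6, 1.7))
    if (res == "TRP" && atom == "NE1") return(c(129.3, 2.1))
    if (res == "HIS" && atom == "ND1") return(c(192.0, 12.0))
    if (res == "HIS" && atom == "NE2") return(c(180.0, 12.0))
    c(120.0, 5.0)
  }

  ms <- t(mapply(rule_row, topo$residue_type, topo$atom_name, topo$element,
                 topo$parent, topo$hybrid, topo$aliphatic))
  out <- tibble::tibble(residue_type = topo$residue_type,
                        atom_name = topo$atom_name,
                        mean = unname(ms[, 1]), sd = unname(ms[, 2]))
  .pkg_cache$shift_stats <- out
  out
}

#' Gaussian shift priors from a statistics table
#'
#' Attaches one Gaussian prior (mean, sd) to every atom of an atom set by
#' looking up the per-(residue type, atom name) statistics table.
#'
#' @param atom_set Atom tibble from [enumerate_atoms()].
#' @param stats_table Statistics tibble with columns `residue_type`,
#'   `atom_name`, `mean`, `sd` (default [default_shift_statistics()]).
#' @return Prior tibble: `residue_number`, `residue_type`, `atom_name`,
#'   `nucleus`, `mean`, `sd`, `source = "statistics"`.
#' @export
statistical_priors <- function(atom_set, stats_table = default_shift_statistics()) {
  pri <- dplyr::left_join(
    dplyr::select(atom_set, "residue_number", "residue_type", "atom_name",
                  "nucleus"),
    stats_table, by = c("residue_type", "atom_name"))
  miss <- which(is.na(pri$mean) | is.na(pri$sd))
  if (length(miss) > 0) {
    m <- pri[miss[1], ]
    stop(sprintf("no statistics entry for atom %s of residue %s %d",
                 m$atom_name, m$residue_type, m$residue_number), call. = FALSE)
  }
  if (any(pri$sd <= 0)) stop("prior sd must be positive", call. = FALSE)
  pri$source <- "statistics"
  pri
}

# Default per-atom-name uncertainties (ppm) for structure-based shift
# predictions, from predictor-vs-database RMSDs.
.predicted_sd_defaults <- c("C" = 0.85, "CA" = 0.77, "CB" = 0.86,
                            "HN" = 0.39, "HA" = 0.20, "N" = 1.98)

#' Overlay predicted backbone shifts onto statistical priors
#'
#' Replaces the statistical prior of each predicted backbone atom
#' (CA, CB, C, HN, HA, N) by a Gaussian centred at the predicted value with
#' a per-atom-name default uncertainty (C 0.85, CA 0.77, CB 0.86, HN 0.39,
#' HA 0.20, N 1.98 ppm), narrowing the assignment search range. All other
#' atoms keep their statistical prior.
#'
#' @param atom_set Atom tibble from [enumerate_atoms()].
#' @param predictions Tibble with columns `residue_number`, `atom_name`,
#'   `shift` (ppm); may carry an `sd` column to override the default.
#' @param stats_table Statistics table used for the fallback priors.
#' @param sd_overrides Optional named numeric vector of per-atom-name sds
#'   replacing the defaults (e.g. `c(CA = 0.5)`).
#' @return Prior tibble as from [statistical_priors()], with `source`
#'   `"predicted"` on overlaid rows.
#' @export
predicted_priors <- function(atom_set, predictions,
                             stats_table = default_shift_statistics(),
                             sd_overrides = NULL) {
  pri <- statistical_priors(atom_set, stats_table)
  if (is.null(predictions) || nrow(predictions) == 0) return(pri)
  predictions$atom_name <- normalize_atom_name(predictions$atom_name)
  bad <- !predictions$atom_name %in% names(.predicted_sd_defaults)
  if (any(bad)) {
    stop(sprintf("prediction for non-backbone atom name '%s' rejected",
                 predictions$atom_name[which(bad)[1]]), call. = FALSE)
  }
  sds <- .predicted_sd_defaults
  if (!is.null(sd_overrides)) sds[names(sd_overrides)] <- sd_overrides
  key <- atom_key(pri$residue_number, pri$atom_name)
  pkey <- atom_key(predictions$residue_number, predictions$atom_name)
  idx <- match(pkey, key)
  keep <- !is.na(idx)
  pri$mean[idx[keep]] <- predictions$shift[keep]
  pri$sd[idx[keep]] <- if ("sd" %in% names(predictions) &&
                           !all(is.na(predictions$sd))) {
    ifelse(is.na(predictions$sd[keep]),
           unname(sds[predictions$atom_name[keep]]),
           predictions$sd[keep])
  } else unname(sds[predictions$atom_name[keep]])
  pri$source[idx[keep]] <- "predicted"
  pri
}
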