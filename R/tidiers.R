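# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-run mapping solution
#'
#' @param x A `shift_mapping` object.
#' @param ... Unused.
#' @return The per-atom shift tibble.
#' @method tidy shift_mapping
#' @export
tidy.shift_mapping <- function(x, ...) x$shifts

#' One-row summary of a mapping solution
#'
#' @param x A `shift_mapping` object.
#' @param ... Unused.
#' @return Tibble with `score`, `n_mapped`, `n_expected`, `n_assigned`.
#' @method glance shift_mapping
#' @export
glance.shift_mapping <- function(x, ...) {
  tibble::tibble(score = x$score, n_mapped = x$n_mapped,
                 n_expected = x$n_expected, n_assigned = nrow(x$shifts))
}

#' Tidy a pipeline result
#'
#' @param x A `shift_assignment` object.
#' @param ... Unused.
#' @return The consensus tibble.
#' @method tidy shift_assignment
#' @export
tidy.shift_assignment <- function(x, ...) tibble::as_tibble(x$consensus)

#' One-row summary of a pipeline result
#'
#' @param x A `shift_assignment` object.
#' @param ... Unused.
#' @return Tibble with run count, assignment counts, S and the accuracy
#'   estimates (plus evaluation metrics when a reference was supplied).
#' @method glance shift_assignment
#' @export
glance.shift_assignment <- function(x, ...) {
  out <- tibble::tibble(
    n_runs = x$n_runs,
    n_assigned = sum(x$consensus$class != "unassigned"),
    n_strong = sum(x$consensus$class == "strong"),
    S = x$estimate$S, A = x$estimate$A, A_strong = x$estimate$A_strong
  )
  if (!is.null(x$evaluation)) out <- dplyr::bind_cols(out, x$evaluation$metrics)
  out
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` object.
#' @param ... Unused.
#' @return The per-atom detail tibble (assigned shift, reference,
#'   correctness).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) tibble::as_tibble(x$detail)

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report` object.
#' @param ... Unused.
#' @return The metrics tibble.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) x$metrics
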