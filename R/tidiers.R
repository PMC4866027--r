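#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an insertion analysis
#'
#' @param x An `insertion_analysis` from [locate_insertion()].
#' @param ... Unused.
#' @return The insertion-call tibble (one row per call), without the
#'   `support` list-column.
#' @method tidy insertion_analysis
#' @export
tidy.insertion_analysis <- function(x, ...) {
  out <- x$calls
  out$support <- NULL
  out
}

#' @rdname tidy.insertion_analysis
#' @return For `glance()`: a one-row tibble with `n_pairs`, `n_orphans`,
#'   `n_calls`, `n_refined`, `n_local_sv`.
#' @method glance insertion_analysis
#' @export
glance.insertion_analysis <- function(x, ...) {
  tibble(
    n_pairs = x$n_pairs,
    n_orphans = sum(x$orphans$aligned, na.rm = TRUE),
    n_calls = nrow(x$calls),
    n_refined = sum(x$calls$refined),
    n_local_sv = nrow(x$local_sv)
  )
}

#' Tidy a comparative report
#'
#' @param x A `somavar_report` from [run_all()].
#' @param ... Unused.
#' @return The per-class SV summary tibble; `glance()` returns one row of
#'   whole-run counts.
#' @method tidy somavar_report
#' @export
tidy.somavar_report <- function(x, ...) {
  x$class_summary %||%
    tibble(class_label = character(), direction = character())
}

#' @rdname tidy.somavar_report
#' @method glance somavar_report
#' @export
glance.somavar_report <- function(x, ...) {
  tibble(
    n_sv_calls = if (is.null(x$calls)) NA_integer_ else
      sum(!x$calls$filtered_as_heterogeneity),
    n_heterogeneity_flagged = if (is.null(x$calls)) NA_integer_ else
      sum(x$calls$filtered_as_heterogeneity),
    n_private_substitutions = if (is.null(x$substitutions)) NA_integer_ else
      nrow(x$substitutions),
    n_insertions = if (is.null(x$insertions)) NA_integer_ else
      nrow(x$insertions),
    n_stages_skipped = length(x$skipped)
  )
}
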