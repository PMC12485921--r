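#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for pipeline result objects
#'
#' `tidy()` returns the per-observation table of a result object (ortholog
#' pairs, selected pattern positions, profile cells, per-record verdicts);
#' `glance()` returns a one-row summary.
#'
#' @param x A result object (`ic_orthology`, `pattern_scan`, `ic_profile`,
#'   `ic_validation`).
#' @param ... Unused.
#' @return A tibble.
#' @name icortho-tidiers
NULL

#' @rdname icortho-tidiers
#' @export
tidy.ic_orthology <- function(x, ...) tibble::as_tibble(x$pairs)

#' @rdname icortho-tidiers
#' @export
glance.ic_orthology <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_one_to_one = sum(x$pairs$relation == "one-to-one"),
    n_co_ortholog = sum(x$pairs$relation == "co-ortholog"),
    n_proteomes = dplyr::n_distinct(x$pairs$proteome),
    n_clusters = dplyr::n_distinct(x$clusters$cluster_id)
  )
}

#' @rdname icortho-tidiers
#' @export
tidy.pattern_scan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "pattern_scan")
  out
}

#' @rdname icortho-tidiers
#' @export
glance.pattern_scan <- function(x, ...) {
  all_cols <- attr(x, "all_columns")
  tibble(
    n_columns = nrow(all_cols),
    n_selected = nrow(x),
    n_skipped = length(attr(x, "skipped")),
    n_perm = attr(x, "n_perm"),
    p_max = attr(x, "p_max")
  )
}

#' @rdname icortho-tidiers
#' @export
tidy.ic_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "ic_profile")
  out
}

#' @rdname icortho-tidiers
#' @export
glance.ic_profile <- function(x, ...) {
  tibble(
    n_ics = dplyr::n_distinct(x$ic),
    n_organisms = dplyr::n_distinct(x$organism),
    n_present = sum(x$state != 0L),
    n_co_ortholog = sum(x$state == 2L),
    occupancy = mean(x$state != 0L)
  )
}

#' @rdname icortho-tidiers
#' @export
tidy.ic_validation <- function(x, ...) tibble::as_tibble(x$verdicts)

#' @rdname icortho-tidiers
#' @export
glance.ic_validation <- function(x, ...) {
  tibble(
    n_records = x$report$n_records,
    n_failed_records = x$report$n_failed_records,
    n_pairs_in = x$report$n_pairs_in,
    n_pairs_out = x$report$n_pairs_out
  )
}
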