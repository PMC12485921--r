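TM_SOURCE_PRECEDENCE <- c("literature", "uniprot", "predictor_a",
                          "predictor_b", "structure")

#' Merge transmembrane-interval annotations from multiple sources
#'
#' Annotation sources are ranked literature > uniprot > predictors >
#' structure (sequential verification order, not a vote); for each protein
#' the highest-precedence non-empty source defines the consensus set
#' (predictor_a and predictor_b count as one rank and are pooled).
#' Overlapping intervals of the same kind within the chosen set are
#' unioned. Intramembrane (`IM`) intervals are kept but never counted as
#' TMs.
#'
#' @param intervals Tibble: `protein`, `source`, `kind` (`TM`/`IM`),
#'   `start`, `end` (1-based inclusive, `start <= end`).
#' @param protein_length Named integer vector (or tibble `protein`,
#'   `length`) giving each protein's length, for bounds checking.
#' @return Consensus tibble: `protein`, `kind`, `start`, `end`, `source`.
#' @export
merge_tm_sources <- function(intervals, protein_length) {
  stopifnot(is.data.frame(intervals))
  if (is.data.frame(protein_length)) {
    protein_length <- setNames(protein_length$length, protein_length$protein)
  }
  if (nrow(intervals) == 0) {
    return(tibble(protein = character(), kind = character(),
                  start = integer(), end = integer(), source = character()))
  }
  if (!all(intervals$source %in% TM_SOURCE_PRECEDENCE)) {
    abort(sprintf("unknown source(s): %s",
                  paste(setdiff(intervals$source, TM_SOURCE_PRECEDENCE),
                        collapse = ", ")))
  }
  if (any(intervals$start < 1 | intervals$start > intervals$end)) {
    abort("intervals must satisfy 1 <= start <= end")
  }
  len <- protein_length[intervals$protein]
  if (anyNA(len)) abort("protein_length must cover every protein")
  if (any(intervals$end > len)) {
    abort("interval end exceeds protein length")
  }

  rank_of <- function(source) {
    # predictors share one rank
    r <- match(source, TM_SOURCE_PRECEDENCE)
    dplyr::if_else(source %in% c("predictor_a", "predictor_b"), 3L, r)
  }
  intervals |>
    mutate(rank = rank_of(.data$source)) |>
    group_by(.data$protein) |>
    filter(.data$rank == min(.data$rank)) |>
    group_by(.data$protein, .data$kind) |>
    dplyr::group_modify(~ union_intervals(.x)) |>
    ungroup() |>
    arrange(.data$protein, .data$start) |>
    select("protein", "kind", "start", "end", "source")
}

#' Union overlapping/adjacent-in-overlap intervals; keeps source labels
#' @noRd
union_intervals <- function(df) {
  df <- arrange(df, .data$start, .data$end)
  starts <- df$start
  ends <- df$end
  out_s <- integer(0); out_e <- integer(0); out_src <- character(0)
  cur_s <- starts[1]; cur_e <- ends[1]; cur_src <- df$source[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) { # overlap
      cur_e <- max(cur_e, ends[i])
      cur_src <- paste(sort(unique(c(cur_src, df$source[i]))), collapse = ";")
    } else {
      out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
      out_src <- c(out_src, cur_src)
      cur_s <- starts[i]; cur_e <- ends[i]; cur_src <- df$source[i]
    }
  }
  tibble(start = c(out_s, cur_s), end = c(out_e, cur_e),
         source = c(out_src, cur_src))
}

#' Call the pore-containing functional domain from consensus TM intervals
#'
#' The domain spans from the first to the last membrane-spanning segment:
#' `start = min(starts)`, `end = max(ends)`. The reported `length` is
#' `end - start` (the span-difference convention used by the source
#' annotation tables, e.g. 228 - 8 = 220 for Aquaporin-1), which is one
#' less than the inclusive residue count -- a deliberate departure from
#' inclusive-length conventions. `n_tm` counts TM-kind intervals only.
#'
#' @param consensus Consensus tibble from [merge_tm_sources()] (one or
#'   more proteins).
#' @return Tibble: `protein`, `start`, `end`, `length`, `n_tm`; proteins
#'   with no intervals are absent (no-domain).
#' @export
#' @examples
#' tm <- aquaporin1_tm_intervals()
#' define_pore_domain(merge_tm_sources(tm, c(AQP1 = 269)))
define_pore_domain <- function(consensus) {
  if (nrow(consensus) == 0) {
    return(tibble(protein = character(), start = integer(), end = integer(),
                  length = integer(), n_tm = integer()))
  }
  consensus |>
    group_by(.data$protein) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_tm = sum(.data$kind == "TM"),
      .groups = "drop"
    ) |>
    mutate(length = .data$end - .data$start) |>
    select("protein", "start", "end", "length", "n_tm")
}

#' Classify a protein's channel unit type
#'
#' A protein with a pore-containing domain is `pore-containing`; one
#' without a pore domain but with experimental evidence of membership in a
#' channel complex is `auxiliary`; otherwise it is `excluded` from the
#' curated channel list.
#'
#' @param units Tibble: `protein`, `has_pore_domain` (logical),
#'   `complex_evidence` (logical).
#' @return Tibble: `protein`, `label`, `rationale`.
#' @export
classify_unit <- function(units) {
  stopifnot(all(c("protein", "has_pore_domain", "complex_evidence") %in%
                  names(units)))
  units |>
    mutate(
      label = dplyr::case_when(
        .data$has_pore_domain ~ "pore-containing",
        .data$complex_evidence ~ "auxiliary",
        TRUE ~ "excluded"
      ),
      rationale = dplyr::case_when(
        .data$has_pore_domain ~ "pore-containing functional domain present",
        .data$complex_evidence ~
          "no pore domain, but experimental evidence of channel-complex membership",
        TRUE ~ "no pore domain and no complex evidence"
      )
    ) |>
    select("protein", "label", "rationale")
}

#' Literature-based transmembrane intervals of human Aquaporin-1
#'
#' The six literature-annotated TM segments of Aquaporin-1 (UniProt
#' P29972, 269 aa), the worked example for pore-domain calling: the
#' consensus spans residues 8--228, domain length 220 under the
#' span-difference convention.
#'
#' @return Tibble: `protein`, `source`, `kind`, `start`, `end`.
#' @export
aquaporin1_tm_intervals <- function() {
  path <- system.file("extdata", "aquaporin1_tm_literature.tsv",
                      package = "icortho", mustWork = TRUE)
  read_tsv_cells(path) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}
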