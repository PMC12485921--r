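#' Scoring scheme for local alignment and E-value statistics
#'
#' Bundles the substitution matrix, affine gap penalties (a gap of length
#' `L` costs `gap_open + L * gap_extend`) and the Karlin--Altschul
#' parameters `K` and `lambda` used to convert raw scores into bitscores
#' and E-values. Defaults are the conventional gapped BLOSUM62 constants
#' (`lambda = 0.267`, `K = 0.041`); the ungapped pair is available via
#' `scoring_scheme(gapped = FALSE)`.
#'
#' @param matrix Substitution matrix name (a matrix shipped with
#'   \pkg{Biostrings}, e.g. `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param K,lambda Karlin--Altschul parameters (finite, positive).
#' @param gapped If `FALSE`, uses the ungapped BLOSUM62 constants
#'   (`lambda = 0.318`, `K = 0.134`).
#' @return A list of class `scoring_scheme`.
#' @export
#' @examples
#' scoring_scheme()
scoring_scheme <- function(matrix = "BLOSUM62",
                           gap_open = 11,
                           gap_extend = 1,
                           K = if (gapped) 0.041 else 0.134,
                           lambda = if (gapped) 0.267 else 0.318,
                           gapped = TRUE) {
  if (is.character(matrix)) {
    name <- matrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  } else {
    name <- "custom"
  }
  if (gap_open < 0 || gap_extend < 0) abort("gap penalties must be >= 0")
  if (!is.finite(K) || !is.finite(lambda) || K <= 0 || lambda <= 0) {
    abort("K and lambda must be finite and positive")
  }
  structure(
    list(
      matrix_name = name, matrix = matrix,
      gap_open = gap_open, gap_extend = gap_extend,
      K = K, lambda = lambda
    ),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> %s, gap open %g / extend %g, K = %g, lambda = %g\n",
    x$matrix_name, x$gap_open, x$gap_extend, x$K, x$lambda
  ))
  invisible(x)
}

#' Optimal Smith--Waterman local alignment of two sequences
#'
#' Computes the optimal local-alignment score under affine gap penalties.
#' When no positive-scoring local alignment exists the score is 0 and the
#' matched intervals are `NA` (the empty alignment).
#'
#' @param query,subject Amino-acid sequences (20-letter alphabet plus X).
#' @param scheme A [scoring_scheme()].
#' @return One-row tibble: `raw_score`, `qstart`, `qend`, `sstart`, `send`
#'   (1-based inclusive intervals).
#' @export
#' @examples
#' local_align("ACDE", "ACDE")
local_align <- function(query, subject, scheme = scoring_scheme()) {
  stopifnot(length(query) == 1L, length(subject) == 1L)
  assert_aa(query, "query")
  assert_aa(subject, "subject")
  hits <- align_query_to_set(query, subject, scheme)
  select(hits, "raw_score", "qstart", "qend", "sstart", "send")
}

#' Align one query against a character vector of subjects (vectorised)
#' @noRd
align_query_to_set <- function(query, subjects, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = Biostrings::AAString(query),
    type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend,
    scoreOnly = FALSE
  )
  raw_score <- Biostrings::score(pa)
  qstart <- Biostrings::start(Biostrings::subject(pa))
  qend <- Biostrings::end(Biostrings::subject(pa))
  sstart <- Biostrings::start(Biostrings::pattern(pa))
  send <- Biostrings::end(Biostrings::pattern(pa))
  none <- raw_score <= 0
  raw_score[none] <- 0
  qstart[none] <- qend[none] <- sstart[none] <- send[none] <- NA_integer_
  tibble(
    raw_score = raw_score,
    qstart = qstart, qend = qend, sstart = sstart, send = send
  )
}

#' Karlin--Altschul E-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' search space of `n` residues.
#'
#' @param raw_score Raw alignment score(s).
#' @param m Query length (>= 1).
#' @param n Search-space length in residues (>= 1); by convention the total
#'   residue count of the searched proteome set.
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value(s).
#' @export
#' @examples
#' hit_evalue(40, m = 100, n = 100)
hit_evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  if (any(m < 1) || any(n < 1)) abort("m and n must be >= 1")
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}

#' Bitscore of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams hit_evalue
#' @return Numeric bitscore(s).
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' All-vs-all local-alignment search with an E-value cutoff
#'
#' Aligns every query against every database sequence, keeps the best local
#' alignment per (query, subject) pair with `E <= e_max`, and returns a
#' deterministic hit table ordered by bitscore (descending), E-value
#' (ascending) and subject id (lexicographic) within each query. The
#' search-space size `n` for E-values is the total residue count of the
#' database, mirroring search-tool convention.
#'
#' @param queries Tibble with columns `protein` and `sequence`.
#' @param database Tibble with columns `protein`, `sequence` and optionally
#'   `organism` (carried through as `proteome`).
#' @param scheme A [scoring_scheme()].
#' @param e_max Maximum E-value retained.
#' @return Tibble: `query`, `subject`, `proteome`, `raw_score`, `bitscore`,
#'   `evalue`, `qstart`, `qend`, `sstart`, `send`.
#' @export
search_all <- function(queries, database, scheme = scoring_scheme(),
                       e_max = 1e-5) {
  stopifnot(is.data.frame(queries), is.data.frame(database))
  if (nrow(database) == 0) abort("database must be non-empty")
  empty <- tibble(
    query = character(), subject = character(), proteome = character(),
    raw_score = numeric(), bitscore = numeric(), evalue = numeric(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer()
  )
  if (nrow(queries) == 0) return(empty)
  assert_aa(queries$sequence, "query sequence")
  assert_aa(database$sequence, "database sequence")
  n_db <- sum(nchar(database$sequence))
  proteome <- if ("organism" %in% names(database)) {
    database$organism
  } else {
    rep(NA_character_, nrow(database))
  }

  hits <- list_rbind(lapply(seq_len(nrow(queries)), function(i) {
    h <- align_query_to_set(queries$sequence[i], database$sequence, scheme)
    mutate(
      h,
      query = queries$protein[i],
      subject = database$protein,
      proteome = proteome,
      bitscore = bitscore(.data$raw_score, scheme),
      # floor at the smallest positive double: underflowed E-values stay
      # positive so cutoffs behave monotonically
      evalue = pmax(
        hit_evalue(.data$raw_score, nchar(queries$sequence[i]), n_db, scheme),
        .Machine$double.xmin
      )
    )
  }))
  hits |>
    filter(.data$raw_score > 0, .data$evalue <= e_max) |>
    arrange(.data$query, desc(.data$bitscore), .data$evalue, .data$subject) |>
    select(
      "query", "subject", "proteome", "raw_score", "bitscore", "evalue",
      "qstart", "qend", "sstart", "send"
    )
}
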