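#' Thresholds for sequence-level quality-control checks
#'
#' The length bounds come straight from the validation procedure
#' (fragments `< 30` aa, fusions/misassemblies `> 5000` aa); the remaining
#' thresholds quantify checks the procedure names without numbers, chosen
#' as reproducible documented defaults: non-standard residue fraction at
#' most 0.05, compositional bias when at least half of the 20-residue
#' sliding windows fall below 2.2 bits of Shannon entropy, sequence
#' versions above 100 flagged unstable, and at least one cross-reference
#' required.
#'
#' @param min_length,max_length Accepted sequence length bounds (aa).
#' @param max_nonstandard Maximum fraction of residues outside the
#'   20-letter alphabet.
#' @param window Entropy window width (residues).
#' @param entropy_min Window entropy floor in bits.
#' @param max_low_entropy_frac Complexity fails when the fraction of
#'   windows below `entropy_min` reaches this value.
#' @param max_version Maximum accepted `sequenceVersion`.
#' @param min_crossrefs Minimum accepted `crossRefCount`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_length = 30, max_length = 5000,
                      max_nonstandard = 0.05,
                      window = 20, entropy_min = 2.2,
                      max_low_entropy_frac = 0.5,
                      max_version = 100, min_crossrefs = 1) {
  structure(
    list(
      min_length = min_length, max_length = max_length,
      max_nonstandard = max_nonstandard,
      window = window, entropy_min = entropy_min,
      max_low_entropy_frac = max_low_entropy_frac,
      max_version = max_version, min_crossrefs = min_crossrefs
    ),
    class = "qc_config"
  )
}

#' Sequence and metadata quality-control checks
#'
#' Evaluates the five named checks of the validation procedure's
#' sequence-QC stage for each record: `length_ok`, `nonstandard_ok`,
#' `complexity_ok`, `version_ok`, `crossrefs_ok`.
#'
#' @param records Tibble with `protein`, `sequence`, `sequenceVersion`,
#'   `crossRefCount`.
#' @param config A [qc_config()].
#' @return Tibble: `protein` plus the five logical check columns.
#' @export
qc_checks <- function(records, config = qc_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(tibble(
      protein = character(), length_ok = logical(), nonstandard_ok = logical(),
      complexity_ok = logical(), version_ok = logical(),
      crossrefs_ok = logical()
    ))
  }
  if (any(!nzchar(records$sequence))) abort("empty sequence")
  len <- nchar(records$sequence)
  nonstd_frac <- vapply(seq_chars(records$sequence), function(ch) {
    mean(!ch %in% AA_ALPHABET20)
  }, numeric(1))
  low_frac <- vapply(
    seq_chars(records$sequence), low_entropy_window_fraction,
    numeric(1),
    window = config$window, entropy_min = config$entropy_min
  )
  tibble(
    protein = records$protein,
    length_ok = len >= config$min_length & len <= config$max_length,
    nonstandard_ok = nonstd_frac <= config$max_nonstandard,
    complexity_ok = low_frac < config$max_low_entropy_frac,
    version_ok = records$sequenceVersion <= config$max_version,
    crossrefs_ok = records$crossRefCount >= config$min_crossrefs
  )
}

#' Fraction of sliding windows below the entropy floor
#' @noRd
low_entropy_window_fraction <- function(chars, window, entropy_min) {
  n <- length(chars)
  if (n <= window) {
    return(as.numeric(entropy_bits(chars) < entropy_min))
  }
  code <- match(chars, unique(chars))
  k <- max(code)
  n_win <- n - window + 1L
  # rolling counts over windows, step 1
  low <- logical(n_win)
  tab <- tabulate(code[seq_len(window)], nbins = k)
  ent <- function(tab) {
    p <- tab[tab > 0] / window
    -sum(p * log2(p))
  }
  low[1L] <- ent(tab) < entropy_min
  if (n_win > 1L) {
    for (i in 2:n_win) {
      out <- code[i - 1L]
      inn <- code[i + window - 1L]
      tab[out] <- tab[out] - 1L
      tab[inn] <- tab[inn] + 1L
      low[i] <- ent(tab) < entropy_min
    }
  }
  mean(low)
}

#' Three-step ortholog validation verdicts
#'
#' Applies the short-circuit validation procedure to each record:
#' * Step 1 (`entry_type`): `Reviewed` records pass outright.
#' * Step 2 (`protein_existence`): `Unreviewed` records with dependable
#'   protein-existence evidence (protein level, transcript level, or
#'   inferred from homology) pass.
#' * Step 3 (`sequence_qc`): remaining records (`Predicted` / `Uncertain`)
#'   pass iff all five [qc_checks()] pass.
#'
#' @param records Record tibble with `protein`, `sequence`, `entryType`,
#'   `proteinExistence`, `sequenceVersion`, `crossRefCount`.
#' @param config A [qc_config()].
#' @return Tibble: `protein`, `pass`, `stage` (deciding stage),
#'   `failed_checks` (semicolon-joined subset of
#'   `version;complexity;nonstandard;length;crossrefs`).
#' @export
validate_record <- function(records, config = qc_config()) {
  stopifnot(is.data.frame(records))
  known_pe <- c(PE_DEPENDABLE, PE_LOW)
  if (!all(records$entryType %in% c("Reviewed", "Unreviewed"))) {
    abort("unknown entryType value")
  }
  if (!all(records$proteinExistence %in% known_pe)) {
    abort("unknown proteinExistence value")
  }
  checks <- qc_checks(records, config)
  fail_labels <- function(row) {
    labs <- c(
      version = "version", complexity = "complexity",
      nonstandard = "nonstandard", length = "length", crossrefs = "crossrefs"
    )
    failed <- c(
      !row$version_ok, !row$complexity_ok, !row$nonstandard_ok,
      !row$length_ok, !row$crossrefs_ok
    )
    paste(labs[failed], collapse = ";")
  }
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    if (records$entryType[i] == "Reviewed") {
      out[[i]] <- list(pass = TRUE, stage = "entry_type", failed_checks = "")
    } else if (records$proteinExistence[i] %in% PE_DEPENDABLE) {
      out[[i]] <- list(pass = TRUE, stage = "protein_existence",
                       failed_checks = "")
    } else {
      row <- checks[i, ]
      all_ok <- row$length_ok && row$nonstandard_ok && row$complexity_ok &&
        row$version_ok && row$crossrefs_ok
      out[[i]] <- list(
        pass = all_ok, stage = "sequence_qc",
        failed_checks = if (all_ok) "" else fail_labels(row)
      )
    }
  }
  tibble(
    protein = records$protein,
    pass = map_lgl(out, "pass"),
    stage = map_chr(out, "stage"),
    failed_checks = map_chr(out, "failed_checks")
  )
}

#' Filter an orthology table by per-target validation verdicts
#'
#' Removes pairs whose target fails validation and reports failure counts
#' per deciding stage and per QC check.
#'
#' @param pairs Pair tibble with a `target` column.
#' @param records Record tibble covering every target in `pairs`.
#' @param config A [qc_config()].
#' @return List of class `ic_validation`: `pairs` (survivors), `verdicts`,
#'   `report` (named list of counts).
#' @export
filter_validated <- function(pairs, records, config = qc_config()) {
  missing <- setdiff(pairs$target, records$protein)
  if (length(missing) > 0) {
    abort(sprintf(
      "missing record/metadata for %d target(s), e.g. %s",
      length(missing), missing[1]
    ))
  }
  verdicts <- validate_record(records, config)
  failed <- filter(verdicts, !.data$pass)
  survivors <- filter(pairs, !.data$target %in% failed$protein)
  check_names <- c("version", "complexity", "nonstandard", "length",
                   "crossrefs")
  per_check <- vapply(check_names, function(ch) {
    sum(stringr::str_detect(
      failed$failed_checks, stringr::fixed(ch)
    ))
  }, integer(1))
  report <- list(
    n_pairs_in = nrow(pairs),
    n_pairs_out = nrow(survivors),
    n_records = nrow(records),
    n_failed_records = nrow(failed),
    failures_per_stage = as.list(table(factor(
      failed$stage, levels = c("entry_type", "protein_existence",
                               "sequence_qc")
    ))),
    failures_per_check = as.list(per_check)
  )
  structure(
    list(pairs = survivors, verdicts = verdicts, report = report),
    class = "ic_validation"
  )
}
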