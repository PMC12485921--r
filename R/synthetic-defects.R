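#' Defect-planting configuration
#'
#' Fractions are independent per-record probabilities for each defect type.
#' A record that draws any defect is routed through the annotation-quality
#' filter's sequence-QC stage (entryType `Unreviewed`, proteinExistence
#' `Predicted` or `Uncertain`) so the defect is disqualifying; clean records
#' are spread across all three short-circuit stages. Planting thresholds
#' mirror the validator defaults in [qc_config()] so the planted `is_valid`
#' label is exactly the verdict the validator must reproduce.
#'
#' @param length_short,length_long,nonstandard,complexity,version,crossrefs
#'   Per-defect planting probabilities in `[0, 1]`.
#' @param reviewed_frac Fraction of clean records given `Reviewed` status.
#' @param dependable_frac Fraction of clean records given `Unreviewed`
#'   status with dependable protein-existence evidence; the remainder are
#'   clean `Unreviewed` + `Predicted`/`Uncertain` records that must pass QC.
#' @return A list of class `defect_config`.
#' @export
defect_config <- function(length_short = 0, length_long = 0,
                          nonstandard = 0, complexity = 0,
                          version = 0, crossrefs = 0,
                          reviewed_frac = 0.5, dependable_frac = 0.3) {
  cfg <- list(
    length_short = length_short, length_long = length_long,
    nonstandard = nonstandard, complexity = complexity,
    version = version, crossrefs = crossrefs,
    reviewed_frac = reviewed_frac, dependable_frac = dependable_frac
  )
  if (any(unlist(cfg) < 0) || any(unlist(cfg) > 1)) {
    abort("all defect_config fractions must lie in [0, 1]")
  }
  if (reviewed_frac + dependable_frac > 1) {
    abort("reviewed_frac + dependable_frac must not exceed 1")
  }
  structure(cfg, class = "defect_config")
}

PE_DEPENDABLE <- c(
  "Evidence at protein level", "Evidence at Transcript level",
  "Inferred from homology"
)
PE_LOW <- c("Predicted", "Uncertain")

#' Plant metadata and sequence defects with known truth labels
#'
#' Mutates a fraction of records to carry annotation defects (fragment
#' truncation, over-long fusion, non-standard residues, low-complexity
#' runs, unstable sequence versions, missing cross-references) and records
#' the resulting ground-truth validity: `is_valid` is `FALSE` iff at least
#' one defect was planted. Defected records are always routed to the
#' sequence-QC stage so that planted defects are visible to the validator.
#'
#' @param records Protein record tibble (from [evolve_sequences()]).
#' @param config A [defect_config()].
#' @param seed Integer seed.
#' @return The records tibble with mutated sequences/metadata and truth
#'   columns `is_valid` and `defects` (semicolon-joined defect labels drawn
#'   from `length`, `nonstandard`, `complexity`, `version`, `crossrefs`).
#' @export
plant_metadata_defects <- function(records, config = defect_config(), seed = 1) {
  stopifnot(inherits(config, "defect_config"), is.data.frame(records))
  with_seed(derive_seed(seed, "metadata_defects"), {
    out <- records
    n <- nrow(out)
    draw <- function(p) runif(n) < p
    short <- draw(config$length_short)
    long <- draw(config$length_long) & !short # at most one length defect
    nonstd <- draw(config$nonstandard)
    lowc <- draw(config$complexity)
    vers <- draw(config$version)
    xref <- draw(config$crossrefs)
    any_defect <- short | long | nonstd | lowc | vers | xref

    defects <- character(n)
    for (i in seq_len(n)) {
      labs <- c(
        if (short[i] || long[i]) "length",
        if (nonstd[i]) "nonstandard",
        if (lowc[i]) "complexity",
        if (vers[i]) "version",
        if (xref[i]) "crossrefs"
      )
      defects[i] <- paste(labs, collapse = ";")

      if (short[i]) {
        len <- sample(10:29, 1L)
        out$sequence[i] <- substr(out$sequence[i], 1L, len)
        out$domain_start[i] <- min(out$domain_start[i], len)
        out$domain_end[i] <- min(out$domain_end[i], len)
      }
      if (long[i]) {
        pad <- paste(sample(AA_ALPHABET20, 5100 - nchar(out$sequence[i]),
                            replace = TRUE), collapse = "")
        out$sequence[i] <- paste0(out$sequence[i], pad)
      }
      if (lowc[i]) {
        chars <- seq_chars(out$sequence[i])[[1]]
        run <- max(2L, round(0.6 * length(chars)))
        start <- sample(seq_len(length(chars) - run + 1L), 1L)
        chars[start:(start + run - 1L)] <- "A"
        out$sequence[i] <- paste(chars, collapse = "")
      }
      if (nonstd[i]) {
        chars <- seq_chars(out$sequence[i])[[1]]
        k <- max(1L, ceiling(0.10 * length(chars)))
        chars[sample(length(chars), k)] <- "X"
        out$sequence[i] <- paste(chars, collapse = "")
      }
      if (vers[i]) out$sequenceVersion[i] <- sample(101:500, 1L)
      if (xref[i]) out$crossRefCount[i] <- 0L

      if (any_defect[i]) {
        out$entryType[i] <- "Unreviewed"
        out$proteinExistence[i] <- sample(PE_LOW, 1L)
      } else {
        u <- runif(1)
        if (u < config$reviewed_frac) {
          out$entryType[i] <- "Reviewed"
          out$proteinExistence[i] <- sample(c(PE_DEPENDABLE, PE_LOW), 1L)
        } else if (u < config$reviewed_frac + config$dependable_frac) {
          out$entryType[i] <- "Unreviewed"
          out$proteinExistence[i] <- sample(PE_DEPENDABLE, 1L)
        } else {
          out$entryType[i] <- "Unreviewed"
          out$proteinExistence[i] <- sample(PE_LOW, 1L)
        }
      }
    }
    out$defects <- defects
    out$is_valid <- !any_defect
    out
  })
}
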