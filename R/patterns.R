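GAP_CHARS <- c("-", ".")

#' Conservative residue-set library used in pattern search
#'
#' All 20 singletons plus the fixed conservative groups ILVM, FYW, KR, DE,
#' ST, NQ; the pattern search picks, per column, the set maximising the
#' contrast score.
#'
#' @return Named list of character vectors.
#' @export
residue_set_library <- function() {
  sets <- c(
    as.list(AA_ALPHABET20),
    list(c("I", "L", "V", "M"), c("F", "Y", "W"), c("K", "R"),
         c("D", "E"), c("S", "T"), c("N", "Q"))
  )
  names(sets) <- vapply(sets, paste, character(1), collapse = "")
  sets
}

#' @noRd
msa_matrix <- function(msa) {
  stopifnot(is.data.frame(msa), all(c("id", "sequence") %in% names(msa)))
  widths <- nchar(msa$sequence)
  if (length(unique(widths)) != 1L) {
    abort("ragged alignment: sequences must all have equal length")
  }
  mat <- do.call(rbind, seq_chars(msa$sequence))
  rownames(mat) <- msa$id
  mat
}

#' Per-column residue counts for a foreground/background partition
#'
#' Counts non-gap residues per column separately in the foreground and
#' background sequence sets. Columns whose foreground is more than
#' `max_gap_frac` gaps are flagged as skipped (and excluded from pattern
#' selection downstream).
#'
#' @param msa Alignment tibble: `id`, `sequence` (equal lengths).
#' @param foreground,background Character vectors of sequence ids
#'   (disjoint). `background = NULL` uses all remaining sequences.
#' @param max_gap_frac Foreground gap-fraction threshold for skipping.
#' @return Tibble of class `ic_column_profiles`: `column`, `residue`,
#'   `fg_count`, `bg_count`, `m` (foreground non-gap total), `n`
#'   (background non-gap total); attribute `skipped` lists skipped columns.
#' @export
column_profiles <- function(msa, foreground, background = NULL,
                            max_gap_frac = 0.5) {
  mat <- msa_matrix(msa)
  background <- background %||% setdiff(msa$id, foreground)
  check_partition(msa$id, foreground, background)
  fg <- mat[match(foreground, rownames(mat)), , drop = FALSE]
  bg <- mat[match(background, rownames(mat)), , drop = FALSE]
  gap_frac <- colMeans(matrix(fg %in% GAP_CHARS, nrow = nrow(fg)))
  skipped <- which(gap_frac > max_gap_frac)

  count_cols <- function(block) {
    lapply(seq_len(ncol(block)), function(j) {
      ch <- block[, j]
      table(ch[!ch %in% GAP_CHARS])
    })
  }
  fg_tab <- count_cols(fg)
  bg_tab <- count_cols(bg)
  rows <- list_rbind(lapply(seq_len(ncol(mat)), function(j) {
    residues <- sort(union(names(fg_tab[[j]]), names(bg_tab[[j]])))
    if (length(residues) == 0) return(NULL)
    tibble(
      column = j,
      residue = residues,
      fg_count = as.integer(fg_tab[[j]][residues] %|0|% residues),
      bg_count = as.integer(bg_tab[[j]][residues] %|0|% residues),
      m = sum(fg_tab[[j]]),
      n = sum(bg_tab[[j]])
    )
  }))
  structure(rows, skipped = as.integer(skipped),
            class = c("ic_column_profiles", class(rows)))
}

#' Zero-filled table lookup
#' @noRd
`%|0|%` <- function(tab, keys) {
  out <- tab[keys]
  out[is.na(out)] <- 0L
  out
}

#' @noRd
check_partition <- function(ids, foreground, background) {
  unknown <- setdiff(c(foreground, background), ids)
  if (length(unknown) > 0) {
    abort(sprintf("unknown sequence id(s): %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  if (length(intersect(foreground, background)) > 0) {
    abort("foreground and background must be disjoint")
  }
  if (length(foreground) == 0 || length(background) == 0) {
    abort("foreground and background must both be non-empty")
  }
}

#' Binomial log-likelihood-ratio contrast score
#'
#' `score = x * log(p/q) + (m - x) * log((1-p)/(1-q))` with pseudocounted
#' frequencies `p = (x + alpha) / (m + 2 alpha)` and
#' `q = (y + alpha) / (n + 2 alpha)`: the log-likelihood gain of modelling
#' the foreground matches with their own frequency rather than the
#' background's. Vectorised over its arguments.
#'
#' @param x Foreground match count (0..m).
#' @param m Foreground non-gap total (>= 1).
#' @param y Background match count (0..n).
#' @param n Background non-gap total (>= 1; may be a pseudo-count mass when
#'   contrasting against a background composition).
#' @param alpha Pseudocount (default 0.5).
#' @return Numeric score(s).
#' @export
#' @examples
#' contrast_score(x = 9, m = 10, y = 5, n = 100)
contrast_score <- function(x, m, y, n, alpha = 0.5) {
  if (any(m < 1) || any(n < 1)) abort("m and n must be >= 1")
  p <- (x + alpha) / (m + 2 * alpha)
  q <- (y + alpha) / (n + 2 * alpha)
  x * log(p / q) + (m - x) * log((1 - p) / (1 - q))
}

#' @noRd
set_membership_matrix <- function() {
  sets <- residue_set_library()
  letters21 <- c(AA_ALPHABET20, "X")
  mem <- matrix(
    0, nrow = length(letters21), ncol = length(sets),
    dimnames = list(letters21, names(sets))
  )
  for (s in seq_along(sets)) mem[sets[[s]], s] <- 1
  mem
}

#' Stacked per-cell set-membership design for fast column scoring:
#' returns n_seq x (L * n_sets) matrix plus the non-gap indicator.
#' @noRd
pattern_design <- function(mat) {
  mem <- set_membership_matrix()
  letters21 <- rownames(mem)
  code <- match(mat, letters21) # NA for gaps
  nongap <- matrix(as.numeric(!is.na(code)), nrow = nrow(mat))
  n_sets <- ncol(mem)
  L <- ncol(mat)
  big <- matrix(0, nrow = nrow(mat), ncol = L * n_sets)
  for (s in seq_len(n_sets)) {
    v <- mem[code, s]
    v[is.na(v)] <- 0
    big[, ((s - 1L) * L + 1L):(s * L)] <- matrix(v, nrow = nrow(mat))
  }
  list(big = big, nongap = nongap, n_sets = n_sets, L = L,
       set_names = colnames(mem))
}

#' Best enriched residue set and score per column, for one or many
#' foreground indicator rows. Returns list(score, set) of n_fg x L.
#' @noRd
score_columns_fast <- function(design, fg_rows, alpha = 0.5) {
  x <- fg_rows %*% design$big                     # n_fg x (L * n_sets)
  m <- fg_rows %*% design$nongap                  # n_fg x L
  tot_x <- matrix(colSums(design$big), nrow = nrow(x), ncol = ncol(x),
                  byrow = TRUE)
  tot_m <- matrix(colSums(design$nongap), nrow = nrow(m), ncol = ncol(m),
                  byrow = TRUE)
  y <- tot_x - x
  n <- tot_m - m
  m_rep <- m[, rep(seq_len(design$L), times = design$n_sets), drop = FALSE]
  n_rep <- n[, rep(seq_len(design$L), times = design$n_sets), drop = FALSE]
  p <- (x + alpha) / (m_rep + 2 * alpha)
  q <- (y + alpha) / (n_rep + 2 * alpha)
  sc <- x * log(p / q) + (m_rep - x) * log((1 - p) / (1 - q))
  sc[p <= q] <- 0 # only enrichment-direction sets count as patterns
  best <- matrix(-Inf, nrow = nrow(sc), ncol = design$L)
  best_set <- matrix(1L, nrow = nrow(sc), ncol = design$L)
  for (s in seq_len(design$n_sets)) {
    block <- sc[, ((s - 1L) * design$L + 1L):(s * design$L), drop = FALSE]
    better <- block > best
    best[better] <- block[better]
    best_set[better] <- s
  }
  list(score = best, set = best_set,
       x = x, m = m, y = y, n = n)
}

#' Select conserved pattern positions by permutation contrast
#'
#' Scores every alignment column by the maximal enriched-set contrast
#' score ([contrast_score()] maximised over [residue_set_library()]), then
#' assigns each column an empirical p-value from `n_perm` random
#' relabelings of the foreground/background partition. Mid-p counting
#' (`p = (0.5 + #\{perm > obs\} + 0.5 #\{perm = obs\}) / (n_perm + 1)`)
#' keeps the discrete permutation p-values calibrated. Columns with more
#' than 50% foreground gaps are skipped.
#'
#' @inheritParams column_profiles
#' @param n_perm Number of permutations (>= 1).
#' @param p_max Selection threshold on the empirical p-value.
#' @param alpha Pseudocount.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A tibble of class `pattern_scan` with the selected columns
#'   (`column`, `residue_set`, `score`, `x`, `m`, `y`, `n`, `p`), sorted
#'   by score; attributes `all_columns` (full scan table), `skipped`,
#'   `n_perm`, `p_max`.
#' @export
select_patterns <- function(msa, foreground, background = NULL,
                            n_perm = 1000, p_max = 0.01,
                            alpha = 0.5, seed = 1) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  mat <- msa_matrix(msa)
  background <- background %||% setdiff(msa$id, foreground)
  check_partition(msa$id, foreground, background)
  used <- c(foreground, background)
  mat <- mat[match(used, rownames(mat)), , drop = FALSE]
  design <- pattern_design(mat)
  n_fg <- length(foreground)
  n_seq <- nrow(mat)

  fg_obs <- matrix(0, 1, n_seq)
  fg_obs[1, seq_len(n_fg)] <- 1
  obs <- score_columns_fast(design, fg_obs, alpha)

  gap_frac <- 1 - obs$m[1, ] / n_fg
  skipped <- which(gap_frac > 0.5)

  perm_rows <- with_seed(derive_seed(seed, "pattern_permutations"), {
    p <- matrix(0, n_perm, n_seq)
    for (r in seq_len(n_perm)) p[r, sample(n_seq, n_fg)] <- 1
    p
  })
  perm <- score_columns_fast(design, perm_rows, alpha)

  obs_score <- obs$score[1, ]
  p_emp <- vapply(seq_len(design$L), function(j) {
    d <- perm$score[, j] - obs_score[j]
    (0.5 + sum(d > 1e-9) + 0.5 * sum(abs(d) <= 1e-9)) / (n_perm + 1)
  }, numeric(1))

  all_columns <- tibble(
    column = seq_len(design$L),
    residue_set = design$set_names[obs$set[1, ]],
    score = obs_score,
    x = as.integer(round(obs$x[1, best_flat_index(obs$set[1, ], design$L)])),
    m = as.integer(obs$m[1, ]),
    y = as.integer(round(obs$y[1, best_flat_index(obs$set[1, ], design$L)])),
    n = as.integer(colSums(design$nongap) - obs$m[1, ]),
    p = p_emp
  )
  all_columns$residue_set[all_columns$score <= 0] <- NA_character_
  selected <- all_columns |>
    filter(!.data$column %in% skipped, .data$p < p_max, .data$score > 0) |>
    arrange(desc(.data$score), .data$column)
  structure(
    selected,
    all_columns = all_columns,
    skipped = as.integer(skipped),
    n_perm = n_perm, p_max = p_max,
    class = c("pattern_scan", class(selected))
  )
}

#' Flat column index of each column's best set in the stacked design
#' @noRd
best_flat_index <- function(best_set, L) {
  (best_set - 1L) * L + seq_len(L)
}

#' Family-shared conserved positions confirmed in every subfamily
#'
#' Contrasts the whole family against a background residue composition
#' (by default the alignment-wide composition), assigns empirical
#' p-values from `n_perm` null columns drawn i.i.d. from that composition,
#' and retains positions whose modal-residue frequency reaches `c_min`
#' within **every** subfamily -- the analogue of positions conserved across
#' all members of a family.
#'
#' @param msa Alignment tibble with `id`, `sequence`, `subfamily`.
#' @param c_min Per-subfamily modal-residue frequency floor in `[0, 1]`.
#' @param composition Optional named numeric background composition over
#'   the 20 residues; defaults to the alignment-wide non-gap composition.
#' @inheritParams select_patterns
#' @return A `pattern_scan` tibble (see [select_patterns()]) with an added
#'   `min_subfamily_conservation` column.
#' @export
family_shared_patterns <- function(msa, c_min = 0.7, composition = NULL,
                                   n_perm = 1000, p_max = 0.01,
                                   alpha = 0.5, seed = 1) {
  stopifnot("subfamily" %in% names(msa))
  sfs <- unique(msa$subfamily)
  if (length(sfs) < 2) abort("family-shared analysis needs >= 2 subfamilies")
  sizes <- table(msa$subfamily)
  if (any(sizes < 2)) abort("every subfamily needs >= 2 sequences")
  mat <- msa_matrix(msa)
  design <- pattern_design(mat)
  m_all <- colSums(design$nongap)

  if (is.null(composition)) {
    res <- mat[!mat %in% GAP_CHARS]
    res <- res[res != "X"]
    composition <- table(factor(res, levels = AA_ALPHABET20))
    composition <- as.numeric(composition) / sum(composition)
    names(composition) <- AA_ALPHABET20
  }
  mem <- set_membership_matrix()[AA_ALPHABET20, , drop = FALSE]
  set_freq <- as.numeric(composition %*% mem)

  n_bg <- nrow(mat) # pseudo-count mass of the composition background
  score_against_composition <- function(x, m) {
    # x: n_sets x L counts; m: length-L totals
    y <- outer(set_freq, rep(1, length(m))) * n_bg
    m_rep <- matrix(m, nrow = length(set_freq), ncol = length(m), byrow = TRUE)
    sc <- contrast_score(x, m_rep, y, n_bg, alpha)
    sc[(x + alpha) / (m_rep + 2 * alpha) <=
         (y + alpha) / (n_bg + 2 * alpha)] <- 0
    sc
  }
  fg_all <- matrix(1, 1, nrow(mat))
  xs <- score_columns_counts(design, fg_all) # n_sets x L counts
  sc <- score_against_composition(xs, m_all)
  obs_score <- apply(sc, 2, max)
  obs_set <- design$set_names[apply(sc, 2, which.max)]

  null_max <- with_seed(derive_seed(seed, "family_shared_null"), {
    vapply(seq_len(n_perm), function(r) {
      col <- sample(AA_ALPHABET20, n_bg, replace = TRUE, prob = composition)
      counts <- as.numeric(table(factor(col, levels = AA_ALPHABET20)) %*% mem)
      max(score_against_composition(
        matrix(counts, ncol = 1), n_bg
      ))
    }, numeric(1))
  })
  p_emp <- vapply(obs_score, function(s) {
    d <- null_max - s
    (0.5 + sum(d > 1e-9) + 0.5 * sum(abs(d) <= 1e-9)) / (n_perm + 1)
  }, numeric(1))

  # per-subfamily modal-residue conservation
  min_cons <- vapply(seq_len(ncol(mat)), function(j) {
    min(vapply(sfs, function(sf) {
      ch <- mat[msa$subfamily == sf, j]
      ch <- ch[!ch %in% GAP_CHARS]
      if (length(ch) == 0) return(0)
      max(table(ch)) / length(ch)
    }, numeric(1)))
  }, numeric(1))

  all_columns <- tibble(
    column = seq_len(ncol(mat)),
    residue_set = obs_set,
    score = obs_score,
    m = as.integer(m_all),
    p = p_emp,
    min_subfamily_conservation = min_cons
  )
  selected <- all_columns |>
    filter(.data$p < p_max, .data$score > 0,
           .data$min_subfamily_conservation >= c_min) |>
    arrange(desc(.data$score), .data$column)
  structure(
    selected,
    all_columns = all_columns,
    skipped = integer(),
    n_perm = n_perm, p_max = p_max,
    class = c("pattern_scan", class(selected))
  )
}

#' Per-set foreground counts (n_sets x L) for one indicator row
#' @noRd
score_columns_counts <- function(design, fg_row) {
  x <- fg_row %*% design$big # 1 x (L * n_sets)
  matrix(x, nrow = design$n_sets, ncol = design$L, byrow = TRUE)
}

#' Map alignment columns to reference-sequence numbering
#'
#' Labels each selected column by the reference residue letter and its
#' 1-based position in the ungapped reference sequence (e.g. `"F44"`).
#' Columns where the reference is gapped get `NA` labels and are flagged.
#'
#' @param msa Alignment tibble.
#' @param positions Tibble with a `column` field (e.g. a `pattern_scan`).
#' @param reference_id Id of the reference sequence within `msa`.
#' @return `positions` plus `label` and `reference_gapped` columns.
#' @export
map_to_reference <- function(msa, positions, reference_id) {
  mat <- msa_matrix(msa)
  if (!reference_id %in% rownames(mat)) {
    abort(sprintf("reference id '%s' not present in alignment", reference_id))
  }
  ref <- mat[reference_id, ]
  nongap <- !ref %in% GAP_CHARS
  number <- cumsum(nongap)
  cols <- positions$column
  labelled <- tibble::as_tibble(positions) |>
    mutate(
      label = dplyr::if_else(
        nongap[cols], paste0(ref[cols], number[cols]), NA_character_
      ),
      reference_gapped = !nongap[cols]
    )
  labelled
}
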