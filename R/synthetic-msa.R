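#' Simulate a patterned multiple sequence alignment
#'
#' Builds an ungapped alignment partitioned into subfamilies with three
#' kinds of columns: *shared* columns carrying one residue across every
#' subfamily, *subfamily* columns carrying a residue specific to one
#' subfamily (background elsewhere), and background columns drawn i.i.d.
#' from a flat composition. Each planted cell is flipped to a random
#' residue with probability `noise`, emulating imperfect conservation.
#'
#' @param n_subfamilies Number of subfamilies (>= 1).
#' @param seqs_per_subfamily Sequences per subfamily (>= 2).
#' @param length Alignment length (>= 1).
#' @param shared_columns Integer vector of family-shared column indices.
#' @param subfamily_columns Named list mapping subfamily id (`"sf1"`, ...)
#'   to its planted column indices; all column sets must be disjoint and
#'   within `[1, length]`.
#' @param noise Per-cell flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list of class `ic_patterned_msa`: `msa` (tibble `id`,
#'   `subfamily`, `sequence`), `truth` (list with `shared_columns`,
#'   `subfamily_columns`, and per-column planted residues).
#' @export
simulate_patterned_msa <- function(n_subfamilies = 4,
                                   seqs_per_subfamily = 50,
                                   length = 100,
                                   shared_columns = integer(),
                                   subfamily_columns = list(),
                                   noise = 0.1,
                                   seed = 1) {
  if (n_subfamilies < 1 || seqs_per_subfamily < 2 || length < 1) {
    abort("need n_subfamilies >= 1, seqs_per_subfamily >= 2, length >= 1")
  }
  if (noise < 0 || noise > 1) abort("noise must lie in [0, 1]")
  sf_ids <- sprintf("sf%d", seq_len(n_subfamilies))
  if (length(subfamily_columns) > 0) {
    if (is.null(names(subfamily_columns)) ||
        !all(names(subfamily_columns) %in% sf_ids)) {
      abort("subfamily_columns must be named by subfamily id (sf1, sf2, ...)")
    }
  }
  all_cols <- c(shared_columns, unlist(subfamily_columns, use.names = FALSE))
  if (any(all_cols < 1 | all_cols > length)) {
    abort("planted columns must lie within [1, length]")
  }
  if (anyDuplicated(all_cols)) {
    abort("shared and subfamily column sets must be disjoint")
  }

  n_seq <- n_subfamilies * seqs_per_subfamily
  subfamily <- rep(sf_ids, each = seqs_per_subfamily)

  with_seed(derive_seed(seed, "patterned_msa"), {
    mat <- matrix(
      sample(AA_ALPHABET20, n_seq * length, replace = TRUE),
      nrow = n_seq, ncol = length
    )
    shared_res <- setNames(
      sample(AA_ALPHABET20, length(shared_columns), replace = TRUE),
      as.character(shared_columns)
    )
    for (col in shared_columns) {
      mat[, col] <- shared_res[[as.character(col)]]
    }
    sf_res <- lapply(subfamily_columns, function(cols) {
      setNames(sample(AA_ALPHABET20, length(cols), replace = TRUE),
               as.character(cols))
    })
    for (sf in names(subfamily_columns)) {
      rows <- which(subfamily == sf)
      for (col in subfamily_columns[[sf]]) {
        mat[rows, col] <- sf_res[[sf]][[as.character(col)]]
      }
    }
    # noise: planted cells only (background cells are already random)
    planted_cells <- function(rows, cols) {
      if (length(cols) == 0) return(NULL)
      cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
    }
    cells <- rbind(
      planted_cells(seq_len(n_seq), shared_columns),
      do.call(rbind, lapply(names(subfamily_columns), function(sf) {
        planted_cells(which(subfamily == sf), subfamily_columns[[sf]])
      }))
    )
    if (!is.null(cells) && noise > 0) {
      flip <- runif(nrow(cells)) < noise
      if (any(flip)) {
        mat[cells[flip, , drop = FALSE]] <-
          sample(AA_ALPHABET20, sum(flip), replace = TRUE)
      }
    }

    msa <- tibble(
      id = sprintf("%s_s%03d", subfamily, sequence_index(subfamily)),
      subfamily = subfamily,
      sequence = apply(mat, 1, paste, collapse = "")
    )
    structure(
      list(
        msa = msa,
        truth = list(
          shared_columns = as.integer(shared_columns),
          subfamily_columns = lapply(subfamily_columns, as.integer),
          shared_residues = shared_res,
          subfamily_residues = sf_res
        )
      ),
      class = "ic_patterned_msa"
    )
  })
}

#' Running index within groups of equal consecutive values
#' @noRd
sequence_index <- function(group) {
  stats::ave(seq_along(group), group, FUN = seq_along)
}
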