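#' Build the ion-channel-by-organism presence matrix
#'
#' Converts a classified ortholog pair table into the three-state profile:
#' `0` no ortholog detected, `1` one-to-one ortholog present, `2`
#' co-ortholog detected (any co-ortholog relation dominates).
#'
#' @param pairs Pair tibble with `ic`, `proteome`, `relation`.
#' @param ic_list Character vector of query ICs (row universe).
#' @param organism_list Character vector of organisms (column universe).
#' @return Long tibble of class `ic_profile`: `ic`, `organism`, `state`
#'   over the complete grid.
#' @export
build_profile <- function(pairs, ic_list, organism_list) {
  if (nrow(pairs) > 0) {
    bad_ic <- setdiff(pairs$ic, ic_list)
    bad_org <- setdiff(pairs$proteome, organism_list)
    if (length(bad_ic) > 0 || length(bad_org) > 0) {
      abort(sprintf(
        "unknown id(s) in pairs: %s",
        paste(head(c(bad_ic, bad_org), 3), collapse = ", ")
      ))
    }
  }
  observed <- pairs |>
    group_by(ic = .data$ic, organism = .data$proteome) |>
    summarise(
      state = if (any(.data$relation == "co-ortholog")) 2L else 1L,
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(ic = ic_list, organism = organism_list)
  out <- grid |>
    left_join(observed, by = c("ic", "organism")) |>
    mutate(state = tidyr::replace_na(.data$state, 0L))
  class(out) <- c("ic_profile", class(out))
  out
}

#' Family-by-lineage ortholog percentage table
#'
#' For family `f` and lineage `l`, the reported percentage is
#' `100 * O_fl / (N_l * S_f)` where `O_fl` counts distinct (ic, organism)
#' cells with a detected ortholog (state != 0), `N_l` is the number of
#' organisms queried in the lineage and `S_f` the number of query ICs in
#' the family. Counting distinct nonzero cells (not co-ortholog
#' multiplicity) bounds the percentage at 100.
#'
#' @param profile An `ic_profile` from [build_profile()].
#' @param family_map Tibble `ic`, `family`, covering all profile rows.
#' @param lineage_map Tibble `organism`, `lineage`, covering all profile
#'   columns.
#' @return Tibble: `family`, `lineage`, `n_orthologs`, `n_organisms`,
#'   `n_ics`, `percent`.
#' @export
percent_heatmap <- function(profile, family_map, lineage_map) {
  if (!all(unique(profile$ic) %in% family_map$ic)) {
    abort("family_map must cover every ic in the profile")
  }
  if (!all(unique(profile$organism) %in% lineage_map$organism)) {
    abort("lineage_map must cover every organism in the profile")
  }
  sizes_f <- family_map |>
    semi_join(distinct(profile, .data$ic), by = "ic") |>
    count(.data$family, name = "n_ics")
  sizes_l <- lineage_map |>
    semi_join(distinct(profile, .data$organism), by = "organism") |>
    count(.data$lineage, name = "n_organisms")
  if (any(sizes_f$n_ics == 0) || any(sizes_l$n_organisms == 0)) {
    abort("families and lineages must have at least one member")
  }
  profile |>
    left_join(family_map, by = "ic") |>
    left_join(lineage_map, by = "organism") |>
    group_by(.data$family, .data$lineage) |>
    summarise(n_orthologs = sum(.data$state != 0L), .groups = "drop") |>
    left_join(sizes_f, by = "family") |>
    left_join(sizes_l, by = "lineage") |>
    mutate(
      percent = 100 * .data$n_orthologs / (.data$n_organisms * .data$n_ics)
    ) |>
    arrange(.data$family, .data$lineage)
}

#' Ward agglomeration with deterministic tie-breaking
#'
#' Agglomerative clustering under the Ward criterion (the merge cost is
#' the increase in total within-cluster variance; heights are reported on
#' the Euclidean-distance scale as in `hclust(method = "ward.D2")`).
#' Distances are updated with the Lance--Williams recurrence. On equal
#' merge costs the pair with the lexicographically smallest original row
#' indices is merged, making the result fully deterministic.
#'
#' @param x Numeric matrix; rows are the objects to cluster.
#' @param k Number of flat clusters (1 to `nrow(x)`); agglomeration stops
#'   after `nrow(x) - k` merges.
#' @return List: `labels` (integer cluster per row, numbered by first
#'   appearance), `heights` (merge heights, length `nrow(x) - k`).
#' @export
ward_cluster <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) abort("k must lie in [1, nrow(x)]")
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d2 <- as.matrix(stats::dist(x))^2
  alive <- rep(TRUE, n)
  heights <- numeric(0)
  n_merges <- n - k
  for (step in seq_len(n_merges)) {
    best <- NULL
    best_d2 <- Inf
    idx <- which(alive)
    for (ii in seq_along(idx)[-length(idx)]) {
      i <- idx[ii]
      for (j in idx[(ii + 1L):length(idx)]) {
        dij <- d2[i, j]
        if (dij < best_d2 - 1e-12) {
          best_d2 <- dij
          best <- c(i, j)
        } else if (abs(dij - best_d2) <= 1e-12) {
          # tie: lowest original-index pair (clusters keyed by their
          # smallest member, i.e. their slot index)
          if (i < best[1] || (i == best[1] && j < best[2])) best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_d2))
    ni <- sizes[i]; nj <- sizes[j]
    for (m in idx) {
      if (m == i || m == j) next
      nm <- sizes[m]
      d2[i, m] <- d2[m, i] <-
        ((ni + nm) * d2[i, m] + (nj + nm) * d2[j, m] - nm * d2[i, j]) /
          (ni + nj + nm)
    }
    sizes[i] <- ni + nj
    active[[i]] <- c(active[[i]], active[[j]])
    alive[j] <- FALSE
  }
  labels <- integer(n)
  for (cl in seq_along(which(alive))) {
    labels[active[[which(alive)[cl]]]] <- cl
  }
  # renumber by first appearance in row order
  labels <- as.integer(factor(labels, levels = unique(labels)))
  list(labels = labels, heights = heights)
}

#' Cluster presence/absence profiles (Ward, Euclidean)
#'
#' Binarises the profile (presence = state != 0), restricts columns to the
#' requested organism scope (typically eukaryotes only, as prokaryotic
#' profiles are too sparse to be informative), and cuts a Ward/Euclidean
#' agglomeration into `k` flat clusters.
#'
#' @param profile An `ic_profile`.
#' @param scope_organisms Organisms (columns) to use; default all.
#' @param k Number of flat clusters (default 9).
#' @return Tibble: `ic`, `cluster` (integers 1..k, numbered by first
#'   appearance in row order).
#' @export
cluster_profiles <- function(profile, scope_organisms = NULL, k = 9) {
  scoped <- profile
  if (!is.null(scope_organisms)) {
    scoped <- filter(profile, .data$organism %in% scope_organisms)
  }
  wide <- scoped |>
    mutate(present = as.integer(.data$state != 0L)) |>
    select("ic", "organism", "present") |>
    tidyr::pivot_wider(names_from = "organism", values_from = "present")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$ic
  if (k < 1 || k > nrow(mat)) abort("k must lie in [1, number of ICs]")
  res <- ward_cluster(mat, k)
  tibble(ic = wide$ic, cluster = res$labels)
}

#' Hypergeometric term enrichment for one member set
#'
#' Upper-tail hypergeometric test `P(X >= k)` for each annotation term,
#' with Benjamini--Hochberg adjustment across the terms tested in this set;
#' rows with `q < fdr_max` are retained, sorted by `q`.
#'
#' @param term_map Tibble `id`, `term` annotating universe members.
#' @param members Character vector, a subset of `universe`.
#' @param universe Character vector of all testable ids.
#' @param fdr_max Adjusted-FDR retention threshold (default 0.01).
#' @return Tibble: `term`, `k` (overlap), `K` (term size), `n` (set size),
#'   `N` (universe size), `p`, `q`.
#' @export
hypergeom_enrich <- function(term_map, members, universe, fdr_max = 0.01) {
  if (length(universe) == 0) abort("universe must be non-empty")
  if (length(members) == 0) abort("member set must be non-empty")
  if (!all(members %in% universe)) abort("members must lie in the universe")
  tm <- term_map |>
    filter(.data$id %in% universe) |>
    distinct(.data$id, .data$term)
  if (nrow(tm) == 0) {
    return(tibble(
      term = character(), k = integer(), K = integer(), n = integer(),
      N = integer(), p = numeric(), q = numeric()
    ))
  }
  n_set <- length(members)
  n_uni <- length(universe)
  rows <- tm |>
    group_by(.data$term) |>
    summarise(
      K = dplyr::n(),
      k = sum(.data$id %in% members),
      .groups = "drop"
    ) |>
    mutate(
      n = n_set, N = n_uni,
      p = phyper(.data$k - 1L, .data$K, .data$N - .data$K, .data$n,
                 lower.tail = FALSE)
    ) |>
    mutate(q = p.adjust(.data$p, method = "BH"))
  rows |>
    filter(.data$q < fdr_max) |>
    arrange(.data$q, .data$term) |>
    select("term", "k", "K", "n", "N", "p", "q")
}

#' Per-cluster hypergeometric enrichment
#'
#' Runs [hypergeom_enrich()] for every cluster in a cluster table.
#'
#' @param clusters Tibble `ic`, `cluster` from [cluster_profiles()].
#' @param term_map Tibble `id`, `term`.
#' @param fdr_max Adjusted-FDR retention threshold.
#' @return Tibble with a leading `cluster` column.
#' @export
enrich_clusters <- function(clusters, term_map, fdr_max = 0.01) {
  universe <- unique(clusters$ic)
  list_rbind(lapply(sort(unique(clusters$cluster)), function(cl) {
    members <- clusters$ic[clusters$cluster == cl]
    hypergeom_enrich(term_map, members, universe, fdr_max) |>
      mutate(cluster = cl, .before = 1)
  }))
}
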