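# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, not from the package's code path.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap local alignment by full dynamic programming.
# A gap of length L costs open + L * ext (the same convention as the
# package's scoring scheme). Returns the optimal local score.
gotoh_local_score <- function(query, subject, mat = blosum62,
                              open = 11, ext = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(q); n <- length(s)
  neg <- -1e9
  H <- matrix(0, m + 1, n + 1)   # best ending in a match/mismatch or start
  E <- matrix(neg, m + 1, n + 1) # gap in query (insertion in subject dim)
  F <- matrix(neg, m + 1, n + 1) # gap in subject
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      diag_sc <- max(H[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) +
        mat[q[i - 1], s[j - 1]]
      H[i, j] <- max(0, diag_sc)
      best <- max(best, H[i, j], E[i, j], F[i, j])
    }
  }
  best
}

# Exhaustive Ward agglomeration recomputing within-cluster sums of squares
# from scratch at every step (no Lance-Williams recurrence). Tie-break:
# lexicographically smallest pair of smallest original member indices.
ward_oracle_labels <- function(x, k) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  sse <- function(members) {
    sub <- x[members, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2, ctr)^2)
  }
  while (length(clusters) > k) {
    best <- NULL; best_cost <- Inf
    mins <- vapply(clusters, min, numeric(1))
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1):length(clusters)) {
        cost <- sse(c(clusters[[a]], clusters[[b]])) -
          sse(clusters[[a]]) - sse(clusters[[b]])
        pair_key <- sort(c(mins[a], mins[b]))
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(a, b); best_key <- pair_key
        } else if (abs(cost - best_cost) <= 1e-12) {
          if (pair_key[1] < best_key[1] ||
              (pair_key[1] == best_key[1] && pair_key[2] < best_key[2])) {
            best <- c(a, b); best_key <- pair_key
          }
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(x))
  for (cl in seq_along(clusters)) labels[clusters[[cl]]] <- cl
  as.integer(factor(labels, levels = unique(labels)))
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  identical(
    as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b)))
  )
}

# Hypergeometric upper tail P(X >= k) by exhaustive subset enumeration.
hyper_enum_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  in_term <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% in_term))
  mean(hits >= k)
}

# Naive double-loop evaluation of the family-by-lineage percentage formula.
percent_oracle <- function(profile, family_map, lineage_map) {
  fams <- sort(unique(family_map$family))
  lins <- sort(unique(lineage_map$lineage))
  out <- list()
  for (f in fams) {
    ics <- family_map$ic[family_map$family == f]
    for (l in lins) {
      orgs <- lineage_map$organism[lineage_map$lineage == l]
      o <- 0
      for (ic in ics) {
        for (org in orgs) {
          st <- profile$state[profile$ic == ic & profile$organism == org]
          if (length(st) == 1 && st != 0) o <- o + 1
        }
      }
      out[[length(out) + 1]] <- data.frame(
        family = f, lineage = l,
        percent = 100 * o / (length(orgs) * length(ics))
      )
    }
  }
  do.call(rbind, out)
}

# Species-overlap reconciliation: relabel gene-tree internals from topology
# alone (duplication iff the child subtrees share an organism), then read
# off ortholog pairs and their one-to-one / co-ortholog status.
reconcile_oracle <- function(family) {
  nodes <- family$nodes
  genes <- family$genes
  kids <- split(nodes$node[!is.na(nodes$parent)],
                nodes$parent[!is.na(nodes$parent)])
  org_sets <- vector("list", nrow(nodes))
  fill_orgs <- function(node) {
    if (nodes$event[node] == "leaf") {
      org_sets[[node]] <<- nodes$organism[node]
      return(org_sets[[node]])
    }
    ch <- kids[[as.character(node)]]
    sets <- lapply(ch, fill_orgs)
    org_sets[[node]] <<- unique(unlist(sets))
    org_sets[[node]]
  }
  root <- nodes$node[is.na(nodes$parent)]
  fill_orgs(root)
  is_dup <- vapply(seq_len(nrow(nodes)), function(node) {
    ch <- kids[[as.character(node)]]
    if (is.null(ch) || length(ch) < 2) return(FALSE)
    sets <- lapply(ch, function(c) org_sets[[c]])
    length(intersect(sets[[1]], sets[[2]])) > 0
  }, logical(1))

  parent <- nodes$parent
  ancestors <- function(node) {
    path <- node
    while (!is.na(parent[node])) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  }
  anc <- lapply(genes$node, ancestors)
  n <- nrow(genes)
  ortho <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j || genes$organism[i] == genes$organism[j]) next
      lca <- intersect(anc[[i]], anc[[j]])[1]
      if (!is_dup[lca]) ortho[i, j] <- ortho[j, i] <- TRUE
    }
  }
  idx <- which(ortho & upper.tri(ortho), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      relation = character()))
  }
  relation <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    n_in_i <- sum(ortho[, j] & genes$organism == genes$organism[i])
    n_in_j <- sum(ortho[, i] & genes$organism == genes$organism[j])
    if (n_in_i == 1 && n_in_j == 1) "one-to-one" else "co-ortholog"
  }, character(1))
  out <- data.frame(
    protein_a = genes$protein[idx[, 1]],
    protein_b = genes$protein[idx[, 2]],
    relation = relation
  )
  out[order(out$protein_a, out$protein_b), ]
}

# Random protein sequence helper.
random_seq <- function(n, letters = c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
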