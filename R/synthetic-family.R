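#' Simulate a gene family along a species tree
#'
#' Evolves a single gene family down the species tree under a birth--death
#' process (duplication and loss per gene lineage, rates per unit branch
#' length). Every internal gene-tree node is labelled `speciation` or
#' `duplication` by construction, and the ground-truth orthology relations
#' are read off the reconciled labels: a cross-species pair is orthologous
#' iff its gene-tree LCA is a speciation node; the pair is `one-to-one` iff
#' each member is the other's only ortholog in its organism, otherwise
#' `co-ortholog`.
#'
#' @param species An `ic_species_tree` from [simulate_species_tree()].
#' @param dup_rate,loss_rate Non-negative event rates per unit branch length.
#' @param seed Integer seed.
#' @param family_id Identifier prefix for protein ids.
#' @return A list of class `ic_gene_family`: `nodes` (gene-tree node table:
#'   `node`, `parent`, `event`, `branch_length`, `organism`), `genes`
#'   (tibble `protein`, `organism`, `node`), `truth` (tibble `protein_a`,
#'   `protein_b`, `relation`), `n_losses`.
#' @export
simulate_gene_family <- function(species,
                                 dup_rate = 0,
                                 loss_rate = 0,
                                 seed = 1,
                                 family_id = "fam01") {
  stopifnot(inherits(species, "ic_species_tree"))
  if (!is.finite(dup_rate) || !is.finite(loss_rate) ||
      dup_rate < 0 || loss_rate < 0) {
    abort("dup_rate and loss_rate must be finite and non-negative")
  }
  tree <- species$tree
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L

  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$n_losses <- 0L
  add_node <- function(parent, event, branch_length, organism = NA_character_) {
    id <- length(env$rows) + 1L
    env$rows[[id]] <- list(
      node = id, parent = parent, event = event,
      branch_length = branch_length, organism = organism
    )
    id
  }

  children_of <- function(sp_node) tree$edge[tree$edge[, 1] == sp_node, 2]
  edge_len <- function(sp_child) {
    tree$edge.length[match(sp_child, tree$edge[, 2])]
  }
  total_rate <- dup_rate + loss_rate

  # one lineage entering species node `sp_node`, hanging from gene node
  # `parent` with `acc` branch length already accumulated
  at_species_node <- function(parent, acc, sp_node) {
    kids <- children_of(sp_node)
    if (length(kids) == 0L) {
      add_node(parent, "leaf", acc, organism = tree$tip.label[sp_node])
      return(invisible(NULL))
    }
    sp_id <- add_node(parent, "speciation", acc)
    for (k in kids) along_branch(sp_id, 0, edge_len(k), k)
    invisible(NULL)
  }

  # lineage travelling along the species branch into `sp_child`, with
  # `remaining` branch length left and `acc` gene-edge length so far
  along_branch <- function(parent, acc, remaining, sp_child) {
    repeat {
      t_ev <- if (total_rate > 0) rexp(1, total_rate) else Inf
      if (t_ev >= remaining) {
        at_species_node(parent, acc + remaining, sp_child)
        return(invisible(NULL))
      }
      acc <- acc + t_ev
      remaining <- remaining - t_ev
      if (runif(1) < dup_rate / total_rate) {
        dup_id <- add_node(parent, "duplication", acc)
        along_branch(dup_id, 0, remaining, sp_child)
        parent <- dup_id
        acc <- 0
        # current lineage continues from the duplication node
      } else {
        env$n_losses <- env$n_losses + 1L
        return(invisible(NULL))
      }
    }
  }

  with_seed(derive_seed(seed, paste0("gene_family_", family_id)), {
    if (n_tip == 1L) {
      root_id <- add_node(NA_integer_, "root", 0)
      add_node(root_id, "leaf", 0, organism = tree$tip.label[1L])
    } else {
      root_id <- add_node(NA_integer_, "speciation", 0)
      for (k in children_of(root)) along_branch(root_id, 0, edge_len(k), k)
    }
  })

  nodes <- list_rbind(lapply(env$rows, as_tibble))
  leaves <- filter(nodes, .data$event == "leaf") |>
    group_by(.data$organism) |>
    mutate(protein = sprintf("%s_%s_g%d", family_id, .data$organism, row_number())) |>
    ungroup()
  genes <- select(leaves, "protein", "organism", "node")

  truth <- truth_orthology(nodes, genes)
  structure(
    list(nodes = nodes, genes = genes, truth = truth, n_losses = env$n_losses),
    class = "ic_gene_family"
  )
}

#' Ground-truth ortholog relations from labelled gene-tree nodes
#' @noRd
truth_orthology <- function(nodes, genes) {
  if (nrow(genes) < 2L) {
    return(tibble(
      protein_a = character(), protein_b = character(), relation = character()
    ))
  }
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
  pairs <- list()
  ortho <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (genes$organism[i] == genes$organism[j]) next
      lca <- intersect(anc[[i]], anc[[j]])[1L]
      if (nodes$event[lca] %in% c("speciation", "root")) {
        ortho[i, j] <- ortho[j, i] <- TRUE
      }
    }
  }
  if (!any(ortho)) {
    return(tibble(
      protein_a = character(), protein_b = character(), relation = character()
    ))
  }
  idx <- which(ortho & upper.tri(ortho), arr.ind = TRUE)
  relation <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    # one-to-one iff neither member has an in-paralog standing in for it:
    # i must be j's only ortholog in i's organism, and vice versa
    n_in_i <- sum(ortho[, j] & genes$organism == genes$organism[i])
    n_in_j <- sum(ortho[, i] & genes$organism == genes$organism[j])
    if (n_in_i == 1L && n_in_j == 1L) "one-to-one" else "co-ortholog"
  }, character(1))
  tibble(
    protein_a = genes$protein[idx[, 1]],
    protein_b = genes$protein[idx[, 2]],
    relation = relation
  ) |>
    arrange(.data$protein_a, .data$protein_b)
}

#' Evolve protein sequences along a simulated gene family
#'
#' Seeds a random root sequence and applies independent per-site
#' replacement along every gene-tree edge: a site changes with probability
#' `1 - exp(-rate * branch_length)` and, when it changes, is redrawn
#' uniformly from the 19 alternative residues. Sites inside the pore-domain
#' span use `rate_domain`, flanking sites `rate_flank`, emulating the slower
#' evolution of pore-containing functional domains relative to their flanks.
#' No indels are introduced, so domain coordinates propagate unchanged.
#'
#' @param family An `ic_gene_family`.
#' @param root_length Root sequence length.
#' @param domain_span Integer vector `c(start, end)`, 1-based inclusive,
#'   within `[1, root_length]`.
#' @param rate_domain,rate_flank Substitution rate multipliers;
#'   `rate_domain <= rate_flank`.
#' @param seed Integer seed.
#' @return Tibble of protein records: `protein`, `organism`, `family`,
#'   `sequence`, `domain_start`, `domain_end`, plus baseline metadata
#'   (`entryType`, `proteinExistence`, `sequenceVersion`, `crossRefCount`)
#'   and truth columns (`is_valid`, `defects`).
#' @export
evolve_sequences <- function(family,
                             root_length = 240L,
                             domain_span = c(81L, 160L),
                             rate_domain = 0.3,
                             rate_flank = 1.0,
                             seed = 1) {
  stopifnot(inherits(family, "ic_gene_family"))
  domain_span <- as.integer(domain_span)
  if (length(domain_span) != 2L || domain_span[1] < 1L ||
      domain_span[2] > root_length || domain_span[1] > domain_span[2]) {
    abort("domain_span must lie within [1, root_length] with start <= end")
  }
  if (rate_domain < 0 || rate_flank < 0 || rate_domain > rate_flank) {
    abort("rates must be non-negative with rate_domain <= rate_flank")
  }

  nodes <- family$nodes
  rate <- rep(rate_flank, root_length)
  rate[domain_span[1]:domain_span[2]] <- rate_domain

  fam_id <- sub("_.*$", "", family$genes$protein[1] %or% "fam")
  seqs <- with_seed(derive_seed(seed, paste0("sequences_", fam_id)), {
    out <- vector("list", nrow(nodes))
    for (i in seq_len(nrow(nodes))) {
      if (is.na(nodes$parent[i])) {
        out[[i]] <- sample(AA_ALPHABET20, root_length, replace = TRUE)
        next
      }
      parent_seq <- out[[nodes$parent[i]]]
      p_sub <- 1 - exp(-rate * nodes$branch_length[i])
      flip <- runif(root_length) < p_sub
      child <- parent_seq
      if (any(flip)) {
        child[flip] <- vapply(
          parent_seq[flip],
          function(a) sample(setdiff(AA_ALPHABET20, a), 1L),
          character(1)
        )
      }
      out[[i]] <- child
    }
    out
  })

  genes <- family$genes
  tibble(
    protein = genes$protein,
    organism = genes$organism,
    family = fam_id,
    sequence = vapply(seqs[genes$node], paste, character(1), collapse = ""),
    domain_start = domain_span[1],
    domain_end = domain_span[2],
    entryType = "Reviewed",
    proteinExistence = "Evidence at protein level",
    sequenceVersion = 1L,
    crossRefCount = 5L,
    is_valid = TRUE,
    defects = ""
  ) |>
    arrange(.data$protein)
}
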