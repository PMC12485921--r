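#' Simulate a species tree with lineage labels
#'
#' Generates a random rooted binary tree whose tips stand in for proteome
#' organisms, each tagged with a taxonomic lineage label and a eukaryote
#' flag. Lineage labels are assigned to contiguous blocks of tips in tree
#' order, so lineages look clade-like without constraining the topology.
#'
#' @param n_taxa Number of tips (positive integer).
#' @param lineage_spec Named integer vector mapping lineage label to tip
#'   count; must sum to `n_taxa`.
#' @param branch_scale Mean branch length in expected substitutions per site
#'   (exponential draws).
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @param prokaryote_lineages Lineage labels flagged as non-eukaryote.
#' @return A list of class `ic_species_tree` with elements `tree` (an
#'   [ape::phylo]) and `taxonomy` (tibble: `organism`, `lineage`,
#'   `eukaryote`).
#' @export
#' @examples
#' sp <- simulate_species_tree(8, c(Mammalia = 4, Bacteria = 4), seed = 1)
#' sp$taxonomy
simulate_species_tree <- function(n_taxa,
                                  lineage_spec,
                                  branch_scale = 0.1,
                                  seed = 1,
                                  prokaryote_lineages = c("Bacteria", "Archaea")) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 1L) abort("n_taxa must be a positive integer")
  if (is.null(names(lineage_spec)) || any(!nzchar(names(lineage_spec)))) {
    abort("lineage_spec must be a named vector of counts")
  }
  if (sum(lineage_spec) != n_taxa) {
    abort("lineage counts in lineage_spec must sum to n_taxa")
  }
  if (branch_scale <= 0) abort("branch_scale must be positive")

  organisms <- sprintf("org%02d", seq_len(n_taxa))
  tree <- with_seed(derive_seed(seed, "species_tree"), {
    if (n_taxa == 1L) {
      single_tip_tree(organisms)
    } else {
      tr <- ape::rtree(
        n_taxa,
        rooted = TRUE,
        br = function(k) stats::rexp(k, rate = 1 / branch_scale)
      )
      tr$tip.label <- organisms[order(order_tips(tr))]
      tr
    }
  })

  # lineage blocks follow tip order so labels are contiguous on the tree
  tip_order <- if (n_taxa == 1L) 1L else order_tips(tree)
  lineages <- rep(names(lineage_spec), times = lineage_spec)
  taxonomy <- tibble(
    organism = tree$tip.label[tip_order],
    lineage = lineages,
    eukaryote = !lineages %in% prokaryote_lineages
  ) |>
    arrange(.data$organism)

  structure(list(tree = tree, taxonomy = taxonomy), class = "ic_species_tree")
}

#' @noRd
single_tip_tree <- function(label) {
  structure(
    list(
      edge = matrix(c(2L, 1L), nrow = 1L),
      tip.label = label,
      edge.length = 0,
      Nnode = 1L
    ),
    class = "phylo",
    order = "cladewise"
  )
}

#' Tip indices in left-to-right plotting order
#' @noRd
order_tips <- function(tree) {
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  edge[edge[, 2] <= ape::Ntip(tree), 2]
}

#' @export
print.ic_species_tree <- function(x, ...) {
  cat(sprintf(
    "<ic_species_tree> %d organisms, %d lineages\n",
    nrow(x$taxonomy), dplyr::n_distinct(x$taxonomy$lineage)
  ))
  print(dplyr::count(x$taxonomy, .data$lineage, .data$eukaryote))
  invisible(x)
}
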