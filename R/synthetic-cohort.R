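#' Simulate a full study cohort: proteomes, queries and orthology truth
#'
#' Convenience wrapper that assembles the desk-scale study conditions: a
#' species tree, `n_families` independent gene families evolved along it,
#' per-protein sequences with a slowly evolving pore domain, optional
#' planted metadata defects, and the pooled ground-truth orthology table.
#' One organism of `reference_lineage` plays the role of the reference
#' proteome (the human stand-in) whose proteins are the ion-channel query
#' set.
#'
#' @inheritParams simulate_species_tree
#' @inheritParams simulate_gene_family
#' @inheritParams evolve_sequences
#' @param n_families Number of independent gene families.
#' @param defects Optional [defect_config()]; `NULL` plants nothing.
#' @param reference_lineage Lineage whose first organism provides the query
#'   proteome.
#' @param seed Master seed; per-family child seeds are derived from it.
#' @return A list of class `ic_cohort`: `species` (the `ic_species_tree`),
#'   `records` (all protein records), `queries` (the reference organism's
#'   records), `reference_organism`, `truth` (pooled truth pairs with a
#'   `family` column), `families` (list of `ic_gene_family`).
#' @export
simulate_cohort <- function(n_taxa = 8,
                            lineage_spec = c(Mammalia = 2, Metazoa = 2,
                                             Fungi = 2, Bacteria = 2),
                            n_families = 12,
                            dup_rate = 0,
                            loss_rate = 0,
                            branch_scale = 0.1,
                            root_length = 240L,
                            domain_span = c(81L, 160L),
                            rate_domain = 0.3,
                            rate_flank = 1.0,
                            defects = NULL,
                            reference_lineage = "Mammalia",
                            seed = 1) {
  species <- simulate_species_tree(
    n_taxa, lineage_spec,
    branch_scale = branch_scale, seed = seed
  )
  fam_ids <- sprintf("fam%02d", seq_len(n_families))
  families <- lapply(fam_ids, function(fid) {
    simulate_gene_family(
      species,
      dup_rate = dup_rate, loss_rate = loss_rate,
      seed = derive_seed(seed, fid), family_id = fid
    )
  })
  names(families) <- fam_ids

  records <- list_rbind(lapply(fam_ids, function(fid) {
    evolve_sequences(
      families[[fid]],
      root_length = root_length, domain_span = domain_span,
      rate_domain = rate_domain, rate_flank = rate_flank,
      seed = derive_seed(seed, fid)
    )
  }))
  if (!is.null(defects)) {
    records <- plant_metadata_defects(records, defects, seed = seed)
  }

  ref_candidates <- filter(species$taxonomy, .data$lineage == reference_lineage)
  if (nrow(ref_candidates) == 0) {
    abort(sprintf("no organism in reference lineage '%s'", reference_lineage))
  }
  reference_organism <- sort(ref_candidates$organism)[1]
  truth <- list_rbind(lapply(fam_ids, function(fid) {
    mutate(families[[fid]]$truth, family = fid)
  }))

  structure(
    list(
      species = species,
      records = records,
      queries = filter(records, .data$organism == reference_organism),
      reference_organism = reference_organism,
      truth = truth,
      families = families
    ),
    class = "ic_cohort"
  )
}

#' @export
print.ic_cohort <- function(x, ...) {
  cat(sprintf(
    "<ic_cohort> %d organisms, %d families, %d proteins (%d queries from %s)\n",
    nrow(x$species$taxonomy), length(x$families), nrow(x$records),
    nrow(x$queries), x$reference_organism
  ))
  invisible(x)
}
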