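test_that("species tree simulation is deterministic and respects lineage spec", {
  sp1 <- simulate_species_tree(8, c(A = 4, B = 4), seed = 11)
  sp2 <- simulate_species_tree(8, c(A = 4, B = 4), seed = 11)
  expect_identical(ape::write.tree(sp1$tree), ape::write.tree(sp2$tree))
  expect_identical(sp1$taxonomy, sp2$taxonomy)
  sp3 <- simulate_species_tree(8, c(A = 4, B = 4), seed = 12)
  expect_false(identical(ape::write.tree(sp1$tree), ape::write.tree(sp3$tree)))

  counts <- table(sp1$taxonomy$lineage)
  expect_equal(as.integer(counts[c("A", "B")]), c(4L, 4L))
  expect_equal(sort(sp1$taxonomy$organism), sort(sp1$tree$tip.label))
  expect_true(all(sp1$tree$edge.length >= 0))
})

test_that("degenerate and invalid species-tree inputs are handled", {
  sp <- simulate_species_tree(1, c(Mammalia = 1), seed = 1)
  expect_equal(ape::Ntip(sp$tree), 1L)
  expect_equal(nrow(sp$taxonomy), 1L)
  expect_error(simulate_species_tree(0, c(A = 0)), "positive")
  expect_error(simulate_species_tree(4, c(A = 3)), "sum to n_taxa")
  expect_false(
    simulate_species_tree(2, c(Bacteria = 2), seed = 1)$taxonomy$eukaryote[1]
  )
})

test_that("without duplication or loss every species carries one one-to-one gene", {
  sp <- simulate_species_tree(6, c(A = 3, B = 3), seed = 2)
  fam <- simulate_gene_family(sp, dup_rate = 0, loss_rate = 0, seed = 2)
  expect_equal(sort(fam$genes$organism), sort(sp$taxonomy$organism))
  expect_equal(nrow(fam$truth), choose(6, 2))
  expect_true(all(fam$truth$relation == "one-to-one"))
  expect_equal(fam$n_losses, 0L)
})

test_that("heavy loss empties some species and removes their truth pairs", {
  sp <- simulate_species_tree(8, c(A = 4, B = 4), branch_scale = 0.5,
                              seed = 3)
  fam <- simulate_gene_family(sp, dup_rate = 0, loss_rate = 6, seed = 3)
  present <- unique(fam$genes$organism)
  absent <- setdiff(sp$taxonomy$organism, present)
  expect_gt(length(absent), 0)
  truth_orgs <- unique(c(
    sub("^fam01_(org[0-9]+)_.*$", "\\1", fam$truth$protein_a),
    sub("^fam01_(org[0-9]+)_.*$", "\\1", fam$truth$protein_b)
  ))
  expect_length(intersect(truth_orgs, absent), 0)
})

test_that("truth relations equal species-overlap reconciliation on duplicated families", {
  found_dup <- FALSE
  for (seed in 1:30) {
    sp <- simulate_species_tree(5, c(A = 3, B = 2), branch_scale = 0.4,
                                seed = seed)
    fam <- simulate_gene_family(sp, dup_rate = 1.2, loss_rate = 0,
                                seed = seed)
    if (nrow(fam$genes) > 12) next
    oracle <- reconcile_oracle(fam)
    expect_equal(
      as.data.frame(fam$truth)[order(fam$truth$protein_a,
                                     fam$truth$protein_b), ],
      oracle,
      ignore_attr = TRUE
    )
    if (any(fam$truth$relation == "co-ortholog")) found_dup <- TRUE
  }
  expect_true(found_dup) # co-ortholog cases were actually exercised
})

test_that("a duplication before speciation yields co-orthologs on both copies", {
  for (seed in 1:50) {
    sp <- simulate_species_tree(2, c(A = 1, B = 1), branch_scale = 1,
                                seed = seed)
    fam <- simulate_gene_family(sp, dup_rate = 0.8, loss_rate = 0,
                                seed = seed)
    per_org <- table(fam$genes$organism)
    if (length(per_org) == 2 && any(per_org > 1)) {
      cross <- fam$truth
      expect_true(all(cross$relation == "co-ortholog"))
      return(invisible(NULL))
    }
  }
  fail("no duplicated two-species family found across seeds")
})

test_that("sequence evolution honours rates and branch lengths", {
  sp <- simulate_species_tree(4, c(A = 2, B = 2), seed = 4)
  fam <- simulate_gene_family(sp, seed = 4)

  frozen <- evolve_sequences(fam, root_length = 60,
                             domain_span = c(21, 40),
                             rate_domain = 0, rate_flank = 0, seed = 4)
  expect_equal(length(unique(frozen$sequence)), 1L)

  again <- evolve_sequences(fam, root_length = 60, domain_span = c(21, 40),
                            rate_domain = 0, rate_flank = 0, seed = 4)
  expect_identical(frozen, again)

  expect_error(
    evolve_sequences(fam, root_length = 60, domain_span = c(0, 40)),
    "domain_span"
  )
  expect_error(
    evolve_sequences(fam, root_length = 60, domain_span = c(1, 10),
                     rate_domain = 1, rate_flank = 0.5),
    "rate_domain <= rate_flank"
  )
})

test_that("pore domain stays more conserved than the flanks", {
  identities <- replicate(100, NA_real_) # filled below
  dom_ident <- c(); flank_ident <- c()
  pair_count <- 0
  seed <- 0
  while (pair_count < 100) {
    seed <- seed + 1
    sp <- simulate_species_tree(2, c(A = 1, B = 1), branch_scale = 0.3,
                                seed = seed)
    fam <- simulate_gene_family(sp, seed = seed)
    recs <- evolve_sequences(fam, root_length = 200,
                             domain_span = c(61, 140),
                             rate_domain = 0.3, rate_flank = 1.0,
                             seed = seed)
    if (nrow(recs) != 2) next
    a <- strsplit(recs$sequence[1], "")[[1]]
    b <- strsplit(recs$sequence[2], "")[[1]]
    dom <- 61:140
    dom_ident <- c(dom_ident, mean(a[dom] == b[dom]))
    flank_ident <- c(flank_ident, mean(a[-dom] == b[-dom]))
    pair_count <- pair_count + 1
  }
  expect_gt(mean(dom_ident), mean(flank_ident))
  expect_gt(
    stats::t.test(dom_ident, flank_ident, alternative = "greater")$statistic,
    2
  )
})

test_that("defect planting is truthful: no defects when all fractions are zero", {
  co <- simulate_cohort(n_taxa = 4,
                        lineage_spec = c(Mammalia = 2, Bacteria = 2),
                        n_families = 2, seed = 5)
  planted <- plant_metadata_defects(co$records, defect_config(), seed = 5)
  expect_true(all(planted$is_valid))
  expect_true(all(planted$defects == ""))
})

test_that("planted defects carry the matching truth labels", {
  co <- simulate_cohort(n_taxa = 4,
                        lineage_spec = c(Mammalia = 2, Bacteria = 2),
                        n_families = 6, seed = 6)
  cfg <- defect_config(length_short = 1)
  planted <- plant_metadata_defects(co$records, cfg, seed = 6)
  expect_true(all(!planted$is_valid))
  expect_true(all(planted$defects == "length"))
  expect_true(all(nchar(planted$sequence) < 30))
  expect_true(all(planted$entryType == "Unreviewed"))
  expect_true(all(planted$proteinExistence %in% c("Predicted", "Uncertain")))

  planted_x <- plant_metadata_defects(co$records,
                                      defect_config(nonstandard = 1),
                                      seed = 6)
  frac_x <- vapply(strsplit(planted_x$sequence, ""), function(ch) {
    mean(ch == "X")
  }, numeric(1))
  expect_true(all(frac_x > 0.05))
  expect_true(all(planted_x$defects == "nonstandard"))
  expect_error(defect_config(nonstandard = 1.2), "\\[0, 1\\]")
})

test_that("patterned MSA plants exactly the requested column structure", {
  out <- simulate_patterned_msa(
    n_subfamilies = 3, seqs_per_subfamily = 10, length = 40,
    shared_columns = c(5, 15),
    subfamily_columns = list(sf1 = 8, sf2 = 22, sf3 = 31),
    noise = 0, seed = 7
  )
  mat <- do.call(rbind, strsplit(out$msa$sequence, ""))
  for (col in c(5, 15)) {
    expect_equal(length(unique(mat[, col])), 1L)
  }
  rows_sf2 <- which(out$msa$subfamily == "sf2")
  expect_equal(length(unique(mat[rows_sf2, 22])), 1L)
  # a subfamily column is not globally conserved
  expect_gt(length(unique(mat[, 22])), 1L)
  # background columns carry many residues
  bg_col <- setdiff(seq_len(40), c(5, 15, 8, 22, 31))[1]
  expect_gt(length(unique(mat[, bg_col])), 5L)

  expect_error(
    simulate_patterned_msa(2, 5, 40, shared_columns = c(3, 3)),
    "disjoint"
  )
  expect_error(
    simulate_patterned_msa(2, 5, 40, shared_columns = 45),
    "within"
  )
})

test_that("with one subfamily, subfamily columns behave like shared columns", {
  out <- simulate_patterned_msa(
    n_subfamilies = 1, seqs_per_subfamily = 12, length = 30,
    subfamily_columns = list(sf1 = c(4, 9)), noise = 0, seed = 8
  )
  mat <- do.call(rbind, strsplit(out$msa$sequence, ""))
  expect_equal(length(unique(mat[, 4])), 1L)
  expect_equal(length(unique(mat[, 9])), 1L)
})
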