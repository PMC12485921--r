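# Point mutations at fixed positions, avoiding the original residue.
mutate_seq <- function(sequence, positions) {
  letters20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ch <- strsplit(sequence, "")[[1]]
  for (p in positions) ch[p] <- setdiff(letters20, ch[p])[1]
  paste(ch, collapse = "")
}

desk_params <- orthology_params(e_reciprocal_max = 1e-3)

test_that("domain mode equals full mode when the domain spans the whole protein", {
  withr::with_seed(31, {
    db <- tibble::tibble(
      protein = c("a", "b"), organism = c("o1", "o2"),
      sequence = c(random_seq(50), random_seq(50))
    )
  })
  queries <- tibble::tibble(
    protein = "a", sequence = db$sequence[1],
    domain_start = 1L, domain_end = 50L
  )
  hits <- forward_search(queries, db, params = desk_params)
  full <- dplyr::select(dplyr::filter(hits, mode == "full"), -mode)
  dom <- dplyr::select(dplyr::filter(hits, mode == "domain"), -mode)
  expect_equal(full, dom)

  expect_error(
    forward_search(dplyr::select(queries, -domain_start), db),
    "domain_start"
  )
})

test_that("an E-value cutoff of zero yields an empty candidate table", {
  db <- tibble::tibble(protein = "a", organism = "o1",
                       sequence = strrep("ACDEFGHIKL", 30))
  queries <- tibble::tibble(protein = "a", sequence = db$sequence,
                            domain_start = 1L, domain_end = 300L)
  hits <- forward_search(queries, db,
                         params = orthology_params(e_forward_max = 0,
                                                   e_reciprocal_max = 1))
  expect_equal(nrow(hits), 0L)
})

test_that("mutual best hits are retained and paralog-shadowed pairs dropped", {
  withr::with_seed(32, {
    base1 <- random_seq(60)
    base2 <- random_seq(60)
  })
  # two clean mutual pairs
  ref <- tibble::tibble(
    protein = c("A1", "A2"), organism = "ref",
    sequence = c(base1, base2),
    domain_start = 1L, domain_end = 60L
  )
  db <- dplyr::bind_rows(ref, tibble::tibble(
    protein = c("B1", "B2"), organism = "tgt",
    sequence = c(mutate_seq(base1, 1:5), mutate_seq(base2, 1:5)),
    domain_start = 1L, domain_end = 60L
  ))
  fwd <- forward_search(ref, db, params = desk_params)
  rbh <- reciprocal_confirm(fwd, ref, db, params = desk_params)
  got <- dplyr::filter(rbh, mode == "full", proteome == "tgt")
  expect_setequal(paste(got$ic, got$target), c("A1 B1", "A2 B2"))

  # a target identical to the query's paralog reciprocates to the paralog
  ref2 <- tibble::tibble(
    protein = c("q", "q2"), organism = "ref",
    sequence = c(mutate_seq(base1, 1:6), base1),
    domain_start = 1L, domain_end = 60L
  )
  db2 <- dplyr::bind_rows(ref2, tibble::tibble(
    protein = "t", organism = "tgt", sequence = base1,
    domain_start = 1L, domain_end = 60L
  ))
  fwd2 <- forward_search(ref2, db2, params = desk_params)
  rbh2 <- reciprocal_confirm(fwd2, ref2, db2, params = desk_params)
  tgt_pairs <- dplyr::filter(rbh2, mode == "full", proteome == "tgt")
  expect_equal(tgt_pairs$ic, "q2")

  expect_equal(nrow(reciprocal_confirm(fwd2[0, ], ref2, db2)), 0L)
})

test_that("flow clustering keeps components apart and cliques together", {
  # two disconnected RBH pairs -> two clusters, all pairs retained
  pairs <- tibble::tibble(
    ic = c("a1", "c1"), target = c("b1", "d1"),
    proteome = "p", mode = "full",
    e_forward = c(1e-40, 1e-35), e_reciprocal = c(1e-41, 1e-36)
  )
  out <- cluster_and_filter(pairs, desk_params)
  expect_equal(nrow(out$pairs), 2L)
  expect_equal(dplyr::n_distinct(out$clusters$cluster_id), 2L)

  # fully connected clique of equal weights -> one cluster
  clique <- tidyr::expand_grid(ic = c("x", "y", "z"),
                               target = c("x", "y", "z")) |>
    dplyr::filter(ic < target) |>
    dplyr::mutate(proteome = "p", mode = "full",
                  e_forward = 1e-30, e_reciprocal = 1e-30)
  out2 <- cluster_and_filter(clique, desk_params)
  expect_equal(dplyr::n_distinct(out2$clusters$cluster_id), 1L)
  expect_equal(nrow(out2$pairs), 3L)
})

test_that("clusters equal connected components on well-separated graphs", {
  withr::with_seed(33, {
    for (trial in 1:10) {
      n_comp <- sample(2:4, 1)
      edges <- purrr::list_rbind(lapply(seq_len(n_comp), function(cmp) {
        size <- sample(2:4, 1)
        members <- sprintf("c%d_n%d", cmp, seq_len(size))
        tibble::tibble(
          ic = members[1], target = members[-1],
          proteome = "p", mode = "full",
          e_forward = 10^(-sample(20:60, size - 1, replace = TRUE)),
          e_reciprocal = 1e-20
        )
      }))
      out <- cluster_and_filter(edges, desk_params)
      membership <- setNames(out$clusters$cluster_id, out$clusters$protein)
      comp_of <- sub("_.*$", "", out$clusters$protein)
      # clusters refine to exactly the components
      expect_equal(
        dplyr::n_distinct(paste(comp_of, membership)),
        dplyr::n_distinct(comp_of)
      )
      expect_equal(dplyr::n_distinct(membership), dplyr::n_distinct(comp_of))
      expect_equal(nrow(out$pairs), nrow(edges))
    }
  })
})

test_that("evidence intersection follows the both-modes rule", {
  full <- tibble::tibble(
    ic = c("a", "a"), target = c("t1", "t2"), proteome = "p",
    e_forward = c(1e-30, 1e-28), e_reciprocal = c(1e-31, 1e-29),
    cluster_id = 1L
  )
  dom <- tibble::tibble(
    ic = "a", target = "t1", proteome = "p",
    e_forward = 1e-20, e_reciprocal = 1e-21, cluster_id = 1L
  )
  both <- intersect_evidence(full, dom)
  expect_equal(both$target, "t1")
  expect_equal(both$evidence, "both")
  expect_equal(both$e_forward, 1e-20) # conservative max of the two modes
  expect_equal(nrow(intersect_evidence(full, dom[0, ])), 0L)
  expect_equal(nrow(intersect_evidence(full[0, ], dom)), 0L)
})

test_that("relationship classification separates one-to-one from co-orthologs", {
  single <- tibble::tibble(ic = "a", target = "t1", proteome = "p1")
  expect_equal(classify_relationship(single)$relation, "one-to-one")

  multi <- tibble::tibble(
    ic = c("a", "a", "b"), target = c("t1", "t2", "t3"),
    proteome = c("p1", "p1", "p2")
  )
  out <- classify_relationship(multi)
  expect_equal(out$relation[out$proteome == "p1"],
               c("co-ortholog", "co-ortholog"))
  expect_equal(out$relation[out$proteome == "p2"], "one-to-one")

  # two ics sharing one target
  shared <- tibble::tibble(
    ic = c("a", "b"), target = "t1", proteome = "p1"
  )
  expect_true(all(classify_relationship(shared)$relation == "co-ortholog"))
})

test_that("relaxing the forward threshold never removes retained hits", {
  co <- simulate_cohort(n_taxa = 4,
                        lineage_spec = c(Mammalia = 2, Bacteria = 2),
                        n_families = 3, seed = 34)
  strict <- forward_search(co$queries, co$records,
                           params = orthology_params(e_forward_max = 1e-20,
                                                     e_reciprocal_max = 1))
  loose <- forward_search(co$queries, co$records,
                          params = orthology_params(e_forward_max = 1e-5,
                                                    e_reciprocal_max = 1))
  expect_true(all(
    paste(strict$query, strict$subject, strict$mode) %in%
      paste(loose$query, loose$subject, loose$mode)
  ))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("a small clean cohort is recovered with high precision and recall", {
  co <- simulate_cohort(n_taxa = 6,
                        lineage_spec = c(Mammalia = 2, Metazoa = 2,
                                         Bacteria = 2),
                        n_families = 4, seed = 35)
  orth <- infer_orthologs(co$queries, co$records, params = desk_params)
  acc <- orthology_accuracy(co, orth)
  expect_gte(acc$precision, 0.95)
  expect_gte(acc$recall, 0.95)
  expect_true(all(orth$pairs$relation == "one-to-one"))
  expect_true(all(orth$pairs$evidence == "both"))

  g <- generics::glance(orth)
  expect_equal(g$n_pairs, nrow(orth$pairs))
  expect_equal(generics::tidy(orth), tibble::as_tibble(orth$pairs))
})
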