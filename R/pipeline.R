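#' Declarative configuration for the end-to-end pipeline
#'
#' Collects every stage parameter with its documented default and
#' validates ranges up front, before any stage runs. Two built-in profiles
#' exist and must be selected explicitly: `"paper"` keeps the documented
#' full-scale thresholds (reciprocal E-value 1e-200), `"desk"` swaps in
#' the desk-scale reciprocal threshold (1e-3) appropriate for short
#' synthetic sequences; an explicit `e_reciprocal_max` overrides either.
#'
#' @param seed Master seed; every stage derives its own child seed from it.
#' @param profile `"desk"` or `"paper"`.
#' @param outdir Output directory for [run_end_to_end()].
#' @param n_taxa,lineage_spec,n_families,dup_rate,loss_rate,branch_scale
#'   Cohort parameters (see [simulate_cohort()]).
#' @param root_length,domain_span,rate_domain,rate_flank Sequence-evolution
#'   parameters.
#' @param defects A [defect_config()] for planted metadata defects.
#' @param e_forward_max Forward E-value cutoff (> 0).
#' @param e_reciprocal_max Reciprocal E-value threshold; `NULL` takes the
#'   profile default.
#' @param inflation,weight_cap Graph-clustering parameters.
#' @param k_clusters Profile cluster count (default 9).
#' @param fdr_max Enrichment FDR threshold (default 0.01).
#' @param n_subfamilies,seqs_per_subfamily,msa_length,n_shared_columns,n_subfamily_columns,msa_noise
#'   Patterned-MSA parameters.
#' @param n_perm,p_max,c_min Pattern-selection parameters.
#' @param qc A [qc_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            profile = c("desk", "paper"),
                            outdir = file.path(tempdir(), "icortho_run"),
                            n_taxa = 8,
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
                            defects = defect_config(
                              length_short = 0.04, length_long = 0.02,
                              nonstandard = 0.04, complexity = 0.04,
                              version = 0.04, crossrefs = 0.04
                            ),
                            e_forward_max = 1e-5,
                            e_reciprocal_max = NULL,
                            inflation = 1.5,
                            weight_cap = 200,
                            k_clusters = 9,
                            fdr_max = 0.01,
                            n_subfamilies = 4,
                            seqs_per_subfamily = 50,
                            msa_length = 100,
                            n_shared_columns = 5,
                            n_subfamily_columns = 3,
                            msa_noise = 0.1,
                            n_perm = 1000,
                            p_max = 0.01,
                            c_min = 0.7,
                            qc = qc_config()) {
  profile <- match.arg(profile)
  if (e_forward_max <= 0) abort("e_forward_max must be > 0")
  e_reciprocal_max <- e_reciprocal_max %||%
    switch(profile, paper = 1e-200, desk = 1e-3)
  if (e_reciprocal_max <= 0) abort("e_reciprocal_max must be > 0")
  if (inflation <= 1) abort("inflation must be > 1")
  if (k_clusters < 1) abort("k_clusters must be >= 1")
  if (fdr_max <= 0 || fdr_max > 1) abort("fdr_max must lie in (0, 1]")
  if (p_max <= 0 || p_max > 1) abort("p_max must lie in (0, 1]")
  if (c_min < 0 || c_min > 1) abort("c_min must lie in [0, 1]")
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (msa_noise < 0 || msa_noise > 1) abort("msa_noise must lie in [0, 1]")
  stopifnot(inherits(defects, "defect_config"), inherits(qc, "qc_config"))
  structure(
    list(
      seed = seed, profile = profile, outdir = outdir,
      n_taxa = n_taxa, lineage_spec = lineage_spec,
      n_families = n_families, dup_rate = dup_rate, loss_rate = loss_rate,
      branch_scale = branch_scale, root_length = root_length,
      domain_span = domain_span, rate_domain = rate_domain,
      rate_flank = rate_flank, defects = defects,
      e_forward_max = e_forward_max, e_reciprocal_max = e_reciprocal_max,
      inflation = inflation, weight_cap = weight_cap,
      k_clusters = k_clusters, fdr_max = fdr_max,
      n_subfamilies = n_subfamilies,
      seqs_per_subfamily = seqs_per_subfamily,
      msa_length = msa_length, n_shared_columns = n_shared_columns,
      n_subfamily_columns = n_subfamily_columns, msa_noise = msa_noise,
      n_perm = n_perm, p_max = p_max, c_min = c_min, qc = qc
    ),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-cohort pipeline end to end
#'
#' Executes all stages in order -- simulate, search, orthology, validate,
#' profile, patterns, pore-domain -- writing every stage output as a
#' plain-text table under `config$outdir` plus a `manifest.json` recording
#' stage, file, content hash, seed and parameters. Reruns with an
#' identical config reproduce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest tibble.
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(x, name, writer = write_tsv_cells) {
    path <- file.path(outdir, name)
    writer(x, path)
    files <<- c(files, path)
    path
  }

  ## 1 -- cohort ------------------------------------------------------
  cohort <- simulate_cohort(
    n_taxa = config$n_taxa, lineage_spec = config$lineage_spec,
    n_families = config$n_families,
    dup_rate = config$dup_rate, loss_rate = config$loss_rate,
    branch_scale = config$branch_scale,
    root_length = config$root_length, domain_span = config$domain_span,
    rate_domain = config$rate_domain, rate_flank = config$rate_flank,
    defects = config$defects, seed = config$seed
  )
  for (org in sort(unique(cohort$records$organism))) {
    put(
      filter(cohort$records, .data$organism == org) |>
        select(id = "protein", "sequence"),
      sprintf("proteome_%s.fasta", org), write_fasta
    )
  }
  put(
    mutate(cohort$species$taxonomy,
           eukaryote = as.character(.data$eukaryote)),
    "taxonomy.tsv"
  )
  put(
    select(cohort$records, -"sequence") |>
      mutate(across(dplyr::where(is.numeric), as.character),
             is_valid = as.character(.data$is_valid)),
    "metadata.tsv"
  )
  put(cohort$truth, "truth_orthology.tsv")
  tree_path <- file.path(outdir, "species_tree.nwk")
  ape::write.tree(cohort$species$tree, tree_path)
  files <- c(files, tree_path)

  msa_seed <- derive_seed(config$seed, "msa_columns")
  planted <- with_seed(msa_seed, {
    cols <- sample(
      config$msa_length,
      config$n_shared_columns +
        config$n_subfamilies * config$n_subfamily_columns
    )
    shared <- cols[seq_len(config$n_shared_columns)]
    rest <- setdiff(cols, shared)
    subfam <- split(
      rest,
      rep(sprintf("sf%d", seq_len(config$n_subfamilies)),
          each = config$n_subfamily_columns)
    )
    list(shared = shared, subfamily = subfam)
  })
  pmsa <- simulate_patterned_msa(
    n_subfamilies = config$n_subfamilies,
    seqs_per_subfamily = config$seqs_per_subfamily,
    length = config$msa_length,
    shared_columns = planted$shared,
    subfamily_columns = planted$subfamily,
    noise = config$msa_noise,
    seed = config$seed
  )
  put(select(pmsa$msa, "id", "sequence"), "patterned_msa.fasta", write_fasta)
  put(select(pmsa$msa, "id", "subfamily"), "msa_subfamilies.tsv")

  ## 2 -- forward search ----------------------------------------------
  scheme <- scoring_scheme()
  params <- orthology_params(
    e_forward_max = config$e_forward_max,
    e_reciprocal_max = config$e_reciprocal_max,
    inflation = config$inflation, weight_cap = config$weight_cap
  )
  hits <- forward_search(cohort$queries, cohort$records, scheme, params)
  put(mutate(hits, across(dplyr::where(is.numeric), format_num)),
      "forward_hits.tsv")

  ## 3 -- orthology ----------------------------------------------------
  orth <- infer_orthologs(cohort$queries, cohort$records, scheme, params)
  put(mutate(orth$pairs, across(dplyr::where(is.numeric), format_num)),
      "orthology.tsv")
  put(orth$clusters |> mutate(cluster_id = as.character(.data$cluster_id)),
      "clusters.tsv")

  ## 4 -- validation ---------------------------------------------------
  val <- filter_validated(orth$pairs, cohort$records, config$qc)
  put(mutate(val$verdicts, pass = as.character(.data$pass)), "verdicts.tsv")
  put(mutate(val$pairs, across(dplyr::where(is.numeric), format_num)),
      "orthology_validated.tsv")
  report_path <- file.path(outdir, "validation_report.json")
  jsonlite::write_json(val$report, report_path, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, report_path)

  ## 5 -- profiling ----------------------------------------------------
  profile <- build_profile(
    val$pairs,
    ic_list = sort(cohort$queries$protein),
    organism_list = sort(cohort$species$taxonomy$organism)
  )
  put(mutate(profile, state = as.character(.data$state)), "profile.tsv")
  family_map <- select(cohort$queries, ic = "protein", "family")
  lineage_map <- select(cohort$species$taxonomy, "organism", "lineage")
  pct <- percent_heatmap(profile, family_map, lineage_map)
  put(mutate(pct, across(dplyr::where(is.numeric), format_num)),
      "percent_heatmap.tsv")
  euk <- cohort$species$taxonomy$organism[cohort$species$taxonomy$eukaryote]
  k_use <- min(config$k_clusters, dplyr::n_distinct(profile$ic))
  prof_clusters <- cluster_profiles(profile, scope_organisms = euk,
                                    k = k_use)
  put(mutate(prof_clusters, cluster = as.character(.data$cluster)),
      "profile_clusters.tsv")
  term_map <- select(cohort$queries, id = "protein", term = "family")
  enrichment <- enrich_clusters(prof_clusters, term_map,
                                fdr_max = config$fdr_max)
  put(mutate(enrichment, across(dplyr::where(is.numeric), format_num)),
      "enrichment.tsv")

  ## 6 -- patterns -----------------------------------------------------
  fg <- pmsa$msa$id[pmsa$msa$subfamily == "sf1"]
  scan <- select_patterns(
    select(pmsa$msa, "id", "sequence"), fg,
    n_perm = config$n_perm, p_max = config$p_max, seed = config$seed
  )
  shared_scan <- family_shared_patterns(
    pmsa$msa,
    c_min = config$c_min, n_perm = config$n_perm, p_max = config$p_max,
    seed = config$seed
  )
  ref_id <- pmsa$msa$id[1]
  put(
    map_to_reference(select(pmsa$msa, "id", "sequence"), scan, ref_id) |>
      mutate(across(dplyr::where(is.numeric), format_num),
             reference_gapped = as.character(.data$reference_gapped)),
    "pattern_positions_sf1.tsv"
  )
  put(
    map_to_reference(select(pmsa$msa, "id", "sequence"), shared_scan,
                     ref_id) |>
      mutate(across(dplyr::where(is.numeric), format_num),
             reference_gapped = as.character(.data$reference_gapped)),
    "pattern_positions_shared.tsv"
  )

  ## 7 -- pore domain --------------------------------------------------
  tm <- cohort$queries |>
    transmute(
      protein = .data$protein, source = "uniprot", kind = "TM",
      start = .data$domain_start, end = .data$domain_end
    )
  consensus <- merge_tm_sources(
    tm, setNames(nchar(cohort$queries$sequence), cohort$queries$protein)
  )
  domains <- define_pore_domain(consensus)
  units <- classify_unit(tibble(
    protein = cohort$queries$protein,
    has_pore_domain = cohort$queries$protein %in% domains$protein,
    complex_evidence = FALSE
  ))
  put(
    left_join(units, domains, by = "protein") |>
      mutate(across(dplyr::where(is.numeric), format_num)),
    "pore_domains.tsv"
  )

  ## manifest ----------------------------------------------------------
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(
      seed = config$seed,
      profile = config$profile,
      parameters = config[!names(config) %in%
                            c("defects", "qc", "lineage_spec")],
      lineage_spec = as.list(config$lineage_spec),
      files = manifest
    ),
    manifest_path, auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    cohort = cohort, hits = hits, orthology = orth, validation = val,
    profile = profile, percent = pct, clusters = prof_clusters,
    enrichment = enrichment, patterns = scan, shared_patterns = shared_scan,
    domains = domains, units = units, manifest = manifest,
    outdir = outdir
  ))
}

#' Fixed-precision numeric formatting for stable table output
#' @noRd
format_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 10, format = "g"))
}
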