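toy_msa <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  tibble::tibble(id = ids, sequence = seqs)
}

test_that("column profiles tally residues and skip gap-dominated columns", {
  msa <- toy_msa(c("ACD-", "ACE-", "GCD-"))
  prof <- column_profiles(msa, foreground = c("s1", "s2"),
                          background = "s3")
  col1 <- dplyr::filter(prof, column == 1)
  expect_equal(col1$fg_count[col1$residue == "A"], 2L)
  expect_equal(col1$bg_count[col1$residue == "G"], 1L)
  col3 <- dplyr::filter(prof, column == 3)
  expect_equal(col3$fg_count[col3$residue == "D"], 1L)
  expect_equal(col3$fg_count[col3$residue == "E"], 1L)
  expect_equal(attr(prof, "skipped"), 4L) # the all-gap column

  expect_error(column_profiles(toy_msa(c("AC", "ACD")), "s1", "s2"),
               "ragged")
  expect_error(column_profiles(msa, c("s1", "ghost"), "s3"), "unknown")
  expect_error(column_profiles(msa, c("s1", "s2"), c("s2", "s3")),
               "disjoint")
})

test_that("contrast score follows the closed form and its limits", {
  # literal evaluation of the pseudocounted log-likelihood ratio
  p_hat <- (9 + 0.5) / (10 + 1)
  q_hat <- (5 + 0.5) / (100 + 1)
  expect_equal(
    contrast_score(9, 10, 5, 100),
    9 * log(p_hat / q_hat) + 1 * log((1 - p_hat) / (1 - q_hat))
  )
  # identical frequencies give (near-)zero score
  expect_lt(abs(contrast_score(5, 10, 50, 100)), 0.05)
  expect_error(contrast_score(1, 0, 1, 10), ">= 1")
})

test_that("a perfectly contrasting column attains the alignment maximum", {
  withr::with_seed(61, {
    n <- 20
    mat <- matrix(sample(c("A", "G", "T", "S"), n * 10, replace = TRUE),
                  nrow = n)
    mat[1:10, 4] <- "C"
    mat[11:20, 4] <- "W"
    msa <- toy_msa(apply(mat, 1, paste, collapse = ""))
  })
  scan <- select_patterns(msa, foreground = msa$id[1:10], n_perm = 200,
                          seed = 61)
  all_cols <- attr(scan, "all_columns")
  expect_equal(which.max(all_cols$score), 4L)
  expect_equal(scan$column[1], 4L)
  expect_equal(scan$p[1], min(attr(scan, "all_columns")$p))
  expect_equal(scan$residue_set[1], "C")
})

test_that("reported pattern sets are always foreground-enriched, never anti-conserved", {
  withr::with_seed(62, {
    n <- 30
    mat <- matrix(sample(c("A", "G", "T", "S", "L", "K"), n * 12,
                         replace = TRUE), nrow = n)
    # column 6: the background is perfectly conserved (C), the foreground
    # carries none of it
    mat[1:15, 6] <- sample(c("A", "G", "T"), 15, replace = TRUE)
    mat[16:30, 6] <- "C"
    msa <- toy_msa(apply(mat, 1, paste, collapse = ""))
  })
  scan <- select_patterns(msa, foreground = msa$id[1:15], n_perm = 300,
                          seed = 62)
  # the background-conserved residue is never reported as the foreground
  # pattern, and every reported set is enriched in the foreground
  row6 <- dplyr::filter(scan, column == 6L)
  if (nrow(row6) > 0) expect_false(row6$residue_set == "C")
  expect_true(all(scan$x / scan$m > scan$y / scan$n))

  # from the conserved side the same column is a genuine pattern
  swapped <- select_patterns(msa, foreground = msa$id[16:30], n_perm = 300,
                             seed = 62)
  expect_true(6L %in% swapped$column)
  expect_equal(swapped$residue_set[swapped$column == 6L], "C")
})

test_that("planted columns are recovered and the permutation null is calibrated", {
  # recovery at generator noise 0.1
  pm <- simulate_patterned_msa(
    n_subfamilies = 4, seqs_per_subfamily = 50, length = 60,
    shared_columns = c(10, 30),
    subfamily_columns = list(sf1 = c(5, 20), sf2 = c(25, 40),
                             sf3 = c(45, 50), sf4 = c(15, 55)),
    noise = 0.1, seed = 63
  )
  fg <- pm$msa$id[pm$msa$subfamily == "sf1"]
  scan <- select_patterns(pm$msa[, c("id", "sequence")], fg,
                          n_perm = 500, seed = 63)
  expect_true(all(pm$truth$subfamily_columns$sf1 %in% scan$column))

  # a random foreground over an i.i.d. alignment selects ~p_max of columns
  null_msa <- simulate_patterned_msa(2, 15, 150, noise = 0, seed = 64)
  null_scan <- select_patterns(
    null_msa$msa[, c("id", "sequence")],
    null_msa$msa$id[null_msa$msa$subfamily == "sf1"],
    n_perm = 500, p_max = 0.01, seed = 64
  )
  expect_lte(nrow(null_scan), 8) # ~1.5 expected; generous upper bound

  expect_error(select_patterns(pm$msa, fg, n_perm = 0), "n_perm")
})

test_that("family-shared analysis recovers shared columns and applies c_min per subfamily", {
  pm <- simulate_patterned_msa(
    n_subfamilies = 3, seqs_per_subfamily = 20, length = 40,
    shared_columns = c(8, 16, 24),
    subfamily_columns = list(sf1 = 3, sf2 = 30, sf3 = 35),
    noise = 0, seed = 65
  )
  shared <- family_shared_patterns(pm$msa, n_perm = 300, seed = 65)
  expect_setequal(shared$column, c(8, 16, 24))

  # a column conserved in all but one subfamily fails the c_min filter
  mat <- do.call(rbind, strsplit(pm$msa$sequence, ""))
  mat[pm$msa$subfamily != "sf3", 12] <- "H"
  msa2 <- pm$msa
  msa2$sequence <- apply(mat, 1, paste, collapse = "")
  shared2 <- family_shared_patterns(msa2, n_perm = 300, seed = 65)
  expect_false(12L %in% shared2$column)
  # with the filter disabled the same column is reported
  shared3 <- family_shared_patterns(msa2, c_min = 0, n_perm = 300,
                                    seed = 65)
  expect_true(12L %in% shared3$column)

  expect_error(
    family_shared_patterns(dplyr::mutate(pm$msa, subfamily = "one")),
    ">= 2 subfamilies"
  )
})

test_that("reference numbering maps columns through gaps correctly", {
  msa <- toy_msa(c("---AC-DE", "WWWACWDE"), ids = c("ref", "other"))
  pos <- tibble::tibble(column = c(4, 5, 6, 8))
  out <- map_to_reference(msa, pos, "ref")
  expect_equal(out$label, c("A1", "C2", NA, "E4"))
  expect_equal(out$reference_gapped, c(FALSE, FALSE, TRUE, FALSE))

  # ungapped reference: label index equals column index
  msa2 <- toy_msa(c("ACDEF", "ACDEF"), ids = c("r", "o"))
  out2 <- map_to_reference(msa2, tibble::tibble(column = 1:5), "r")
  expect_equal(out2$label, paste0(strsplit("ACDEF", "")[[1]], 1:5))

  # numbering is a bijection between non-gap columns and 1..L_ref
  ref_chars <- strsplit("---AC-DE", "")[[1]]
  full <- map_to_reference(msa, tibble::tibble(column = 1:8), "ref")
  labs <- full$label[!is.na(full$label)]
  expect_equal(as.integer(sub("^[A-Z]", "", labs)),
               seq_len(sum(!ref_chars %in% c("-", "."))))

  expect_error(map_to_reference(msa, pos, "ghost"), "not present")
})

test_that("pattern scan objects expose tidy, glance and plots", {
  pm <- simulate_patterned_msa(2, 10, 30, shared_columns = 5,
                               noise = 0, seed = 66)
  fg <- pm$msa$id[pm$msa$subfamily == "sf1"]
  scan <- select_patterns(pm$msa[, c("id", "sequence")], fg, n_perm = 100,
                          seed = 66)
  td <- generics::tidy(scan)
  expect_false(inherits(td, "pattern_scan"))
  g <- generics::glance(scan)
  expect_equal(g$n_columns, 30L)
  expect_equal(g$n_perm, 100)
  p <- ggplot2::autoplot(scan)
  expect_s3_class(p, "ggplot")
})
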