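test_that("mean normalization equalizes channel means and is a fixed point", {
  des <- fixture_design()
  withr::with_seed(1, {
    tbl <- tibble::as_tibble(matrix(rlnorm(300, 14, 1), 50, 6,
                                    dimnames = list(NULL, des$channel_labels)))
  })
  norm <- mean_normalize(tbl, des)
  m <- oracle_channel_means(norm, des$channel_labels)
  expect_equal(unname(m), rep(mean(oracle_channel_means(tbl, des$channel_labels)), 6),
               tolerance = 1e-12)
  # already-normalized tables pass through unchanged
  expect_equal(as.data.frame(mean_normalize(norm, des)), as.data.frame(norm),
               tolerance = 1e-12)
})

test_that("scaling one channel is undone by normalization (ratios restored)", {
  des <- fixture_design()
  withr::with_seed(2, {
    tbl <- tibble::as_tibble(matrix(rlnorm(120, 14, 1), 20, 6,
                                    dimnames = list(NULL, des$channel_labels)))
  })
  scaled <- tbl
  scaled[["CK-02"]] <- scaled[["CK-02"]] * 10
  n1 <- mean_normalize(tbl, des)
  n2 <- mean_normalize(scaled, des)
  r1 <- n1[["CK-02"]] / n1[["CK-01"]]
  r2 <- n2[["CK-02"]] / n2[["CK-01"]]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("missing cells survive normalization and all-missing channels error", {
  des <- fixture_design()
  tbl <- dplyr::bind_rows(
    make_peptide_table("p", "PEPTIDEK", c(1, NA, 3), c(2, 2, 2)),
    make_peptide_table("p", "GGGGGGK", c(2, 4, 3), c(2, 2, 2))
  )
  norm <- mean_normalize(tbl, des)
  expect_true(is.na(norm[["CK-02"]][1]))
  expect_false(anyNA(norm[["CK-02"]][2]))
  tbl2 <- make_peptide_table("p", "PEPTIDEK", c(NA, NA, NA), c(2, 2, 2))
  expect_error(mean_normalize(tbl2, des), "CK-0")
})

test_that("a single unique peptide gives its exact ratio and the median rules proteins", {
  des <- fixture_design()
  tbl <- make_peptide_table("p1", "AAAAK", c(2, 2, 2), c(4, 4, 4))
  pr <- quantify_proteins(tbl, des)
  expect_equal(pr$ratio, 2)
  expect_equal(pr$log2_ratio, 1)

  tbl3 <- dplyr::bind_rows(
    make_peptide_table("p1", "AAAAK", c(2, 2, 2), c(2, 2, 2)),
    make_peptide_table("p1", "CCCCK", c(2, 2, 2), c(4, 4, 4)),
    make_peptide_table("p1", "DDDDK", c(1, 1, 1), c(9, 9, 9))
  )
  pr3 <- quantify_proteins(tbl3, des)
  expect_equal(pr3$ratio, 2)
  expect_equal(pr3$n_unique_peptides, 3L)
})

test_that("shared peptides are excluded and missingness rules unquantify proteins", {
  des <- fixture_design()
  tbl <- dplyr::bind_rows(
    make_peptide_table("p1", "AAAAK", c(2, 2, 2), c(4, 4, 4), is_unique = 0L),
    make_peptide_table("p2", "AAAAK", c(2, 2, 2), c(4, 4, 4), is_unique = 0L),
    make_peptide_table("p3", "EEEEK", c(2, NA, NA), c(4, 4, 4))
  )
  pr <- quantify_proteins(tbl, des)
  expect_setequal(as.character(pr$reg_class), "unquantified")
  expect_true(all(is.na(pr$ratio)))
})

test_that("classification respects thresholds, p-values, and is monotone in fc", {
  des <- fixture_design()
  # clear doubling with tight replicates: significant
  up <- make_peptide_table("p1", "AAAAK", c(100, 101, 99), c(200, 202, 198))
  dn <- make_peptide_table("p2", "CCCCK", c(200, 202, 198), c(100, 101, 99))
  flat <- make_peptide_table("p3", "DDDDK", c(100, 101, 99), c(101, 99, 100))
  pr <- quantify_proteins(dplyr::bind_rows(up, dn, flat), des)
  expect_equal(as.character(pr$reg_class), c("up", "down", "unchanged"))

  # raising the fold threshold can only demote up/down to unchanged
  for (fc in c(1.5, 2.5, 4)) {
    pr2 <- quantify_proteins(dplyr::bind_rows(up, dn, flat), des,
                             quant_config(fc_threshold = fc))
    demoted <- as.character(pr2$reg_class)
    was <- as.character(pr$reg_class)
    expect_true(all(demoted == was | (was %in% c("up", "down") & demoted == "unchanged")))
  }

  # ratio above threshold but no significance: unchanged under the default
  noisy <- make_peptide_table("p4", "FFFFK", c(50, 100, 200), c(80, 160, 300))
  prn <- quantify_proteins(noisy, des)
  expect_equal(as.character(prn$reg_class), "unchanged")
  # ratio-only reading calls it up
  prr <- quantify_proteins(noisy, des, quant_config(use_pvalue = FALSE))
  expect_equal(as.character(prr$reg_class), "up")
})

test_that("classes partition every protein at any configuration", {
  s <- generate_proteome(30, c(100, 200), seed = 21)
  pl <- plant_sites_and_motifs(s, 0.1, seed = 22)
  tr <- assign_effects(pl$proteins, pl$sites, seed = 23)
  peps <- digest_tryptic(pl$proteins)
  tabs <- simulate_intensities(pl$proteins, peps, pl$sites, tr,
                               missing_rate = 0.3, seed = 24)
  des <- fixture_design()
  pr <- quantify_proteins(mean_normalize(tabs$peptides, des), des)
  expect_true(all(!is.na(pr$reg_class)))
  expect_true(all(as.character(pr$reg_class) %in%
                    c("up", "down", "unchanged", "unquantified")))
})

test_that("site ratios are normalized by the protein ratio and classified on it", {
  des <- fixture_design()
  prot <- quantify_proteins(
    make_peptide_table("p1", "AAAAK", c(100, 101, 99), c(200, 202, 198)), des)
  expect_equal(prot$ratio, 2, tolerance = 1e-6)

  # raw site ratio 2 = protein ratio 2: protein-level artifact, unchanged
  st <- make_site_table("p1", 5L, c(50, 50.5, 49.5), c(100, 101, 99))
  sr <- quantify_sites(st, prot, des)
  expect_equal(sr$norm_ratio, 1, tolerance = 1e-4)
  expect_equal(as.character(sr$reg_class), "unchanged")

  # pure site effect on a flat protein
  prot2 <- quantify_proteins(
    make_peptide_table("p2", "CCCCK", c(100, 101, 99), c(100, 99, 101)), des)
  st2 <- make_site_table("p2", 7L, c(50, 50.5, 49.5), c(150, 151.5, 148.5))
  sr2 <- quantify_sites(st2, prot2, des)
  expect_equal(sr2$norm_ratio, 3, tolerance = 1e-2)
  expect_equal(as.character(sr2$reg_class), "up")
  expect_lt(sr2$p_value, 0.05)
})

test_that("the localization filter and lysine validation are enforced", {
  des <- fixture_design()
  prot <- quantify_proteins(
    make_peptide_table("p1", "AAAAK", c(100, 101, 99), c(100, 101, 99)), des)
  st <- dplyr::bind_rows(
    make_site_table("p1", 5L, c(50, 50, 50), c(100, 100, 100), loc = 0.74),
    make_site_table("p1", 5L, c(50, 50, 50), c(100, 100, 100), loc = 0.76)
  )
  sr <- quantify_sites(st, prot, des)
  expect_equal(nrow(sr), 1)

  proteins <- tibble::tibble(protein_id = "p1", sequence = "AAAAKAAAA")
  st_bad <- make_site_table("p1", 3L, c(1, 1, 1), c(1, 1, 1))
  expect_error(quantify_sites(st_bad, prot, des, proteins = proteins),
               "not a lysine")
})

test_that("sites of unquantified proteins fall back to the raw ratio with a flag", {
  des <- fixture_design()
  prot <- quantify_proteins(
    make_peptide_table("p1", "AAAAK", c(2, NA, NA), c(4, 4, 4)), des)
  st <- make_site_table("p1", 5L, c(50, 50.5, 49.5), c(150, 151.5, 148.5))
  sr <- quantify_sites(st, prot, des)
  expect_true(is.na(sr$norm_ratio))
  expect_equal(sr$norm_basis, "raw")
  expect_equal(as.character(sr$reg_class), "up")
})

test_that("ratios, p-values and classes are invariant to channel rescaling", {
  s <- generate_proteome(25, c(100, 200), seed = 31)
  pl <- plant_sites_and_motifs(s, 0.15, seed = 32)
  tr <- assign_effects(pl$proteins, pl$sites, seed = 33)
  peps <- digest_tryptic(pl$proteins)
  tabs <- simulate_intensities(pl$proteins, peps, pl$sites, tr, seed = 34)
  des <- fixture_design()

  scaled_p <- tabs$peptides
  scaled_p[["T-02"]] <- scaled_p[["T-02"]] * 7.3
  pr1 <- quantify_proteins(mean_normalize(tabs$peptides, des), des)
  pr2 <- quantify_proteins(mean_normalize(scaled_p, des), des)
  expect_equal(pr1$ratio, pr2$ratio, tolerance = 1e-9)
  expect_equal(pr1$p_value, pr2$p_value, tolerance = 1e-9)
  expect_identical(as.character(pr1$reg_class), as.character(pr2$reg_class))
})

test_that("norm_ratio times protein ratio recovers the raw ratio exactly", {
  s <- generate_proteome(40, c(100, 200), seed = 41)
  pl <- plant_sites_and_motifs(s, 0.2, seed = 42)
  tr <- assign_effects(pl$proteins, pl$sites, seed = 43)
  peps <- digest_tryptic(pl$proteins)
  tabs <- simulate_intensities(pl$proteins, peps, pl$sites, tr, seed = 44)
  des <- fixture_design()
  pr <- quantify_proteins(mean_normalize(tabs$peptides, des), des)
  sr <- quantify_sites(mean_normalize(tabs$sites, des), pr, des)
  prat <- pr$ratio[match(sr$protein_id, pr$protein_id)]
  ok <- !is.na(sr$norm_ratio) & !is.na(prat)
  expect_gt(sum(ok), 10)
  rel_err <- abs(sr$norm_ratio[ok] * prat[ok] - sr$raw_ratio[ok]) / sr$raw_ratio[ok]
  expect_true(all(rel_err < 1e-9))
})
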