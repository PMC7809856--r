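null_truth <- function(proteins, sites) {
  ground_truth(
    tibble::tibble(protein_id = proteins$protein_id, log2_effect = 0),
    tibble::tibble(protein_id = sites$protein_id, position = sites$position,
                   log2_site_effect = 0)
  )
}

setup_sim <- function(n = 20, site_fraction = 0.1, seed = 1) {
  p <- generate_proteome(n, c(100, 200), seed = seed)
  pl <- plant_sites_and_motifs(p, site_fraction, seed = seed + 1)
  peps <- digest_tryptic(pl$proteins)
  list(proteins = pl$proteins, sites = pl$sites, peptides = peps)
}

test_that("the noiseless null gives unit T/CK ratios everywhere", {
  s <- setup_sim()
  tr <- null_truth(s$proteins, s$sites)
  tabs <- simulate_intensities(s$proteins, s$peptides, s$sites, tr,
                               noise_sd = 1e-9, missing_rate = 0, seed = 2)
  ck <- as.matrix(tabs$peptides[, c("CK-01", "CK-02", "CK-03")])
  tt <- as.matrix(tabs$peptides[, c("T-01", "T-02", "T-03")])
  expect_equal(rowMeans(tt) / rowMeans(ck), rep(1, nrow(ck)), tolerance = 1e-6)
})

test_that("a +1 log2 protein effect doubles peptide and raw site ratios", {
  s <- setup_sim()
  tr <- null_truth(s$proteins, s$sites)
  tr$protein_effects$log2_effect <- 1
  tabs <- simulate_intensities(s$proteins, s$peptides, s$sites, tr,
                               noise_sd = 1e-9, missing_rate = 0, seed = 3)
  for (tab in tabs) {
    ck <- as.matrix(tab[, c("CK-01", "CK-02", "CK-03")])
    tt <- as.matrix(tab[, c("T-01", "T-02", "T-03")])
    expect_equal(rowMeans(tt) / rowMeans(ck), rep(2, nrow(ck)), tolerance = 1e-6)
  }
})

test_that("site effects add to protein effects on site rows only", {
  s <- setup_sim()
  tr <- null_truth(s$proteins, s$sites)
  tr$site_effects$log2_site_effect <- 1.5
  tabs <- simulate_intensities(s$proteins, s$peptides, s$sites, tr,
                               noise_sd = 1e-9, missing_rate = 0, seed = 4)
  ck <- as.matrix(tabs$sites[, c("CK-01", "CK-02", "CK-03")])
  tt <- as.matrix(tabs$sites[, c("T-01", "T-02", "T-03")])
  expect_equal(rowMeans(tt) / rowMeans(ck), rep(2^1.5, nrow(ck)), tolerance = 1e-6)
})

test_that("null log2 ratio spread matches the closed-form replicate-mean sd", {
  p <- generate_proteome(300, c(100, 200), seed = 11)
  pl <- plant_sites_and_motifs(p, 0, seed = 1)
  peps <- digest_tryptic(pl$proteins)
  tr <- null_truth(p, pl$sites)
  noise <- 0.25
  tabs <- simulate_intensities(p, peps, pl$sites, tr, noise_sd = noise,
                               missing_rate = 0, seed = 11)
  ck <- as.matrix(tabs$peptides[, c("CK-01", "CK-02", "CK-03")])
  tt <- as.matrix(tabs$peptides[, c("T-01", "T-02", "T-03")])
  lr <- log2(rowMeans(tt) / rowMeans(ck))
  # difference of two 3-replicate means on the log2 scale: sd = noise * sqrt(2/3)
  expect_lt(abs(sd(lr) - noise * sqrt(2 / 3)) / (noise * sqrt(2 / 3)), 0.1)
})

test_that("simulation is deterministic and respects missingness and the design", {
  s <- setup_sim()
  tr <- null_truth(s$proteins, s$sites)
  t1 <- simulate_intensities(s$proteins, s$peptides, s$sites, tr,
                             missing_rate = 0.2, seed = 5)
  t2 <- simulate_intensities(s$proteins, s$peptides, s$sites, tr,
                             missing_rate = 0.2, seed = 5)
  expect_identical(t1, t2)
  ck <- as.matrix(t1$peptides[, c("CK-01", "CK-02", "CK-03")])
  miss <- mean(is.na(ck))
  expect_gt(miss, 0.1)
  expect_lt(miss, 0.3)

  bad_design <- structure(list(channel_labels = c("a", "b"),
                               group_of = c(a = "CK", b = "T")),
                          class = "kcr_design")
  expect_error(channel_design(letters[1:6], rep("CK", 6)), "3 CK and 3 T")
  expect_error(simulate_intensities(s$proteins, s$peptides, s$sites, tr,
                                    design = unclass(bad_design), seed = 1),
               "channel_design")
})

test_that("localization probabilities straddle the 0.75 filter", {
  s <- setup_sim(n = 60, site_fraction = 0.3)
  tr <- null_truth(s$proteins, s$sites)
  tabs <- simulate_intensities(s$proteins, s$peptides, s$sites, tr, seed = 6)
  lp <- tabs$sites$localization_prob
  expect_gt(sum(lp > 0.75), 0)
  expect_gt(sum(lp <= 0.75), 0)
  expect_true(all(lp >= 0 & lp <= 1))
})
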