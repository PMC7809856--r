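test_that("binomial upper tail matches direct summation and handles boundaries", {
  expect_equal(binomial_upper_tail(0, 10, 0.3), 1)
  expect_equal(binomial_upper_tail(20, 20, 1), 1)
  # exhaustive summation oracle
  direct <- sum(dbinom(5:20, 20, 0.1))
  expect_equal(binomial_upper_tail(5, 20, 0.1), direct, tolerance = 1e-12)
  for (case in list(c(3, 8, 0.5), c(7, 7, 0.2), c(1, 50, 0.01))) {
    expect_equal(binomial_upper_tail(case[1], case[2], case[3]),
                 sum(dbinom(case[1]:case[2], case[2], case[3])),
                 tolerance = 1e-12)
  }
  expect_error(binomial_upper_tail(5, 3, 0.5), "k <= n")
  expect_error(binomial_upper_tail(1, 3, 1.5), "\\[0, 1\\]")
})

test_that("a null foreground drawn from the background yields no motifs", {
  bg <- random_windows(800, seed = 71)
  fg <- bg[seq(1, 800, by = 4)]
  m <- find_motifs(fg, bg, min_occurrences = 10)
  expect_equal(nrow(m), 0)
})

test_that("a planted single-constraint motif is found first and matches the brute-force scan", {
  withr::with_seed(72, {
    bg <- random_windows(2000, seed = 73)
    fg <- random_windows(100, seed = 74)
    # plant D at +1 in 60 of 100 foreground windows
    idx <- sample(100, 60)
    substr(fg[idx], 12, 12) <- "D"
  })
  m <- find_motifs(fg, bg, min_occurrences = 20)
  expect_gte(nrow(m), 1)
  cons <- m$constraints[[1]]
  expect_equal(cons$offset, 1L)
  expect_equal(cons$residue, "D")
  # the first accepted constraint is the argmin of the brute-force p table
  scan <- oracle_motif_scan(fg, bg)
  best <- scan[which.min(scan$p), ]
  expect_equal(cons$offset, best$offset)
  expect_equal(cons$residue, best$residue)
  expect_gt(m$fold_increase[1], 1)
  expect_true(all(m$step_pvalues[[1]] <= 1e-6))
})

test_that("emitted motifs satisfy the count thresholds and consume disjoint windows", {
  p <- generate_proteome(250, c(200, 400), seed = 75)
  specs <- list(motif_spec(c(-1, 1), c("F", "E"), 0.25),
                motif_spec(1, "K", 0.25))
  pl <- plant_sites_and_motifs(p, 0.12, specs, seed = 76)
  fg <- extract_windows(pl$proteins, pl$sites)$window
  bg <- background_windows(pl$proteins)$window
  m <- find_motifs(fg, bg)
  expect_gte(nrow(m), 2)
  expect_true(all(m$fg_matches >= 20))
  expect_true(all(vapply(m$step_pvalues, max, numeric(1)) <= 1e-6))
  # planted FKcrE recovered with exactly those constraints
  fke <- m[m$name == "FKcrE", ]
  expect_equal(nrow(fke), 1)
  expect_equal(fke$constraints[[1]]$offset, c(-1L, 1L))
  expect_equal(fke$constraints[[1]]$residue, c("F", "E"))
  # consumed foreground sets are disjoint across motifs
  expect_lte(sum(m$fg_consumed), length(fg))
  expect_true(all(m$fg_consumed >= 1))
})

test_that("window order does not change the motif output", {
  p <- generate_proteome(150, c(200, 300), seed = 77)
  pl <- plant_sites_and_motifs(p, 0.1, list(motif_spec(1, "D", 0.5)), seed = 78)
  fg <- extract_windows(pl$proteins, pl$sites)$window
  bg <- background_windows(pl$proteins)$window
  m1 <- find_motifs(fg, bg, min_occurrences = 10)
  withr::with_seed(79, {
    m2 <- find_motifs(sample(fg), sample(bg), min_occurrences = 10)
  })
  expect_equal(m1$name, m2$name)
  expect_equal(m1$fg_matches, m2$fg_matches)
  expect_equal(m1$fold_increase, m2$fold_increase)
})

test_that("mixed window lengths are rejected", {
  expect_error(find_motifs(c("AKA", "AAKAA"), c("AKA")), "mixed lengths")
})

test_that("the enrichment matrix matches an independent recount and flags undefined cells", {
  fg <- random_windows(200, seed = 81)
  bg <- random_windows(1000, seed = 82)
  em <- tidy(enrichment_matrix(fg, bg))
  # identity case: all defined cells are zero
  em0 <- tidy(enrichment_matrix(fg, fg))
  expect_true(all(abs(em0$log2_odds[!is.na(em0$log2_odds)]) < 1e-12))
  # recount oracle on a handful of cells
  for (cell in list(list(o = -3, r = "A"), list(o = 5, r = "W"), list(o = 1, r = "K"))) {
    col <- cell$o + 11
    fgc <- sum(substring(fg, col, col) == cell$r)
    bgc <- sum(substring(bg, col, col) == cell$r)
    expected <- log2((fgc + 0.5) / (length(fg) + 10)) - log2((bgc + 0.5) / (length(bg) + 10))
    got <- em$log2_odds[em$offset == cell$o & em$residue == cell$r]
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # center column undefined
  expect_true(all(is.na(em$log2_odds[em$offset == 0])))
})

test_that("a residue forced at one offset is the matrix maximum there", {
  fg <- random_windows(100, seed = 83)
  substr(fg, 12, 12) <- "E"
  bg <- random_windows(2000, seed = 84)
  em <- tidy(enrichment_matrix(fg, bg))
  em_def <- em[!is.na(em$log2_odds), ]
  top <- em_def[which.max(em_def$log2_odds), ]
  expect_equal(top$offset, 1)
  expect_equal(top$residue, "E")
})
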