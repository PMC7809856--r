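# Small shared fixtures, built in code.

fixture_design <- function() channel_design()

# a tiny peptide table with known intensities: one row per peptide
make_peptide_table <- function(protein_id, peptide_seq, ck, t, is_unique = 1L) {
  stopifnot(length(ck) == 3, length(t) == 3)
  tibble::tibble(
    peptide_seq = peptide_seq, protein_id = protein_id, is_unique = is_unique,
    `CK-01` = ck[1], `CK-02` = ck[2], `CK-03` = ck[3],
    `T-01` = t[1], `T-02` = t[2], `T-03` = t[3]
  )
}

make_site_table <- function(protein_id, position, ck, t, loc = 0.99) {
  tibble::tibble(
    protein_id = protein_id, position = position,
    window = NA_character_, localization_prob = loc,
    `CK-01` = ck[1], `CK-02` = ck[2], `CK-03` = ck[3],
    `T-01` = t[1], `T-02` = t[2], `T-03` = t[3]
  )
}

# deterministic random window sets over the standard alphabet
random_windows <- function(n, width = 21, seed = 1, center = "K") {
  AA <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      w <- sample(AA, width, replace = TRUE)
      w[(width + 1) %/% 2] <- center
      paste(w, collapse = "")
    }, character(1))
  })
}
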