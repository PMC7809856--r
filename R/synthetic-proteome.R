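#' Generate a synthetic proteome
#'
#' Draws protein sequences with independent residues from a fixed composition,
#' emulating the protein database a search engine would be run against.
#' Lengths are uniform over `length_range`. Fully deterministic for a fixed
#' seed.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer vector of length 2, residue-count interval
#'   within `[30, 5000]`.
#' @param residue_frequencies Named 20-vector of residue probabilities
#'   summing to 1; defaults to [aa_frequencies()].
#' @param seed Integer seed.
#' @return A tibble with columns `protein_id`, `sequence`, `description`.
#' @export
#' @examples
#' generate_proteome(3, c(50, 80), seed = 1)
generate_proteome <- function(n_proteins,
                              length_range = c(100, 600),
                              residue_frequencies = aa_frequencies(),
                              seed = 1L) {
  stopifnot(length(n_proteins) == 1, n_proteins >= 1)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 30 || length_range[2] > 5000) {
    abort("`length_range` must be an interval within [30, 5000].")
  }
  freq <- check_residue_frequencies(residue_frequencies)
  with_seed(as.integer(seed), {
    # sample.int avoids sample()'s scalar expansion when the range is one value
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste(sample(AA20, l, replace = TRUE, prob = freq), collapse = "")
    }, character(1))
    tibble(
      protein_id = sprintf("P%05d", seq_len(n_proteins)),
      sequence = seqs,
      description = sprintf("synthetic protein %d (len %d)", seq_len(n_proteins), lens)
    )
  })
}

#' In silico tryptic digestion
#'
#' Cleaves each protein C-terminal to K or R except when the next residue is
#' proline, then drops peptides outside `[min_len, max_len]`. Before the
#' length filter, the peptides of a protein tile its sequence exactly.
#'
#' @param proteins Data frame with `protein_id` and `sequence`.
#' @param min_len,max_len Retained peptide length bounds; the search-engine
#'   style default keeps peptides of 7-45 residues.
#' @return A tibble with `protein_id`, `peptide`, `start`, `end` (1-based,
#'   inclusive residue coordinates).
#' @export
#' @examples
#' digest_tryptic(tibble::tibble(protein_id = "p", sequence = "AAAKGGGRCCC"),
#'                min_len = 1, max_len = 99)
digest_tryptic <- function(proteins, min_len = 7L, max_len = 45L) {
  check_protein_df(proteins)
  if (!(min_len >= 1 && min_len <= max_len)) {
    abort("need 1 <= min_len <= max_len.")
  }
  out <- map2(proteins$protein_id, proteins$sequence, function(id, seq) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(chars)
    nxt <- c(chars[-1], "")
    cut_after <- which(chars %in% c("K", "R") & nxt != "P" & seq_len(n) < n)
    starts <- c(1L, cut_after + 1L)
    ends <- c(cut_after, n)
    tibble(
      protein_id = id,
      peptide = substring(seq, starts, ends),
      start = starts,
      end = ends
    )
  })
  res <- list_rbind(out)
  len <- nchar(res$peptide)
  res[len >= min_len & len <= max_len, ]
}
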