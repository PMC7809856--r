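#' Extract flanking-sequence windows around modified lysines
#'
#' Returns, for each site, the `2 * flank + 1`-mer centered on the modified
#' lysine, padded with `pad` where the protein terminus truncates the flank.
#' With the default flank of 10 the window is a 21-mer with the K at
#' position 11.
#'
#' @param proteins Tibble `protein_id`, `sequence`.
#' @param sites Tibble `protein_id`, `position` (1-based; must be a K).
#' @param flank Number of residues on each side.
#' @param pad Single padding character.
#' @return A tibble `protein_id`, `position`, `window`.
#' @export
#' @examples
#' p <- tibble::tibble(protein_id = "p", sequence = "AAAAKCCCCC")
#' extract_windows(p, tibble::tibble(protein_id = "p", position = 5))
extract_windows <- function(proteins, sites, flank = 10L, pad = "_") {
  check_protein_df(proteins)
  stopifnot(nchar(pad) == 1, flank >= 1)
  idx <- match(sites$protein_id, proteins$protein_id)
  if (anyNA(idx)) {
    abort(sprintf("sites refer to unknown proteins: %s",
                  paste(unique(sites$protein_id[is.na(idx)]), collapse = ", ")))
  }
  seqs <- proteins$sequence[idx]
  len <- nchar(seqs)
  pos <- sites$position
  bad <- pos < 1 | pos > len | substring(seqs, pos, pos) != "K"
  if (any(bad)) {
    abort(sprintf("site position is not a lysine of its protein: %s",
                  paste(sprintf("%s:%d", sites$protein_id[bad], pos[bad])[
                    seq_len(min(5, sum(bad)))], collapse = ", ")))
  }
  padded <- paste0(strrep(pad, flank), seqs, strrep(pad, flank))
  win <- substring(padded, pos, pos + 2L * flank)  # pos in padded coords = pos - 1 + flank + 1
  tibble(protein_id = sites$protein_id, position = pos, window = win)
}

#' Windows around every occurrence of a residue (motif background)
#'
#' One window per occurrence of `residue` in every protein of the database,
#' with the same length and padding rules as [extract_windows()]. This is
#' the background set of the motif search: all lysines of the searched
#' database, not just the modified ones.
#'
#' @inheritParams extract_windows
#' @param residue Central residue, default `"K"`.
#' @return A tibble `protein_id`, `position`, `window`.
#' @export
background_windows <- function(proteins, residue = "K", flank = 10L, pad = "_") {
  check_protein_df(proteins)
  hits <- str_locate_all(proteins$sequence, stringr::fixed(residue))
  sites <- list_rbind(imap(hits, function(m, i) {
    tibble(protein_id = proteins$protein_id[i], position = m[, 1])
  }))
  if (nrow(sites) == 0) {
    return(tibble(protein_id = character(), position = integer(), window = character()))
  }
  extract_windows(proteins, sites, flank = flank, pad = pad)
}
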