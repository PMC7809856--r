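#' Count conserved lysines in a global ortholog alignment
#'
#' Maps every lysine of the query through the alignment and calls it
#' conserved when the aligned subject column is also a lysine (a gap is not
#' conserved). Lysines are partitioned into crotonylated (`kcr_positions`)
#' and control (all other query lysines).
#'
#' @param alignment A global [align_pair()] result for the pair.
#' @param kcr_positions Integer positions (1-based, in the unaligned query)
#'   of crotonylated lysines; each must be a K of the query.
#' @return A one-row tibble `kcr_conserved`, `kcr_total`, `ctrl_conserved`,
#'   `ctrl_total`.
#' @export
count_conservation <- function(alignment, kcr_positions) {
  stopifnot(inherits(alignment, "kcr_alignment"), alignment$mode == "global")
  pat <- strsplit(alignment$pattern, "", fixed = TRUE)[[1]]
  sub <- strsplit(alignment$subject, "", fixed = TRUE)[[1]]
  non_gap <- pat != "-"
  # alignment column of each query residue
  col_of <- which(non_gap)
  query_chars <- pat[non_gap]
  kpos <- which(query_chars == "K")
  if (!all(kcr_positions %in% kpos)) {
    abort("kcr_positions must all be lysines of the query sequence.")
  }
  conserved <- sub[col_of[kpos]] == "K"
  is_kcr <- kpos %in% kcr_positions
  tibble(
    kcr_conserved = sum(conserved[is_kcr]),
    kcr_total = sum(is_kcr),
    ctrl_conserved = sum(conserved[!is_kcr]),
    ctrl_total = sum(!is_kcr)
  )
}

#' Cross-species conservation of crotonylated lysines
#'
#' For each species: finds reciprocal-best-hit orthologs of the query
#' proteome, aligns each ortholog pair globally, counts conserved
#' crotonylated and control lysines across all pairs, and tests the
#' difference in conservation between the two classes with a two-tailed
#' Fisher exact test.
#'
#' @param query_proteins Query proteome tibble (`protein_id`, `sequence`).
#' @param subject_proteins Tibble with a `species` column plus
#'   `protein_id`, `sequence` (e.g. `generate_orthologs()$orthologs`).
#' @param sites Tibble `protein_id`, `position` of crotonylated lysines of
#'   the query proteome.
#' @param scheme A [scoring_scheme()].
#' @param score_min Minimum RBH score, see [find_rbh()].
#' @return A tibble of class `kcr_conservation`, one row per species:
#'   `species`, `n_orthologs`, `kcr_conserved`, `kcr_total`,
#'   `ctrl_conserved`, `ctrl_total`, `kcr_pct`, `ctrl_pct`, `fisher_p`.
#'   The per-pair ortholog table is attached as attribute `"orthologs"`.
#' @export
conserve_species <- function(query_proteins, subject_proteins, sites,
                             scheme = scoring_scheme(), score_min = 50) {
  check_protein_df(query_proteins, "query_proteins")
  if (!"species" %in% names(subject_proteins)) {
    abort("`subject_proteins` needs a `species` column.")
  }
  res <- list()
  orth_all <- list()
  for (sp in unique(subject_proteins$species)) {
    db <- subject_proteins[subject_proteins$species == sp,
                           c("protein_id", "sequence"), drop = FALSE]
    pairs <- find_rbh(query_proteins, db, scheme, score_min)
    orth_all[[sp]] <- mutate(pairs, species = sp, .before = 1)
    counts <- tibble(kcr_conserved = 0L, kcr_total = 0L,
                     ctrl_conserved = 0L, ctrl_total = 0L)
    for (i in seq_len(nrow(pairs))) {
      qseq <- query_proteins$sequence[query_proteins$protein_id == pairs$query_id[i]]
      sseq <- db$sequence[db$protein_id == pairs$subject_id[i]]
      aln <- align_pair(qseq, sseq, scheme, mode = "global")
      kcr_pos <- sites$position[sites$protein_id == pairs$query_id[i]]
      cc <- count_conservation(aln, kcr_pos)
      counts <- tibble(kcr_conserved = counts$kcr_conserved + cc$kcr_conserved,
                       kcr_total = counts$kcr_total + cc$kcr_total,
                       ctrl_conserved = counts$ctrl_conserved + cc$ctrl_conserved,
                       ctrl_total = counts$ctrl_total + cc$ctrl_total)
    }
    p <- fisher_two_tailed(matrix(c(
      counts$kcr_conserved, counts$kcr_total - counts$kcr_conserved,
      counts$ctrl_conserved, counts$ctrl_total - counts$ctrl_conserved
    ), nrow = 2, byrow = TRUE))
    res[[sp]] <- tibble(
      species = sp,
      n_orthologs = nrow(pairs),
      counts,
      kcr_pct = 100 * counts$kcr_conserved / counts$kcr_total,
      ctrl_pct = 100 * counts$ctrl_conserved / counts$ctrl_total,
      fisher_p = p
    )
  }
  out <- new_kcr_result(list_rbind(res), "kcr_conservation")
  attr(out, "orthologs") <- list_rbind(orth_all)
  out
}
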