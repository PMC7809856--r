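#' Simulate ortholog proteomes with controlled lysine conservation
#'
#' Each ortholog is derived from its source protein by independent residue
#' substitution, with lysines treated specially: a crotonylated lysine is
#' retained with probability `kcr_keep` and any other lysine with probability
#' `control_keep`; a lysine that is not retained, and any substituted
#' non-lysine residue, is replaced by a residue that is never K, so the
#' recorded retention draws are exactly the conservation ground truth. No
#' insertions or deletions are introduced.
#'
#' @param proteins Source proteome tibble (`protein_id`, `sequence`).
#' @param species_names Character vector of species to derive.
#' @param substitution_rate Per-residue substitution probability for
#'   non-lysine residues, in `[0, 1]`.
#' @param kcr_sites Tibble `protein_id`, `position` of crotonylated lysines.
#' @param kcr_keep,control_keep Retention probabilities for crotonylated and
#'   control lysines, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `orthologs` (tibble `species`, `protein_id` of the
#'   ortholog, `source_id`, `sequence`, `description`) and `truth` (tibble
#'   `species`, `protein_id`, `position`, `is_kcr`, `retained` recording
#'   every lysine retention draw).
#' @export
generate_orthologs <- function(proteins, species_names, substitution_rate,
                               kcr_sites, kcr_keep, control_keep, seed = 1L) {
  check_protein_df(proteins)
  rates <- c(substitution_rate, kcr_keep, control_keep)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1].")
  non_k <- setdiff(AA20, "K")
  kcr_key <- paste(kcr_sites$protein_id, kcr_sites$position)

  with_seed(as.integer(seed), {
    orths <- list()
    truths <- list()
    for (sp in species_names) {
      seqs <- character(nrow(proteins))
      tr <- vector("list", nrow(proteins))
      for (i in seq_len(nrow(proteins))) {
        chars <- strsplit(proteins$sequence[i], "", fixed = TRUE)[[1]]
        kpos <- which(chars == "K")
        is_kcr <- paste(proteins$protein_id[i], kpos) %in% kcr_key
        keep_p <- ifelse(is_kcr, kcr_keep, control_keep)
        retained <- runif(length(kpos)) < keep_p
        lost <- kpos[!retained]
        if (length(lost)) chars[lost] <- sample(non_k, length(lost), replace = TRUE)
        other <- which(!(seq_along(chars) %in% kpos))
        sub_idx <- other[runif(length(other)) < substitution_rate]
        if (length(sub_idx)) {
          # replace with a residue different from the original and never K
          chars[sub_idx] <- vapply(chars[sub_idx], function(r) {
            sample(setdiff(non_k, r), 1)
          }, character(1))
        }
        seqs[i] <- paste(chars, collapse = "")
        if (length(kpos)) {
          tr[[i]] <- tibble(species = sp, protein_id = proteins$protein_id[i],
                            position = kpos, is_kcr = is_kcr, retained = retained)
        }
      }
      orths[[sp]] <- tibble(
        species = sp,
        protein_id = paste(sp, proteins$protein_id, sep = "_"),
        source_id = proteins$protein_id,
        sequence = seqs,
        description = sprintf("%s ortholog of %s", sp, proteins$protein_id)
      )
      truths[[sp]] <- list_rbind(tr[!vapply(tr, is.null, logical(1))])
    }
    list(orthologs = list_rbind(orths), truth = list_rbind(truths))
  })
}
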