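#' Protein alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties used for both local
#' (hit-ranking) and global (conservation-counting) alignment. A gap of
#' length L costs `gap_open + L * gap_extend`, the BLAST convention.
#'
#' @param substitution_matrix A symmetric 20x20 (or larger) integer scoring
#'   matrix; default BLOSUM62.
#' @param gap_open,gap_extend Positive penalty magnitudes (defaults 11 and 1).
#' @return A list of class `kcr_scoring`.
#' @export
#' @examples
#' scoring_scheme()$gap_open
scoring_scheme <- function(substitution_matrix = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(substitution_matrix)) {
    substitution_matrix <- blosum62_matrix()
  }
  if (!isSymmetric(unname(substitution_matrix))) {
    abort("`substitution_matrix` must be symmetric.")
  }
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive magnitudes.")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "kcr_scoring")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Pairwise protein alignment with affine gaps
#'
#' Exact dynamic-programming alignment: Smith-Waterman in `local` mode
#' (used to rank candidate ortholog hits, in place of a heuristic BLASTP
#' search) and Needleman-Wunsch in `global` mode (used to map lysine
#' positions between an ortholog pair).
#'
#' @param a,b Amino-acid sequences (non-empty strings over the 20 standard
#'   residues).
#' @param scheme A [scoring_scheme()].
#' @param mode `"global"` or `"local"`.
#' @return A list of class `kcr_alignment`: `score`, `pattern` and
#'   `subject` (aligned strings with `-` gaps), `mode`.
#' @export
align_pair <- function(a, b, scheme = scoring_scheme(), mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty.")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = mode
  )
  structure(
    list(score = Biostrings::score(pa),
         pattern = as.character(Biostrings::alignedPattern(pa)),
         subject = as.character(Biostrings::alignedSubject(pa)),
         mode = mode),
    class = "kcr_alignment"
  )
}

local_score_many <- function(patterns, subject, scheme) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "local", scoreOnly = TRUE
  )
}

#' Reciprocal-best-hit ortholog detection
#'
#' Scores every query against every subject with local alignment and keeps
#' pairs in which each protein is the other's best-scoring hit. Ties on the
#' best score are broken by lexicographic id (and reported via a message);
#' pairs below `score_min` are dropped to avoid spurious matches between
#' unrelated short proteins.
#'
#' @param query_db,subject_db Proteome tibbles (`protein_id`, `sequence`).
#' @param scheme A [scoring_scheme()].
#' @param score_min Minimum forward local score for a pair to be kept.
#' @return A tibble `query_id`, `subject_id`, `forward_score`,
#'   `reverse_score`.
#' @export
find_rbh <- function(query_db, subject_db, scheme = scoring_scheme(),
                     score_min = 50) {
  check_protein_df(query_db, "query_db")
  check_protein_df(subject_db, "subject_db")
  if (nrow(query_db) == 0 || nrow(subject_db) == 0) abort("empty database.")

  best_hit <- function(db_seqs, db_ids, target_seq) {
    sc <- local_score_many(db_seqs, target_seq, scheme)
    top <- max(sc)
    cand <- db_ids[sc == top]
    if (length(cand) > 1) {
      message(sprintf("best-hit tie broken lexicographically among: %s",
                      paste(sort(cand), collapse = ", ")))
    }
    list(id = sort(cand)[1], score = top)
  }

  fwd <- map(seq_len(nrow(query_db)), function(i) {
    best_hit(subject_db$sequence, subject_db$protein_id, query_db$sequence[i])
  })
  rev <- map(seq_len(nrow(subject_db)), function(j) {
    best_hit(query_db$sequence, query_db$protein_id, subject_db$sequence[j])
  })
  rev_best <- setNames(map_chr(rev, "id"), subject_db$protein_id)
  rev_score <- setNames(map_dbl(rev, "score"), subject_db$protein_id)

  rows <- list()
  for (i in seq_len(nrow(query_db))) {
    qid <- query_db$protein_id[i]
    sid <- fwd[[i]]$id
    if (fwd[[i]]$score >= score_min && rev_best[[sid]] == qid) {
      rows[[length(rows) + 1L]] <- tibble(
        query_id = qid, subject_id = sid,
        forward_score = fwd[[i]]$score, reverse_score = rev_score[[sid]]
      )
    }
  }
  if (length(rows)) list_rbind(rows) else
    tibble(query_id = character(), subject_id = character(),
           forward_score = numeric(), reverse_score = numeric())
}
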