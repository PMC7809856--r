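#' Read a protein-term annotation map
#'
#' Tab-separated file with columns `protein_id`, `term_id` and optional
#' `namespace`, `label`. Terms annotating no protein are rejected (they
#' cannot arise from a well-formed map and usually indicate a join error
#' upstream).
#'
#' @param path Path to the TSV.
#' @return A tibble `protein_id`, `term_id`, `namespace`, `label`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("protein_id", "term_id") %in% names(ann))) {
    abort("annotation file needs columns protein_id and term_id.")
  }
  if (!"namespace" %in% names(ann)) ann$namespace <- NA_character_
  if (!"label" %in% names(ann)) ann$label <- NA_character_
  if (any(is.na(ann$protein_id) | is.na(ann$term_id))) {
    abort("annotation rows with missing protein_id/term_id.")
  }
  as_tibble(ann[, c("protein_id", "term_id", "namespace", "label")])
}

#' Fisher exact term enrichment of a differential protein set
#'
#' For each term, tests over-/under-representation of the term among the
#' differential proteins relative to the identified background with the
#' two-tailed Fisher exact test, then corrects across terms
#' (Benjamini-Hochberg by default).
#'
#' @param differential Character vector of differential protein ids; must
#'   be a subset of `background`.
#' @param background Character vector of identified protein ids.
#' @param annotations Annotation tibble (`protein_id`, `term_id`, optional
#'   `namespace`, `label`), e.g. from [read_annotations()].
#' @param q_threshold Significance threshold applied to the corrected
#'   p-value in the `significant` column.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return A tibble of class `kcr_enrichment` sorted by p-value: `term_id`,
#'   `namespace`, `label`, `k` (differential with term), `n` (differential
#'   total), `K` (background with term), `N` (background total), `fold`,
#'   `p`, `q`, `significant`.
#' @export
enrich <- function(differential, background, annotations, q_threshold = 0.05,
                   method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  differential <- unique(differential)
  background <- unique(background)
  extra <- setdiff(differential, background)
  if (length(extra)) {
    abort(sprintf("differential proteins outside the background: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  ann <- annotations[annotations$protein_id %in% background, , drop = FALSE]
  n <- length(differential)
  N <- length(background)
  by_term <- split(ann$protein_id, ann$term_id)
  meta <- ann[!duplicated(ann$term_id), c("term_id", "namespace", "label")]

  rows <- imap(by_term, function(prots, term) {
    prots <- unique(prots)
    K <- length(prots)
    k <- sum(differential %in% prots)
    p <- fisher_two_tailed(matrix(c(k, n - k, K - k, N - n - (K - k)),
                                  2, 2, byrow = TRUE))
    tibble(term_id = term, k = k, n = n, K = K, N = N,
           fold = (k / n) / (K / N), p = p)
  })
  out <- list_rbind(rows)
  out$q <- p.adjust(out$p, method = method)
  out$significant <- out$q < q_threshold
  out <- left_join(out, meta, by = "term_id")
  out <- out[order(out$p, out$term_id),
             c("term_id", "namespace", "label", "k", "n", "K", "N",
               "fold", "p", "q", "significant")]
  new_kcr_result(out, "kcr_enrichment")
}
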