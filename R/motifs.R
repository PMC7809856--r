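#' Binomial upper-tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, the significance kernel of the
#' iterative motif search. Computed through the stable regularized
#' incomplete-beta tail, so tiny tail probabilities keep full relative
#' accuracy.
#'
#' @param k Number of successes observed, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Success probability in `[0, 1]`.
#' @return `P(X >= k)`, a probability.
#' @export
#' @examples
#' binomial_upper_tail(5, 20, 0.1)
binomial_upper_tail <- function(k, n, p) {
  if (any(k < 0 | k > n | n < 0)) abort("need 0 <= k <= n.")
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  ifelse(k == 0, 1, pbinom(k - 1, n, p, lower.tail = FALSE))
}

win_matrix <- function(windows) {
  w <- unique(nchar(windows))
  if (length(w) != 1) abort("windows have mixed lengths.")
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = w, byrow = TRUE)
}

motif_name <- function(offsets, residues, flank = 10L) {
  ord <- order(offsets)
  offsets <- offsets[ord]; residues <- residues[ord]
  lo <- min(c(offsets, 0L)); hi <- max(c(offsets, 0L))
  out <- character(0)
  for (o in lo:hi) {
    out <- c(out, if (o == 0L) "Kcr"
             else if (o %in% offsets) residues[match(o, offsets)]
             else ".")
  }
  paste(out, collapse = "")
}

count_matches <- function(mat, cols, residues) {
  ok <- rep(TRUE, nrow(mat))
  for (j in seq_along(cols)) ok <- ok & mat[, cols[j]] == residues[j]
  ok
}

#' Iterative motif discovery around modified lysines (motif-x style)
#'
#' Greedily builds motifs from position-specific residue enrichments. At
#' each step, every unfixed `(offset, residue)` candidate is scored by the
#' binomial upper-tail probability of its foreground count given the
#' residue's frequency at that offset in the current background; the most
#' significant candidate passing `p_threshold` and `min_occurrences` is
#' fixed and both sets are reduced to the matching windows. When no
#' candidate passes, the motif is emitted, its foreground matches are
#' removed, the background is restored, and the search restarts. Reported
#' match counts and fold increase are computed against the original
#' foreground and background sets. Padding characters are excluded from
#' both numerator and denominator of positional frequencies. Ties on the
#' p-value are broken by smaller absolute offset, then negative before
#' positive offset, then alphabetical residue, so results do not depend on
#' window order.
#'
#' @param fg Character vector of foreground windows (equal odd length,
#'   central K), e.g. `extract_windows(...)$window`.
#' @param bg Character vector of background windows, e.g.
#'   `background_windows(...)$window`.
#' @param p_threshold Per-step binomial significance threshold.
#' @param min_occurrences Minimum foreground matches per step.
#' @param max_motifs Stop after this many motifs.
#' @param pad Padding character.
#' @return A tibble of class `kcr_motifs`, one row per motif: `name`,
#'   `constraints` (list column of tibbles `offset`, `residue`),
#'   `fg_matches`, `fg_total`, `bg_matches`, `bg_total`, `fold_increase`
#'   (all against the original input sets), `fg_consumed` (foreground
#'   windows removed when the motif was emitted; consumed sets are disjoint
#'   across motifs), `step_pvalues` (list column).
#' @export
find_motifs <- function(fg, bg, p_threshold = 1e-6, min_occurrences = 20L,
                        max_motifs = 50L, pad = "_") {
  if (length(fg) == 0) abort("foreground is empty.")
  fg_mat <- win_matrix(fg)
  bg_mat <- win_matrix(bg)
  if (ncol(fg_mat) != ncol(bg_mat)) abort("foreground/background window lengths differ.")
  w <- ncol(fg_mat)
  if (w %% 2 != 1) abort("windows must have odd length.")
  flank <- (w - 1L) %/% 2L
  center <- flank + 1L
  if (!all(fg_mat[, center] == fg_mat[1, center])) abort("mixed central residues.")

  offsets_all <- setdiff(seq_len(w) - center, 0L)
  fg_total <- nrow(fg_mat)
  bg_total <- nrow(bg_mat)

  fg_left <- rep(TRUE, fg_total)
  motifs <- list()

  repeat {
    cur_fg <- which(fg_left)
    cur_bg <- seq_len(bg_total)
    fixed <- tibble(offset = integer(), residue = character())
    step_p <- numeric(0)

    repeat {
      if (length(cur_fg) == 0) break
      best <- NULL
      for (o in offsets_all) {
        if (o %in% fixed$offset) next
        col <- o + center
        fg_col <- fg_mat[cur_fg, col]
        bg_col <- bg_mat[cur_bg, col]
        fg_col <- fg_col[fg_col != pad]
        bg_col <- bg_col[bg_col != pad]
        n_eff <- length(fg_col)
        bg_n <- length(bg_col)
        if (n_eff == 0 || bg_n == 0) next
        k_vec <- tabulate(factor(fg_col, levels = AA20), nbins = 20L)
        p0_vec <- tabulate(factor(bg_col, levels = AA20), nbins = 20L) / bg_n
        pv <- binomial_upper_tail(k_vec, n_eff, p0_vec)
        ok <- pv <= p_threshold & k_vec >= min_occurrences
        if (!any(ok)) next
        for (r in which(ok)) {
          cand <- list(offset = o, residue = AA20[r], p = pv[r], k = k_vec[r])
          if (is.null(best) || better_candidate(cand, best)) best <- cand
        }
      }
      if (is.null(best)) break
      col <- best$offset + center
      cur_fg <- cur_fg[fg_mat[cur_fg, col] == best$residue]
      cur_bg <- cur_bg[bg_mat[cur_bg, col] == best$residue]
      fixed <- bind_rows(fixed, tibble(offset = best$offset, residue = best$residue))
      step_p <- c(step_p, best$p)
    }

    if (nrow(fixed) == 0) break
    cols <- fixed$offset + center
    fg_match_all <- count_matches(fg_mat, cols, fixed$residue)
    bg_match_all <- count_matches(bg_mat, cols, fixed$residue)
    fgm <- sum(fg_match_all); bgm <- sum(bg_match_all)
    motifs[[length(motifs) + 1L]] <- tibble(
      name = motif_name(fixed$offset, fixed$residue),
      constraints = list(arrange(fixed, .data$offset)),
      fg_matches = fgm, fg_total = fg_total,
      bg_matches = bgm, bg_total = bg_total,
      fold_increase = (fgm / fg_total) / (bgm / bg_total),
      fg_consumed = length(cur_fg),
      step_pvalues = list(step_p)
    )
    fg_left[cur_fg] <- FALSE
    if (length(motifs) >= max_motifs || !any(fg_left)) break
  }

  out <- if (length(motifs)) list_rbind(motifs) else
    tibble(name = character(), constraints = list(), fg_matches = integer(),
           fg_total = integer(), bg_matches = integer(), bg_total = integer(),
           fold_increase = numeric(), fg_consumed = integer(),
           step_pvalues = list())
  new_kcr_result(out, "kcr_motifs")
}

# deterministic tie-break: p, then |offset|, then negative offset, then residue
better_candidate <- function(a, b) {
  if (a$p != b$p) return(a$p < b$p)
  if (abs(a$offset) != abs(b$offset)) return(abs(a$offset) < abs(b$offset))
  if (a$offset != b$offset) return(a$offset < b$offset)
  a$residue < b$residue
}

#' Position-by-residue enrichment matrix of motif windows
#'
#' Log2 odds of each residue at each flanking position in the foreground
#' relative to the background, with a symmetric pseudocount; the basis of
#' the residue-abundance intensity map. Padding characters are excluded
#' from the counts; cells for residues absent from both sets at a position,
#' and the central column, are undefined (`NA`).
#'
#' @inheritParams find_motifs
#' @param pseudocount Added to each residue count (and 20 times to each
#'   denominator).
#' @return A tibble of class `kcr_enrichment_matrix` with columns `offset`,
#'   `residue`, `log2_odds` (one row per position x residue).
#' @export
enrichment_matrix <- function(fg, bg, pseudocount = 0.5, pad = "_") {
  fg_mat <- win_matrix(fg)
  bg_mat <- win_matrix(bg)
  if (ncol(fg_mat) != ncol(bg_mat)) abort("foreground/background window lengths differ.")
  w <- ncol(fg_mat)
  center <- (w + 1L) %/% 2L
  rows <- list()
  for (col in seq_len(w)) {
    o <- col - center
    fg_col <- fg_mat[, col]; fg_col <- fg_col[fg_col != pad]
    bg_col <- bg_mat[, col]; bg_col <- bg_col[bg_col != pad]
    fgc <- tabulate(factor(fg_col, levels = AA20), nbins = 20L)
    bgc <- tabulate(factor(bg_col, levels = AA20), nbins = 20L)
    val <- log2((fgc + pseudocount) / (length(fg_col) + 20 * pseudocount)) -
      log2((bgc + pseudocount) / (length(bg_col) + 20 * pseudocount))
    val[fgc + bgc == 0] <- NA_real_
    if (o == 0L) val[] <- NA_real_
    rows[[col]] <- tibble(offset = o, residue = AA20, log2_odds = val)
  }
  new_kcr_result(list_rbind(rows), "kcr_enrichment_matrix")
}
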