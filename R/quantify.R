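#' Quantification configuration
#'
#' Thresholds and policies shared by protein and site quantification.
#'
#' @param fc_threshold Fold-change cutoff (> 1); a protein/site is up when
#'   its ratio exceeds this and down when it falls below its reciprocal.
#' @param alpha P-value cutoff in (0, 1).
#' @param loc_prob_min Site localization-probability cutoff; sites must
#'   exceed it (strictly) to be quantified.
#' @param min_values_per_group Minimum non-missing intensities per group for
#'   a peptide or site to contribute a ratio (default 2 of 3).
#' @param use_pvalue If `TRUE` (default) regulation calls require both the
#'   fold-change and the p-value condition; `FALSE` uses the ratio alone.
#' @param var_equal `FALSE` (default) for the Welch two-sample t-test,
#'   `TRUE` for pooled variance.
#' @return A list of class `kcr_config`.
#' @export
#' @examples
#' quant_config()
quant_config <- function(fc_threshold = 1.2, alpha = 0.05, loc_prob_min = 0.75,
                         min_values_per_group = 2L, use_pvalue = TRUE,
                         var_equal = FALSE) {
  if (fc_threshold <= 1) abort("`fc_threshold` must exceed 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (loc_prob_min < 0 || loc_prob_min > 1) abort("`loc_prob_min` must lie in [0, 1].")
  structure(
    list(fc_threshold = fc_threshold, alpha = alpha, loc_prob_min = loc_prob_min,
         min_values_per_group = as.integer(min_values_per_group),
         use_pvalue = isTRUE(use_pvalue), var_equal = isTRUE(var_equal)),
    class = "kcr_config"
  )
}

#' Mean-normalize reporter intensities across channels
#'
#' Rescales each channel multiplicatively so that its mean over non-missing
#' rows equals the grand mean of the per-channel means before normalization,
#' centering the distribution of quantitative values. Missing cells stay
#' missing; non-channel columns pass through untouched.
#'
#' @param tbl Peptide or site intensity table containing one column per
#'   channel of `design`.
#' @param design A [channel_design()].
#' @return The table with normalized channel columns.
#' @export
mean_normalize <- function(tbl, design) {
  chan <- design$channel_labels
  missing_cols <- setdiff(chan, names(tbl))
  if (length(missing_cols)) {
    abort(sprintf("table lacks channel column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  means <- vapply(chan, function(cn) mean(tbl[[cn]], na.rm = TRUE), numeric(1))
  all_missing <- chan[is.nan(means) | is.na(means)]
  if (length(all_missing)) {
    abort(sprintf("channel(s) entirely missing: %s", paste(all_missing, collapse = ", ")))
  }
  grand <- mean(means)
  for (cn in chan) tbl[[cn]] <- tbl[[cn]] * (grand / means[[cn]])
  tbl
}

welch_log2_p <- function(t_vals, ck_vals, var_equal = FALSE) {
  t_vals <- t_vals[!is.na(t_vals) & t_vals > 0]
  ck_vals <- ck_vals[!is.na(ck_vals) & ck_vals > 0]
  if (length(t_vals) < 2 || length(ck_vals) < 2) return(NA_real_)
  lt <- log2(t_vals); lc <- log2(ck_vals)
  if (stats::sd(lt) == 0 && stats::sd(lc) == 0) {
    return(if (isTRUE(all.equal(mean(lt), mean(lc)))) 1 else NA_real_)
  }
  tryCatch(t.test(lt, lc, var.equal = var_equal)$p.value, error = function(e) NA_real_)
}

group_ratio <- function(mat_t, mat_ck, min_values) {
  n_t <- rowSums(!is.na(mat_t))
  n_ck <- rowSums(!is.na(mat_ck))
  r <- rowMeans(mat_t, na.rm = TRUE) / rowMeans(mat_ck, na.rm = TRUE)
  r[n_t < min_values | n_ck < min_values] <- NA_real_
  r
}

classify_reg <- function(ratio, p_value, config) {
  cls <- rep("unchanged", length(ratio))
  pass_p <- if (config$use_pvalue) !is.na(p_value) & p_value < config$alpha else TRUE
  cls[!is.na(ratio) & ratio > config$fc_threshold & pass_p] <- "up"
  cls[!is.na(ratio) & ratio < 1 / config$fc_threshold & pass_p] <- "down"
  cls[is.na(ratio)] <- "unquantified"
  factor(cls, levels = c("up", "down", "unchanged", "unquantified"))
}

#' Quantify proteins from a peptide-level reporter table
#'
#' For each unique peptide the treatment/control ratio is the ratio of the
#' group means of its non-missing intensities (each group needing at least
#' `min_values_per_group` values); the protein ratio is the median of its
#' unique-peptide ratios. The p-value is a two-sample two-tailed t-test on
#' the per-channel log2 protein intensities, where the protein intensity of
#' a channel is the sum of its unique-peptide intensities. Proteins are
#' classified up/down at the fold-change (and, by default, p-value)
#' thresholds of `config`. The table should be mean-normalized first.
#'
#' @param peptide_table Tibble with `peptide_seq`, `protein_id`, `is_unique`
#'   and one intensity column per channel.
#' @param design A [channel_design()].
#' @param config A [quant_config()].
#' @return A tibble of class `kcr_protein_quant` with columns `protein_id`,
#'   `ratio`, `log2_ratio`, `p_value`, `n_unique_peptides`, `reg_class`.
#' @export
quantify_proteins <- function(peptide_table, design, config = quant_config()) {
  chan <- design$channel_labels
  stopifnot(all(chan %in% names(peptide_table)))
  ck <- design_channels(design, "CK")
  tt <- design_channels(design, "T")

  uniq <- peptide_table[peptide_table$is_unique == 1, , drop = FALSE]
  prot_ids <- sort(unique(peptide_table$protein_id))

  mat_t <- as.matrix(uniq[, tt, drop = FALSE])
  mat_ck <- as.matrix(uniq[, ck, drop = FALSE])
  pep_ratio <- group_ratio(mat_t, mat_ck, config$min_values_per_group)

  by_prot <- split(seq_len(nrow(uniq)), uniq$protein_id)
  res <- map(prot_ids, function(pid) {
    idx <- by_prot[[pid]]
    if (is.null(idx)) {
      return(tibble(protein_id = pid, ratio = NA_real_, p_value = NA_real_,
                    n_unique_peptides = 0L))
    }
    r <- pep_ratio[idx]
    r <- r[!is.na(r)]
    ratio <- if (length(r)) median(r) else NA_real_
    chan_sum_t <- colSums(mat_t[idx, , drop = FALSE], na.rm = TRUE)
    chan_sum_ck <- colSums(mat_ck[idx, , drop = FALSE], na.rm = TRUE)
    p <- if (length(r)) welch_log2_p(chan_sum_t, chan_sum_ck, config$var_equal) else NA_real_
    tibble(protein_id = pid, ratio = ratio, p_value = p,
           n_unique_peptides = length(r))
  })
  out <- list_rbind(res)
  out$log2_ratio <- log2(out$ratio)
  out$reg_class <- classify_reg(out$ratio, out$p_value, config)
  out <- out[, c("protein_id", "ratio", "log2_ratio", "p_value",
                 "n_unique_peptides", "reg_class")]
  new_kcr_result(out, "kcr_protein_quant", config)
}

#' Quantify crotonylation sites with protein-level normalization
#'
#' Sites failing the localization filter (probability not above
#' `loc_prob_min`) are dropped. Each remaining site's raw treatment/control
#' ratio and p-value are computed as for a single peptide; the normalized
#' ratio divides the raw ratio by the parent protein's ratio, removing
#' changes caused by protein abundance. Sites whose parent protein is not
#' quantified are classified on the raw ratio and flagged (`norm_basis =
#' "raw"`). Regulation is called on the normalized ratio at the thresholds
#' of `config`.
#'
#' @param site_table Tibble with `protein_id`, `position`,
#'   `localization_prob` and intensity columns (mean-normalized).
#' @param protein_results Output of [quantify_proteins()].
#' @param design A [channel_design()].
#' @param config A [quant_config()].
#' @param proteins Optional proteome tibble; when given, site positions are
#'   checked to be lysines of their protein.
#' @return A tibble of class `kcr_site_quant` with `protein_id`, `position`,
#'   `raw_ratio`, `norm_ratio`, `log2_norm_ratio`, `p_value`, `reg_class`,
#'   `norm_basis`.
#' @export
quantify_sites <- function(site_table, protein_results, design,
                           config = quant_config(), proteins = NULL) {
  chan <- design$channel_labels
  stopifnot(all(chan %in% names(site_table)))
  if (!is.null(proteins)) {
    idx <- match(site_table$protein_id, proteins$protein_id)
    ctr <- substring(proteins$sequence[idx], site_table$position, site_table$position)
    bad <- is.na(ctr) | ctr != "K"
    if (any(bad)) {
      abort(sprintf("site position is not a lysine: %s",
                    paste(sprintf("%s:%d", site_table$protein_id[bad],
                                  site_table$position[bad])[seq_len(min(5, sum(bad)))],
                          collapse = ", ")))
    }
  }
  if ("localization_prob" %in% names(site_table)) {
    site_table <- site_table[site_table$localization_prob > config$loc_prob_min, ,
                             drop = FALSE]
  }
  ck <- design_channels(design, "CK")
  tt <- design_channels(design, "T")
  mat_t <- as.matrix(site_table[, tt, drop = FALSE])
  mat_ck <- as.matrix(site_table[, ck, drop = FALSE])

  raw_ratio <- group_ratio(mat_t, mat_ck, config$min_values_per_group)
  p <- vapply(seq_len(nrow(site_table)), function(i) {
    welch_log2_p(mat_t[i, ], mat_ck[i, ], config$var_equal)
  }, numeric(1))
  p[is.na(raw_ratio)] <- NA_real_

  prot_ratio <- protein_results$ratio[match(site_table$protein_id,
                                            protein_results$protein_id)]
  norm_ratio <- raw_ratio / prot_ratio
  norm_basis <- ifelse(is.na(prot_ratio), "raw", "protein_normalized")
  class_ratio <- ifelse(is.na(prot_ratio), raw_ratio, norm_ratio)

  out <- tibble(
    protein_id = site_table$protein_id,
    position = site_table$position,
    raw_ratio = raw_ratio,
    norm_ratio = norm_ratio,
    log2_norm_ratio = log2(norm_ratio),
    p_value = p,
    reg_class = classify_reg(class_ratio, p, config),
    norm_basis = norm_basis
  )
  new_kcr_result(out, "kcr_site_quant", config)
}

new_kcr_result <- function(tbl, cls, config = NULL) {
  tbl <- as_tibble(tbl)
  class(tbl) <- c(cls, class(tbl))
  if (!is.null(config)) attr(tbl, "config") <- config
  tbl
}
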