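#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_hline
#'   geom_vline scale_fill_gradient2 labs theme_minimal
#' @export
ggplot2::autoplot

#' Heatmap of the position-by-residue enrichment matrix
#'
#' Intensity map of residue enrichment (red) and depletion (blue) around
#' the modified lysine.
#'
#' @param object An [enrichment_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kcr_enrichment_matrix
#' @export
autoplot.kcr_enrichment_matrix <- function(object, ...) {
  df <- tidy(object)
  df$residue <- factor(df$residue, levels = rev(sort(unique(df$residue))))
  ggplot(df, aes(x = .data$offset, y = .data$residue, fill = .data$log2_odds)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         na.value = "grey85") +
    labs(x = "position relative to modified K", y = NULL,
         fill = "log2 fg/bg") +
    theme_minimal()
}

#' Quadrant plot of protein versus crotonylation change
#'
#' Each point is a protein present in both datasets, placed by its protein
#' log2 ratio (x) and the normalized log2 ratio of its representative site
#' (y); quadrants 2 and 4 hold proteins whose modification changes against
#' protein abundance.
#'
#' @param object A [crosstalk()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kcr_crosstalk
#' @export
autoplot.kcr_crosstalk <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$protein_log2_ratio) & !is.na(df$site_log2_norm_ratio), ]
  ggplot(df, aes(x = .data$protein_log2_ratio, y = .data$site_log2_norm_ratio,
                 colour = .data$relation)) +
    geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey50") +
    geom_point(alpha = 0.7) +
    labs(x = "protein log2 (T/CK)", y = "site normalized log2 (T/CK)",
         colour = NULL) +
    theme_minimal()
}

#' Volcano plot of site-level quantification
#'
#' Normalized log2 ratio against -log10 p-value, coloured by regulation
#' call.
#'
#' @param object A [quantify_sites()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kcr_site_quant
#' @export
autoplot.kcr_site_quant <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$p_value) & !is.na(df$log2_norm_ratio), ]
  ggplot(df, aes(x = .data$log2_norm_ratio, y = -log10(.data$p_value),
                 colour = .data$reg_class)) +
    geom_point(alpha = 0.7) +
    labs(x = "normalized log2 (T/CK)", y = "-log10 p", colour = NULL) +
    theme_minimal()
}

#' Dot plot of term-enrichment results
#'
#' Fold enrichment against terms ordered by significance.
#'
#' @param object An [enrich()] result.
#' @param top Number of terms shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kcr_enrichment
#' @export
autoplot.kcr_enrichment <- function(object, top = 20, ...) {
  df <- head(tidy(object), top)
  df$term_id <- factor(df$term_id, levels = rev(df$term_id))
  ggplot(df, aes(x = .data$fold, y = .data$term_id, size = .data$k,
                 colour = -log10(.data$q))) +
    geom_point() +
    labs(x = "fold enrichment", y = NULL, size = "k", colour = "-log10 q") +
    theme_minimal()
}
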