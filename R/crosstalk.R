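#' Classify protein/crotonylation crosstalk
#'
#' Joins protein-level and site-level results per protein and labels the
#' relation between the two layers: `consistent` when the protein is
#' regulated and at least one site is regulated in the same direction with
#' no site in the opposite direction; `opposite` when every regulated site
#' changes against the protein; `mixed` when regulated sites go both ways;
#' `none` when the protein appears in both datasets but no
#' concordant/discordant regulated pair exists; `protein_only` / `site_only`
#' when the protein is missing from one dataset. Each protein also receives
#' the quadrant of its representative site (smallest p-value, ties broken by
#' effect size) in the (protein log2 ratio, site normalized log2 ratio)
#' plane: quadrant 1 = (+,+), 2 = (-,+), 3 = (-,-), 4 = (+,-).
#'
#' @param protein_results [quantify_proteins()] output.
#' @param site_results [quantify_sites()] output.
#' @return A tibble of class `kcr_crosstalk` with `protein_id`,
#'   `protein_class`, `site_class`, `relation`, `quadrant`,
#'   `protein_log2_ratio`, `site_log2_norm_ratio`. Summary counts are
#'   available via [glance()].
#' @export
crosstalk <- function(protein_results, site_results) {
  sgn_of <- function(cls) ifelse(cls == "up", 1L, ifelse(cls == "down", -1L, 0L))

  site_sum <- site_results |>
    group_by(.data$protein_id) |>
    arrange(.data$p_value, desc(abs(.data$log2_norm_ratio)), .data$position,
            .by_group = TRUE) |>
    summarise(
      site_class = as.character(first(.data$reg_class)),
      site_log2_norm_ratio = first(.data$log2_norm_ratio),
      n_up = sum(.data$reg_class == "up"),
      n_down = sum(.data$reg_class == "down"),
      .groups = "drop"
    )

  joined <- full_join(
    tibble(protein_id = protein_results$protein_id,
           protein_class = as.character(protein_results$reg_class),
           protein_log2_ratio = protein_results$log2_ratio),
    site_sum,
    by = "protein_id"
  )

  rel <- pmap_chr_safe(joined, function(row) {
    if (is.na(row$site_class)) return("protein_only")
    if (is.na(row$protein_class)) return("site_only")
    ps <- sgn_of(row$protein_class)
    has_same <- (ps > 0 && row$n_up > 0) || (ps < 0 && row$n_down > 0)
    has_opp <- (ps > 0 && row$n_down > 0) || (ps < 0 && row$n_up > 0)
    if (ps == 0) return("none")
    if (has_same && !has_opp) return("consistent")
    if (has_opp && !has_same) return("opposite")
    if (has_same && has_opp) return("mixed")
    "none"
  })

  quad <- with(joined, {
    q <- rep(NA_integer_, nrow(joined))
    pl <- protein_log2_ratio
    sl <- site_log2_norm_ratio
    ok <- !is.na(pl) & !is.na(sl) & pl != 0 & sl != 0
    q[ok & pl > 0 & sl > 0] <- 1L
    q[ok & pl < 0 & sl > 0] <- 2L
    q[ok & pl < 0 & sl < 0] <- 3L
    q[ok & pl > 0 & sl < 0] <- 4L
    q
  })

  out <- tibble(
    protein_id = joined$protein_id,
    protein_class = joined$protein_class,
    site_class = joined$site_class,
    relation = factor(rel, levels = c("consistent", "opposite", "mixed", "none",
                                      "protein_only", "site_only")),
    quadrant = quad,
    protein_log2_ratio = joined$protein_log2_ratio,
    site_log2_norm_ratio = joined$site_log2_norm_ratio
  )
  new_kcr_result(out, "kcr_crosstalk")
}

pmap_chr_safe <- function(df, f) {
  vapply(seq_len(nrow(df)), function(i) f(df[i, ]), character(1))
}
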