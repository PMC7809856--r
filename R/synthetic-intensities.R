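#' TMT channel design (3 control vs 3 treatment)
#'
#' @param labels Ordered channel labels, 6 of them.
#' @param groups Group of each channel, `"CK"` (control) or `"T"` (treatment);
#'   exactly three of each.
#' @return A list of class `kcr_design` with `channel_labels` and `group_of`.
#' @export
#' @examples
#' channel_design()
channel_design <- function(labels = c("CK-01", "CK-02", "CK-03", "T-01", "T-02", "T-03"),
                           groups = c("CK", "CK", "CK", "T", "T", "T")) {
  if (length(labels) != 6 || length(groups) != 6 ||
      sum(groups == "CK") != 3 || sum(groups == "T") != 3) {
    abort("the design needs exactly 6 channels: 3 CK and 3 T.")
  }
  if (anyDuplicated(labels)) abort("duplicate channel labels.")
  structure(list(channel_labels = labels, group_of = setNames(groups, labels)),
            class = "kcr_design")
}

design_channels <- function(design, group) {
  design$channel_labels[design$group_of[design$channel_labels] == group]
}

#' Simulate TMT reporter-intensity tables for peptides and Kcr sites
#'
#' Intensities are log-normal: a control channel of a peptide has log2
#' intensity `base_log2_mean + protein baseline + peptide offset +
#' N(0, noise_sd)`; treatment channels add the protein's ground-truth log2
#' effect, and site rows additionally add the site-level effect, so the
#' protein- and site-level signals are separable exactly as the downstream
#' normalization assumes. Cells are deleted completely at random at
#' `missing_rate`. Each site row carries a localization probability drawn
#' from a two-component Beta mixture with mass above and below 0.75.
#'
#' @param proteins,peptides,sites Proteome, [digest_tryptic()] output, and
#'   site tibble (`protein_id`, `position`).
#' @param truth A [ground_truth()] object (effects of missing proteins/sites
#'   are taken as 0).
#' @param design A [channel_design()].
#' @param base_log2_mean Grand log2 intensity location (reporter-ion scale).
#' @param protein_baseline_sd Log2 spread of per-protein abundance.
#' @param peptide_sd Log2 spread of per-peptide (ionization) offsets; cancels
#'   in every ratio.
#' @param noise_sd Log2 measurement noise, > 0.
#' @param missing_rate Per-cell missing probability in `[0, 1)`.
#' @param loc_high_frac Mixture weight of the well-localized component.
#' @param seed Integer seed.
#' @return A list with tibbles `peptides` (`peptide_seq`, `protein_id`,
#'   `is_unique`, one intensity column per channel) and `sites`
#'   (`protein_id`, `position`, `window`, `localization_prob`, intensities).
#' @export
simulate_intensities <- function(proteins, peptides, sites, truth,
                                 design = channel_design(),
                                 base_log2_mean = 20,
                                 protein_baseline_sd = 2,
                                 peptide_sd = 1,
                                 noise_sd = 0.3,
                                 missing_rate = 0.05,
                                 loc_high_frac = 0.85,
                                 seed = 1L) {
  check_protein_df(proteins)
  if (!inherits(design, "kcr_design")) abort("`design` must be a channel_design().")
  if (!inherits(truth, "kcr_truth")) abort("`truth` must be a ground_truth().")
  stopifnot(noise_sd > 0, missing_rate >= 0, missing_rate < 1)

  chan <- design$channel_labels
  is_t <- design$group_of[chan] == "T"
  pe <- setNames(truth$protein_effects$log2_effect, truth$protein_effects$protein_id)
  se_key <- paste(truth$site_effects$protein_id, truth$site_effects$position)
  se <- setNames(truth$site_effects$log2_site_effect, se_key)

  with_seed(as.integer(seed), {
    baseline <- setNames(rnorm(nrow(proteins), 0, protein_baseline_sd),
                         proteins$protein_id)

    sim_block <- function(prot_ids, row_effect) {
      n <- length(prot_ids)
      off <- rnorm(n, 0, peptide_sd)
      mu <- base_log2_mean + baseline[prot_ids] + off
      m <- matrix(rnorm(n * 6L, 0, noise_sd), n, 6L)
      m <- m + mu + outer(row_effect, as.numeric(is_t))
      m <- 2^m
      if (missing_rate > 0) m[matrix(runif(n * 6L) < missing_rate, n, 6L)] <- NA_real_
      colnames(m) <- chan
      m
    }

    pep_eff <- ifelse(is.na(pe[peptides$protein_id]), 0, pe[peptides$protein_id])
    pep_mat <- sim_block(peptides$protein_id, unname(pep_eff))

    n_prot_per_pep <- tapply(peptides$protein_id, peptides$peptide,
                             function(x) length(unique(x)))
    is_unique <- as.integer(n_prot_per_pep[peptides$peptide] == 1)

    pep_tbl <- bind_cols(
      tibble(peptide_seq = peptides$peptide, protein_id = peptides$protein_id,
             is_unique = unname(is_unique)),
      as_tibble(pep_mat)
    )

    if (nrow(sites) > 0) {
      s_pe <- ifelse(is.na(pe[sites$protein_id]), 0, pe[sites$protein_id])
      s_se <- se[paste(sites$protein_id, sites$position)]
      s_se <- ifelse(is.na(s_se), 0, s_se)
      site_mat <- sim_block(sites$protein_id, unname(s_pe + s_se))
      hi <- runif(nrow(sites)) < loc_high_frac
      loc <- ifelse(hi, rbeta(nrow(sites), 38, 2), rbeta(nrow(sites), 20, 20))
      win <- extract_windows(proteins, sites)$window
      site_tbl <- bind_cols(
        tibble(protein_id = sites$protein_id, position = sites$position,
               window = win, localization_prob = loc),
        as_tibble(site_mat)
      )
    } else {
      site_tbl <- bind_cols(
        tibble(protein_id = character(), position = integer(),
               window = character(), localization_prob = numeric()),
        as_tibble(matrix(numeric(0), 0, 6, dimnames = list(NULL, chan)))
      )
    }
    list(peptides = pep_tbl, sites = site_tbl)
  })
}
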