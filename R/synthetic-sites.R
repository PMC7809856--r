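#' Describe a sequence motif to plant around modified lysines
#'
#' A motif is a set of `(offset, residue)` constraints relative to the
#' modified lysine at offset 0 (which is never itself constrained), plus the
#' fraction of planted sites that should carry it.
#'
#' @param offsets Integer offsets in `[-10, 10]`, excluding 0.
#' @param residues One-letter residue codes, one per offset.
#' @param prevalence Probability in `[0, 1]` that a planted site carries this
#'   motif.
#' @return A list of class `kcr_motif_spec`.
#' @export
#' @examples
#' motif_spec(c(-1, 1), c("F", "E"), prevalence = 0.3)
motif_spec <- function(offsets, residues, prevalence) {
  offsets <- as.integer(offsets)
  if (length(offsets) != length(residues) || length(offsets) == 0) {
    abort("`offsets` and `residues` must be non-empty and the same length.")
  }
  if (any(offsets == 0L)) {
    abort("motif offset 0 is the modified lysine itself and cannot be constrained.")
  }
  if (any(abs(offsets) > 10L)) abort("motif offsets must lie in [-10, 10].")
  if (anyDuplicated(offsets)) abort("duplicate motif offsets.")
  if (!all(residues %in% AA20)) abort("motif residues must be standard one-letter codes.")
  if (prevalence < 0 || prevalence > 1) abort("`prevalence` must be in [0, 1].")
  ord <- order(offsets)
  structure(
    list(offsets = offsets[ord], residues = as.character(residues)[ord],
         prevalence = prevalence),
    class = "kcr_motif_spec"
  )
}

#' Plant crotonylation sites and sequence motifs in a proteome
#'
#' Selects lysines as modified (Kcr) sites at rate `site_fraction` and writes
#' planted motifs into the flanking sequence of a `prevalence`-controlled
#' subset of them. When motifs are planted, sites within the same protein are
#' kept at least 11 residues apart so that editing one site's flank can never
#' destroy another site's lysine: the ground truth stays exact.
#'
#' @param proteins Data frame with `protein_id`, `sequence`.
#' @param site_fraction Probability that a lysine becomes a Kcr site.
#' @param motif_specs List of [motif_spec()] objects; prevalences must sum to
#'   at most 1 (the remainder of sites get no motif).
#' @param seed Integer seed.
#' @return A list with `proteins` (sequences after motif planting), `sites`
#'   (tibble `protein_id`, `position`, `motif`), and `planted_motifs` (the
#'   specs).
#' @export
plant_sites_and_motifs <- function(proteins, site_fraction, motif_specs = list(),
                                   seed = 1L) {
  check_protein_df(proteins)
  stopifnot(site_fraction >= 0, site_fraction <= 1)
  if (length(motif_specs) > 0 &&
      !all(vapply(motif_specs, inherits, logical(1), "kcr_motif_spec"))) {
    abort("`motif_specs` must be a list of motif_spec() objects.")
  }
  prev <- vapply(motif_specs, `[[`, numeric(1), "prevalence")
  if (sum(prev) > 1 + 1e-12) abort("motif prevalences sum above 1.")
  have_motifs <- length(motif_specs) > 0

  with_seed(as.integer(seed), {
    seqs <- proteins$sequence
    names(seqs) <- proteins$protein_id
    sites <- vector("list", nrow(proteins))
    for (i in seq_len(nrow(proteins))) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      kpos <- which(chars == "K")
      if (length(kpos) == 0) next
      picked <- kpos[runif(length(kpos)) < site_fraction]
      if (have_motifs && length(picked) > 1) {
        # enforce >= 11 residue spacing so motif planting cannot hit a site
        keep <- picked[1]
        for (p in picked[-1]) if (min(abs(p - keep)) > 10) keep <- c(keep, p)
        picked <- keep
      }
      if (length(picked) == 0) next
      motif_of <- rep(NA_integer_, length(picked))
      if (have_motifs) {
        draw <- runif(length(picked))
        cuts <- cumsum(prev)
        for (j in seq_along(picked)) {
          m <- which(draw[j] <= cuts)[1]
          if (is.na(m)) next
          spec <- motif_specs[[m]]
          tgt <- picked[j] + spec$offsets
          if (any(tgt < 1 | tgt > length(chars))) next  # flank truncated: skip planting
          chars[tgt] <- spec$residues
          motif_of[j] <- m
        }
      }
      seqs[i] <- paste(chars, collapse = "")
      sites[[i]] <- tibble(protein_id = proteins$protein_id[i], position = picked,
                           motif = motif_of)
    }
    site_tbl <- list_rbind(sites[!vapply(sites, is.null, logical(1))])
    if (is.null(site_tbl) || nrow(site_tbl) == 0) {
      site_tbl <- tibble(protein_id = character(), position = integer(),
                         motif = integer())
    }
    out_proteins <- proteins
    out_proteins$sequence <- unname(seqs)
    # every site must still be a lysine after planting
    ctr <- str_sub(out_proteins$sequence[match(site_tbl$protein_id, out_proteins$protein_id)],
                   site_tbl$position, site_tbl$position)
    stopifnot(all(ctr == "K"))
    list(proteins = out_proteins, sites = site_tbl, planted_motifs = motif_specs)
  })
}

#' Assign ground-truth differential effects to proteins and sites
#'
#' Marks a fraction of proteins as differentially abundant between treatment
#' and control, and a fraction of Kcr sites as carrying an additional
#' site-level (modification stoichiometry) effect, on the log2 scale.
#'
#' @param proteins,sites Output of [generate_proteome()] /
#'   [plant_sites_and_motifs()].
#' @param frac_protein_de Fraction of proteins with a non-zero effect.
#' @param protein_effect Log2 effect magnitude; sign drawn at random.
#' @param frac_site_de Fraction of sites with an additional site effect.
#' @param site_effect Log2 site-effect magnitude; sign drawn at random.
#' @param seed Integer seed.
#' @return A list of class `kcr_truth` with tibbles `protein_effects`
#'   (`protein_id`, `log2_effect`) covering every protein (0 for nulls) and
#'   `site_effects` (`protein_id`, `position`, `log2_site_effect`) covering
#'   every site.
#' @export
assign_effects <- function(proteins, sites,
                           frac_protein_de = 0.1, protein_effect = 1,
                           frac_site_de = 0.1, site_effect = 1.5,
                           seed = 1L) {
  check_protein_df(proteins)
  with_seed(as.integer(seed), {
    np <- nrow(proteins)
    pe <- rep(0, np)
    n_de <- round(frac_protein_de * np)
    if (n_de > 0) {
      idx <- sample.int(np, n_de)
      pe[idx] <- protein_effect * sample(c(-1, 1), n_de, replace = TRUE)
    }
    ns <- nrow(sites)
    se <- rep(0, ns)
    n_sde <- round(frac_site_de * ns)
    if (n_sde > 0) {
      idx <- sample.int(ns, n_sde)
      se[idx] <- site_effect * sample(c(-1, 1), n_sde, replace = TRUE)
    }
    ground_truth(
      protein_effects = tibble(protein_id = proteins$protein_id, log2_effect = pe),
      site_effects = tibble(protein_id = sites$protein_id,
                            position = sites$position, log2_site_effect = se)
    )
  })
}

#' Construct a ground-truth container
#'
#' Bundles the known simulation truth used by parameter-recovery tests:
#' per-protein log2 treatment effects, per-site additional log2 effects,
#' planted motif specs, and per-species lysine retention rates.
#'
#' @param protein_effects Tibble `protein_id`, `log2_effect`.
#' @param site_effects Tibble `protein_id`, `position`, `log2_site_effect`.
#' @param planted_motifs Optional list of [motif_spec()].
#' @param conservation_rates Optional tibble `species`, `kcr_keep`,
#'   `control_keep` with rates in `[0, 1]`.
#' @return A list of class `kcr_truth`.
#' @export
ground_truth <- function(protein_effects, site_effects,
                         planted_motifs = list(), conservation_rates = NULL) {
  stopifnot(all(c("protein_id", "log2_effect") %in% names(protein_effects)),
            all(c("protein_id", "position", "log2_site_effect") %in% names(site_effects)))
  if (!is.null(conservation_rates)) {
    r <- c(conservation_rates$kcr_keep, conservation_rates$control_keep)
    if (any(r < 0 | r > 1)) abort("conservation rates must be in [0, 1].")
  }
  structure(
    list(protein_effects = as_tibble(protein_effects),
         site_effects = as_tibble(site_effects),
         planted_motifs = planted_motifs,
         conservation_rates = conservation_rates),
    class = "kcr_truth"
  )
}
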