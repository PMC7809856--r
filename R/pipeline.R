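#' Enrichment-efficiency report formula
#'
#' Percentage of enriched peptides that carry the target modification,
#' rounded to one decimal as printed in run reports.
#'
#' @param n_modified Number of modified peptides.
#' @param n_total Total number of peptides in the enriched fraction.
#' @return A percentage rounded to 1 decimal.
#' @export
#' @examples
#' enrichment_efficiency(2173, 2238)
enrichment_efficiency <- function(n_modified, n_total) {
  stopifnot(n_total > 0, n_modified >= 0, n_modified <= n_total)
  round(100 * n_modified / n_total, 1)
}

#' Site-multiplicity summary of modified proteins
#'
#' Counts, for each number of modification sites per protein, how many
#' proteins carry exactly that many sites, with the percentage of all
#' modified proteins (rounded to two decimals, the report convention).
#'
#' @param sites Tibble with `protein_id`, one row per site.
#' @return A tibble `n_sites`, `n_proteins`, `pct`.
#' @export
#' @examples
#' site_multiplicity(tibble::tibble(protein_id = c("a", "a", "b")))
site_multiplicity <- function(sites) {
  per_prot <- table(sites$protein_id)
  tab <- table(as.integer(per_prot))
  tibble(
    n_sites = as.integer(names(tab)),
    n_proteins = as.integer(tab),
    pct = round(100 * as.integer(tab) / length(per_prot), 2)
  )
}

#' Full run configuration
#'
#' Bundles simulation, quantification, motif, and conservation parameters
#' for [pipeline_run()]. Serializes losslessly through [write_run_config()]
#' / [read_run_config()].
#'
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param n_proteins,length_range,site_fraction Proteome/site simulation.
#' @param frac_protein_de,protein_effect,frac_site_de,site_effect Planted
#'   log2 effects.
#' @param motif_specs List of [motif_spec()] to plant.
#' @param noise_sd,missing_rate,base_log2_mean,protein_baseline_sd,peptide_sd
#'   Intensity model.
#' @param species,substitution_rate,kcr_keep,control_keep Ortholog
#'   simulation.
#' @param quant A [quant_config()].
#' @param p_threshold,min_occurrences Motif search parameters.
#' @param score_min RBH score floor.
#' @param out_dir Optional output directory for TSVs.
#' @return A list of class `kcr_run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_proteins = 300L,
                       length_range = c(100L, 400L),
                       site_fraction = 0.05,
                       frac_protein_de = 0.1,
                       protein_effect = 1,
                       frac_site_de = 0.1,
                       site_effect = 1.5,
                       motif_specs = list(motif_spec(c(-1, 1), c("F", "E"), 0.3)),
                       noise_sd = 0.25,
                       missing_rate = 0.05,
                       base_log2_mean = 20,
                       protein_baseline_sd = 2,
                       peptide_sd = 1,
                       species = c("tea", "rice"),
                       substitution_rate = 0.1,
                       kcr_keep = 0.8,
                       control_keep = 0.5,
                       quant = quant_config(),
                       p_threshold = 1e-6,
                       min_occurrences = 20L,
                       score_min = 50,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "kcr_run_config")
}

#' Write / read a run configuration
#'
#' Flat `key=value` text serialization; nested pieces are stored as
#' deparsed R expressions so that `read_run_config(write_run_config(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the configuration.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "kcr_run_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s=%s", k, paste(deparse(config[[k]], control = "all"), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- str_split(lines, "=", n = 2)
  cfg <- lapply(kv, function(p) eval(parse(text = p[2]), envir = asNamespace("kcrquant")))
  names(cfg) <- vapply(kv, `[[`, character(1), 1)
  structure(cfg, class = "kcr_run_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a proteome with planted modification sites, motifs, effects
#' and orthologs, then executes every analysis stage: mean normalization,
#' protein quantification, localization-filtered site quantification with
#' protein normalization, crosstalk classification, motif discovery,
#' cross-species conservation, and (optionally) term enrichment against a
#' supplied annotation map. Deterministic for a fixed `config$seed`. If a
#' stage fails, the run aborts naming the stage and partial outputs under
#' `config$out_dir` are removed.
#'
#' @param config A [run_config()].
#' @param annotations Optional annotation tibble for the enrichment stage.
#' @return A list of class `kcr_run` with elements `proteins`, `sites`,
#'   `truth`, `tables` (simulated intensity tables), `protein_results`,
#'   `site_results`, `crosstalk`, `motifs`, `conservation`, `ortholog_truth`,
#'   `enrichment` (or `NULL`), and `summary` (named list of report counts).
#' @export
pipeline_run <- function(config = run_config(), annotations = NULL) {
  stopifnot(inherits(config, "kcr_run_config"))
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (length(written)) unlink(written)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  seed <- as.integer(config$seed)
  design <- channel_design()

  sim <- stage("simulate", {
    prot <- generate_proteome(config$n_proteins, config$length_range, seed = seed)
    planted <- plant_sites_and_motifs(prot, config$site_fraction,
                                      config$motif_specs, seed = seed + 1L)
    truth <- assign_effects(planted$proteins, planted$sites,
                            config$frac_protein_de, config$protein_effect,
                            config$frac_site_de, config$site_effect,
                            seed = seed + 2L)
    peps <- digest_tryptic(planted$proteins)
    tabs <- simulate_intensities(planted$proteins, peps, planted$sites, truth,
                                 design, config$base_log2_mean,
                                 config$protein_baseline_sd, config$peptide_sd,
                                 config$noise_sd, config$missing_rate,
                                 seed = seed + 3L)
    list(proteins = planted$proteins, sites = planted$sites, truth = truth,
         tables = tabs)
  })

  norm_pep <- stage("normalize", mean_normalize(sim$tables$peptides, design))
  norm_site <- stage("normalize", mean_normalize(sim$tables$sites, design))
  prot_res <- stage("quantify_proteins",
                    quantify_proteins(norm_pep, design, config$quant))
  site_res <- stage("quantify_sites",
                    quantify_sites(norm_site, prot_res, design, config$quant,
                                   proteins = sim$proteins))
  xt <- stage("crosstalk", crosstalk(prot_res, site_res))

  motifs <- stage("motifs", {
    fg <- extract_windows(sim$proteins, sim$sites)$window
    bg <- background_windows(sim$proteins)$window
    find_motifs(fg, bg, config$p_threshold, config$min_occurrences)
  })

  cons <- stage("conservation", {
    orth <- generate_orthologs(sim$proteins, config$species,
                               config$substitution_rate, sim$sites,
                               config$kcr_keep, config$control_keep,
                               seed = seed + 4L)
    summ <- conserve_species(sim$proteins, orth$orthologs, sim$sites,
                             score_min = config$score_min)
    list(summary = summ, truth = orth$truth)
  })

  enr <- if (!is.null(annotations)) {
    stage("enrichment", {
      de <- prot_res$protein_id[prot_res$reg_class %in% c("up", "down")]
      enrich(de, prot_res$protein_id, annotations)
    })
  } else NULL

  summary <- stage("summary", {
    n_sites_quant <- sum(!is.na(site_res$raw_ratio))
    n_sites_norm <- sum(site_res$norm_basis == "protein_normalized" &
                          !is.na(site_res$norm_ratio))
    mult <- site_multiplicity(sim$sites)
    rel <- table(xt$relation)
    list(
      n_proteins_identified = nrow(sim$proteins),
      n_proteins_quantified = sum(!is.na(prot_res$ratio)),
      n_proteins_up = sum(prot_res$reg_class == "up"),
      n_proteins_down = sum(prot_res$reg_class == "down"),
      n_peptides = nrow(sim$tables$peptides),
      n_modified_peptides = nrow(sim$tables$sites),
      # the simulated affinity enrichment is perfect: every enriched row is modified
      enrichment_efficiency = enrichment_efficiency(
        nrow(sim$tables$sites), nrow(sim$tables$sites)),
      n_sites = nrow(sim$sites),
      n_site_proteins = length(unique(sim$sites$protein_id)),
      pct_single_site = mult$pct[match(1L, mult$n_sites)],
      n_sites_quantified = n_sites_quant,
      n_sites_normalized = n_sites_norm,
      n_sites_up = sum(site_res$reg_class == "up"),
      n_sites_down = sum(site_res$reg_class == "down"),
      n_motifs = nrow(motifs),
      n_crosstalk_consistent = unname(rel["consistent"]),
      n_crosstalk_opposite = unname(rel["opposite"])
    )
  })

  out <- structure(
    list(proteins = sim$proteins, sites = sim$sites, truth = sim$truth,
         tables = sim$tables, protein_results = prot_res,
         site_results = site_res, crosstalk = xt, motifs = motifs,
         conservation = cons$summary, ortholog_truth = cons$truth,
         enrichment = enr, summary = summary, config = config),
    class = "kcr_run"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(tbl, fn) {
      p <- file.path(config$out_dir, fn)
      written <<- c(written, p)
      write_result_tsv(tbl, p, config)
    }
    stage("write", {
      w(prot_res, "protein_results.tsv")
      w(site_res, "site_results.tsv")
      w(xt, "crosstalk.tsv")
      w(motifs, "motifs.tsv")
      w(cons$summary, "conservation.tsv")
      if (!is.null(enr)) w(enr, "enrichment.tsv")
      write_fasta(sim$proteins, file.path(config$out_dir, "proteome.fasta"))
    })
  }
  out
}

#' @export
print.kcr_run <- function(x, ...) {
  s <- x$summary
  cat("kcr pipeline run\n")
  cat(sprintf("  proteins: %d identified, %d quantified, %d up / %d down\n",
              s$n_proteins_identified, s$n_proteins_quantified,
              s$n_proteins_up, s$n_proteins_down))
  cat(sprintf("  peptides: %d unmodified + %d modified (enrichment efficiency %.1f%%)\n",
              s$n_peptides, s$n_modified_peptides, s$enrichment_efficiency))
  cat(sprintf("  sites: %d in %d proteins (%.2f%% single-site), %d quantified, %d normalized, %d up / %d down\n",
              s$n_sites, s$n_site_proteins, s$pct_single_site,
              s$n_sites_quantified, s$n_sites_normalized,
              s$n_sites_up, s$n_sites_down))
  cat(sprintf("  motifs: %d; crosstalk: %d consistent / %d opposite\n",
              s$n_motifs, s$n_crosstalk_consistent, s$n_crosstalk_opposite))
  invisible(x)
}
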