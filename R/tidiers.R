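#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for kcrquant results
#'
#' `tidy()` returns the result as a plain tibble (list columns expanded
#' where that is the natural long form); `glance()` returns a one-row
#' summary.
#'
#' @param x A kcrquant result object.
#' @param ... Unused.
#' @return A tibble.
#' @name kcr-tidiers
NULL

#' @rdname kcr-tidiers
#' @method tidy kcr_protein_quant
#' @export
tidy.kcr_protein_quant <- function(x, ...) {
  # drop result-specific classes and attributes, keep the plain tibble
  for (a in setdiff(names(attributes(x)), c("names", "row.names", "class"))) {
    attr(x, a) <- NULL
  }
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @rdname kcr-tidiers
#' @method tidy kcr_site_quant
#' @export
tidy.kcr_site_quant <- tidy.kcr_protein_quant

#' @rdname kcr-tidiers
#' @method tidy kcr_crosstalk
#' @export
tidy.kcr_crosstalk <- tidy.kcr_protein_quant

#' @rdname kcr-tidiers
#' @method tidy kcr_conservation
#' @export
tidy.kcr_conservation <- tidy.kcr_protein_quant

#' @rdname kcr-tidiers
#' @method tidy kcr_enrichment
#' @export
tidy.kcr_enrichment <- tidy.kcr_protein_quant

#' @rdname kcr-tidiers
#' @method tidy kcr_enrichment_matrix
#' @export
tidy.kcr_enrichment_matrix <- tidy.kcr_protein_quant

#' @rdname kcr-tidiers
#' @method tidy kcr_motifs
#' @export
tidy.kcr_motifs <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out |>
    select(!"step_pvalues") |>
    unnest("constraints")
}

#' @rdname kcr-tidiers
#' @method glance kcr_protein_quant
#' @export
glance.kcr_protein_quant <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_quantified = sum(!is.na(x$ratio)),
    n_up = sum(x$reg_class == "up"),
    n_down = sum(x$reg_class == "down")
  )
}

#' @rdname kcr-tidiers
#' @method glance kcr_site_quant
#' @export
glance.kcr_site_quant <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_quantified = sum(!is.na(x$raw_ratio)),
    n_normalized = sum(x$norm_basis == "protein_normalized" & !is.na(x$norm_ratio)),
    n_up = sum(x$reg_class == "up"),
    n_down = sum(x$reg_class == "down")
  )
}

#' @rdname kcr-tidiers
#' @method glance kcr_crosstalk
#' @export
glance.kcr_crosstalk <- function(x, ...) {
  tibble(
    n_overlap = sum(!x$relation %in% c("protein_only", "site_only")),
    n_consistent = sum(x$relation == "consistent"),
    n_opposite = sum(x$relation == "opposite"),
    n_mixed = sum(x$relation == "mixed")
  )
}

#' @rdname kcr-tidiers
#' @method glance kcr_motifs
#' @export
glance.kcr_motifs <- function(x, ...) {
  tibble(
    n_motifs = nrow(x),
    max_fold_increase = if (nrow(x)) max(x$fold_increase) else NA_real_,
    n_fg_covered = sum(x$fg_matches)
  )
}

#' @rdname kcr-tidiers
#' @method glance kcr_enrichment
#' @export
glance.kcr_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$significant))
}
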