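#' Read a protein database from FASTA
#'
#' Standard multi-FASTA; the header token before the first whitespace is the
#' protein id, the remainder the description. Sequences are uppercased and
#' validated against the 20 standard residues; duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble `protein_id`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate protein id in %s: %s", path, paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(ss))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(sprintf("record without sequence: %s", paste(ids[empty], collapse = ", ")))
  }
  bad <- !grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")), seqs)
  if (any(bad)) {
    abort(sprintf("illegal characters in record(s): %s", paste(ids[bad], collapse = ", ")))
  }
  tibble(protein_id = ids, sequence = unname(seqs), description = desc)
}

#' Write a protein database to FASTA
#'
#' @param proteins Tibble `protein_id`, `sequence`, optional `description`.
#' @param path Output path.
#' @param width Sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  check_protein_df(proteins)
  desc <- proteins$description %||% rep("", nrow(proteins))
  if (is.null(proteins$description)) desc <- rep("", nrow(proteins))
  ss <- Biostrings::BStringSet(proteins$sequence)
  names(ss) <- ifelse(nzchar(desc), paste(proteins$protein_id, desc), proteins$protein_id)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Read a peptide- or site-level reporter-intensity table
#'
#' Tab-separated with one column per channel of the design; empty cells are
#' missing values. Channel columns must all be present; negative
#' intensities are an error with the offending row number; numeric columns
#' not in the design and not recognized metadata are ignored with a
#' warning.
#'
#' @param path Path to the TSV.
#' @param design A [channel_design()].
#' @return A tibble with metadata columns and one numeric column per
#'   channel.
#' @export
read_quant_table <- function(path, design) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         na = c("", "NA"))
  chan <- design$channel_labels
  missing_cols <- setdiff(chan, names(tbl))
  if (length(missing_cols)) {
    abort(sprintf("table lacks channel column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  meta_known <- c("peptide_seq", "protein_id", "is_unique", "position",
                  "window", "localization_prob")
  stray <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                   c(chan, meta_known))
  if (length(stray)) {
    warn(sprintf("ignoring unknown numeric column(s): %s", paste(stray, collapse = ", ")))
    tbl <- tbl[, setdiff(names(tbl), stray), drop = FALSE]
  }
  for (cn in chan) {
    if (is.logical(tbl[[cn]]) && all(is.na(tbl[[cn]]))) {
      tbl[[cn]] <- as.numeric(tbl[[cn]])  # all-missing column parsed as logical
    }
    v <- tbl[[cn]]
    if (!is.numeric(v)) abort(sprintf("channel %s is not numeric.", cn))
    neg <- which(v < 0)
    if (length(neg)) {
      abort(sprintf("negative intensity in channel %s at row(s) %s.",
                    cn, paste(head(neg, 5), collapse = ", ")))
    }
  }
  tbl
}

#' Write a result table as TSV with a provenance header
#'
#' Plain tab-separated output preceded by a comment line carrying the
#' package version and a hash of the effective configuration, so outputs
#' are traceable to the run that produced them.
#'
#' @param tbl Data frame to write (list columns are dropped).
#' @param path Output path.
#' @param config Optional configuration list included in the hash.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(tbl, path, config = NULL) {
  keep <- !vapply(tbl, is.list, logical(1))
  tbl <- as.data.frame(tbl)[, keep, drop = FALSE]
  hdr <- sprintf("# kcrquant %s config_hash=%s",
                 as.character(utils::packageVersion("kcrquant")),
                 hash(config))
  writeLines(hdr, path)
  suppressWarnings(
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  )
  invisible(path)
}
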