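# File-format readers and writers. All tabular files are UTF-8 TSV with a
# header row; empty fields encode missing values; leading '#' lines are
# comments. All residue coordinates are 1-based inclusive, initiator Met = 1.

COORD_COMMENT <- "# coordinates: 1-based inclusive residue indices, initiator Met = 1"

#' Read a proteome from FASTA (with optional signal-peptide sidecar)
#'
#' @param fasta Path to a FASTA file of protein sequences. The protein id is
#'   the first whitespace-delimited token of each header; the remainder is
#'   kept as the description.
#' @param signal_tsv Optional path to a TSV with columns `protein_id`,
#'   `signal_peptide_end` (1-based inclusive index of the last signal-peptide
#'   residue).
#' @return A proteome tibble: `protein_id`, `description`, `sequence`,
#'   `signal_peptide_end`.
#' @export
read_proteome <- function(fasta, signal_tsv = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- tibble::tibble(protein_id = unname(ids),
                        description = unname(desc),
                        sequence = unname(toupper(as.character(aa))),
                        signal_peptide_end = NA_integer_)
  if (!is.null(signal_tsv)) {
    sp <- readr::read_tsv(signal_tsv, comment = "#",
                          col_types = readr::cols(
                            protein_id = readr::col_character(),
                            signal_peptide_end = readr::col_integer()))
    stop_if(!all(c("protein_id", "signal_peptide_end") %in% names(sp)),
            "signal-peptide sidecar needs columns `protein_id`, `signal_peptide_end`")
    out$signal_peptide_end <-
      sp$signal_peptide_end[match(out$protein_id, sp$protein_id)]
  }
  check_proteome(out)
  out
}

#' Write a proteome to FASTA (and optional signal-peptide sidecar)
#'
#' @param proteome A proteome tibble (see [read_proteome()]).
#' @param fasta Output FASTA path.
#' @param signal_tsv Optional output path for the signal-peptide sidecar TSV;
#'   only proteins with an annotation are written.
#' @return `fasta`, invisibly.
#' @export
write_proteome <- function(proteome, fasta, signal_tsv = NULL) {
  check_proteome(proteome)
  aa <- Biostrings::AAStringSet(proteome$sequence)
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  names(aa) <- trimws(paste(proteome$protein_id, desc))
  Biostrings::writeXStringSet(aa, fasta)
  if (!is.null(signal_tsv) && "signal_peptide_end" %in% names(proteome)) {
    sp <- proteome[!is.na(proteome$signal_peptide_end),
                   c("protein_id", "signal_peptide_end")]
    write_tsv_commented(sp, signal_tsv)
  }
  invisible(fasta)
}

write_tsv_commented <- function(tbl, path, comment = COORD_COMMENT) {
  body <- readr::format_tsv(tbl, na = "")
  writeLines(c(comment, sub("\n$", "", body)), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write peptide quantification tables
#'
#' TSV with columns `protein_id`, `start`, `end`, `sequence`, `mod_label`,
#' `charge` followed by one numeric intensity column per channel (empty field
#' = missing). `read_peptide_table()` reports a schema error naming any
#' missing required column and a row error (with the file line number) for
#' non-numeric intensities.
#'
#' @param path File path.
#' @param channels Optional character vector naming the expected channel
#'   columns; by default every column after the six identifying ones is
#'   treated as a channel.
#' @return A peptide quant tibble.
#' @export
read_peptide_table <- function(path, channels = NULL) {
  raw <- readr::read_tsv(path, comment = "#", na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("protein_id", "start", "end", "sequence", "mod_label", "charge")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("peptide table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "dppsubs_error_schema")
  }
  if (is.null(channels)) channels <- setdiff(names(raw), c(need, "role"))
  out <- raw
  for (col in c("start", "end", "charge")) out[[col]] <- as.integer(raw[[col]])
  for (col in channels) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(num))
    if (length(bad) > 0) {
      rlang::abort(paste0("non-numeric intensity in column `", col,
                          "`, data row(s): ", paste(head(bad, 5), collapse = ", ")),
                   class = "dppsubs_error_row")
    }
    out[[col]] <- num
  }
  out
}

#' @rdname read_peptide_table
#' @param rows Peptide quant tibble to write.
#' @export
write_peptide_table <- function(rows, path) {
  write_tsv_commented(rows, path)
}

#' Read a protein-group LFQ table
#'
#' The native dialect uses columns `protein_id`, logical `reverse`,
#' `contaminant`, `only_by_site`, and one numeric log2-intensity column per
#' sample. The `"maxquant"` dialect adapts a MaxQuant proteinGroups export:
#' flag columns `Reverse`, `Potential contaminant`, `Only identified by site`
#' marked `"+"`, sample intensities in `LFQ intensity <sample>` columns
#' (log2-transformed on read; 0 = missing), and the protein id taken from
#' `Majority protein IDs` (first entry) or `Protein IDs`.
#'
#' @param path File path.
#' @param dialect `"dppsubs"` (default) or `"maxquant"`.
#' @return A protein-group tibble in the native schema.
#' @export
read_protein_groups <- function(path, dialect = c("dppsubs", "maxquant")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, comment = if (dialect == "dppsubs") "#" else "",
                         na = c("", "NA"), progress = FALSE,
                         col_types = readr::cols())
  if (dialect == "dppsubs") {
    need <- c("protein_id", "reverse", "contaminant", "only_by_site")
    missing_cols <- setdiff(need, names(raw))
    stop_if(length(missing_cols) > 0,
            paste0("protein-group table missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    for (f in c("reverse", "contaminant", "only_by_site")) {
      raw[[f]] <- raw[[f]] %in% c(TRUE, "TRUE", "+")
    }
    return(raw)
  }
  id_col <- intersect(c("Majority protein IDs", "Protein IDs"), names(raw))[1]
  stop_if(is.na(id_col), "no protein id column found in MaxQuant table")
  lfq_cols <- grep("^LFQ intensity ", names(raw), value = TRUE)
  stop_if(length(lfq_cols) == 0, "no `LFQ intensity` columns found")
  out <- tibble::tibble(
    protein_id = sub(";.*$", "", raw[[id_col]]),
    reverse = !is.na(raw[["Reverse"]]) & raw[["Reverse"]] == "+",
    contaminant = !is.na(raw[["Potential contaminant"]]) &
      raw[["Potential contaminant"]] == "+",
    only_by_site = !is.na(raw[["Only identified by site"]]) &
      raw[["Only identified by site"]] == "+")
  for (col in lfq_cols) {
    v <- as.numeric(raw[[col]])
    v[!is.na(v) & v == 0] <- NA_real_
    out[[sub("^LFQ intensity ", "", col)]] <- log2(v)
  }
  out
}

#' Read and write in-vitro digestion time courses
#'
#' TSV with columns `peptide_id`, `enzyme_label`, `time_min`, `replicate`,
#' `intensity`.
#'
#' @param path File path.
#' @return A long time-course tibble.
#' @export
read_timecourse <- function(path) {
  tc <- readr::read_tsv(path, comment = "#", na = c("", "NA"),
                        progress = FALSE,
                        col_types = readr::cols(
                          peptide_id = readr::col_character(),
                          enzyme_label = readr::col_character(),
                          time_min = readr::col_double(),
                          replicate = readr::col_integer(),
                          intensity = readr::col_double()))
  need <- c("peptide_id", "enzyme_label", "time_min", "replicate", "intensity")
  missing_cols <- setdiff(need, names(tc))
  stop_if(length(missing_cols) > 0,
          paste0("time-course table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  tc
}

#' @rdname read_timecourse
#' @param tc Time-course tibble to write.
#' @export
write_timecourse <- function(tc, path) {
  write_tsv_commented(tc, path, comment = "# time_min: reaction time in minutes")
}

#' Write the cleavage-candidate table
#'
#' @param candidates Candidate tibble from [build_candidate_table()] or
#'   `tidy()` of a `substrate_calls` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  write_tsv_commented(candidates, path)
}

#' Write a volcano table
#'
#' @param volcano Volcano tibble (from `tidy()` of an `ipms_fit`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_volcano <- function(volcano, path) {
  write_tsv_commented(volcano, path,
                      comment = "# diff: mean log2 difference (bait - control)")
}
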