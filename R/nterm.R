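# Expected mature N-terminus annotation, in-silico semi-specific digestion,
# dipeptidyl cleavage arithmetic and P-position annotation.
# Coordinates: 1-based inclusive residue indices, initiator Met = 1.

#' Annotate the expected mature N-terminus of each protein
#'
#' Determines where the mature (post-processing) N-terminus of each protein is
#' expected, applying two co-translational rules in order of precedence:
#'
#' 1. **Signal peptide**: if `signal_peptide_end` is annotated, the signal
#'    peptide is removed and the mature N-terminus starts at
#'    `signal_peptide_end + 1`.
#' 2. **Initiator-Met excision**: if residue 1 is Met and residue 2 is one of
#'    Gly, Ala, Ser, Thr, Cys, Pro or Val, Met1 is excised and the mature
#'    N-terminus is residue 2.
#'
#' Otherwise the mature N-terminus is residue 1. Exactly one rule fires per
#' protein. `X` or any residue outside the excision set at position 2 leaves
#' the annotated start unchanged.
#'
#' @param proteome A data frame with columns `protein_id`, `sequence` and
#'   optionally `signal_peptide_end` (1-based inclusive index of the last
#'   signal-peptide residue; `NA` when absent).
#' @return A tibble with columns `protein_id`, `start` (1-based mature start)
#'   and `rule` (`"signal_peptide"`, `"imet_excision"` or `"none"`).
#' @examples
#' prot <- tibble::tibble(protein_id = "P1", sequence = "MVTAQLK")
#' mature_nterm(prot) # initiator-Met excision: start = 2
#' @export
mature_nterm <- function(proteome) {
  check_proteome(proteome)
  sp <- if ("signal_peptide_end" %in% names(proteome)) {
    as.integer(proteome$signal_peptide_end)
  } else {
    rep(NA_integer_, nrow(proteome))
  }
  len <- nchar(proteome$sequence)
  bad <- !is.na(sp) & (sp < 1L | sp >= len)
  if (any(bad)) {
    rlang::abort(
      paste0("invalid signal-peptide annotation (must satisfy 1 <= end < protein length) for: ",
             paste(proteome$protein_id[bad], collapse = ", ")),
      class = "dppsubs_error_annotation")
  }
  res2 <- substr(proteome$sequence, 2L, 2L)
  imet <- substr(proteome$sequence, 1L, 1L) == "M" & res2 %in% IMET_EXCISION_SET
  rule <- dplyr::case_when(!is.na(sp) ~ "signal_peptide",
                           imet ~ "imet_excision",
                           TRUE ~ "none")
  start <- dplyr::case_when(rule == "signal_peptide" ~ sp + 1L,
                            rule == "imet_excision" ~ 2L,
                            TRUE ~ 1L)
  tibble::tibble(protein_id = proteome$protein_id, start = start, rule = rule)
}

check_proteome <- function(proteome) {
  stop_if(!is.data.frame(proteome) ||
            !all(c("protein_id", "sequence") %in% names(proteome)),
          "`proteome` must be a data frame with columns `protein_id` and `sequence`")
  stop_if(any(nchar(proteome$sequence) < 1L), "protein sequences must have length >= 1")
  stop_if(anyDuplicated(proteome$protein_id) > 0L, "`protein_id` values must be unique")
}

#' Enumerate digestion peptides (fully and semi-specific)
#'
#' Enumerates all peptides compatible with the digestion parameters: fully
#' specific peptides (both termini at protease cleavage sites or protein
#' termini, with at most `max_missed_cleavages` internal sites) and, when
#' `semi_specific` is `TRUE`, all peptides with exactly one specific terminus
#' (the other terminus arising e.g. from in-vivo proteolysis). Results are
#' filtered by the length window and deduplicated by span.
#'
#' @inheritParams mature_nterm
#' @param params A [digest_params()] object.
#' @return A tibble with columns `protein_id`, `start`, `end`, `sequence`,
#'   `length` and `specificity` (`"full"`, `"semi_nterm"` = only the
#'   N-terminus is specific, `"semi_cterm"` = only the C-terminus).
#' @export
digest_semi <- function(proteome, params = digest_params()) {
  check_proteome(proteome)
  out <- purrr::map2(proteome$protein_id, proteome$sequence,
                     digest_one, params = params)
  empty <- tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), sequence = character(),
                          length = integer(), specificity = character())
  dplyr::bind_rows(empty, out)
}

digest_one <- function(protein_id, sequence, params) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  is_site <- chars %in% params$cleave_after
  if (params$block_proline && n > 1L) {
    blocked <- c(chars[-1] == "P", FALSE)
    is_site <- is_site & !blocked
  }
  sites <- which(is_site)
  # S[k+1] = number of sites at positions <= k; missed(a, b) = sites in [a, b-1]
  S <- c(0L, cumsum(is_site))
  missed <- function(a, b) S[b] - S[a]

  starts_spec <- unique(c(1L, sites + 1L))
  starts_spec <- starts_spec[starts_spec <= n]
  ends_spec <- unique(c(sites, n))

  cand_a <- integer(0)
  cand_b <- integer(0)
  # N-terminus specific: any end within the length window
  for (a in starts_spec) {
    lo <- a + params$min_length - 1L
    hi <- min(a + params$max_length - 1L, n)
    if (lo > hi) next
    b <- seq.int(lo, hi)
    cand_a <- c(cand_a, rep.int(a, length(b)))
    cand_b <- c(cand_b, b)
  }
  # C-terminus specific: any start within the length window
  for (b in ends_spec) {
    lo <- max(b - params$max_length + 1L, 1L)
    hi <- b - params$min_length + 1L
    if (hi < lo) next
    a <- seq.int(lo, hi)
    cand_a <- c(cand_a, a)
    cand_b <- c(cand_b, rep.int(b, length(a)))
  }
  if (length(cand_a) == 0L) return(NULL)
  spans <- unique(data.frame(a = cand_a, b = cand_b))
  len <- spans$b - spans$a + 1L
  keep <- len >= params$min_length & len <= params$max_length &
    mapply(missed, spans$a, spans$b) <= params$max_missed_cleavages
  spans <- spans[keep, , drop = FALSE]
  if (nrow(spans) == 0L) return(NULL)
  n_spec <- spans$a %in% starts_spec
  c_spec <- spans$b %in% ends_spec
  if (!params$semi_specific) {
    full_only <- n_spec & c_spec
    spans <- spans[full_only, , drop = FALSE]
    n_spec <- n_spec[full_only]
    c_spec <- c_spec[full_only]
    if (nrow(spans) == 0L) return(NULL)
  }
  spec <- dplyr::case_when(n_spec & c_spec ~ "full",
                           n_spec ~ "semi_nterm",
                           TRUE ~ "semi_cterm")
  ord <- order(spans$a, spans$b)
  tibble::tibble(protein_id = protein_id,
                 start = as.integer(spans$a[ord]),
                 end = as.integer(spans$b[ord]),
                 sequence = substring(sequence, spans$a[ord], spans$b[ord]),
                 length = as.integer(spans$b[ord] - spans$a[ord] + 1L),
                 specificity = spec[ord])
}

#' Apply dipeptidyl cleavage cycles to peptide spans
#'
#' A dipeptidyl peptidase removes one dipeptide per cycle from the free
#' N-terminus of its substrate: each cycle shifts the span start by +2
#' residues and shortens the peptide by exactly 2 residues, leaving the end
#' unchanged.
#'
#' @param spans A data frame with columns `start`, `end` and optionally
#'   `sequence` (updated when present).
#' @param cycles Positive integer number of dipeptide removals (default 1).
#' @return `spans` with `start` advanced by `2 * cycles` (and `sequence`
#'   trimmed accordingly).
#' @export
dipeptidyl_cleave <- function(spans, cycles = 1L) {
  stop_if(!is.data.frame(spans) || !all(c("start", "end") %in% names(spans)),
          "`spans` must be a data frame with columns `start` and `end`")
  cycles <- as.integer(cycles)
  stop_if(is.na(cycles) || cycles < 1L, "`cycles` must be a positive integer")
  len <- spans$end - spans$start + 1L
  short <- len < 2L * cycles + 1L
  if (any(short)) {
    rlang::abort(
      paste0("span too short for ", cycles, " dipeptidyl cleavage cycle(s): ",
             "need length >= ", 2L * cycles + 1L, " but got ",
             paste(len[short], collapse = ", ")),
      class = "dppsubs_error_precondition")
  }
  spans$start <- spans$start + 2L * cycles
  if ("sequence" %in% names(spans)) {
    spans$sequence <- substring(spans$sequence, 2L * cycles + 1L)
  }
  if ("length" %in% names(spans)) {
    spans$length <- spans$end - spans$start + 1L
  }
  tibble::as_tibble(spans)
}

#' Classify peptide origin relative to the mature N-terminus
#'
#' A peptide starting exactly at the expected mature N-terminus is an
#' `nterm_substrate` (the intact protein N-terminus); a peptide starting a
#' positive even number of residues downstream (up to `max_cycles` dipeptide
#' steps) is an `nterm_product` of sequential dipeptidyl processing; anything
#' else -- including odd offsets -- is `internal`.
#'
#' @param spans A data frame with columns `protein_id` and `start`.
#' @param mature Output of [mature_nterm()] for the same proteome.
#' @param max_cycles Maximum number of dipeptide removal cycles considered
#'   (default 15).
#' @return `spans` with added columns `mature_start`, `offset`
#'   (`start - mature_start`), `origin` (`"nterm_substrate"`,
#'   `"nterm_product"`, `"internal"`) and `cycles` (number of dipeptide steps
#'   for products, otherwise `NA`).
#' @export
classify_origin <- function(spans, mature, max_cycles = 15L) {
  stop_if(!is.data.frame(spans) || !all(c("protein_id", "start") %in% names(spans)),
          "`spans` must be a data frame with columns `protein_id` and `start`")
  m <- dplyr::select(mature, "protein_id", mature_start = "start")
  out <- dplyr::left_join(spans, m, by = "protein_id")
  if (anyNA(out$mature_start)) {
    missing <- unique(out$protein_id[is.na(out$mature_start)])
    rlang::abort(paste0("no mature N-terminus annotation for: ",
                        paste(missing, collapse = ", ")),
                 class = "dppsubs_error")
  }
  offset <- out$start - out$mature_start
  is_product <- offset > 0L & offset %% 2L == 0L & offset %/% 2L <= max_cycles
  out$offset <- offset
  out$origin <- dplyr::case_when(offset == 0L ~ "nterm_substrate",
                                 is_product ~ "nterm_product",
                                 TRUE ~ "internal")
  out$cycles <- ifelse(is_product, offset %/% 2L, NA_integer_)
  tibble::as_tibble(out)
}

#' Annotate P2/P1/P1' residues for substrate spans
#'
#' For a substrate peptide beginning at the mature N-terminus, the scissile
#' bond of a dipeptidyl peptidase lies C-terminal to the second residue: P2 is
#' the first residue of the span, P1 the second (cleavage occurs after it) and
#' P1' the third (the first residue of the product).
#'
#' @param spans A data frame with columns `protein_id`, `start`, `end`.
#' @param proteome Proteome data frame with `protein_id` and `sequence`.
#' @return `spans` with added character columns `P2`, `P1`, `P1prime`.
#' @examples
#' prot <- tibble::tibble(protein_id = "P1", sequence = "MVTAQLK")
#' spans <- tibble::tibble(protein_id = "P1", start = 2L, end = 7L)
#' p_positions(spans, prot) # P2 = V, P1 = T, P1' = A
#' @export
p_positions <- function(spans, proteome) {
  check_proteome(proteome)
  stop_if(!is.data.frame(spans) ||
            !all(c("protein_id", "start", "end") %in% names(spans)),
          "`spans` must be a data frame with columns `protein_id`, `start`, `end`")
  len <- spans$end - spans$start + 1L
  if (any(len < 3L)) {
    rlang::abort("P-position annotation requires span length >= 3",
                 class = "dppsubs_error_precondition")
  }
  seqs <- dplyr::select(proteome, "protein_id", .prot_seq = "sequence")
  out <- dplyr::left_join(spans, seqs, by = "protein_id")
  stop_if(anyNA(out$.prot_seq), "span references a protein absent from `proteome`")
  out$P2 <- substr(out$.prot_seq, out$start, out$start)
  out$P1 <- substr(out$.prot_seq, out$start + 1L, out$start + 1L)
  out$P1prime <- substr(out$.prot_seq, out$start + 2L, out$start + 2L)
  out$.prot_seq <- NULL
  tibble::as_tibble(out)
}
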