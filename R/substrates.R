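# Candidate calling in the two-mutant fold-change plane: quadrant
# classification, substrate-product pairing by start offset and Manhattan
# geometry, and candidate-table assembly.

#' Classify peptides into fold-change quadrants
#'
#' Assigns each peptide exactly one label from the two-mutant fold-change
#' plane:
#' * `position_filtered` -- starts beyond `max_start` in its protein;
#' * `substrate_candidate` -- up in both mutant comparisons beyond the
#'   threshold and starting at the expected mature N-terminus;
#' * `product_candidate` -- down in both comparisons beyond the threshold and
#'   starting an even number of dipeptide steps downstream;
#' * `discordant` -- the two comparisons disagree in sign while at least one
#'   exceeds the threshold;
#' * `unchanged` -- everything else.
#'
#' @param tbl A data frame with columns `start`, `fc_del`, `fc_cat` and
#'   `origin` (from [classify_origin()]).
#' @param params A [pairing_params()] object.
#' @return `tbl` with an added `label` column.
#' @export
quadrant_classify <- function(tbl, params = pairing_params()) {
  need <- c("start", "fc_del", "fc_cat", "origin")
  stop_if(!all(need %in% names(tbl)),
          paste0("`tbl` must have columns: ", paste(need, collapse = ", ")))
  stop_if(anyNA(tbl$fc_del) || anyNA(tbl$fc_cat),
          "fold changes must be finite; impute before classifying")
  thr <- params$fc_threshold
  tbl$label <- dplyr::case_when(
    tbl$start > params$max_start ~ "position_filtered",
    tbl$fc_del > thr & tbl$fc_cat > thr &
      tbl$origin == "nterm_substrate" ~ "substrate_candidate",
    tbl$fc_del < -thr & tbl$fc_cat < -thr &
      tbl$origin == "nterm_product" ~ "product_candidate",
    abs(tbl$fc_del) <= thr & abs(tbl$fc_cat) <= thr ~ "unchanged",
    sign(tbl$fc_del) != sign(tbl$fc_cat) ~ "discordant",
    TRUE ~ "unchanged")
  tibble::as_tibble(tbl)
}

member_gate <- function(fc_del, fc_cat, thr, gate) {
  if (gate == "both") {
    abs(fc_del) > thr & abs(fc_cat) > thr
  } else {
    abs(fc_del) > thr | abs(fc_cat) > thr
  }
}

#' Pair substrate and product peptides within proteins
#'
#' Emits substrate--product pairs `(s, p)` from the same protein where the
#' start offset `p$start - s$start` is an allowed dipeptide step, at least one
#' member exceeds the fold-change threshold (see `fc_gate`), the pair is
#' separated by at least `manhattan_min` in Manhattan distance over the two
#' fold-change coordinates, and (by default) the substrate member moves up
#' while the product member moves down in the mutant-vs-wildtype orientation.
#' Peptides labeled `position_filtered` (starting beyond `max_start`) never
#' join pairs. Each peptide joins at most one pair; matching is greedy by largest
#' Manhattan distance (ties broken by smaller offset, then lexicographic
#' keys) or, optionally, exhaustive.
#'
#' @param tbl Labeled peptide table with columns `key`, `protein_id`, `start`,
#'   `fc_del`, `fc_cat` (e.g. from [quadrant_classify()]).
#' @param params A [pairing_params()] object.
#' @return A tibble of pairs with member keys, starts, fold changes, the start
#'   offset and the Manhattan distance.
#' @export
pair_candidates <- function(tbl, params = pairing_params()) {
  need <- c("key", "protein_id", "start", "fc_del", "fc_cat")
  stop_if(!all(need %in% names(tbl)),
          paste0("`tbl` must have columns: ", paste(need, collapse = ", ")))
  empty <- tibble::tibble(protein_id = character(),
                          substrate_key = character(), product_key = character(),
                          substrate_start = integer(), product_start = integer(),
                          start_offset = integer(), manhattan_d = double(),
                          fc_del_sub = double(), fc_cat_sub = double(),
                          fc_del_prod = double(), fc_cat_prod = double())
  # position-filtered peptides are outside the candidate analysis entirely
  if ("label" %in% names(tbl)) {
    tbl <- tbl[tbl$label != "position_filtered", , drop = FALSE]
  }
  if (nrow(tbl) < 2L) return(empty)

  s <- dplyr::select(tbl, "protein_id", substrate_key = "key",
                     substrate_start = "start",
                     fc_del_sub = "fc_del", fc_cat_sub = "fc_cat")
  p <- dplyr::select(tbl, "protein_id", product_key = "key",
                     product_start = "start",
                     fc_del_prod = "fc_del", fc_cat_prod = "fc_cat")
  cand <- dplyr::inner_join(s, p, by = "protein_id",
                            relationship = "many-to-many")
  cand$start_offset <- cand$product_start - cand$substrate_start
  cand <- cand[cand$start_offset %in% params$allowed_offsets, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  gate <- member_gate(cand$fc_del_sub, cand$fc_cat_sub,
                      params$fc_threshold, params$fc_gate) |
    member_gate(cand$fc_del_prod, cand$fc_cat_prod,
                params$fc_threshold, params$fc_gate)
  cand <- cand[gate, , drop = FALSE]
  if (params$require_opposite_sign && nrow(cand) > 0L) {
    keep <- cand$fc_del_sub > 0 & cand$fc_cat_sub > 0 &
      cand$fc_del_prod < 0 & cand$fc_cat_prod < 0
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(empty)
  cand$manhattan_d <- abs(cand$fc_del_sub - cand$fc_del_prod) +
    abs(cand$fc_cat_sub - cand$fc_cat_prod)
  keep <- if (params$manhattan_cmp == "ge") {
    cand$manhattan_d >= params$manhattan_min
  } else {
    cand$manhattan_d <= params$manhattan_min
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  cand <- cand[order(-cand$manhattan_d, cand$start_offset,
                     cand$substrate_key, cand$product_key), , drop = FALSE]
  sel <- if (params$matching == "greedy") {
    greedy_matching(cand)
  } else {
    exhaustive_matching(cand)
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(-out$manhattan_d, out$start_offset,
                   out$substrate_key, out$product_key), , drop = FALSE]
  tibble::as_tibble(out[, names(empty)])
}

greedy_matching <- function(cand) {
  used <- character(0)
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sk <- cand$substrate_key[i]
    pk <- cand$product_key[i]
    if (!(sk %in% used) && !(pk %in% used)) {
      sel[i] <- TRUE
      used <- c(used, sk, pk)
    }
  }
  which(sel)
}

# Maximum total-Manhattan-distance one-to-one matching by branch-and-bound,
# per protein (candidate sets are small).
exhaustive_matching <- function(cand) {
  pick <- integer(0)
  for (pid in unique(cand$protein_id)) {
    idx <- which(cand$protein_id == pid)
    suffix <- rev(cumsum(rev(cand$manhattan_d[idx])))
    best <- list(score = -Inf, sel = integer(0))
    recurse <- function(i, used, sel, score) {
      if (i > length(idx)) {
        if (score > best$score) best <<- list(score = score, sel = sel)
        return(invisible(NULL))
      }
      if (score + suffix[i] <= best$score) return(invisible(NULL))
      j <- idx[i]
      sk <- cand$substrate_key[j]
      pk <- cand$product_key[j]
      if (!(sk %in% used) && !(pk %in% used)) {
        recurse(i + 1L, c(used, sk, pk), c(sel, j),
                score + cand$manhattan_d[j])
      }
      recurse(i + 1L, used, sel, score)
    }
    recurse(1L, character(0), integer(0), 0)
    pick <- c(pick, best$sel)
  }
  sort(pick)
}

#' Assemble the cleavage-candidate table
#'
#' One record per substrate--product pair plus one per unpaired
#' `substrate_candidate` or `product_candidate`. P2/P1/P1' residues are read
#' from the proteome at the (inferred) substrate start: the substrate member's
#' start for pairs and substrate singletons, `start - 2` for product
#' singletons. Candidates whose P positions fall outside the protein are
#' flagged (`p_ok = FALSE`), never dropped. `evidence_score` is the maximum
#' over members of `min(|fc_del|, |fc_cat|)`; output is sorted paired-first,
#' then by descending score.
#'
#' @param pairs Output of [pair_candidates()].
#' @param labeled Labeled peptide table from [quadrant_classify()] (must carry
#'   `key`, `protein_id`, `start`, `end`, `fc_del`, `fc_cat`, `label`).
#' @param proteome Proteome data frame with `protein_id` and `sequence`.
#' @return A tibble, one row per cleavage candidate.
#' @export
build_candidate_table <- function(pairs, labeled, proteome) {
  check_proteome(proteome)
  ends <- dplyr::select(labeled, "key", .end = "end")
  paired <- NULL
  if (nrow(pairs) > 0L) {
    paired <- pairs
    paired$substrate_end <- ends$.end[match(paired$substrate_key, ends$key)]
    paired$product_end <- ends$.end[match(paired$product_key, ends$key)]
    paired$paired <- TRUE
    paired$inferred_substrate_start <- paired$substrate_start
    paired$evidence_score <- pmax(
      pmin(abs(paired$fc_del_sub), abs(paired$fc_cat_sub)),
      pmin(abs(paired$fc_del_prod), abs(paired$fc_cat_prod)))
  }

  in_pair <- unique(c(pairs$substrate_key, pairs$product_key))
  singles <- labeled[labeled$label %in% c("substrate_candidate", "product_candidate") &
                       !(labeled$key %in% in_pair), , drop = FALSE]
  single_rec <- NULL
  if (nrow(singles) > 0L) {
    is_sub <- singles$label == "substrate_candidate"
    single_rec <- tibble::tibble(
      protein_id = singles$protein_id,
      substrate_key = ifelse(is_sub, singles$key, NA_character_),
      product_key = ifelse(is_sub, NA_character_, singles$key),
      substrate_start = ifelse(is_sub, singles$start, NA_integer_),
      product_start = ifelse(is_sub, NA_integer_, singles$start),
      start_offset = NA_integer_,
      manhattan_d = NA_real_,
      fc_del_sub = ifelse(is_sub, singles$fc_del, NA_real_),
      fc_cat_sub = ifelse(is_sub, singles$fc_cat, NA_real_),
      fc_del_prod = ifelse(is_sub, NA_real_, singles$fc_del),
      fc_cat_prod = ifelse(is_sub, NA_real_, singles$fc_cat),
      substrate_end = ifelse(is_sub, singles$end, NA_integer_),
      product_end = ifelse(is_sub, NA_integer_, singles$end),
      paired = FALSE,
      inferred_substrate_start = ifelse(is_sub, singles$start,
                                        singles$start - 2L),
      evidence_score = pmin(abs(singles$fc_del), abs(singles$fc_cat)))
  }

  out <- dplyr::bind_rows(paired, single_rec)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(protein_id = character(), paired = logical(),
                          substrate_start = integer(), substrate_end = integer(),
                          product_start = integer(), product_end = integer(),
                          inferred_substrate_start = integer(),
                          P2 = character(), P1 = character(), P1prime = character(),
                          p_ok = logical(),
                          fc_del_sub = double(), fc_cat_sub = double(),
                          fc_del_prod = double(), fc_cat_prod = double(),
                          manhattan_d = double(), evidence_score = double()))
  }
  seqs <- stats::setNames(proteome$sequence, proteome$protein_id)
  pseq <- unname(seqs[out$protein_id])
  a <- out$inferred_substrate_start
  out$p_ok <- !is.na(pseq) & !is.na(a) & a >= 1L & (a + 2L) <= nchar(pseq)
  out$P2 <- ifelse(out$p_ok, substr(pseq, a, a), NA_character_)
  out$P1 <- ifelse(out$p_ok, substr(pseq, a + 1L, a + 1L), NA_character_)
  out$P1prime <- ifelse(out$p_ok, substr(pseq, a + 2L, a + 2L), NA_character_)
  out <- out[order(-out$paired, -out$evidence_score, out$protein_id), , drop = FALSE]
  cols <- c("protein_id", "paired", "substrate_start", "substrate_end",
            "product_start", "product_end", "inferred_substrate_start",
            "P2", "P1", "P1prime", "p_ok",
            "fc_del_sub", "fc_cat_sub", "fc_del_prod", "fc_cat_prod",
            "manhattan_d", "evidence_score")
  tibble::as_tibble(out[, cols])
}

#' Call protease substrates from a TAILS peptide quant table
#'
#' End-to-end candidate discovery: normalizes and imputes the reporter matrix,
#' computes mutant-vs-wildtype fold changes, annotates each peptide's origin
#' relative to the expected mature N-terminus, classifies fold-change
#' quadrants, pairs substrate and product peptides and assembles the
#' candidate table.
#'
#' Peptides detected exclusively on one side of a comparison (at least one
#' channel there, none on the other side) carry more information than their
#' imputed fold change conveys; such detected-only rows have their log2 fold change
#' recorded as `+/- absent_fc` (a documented finite cap) before
#' classification. Set `absent_fc = NULL` to disable.
#'
#' @inheritParams peptide_fold_changes
#' @param proteome Proteome data frame (`protein_id`, `sequence`, optional
#'   `signal_peptide_end`).
#' @param pairing A [pairing_params()] object.
#' @param max_cycles Maximum dipeptide removal cycles for origin
#'   classification (default 15).
#' @param absent_fc Finite log2 fold change assigned to detected-only rows
#'   (default 10); `NULL` disables the rule.
#' @param exclude_nterm_acetyl If `TRUE`, peptides whose `mod_label` contains
#'   "acetyl" (case-insensitive) are removed before analysis (their N-termini
#'   are blocked co-translationally, not by the protease); default `FALSE`.
#' @return An object of class `substrate_calls`: a list with `candidates`
#'   (the cleavage-candidate tibble), `pairs`, `peptides` (the labeled
#'   per-peptide table) and the parameters used. [tidy()] returns the
#'   candidate table, [glance()] a one-row summary.
#' @export
call_substrates <- function(rows, proteome, design = default_channel_design(),
                            pairing = pairing_params(),
                            impute = impute_params(), max_cycles = 15L,
                            fc_mode = c("imputed", "observed"),
                            absent_fc = 10, exclude_nterm_acetyl = FALSE) {
  fc_mode <- match.arg(fc_mode)
  if (isTRUE(exclude_nterm_acetyl)) {
    rows <- rows[!grepl("acetyl", rows$mod_label, ignore.case = TRUE), ,
                 drop = FALSE]
  }
  fc <- peptide_fold_changes(rows, design = design, impute = impute,
                             fc_mode = fc_mode)
  if (!is.null(absent_fc)) {
    stop_if(!(absent_fc > 0), "`absent_fc` must be positive or NULL")
    for (col in grep("^detect_", names(fc), value = TRUE)) {
      fc_col <- sub("^detect", "fc", col)
      fc[[fc_col]] <- dplyr::case_when(
        fc[[col]] == "mutant_only" ~ absent_fc,
        fc[[col]] == "wildtype_only" ~ -absent_fc,
        TRUE ~ fc[[fc_col]])
    }
  }
  mature <- mature_nterm(proteome)
  fc <- classify_origin(fc, mature, max_cycles = max_cycles)
  labeled <- quadrant_classify(fc, pairing)
  pairs <- pair_candidates(labeled, pairing)
  candidates <- build_candidate_table(pairs, labeled, proteome)
  structure(list(candidates = candidates, pairs = pairs, peptides = labeled,
                 pairing = pairing, impute = impute, fc_mode = fc_mode,
                 absent_fc = absent_fc, max_cycles = max_cycles),
            class = "substrate_calls")
}

#' @export
print.substrate_calls <- function(x, ...) {
  cat("<substrate_calls>\n")
  cat("  peptides analyzed: ", nrow(x$peptides), "\n", sep = "")
  cat("  substrate-product pairs: ", nrow(x$pairs), "\n", sep = "")
  cat("  cleavage candidates: ", nrow(x$candidates),
      " (", sum(x$candidates$paired), " paired)\n", sep = "")
  invisible(x)
}

#' @rdname call_substrates
#' @param x A `substrate_calls` object.
#' @param ... Unused.
#' @export
tidy.substrate_calls <- function(x, ...) {
  x$candidates
}

#' @rdname call_substrates
#' @export
glance.substrate_calls <- function(x, ...) {
  tibble::tibble(n_peptides = nrow(x$peptides),
                 n_pairs = nrow(x$pairs),
                 n_candidates = nrow(x$candidates),
                 n_substrate_candidates =
                   sum(x$peptides$label == "substrate_candidate"),
                 n_product_candidates =
                   sum(x$peptides$label == "product_candidate"),
                 fc_threshold = x$pairing$fc_threshold,
                 manhattan_min = x$pairing$manhattan_min)
}

#' Score candidate calls against simulation ground truth
#'
#' Sensitivity is the fraction of true substrates recovered by any candidate
#' record (pair or singleton) whose inferred substrate start matches the true
#' cleavage site; the false-pair fraction is the proportion of emitted pairs
#' that do not correspond to a true substrate at the true site.
#'
#' @param calls A `substrate_calls` object (or its candidate tibble).
#' @param truth Ground-truth tibble with columns `protein_id` and
#'   `mature_start` (e.g. from [simulate_proteome()]).
#' @return A one-row tibble: `n_truth`, `n_candidates`, `n_pairs`,
#'   `n_recovered`, `sensitivity`, `n_false_pairs`, `false_pair_fraction`.
#' @export
evaluate_recovery <- function(calls, truth) {
  cand <- if (inherits(calls, "substrate_calls")) calls$candidates else calls
  stop_if(!all(c("protein_id", "mature_start") %in% names(truth)),
          "`truth` must have columns `protein_id` and `mature_start`")
  truth_key <- paste(truth$protein_id, truth$mature_start)
  cand_key <- paste(cand$protein_id, cand$inferred_substrate_start)
  recovered <- truth_key %in% cand_key
  pair_rows <- cand[cand$paired, , drop = FALSE]
  pair_key <- paste(pair_rows$protein_id, pair_rows$inferred_substrate_start)
  false_pairs <- sum(!(pair_key %in% truth_key))
  tibble::tibble(n_truth = nrow(truth),
                 n_candidates = nrow(cand),
                 n_pairs = nrow(pair_rows),
                 n_recovered = sum(recovered),
                 sensitivity = ifelse(nrow(truth) > 0,
                                      sum(recovered) / nrow(truth), NA_real_),
                 n_false_pairs = false_pairs,
                 false_pair_fraction = ifelse(nrow(pair_rows) > 0,
                                              false_pairs / nrow(pair_rows), 0))
}
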