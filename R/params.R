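# Parameter constructors. All coordinates in this package are 1-based inclusive
# residue indices with the initiator Met at position 1.

stop_if <- function(cond, msg, class = "dppsubs_error") {
  if (isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(NULL)
}

#' Digestion parameters
#'
#' Controls in-silico digestion. The defaults describe Arg-C-like specificity
#' (cleavage C-terminal to Arg) with at most one missed cleavage and a
#' detectability length window of 7--40 residues, the regime in which TAILS
#' peptides are typically identified. Proline blocking (no cleavage before Pro)
#' is off by default and available as a flag.
#'
#' @param cleave_after Character vector of residues after which the protease
#'   cleaves (default `"R"`).
#' @param max_missed_cleavages Maximum number of internal (missed) cleavage
#'   sites tolerated inside a peptide (default 1).
#' @param min_length,max_length Peptide length window in residues (defaults 7
#'   and 40).
#' @param semi_specific If `TRUE` (default), peptides with exactly one
#'   protease-generated terminus are enumerated in addition to fully specific
#'   peptides.
#' @param block_proline If `TRUE`, a site followed by Pro is not cleaved
#'   (default `FALSE`).
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(cleave_after = "R", max_missed_cleavages = 1L,
                          min_length = 7L, max_length = 40L,
                          semi_specific = TRUE, block_proline = FALSE) {
  stop_if(min_length < 1, "`min_length` must be >= 1")
  stop_if(max_missed_cleavages < 0, "`max_missed_cleavages` must be >= 0")
  stop_if(max_length < min_length, "`max_length` must be >= `min_length`")
  stop_if(length(cleave_after) < 1, "`cleave_after` must name at least one residue")
  structure(list(cleave_after = toupper(cleave_after),
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 semi_specific = isTRUE(semi_specific),
                 block_proline = isTRUE(block_proline)),
            class = "digest_params")
}

#' MinProb imputation parameters
#'
#' Missing (non-detected) reporter values are drawn per channel from
#' `Normal(center, sd)` where `center` is the `q`-quantile of the observed
#' values in that channel and `sd` is `sd_scale` times their standard
#' deviation, modelling detection-limited (left-censored) missingness.
#'
#' @param q Quantile of the observed values used as the imputation center
#'   (default 0.01).
#' @param sd_scale Multiplier on the observed standard deviation (default 0.3).
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A list of class `impute_params`.
#' @export
impute_params <- function(q = 0.01, sd_scale = 0.3, seed = 1L) {
  stop_if(!(q > 0 && q < 0.5), "`q` must lie in (0, 0.5)")
  stop_if(!(sd_scale > 0), "`sd_scale` must be > 0")
  stop_if(is.null(seed) || is.na(seed), "`seed` is mandatory")
  structure(list(q = q, sd_scale = sd_scale, seed = as.integer(seed)),
            class = "impute_params")
}

#' Substrate/product pairing parameters
#'
#' The geometry of the two-mutant fold-change plane used for candidate calling
#' and substrate--product pairing: candidates must exceed `fc_threshold`
#' (absolute log2 units) in both mutant-vs-wildtype comparisons, peptide pairs
#' must start `allowed_offsets` residues apart (one dipeptide step = 2), be
#' separated by a Manhattan distance of at least `manhattan_min` in fold-change
#' space, and (by default) move in opposite directions: substrates accumulate
#' in protease-deficient mutants while products are enriched in wild-type.
#'
#' @param fc_threshold Absolute log2 fold-change threshold (default 2).
#' @param max_start Peptides starting beyond this residue index in their
#'   protein are position-filtered from candidacy (default 50).
#' @param manhattan_min Minimum Manhattan separation of a pair in
#'   (fc_del, fc_cat) space, log2 units (default 4).
#' @param allowed_offsets Allowed start differences (product start minus
#'   substrate start) in residues; positive even integers (default 2).
#' @param require_opposite_sign If `TRUE` (default) the substrate member must
#'   move up and the product member down in the mutant-vs-wildtype orientation.
#' @param manhattan_cmp `"ge"` (default) keeps pairs with distance
#'   `>= manhattan_min`; `"le"` implements the alternative reading
#'   (`<= manhattan_min`).
#' @param fc_gate `"both"` (default) requires at least one pair member to
#'   exceed `fc_threshold` in both comparisons; `"either"` requires only one
#'   comparison.
#' @param matching `"greedy"` (default) one-to-one matching by descending
#'   Manhattan distance (ties: smaller offset, then lexicographic keys);
#'   `"exhaustive"` maximizes the total Manhattan distance over all
#'   one-to-one matchings.
#' @return A list of class `pairing_params`.
#' @export
pairing_params <- function(fc_threshold = 2, max_start = 50L, manhattan_min = 4,
                           allowed_offsets = 2L, require_opposite_sign = TRUE,
                           manhattan_cmp = c("ge", "le"),
                           fc_gate = c("both", "either"),
                           matching = c("greedy", "exhaustive")) {
  stop_if(!(fc_threshold > 0), "`fc_threshold` must be > 0")
  stop_if(manhattan_min < 0, "`manhattan_min` must be >= 0")
  offs <- as.integer(allowed_offsets)
  stop_if(any(offs <= 0L) || any(offs %% 2L != 0L),
          "`allowed_offsets` must be positive even integers (dipeptide steps)")
  structure(list(fc_threshold = fc_threshold, max_start = as.integer(max_start),
                 manhattan_min = manhattan_min, allowed_offsets = offs,
                 require_opposite_sign = isTRUE(require_opposite_sign),
                 manhattan_cmp = match.arg(manhattan_cmp),
                 fc_gate = match.arg(fc_gate),
                 matching = match.arg(matching)),
            class = "pairing_params")
}

#' Permutation-test parameters for IP-MS enrichment
#'
#' Parameters of the S0-moderated two-sample statistic and its permutation
#' false-discovery-rate calibration, plus the Gaussian-downshift imputation
#' applied to protein-group tables before testing.
#'
#' @param s0 Non-negative variance offset added to the pooled standard error in
#'   the denominator of the statistic (default 2).
#' @param fdr_target Target permutation FDR in (0, 1) (default 0.05).
#' @param n_permutations Number of random group relabelings requested
#'   (default 250). If fewer distinct relabelings exist, all are used with a
#'   warning.
#' @param seed Integer seed for relabeling sampling and imputation.
#' @param impute_width,impute_downshift Gaussian-downshift imputation: missing
#'   values are drawn from `Normal(mean - downshift * sd, width * sd)` computed
#'   per sample over observed values (defaults 0.3 and 1.8).
#' @param estimator `"mean"` (default): FDR(t) uses the add-one-corrected mean
#'   permutation exceedance `((1 + B) / (P + 1)) / m`; `"median"`: the median
#'   across relabelings of the per-relabeling exceedance count, divided by `m`.
#' @return A list of class `perm_test_params`.
#' @seealso [perm_preset_strict()], [perm_preset_permissive()]
#' @export
perm_test_params <- function(s0 = 2, fdr_target = 0.05, n_permutations = 250L,
                             seed = 1L, impute_width = 0.3,
                             impute_downshift = 1.8,
                             estimator = c("mean", "median")) {
  stop_if(s0 < 0, "`s0` must be >= 0")
  stop_if(!(fdr_target > 0 && fdr_target < 1), "`fdr_target` must lie in (0, 1)")
  stop_if(n_permutations < 25, "`n_permutations` must be >= 25")
  structure(list(s0 = s0, fdr_target = fdr_target,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), impute_width = impute_width,
                 impute_downshift = impute_downshift,
                 estimator = match.arg(estimator)),
            class = "perm_test_params")
}

#' @rdname perm_test_params
#' @param ... Overrides passed on to [perm_test_params()].
#' @export
perm_preset_strict <- function(...) {
  perm_test_params(s0 = 2, fdr_target = 0.05, ...)
}

#' @rdname perm_test_params
#' @export
perm_preset_permissive <- function(...) {
  perm_test_params(s0 = 1.22, fdr_target = 0.1, ...)
}
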