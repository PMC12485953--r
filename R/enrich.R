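# IP-MS differential enrichment: protein-group filtering, Gaussian-downshift
# imputation, S0-moderated two-sample statistic, permutation FDR, volcano.

#' Filter flagged protein groups
#'
#' Removes rows flagged as reversed (decoy) hits, potential contaminants, or
#' identified only by a modification site; row order is otherwise preserved.
#'
#' @param tbl Protein-group tibble with logical columns `reverse`,
#'   `contaminant`, `only_by_site` (see [read_protein_groups()]).
#' @return The filtered tibble.
#' @export
filter_protein_groups <- function(tbl) {
  flags <- c("reverse", "contaminant", "only_by_site")
  stop_if(!all(flags %in% names(tbl)),
          paste0("`tbl` must have logical columns: ",
                 paste(flags, collapse = ", ")))
  drop <- (tbl$reverse %in% TRUE) | (tbl$contaminant %in% TRUE) |
    (tbl$only_by_site %in% TRUE)
  tibble::as_tibble(tbl[!drop, , drop = FALSE])
}

#' Gaussian-downshift imputation of missing log2 intensities
#'
#' Per sample (column), missing values are drawn from
#' `Normal(mean_obs - downshift * sd_obs, width * sd_obs)`, simulating signals
#' of low-abundance proteins near the detection limit. Observed values are
#' untouched; identical seeds give identical output.
#'
#' @param x Numeric matrix of log2 intensities (`NA` = missing), samples in
#'   columns.
#' @param width,downshift Width and downshift of the imputation distribution
#'   in units of the per-sample standard deviation (defaults 0.3 and 1.8).
#' @param seed Integer seed.
#' @return The matrix with all `NA` cells imputed.
#' @export
impute_gaussian_downshift <- function(x, width = 0.3, downshift = 1.8,
                                      seed = 1L) {
  x <- as.matrix(x)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 3L)) {
    bad <- colnames(x)[n_obs < 3L]
    if (is.null(bad)) bad <- which(n_obs < 3L)
    rlang::abort(paste0("sample(s) with fewer than 3 observed values: ",
                        paste(bad, collapse = ", ")),
                 class = "dppsubs_error_input")
  }
  if (!anyNA(x)) return(x)
  ord <- canonical_row_order(x)
  x <- x[ord, , drop = FALSE]
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (!any(miss)) next
      obs <- x[!miss, j]
      x[miss, j] <- stats::rnorm(sum(miss),
                                 mean = mean(obs) - downshift * stats::sd(obs),
                                 sd = width * stats::sd(obs))
    }
  })
  x[order(ord), , drop = FALSE]
}

#' S0-moderated two-sample statistic
#'
#' `d = (mean(a) - mean(b)) / (se + s0)` where `se` is the pooled two-sample
#' standard error of the Student t-test and `s0` a non-negative variance
#' offset that de-emphasizes small-variance, small-effect features. With
#' `s0 = 0`, `d` equals the classical equal-variance two-sample t statistic.
#'
#' @param a,b Numeric vectors of at least two values each.
#' @param s0 Non-negative variance offset (default 0).
#' @return The statistic (a single number).
#' @export
s0_statistic <- function(a, b, s0 = 0) {
  stop_if(length(a) < 2L || length(b) < 2L,
          "both groups need at least 2 values")
  stop_if(s0 < 0, "`s0` must be >= 0")
  se <- pooled_se(matrix(a, nrow = 1), matrix(b, nrow = 1))
  if (se == 0 && s0 == 0) {
    rlang::abort("zero variance in both groups with s0 = 0: statistic undefined",
                 class = "dppsubs_error_input")
  }
  (mean(a) - mean(b)) / (se + s0)
}

# Row-wise pooled standard error for matrices (proteins x samples per group).
pooled_se <- function(A, B) {
  nA <- ncol(A)
  nB <- ncol(B)
  vA <- matrixStats_rowVars(A)
  vB <- matrixStats_rowVars(B)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  sqrt(sp2 * (1 / nA + 1 / nB))
}

matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

row_d_stat <- function(x, idxA, idxB, s0) {
  A <- x[, idxA, drop = FALSE]
  B <- x[, idxB, drop = FALSE]
  unname((rowMeans(A) - rowMeans(B)) / (pooled_se(A, B) + s0))
}

# Distinct group-A index sets (columns of combn) excluding the observed
# assignment and, for equal group sizes, its mirror image: both reproduce the
# observed statistics and carry no information about the null.
relabelings <- function(n, idxA, n_permutations, seed) {
  all_assign <- utils::combn(n, length(idxA))
  obs <- sort(idxA)
  is_obs <- apply(all_assign, 2L, function(col) identical(col, obs))
  mirror <- sort(setdiff(seq_len(n), idxA))
  is_mirror <- if (length(mirror) == length(idxA)) {
    apply(all_assign, 2L, function(col) identical(col, mirror))
  } else {
    rep(FALSE, ncol(all_assign))
  }
  pool <- all_assign[, !(is_obs | is_mirror), drop = FALSE]
  if (ncol(pool) <= n_permutations) {
    if (ncol(pool) < n_permutations) {
      rlang::warn(paste0("only ", ncol(pool),
                         " distinct relabelings available; using all of them"),
                  class = "dppsubs_warning_permutations")
    }
    return(pool)
  }
  withr::with_seed(as.integer(seed), {
    pool[, sample.int(ncol(pool), n_permutations), drop = FALSE]
  })
}

#' Permutation-based FDR for the S0-moderated statistic
#'
#' Computes the observed `|d|` per protein, recomputes all `|d*|` under random
#' relabelings of the sample-group assignment, and for each candidate
#' threshold `t` (the observed `|d|` values) estimates
#' `FDR(t) = exceed(t) / max(1, #observed >= t)` where `exceed(t)` is the
#' add-one-corrected mean permutation exceedance `(1 + B(t)) / (P + 1)`
#' (estimator `"mean"`) or the median across relabelings of the
#' per-relabeling count (estimator `"median"`). The significance cutoff is
#' the smallest `t` with `FDR(t) <= fdr_target`; the relabeling pool excludes
#' the observed assignment and its group-swap mirror.
#'
#' @param x Complete numeric matrix of log2 intensities (proteins x samples)
#'   with row names identifying proteins.
#' @param groups Character/factor vector along the columns of `x` with exactly
#'   two levels; the first level (alphabetically, or the factor's first level)
#'   is treated as group A (bait).
#' @param params A [perm_test_params()] object.
#' @return A list: `table` (tibble with `protein_id`, `diff`, `d_stat`,
#'   `significant`), `cutoff` (the `|d|` cutoff, `Inf` if nothing passes),
#'   `n_permutations_used`, and the params.
#' @export
permutation_fdr <- function(x, groups, params = perm_test_params()) {
  x <- as.matrix(x)
  stop_if(anyNA(x), "matrix must be complete; impute first")
  stop_if(length(groups) != ncol(x),
          "`groups` must have one entry per column of `x`")
  lev <- if (is.factor(groups)) levels(groups) else sort(unique(as.character(groups)))
  stop_if(length(lev) != 2L, "`groups` must have exactly two levels")
  idxA <- which(as.character(groups) == lev[1])
  idxB <- which(as.character(groups) == lev[2])
  stop_if(length(idxA) < 2L || length(idxB) < 2L,
          "each group needs at least 2 samples")

  d_obs <- row_d_stat(x, idxA, idxB, params$s0)
  abs_obs <- abs(d_obs)
  pool <- relabelings(ncol(x), idxA, params$n_permutations, params$seed)
  P <- ncol(pool)
  abs_perm <- matrix(0, nrow = nrow(x), ncol = P)
  for (k in seq_len(P)) {
    iA <- pool[, k]
    iB <- setdiff(seq_len(ncol(x)), iA)
    abs_perm[, k] <- abs(row_d_stat(x, iA, iB, params$s0))
  }

  thresholds <- sort(unique(abs_obs))
  m <- vapply(thresholds, function(t) sum(abs_obs >= t), integer(1))
  if (params$estimator == "mean") {
    perm_sorted <- sort(as.vector(abs_perm))
    B <- length(perm_sorted) -
      findInterval(thresholds, perm_sorted, left.open = TRUE)
    exceed <- (1 + B) / (P + 1)
  } else {
    exceed <- vapply(thresholds, function(t) {
      stats::median(colSums(abs_perm >= t))
    }, numeric(1))
  }
  fdr <- pmin(1, exceed / pmax(1L, m))
  ok <- which(fdr <= params$fdr_target)
  cutoff <- if (length(ok) > 0) min(thresholds[ok]) else Inf

  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  list(table = tibble::tibble(protein_id = ids,
                              diff = unname(rowMeans(x[, idxA, drop = FALSE]) -
                                              rowMeans(x[, idxB, drop = FALSE])),
                              d_stat = d_obs,
                              significant = abs_obs >= cutoff),
       cutoff = cutoff,
       n_permutations_used = P,
       groups = stats::setNames(list(idxA, idxB), lev),
       params = params)
}

#' IP-MS differential enrichment analysis
#'
#' The full protein-group workflow: flag filtering, log2 matrix assembly,
#' Gaussian-downshift imputation of missing values, the S0-moderated
#' statistic with permutation-FDR significance calling, and classical
#' two-tailed Student t p-values (s0-free) for the volcano y-axis. The
#' significance call derives from the S0/permutation procedure; the p-value
#' is reported alongside, never conflated with it.
#'
#' @param tbl Protein-group tibble with `protein_id`, logical flag columns
#'   (`reverse`, `contaminant`, `only_by_site`) and one numeric log2-intensity
#'   column per sample (`NA` = missing).
#' @param sample_groups Named character vector or list mapping each sample
#'   column name to its group (e.g. `c(bait_1 = "bait", ..., ctrl_3 = "control")`).
#'   The alphabetically first group is the bait side of `diff`.
#' @param params A [perm_test_params()] object.
#' @return An object of class `ipms_fit`; [tidy()] returns the volcano table
#'   (one `VolcanoRow` per protein: `protein_id`, `diff`, `d_stat`,
#'   `p_value`, `significant`, `side`), [glance()] a one-row summary,
#'   [autoplot.ipms_fit()] the volcano plot.
#' @export
ipms_enrichment <- function(tbl, sample_groups, params = perm_test_params()) {
  tbl <- filter_protein_groups(tbl)
  samples <- names(sample_groups)
  stop_if(is.null(samples) || !all(samples %in% names(tbl)),
          "`sample_groups` must be named by sample columns present in `tbl`")
  x <- as.matrix(tbl[, samples, drop = FALSE])
  rownames(x) <- tbl$protein_id
  if (anyNA(x)) {
    x <- impute_gaussian_downshift(x, width = params$impute_width,
                                   downshift = params$impute_downshift,
                                   seed = params$seed)
  }
  groups <- unlist(sample_groups, use.names = FALSE)
  fit <- permutation_fdr(x, groups, params)

  lev <- names(fit$groups)
  idxA <- fit$groups[[1]]
  idxB <- fit$groups[[2]]
  se <- unname(pooled_se(x[, idxA, drop = FALSE], x[, idxB, drop = FALSE]))
  tstat <- ifelse(se > 0, fit$table$diff / se, Inf * sign(fit$table$diff))
  df <- length(idxA) + length(idxB) - 2
  p <- 2 * stats::pt(-abs(tstat), df = df)

  vol <- fit$table
  vol$p_value <- p
  vol$side <- dplyr::case_when(vol$significant & vol$diff > 0 ~ lev[1],
                               vol$significant & vol$diff < 0 ~ lev[2],
                               TRUE ~ "none")
  vol <- vol[, c("protein_id", "diff", "d_stat", "p_value", "significant", "side")]
  structure(list(table = vol, cutoff = fit$cutoff,
                 n_permutations_used = fit$n_permutations_used,
                 group_levels = lev, params = params),
            class = "ipms_fit")
}

#' @export
print.ipms_fit <- function(x, ...) {
  cat("<ipms_fit>\n")
  cat("  proteins tested: ", nrow(x$table), "\n", sep = "")
  cat("  |d| cutoff (FDR ", x$params$fdr_target, ", S0 ", x$params$s0, "): ",
      format(x$cutoff, digits = 4), "\n", sep = "")
  cat("  significant: ", sum(x$table$significant), " (",
      sum(x$table$side == x$group_levels[1]), " on the ", x$group_levels[1],
      " side)\n", sep = "")
  invisible(x)
}

#' @rdname ipms_enrichment
#' @param x An `ipms_fit` object.
#' @param ... Unused.
#' @export
tidy.ipms_fit <- function(x, ...) {
  x$table
}

#' @rdname ipms_enrichment
#' @export
glance.ipms_fit <- function(x, ...) {
  tibble::tibble(n_proteins = nrow(x$table),
                 n_significant = sum(x$table$significant),
                 cutoff = x$cutoff,
                 s0 = x$params$s0,
                 fdr_target = x$params$fdr_target,
                 n_permutations_used = x$n_permutations_used)
}

#' @rdname ipms_enrichment
#' @param fit An `ipms_fit` object.
#' @export
ipms_volcano <- function(fit) {
  stopifnot(inherits(fit, "ipms_fit"))
  fit$table
}
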