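# Reporter-intensity matrix processing: log2 transform, median-centering
# normalization, MinProb imputation and per-peptide fold changes.

#' Log2-transform a non-negative intensity matrix
#'
#' Positive intensities are log2-transformed; zeros denote non-detection and
#' become missing (`NA`); missing values are preserved. Negative intensities
#' are an input error.
#'
#' @param x Numeric matrix of raw reporter intensities (rows = peptides,
#'   columns = channels). `NA` encodes missing.
#' @return A numeric matrix of log2 intensities with `NA` for missing cells.
#' @export
log2_transform <- function(x) {
  x <- as.matrix(x)
  stop_if(!is.numeric(x), "`x` must be numeric")
  if (any(x < 0, na.rm = TRUE)) {
    rlang::abort("negative intensities are not allowed",
                 class = "dppsubs_error_input")
  }
  x[!is.na(x) & x == 0] <- NA_real_
  log2(x)
}

#' Median-center each channel of a log-intensity matrix
#'
#' Subtracts the per-column median of the observed values, so every column's
#' observed median is exactly zero afterwards. Missing entries are untouched.
#' Median centering is idempotent.
#'
#' @param x Numeric matrix of log2 intensities (`NA` = missing).
#' @return The centered matrix.
#' @export
median_center <- function(x) {
  x <- as.matrix(x)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0L)) {
    bad <- colnames(x)[n_obs == 0L]
    if (is.null(bad)) bad <- which(n_obs == 0L)
    rlang::abort(paste0("channel(s) with no observed values: ",
                        paste(bad, collapse = ", ")),
                 class = "dppsubs_error_input")
  }
  meds <- apply(x, 2L, stats::median, na.rm = TRUE)
  sweep(x, 2L, meds, "-")
}

#' MinProb imputation of missing log intensities
#'
#' Fills each missing cell with a draw from `Normal(center_c, sd_c)` where,
#' per channel `c`, `center_c` is the `q`-quantile of the observed values and
#' `sd_c` is `sd_scale` times their standard deviation. This places imputed
#' values near the channel's detection limit, modelling left-censored
#' missingness. Observed cells are never modified; identical seeds give
#' bitwise-identical output.
#'
#' @param x Numeric matrix of log2 intensities (`NA` = missing).
#' @param params An [impute_params()] object.
#' @return The matrix with all `NA` cells imputed.
#' @export
minprob_impute <- function(x, params = impute_params()) {
  x <- as.matrix(x)
  stopifnot(inherits(params, "impute_params"))
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 3L)) {
    bad <- colnames(x)[n_obs < 3L]
    if (is.null(bad)) bad <- which(n_obs < 3L)
    rlang::abort(paste0("channel(s) with fewer than 3 observed values: ",
                        paste(bad, collapse = ", ")),
                 class = "dppsubs_error_input")
  }
  if (!anyNA(x)) return(x)
  # Draws are made in a canonical row order so that results are identical for
  # the same rows regardless of their ordering in the input.
  ord <- canonical_row_order(x)
  x <- x[ord, , drop = FALSE]
  withr::with_seed(params$seed, {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (!any(miss)) next
      obs <- x[!miss, j]
      center <- stats::quantile(obs, probs = params$q, names = FALSE)
      sdev <- params$sd_scale * stats::sd(obs)
      x[miss, j] <- stats::rnorm(sum(miss), mean = center, sd = sdev)
    }
  })
  x[order(ord), , drop = FALSE]
}

canonical_row_order <- function(x) {
  if (is.null(rownames(x))) seq_len(nrow(x)) else order(rownames(x))
}

#' TMT channel design
#'
#' Maps reporter channels to genotypes and replicate indices. The default
#' design is the 6-plex layout used throughout this package: three genotypes
#' (`wildtype`, the protease deletion `dpf3_del` and the catalytically dead
#' point mutant `dpf3_S784A`), each in duplicate.
#'
#' @param channel Character vector of channel/column names.
#' @param genotype Character vector, one genotype per channel.
#' @param replicate Integer replicate index per channel.
#' @return A tibble with columns `channel`, `genotype`, `replicate`.
#' @export
channel_design <- function(channel, genotype, replicate) {
  stop_if(length(channel) != length(genotype) ||
            length(channel) != length(replicate),
          "`channel`, `genotype` and `replicate` must have equal length")
  stop_if(anyDuplicated(channel) > 0L, "channel names must be unique")
  tibble::tibble(channel = as.character(channel),
                 genotype = as.character(genotype),
                 replicate = as.integer(replicate))
}

#' @rdname channel_design
#' @export
default_channel_design <- function() {
  channel_design(channel = paste0("ch", 1:6),
                 genotype = rep(c("wildtype", "dpf3_del", "dpf3_S784A"), each = 2),
                 replicate = rep(1:2, times = 3))
}

fc_col_name <- function(genotype) {
  dplyr::case_when(genotype == "dpf3_del" ~ "fc_del",
                   genotype == "dpf3_S784A" ~ "fc_cat",
                   TRUE ~ paste0("fc_", genotype))
}

check_design <- function(x, design, reference) {
  stop_if(!all(c("channel", "genotype") %in% names(design)),
          "`design` must have columns `channel` and `genotype`")
  missing_ch <- setdiff(design$channel, colnames(x))
  stop_if(length(missing_ch) > 0,
          paste0("channels absent from the matrix: ",
                 paste(missing_ch, collapse = ", ")))
  counts <- table(design$genotype)
  stop_if(!(reference %in% names(counts)),
          paste0("reference genotype `", reference, "` has no channels"))
  stop_if(any(counts < 1L), "every genotype must have at least one channel")
}

#' Per-peptide log2 fold changes between mutant and wild-type channels
#'
#' For each non-reference genotype, computes the mean of its log2 channels
#' minus the mean of the reference (wild-type) channels, plus the grand mean
#' abundance. With the default genotypes the fold-change columns are named
#' `fc_del` (deletion vs wild-type) and `fc_cat` (catalytic mutant vs
#' wild-type) -- the coordinates of the two-mutant fold-change plane.
#'
#' @param x Complete (imputed) numeric matrix of log2 intensities with row
#'   names identifying peptides.
#' @param design A [channel_design()] tibble.
#' @param reference Reference genotype (default `"wildtype"`).
#' @param na_rm If `TRUE`, means are taken over observed values only and the
#'   matrix may contain `NA` (a genotype with no observed value in a row gives
#'   `NaN`); by default the matrix must be complete.
#' @return A tibble with columns `key`, one fold-change column per mutant
#'   genotype, and `mean_abundance`.
#' @export
comparison_fc <- function(x, design = default_channel_design(),
                          reference = "wildtype", na_rm = FALSE) {
  x <- as.matrix(x)
  check_design(x, design, reference)
  if (!na_rm && anyNA(x[, design$channel, drop = FALSE])) {
    rlang::abort("matrix contains missing values; impute first or set `na_rm = TRUE`",
                 class = "dppsubs_error_input")
  }
  genos <- unique(design$genotype)
  mutants <- setdiff(genos, reference)
  g_mean <- function(g) {
    ch <- design$channel[design$genotype == g]
    rowMeans(x[, ch, drop = FALSE], na.rm = na_rm)
  }
  ref_mean <- g_mean(reference)
  keys <- rownames(x)
  if (is.null(keys)) keys <- as.character(seq_len(nrow(x)))
  out <- tibble::tibble(key = keys)
  for (g in mutants) {
    out[[fc_col_name(g)]] <- unname(g_mean(g) - ref_mean)
  }
  out$mean_abundance <-
    unname(rowMeans(x[, design$channel, drop = FALSE], na.rm = na_rm))
  out
}

peptide_key <- function(rows) {
  paste(rows$protein_id, rows$start, rows$end, rows$mod_label, rows$charge,
        sep = "/")
}

detect_col_name <- function(genotype) {
  sub("^fc", "detect", fc_col_name(genotype))
}

#' Normalize, impute and compute fold changes for a peptide quant table
#'
#' The standard reporter-matrix workflow: log2 transform (zeros become
#' missing), per-channel median centering, MinProb imputation and
#' mutant-vs-wild-type fold changes. In addition to fold changes the result
#' records, per comparison, the pre-imputation detection pattern of each
#' peptide (`"both"`, `"mutant_only"` = detected in at least one mutant
#' channel and no wild-type channel, `"wildtype_only"`, `"neither"`), which
#' downstream candidate calling can use for detected-only ("on/off") handling.
#'
#' @param rows Peptide quant tibble with columns `protein_id`, `start`, `end`,
#'   `sequence`, `mod_label`, `charge` and one numeric intensity column per
#'   channel in `design` (`NA` or 0 = not detected).
#' @param design A [channel_design()] tibble.
#' @param impute An [impute_params()] object.
#' @param fc_mode `"imputed"` (default): fold changes from the complete
#'   imputed matrix; `"observed"`: means over observed values only.
#' @param reference Reference genotype (default `"wildtype"`).
#' @return A tibble with the identifying columns of `rows`, `key`, fold-change
#'   columns, `mean_abundance` and one detection-pattern column per
#'   comparison (e.g. `detect_del`, `detect_cat`).
#' @export
peptide_fold_changes <- function(rows, design = default_channel_design(),
                                 impute = impute_params(),
                                 fc_mode = c("imputed", "observed"),
                                 reference = "wildtype") {
  fc_mode <- match.arg(fc_mode)
  need <- c("protein_id", "start", "end", "sequence", "mod_label", "charge")
  missing_cols <- setdiff(c(need, design$channel), names(rows))
  stop_if(length(missing_cols) > 0,
          paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  key <- peptide_key(rows)
  stop_if(anyDuplicated(key) > 0L,
          "duplicate peptide keys (protein/start/end/mod_label/charge)")
  mat <- as.matrix(rows[, design$channel, drop = FALSE])
  rownames(mat) <- key
  lg <- log2_transform(mat)
  lg <- median_center(lg)
  obs <- !is.na(lg)

  if (fc_mode == "imputed") {
    full <- minprob_impute(lg, impute)
    fc <- comparison_fc(full, design, reference = reference)
  } else {
    fc <- comparison_fc(lg, design, reference = reference, na_rm = TRUE)
  }

  mutants <- setdiff(unique(design$genotype), reference)
  ref_ch <- design$channel[design$genotype == reference]
  ref_obs <- rowSums(obs[, ref_ch, drop = FALSE])
  n_ref <- length(ref_ch)
  for (g in mutants) {
    ch <- design$channel[design$genotype == g]
    g_obs <- rowSums(obs[, ch, drop = FALSE])
    fc[[detect_col_name(g)]] <- dplyr::case_when(
      g_obs > 0L & ref_obs == 0L ~ "mutant_only",
      g_obs == 0L & ref_obs > 0L ~ "wildtype_only",
      g_obs > 0L & ref_obs > 0L ~ "both",
      TRUE ~ "neither")
  }
  dplyr::bind_cols(tibble::as_tibble(rows[, need]), fc)
}
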