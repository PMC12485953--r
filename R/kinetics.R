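# In-vitro digestion time courses: replicate summaries and product-formation
# calls for active enzyme vs catalytic-mutant reactions.

#' Summarize a product-peptide time course
#'
#' Arithmetic mean of the replicate intensities per timepoint, with the
#' replicate count, per peptide and enzyme.
#'
#' @param tc Long time-course tibble with columns `peptide_id`,
#'   `enzyme_label`, `time_min`, `intensity` (and optionally `replicate`).
#' @return A tibble with `peptide_id`, `enzyme_label`, `time_min`,
#'   `mean_intensity`, `n_replicates`, sorted by time within each series.
#' @export
summarize_timecourse <- function(tc) {
  need <- c("peptide_id", "enzyme_label", "time_min", "intensity")
  stop_if(!all(need %in% names(tc)),
          paste0("`tc` must have columns: ", paste(need, collapse = ", ")))
  stop_if(anyNA(tc$intensity), "missing intensities in time course")
  stop_if(any(tc$intensity < 0), "intensities must be >= 0")
  out <- dplyr::summarise(
    dplyr::group_by(tc, .data$peptide_id, .data$enzyme_label, .data$time_min),
    mean_intensity = mean(.data$intensity),
    n_replicates = dplyr::n(),
    .groups = "drop")
  dplyr::arrange(out, .data$peptide_id, .data$enzyme_label, .data$time_min)
}

#' Call product formation from a digestion time course
#'
#' A product is called formed when the final-timepoint mean intensity is at
#' least `fold_over_baseline` times the first-timepoint mean (the baseline is
#' floored at `floor_frac` times the series maximum, so a zero baseline does
#' not produce spurious infinite ratios) and the per-step mean profile is
#' non-decreasing in at least half of the steps. The call is ratio-based:
#' rescaling all intensities by a positive constant does not change it. A
#' series that never rises above zero is never called formed.
#'
#' When both an active-enzyme and a catalytic-mutant series are present, the
#' peptide sets of the two series must match.
#'
#' @param tc Long time-course tibble (see [summarize_timecourse()]).
#' @param fold_over_baseline Required fold increase of the final over the
#'   baseline mean (default 5).
#' @param floor_frac Baseline floor as a fraction of the series maximum mean
#'   (default 1e-3).
#' @return A tibble with one row per `peptide_id` x `enzyme_label`:
#'   `formed` (logical), `fold_change`, `baseline_mean`, `final_mean`,
#'   `n_timepoints`.
#' @export
call_product_formation <- function(tc, fold_over_baseline = 5,
                                   floor_frac = 1e-3) {
  stop_if(!(fold_over_baseline > 0), "`fold_over_baseline` must be > 0")
  means <- summarize_timecourse(tc)
  labs <- unique(means$enzyme_label)
  if (length(labs) > 1L) {
    sets <- lapply(labs, function(l) {
      sort(unique(means$peptide_id[means$enzyme_label == l]))
    })
    same <- all(vapply(sets[-1], identical, logical(1), y = sets[[1]]))
    if (!same) {
      rlang::abort("mismatched peptide sets between enzyme series",
                   class = "dppsubs_error_input")
    }
  }
  one_call <- function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    m <- d$mean_intensity
    baseline <- m[1]
    final <- m[length(m)]
    floor_v <- floor_frac * max(m)
    denom <- max(baseline, floor_v)
    steps <- diff(m)
    nondec_ok <- length(steps) == 0L ||
      sum(steps >= 0) >= ceiling(length(steps) / 2)
    formed <- max(m) > 0 && final >= fold_over_baseline * denom && nondec_ok
    tibble::tibble(formed = formed,
                   fold_change = ifelse(denom > 0, final / denom, NA_real_),
                   baseline_mean = baseline, final_mean = final,
                   n_timepoints = length(m))
  }
  grp <- dplyr::group_by(means, .data$peptide_id, .data$enzyme_label)
  out <- dplyr::reframe(grp, one_call(dplyr::pick(dplyr::everything())))
  dplyr::arrange(tibble::as_tibble(out), .data$peptide_id, .data$enzyme_label)
}
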