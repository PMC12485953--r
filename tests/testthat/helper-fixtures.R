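# Shared fixtures and independent oracles, built in code.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, seed = NULL) {
  draw <- function() paste(c("M", sample(AA_LETTERS, len - 1, replace = TRUE)),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

toy_proteome <- function() {
  tibble::tibble(
    protein_id = c("MEP1L", "NOEXC", "SIGP"),
    description = c("Thr-at-P1 substrate-like", "no excision", "signal peptide"),
    sequence = c("MVTAQSLKNDFGHQWER",       # Met + Val2 -> iMet excision
                 "MDEAQSLKNDFGHQWER",       # Asp2 -> no excision
                 paste0(random_protein(40, seed = 7))),
    signal_peptide_end = c(NA, NA, 20L))
}

# Exhaustive brute-force digestion oracle: every substring, checked directly
# against the definitions (independent of the package's interval enumeration).
bf_digest <- function(sequence, params) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_site <- chars %in% params$cleave_after
  if (params$block_proline && n > 1) {
    is_site <- is_site & !c(chars[-1] == "P", FALSE)
  }
  sites <- which(is_site)
  res <- list()
  for (a in seq_len(n)) {
    for (b in a:n) {
      len <- b - a + 1
      if (len < params$min_length || len > params$max_length) next
      nspec <- a == 1 || (a - 1) %in% sites
      cspec <- b == n || b %in% sites
      missed <- sum(sites >= a & sites <= b - 1)
      if (missed > params$max_missed_cleavages) next
      ok <- if (params$semi_specific) nspec || cspec else nspec && cspec
      if (ok) res[[length(res) + 1]] <- c(a, b)
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, res)
  out <- tibble::tibble(start = m[, 1], end = m[, 2])
  dplyr::arrange(out, start, end)
}

# A tiny hand-buildable peptide quant table on the default 6-channel design.
toy_quant_rows <- function(intensities) {
  n <- nrow(intensities)
  dplyr::bind_cols(
    tibble::tibble(protein_id = paste0("P", seq_len(n)),
                   start = 2L, end = 20L,
                   sequence = strrep("A", 19),
                   mod_label = "none", charge = 2L),
    tibble::as_tibble(intensities))
}
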