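# Synthetic-data generators with known ground truth: proteomes with planted
# dipeptidyl-peptidase substrates, TAILS reporter experiments and IP-MS LFQ
# tables. Everything is seeded and bit-reproducible.

#' Configuration of the synthetic TAILS experiment
#'
#' The generator emulates the statistical structure a TAILS substrate screen
#' assumes: a proteome with a known set of substrates whose P1 residues follow
#' configurable specificity weights; per-genotype substrate-to-product
#' conversion fractions (near-complete in the protease-proficient wild-type,
#' near-zero in the two loss-of-function mutants); log-normal protein
#' abundances; multiplicative reporter noise; and intensity-dependent
#' (missing-not-at-random) dropout.
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param length_range Protein length range in residues (default 150--400).
#' @param signal_fraction Fraction of proteins with an annotated signal
#'   peptide (default 0.15).
#' @param signal_end_range Signal-peptide end positions, sampled uniformly
#'   (default 15--25, the range in which secreted-protein neo-N-termini
#'   cluster).
#' @param n_substrates Number of true substrates planted (default 50).
#' @param p1_weights Named non-negative weights giving the relative cleavage
#'   efficiency by P1 residue (defaults P 1.0, A 0.8, S 0.3, T 0.3, G 0.2;
#'   all other residues 0).
#' @param conversion Named per-genotype fraction of substrate molecules
#'   converted to product (defaults: wildtype 0.9, dpf3_del 0.02,
#'   dpf3_S784A 0.02 -- both mutants are loss-of-function).
#' @param abundance_mean,abundance_sd Log2-normal protein abundance
#'   parameters (defaults 20 and 2).
#' @param noise_sd Reporter noise standard deviation in log2 units
#'   (default 0.3).
#' @param mnar Enable intensity-dependent dropout (default `TRUE`).
#' @param mnar_quantile Quantile of the realized log2 intensities at which
#'   the dropout probability is 0.5 (default 0.10).
#' @param mnar_slope Logistic slope per log2 unit (default 1).
#' @param n_background Background internal (fully specific) peptides sampled
#'   per protein (default 3).
#' @param nterm_peptide_range Length range of the planted N-terminal tryptic
#'   peptide of substrate proteins (default 14--28).
#' @param digest A [digest_params()] object used for the N-terminal peptide
#'   window and the background digest.
#' @param seed Mandatory integer seed.
#' @return A list of class `tails_sim_config`.
#' @export
tails_sim_config <- function(n_proteins = 1000L, length_range = c(150L, 400L),
                             signal_fraction = 0.15,
                             signal_end_range = c(15L, 25L),
                             n_substrates = 50L,
                             p1_weights = c(P = 1, A = 0.8, S = 0.3,
                                            T = 0.3, G = 0.2),
                             conversion = c(wildtype = 0.9, dpf3_del = 0.02,
                                            dpf3_S784A = 0.02),
                             abundance_mean = 20, abundance_sd = 2,
                             noise_sd = 0.3, mnar = TRUE,
                             mnar_quantile = 0.10, mnar_slope = 1,
                             n_background = 3L,
                             nterm_peptide_range = c(14L, 28L),
                             digest = digest_params(), seed = NULL) {
  stop_if(is.null(seed) || is.na(seed), "`seed` is mandatory")
  stop_if(n_substrates > n_proteins, "`n_substrates` cannot exceed `n_proteins`")
  stop_if(!(signal_fraction >= 0 && signal_fraction <= 1),
          "`signal_fraction` must lie in [0, 1]")
  stop_if(any(conversion < 0 | conversion > 1),
          "`conversion` fractions must lie in [0, 1]")
  stop_if(is.null(names(conversion)), "`conversion` must be named by genotype")
  stop_if(any(p1_weights < 0), "`p1_weights` must be non-negative")
  stop_if(noise_sd < 0, "`noise_sd` must be >= 0")
  stop_if(nterm_peptide_range[1] < digest$min_length + 2L,
          "N-terminal peptides must stay detectable after one dipeptide removal")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 signal_fraction = signal_fraction,
                 signal_end_range = as.integer(signal_end_range),
                 n_substrates = as.integer(n_substrates),
                 p1_weights = p1_weights, conversion = conversion,
                 abundance_mean = abundance_mean, abundance_sd = abundance_sd,
                 noise_sd = noise_sd, mnar = isTRUE(mnar),
                 mnar_quantile = mnar_quantile, mnar_slope = mnar_slope,
                 n_background = as.integer(n_background),
                 nterm_peptide_range = as.integer(nterm_peptide_range),
                 digest = digest, seed = as.integer(seed)),
            class = "tails_sim_config")
}

#' Generate a synthetic proteome with planted substrates
#'
#' Random sequences over the 20-letter alphabet beginning with Met. A fraction
#' of proteins receives a signal-peptide annotation. Planted substrates get a
#' well-defined mature N-terminus (signal-peptide end, or residue 2 via a
#' position-2 residue from the initiator-Met excision set), a P1 residue at
#' mature start + 1 drawn proportional to the specificity weights, and a
#' cleavage-site residue planted so the N-terminal tryptic peptide falls in
#' the detectable length window (no earlier site intervenes).
#'
#' @param config A [tails_sim_config()] object.
#' @return A list with `proteome` (tibble: `protein_id`, `description`,
#'   `sequence`, `signal_peptide_end`) and `truth` (tibble: `protein_id`,
#'   `mature_start`, `nterm_peptide_end`, `P2`, `P1`, `P1prime`).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "tails_sim_config"))
  cleave <- config$digest$cleave_after
  non_site <- setdiff(AA20, cleave)
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   n, replace = TRUE)
    chars <- lapply(lens, function(L) {
      c("M", sample(AA20, L - 1L, replace = TRUE))
    })
    has_sp <- stats::runif(n) < config$signal_fraction
    sp_end <- ifelse(has_sp,
                     sample(seq(config$signal_end_range[1],
                                config$signal_end_range[2]),
                            n, replace = TRUE),
                     NA_integer_)
    subs <- sort(sample.int(n, config$n_substrates))
    mature <- integer(length(subs))
    pep_end <- integer(length(subs))
    w <- config$p1_weights[config$p1_weights > 0]
    for (i in seq_along(subs)) {
      k <- subs[i]
      if (has_sp[k]) {
        m <- sp_end[k] + 1L
      } else {
        chars[[k]][2] <- sample(IMET_EXCISION_SET, 1L)
        m <- 2L
      }
      L <- sample(seq(config$nterm_peptide_range[1],
                      config$nterm_peptide_range[2]), 1L)
      win <- seq.int(m, m + L - 2L)
      hit <- chars[[k]][win] %in% cleave
      if (any(hit)) {
        chars[[k]][win[hit]] <- sample(non_site, sum(hit), replace = TRUE)
      }
      chars[[k]][m + L - 1L] <- cleave[1]
      chars[[k]][m + 1L] <- sample(names(w), 1L, prob = w)
      mature[i] <- m
      pep_end[i] <- m + L - 1L
    }
    seqs <- vapply(chars, paste, character(1), collapse = "")
    ids <- sprintf("PROT%05d", seq_len(n))
    proteome <- tibble::tibble(protein_id = ids,
                               description = "synthetic protein",
                               sequence = seqs,
                               signal_peptide_end = as.integer(sp_end))
    truth <- tibble::tibble(protein_id = ids[subs],
                            mature_start = mature,
                            nterm_peptide_end = pep_end,
                            P2 = substr(seqs[subs], mature, mature),
                            P1 = substr(seqs[subs], mature + 1L, mature + 1L),
                            P1prime = substr(seqs[subs], mature + 2L,
                                             mature + 2L))
    list(proteome = proteome, truth = truth)
  })
}

first_site_in_window <- function(sequence, from, cleave, min_len, max_len) {
  chars <- strsplit(sequence, "")[[1]]
  sites <- which(chars %in% cleave)
  sites <- sites[sites >= from + min_len - 1L & sites <= from + max_len - 1L]
  if (length(sites) == 0L) NA_integer_ else sites[1]
}

#' Simulate a TAILS reporter-ion experiment
#'
#' For every protein with a detectable N-terminal tryptic peptide the
#' generator emits that peptide; for planted substrates it additionally emits
#' the dipeptide-shifted product peptide, splitting the protein's molecules
#' between substrate and product according to each genotype's conversion
#' fraction. Background internal fully-specific peptides are sampled from the
#' digest. Channel intensities are `abundance x split x 2^eps` with
#' `eps ~ Normal(0, noise_sd)`; a structurally absent species has intensity
#' exactly 0 (encoded as 0 in the table; the log2 transform treats it as
#' non-detection); stochastic dropout follows a logistic
#' missing-not-at-random curve on log2 intensity (encoded as `NA`). Rows
#' never observed in any channel are not emitted.
#'
#' In the noiseless limit the observed log2 fold change of a substrate
#' peptide (mutant vs wild-type) equals
#' `log2((1 - conversion_mut) / (1 - conversion_wt))` exactly.
#'
#' @param proteome,truth Output of [simulate_proteome()].
#' @param config The same [tails_sim_config()] object.
#' @return A list with `rows` (peptide quant tibble with channels `ch1..ch6`
#'   and a `role` column: substrate/product/nterm/background), `design`
#'   (the [default_channel_design()]) and `truth` (augmented with the
#'   conversion fractions used).
#' @export
simulate_tails <- function(proteome, truth, config) {
  stopifnot(inherits(config, "tails_sim_config"))
  design <- default_channel_design()
  stop_if(!all(design$genotype %in% names(config$conversion)),
          "`conversion` must name every genotype in the channel design")
  mature <- mature_nterm(proteome)
  mat_start <- stats::setNames(mature$start, mature$protein_id)
  min_len <- config$digest$min_length
  max_len <- config$digest$max_length

  is_sub <- proteome$protein_id %in% truth$protein_id
  tr_end <- stats::setNames(truth$nterm_peptide_end, truth$protein_id)

  ends <- vapply(seq_len(nrow(proteome)), function(i) {
    pid <- proteome$protein_id[i]
    if (is_sub[i]) return(tr_end[[pid]])
    first_site_in_window(proteome$sequence[i], mat_start[[pid]],
                         config$digest$cleave_after, min_len, max_len)
  }, integer(1))

  has_nterm <- !is.na(ends)
  nt <- tibble::tibble(protein_id = proteome$protein_id[has_nterm],
                       start = unname(mat_start[proteome$protein_id[has_nterm]]),
                       end = ends[has_nterm],
                       role = ifelse(is_sub[has_nterm], "substrate", "nterm"))
  prod <- nt[nt$role == "substrate", , drop = FALSE]
  if (nrow(prod) > 0L) {
    prod$start <- prod$start + 2L
    prod$role <- "product"
  }

  withr::with_seed(config$seed + 1L, {
    bg <- NULL
    if (config$n_background > 0L) {
      bg_params <- config$digest
      bg_params$semi_specific <- FALSE
      bg_all <- digest_semi(proteome, bg_params)
      bg_all <- dplyr::left_join(
        bg_all, dplyr::select(mature, "protein_id", .mat = "start"),
        by = "protein_id")
      bg_all <- bg_all[bg_all$start > bg_all$.mat + 2L, , drop = FALSE]
      if (nrow(bg_all) > 0L) {
        bg_all <- bg_all[sample.int(nrow(bg_all)), , drop = FALSE]
        grp <- split(seq_len(nrow(bg_all)), bg_all$protein_id)
        keep <- unlist(lapply(grp, function(ix) {
          ix[seq_len(min(length(ix), config$n_background))]
        }), use.names = FALSE)
        bg <- tibble::tibble(protein_id = bg_all$protein_id[keep],
                             start = bg_all$start[keep],
                             end = bg_all$end[keep],
                             role = "background")
      }
    }
    rows <- dplyr::bind_rows(nt, prod, bg)
    rows <- rows[order(rows$protein_id, rows$start, rows$end), , drop = FALSE]
    rows$sequence <- substr(
      stats::setNames(proteome$sequence,
                      proteome$protein_id)[rows$protein_id],
      rows$start, rows$end)
    rows$mod_label <- "none"
    rows$charge <- 2L

    log2a <- stats::rnorm(nrow(proteome), config$abundance_mean,
                          config$abundance_sd)
    names(log2a) <- proteome$protein_id
    conv <- config$conversion[design$genotype]
    frac <- matrix(1, nrow = nrow(rows), ncol = nrow(design))
    for (j in seq_len(nrow(design))) {
      frac[rows$role == "substrate", j] <- 1 - conv[j]
      frac[rows$role == "product", j] <- conv[j]
    }
    eps <- matrix(stats::rnorm(nrow(rows) * nrow(design), 0, config$noise_sd),
                  nrow = nrow(rows))
    inten <- frac * 2^(log2a[rows$protein_id] + eps)

    if (config$mnar) {
      pos <- inten > 0
      lg <- log2(inten[pos])
      midpoint <- stats::quantile(lg, config$mnar_quantile, names = FALSE)
      p_miss <- stats::plogis(-(lg - midpoint) * config$mnar_slope)
      dropped <- stats::runif(length(lg)) < p_miss
      inten[pos][dropped] <- NA_real_
    }
    colnames(inten) <- design$channel
    observed <- rowSums(!is.na(inten) & inten > 0, na.rm = TRUE) > 0L
    rows <- dplyr::bind_cols(rows, tibble::as_tibble(inten))[observed, ,
                                                            drop = FALSE]
  })
  truth$conversion_wildtype <- unname(config$conversion["wildtype"])
  list(rows = tibble::as_tibble(rows), design = design, truth = truth)
}

#' Configuration of the synthetic IP-MS experiment
#'
#' @param n_proteins Number of (unflagged) protein groups (default 500).
#' @param n_per_group Samples per group (bait and control; default 3).
#' @param base_mean,base_sd Protein-level log2 LFQ intensity distribution
#'   (defaults 25 and 3).
#' @param noise_sd Per-sample log2 noise (default 0.3).
#' @param n_enriched Number of proteins enriched on the bait side (default 0;
#'   a global null).
#' @param effect_size Log2 shift added to bait samples of enriched proteins
#'   (default 5).
#' @param flagged_fraction Fraction (of `n_proteins`) of additional decoy /
#'   contaminant / site-only flagged rows included to exercise filtering
#'   (default 0.05).
#' @param missing_fraction Fraction of cells set missing at random
#'   (default 0).
#' @param seed Mandatory integer seed.
#' @return A list of class `ipms_sim_config`.
#' @export
ipms_sim_config <- function(n_proteins = 500L, n_per_group = 3L,
                            base_mean = 25, base_sd = 3, noise_sd = 0.3,
                            n_enriched = 0L, effect_size = 5,
                            flagged_fraction = 0.05, missing_fraction = 0,
                            seed = NULL) {
  stop_if(is.null(seed) || is.na(seed), "`seed` is mandatory")
  stop_if(n_enriched > n_proteins, "`n_enriched` cannot exceed `n_proteins`")
  stop_if(!(flagged_fraction >= 0 && flagged_fraction <= 1),
          "`flagged_fraction` must lie in [0, 1]")
  stop_if(!(missing_fraction >= 0 && missing_fraction < 1),
          "`missing_fraction` must lie in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_per_group = as.integer(n_per_group),
                 base_mean = base_mean, base_sd = base_sd, noise_sd = noise_sd,
                 n_enriched = as.integer(n_enriched),
                 effect_size = effect_size,
                 flagged_fraction = flagged_fraction,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "ipms_sim_config")
}

#' Simulate an IP-MS protein-group table
#'
#' Protein-level log2 intensities for bait and control pulldowns with
#' per-sample noise; a configured set of proteins receives a log2 enrichment
#' shift on the bait side, and a configured fraction of flagged
#' (reverse / contaminant / site-only) rows is appended to exercise
#' filtering.
#'
#' @param config An [ipms_sim_config()] object.
#' @return A list with `table` (tibble: `protein_id`, flag columns, one log2
#'   intensity column per sample), `truth` (tibble of enriched proteins with
#'   their effect sizes) and `sample_groups` (named vector suitable for
#'   [ipms_enrichment()]).
#' @export
simulate_ipms <- function(config) {
  stopifnot(inherits(config, "ipms_sim_config"))
  ng <- config$n_per_group
  samples <- c(paste0("bait_", seq_len(ng)), paste0("ctrl_", seq_len(ng)))
  groups <- stats::setNames(rep(c("bait", "control"), each = ng), samples)
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    base <- stats::rnorm(n, config$base_mean, config$base_sd)
    mat <- base + matrix(stats::rnorm(n * 2 * ng, 0, config$noise_sd),
                         nrow = n)
    enriched <- integer(0)
    if (config$n_enriched > 0L) {
      enriched <- sort(sample.int(n, config$n_enriched))
      mat[enriched, seq_len(ng)] <- mat[enriched, seq_len(ng)] +
        config$effect_size
    }
    colnames(mat) <- samples
    ids <- sprintf("IPMS%05d", seq_len(n))
    tbl <- dplyr::bind_cols(
      tibble::tibble(protein_id = ids, reverse = FALSE, contaminant = FALSE,
                     only_by_site = FALSE),
      tibble::as_tibble(mat))

    n_flag <- round(config$flagged_fraction * n)
    if (n_flag > 0L) {
      fmat <- stats::rnorm(n_flag, config$base_mean, config$base_sd) +
        matrix(stats::rnorm(n_flag * 2 * ng, 0, config$noise_sd),
               nrow = n_flag)
      colnames(fmat) <- samples
      which_flag <- sample(c("reverse", "contaminant", "only_by_site"),
                           n_flag, replace = TRUE)
      ftbl <- dplyr::bind_cols(
        tibble::tibble(protein_id = sprintf("FLAG%05d", seq_len(n_flag)),
                       reverse = which_flag == "reverse",
                       contaminant = which_flag == "contaminant",
                       only_by_site = which_flag == "only_by_site"),
        tibble::as_tibble(fmat))
      tbl <- dplyr::bind_rows(tbl, ftbl)
    }
    if (config$missing_fraction > 0) {
      for (s in samples) {
        drop <- stats::runif(nrow(tbl)) < config$missing_fraction
        tbl[[s]][drop] <- NA_real_
      }
    }
    truth <- tibble::tibble(protein_id = ids[enriched],
                            effect = config$effect_size)
    list(table = tbl, truth = truth, sample_groups = groups)
  })
}
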