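# Synthetic-data generators: determinism, planted truth, noise and
# missingness structure.

test_that("proteome generation is seeded and plants the requested substrates", {
  cfg <- tails_sim_config(n_proteins = 120, n_substrates = 12, seed = 101)
  a <- simulate_proteome(cfg)
  b <- simulate_proteome(cfg)
  expect_identical(a, b)
  expect_false(identical(
    a$proteome$sequence,
    simulate_proteome(tails_sim_config(n_proteins = 120, n_substrates = 12,
                                       seed = 102))$proteome$sequence))
  expect_equal(nrow(a$truth), 12L)
  expect_true(all(a$truth$protein_id %in% a$proteome$protein_id))

  # truth P positions agree with the sequences and the mature-N-terminus rules
  mat <- mature_nterm(a$proteome)
  m <- mat$start[match(a$truth$protein_id, mat$protein_id)]
  expect_equal(m, a$truth$mature_start)
  spans <- tibble::tibble(protein_id = a$truth$protein_id,
                          start = a$truth$mature_start,
                          end = a$truth$nterm_peptide_end)
  pp <- p_positions(spans, a$proteome)
  expect_equal(pp$P2, a$truth$P2)
  expect_equal(pp$P1, a$truth$P1)
  expect_equal(pp$P1prime, a$truth$P1prime)
  # the planted cleavage site ends the N-terminal tryptic peptide
  expect_true(all(substr(
    a$proteome$sequence[match(a$truth$protein_id, a$proteome$protein_id)],
    a$truth$nterm_peptide_end, a$truth$nterm_peptide_end) == "R"))
  expect_error(tails_sim_config(n_proteins = 5, n_substrates = 6, seed = 1))
})

test_that("planted P1 composition follows the specificity weights", {
  cfg <- tails_sim_config(n_proteins = 2500, n_substrates = 2500,
                          length_range = c(60L, 80L), seed = 7)
  tr <- simulate_proteome(cfg)$truth
  w <- cfg$p1_weights / sum(cfg$p1_weights)
  counts <- table(factor(tr$P1, levels = names(w)))
  expect_equal(sum(counts), 2500)
  chi <- chisq.test(counts, p = w)
  expect_gt(chi$p.value, 1e-4)
})

test_that("noiseless fold changes match the conversion closed form", {
  cfg <- tails_sim_config(n_proteins = 150, n_substrates = 15, noise_sd = 0,
                          mnar = FALSE, seed = 5)
  sim <- simulate_proteome(cfg)
  tl <- simulate_tails(sim$proteome, sim$truth, cfg)
  # raw observed fold changes (no centering/imputation needed: complete data)
  m <- log2_transform(as.matrix(tl$rows[, tl$design$channel]))
  rownames(m) <- paste(tl$rows$protein_id, tl$rows$start, sep = "/")
  fc <- comparison_fc(m, tl$design, na_rm = TRUE)
  sub_keys <- paste(sim$truth$protein_id, sim$truth$mature_start, sep = "/")
  got <- fc[fc$key %in% sub_keys, ]
  want <- log2((1 - 0.02) / (1 - 0.9))
  expect_equal(nrow(got), nrow(sim$truth))
  expect_lt(max(abs(got$fc_del - want)), 1e-9)
  expect_lt(max(abs(got$fc_cat - want)), 1e-9)
})

test_that("full conversion with zero noise gives structural zeros", {
  cfg <- tails_sim_config(n_proteins = 60, n_substrates = 6, noise_sd = 0,
                          mnar = FALSE,
                          conversion = c(wildtype = 1, dpf3_del = 0,
                                         dpf3_S784A = 0),
                          seed = 9)
  sim <- simulate_proteome(cfg)
  tl <- simulate_tails(sim$proteome, sim$truth, cfg)
  des <- tl$design
  wt <- des$channel[des$genotype == "wildtype"]
  mut <- des$channel[des$genotype != "wildtype"]
  prods <- tl$rows[tl$rows$role == "product", ]
  subs <- tl$rows[tl$rows$role == "substrate", ]
  expect_true(all(as.matrix(prods[, mut]) == 0))
  expect_true(all(as.matrix(prods[, wt]) > 0))
  expect_true(all(as.matrix(subs[, wt]) == 0))
  expect_true(all(as.matrix(subs[, mut]) > 0))
})

test_that("dropout is missing-not-at-random: rates fall with intensity", {
  cfg_on <- tails_sim_config(n_proteins = 400, n_substrates = 20, seed = 33)
  cfg_off <- tails_sim_config(n_proteins = 400, n_substrates = 20, seed = 33,
                              mnar = FALSE)
  sim <- simulate_proteome(cfg_on)
  on <- simulate_tails(sim$proteome, sim$truth, cfg_on)
  off <- simulate_tails(sim$proteome, sim$truth, cfg_off)
  ch <- on$design$channel
  key <- function(rows) paste(rows$protein_id, rows$start, rows$end)
  common <- intersect(key(on$rows), key(off$rows))
  m_on <- as.matrix(on$rows[match(common, key(on$rows)), ch])
  m_off <- as.matrix(off$rows[match(common, key(off$rows)), ch])
  # the underlying intensities are shared: observed cells agree exactly
  obs <- !is.na(m_on)
  expect_identical(m_on[obs], m_off[obs])
  lg <- log2(m_off[m_off > 0])
  missing <- is.na(m_on[m_off > 0])
  decile <- cut(lg, breaks = quantile(lg, 0:10 / 10), include.lowest = TRUE)
  rate <- tapply(missing, decile, mean)
  # monotone decrease across deciles, allowing small sampling wiggle
  expect_lt(rate[10], rate[1])
  expect_true(all(diff(rate) < 0.08))
  expect_gt(mean(missing), 0.05)
  expect_lt(mean(missing), 0.35)
})

test_that("TAILS tables are bit-reproducible under a fixed seed", {
  cfg <- tails_sim_config(n_proteins = 80, n_substrates = 8, seed = 55)
  sim <- simulate_proteome(cfg)
  expect_identical(simulate_tails(sim$proteome, sim$truth, cfg)$rows,
                   simulate_tails(sim$proteome, sim$truth, cfg)$rows)
})

test_that("IP-MS simulation plants effects and flags", {
  cfg <- ipms_sim_config(n_proteins = 200, n_enriched = 5,
                         flagged_fraction = 0.1, seed = 12)
  sim <- simulate_ipms(cfg)
  expect_identical(sim, simulate_ipms(cfg))
  flagged <- sim$table$reverse | sim$table$contaminant | sim$table$only_by_site
  expect_equal(sum(flagged), 20L)
  expect_equal(nrow(sim$table), 220L)
  expect_equal(nrow(sim$truth), 5L)
  # planted proteins show the configured shift
  bait <- paste0("bait_", 1:3)
  ctrl <- paste0("ctrl_", 1:3)
  rowsE <- sim$table[match(sim$truth$protein_id, sim$table$protein_id), ]
  diffs <- rowMeans(as.matrix(rowsE[, bait])) - rowMeans(as.matrix(rowsE[, ctrl]))
  expect_true(all(abs(diffs - 5) < 1.5))
  # planted set recovered exactly at the strict preset
  fit <- suppressWarnings(ipms_enrichment(sim$table, sim$sample_groups,
                                          perm_preset_strict(seed = 3)))
  expect_setequal(fit$table$protein_id[fit$table$significant],
                  sim$truth$protein_id)
})
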