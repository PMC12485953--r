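# Mature-N-terminus rules, digestion enumeration, dipeptidyl arithmetic and
# P-position annotation.

test_that("mature N-terminus rules fire correctly and exclusively", {
  prot <- tibble::tibble(
    protein_id = c("imet", "none", "sig", "sig_over_imet", "frag", "xpos2"),
    sequence = c("MVTAQLKRS",      # Val at 2 -> excision
                 "MDEAQLKRS",      # Asp at 2 -> no rule
                 paste0(strrep("A", 25), "KRS"),
                 paste0("MV", strrep("A", 23), "KRS"),
                 "VTAQLKRS",       # fragment not starting with Met
                 "MXTAQLKRS"),     # ambiguous residue at 2 -> no rule
    signal_peptide_end = c(NA, NA, 20L, 20L, NA, NA))
  res <- mature_nterm(prot)
  expect_equal(res$start, c(2L, 1L, 21L, 21L, 1L, 1L))
  expect_equal(res$rule, c("imet_excision", "none", "signal_peptide",
                           "signal_peptide", "none", "none"))
  # idempotent / deterministic
  expect_identical(res, mature_nterm(prot))
})

test_that("invalid signal-peptide annotations are rejected", {
  bad <- tibble::tibble(protein_id = "tiny", sequence = "M",
                        signal_peptide_end = 1L)
  expect_error(mature_nterm(bad), class = "dppsubs_error_annotation")
  bad2 <- tibble::tibble(protein_id = "neg", sequence = "MVTAQ",
                         signal_peptide_end = 0L)
  expect_error(mature_nterm(bad2), class = "dppsubs_error_annotation")
})

test_that("fully specific digestion matches the worked examples", {
  prot <- tibble::tibble(protein_id = "toy", sequence = "MKRAAAR")
  p0 <- digest_params(cleave_after = "R", max_missed_cleavages = 0,
                      min_length = 1, max_length = 40, semi_specific = FALSE)
  d0 <- digest_semi(prot, p0)
  expect_setequal(paste(d0$start, d0$end), c("1 3", "4 7"))
  expect_setequal(d0$sequence, c("MKR", "AAAR"))

  p1 <- digest_params(cleave_after = "R", max_missed_cleavages = 1,
                      min_length = 1, max_length = 40, semi_specific = FALSE)
  d1 <- digest_semi(prot, p1)
  expect_setequal(paste(d1$start, d1$end), c("1 3", "4 7", "1 7"))
})

test_that("semi-specific enumeration agrees with the brute-force oracle", {
  withr::with_seed(11, {
    for (i in 1:25) {
      len <- sample(5:30, 1)
      seq <- random_protein(len)
      params <- digest_params(
        cleave_after = sample(list("R", c("K", "R")), 1)[[1]],
        max_missed_cleavages = sample(0:2, 1),
        min_length = sample(1:4, 1), max_length = sample(8:40, 1),
        semi_specific = sample(c(TRUE, FALSE), 1),
        block_proline = sample(c(TRUE, FALSE), 1))
      got <- digest_semi(tibble::tibble(protein_id = "p", sequence = seq),
                         params)
      want <- bf_digest(seq, params)
      expect_equal(nrow(got), nrow(want),
                   info = paste("protein", seq))
      expect_identical(paste(got$start, got$end), paste(want$start, want$end))
    }
  })
})

test_that("dipeptidyl cleavage shifts the start by two per cycle", {
  span <- tibble::tibble(protein_id = "MEP1L", start = 2L, end = 26L,
                         sequence = paste(rep("A", 25), collapse = ""))
  one <- dipeptidyl_cleave(span, 1)
  expect_equal(one$start, 4L)
  expect_equal(one$end, 26L)
  expect_equal(nchar(span$sequence) - nchar(one$sequence), 2L)

  many <- dipeptidyl_cleave(tibble::tibble(protein_id = "WAGO1L", start = 2L,
                                           end = 40L),
                            cycles = 13)
  expect_equal(many$start, 28L)

  # composition: two single cycles equal one double cycle
  twice <- dipeptidyl_cleave(dipeptidyl_cleave(span, 1), 1)
  expect_identical(twice, dipeptidyl_cleave(span, 2))

  expect_error(dipeptidyl_cleave(tibble::tibble(start = 1L, end = 2L), 1),
               class = "dppsubs_error_precondition")
})

test_that("origin classification distinguishes substrates, products, internal", {
  prot <- tibble::tibble(protein_id = "P", sequence = random_protein(60, 3))
  mature <- tibble::tibble(protein_id = "P", start = 2L, rule = "imet_excision")
  spans <- tibble::tibble(protein_id = "P",
                          start = c(2L, 4L, 33L, 28L, 3L, 40L),
                          end = 50L)
  res <- classify_origin(spans, mature, max_cycles = 15)
  expect_equal(res$origin, c("nterm_substrate", "nterm_product", "internal",
                             "nterm_product", "internal", "internal"))
  expect_equal(res$cycles, c(NA, 1L, NA, 13L, NA, NA))
  # offset 38 would need 19 cycles > max_cycles
  expect_equal(res$origin[res$start == 40L], "internal")
})

test_that("products of k cleavage cycles classify as nterm_product(k)", {
  prot <- tibble::tibble(protein_id = "P", sequence = random_protein(80, 5))
  mature <- mature_nterm(prot)
  sub <- tibble::tibble(protein_id = "P", start = mature$start, end = 60L)
  expect_equal(classify_origin(sub, mature)$origin, "nterm_substrate")
  for (k in c(1L, 2L, 7L, 15L)) {
    prod <- dipeptidyl_cleave(sub, k)
    res <- classify_origin(prod, mature, max_cycles = 15)
    expect_equal(res$origin, "nterm_product")
    expect_equal(res$cycles, k)
  }
})

test_that("P positions read the residues flanking the scissile bond", {
  prot <- tibble::tibble(protein_id = "MEP1L",
                         sequence = "MVTAQSLKNDFGHQWER")
  span <- tibble::tibble(protein_id = "MEP1L", start = 2L, end = 17L)
  res <- p_positions(span, prot)
  expect_equal(c(res$P2, res$P1, res$P1prime), c("V", "T", "A"))

  # positional lookup anywhere in the protein
  span2 <- tibble::tibble(protein_id = "MEP1L", start = 5L, end = 10L)
  res2 <- p_positions(span2, prot)
  expect_equal(c(res2$P2, res2$P1, res2$P1prime), c("Q", "S", "L"))

  expect_error(p_positions(tibble::tibble(protein_id = "MEP1L",
                                          start = 2L, end = 3L), prot),
               class = "dppsubs_error_precondition")
})
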