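# Quadrant classification, pairing geometry and candidate-table assembly.

labeled_row <- function(key, protein_id, start, fc_del, fc_cat,
                        origin = "internal", end = start + 20L,
                        label = "unchanged") {
  tibble::tibble(key = key, protein_id = protein_id, start = as.integer(start),
                 end = as.integer(end), fc_del = fc_del, fc_cat = fc_cat,
                 origin = origin, label = label)
}

test_that("quadrant classification follows the fold-change plane rules", {
  tbl <- dplyr::bind_rows(
    labeled_row("a", "P1", 2, 2.5, 2.5, origin = "nterm_substrate"),
    labeled_row("b", "P1", 4, -2.5, -2.5, origin = "nterm_product"),
    labeled_row("c", "P2", 60, 2.5, 2.5, origin = "nterm_substrate"),
    labeled_row("d", "P3", 2, 0.5, -0.5, origin = "nterm_substrate"),
    labeled_row("e", "P4", 2, 2.5, -2.5, origin = "nterm_substrate"),
    labeled_row("f", "P5", 10, 2.5, 2.5, origin = "internal"))
  res <- quadrant_classify(tbl, pairing_params())
  expect_equal(res$label,
               c("substrate_candidate", "product_candidate",
                 "position_filtered", "unchanged", "discordant", "unchanged"))
})

test_that("pairing respects offset, gate, Manhattan distance and orientation", {
  params <- pairing_params()
  # canonical substrate/product pair: offset 2, distance 10
  tbl <- dplyr::bind_rows(
    labeled_row("s", "CCT4L", 2, 2.5, 2.5, origin = "nterm_substrate"),
    labeled_row("p", "CCT4L", 4, -2.5, -2.5, origin = "nterm_product"))
  pairs <- pair_candidates(tbl, params)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$manhattan_d, 10)
  expect_equal(pairs$start_offset, 2L)

  # no member beyond the threshold -> no pair
  weak <- dplyr::bind_rows(
    labeled_row("s", "P", 2, 1, 1), labeled_row("p", "P", 4, -0.5, -0.5))
  expect_equal(nrow(pair_candidates(weak, params)), 0L)

  # odd offset is not a dipeptide step
  odd <- dplyr::bind_rows(
    labeled_row("s", "P", 2, 2.5, 2.5), labeled_row("p", "P", 5, -2.5, -2.5))
  expect_equal(nrow(pair_candidates(odd, params)), 0L)

  # same-sign movement rejected when orientation is required
  same <- dplyr::bind_rows(
    labeled_row("s", "P", 2, 2.5, 2.5), labeled_row("p", "P", 4, 2.5, 2.5))
  expect_equal(nrow(pair_candidates(same, params)), 0L)
  relaxed <- pairing_params(require_opposite_sign = FALSE, manhattan_min = 0)
  expect_equal(nrow(pair_candidates(same, relaxed)), 1L)

  # Manhattan minimum filters close pairs
  close <- dplyr::bind_rows(
    labeled_row("s", "P", 2, 2.5, 2.5), labeled_row("p", "P", 4, -0.2, -0.2))
  expect_equal(nrow(pair_candidates(close, pairing_params(manhattan_min = 11))),
               0L)
  expect_equal(nrow(pair_candidates(close, params)), 1L)
})

test_that("pairing is one-to-one, order-invariant and monotone in manhattan_min", {
  withr::with_seed(31, {
    tbl <- dplyr::bind_rows(lapply(1:40, function(i) {
      pid <- paste0("P", sample(8, 1))
      up <- runif(1) < 0.5
      labeled_row(paste0("k", i), pid, sample(seq(2, 20, by = 2), 1),
                  fc_del = (if (up) 1 else -1) * runif(1, 0, 4),
                  fc_cat = (if (up) 1 else -1) * runif(1, 0, 4))
    }))
  })
  params <- pairing_params()
  pairs <- pair_candidates(tbl, params)
  members <- c(pairs$substrate_key, pairs$product_key)
  expect_equal(anyDuplicated(members), 0L)

  shuffled <- tbl[withr::with_seed(32, sample(nrow(tbl))), ]
  pairs2 <- pair_candidates(shuffled, params)
  expect_identical(
    dplyr::arrange(pairs, substrate_key),
    dplyr::arrange(pairs2, substrate_key))

  loose <- pair_candidates(tbl, pairing_params(manhattan_min = 0))
  strict <- pair_candidates(tbl, pairing_params(manhattan_min = 6))
  strict_ids <- paste(strict$substrate_key, strict$product_key)
  loose_ids <- paste(loose$substrate_key, loose$product_key)
  expect_gte(nrow(loose), nrow(strict))
})

test_that("exhaustive matching never scores below greedy", {
  withr::with_seed(33, {
    tbl <- dplyr::bind_rows(lapply(1:12, function(i) {
      labeled_row(paste0("k", i), "P1", sample(seq(2, 16, by = 2), 1),
                  fc_del = runif(1, -4, 4), fc_cat = runif(1, -4, 4))
    }))
  })
  params_g <- pairing_params(require_opposite_sign = FALSE, manhattan_min = 0)
  params_e <- pairing_params(require_opposite_sign = FALSE, manhattan_min = 0,
                             matching = "exhaustive")
  g <- pair_candidates(tbl, params_g)
  e <- pair_candidates(tbl, params_e)
  expect_gte(sum(e$manhattan_d), sum(g$manhattan_d))
})

test_that("candidate table carries P positions and evidence scores", {
  prot <- tibble::tibble(protein_id = "MEP1L", sequence = "MVTAQSLKNDFGHQWER")
  tbl <- dplyr::bind_rows(
    labeled_row("s", "MEP1L", 2, 2.5, 3.0, origin = "nterm_substrate",
                end = 17L, label = "substrate_candidate"),
    labeled_row("p", "MEP1L", 4, -4.0, -3.5, origin = "nterm_product",
                end = 17L, label = "product_candidate"))
  pairs <- pair_candidates(tbl, pairing_params())
  cand <- build_candidate_table(pairs, tbl, prot)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$paired)
  expect_equal(c(cand$P2, cand$P1, cand$P1prime), c("V", "T", "A"))
  # evidence: max over members of min(|fc_del|, |fc_cat|)
  expect_equal(cand$evidence_score, 3.5)

  # empty input -> empty table
  empty <- build_candidate_table(pair_candidates(tbl[0, ], pairing_params()),
                                 tbl[0, ], prot)
  expect_equal(nrow(empty), 0L)

  # a lone product at start 4 infers substrate start 2 and P positions
  lone <- labeled_row("p", "MEP1L", 4, -4.0, -3.5, origin = "nterm_product",
                      end = 17L, label = "product_candidate")
  cand2 <- build_candidate_table(pair_candidates(lone, pairing_params()),
                                 lone, prot)
  expect_equal(cand2$inferred_substrate_start, 2L)
  want <- p_positions(tibble::tibble(protein_id = "MEP1L", start = 2L,
                                     end = 17L), prot)
  expect_equal(c(cand2$P2, cand2$P1, cand2$P1prime),
               c(want$P2, want$P1, want$P1prime))

  # out-of-range P positions are flagged, not dropped
  edge <- labeled_row("q", "MEP1L", 2, -4.0, -3.5, origin = "nterm_product",
                      end = 17L, label = "product_candidate")
  cand3 <- build_candidate_table(pair_candidates(edge, pairing_params()),
                                 edge, prot)
  expect_equal(nrow(cand3), 1L)
  expect_false(cand3$p_ok)
  expect_true(is.na(cand3$P2))
})

test_that("full pipeline recovers a hand-built substrate/product signal", {
  des <- default_channel_design()
  prot <- tibble::tibble(
    protein_id = c("MEP1L", "BYSTD"),
    sequence = c("MVTAQSLKNDFGHQWERAAKLMNPQ", "MDEAQSLKNDFGHQWERAAKLMNPQ"))
  base <- 2^20
  inten <- rbind(
    c(base * 0.1, base * 0.1, base, base, base, base),          # substrate up
    c(base, base, base * 0.05, base * 0.05, base * 0.05, base * 0.05), # product down
    matrix(2^rnorm(6 * 30, 20, 0.2), ncol = 6))                 # bystanders
  colnames(inten) <- des$channel
  rows <- dplyr::bind_cols(
    tibble::tibble(protein_id = c("MEP1L", "MEP1L", rep("BYSTD", 30)),
                   start = c(2L, 4L, rep(30L, 30)),
                   end = c(17L, 17L, 40L + seq_len(30)),
                   sequence = "X", mod_label = "none",
                   charge = c(2L, 2L, seq_len(30) + 1L)),
    tibble::as_tibble(inten))
  calls <- call_substrates(rows, prot, des)
  expect_equal(nrow(calls$pairs), 1L)
  cand <- tidy(calls)
  expect_equal(cand$protein_id[1], "MEP1L")
  expect_equal(c(cand$P2[1], cand$P1[1], cand$P1prime[1]), c("V", "T", "A"))
  g <- glance(calls)
  expect_equal(g$n_pairs, 1L)
})
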