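test_that("normalized bit score matches the idealized scoring scheme", {
  expect_equal(normalized_bit_score(1000, 0, 0, 1000), 2.0)
  expect_equal(normalized_bit_score(750, 0, 0, 1000), 1.5)
  expect_equal(normalized_bit_score(900, 50, 2, 1000), 1.69) # (1800-100-10)/1000
  expect_equal(normalized_bit_score(0, 0, 0, 1000), 0)
  # heavily penalized alignments clamp at zero rather than going negative
  expect_equal(normalized_bit_score(10, 500, 0, 1000), 0)
  # an external aligner-reported score overrides the idealized formula
  expect_equal(normalized_bit_score(1000, 0, 0, 1000, external_bits = 1950),
               1.95)
  expect_error(normalized_bit_score(100, 0, 0, 0), "ref_length")
})

test_that("BS strictly decreases in mismatches and gap openings", {
  base <- normalized_bit_score(900, 0, 0, 1000)
  for (x in 1:5) {
    expect_lt(normalized_bit_score(900, x, 0, 1000),
              normalized_bit_score(900, x - 1, 0, 1000))
    expect_lt(normalized_bit_score(900, 0, x, 1000),
              normalized_bit_score(900, 0, x - 1, 1000))
  }
  expect_equal(normalized_bit_score(900, 0, 0, 1000), base)
})

test_that("SFB is fragments over reference length, split-invariant", {
  expect_equal(sequenced_fragments_per_bp(200, 1000), 0.2)
  expect_equal(sequenced_fragments_per_bp(c(150, 50), 1000), 0.2)
  expect_equal(sequenced_fragments_per_bp(c(100, 60, 40), 1000), 0.2)
  expect_equal(sequenced_fragments_per_bp(0, 1000), 0)
  expect_error(sequenced_fragments_per_bp(10, 0), "ref_length")
})

qd_fixture <- function() {
  reference <- tibble::tibble(seq_id = c("g1", "g2", "g3"),
                              length = c(1000L, 500L, 800L))
  aln <- dplyr::bind_rows(
    aln_row("u1", "g1", q_end = 1000L, s_end = 1000L, bit_score = 2000),
    aln_row("u2", "g2", q_end = 400L, s_end = 400L, bit_score = 800),
    aln_row("u3", "g3", q_end = 560L, s_end = 560L, bit_score = 1120)
  )
  assignments <- assign_best_loci(aln)
  counts <- toy_counts(u1 = 200, u2 = 10, u3 = 40)
  list(reference = reference, assignments = assignments, counts = counts)
}

test_that("the quality-depth table takes best-alignment BS and summed SFB", {
  f <- qd_fixture()
  qd <- build_quality_depth_table(f$assignments, f$counts, f$reference)
  expect_equal(nrow(qd), 3)
  # worked example: perfect 1000 bp unigene with 200 fragments
  g1 <- qd[qd$gene_id == "g1", ]
  expect_equal(g1$bs, 2.0)
  expect_equal(g1$sfb, 0.2)
  expect_equal(g1$best_unigene, "u1")
  # BS {2.0, 1.6, 1.4} -> 2 genes above 1.5
  expect_equal(sort(round(qd$bs, 10)), c(1.4, 1.6, 2.0))
  expect_equal(qd_high_count(qd), 2L)

  # fragments split across two unigenes of one gene sum before normalizing
  aln2 <- dplyr::bind_rows(
    aln_row("u1", "g1", q_end = 600L, s_end = 600L, bit_score = 1200),
    aln_row("u1b", "g1", q_end = 400L, s_start = 601L, s_end = 1000L,
            bit_score = 800)
  )
  qd2 <- build_quality_depth_table(assign_best_loci(aln2),
                                   toy_counts(u1 = 150, u1b = 50),
                                   f$reference[1, ])
  expect_equal(qd2$sfb, 0.2)
  expect_equal(qd2$bs, 1.2)  # best alignment only, not the sum

  # empty assembly: all zero, count zero
  qd0 <- build_quality_depth_table(f$assignments[0, ], f$counts[0, ],
                                   f$reference)
  expect_equal(qd0$bs, c(0, 0, 0))
  expect_equal(qd_high_count(qd0), 0L)

  bad <- dplyr::mutate(f$assignments, gene_id = "missing")
  expect_error(build_quality_depth_table(bad, f$counts, f$reference),
               "absent from reference")
})

test_that("threshold counts are monotone non-increasing in the threshold", {
  f <- qd_fixture()
  qd <- build_quality_depth_table(f$assignments, f$counts, f$reference)
  ts <- seq(0, 2.5, by = 0.25)
  counts <- vapply(ts, function(t) qd_high_count(qd, t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("conserved-ortholog recovery reports tail fractions", {
  qd <- tibble::tibble(gene_id = paste0("g", 1:4), bs = c(2, 2, 1.2, 0),
                       sfb = 1, best_unigene = NA, ref_length = 1000L)
  cov <- tibble::tibble(gene_id = paste0("g", 1:4),
                        breadth_pct = c(100, 95, 80, 0),
                        n_unigenes = c(1L, 1L, 1L, 0L),
                        status = c(rep("covered", 3), "no_hit"))
  res <- uco_recovery(qd, cov, paste0("g", 1:4))
  expect_equal(res$frac_cov90, 0.5)
  expect_equal(res$frac_cov99, 0.25)
  expect_equal(res$frac_bs_high, 0.5)
  # perfect recovery
  perfect <- uco_recovery(dplyr::mutate(qd, bs = 2),
                          dplyr::mutate(cov, breadth_pct = 100),
                          paste0("g", 1:4))
  expect_equal(perfect$frac_bs_high, 1)
  expect_equal(perfect$frac_cov99, 1)
  expect_warning(res2 <- uco_recovery(qd, cov, c("g1", "gZZ")), "absent")
  expect_equal(res2$n_listed, 1)
  expect_error(uco_recovery(qd, cov, character(0)), "empty")
})

test_that("paralog pairing is reciprocal-best-hit with per-mate classes", {
  hits <- dplyr::bind_rows(
    aln_row("gA", "gB", bit_score = 900),
    aln_row("gB", "gA", bit_score = 900),
    aln_row("gC", "gB", bit_score = 700),  # one-sided: no pair
    aln_row("gB", "gC", bit_score = 100),
    aln_row("gA", "gA", bit_score = 2000)  # self-hit ignored
  )
  qd <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                       bs = c(1.8, 1.7, 0.5), sfb = c(0.3, 0.05, 0.2),
                       best_unigene = NA, ref_length = 1000L)
  pairs <- paralog_pairs(hits, qd)
  expect_equal(nrow(pairs), 1)
  expect_equal(c(pairs$gene_a, pairs$gene_b), c("gA", "gB"))
  expect_equal(pairs$expression_class, "one_expressed")  # 0.3 vs 0.05
  expect_equal(pairs$assembly_class, "both_high")        # 1.8 and 1.7 > 1.5
  # every gene appears in at most one pair
  expect_false(any(duplicated(c(pairs$gene_a, pairs$gene_b))))
})

test_that("the CRG subset keeps the lowest-Ks expressed pairs under the cap", {
  qd <- tibble::tibble(gene_id = sprintf("g%02d", 1:8), bs = 2, sfb = 1,
                       best_unigene = NA, ref_length = 1000L)
  hits <- purrr::map_dfr(seq(1, 8, by = 2), function(i) {
    a <- sprintf("g%02d", i); b <- sprintf("g%02d", i + 1)
    dplyr::bind_rows(aln_row(a, b, bit_score = 500),
                     aln_row(b, a, bit_score = 500))
  })
  ks <- tibble::tibble(gene_a = sprintf("g%02d", c(1, 3, 5, 7)),
                       gene_b = sprintf("g%02d", c(2, 4, 6, 8)),
                       ks = c(0.05, 0.15, 0.5, 0.1))
  cfg <- eval_config(crg_max_pairs = 2)
  pairs <- paralog_pairs(hits, qd, ks = ks, config = cfg)
  expect_equal(nrow(pairs), 4)
  crg <- pairs[pairs$is_crg, ]
  # ks 0.5 exceeds the 0.2 ceiling; cap 2 keeps the two lowest (0.05, 0.1)
  expect_setequal(crg$ks, c(0.05, 0.1))
})
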