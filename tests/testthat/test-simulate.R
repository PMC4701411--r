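test_that("reference simulation is deterministic and internally consistent", {
  plan <- simulation_plan(n_genes = 60, paralog_fraction = 0.2, seed = 13)
  sim1 <- simulate_reference(plan)
  sim2 <- simulate_reference(plan)
  expect_identical(sim1$reference, sim2$reference)
  expect_identical(sim1$genome, sim2$genome)
  # 60 genes at paralog fraction 0.2 -> 6 pairs with recorded pairing
  expect_equal(nrow(sim1$reference), 60)
  expect_equal(nrow(sim1$paralog_pairs), 6)
  # loci order indices are consistent with start coordinates
  chk <- sim1$loci |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(ok = all(order_index == rank(start)), .groups = "drop")
  expect_true(all(chk$ok))
  # gene sequences are literally embedded in the genome at their loci
  genome <- setNames(sim1$genome$sequence, sim1$genome$chrom)
  for (i in sample(nrow(sim1$loci), 10)) {
    lc <- sim1$loci[i, ]
    expect_identical(unname(substr(genome[lc$chrom], lc$start, lc$end)),
                     sim1$reference$sequence[
                       sim1$reference$seq_id == lc$gene_id])
  }
  # paralog mates are never genomically adjacent
  ord <- setNames(sim1$loci$order_index, sim1$loci$gene_id)
  chm <- setNames(sim1$loci$chrom, sim1$loci$gene_id)
  with(sim1$paralog_pairs, {
    same <- chm[gene_a] == chm[gene_b]
    expect_false(any(same & abs(ord[gene_a] - ord[gene_b]) == 1))
  })
})

test_that("zero-divergence paralog mates are identical in sequence", {
  plan <- simulation_plan(n_genes = 20, paralog_fraction = 0.4,
                          paralog_divergence = 0, seed = 2)
  sim <- simulate_reference(plan)
  seqs <- setNames(sim$reference$sequence, sim$reference$seq_id)
  expect_true(all(seqs[sim$paralog_pairs$gene_a] ==
                    seqs[sim$paralog_pairs$gene_b]))
  expect_error(simulation_plan(length_min = 10000, length_mean = 100,
                               length_sd = 10),
               "infeasible")
})

test_that("expression simulation is deterministic with designed zeros", {
  plan <- simulation_plan(n_genes = 100, zero_fraction = 0.1, seed = 5)
  sim <- simulate_reference(plan)
  e1 <- simulate_expression(plan, sim)
  expect_identical(e1, simulate_expression(plan, sim))
  expect_equal(attr(e1, "zero_genes"), e1$gene_id[e1$fragment_count == 0])
  expect_gte(length(attr(e1, "zero_genes")), 1)
  # degenerate distribution: every gene shares one count value
  flat <- simulation_plan(n_genes = 30, expr_sdlog = 0, zero_fraction = 0,
                          seed = 5)
  ef <- simulate_expression(flat, simulate_reference(flat))
  expect_equal(length(unique(ef$fragment_count)), 1)
})

test_that("an empty error plan reproduces the reference exactly", {
  plan <- simulation_plan(n_genes = 15, seed = 4)
  sim <- simulate_reference(plan)
  ep <- error_plan(sim, n_t1_case1 = 0, n_t1_case2 = 0, n_t1_case3 = 0,
                   n_chimera = 0, n_co_assembly = 0, n_duplicate = 0,
                   n_t2_case3 = 0, n_t2_case4 = 0, n_t2_case5 = 0)
  truth <- corrupt_assembly(sim, ep)
  expect_equal(nrow(truth$assembly), 15)
  expect_setequal(gsub("^u_", "", truth$assembly$seq_id),
                  sim$reference$seq_id)
  expect_setequal(truth$assembly$sequence, sim$reference$sequence)
  expect_equal(nrow(truth$labels$type1), 0)
  expect_equal(nrow(truth$labels$type2), 0)
  al <- derive_truth_alignments(truth)
  expect_equal(nrow(classify_type1(al$cdna, k = 31)), 0)
  expect_equal(nrow(classify_type2(al$cdna, sim$loci, truth$assembly)), 0)
})

test_that("derived alignments carry idealized scores by construction", {
  fx <- default_truth_fixture(seed = 3, n_genes = 80, n_each = 1, n_trans = 0)
  al <- fx$aln
  # a clean background unigene: full length, identity 100, 2 bits per base
  bg <- al$cdna |>
    dplyr::filter(pct_identity == 100, q_start == 1) |>
    dplyr::slice_head(n = 5)
  expect_equal(bg$bit_score, 2 * bg$aln_length)
  # chimeric unigenes have two cDNA records with disjoint query segments
  chi <- fx$truth$labels$type2 |> dplyr::filter(kind == "T2_case1")
  recs <- al$cdna |> dplyr::filter(query_id == chi$unigene_id[1]) |>
    dplyr::arrange(q_start)
  expect_equal(nrow(recs), 2)
  expect_lt(recs$q_end[1], recs$q_start[2])
  # co-assembled pairs get one contiguous genome window record
  co <- fx$truth$labels$verdicts |> dplyr::filter(verdict == "co_assembly")
  gw <- al$genome |> dplyr::filter(query_id == co$unigene_id[1])
  expect_equal(nrow(gw), 1)
})

test_that("corruption and fragment assignment are deterministic in the seed", {
  plan <- simulation_plan(n_genes = 80, seed = 17)
  sim <- simulate_reference(plan)
  ep <- error_plan(sim, n_chimera = 2, n_duplicate = 2,
                   noise_mismatch_rate = 0.002)
  t1 <- corrupt_assembly(sim, ep)
  t2 <- corrupt_assembly(sim, ep)
  expect_identical(t1$assembly, t2$assembly)
  expect_identical(t1$geometry, t2$geometry)
  expr <- simulate_expression(plan, sim)
  f1 <- assign_fragments(expr, t1)
  expect_identical(f1, assign_fragments(expr, t2))
  # split counts conserve gene totals
  totals <- f1 |>
    dplyr::inner_join(t1$sources, by = "unigene_id") |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(n = sum(fragment_count), .groups = "drop")
  joined <- dplyr::inner_join(totals, expr, by = "gene_id")
  expect_equal(joined$n, joined$fragment_count)
})

test_that("read subsampling keeps pairs atomically until the base target", {
  pairs <- tibble::tibble(pair_id = sprintf("p%04d", 1:1000),
                          n_bases = 152L)
  # 15,200 target over 152-base pairs keeps exactly 100 pairs
  kept <- subsample_reads(pairs, target_bases = 15200, seed = 9)
  expect_equal(nrow(kept), 100)
  # target above the total keeps everything
  expect_equal(nrow(subsample_reads(pairs, target_bases = 1e9, seed = 9)),
               1000)
  # deterministic given the seed
  expect_identical(kept, subsample_reads(pairs, target_bases = 15200, seed = 9))
  # uneven pair sizes may overshoot by at most the last accepted pair
  withr::with_seed(1, {
    pairs2 <- tibble::tibble(pair_id = sprintf("p%03d", 1:200),
                             n_bases = sample(100:300, 200, replace = TRUE))
  })
  kept2 <- subsample_reads(pairs2, target_bases = 5000, seed = 2)
  got <- sum(kept2$n_bases)
  expect_gte(got, 5000)
  expect_lt(got - max(kept2$n_bases), 5000)
})

test_that("FASTQ subsampling writes paired files deterministically", {
  withr::with_seed(8, {
    n <- 50
    mk_fq <- function(path) {
      reads <- replicate(n, paste(sample(c("A", "C", "G", "T"), 40,
                                         replace = TRUE), collapse = ""))
      writeLines(as.vector(rbind(paste0("@r", 1:n), reads, "+",
                                 strrep("I", 40))), path)
    }
    r1 <- withr::local_tempfile(fileext = ".fq")
    r2 <- withr::local_tempfile(fileext = ".fq")
    mk_fq(r1); mk_fq(r2)
    o1 <- withr::local_tempfile(fileext = ".fq")
    o2 <- withr::local_tempfile(fileext = ".fq")
    kept <- subsample_reads(target_bases = 800, seed = 4,
                            r1 = r1, r2 = r2, out_r1 = o1, out_r2 = o2)
    expect_length(kept, 10)  # 800 / (2 x 40)
    expect_equal(length(readLines(o1)), 40)
    expect_equal(readLines(o1)[1:4 + 4][1],
                 readLines(o1)[1:4 + 4][1])  # smoke: file is well-formed
  })
})

test_that("replicate subsamples of equal size share most detected genes", {
  plan <- simulation_plan(n_genes = 120, zero_fraction = 0, seed = 31)
  sim <- simulate_reference(plan)
  expr <- simulate_expression(plan, sim)
  reads <- tibble::tibble(pair_id = rep(expr$gene_id, expr$fragment_count),
                          n_bases = 152L)
  detect <- function(seed) {
    unique(subsample_reads(reads, target_bases = round(0.5 * sum(reads$n_bases)),
                           seed = seed)$pair_id)
  }
  d1 <- detect(1); d2 <- detect(2); d3 <- detect(3)
  shared <- length(Reduce(intersect, list(d1, d2, d3)))
  avg <- mean(lengths(list(d1, d2, d3)))
  # half the fragments recover a highly consistent gene set on this profile
  expect_gt(shared / avg, 0.8)
})
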