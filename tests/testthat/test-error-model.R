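# --- Type I ---------------------------------------------------------------

test_that("Type I cases follow the gap / insufficient / conflict taxonomy", {
  k <- 31L
  gap <- classify_type1(gene_hits(list(c(1, 400), c(501, 1000))), k)
  expect_equal(gap$kind, "T1_case1")
  expect_equal(gap$gap, 100L)

  insuf <- classify_type1(gene_hits(list(c(1, 500), c(480, 1000))), k)
  expect_equal(insuf$kind, "T1_case2")
  expect_equal(insuf$overlap, 21L)

  confl <- classify_type1(gene_hits(list(c(1, 500), c(450, 1000))), k)
  expect_equal(confl$kind, "T1_case3")
  expect_equal(confl$overlap, 51L)

  expect_equal(nrow(classify_type1(gene_hits(list(c(1, 1000))), k)), 0)
  expect_error(classify_type1(gene_hits(list(c(1, 10))), k = 1), "k must")
})

test_that("Type I boundary is exact: overlap k-1 is Case II, k is Case III", {
  k <- 31L
  at_km1 <- classify_type1(gene_hits(list(c(1, 500), c(471, 1000))), k)
  expect_equal(at_km1$overlap, k - 1L)
  expect_equal(at_km1$kind, "T1_case2")
  at_k <- classify_type1(gene_hits(list(c(1, 500), c(470, 1000))), k)
  expect_equal(at_k$overlap, k)
  expect_equal(at_k$kind, "T1_case3")
  # abutting intervals: overlap 0 is still Case II
  abut <- classify_type1(gene_hits(list(c(1, 500), c(501, 1000))), k)
  expect_equal(abut$overlap, 0L)
  expect_equal(abut$kind, "T1_case2")
})

# --- Type II --------------------------------------------------------------

t2_hits <- function(segs, genes = c("gA", "gB"), bits = NULL, unigene = "u1") {
  purrr::imap_dfr(segs, function(sg, i) {
    aln_row(query_id = unigene, subject_id = genes[i],
            q_start = sg[1], q_end = sg[2],
            s_start = 1L, s_end = sg[2] - sg[1] + 1L,
            bit_score = if (is.null(bits)) NULL else bits[i])
  })
}

u1k <- function() toy_unigenes("u1", 1000L)

test_that("Type II cases classify by query-segment geometry", {
  loci <- toy_loci(c("gA", "gX", "gB"))  # gA and gB are NOT adjacent
  # Case I: disjoint segments to non-adjacent genes
  c1 <- classify_type2(t2_hits(list(c(1, 500), c(520, 1000))), loci, u1k())
  expect_equal(c1$kind, "T2_case1")
  expect_equal(c1$adjacency, "non_adjacent")
  # Case II: equal full-length hits
  c2 <- classify_type2(t2_hits(list(c(1, 1000), c(1, 1000)), bits = c(2000, 2000)),
                       loci, u1k())
  expect_equal(c2$kind, "T2_case2")
  # Case III: proper containment (precedence over Case IV)
  c3 <- classify_type2(t2_hits(list(c(1, 1000), c(100, 950))), loci, u1k())
  expect_equal(c3$kind, "T2_case3")
  # Case IV: staggered overlap > 80% of unigene length
  c4 <- classify_type2(t2_hits(list(c(1, 900), c(50, 1000))), loci, u1k())
  expect_equal(c4$kind, "T2_case4")
  expect_true(c4$seg_overlap > 800)
  # Case V: staggered overlap <= 80%
  c5 <- classify_type2(t2_hits(list(c(1, 600), c(401, 1000))), loci, u1k())
  expect_equal(c5$kind, "T2_case5")
  # single gene: never an event
  one <- classify_type2(t2_hits(list(c(1, 500)), genes = "gA"), loci, u1k())
  expect_equal(nrow(one), 0)
})

test_that("adjacent-gene pairs are excluded as co-assemblies", {
  loci <- toy_loci(c("gA", "gB"))  # adjacent
  res <- classify_type2(t2_hits(list(c(1, 500), c(520, 1000))), loci, u1k())
  expect_equal(nrow(res), 0)
  # same geometry across chromosomes is never adjacent
  loci2 <- toy_loci(c("gA", "gB"), chrom = c("chr1", "chr2"))
  res2 <- classify_type2(t2_hits(list(c(1, 500), c(520, 1000))), loci2, u1k())
  expect_equal(res2$kind, "T2_case1")
})

test_that("hits below the identity floor are ignored; missing annotation is flagged", {
  loci <- toy_loci(c("gA", "gX", "gB"))
  hits <- t2_hits(list(c(1, 500), c(520, 1000)))
  hits$pct_identity[2] <- 95  # below the 99% default
  expect_equal(nrow(classify_type2(hits, loci, u1k())), 0)
  # gB missing from the annotation: event still emitted, adjacency unknown
  res <- classify_type2(t2_hits(list(c(1, 500), c(520, 1000))),
                        toy_loci("gA"), u1k())
  expect_equal(res$adjacency, "unknown")
  expect_equal(res$kind, "T2_case1")
})

# --- Chimera adjudication -------------------------------------------------

gen_hits <- function(rows, unigene = "u1") {
  purrr::map_dfr(rows, function(r) {
    aln_row(query_id = unigene, subject_id = r$chrom,
            pct_identity = r$id %||% 100,
            q_start = r$q[1], q_end = r$q[2],
            s_start = r$s[1], s_end = r$s[2],
            e_value = r$e %||% 0)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("chimera adjudication separates co-assembly, duplicates and chimeras", {
  u <- u1k()
  # one contiguous full-length genomic window -> co-assembly
  co <- adjudicate_chimera(gen_hits(list(
    list(chrom = "chr1", q = c(1, 1000), s = c(5001, 6000)))), u)
  expect_equal(co$verdict, "co_assembly")
  # spliced alignment: two same-chromosome hits separated by an intron-scale
  # gap merge into one window -> still co-assembly
  spliced <- adjudicate_chimera(gen_hits(list(
    list(chrom = "chr1", q = c(1, 500), s = c(5001, 5500)),
    list(chrom = "chr1", q = c(501, 1000), s = c(7000, 7499)))), u)
  expect_equal(spliced$verdict, "co_assembly")
  # two distinct full-length windows -> ambiguous duplicate
  dup <- adjudicate_chimera(gen_hits(list(
    list(chrom = "chr1", q = c(1, 1000), s = c(5001, 6000)),
    list(chrom = "chr2", q = c(1, 1000), s = c(9001, 10000)))), u)
  expect_equal(dup$verdict, "ambiguous_duplicate")
  # halves on two chromosomes, neither window near-complete -> chimera
  chi <- adjudicate_chimera(gen_hits(list(
    list(chrom = "chr1", q = c(1, 500), s = c(5001, 5500)),
    list(chrom = "chr2", q = c(501, 1000), s = c(9001, 9500)))), u)
  expect_equal(chi$verdict, "chimera")
  # all hits below the identity filter -> unresolved
  bad <- adjudicate_chimera(gen_hits(list(
    list(chrom = "chr1", q = c(1, 1000), s = c(5001, 6000), id = 85))), u)
  expect_equal(bad$verdict, "unresolved")
})

test_that("trans-splice verdicts require the candidate flag", {
  u <- u1k()
  hits <- gen_hits(list(
    list(chrom = "chr1", q = c(1, 500), s = c(5001, 5500)),
    list(chrom = "chr1", q = c(501, 1000), s = c(90001, 90500))))
  unflagged <- adjudicate_chimera(hits, u)
  expect_equal(unflagged$verdict, "chimera")
  flagged <- adjudicate_chimera(hits, u, trans_splice_ids = "u1")
  expect_equal(flagged$verdict, "trans_spliced_candidate")
})

# --- Report ---------------------------------------------------------------

test_that("the error report counts kinds and computes the Type II rate", {
  events <- tibble::tibble(
    kind = c("T2_case1", "T2_case1", "T2_case3", "T2_case5"),
    unigene_id = paste0("u", 1:4)
  )
  assignments <- tibble::tibble(unigene_id = paste0("u", 1:20000),
                                gene_id = paste0("g", 1:20000))
  rep <- summarize_error_report(events, assignments,
                                detected_genes = paste0("g", 1:20000))
  expect_equal(rep$type2_rate, 4 / 20000)
  expect_equal(rep$T2_case1, 2L)
  expect_equal(rep$T1_case1, 0L)

  zero <- summarize_error_report(events[0, ], assignments[1:8, ],
                                 detected_genes = paste0("g", 1:10))
  expect_equal(zero$type2_rate, 0)
  expect_equal(zero$no_hit_genes, 2L)
})
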