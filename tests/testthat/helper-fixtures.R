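# Shared fixture builders. All fixtures are generated in code.

# a minimal 12-column alignment row with overridable fields
aln_row <- function(query_id = "u1", subject_id = "g1", pct_identity = 100,
                    aln_length = NULL, mismatches = 0L, gap_openings = 0L,
                    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
                    e_value = 0, bit_score = NULL) {
  if (is.null(aln_length)) aln_length <- abs(q_end - q_start) + 1L
  if (is.null(bit_score)) bit_score <- 2 * (aln_length - mismatches)
  tibble::tibble(query_id, subject_id, pct_identity,
                 aln_length = as.integer(aln_length),
                 mismatches = as.integer(mismatches),
                 gap_openings = as.integer(gap_openings),
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 s_start = as.integer(s_start), s_end = as.integer(s_end),
                 e_value, bit_score)
}

# alignments of several unigenes to one gene, given subject intervals
gene_hits <- function(intervals, gene = "g1") {
  purrr::imap_dfr(intervals, function(iv, i) {
    aln_row(query_id = paste0("u", i), subject_id = gene,
            q_start = 1L, q_end = iv[2] - iv[1] + 1L,
            s_start = iv[1], s_end = iv[2])
  })
}

# a small annotation with genes in order along chromosomes;
# genes is a tibble(gene_id, chrom) or a character vector (one chrom)
toy_loci <- function(gene_id, chrom = "chr1", gene_length = 1000L,
                     gap = 500L) {
  tibble::tibble(gene_id = gene_id, chrom = chrom) |>
    dplyr::group_by(chrom) |>
    dplyr::mutate(
      order_index = dplyr::row_number(),
      start = (order_index - 1L) * (gene_length + gap) + 1L,
      end = start + gene_length - 1L,
      strand = "+"
    ) |>
    dplyr::ungroup() |>
    dplyr::select(gene_id, chrom, start, end, strand, order_index)
}

toy_unigenes <- function(ids, lengths) {
  tibble::tibble(seq_id = ids, sequence = strrep("A", lengths),
                 length = as.integer(lengths), n_count = 0L)
}

toy_counts <- function(...) {
  x <- c(...)
  tibble::tibble(unigene_id = names(x), fragment_count = as.integer(x))
}

# independent brute-force oracles ------------------------------------------

# coverage breadth by marking a boolean base mask
oracle_breadth <- function(intervals, gene_length) {
  mask <- logical(gene_length)
  for (iv in intervals) mask[iv[1]:iv[2]] <- TRUE
  100 * sum(mask) / gene_length
}

# N50 by enumerating candidate lengths
oracle_n50 <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(as.numeric(lengths[lengths >= L])) >= total / 2) return(L)
  }
  min(lengths)
}

# E[unique unigenes] after m draws without replacement, by full enumeration
# of which fragments are drawn (hypergeometric per unigene)
oracle_expected_unique <- function(counts, m) {
  total <- sum(counts)
  sum(vapply(counts, function(ci) {
    1 - choose(total - ci, m) / choose(total, m)
  }, numeric(1)))
}

# exact sd of the unique-unigene count after m draws without replacement,
# via inclusion-exclusion over detection indicators
oracle_unique_sd <- function(counts, m) {
  total <- sum(counts)
  q <- choose(total - counts, m) / choose(total, m)  # miss probabilities
  v <- sum(q * (1 - q))
  n <- length(counts)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      qij <- choose(total - counts[i] - counts[j], m) / choose(total, m)
      v <- v + (qij - q[i] * q[j])
    }
  }
  sqrt(max(v, 0))
}

# default fixture used by several test files
default_truth_fixture <- function(seed = 11, n_genes = 150,
                                  n_each = 3, n_trans = 2) {
  plan <- simulation_plan(n_genes = n_genes, paralog_fraction = 0.2,
                          seed = seed)
  sim <- simulate_reference(plan)
  ep <- error_plan(sim,
                   n_t1_case1 = n_each, n_t1_case2 = n_each,
                   n_t1_case3 = n_each, n_chimera = n_each,
                   n_co_assembly = n_each, n_duplicate = n_each,
                   n_t2_case3 = n_each, n_t2_case4 = n_each,
                   n_t2_case5 = n_each, n_trans_splice = n_trans)
  truth <- corrupt_assembly(sim, ep)
  list(plan = plan, sim = sim, eplan = ep, truth = truth,
       aln = derive_truth_alignments(truth))
}
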