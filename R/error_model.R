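t1_kinds <- c("T1_case1", "T1_case2", "T1_case3")
t2_kinds <- c("T2_case1", "T2_case2", "T2_case3", "T2_case4", "T2_case5")
error_kinds <- c(t1_kinds, t2_kinds)

#' Classify Type I (fragmentation) errors
#'
#' Type I errors are failures to assemble one locus into one unigene. For
#' each reference gene, each unigene's single best alignment to that gene is
#' taken, the canonical subject intervals are sorted by start, and every
#' consecutive pair of distinct-unigene intervals is classified:
#'
#' * a positive subject-coordinate gap between the intervals is a coverage
#'   gap (**Case I**);
#' * an overlap of `0` to `k - 1` bases is an insufficient overlap — too
#'   short for the assembler's k-mer graph to have joined the pieces
#'   (**Case II**);
#' * an overlap greater than `k - 1` bases is a conflicting overlap — the
#'   pieces shared enough sequence to be joined but were not (**Case III**).
#'
#' A gene represented by a single unigene yields no events.
#'
#' @param aln Alignments of unigenes to reference cDNAs.
#' @param k Assembly k-mer value (>= 2).
#' @return A tibble of events: `kind`, `gene_id`, `unigene_a`, `unigene_b`,
#'   `gap`, `overlap` (exactly one of `gap`/`overlap` is meaningful per row;
#'   the other is `NA`).
#' @export
classify_type1 <- function(aln, k = 31L) {
  if (k < 2) abort("k must be >= 2")
  empty <- tibble(kind = character(), gene_id = character(),
                  unigene_a = character(), unigene_b = character(),
                  gap = integer(), overlap = integer())
  if (nrow(aln) == 0) return(empty)
  best <- canonicalize_alignments(aln) |>
    arrange(subject_id, query_id, desc(bit_score), e_value) |>
    distinct(subject_id, query_id, .keep_all = TRUE)
  events <- best |>
    group_by(subject_id) |>
    filter(n() > 1) |>
    arrange(s_start, s_end, query_id, .by_group = TRUE) |>
    mutate(
      nxt_query = lead(query_id),
      nxt_start = lead(s_start),
      nxt_end = lead(s_end)
    ) |>
    ungroup() |>
    filter(!is.na(nxt_query))
  if (nrow(events) == 0) return(empty)
  events |>
    mutate(
      gap_ = nxt_start - s_end - 1L,
      overlap_ = pmin(s_end, nxt_end) - nxt_start + 1L,
      kind = case_when(
        gap_ > 0L ~ "T1_case1",
        overlap_ <= k - 1L ~ "T1_case2",
        TRUE ~ "T1_case3"
      )
    ) |>
    transmute(
      kind,
      gene_id = subject_id,
      unigene_a = query_id,
      unigene_b = nxt_query,
      gap = ifelse(kind == "T1_case1", gap_, NA_integer_),
      overlap = ifelse(kind == "T1_case1", NA_integer_, overlap_)
    )
}

#' Classify Type II (annotation ambiguity) errors
#'
#' A Type II error is a unigene whose high-identity alignments point at two
#' reference loci. Alignments below `type2_identity_min` percent identity are
#' discarded; the two most significant loci (per-gene best hits, ranked by
#' bit score, e-value, gene id) are considered. Unigenes whose two top genes
#' are adjacent on the chromosome (order indices differing by one) are
#' excluded — with unstranded libraries those are legitimate co-assemblies
#' of neighbouring genes, not errors. The remaining unigenes are classified
#' by the geometry of the two query segments, evaluated with precedence
#' Case I > II > III > IV > V:
#'
#' * **Case I** — segments effectively disjoint (overlap at most
#'   `t2_seg_overlap_max` bases): the chimera-indicative case;
#' * **Case II** — equal bit scores and near-identical segments: the unigene
#'   aligns equally to two genes;
#' * **Case III** — one segment properly contained in the other: the whole
#'   sequence matches one gene and a subsequence matches another;
#' * **Case IV** — segments overlap more than `type2_overlap_frac` of the
#'   unigene length;
#' * **Case V** — segments overlap at most that fraction.
#'
#' @param aln Alignments of unigenes to reference cDNAs.
#' @param loci Gene annotation tibble from [read_gene_annotation()].
#' @param unigenes Tibble with `seq_id` and `length` (e.g. from
#'   [read_fasta()]) giving unigene lengths.
#' @param config An [eval_config()] list.
#' @return A tibble of events: `kind`, `unigene_id`, `gene_a`, `gene_b`,
#'   query segment coordinates, `seg_overlap`, `adjacency` (`"non_adjacent"`
#'   or `"unknown"` when a gene lacks annotation).
#' @export
classify_type2 <- function(aln, loci, unigenes, config = eval_config()) {
  empty <- tibble(kind = character(), unigene_id = character(),
                  gene_a = character(), gene_b = character(),
                  qa_start = integer(), qa_end = integer(),
                  qb_start = integer(), qb_end = integer(),
                  seg_overlap = integer(), adjacency = character())
  hits <- aln |> filter(pct_identity >= config$type2_identity_min)
  if (nrow(hits) == 0) return(empty)
  # per (unigene, gene) best alignment, then the two most significant genes
  per_gene <- hits |>
    arrange(query_id, desc(bit_score), e_value, subject_id) |>
    distinct(query_id, subject_id, .keep_all = TRUE)
  top2 <- per_gene |>
    group_by(query_id) |>
    filter(n() >= 2) |>
    slice_head(n = 2) |>
    summarise(
      gene_a = subject_id[1], gene_b = subject_id[2],
      qa_start = q_start[1], qa_end = q_end[1],
      qb_start = q_start[2], qb_end = q_end[2],
      bit_a = bit_score[1], bit_b = bit_score[2],
      .groups = "drop"
    )
  if (nrow(top2) == 0) return(empty)
  ann <- loci |> select(gene_id, chrom, order_index)
  lens <- unigenes |> select(seq_id, unigene_length = length)
  tol <- config$t2_seg_overlap_max
  top2 |>
    left_join(ann, by = c("gene_a" = "gene_id")) |>
    left_join(ann, by = c("gene_b" = "gene_id"), suffix = c("_a", "_b")) |>
    left_join(lens, by = c("query_id" = "seq_id")) |>
    mutate(
      adjacent = chrom_a == chrom_b & abs(order_index_a - order_index_b) == 1L,
      adjacency = case_when(
        is.na(adjacent) ~ "unknown",
        adjacent ~ "adjacent",
        TRUE ~ "non_adjacent"
      )
    ) |>
    filter(adjacency != "adjacent") |>
    mutate(
      seg_overlap = pmax(0L, pmin(qa_end, qb_end) - pmax(qa_start, qb_start) + 1L),
      contained = (qb_start >= qa_start & qb_end <= qa_end &
                     (qb_start > qa_start | qb_end < qa_end)) |
                  (qa_start >= qb_start & qa_end <= qb_end &
                     (qa_start > qb_start | qa_end < qb_end)),
      near_identical = bit_a == bit_b &
        abs(qa_start - qb_start) <= tol & abs(qa_end - qb_end) <= tol,
      kind = case_when(
        seg_overlap <= tol ~ "T2_case1",
        near_identical ~ "T2_case2",
        contained ~ "T2_case3",
        seg_overlap > config$type2_overlap_frac * unigene_length ~ "T2_case4",
        TRUE ~ "T2_case5"
      )
    ) |>
    transmute(kind, unigene_id = query_id, gene_a, gene_b,
              qa_start, qa_end, qb_start, qb_end, seg_overlap, adjacency)
}

#' Adjudicate putative chimeras with genome alignments
#'
#' Aligning a suspect unigene to genomic sequence separates true chimeras
#' from legitimate co-assemblies of neighbouring genes and from ambiguous
#' matches to duplicated genes. Alignments below `chimera_identity_min`
#' percent identity or above `chimera_evalue_max` e-value are discarded.
#' Surviving hits on the same chromosome and strand separated by at most
#' `chimera_merge_gap` bases (intron-scale gaps) are merged into genomic
#' windows, and each window's coverage of the unigene (union of its hits'
#' query segments) is measured:
#'
#' * no surviving hits — `unresolved`;
#' * two or more windows each covering at least `chimera_cover_frac` of the
#'   unigene — `ambiguous_duplicate` (matches to closely related or
#'   duplicated genes);
#' * exactly one such window — `co_assembly` (the unigene maps contiguously,
#'   e.g. across two adjacent genes);
#' * otherwise, if the unigene is flagged as a trans-splice candidate and two
#'   disjoint query segments hit distinct windows on one chromosome —
#'   `trans_spliced_candidate`;
#' * otherwise — `chimera`.
#'
#' @param genome_aln Alignments of unigenes to genomic sequence.
#' @param unigenes Tibble with `seq_id` and `length` for the unigenes.
#' @param config An [eval_config()] list.
#' @param trans_splice_ids Optional identifiers of annotated trans-splice
#'   candidates (the geometry alone cannot distinguish these from chimeras).
#' @return A tibble: `unigene_id`, `verdict`, `n_windows`,
#'   `supporting_alignments`.
#' @export
adjudicate_chimera <- function(genome_aln, unigenes, config = eval_config(),
                               trans_splice_ids = NULL) {
  if (!"query_id" %in% names(genome_aln) && "unigene_id" %in% names(genome_aln)) {
    genome_aln <- genome_aln |> rename(query_id = unigene_id)
  }
  all_ids <- unique(genome_aln$query_id)
  hits <- canonicalize_alignments(genome_aln) |>
    filter(pct_identity >= config$chimera_identity_min,
           e_value <= config$chimera_evalue_max)
  lens <- setNames(unigenes$length, unigenes$seq_id)
  verdict_for <- function(df) {
    uid <- df$query_id[1]
    L <- lens[[uid]]
    win <- df |>
      arrange(subject_id, strand, s_start) |>
      group_by(subject_id, strand) |>
      mutate(window = cumsum(
        s_start - dplyr::lag(cummax(s_end), default = s_start[1]) - 1L >
          config$chimera_merge_gap)) |>
      group_by(subject_id, strand, window) |>
      summarise(
        q_cover = sum(IRanges::width(
          IRanges::reduce(IRanges::IRanges(start = q_start, end = q_end)))) / L,
        q_lo = min(q_start), q_hi = max(q_end),
        .groups = "drop"
      )
    n_full <- sum(win$q_cover >= config$chimera_cover_frac)
    verdict <- if (n_full >= 2) {
      "ambiguous_duplicate"
    } else if (n_full == 1) {
      "co_assembly"
    } else if (uid %in% trans_splice_ids && nrow(win) >= 2 &&
               any(duplicated(win$subject_id)) &&
               segments_disjoint(win)) {
      "trans_spliced_candidate"
    } else {
      "chimera"
    }
    tibble(unigene_id = uid, verdict = verdict,
           n_windows = nrow(win), supporting_alignments = nrow(df))
  }
  resolved <- if (nrow(hits) > 0) {
    hits |>
      group_by(query_id) |>
      group_split() |>
      map_dfr(verdict_for)
  } else {
    tibble(unigene_id = character(), verdict = character(),
           n_windows = integer(), supporting_alignments = integer())
  }
  missing <- setdiff(all_ids, resolved$unigene_id)
  bind_rows(
    resolved,
    tibble(unigene_id = missing, verdict = "unresolved",
           n_windows = 0L, supporting_alignments = 0L)
  )
}

# are the query footprints of the windows pairwise non-overlapping?
segments_disjoint <- function(win) {
  win <- win[order(win$q_lo), ]
  all(win$q_lo[-1] > head(win$q_hi, -1))
}

#' Summarise classified error events into an assembly error report
#'
#' @param events Event tibble(s) from [classify_type1()] and
#'   [classify_type2()] (rows may be mixed; only `kind` and `unigene_id` /
#'   `unigene_a` are consulted).
#' @param assignments Per-unigene locus assignments from
#'   [assign_best_loci()]; its row count is the number of reference-aligned
#'   unigenes, the Type II rate denominator.
#' @param detected_genes Character vector of the detected reference gene set.
#' @return A one-row tibble with one count column per error kind, the
#'   `type2_rate` (ambiguously aligned unigenes over all reference-aligned
#'   unigenes), `n_aligned_unigenes` and `no_hit_genes`.
#' @export
summarize_error_report <- function(events, assignments, detected_genes) {
  if (is.list(events) && !is.data.frame(events)) events <- bind_rows(events)
  if (nrow(events) == 0) {
    counts <- setNames(rep(0L, length(error_kinds)), error_kinds)
    t2_unigenes <- character(0)
  } else {
    stopifnot(all(events$kind %in% error_kinds))
    counts <- table(factor(events$kind, levels = error_kinds))
    counts <- setNames(as.integer(counts), error_kinds)
    t2_unigenes <- unique(events$unigene_id[events$kind %in% t2_kinds])
    t2_unigenes <- t2_unigenes[!is.na(t2_unigenes)]
  }
  n_aligned <- nrow(assignments)
  bind_cols(
    as_tibble(as.list(counts)),
    tibble(
      type2_rate = if (n_aligned > 0) length(t2_unigenes) / n_aligned else 0,
      n_aligned_unigenes = n_aligned,
      no_hit_genes = length(setdiff(detected_genes, assignments$gene_id))
    )
  )
}
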