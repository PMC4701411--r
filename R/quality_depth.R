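#' Normalized bit score (BS)
#'
#' The alignment bit score of a unigene's best hit divided by the reference
#' cDNA length, in bits per reference base. A perfectly matched full-length
#' alignment scores 2.0; an error-free alignment covering 75% of the
#' reference scores 1.5, so the statistic reads primarily as reconstructed
#' length, discounted by errors. When no external (aligner-reported) bit
#' score is supplied, an idealized score is computed as
#' `B = 2*matches - 2*mismatches - 5*gap_openings`, clamped at zero — +2
#' bits per matched base (forcing the 2.0 full-length ideal), mismatch
#' penalty -2, gap penalty -5. Real aligner bit scores run slightly below 2
#' bits per base and may be passed through `external_bits`.
#'
#' @param matches Matched bases in the alignment.
#' @param mismatches Mismatched bases.
#' @param gap_openings Gap openings.
#' @param ref_length Reference cDNA length in bases (> 0).
#' @param external_bits Optional aligner-reported bit score; when given it
#'   overrides the idealized formula and is simply divided by `ref_length`.
#' @return The BS value (vectorized over its arguments).
#' @examples
#' normalized_bit_score(1000, 0, 0, 1000) # 2.0, the ideal
#' normalized_bit_score(750, 0, 0, 1000)  # 1.5, a 75%-length reconstruction
#' @export
normalized_bit_score <- function(matches, mismatches = 0, gap_openings = 0,
                                 ref_length, external_bits = NULL) {
  if (any(ref_length <= 0)) abort("ref_length must be > 0")
  stopifnot(all(matches >= 0), all(mismatches >= 0), all(gap_openings >= 0))
  if (!is.null(external_bits)) return(external_bits / ref_length)
  bits <- pmax(0, 2 * matches - 2 * mismatches - 5 * gap_openings)
  bits / ref_length
}

#' Sequenced fragments per base pair (SFB)
#'
#' The normalized sequencing-depth metric: total mapped fragments (read
#' pairs or orphan reads, each counting once) attributed to a gene, divided
#' by its reference cDNA length. Fragments from all unigenes assigned to the
#' gene are summed before normalizing, so the value is invariant to how the
#' fragments are split among the gene's unigenes.
#'
#' @param fragments Fragment counts — a vector is summed.
#' @param ref_length Reference cDNA length in bases (> 0).
#' @return The SFB value.
#' @examples
#' sequenced_fragments_per_bp(200, 1000)        # 0.2
#' sequenced_fragments_per_bp(c(150, 50), 1000) # also 0.2
#' @export
sequenced_fragments_per_bp <- function(fragments, ref_length) {
  if (length(ref_length) != 1 || ref_length <= 0) {
    abort("ref_length must be a single value > 0")
  }
  stopifnot(all(fragments >= 0))
  sum(fragments) / ref_length
}

#' Build the per-gene quality-versus-depth table
#'
#' For every reference gene: BS from the single best alignment among the
#' unigenes assigned to that locus (alignments of equal or lower bit score
#' than the best are excluded, simulating best-hit identification without a
#' genome), and SFB from the summed fragment counts of all assigned
#' unigenes. Genes with no assigned unigene get BS 0, SFB 0 and no best
#' unigene. The count of genes with BS above `bs_threshold` — the
#' high-quality tail — is attached as attribute `n_high` (see
#' [qd_high_count()]).
#'
#' @param assignments Per-unigene assignments from [assign_best_loci()].
#' @param counts Fragment count tibble (`unigene_id`, `fragment_count`).
#' @param reference Reference tibble (`seq_id`, `length`).
#' @param config An [eval_config()] list.
#' @return A tibble with one row per reference gene: `gene_id`, `bs`, `sfb`,
#'   `best_unigene`, `ref_length`.
#' @export
build_quality_depth_table <- function(assignments, counts, reference,
                                      config = eval_config()) {
  unknown <- setdiff(unique(assignments$gene_id), reference$seq_id)
  if (length(unknown) > 0) {
    abort(paste0("assigned gene(s) absent from reference: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  best <- assignments |>
    arrange(gene_id, desc(bit_score), e_value, unigene_id) |>
    distinct(gene_id, .keep_all = TRUE) |>
    select(gene_id, best_unigene = unigene_id, bit_score)
  frag <- assignments |>
    left_join(counts, by = "unigene_id") |>
    mutate(fragment_count = dplyr::coalesce(fragment_count, 0L)) |>
    group_by(gene_id) |>
    summarise(fragments = sum(fragment_count), .groups = "drop")
  qd <- reference |>
    select(gene_id = seq_id, ref_length = length) |>
    left_join(best, by = "gene_id") |>
    left_join(frag, by = "gene_id") |>
    mutate(
      bs = dplyr::coalesce(bit_score, 0) / ref_length,
      sfb = dplyr::coalesce(fragments, 0) / ref_length
    ) |>
    select(gene_id, bs, sfb, best_unigene, ref_length)
  attr(qd, "n_high") <- sum(qd$bs > config$bs_threshold)
  qd
}

#' Count high-quality genes in a quality-depth table
#'
#' @param qd Table from [build_quality_depth_table()].
#' @param threshold BS threshold; defaults to the count computed at build
#'   time (stored in attribute `n_high`).
#' @return Integer count of genes with `bs` above the threshold.
#' @export
qd_high_count <- function(qd, threshold = NULL) {
  if (is.null(threshold)) {
    n <- attr(qd, "n_high")
    if (!is.null(n)) return(as.integer(n))
    threshold <- 1.5
  }
  sum(qd$bs > threshold)
}

#' Conserved-ortholog recovery summary
#'
#' Measures how completely a curated list of conserved, broadly expressed
#' single-copy genes (e.g. ultra-conserved orthologs) is recovered: the
#' fraction reconstructed with BS above the high-quality threshold, and the
#' fractions covered more than 90% and 99% by the assembly.
#'
#' @param qd Table from [build_quality_depth_table()].
#' @param coverage Table from [coverage_breadth()].
#' @param uco_ids Character vector of conserved-ortholog gene identifiers;
#'   identifiers absent from the reference are dropped with a warning.
#' @param config An [eval_config()] list.
#' @return A one-row tibble: `n_listed`, `frac_bs_high`, `frac_cov90`,
#'   `frac_cov99`.
#' @export
uco_recovery <- function(qd, coverage, uco_ids, config = eval_config()) {
  if (length(uco_ids) == 0) abort("empty conserved-ortholog list")
  unknown <- setdiff(uco_ids, qd$gene_id)
  if (length(unknown) > 0) {
    warn(paste0("dropping ", length(unknown),
                " listed gene(s) absent from the reference"))
    uco_ids <- setdiff(uco_ids, unknown)
  }
  if (length(uco_ids) == 0) abort("no listed genes found in the reference")
  q <- qd |> filter(gene_id %in% uco_ids)
  cv <- coverage |> filter(gene_id %in% uco_ids)
  tibble(
    n_listed = length(uco_ids),
    frac_bs_high = mean(q$bs > config$bs_threshold),
    frac_cov90 = mean(cv$breadth_pct > 90),
    frac_cov99 = mean(cv$breadth_pct > 99)
  )
}

#' Paralog pair analysis: expressed gene pairs and closely related genes
#'
#' Pairs reference genes by reciprocal best hit (RBH) in an all-versus-all
#' alignment of the reference against itself, then classifies each pair by
#' expression (both mates at SFB at or above `sfb_threshold`, one, or
#' neither) and by assembly success (both mates above `bs_threshold`, one,
#' both present but low, one missing, both missing — presence meaning any
#' alignment, BS > 0). Pairs with both mates expressed are the expressed
#' gene pairs (EGPs); when per-pair Ks values are supplied, the closely
#' related gene (CRG) subset is the lowest-Ks EGPs with
#' `ks < crg_ks_max`, capped at `crg_max_pairs` pairs.
#'
#' @param self_hits All-versus-all alignment tibble among reference genes
#'   (self-hits, `query_id == subject_id`, are ignored).
#' @param qd Table from [build_quality_depth_table()].
#' @param ks Optional tibble of pair Ks values: `gene_a`, `gene_b`, `ks`
#'   (order-insensitive).
#' @param config An [eval_config()] list.
#' @return A tibble of unordered pairs: `gene_a`, `gene_b`, per-mate `sfb`
#'   and `bs`, `expression_class`, `assembly_class`, `ks`, `is_crg`.
#' @export
paralog_pairs <- function(self_hits, qd, ks = NULL, config = eval_config()) {
  hits <- self_hits |> filter(query_id != subject_id)
  empty <- tibble(gene_a = character(), gene_b = character(),
                  sfb_a = double(), sfb_b = double(),
                  bs_a = double(), bs_b = double(),
                  expression_class = character(),
                  assembly_class = character(),
                  ks = double(), is_crg = logical())
  if (nrow(hits) == 0) return(empty)
  best <- hits |>
    arrange(query_id, desc(bit_score), e_value, subject_id) |>
    distinct(query_id, .keep_all = TRUE) |>
    select(query_id, best = subject_id)
  mutual <- best |>
    inner_join(best, by = c("best" = "query_id"), suffix = c("", "_rev")) |>
    filter(best_rev == query_id, query_id < best) |>
    select(gene_a = query_id, gene_b = best)
  if (nrow(mutual) == 0) return(empty)
  per_gene <- qd |> select(gene_id, sfb, bs)
  pairs <- mutual |>
    left_join(per_gene, by = c("gene_a" = "gene_id")) |>
    left_join(per_gene, by = c("gene_b" = "gene_id"),
              suffix = c("_a", "_b")) |>
    mutate(
      sfb_a = dplyr::coalesce(sfb_a, 0), sfb_b = dplyr::coalesce(sfb_b, 0),
      bs_a = dplyr::coalesce(bs_a, 0), bs_b = dplyr::coalesce(bs_b, 0),
      n_expr = (sfb_a >= config$sfb_threshold) + (sfb_b >= config$sfb_threshold),
      expression_class = c("neither", "one_expressed", "both_expressed")[n_expr + 1L],
      n_high = (bs_a > config$bs_threshold) + (bs_b > config$bs_threshold),
      n_present = (bs_a > 0) + (bs_b > 0),
      assembly_class = case_when(
        n_present == 0 ~ "both_missing",
        n_present == 1 ~ "one_missing",
        n_high == 2 ~ "both_high",
        n_high == 1 ~ "one_high",
        TRUE ~ "both_present_low"
      )
    ) |>
    select(-n_expr, -n_high, -n_present)
  if (!is.null(ks)) {
    ks2 <- bind_rows(
      ks |> select(gene_a, gene_b, ks),
      ks |> select(gene_a = gene_b, gene_b = gene_a, ks)
    ) |> distinct(gene_a, gene_b, .keep_all = TRUE)
    pairs <- pairs |> left_join(ks2, by = c("gene_a", "gene_b"))
  } else {
    pairs$ks <- NA_real_
  }
  crg_rank <- rank(ifelse(
    pairs$expression_class == "both_expressed" &
      !is.na(pairs$ks) & pairs$ks < config$crg_ks_max,
    pairs$ks, Inf), ties.method = "first")
  pairs$is_crg <- is.finite(pairs$ks) & pairs$ks < config$crg_ks_max &
    pairs$expression_class == "both_expressed" &
    crg_rank <= config$crg_max_pairs
  pairs
}
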