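#' Cumulative coverage breadth of reference transcripts
#'
#' For each reference gene, the percentage of its bases covered by the union
#' of all aligned unigene segments — cumulative across unigenes, not limited
#' to the single best one. Genes with no alignment are reported with breadth
#' 0 and status `"no_hit"`.
#'
#' @param aln Alignment tibble of unigenes versus reference cDNAs.
#' @param reference Reference tibble from [read_fasta()] (`seq_id`, `length`).
#' @return A tibble with one row per reference gene: `gene_id`,
#'   `breadth_pct`, `n_unigenes`, `status`.
#' @examples
#' ref <- tibble::tibble(seq_id = "g1", length = 1000L)
#' aln <- tibble::tibble(query_id = c("u1", "u2"), subject_id = "g1",
#'   pct_identity = 100, aln_length = c(400L, 500L), mismatches = 0L,
#'   gap_openings = 0L, q_start = 1L, q_end = c(400L, 500L),
#'   s_start = c(1L, 501L), s_end = c(400L, 1000L),
#'   e_value = 0, bit_score = c(800, 1000))
#' coverage_breadth(aln, ref) # 90% breadth
#' @export
coverage_breadth <- function(aln, reference) {
  stopifnot(all(c("seq_id", "length") %in% names(reference)))
  aln <- canonicalize_alignments(aln)
  ref_len <- setNames(reference$length, reference$seq_id)
  unknown <- setdiff(unique(aln$subject_id), names(ref_len))
  if (length(unknown) > 0) {
    abort(paste0("alignment subject(s) absent from reference: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (any(aln$s_end > ref_len[aln$subject_id])) {
    abort("alignment interval extends beyond reference gene length")
  }
  covered <- if (nrow(aln) > 0) {
    aln |>
      group_by(gene_id = subject_id) |>
      summarise(
        covered_bases = sum(IRanges::width(
          IRanges::reduce(IRanges::IRanges(start = s_start, end = s_end)))),
        n_unigenes = n_distinct(query_id),
        .groups = "drop"
      )
  } else {
    tibble(gene_id = character(), covered_bases = integer(),
           n_unigenes = integer())
  }
  reference |>
    select(gene_id = seq_id, length) |>
    left_join(covered, by = "gene_id") |>
    mutate(
      covered_bases = dplyr::coalesce(covered_bases, 0L),
      n_unigenes = dplyr::coalesce(n_unigenes, 0L),
      breadth_pct = 100 * covered_bases / length,
      status = ifelse(n_unigenes == 0, "no_hit", "covered")
    ) |>
    select(gene_id, breadth_pct, n_unigenes, status)
}

#' Bin coverage breadths into a histogram
#'
#' Bins genes by coverage breadth in 5% or 10% increments, with a `no_hit`
#' bin for genes with no alignment, plus two cumulative tail counts for genes
#' covered >90% and >99%. The exclusive bins (everything except the tail
#' rows) sum to the number of genes; the `>90` and `>99` rows are cumulative
#' tail counts overlapping the top bins, flagged by `is_cumulative`.
#'
#' @param coverage Tibble from [coverage_breadth()].
#' @param scheme `"five_pct"` or `"ten_pct"` bin width.
#' @return A tibble with columns `bin`, `count`, `is_cumulative`.
#' @export
coverage_histogram <- function(coverage, scheme = c("five_pct", "ten_pct")) {
  scheme <- match.arg(scheme)
  width <- if (scheme == "five_pct") 5 else 10
  breaks <- seq(0, 100, by = width)
  b <- coverage$breadth_pct
  no_hit <- coverage$status == "no_hit"
  stopifnot(all(b >= 0 & b <= 100))
  # right-closed bins over genes that have a hit; a hit gene at breadth 0
  # (degenerate) falls into the first bin
  idx <- pmax(1L, as.integer(ceiling(b[!no_hit] / width)))
  labels <- paste0("(", breaks[-length(breaks)], ",", breaks[-1], "]")
  counts <- tabulate(idx, nbins = length(labels))
  bind_rows(
    tibble(bin = "no_hit", count = sum(no_hit), is_cumulative = FALSE),
    tibble(bin = labels, count = counts, is_cumulative = FALSE),
    tibble(bin = ">90", count = sum(b > 90), is_cumulative = TRUE),
    tibble(bin = ">99", count = sum(b > 99), is_cumulative = TRUE)
  )
}

#' Aggregate mismatch and gap-opening rates
#'
#' The ratio of mismatches to total aligned bases and of gap openings to
#' total aligned bases, summed over all alignments.
#'
#' @param aln Alignment tibble.
#' @return A one-row tibble: `mismatch_rate`, `gap_opening_rate`,
#'   `aligned_bases`. With no alignments the rates are `NA`.
#' @export
alignment_error_rates <- function(aln) {
  if (nrow(aln) == 0 || sum(aln$aln_length) == 0) {
    return(tibble(mismatch_rate = NA_real_, gap_opening_rate = NA_real_,
                  aligned_bases = 0L))
  }
  total <- sum(aln$aln_length)
  tibble(
    mismatch_rate = sum(aln$mismatches) / total,
    gap_opening_rate = sum(aln$gap_openings) / total,
    aligned_bases = as.integer(total)
  )
}
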