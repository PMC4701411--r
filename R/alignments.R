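#' Canonicalize alignment subject coordinates
#'
#' Minus-strand alignments are reported with subject start greater than
#' subject end. Canonicalization swaps them so `s_start <= s_end` always, and
#' records the strand in a `strand` column (`"+"` or `"-"`). Query coordinates
#' are untouched. Idempotent: a tibble that already carries a `strand` column
#' is returned with coordinates re-checked but unchanged.
#'
#' @param aln Alignment tibble (12 standard columns).
#' @return The tibble with `s_start <= s_end` and a `strand` column.
#' @export
canonicalize_alignments <- function(aln) {
  if (!"strand" %in% names(aln)) {
    aln$strand <- ifelse(aln$s_start > aln$s_end, "-", "+")
  }
  flip <- aln$s_start > aln$s_end
  if (any(flip)) {
    tmp <- aln$s_start[flip]
    aln$s_start[flip] <- aln$s_end[flip]
    aln$s_end[flip] <- tmp
  }
  aln
}

#' Assign each unigene to its best reference locus
#'
#' For every query (unigene) the most significant subject (reference gene) is
#' recorded: highest bit score, ties broken by lower e-value, then by
#' lexicographically smaller subject identifier so the assignment is
#' deterministic. With `keep_two = TRUE` the second most significant
#' *distinct* gene is recorded as `runner_up_gene` (used by the Type II
#' machinery, which considers the two most significant loci).
#'
#' @param aln Alignment tibble; may contain several hits per unigene.
#' @param keep_two Record the runner-up gene as well?
#' @return A tibble with one row per unigene: `unigene_id`, `gene_id`, the
#'   best alignment's columns, and optionally `runner_up_gene`.
#' @export
assign_best_loci <- function(aln, keep_two = FALSE) {
  if (nrow(aln) == 0) abort("no alignments to assign")
  ranked <- aln |>
    arrange(query_id, desc(bit_score), e_value, subject_id)
  best <- ranked |>
    distinct(query_id, .keep_all = TRUE) |>
    rename(unigene_id = query_id, gene_id = subject_id)
  if (keep_two) {
    runner <- ranked |>
      group_by(query_id) |>
      filter(subject_id != subject_id[1]) |>
      summarise(runner_up_gene = subject_id[1], .groups = "drop")
    best <- best |>
      left_join(runner, by = c("unigene_id" = "query_id"))
  }
  best
}
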