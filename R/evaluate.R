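#' Evaluate an assembly against a reference
#'
#' The one-stop pipeline: assigns unigenes to loci, computes cumulative
#' coverage and its histogram, aggregate mismatch/gap rates, Type I and
#' Type II error events and the error report, the quality-versus-depth (BS
#' versus SFB) table, length statistics with the short-cutoff N50 sweep,
#' and — when the corresponding inputs are given — chimera adjudication,
#' conserved-ortholog recovery, the mappable-read fraction and the
#' superior-assembly checklist.
#'
#' @param assembly Unigene tibble from [read_fasta()].
#' @param reference Reference transcript tibble from [read_fasta()].
#' @param alignments Unigene-versus-reference alignment tibble.
#' @param counts Per-unigene fragment count tibble.
#' @param loci Optional gene annotation tibble (enables Type II
#'   classification with adjacency exclusion).
#' @param genome_alignments Optional unigene-versus-genome alignment tibble
#'   (enables chimera adjudication).
#' @param uco_ids Optional conserved-ortholog identifiers.
#' @param expected_transcripts,total_reads Optional checklist inputs: the
#'   expected transcript count and the total read (fragment) count used as
#'   the mappable-fraction denominator.
#' @param trans_splice_ids Optional annotated trans-splice candidates.
#' @param config An [eval_config()] list.
#' @return An object of class `"asm_eval"`: a named list of result tibbles
#'   (`coverage`, `histogram`, `error_rates`, `type1`, `type2`,
#'   `error_report`, `qd`, `lengths`, `n50_sweep`, and optionally
#'   `chimera`, `uco`, `checklist`), with [tidy()], [glance()],
#'   [autoplot()] and `print()` methods.
#' @export
evaluate_assembly <- function(assembly, reference, alignments, counts,
                              loci = NULL, genome_alignments = NULL,
                              uco_ids = NULL, expected_transcripts = NULL,
                              total_reads = NULL, trans_splice_ids = NULL,
                              config = eval_config()) {
  assignments <- assign_best_loci(alignments, keep_two = TRUE)
  coverage <- coverage_breadth(alignments, reference)
  histogram <- coverage_histogram(coverage)
  error_rates <- alignment_error_rates(alignments)
  type1 <- classify_type1(alignments, k = config$k)
  type2 <- if (!is.null(loci)) {
    classify_type2(alignments, loci, assembly, config)
  } else {
    classify_type2(alignments,
                   tibble(gene_id = character(), chrom = character(),
                          order_index = integer()),
                   assembly, config)
  }
  error_report <- summarize_error_report(list(type1, type2), assignments,
                                         detected_genes = reference$seq_id)
  qd <- build_quality_depth_table(assignments, counts, reference, config)
  lengths <- length_stats(assembly$length, assembly$n_count,
                          min_len = config$min_unigene_length)
  sweep <- n50_cutoff_sweep(assembly$length)

  out <- list(
    coverage = coverage, histogram = histogram, error_rates = error_rates,
    type1 = type1, type2 = type2, error_report = error_report, qd = qd,
    lengths = lengths, n50_sweep = sweep
  )
  if (!is.null(genome_alignments)) {
    suspects <- unique(type2$unigene_id)
    gal <- genome_alignments |> filter(query_id %in% suspects)
    out$chimera <- adjudicate_chimera(gal, assembly, config,
                                      trans_splice_ids = trans_splice_ids)
  }
  if (!is.null(uco_ids)) {
    out$uco <- uco_recovery(qd, coverage, uco_ids, config)
  }
  if (!is.null(expected_transcripts) && !is.null(total_reads) &&
      !is.null(out$uco)) {
    mp <- mappable_fraction(sum(counts$fragment_count), total_reads)
    out$checklist <- superior_checklist(
      mappable_pct = mp, n_unigenes = nrow(assembly),
      expected_transcripts = expected_transcripts,
      n50_length = lengths$n50_length, uco = out$uco, config = config
    )
  }
  structure(out, class = "asm_eval", config = config)
}

#' @export
print.asm_eval <- function(x, ...) {
  cat("<asm_eval>\n")
  cat(sprintf("  genes in reference     %d\n", nrow(x$coverage)))
  cat(sprintf("  unigenes (>= min len)  %d\n", x$lengths$n_sequences))
  cat(sprintf("  N50 length             %d bp\n", x$lengths$n50_length))
  cat(sprintf("  genes with BS > %.1f    %d\n",
              attr(x, "config")$bs_threshold, qd_high_count(x$qd)))
  cat(sprintf("  Type II rate           %.4g\n", x$error_report$type2_rate))
  if (!is.null(x$checklist)) {
    cat(sprintf("  checklist overall      %s\n",
                ifelse(x$checklist$overall, "PASS", "FAIL")))
  }
  invisible(x)
}

#' Tidy the per-gene results of an assembly evaluation
#'
#' @param x An `"asm_eval"` object.
#' @param ... Unused.
#' @return A tibble with one row per reference gene joining the
#'   quality-depth table (BS, SFB, best unigene) and coverage breadth.
#' @method tidy asm_eval
#' @export
tidy.asm_eval <- function(x, ...) {
  x$qd |>
    left_join(x$coverage, by = "gene_id")
}

#' One-row summary of an assembly evaluation
#'
#' @param x An `"asm_eval"` object.
#' @param ... Unused.
#' @return A one-row tibble: unigene count, median and N50 length, assembly
#'   megabases, ambiguous-base content, genes detected, mean coverage
#'   breadth, high-quality gene count, error-event counts and Type II rate.
#' @method glance asm_eval
#' @export
glance.asm_eval <- function(x, ...) {
  tibble(
    n_unigenes = x$lengths$n_sequences,
    median_length = x$lengths$median_length,
    n50_length = x$lengths$n50_length,
    assembly_mbp = x$lengths$n50_mbp,
    n_content = x$lengths$n_content,
    genes_detected = sum(x$coverage$status == "covered"),
    mean_breadth_pct = mean(x$coverage$breadth_pct),
    n_bs_high = qd_high_count(x$qd),
    n_type1 = nrow(x$type1),
    n_type2 = nrow(x$type2),
    type2_rate = x$error_report$type2_rate,
    mismatch_rate = x$error_rates$mismatch_rate,
    gap_opening_rate = x$error_rates$gap_opening_rate
  )
}

#' @rdname plot_quality_depth
#' @param object An `"asm_eval"` object.
#' @param ... Unused.
#' @method autoplot asm_eval
#' @export
autoplot.asm_eval <- function(object, ...) {
  plot_quality_depth(object$qd, config = attr(object, "config"))
}
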