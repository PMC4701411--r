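#' Quality-versus-depth plot
#'
#' Plots normalized bit score (assembly quality, ideal 2.0) against
#' sequenced fragments per base pair (sequencing depth, log scale) for
#' every detected gene, with the count of genes above the high-quality BS
#' threshold printed in the plot area. High-quality full-length
#' reconstructions accumulate near BS 1.75–2; a persistence of low-BS
#' genes at high SFB flags assembly failure for highly expressed
#' transcripts.
#'
#' @param qd Table from [build_quality_depth_table()].
#' @param config An [eval_config()] list (for the BS threshold).
#' @return A ggplot object.
#' @export
plot_quality_depth <- function(qd, config = eval_config()) {
  detected <- qd |> filter(sfb > 0 | bs > 0)
  n_high <- sum(detected$bs > config$bs_threshold)
  ggplot(detected |> filter(sfb > 0), aes(x = sfb, y = bs)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = config$bs_threshold, linetype = "dashed",
               colour = "grey40") +
    scale_x_log10() +
    annotate("text", x = Inf, y = 0.1, hjust = 1.1,
             label = paste0("n(BS > ", config$bs_threshold, ") = ", n_high)) +
    labs(x = "Sequence depth (sequenced fragments / bp)",
         y = "Assembly quality (normalized bit score)") +
    theme_minimal()
}

#' Coverage-breadth histogram plot
#'
#' @param histogram Table from [coverage_histogram()].
#' @return A ggplot object; the cumulative `>90` / `>99` tail bars are
#'   shown alongside the exclusive bins in a lighter shade.
#' @export
plot_coverage_histogram <- function(histogram) {
  histogram |>
    mutate(bin = factor(bin, levels = bin)) |>
    ggplot(aes(x = bin, y = count, fill = is_cumulative)) +
    geom_col(show.legend = FALSE) +
    scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "grey70")) +
    labs(x = "Coverage breadth bin (%)", y = "Genes") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Read titration (gene accumulation) plot
#'
#' @param curve Table from [titration_curve()].
#' @param expected Optional table from [expected_titration_curve()], drawn
#'   as a line over the observed points.
#' @return A ggplot object.
#' @export
plot_titration <- function(curve, expected = NULL) {
  p <- ggplot(curve, aes(x = reads_sampled, y = unique_unigenes)) +
    geom_point(size = 0.9) +
    labs(x = "Reads sampled", y = "Unique unigenes detected") +
    theme_minimal()
  if (!is.null(expected)) {
    p <- p + geom_line(data = expected,
                       aes(x = reads_sampled, y = .data$expected_unigenes),
                       colour = "steelblue")
  }
  p
}

#' N50 cutoff-sweep plot
#'
#' @param sweep Table from [n50_cutoff_sweep()].
#' @return A ggplot object with N50 length against the short-sequence
#'   cutoff imposed.
#' @export
plot_n50_sweep <- function(sweep) {
  ggplot(sweep, aes(x = cutoff, y = .data$n50_length)) +
    geom_line() +
    geom_point() +
    labs(x = "Minimum length cutoff (bp)", y = "N50 length (bp)") +
    theme_minimal()
}
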