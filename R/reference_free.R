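#' Assembly length statistics
#'
#' Sequences shorter than `min_len` are removed first. N50 is the unigene
#' length at which the cumulative assembled bases, taken from the longest
#' sequence downward, first reach 50% of the total assembly length.
#'
#' @param lengths Unigene lengths in bases.
#' @param n_counts Ambiguous-base counts per unigene (recycled scalar 0 by
#'   default); summed over the retained sequences.
#' @param min_len Minimum retained length.
#' @return A one-row tibble: `n_sequences`, `median_length`, `max_length`,
#'   `n50_length`, `n50_mbp` (total retained megabases), `n_content`.
#' @examples
#' length_stats(c(400, 300, 200, 100), min_len = 0) # N50 300
#' @export
length_stats <- function(lengths, n_counts = 0L, min_len = 100L) {
  stopifnot(all(lengths >= 0))
  if (length(n_counts) == 1) n_counts <- rep(n_counts, length(lengths))
  stopifnot(length(n_counts) == length(lengths))
  keep <- lengths >= min_len
  lengths <- lengths[keep]
  n_counts <- n_counts[keep]
  if (length(lengths) == 0) abort("no sequences remain after length filtering")
  tibble(
    n_sequences = length(lengths),
    median_length = median(lengths),
    max_length = max(lengths),
    n50_length = n50(lengths),
    n50_mbp = sum(lengths) / 1e6,
    n_content = sum(n_counts)
  )
}

n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' N50 under a sweep of short-sequence cutoffs
#'
#' Filters short unigenes at each cutoff and reports the N50 length and
#' retained megabases, revealing how much of an assembly's apparent
#' difference lives in short sequences.
#'
#' @param lengths Unigene lengths in bases.
#' @param cutoffs Minimum-length cutoffs, by default 100 to 600 bp in 100 bp
#'   steps.
#' @return A tibble with one row per cutoff: `cutoff`, `n_sequences`,
#'   `n50_length`, `mbp`.
#' @export
n50_cutoff_sweep <- function(lengths, cutoffs = seq(100L, 600L, by = 100L)) {
  map_dfr(cutoffs, function(ct) {
    kept <- lengths[lengths >= ct]
    if (length(kept) == 0) {
      return(tibble(cutoff = ct, n_sequences = 0L,
                    n50_length = NA_integer_, mbp = 0))
    }
    tibble(cutoff = ct, n_sequences = length(kept),
           n50_length = n50(kept), mbp = sum(kept) / 1e6)
  })
}

#' Percentage of reads mappable to an assembly
#'
#' @param mapped_reads Reads that map to the assembly.
#' @param total_reads Denominator. Conventions differ (all trimmed reads, or
#'   reads mapping to a reference cDNA set); `mapped_reads > total_reads` is
#'   therefore permitted with a warning rather than an error.
#' @return The percentage, with the denominator recorded in attribute
#'   `denominator`.
#' @export
mappable_fraction <- function(mapped_reads, total_reads) {
  if (total_reads <= 0) abort("total_reads must be > 0")
  if (mapped_reads > total_reads) {
    warn("mapped_reads exceeds total_reads; check denominator convention")
  }
  structure(100 * mapped_reads / total_reads, denominator = total_reads)
}

#' Read titration (gene accumulation) curve
#'
#' Randomly samples mapped fragments without replacement from the per-unigene
#' count table and records the number of distinct unigenes detected every
#' `step` fragments, mirroring species accumulation curves: a sharp early
#' rise followed by saturation indicates a contiguous, representative
#' assembly. The final point is always the exact endpoint (all fragments,
#' all unigenes with at least one fragment).
#'
#' @param counts Fragment count tibble (`unigene_id`, `fragment_count`).
#' @param step Fragments between recorded points.
#' @param seed Integer seed; the curve is reproducible given the seed.
#' @return A tibble with columns `reads_sampled`, `unique_unigenes`, plus
#'   attributes `endpoint_reads` and `endpoint_unigenes`.
#' @export
titration_curve <- function(counts, step = 1000L, seed = 1L) {
  counts <- counts |> filter(fragment_count > 0)
  total <- sum(counts$fragment_count)
  if (total <= 0) abort("count table has no mapped fragments")
  reads <- rep.int(seq_len(nrow(counts)), counts$fragment_count)
  perm <- withr::with_seed(seed, sample(reads))
  cum_unique <- cumsum(!duplicated(perm))
  at <- seq(step, total, by = step)
  if (length(at) == 0 || tail(at, 1) != total) at <- c(at, total)
  out <- tibble(reads_sampled = as.integer(at),
                unique_unigenes = cum_unique[at])
  attr(out, "endpoint_reads") <- as.integer(total)
  attr(out, "endpoint_unigenes") <- nrow(counts)
  out
}

#' Expected titration curve (closed form)
#'
#' The analytic counterpart of [titration_curve()]: under sampling without
#' replacement of `m` fragments from a table with per-unigene counts `c_i`
#' and total `T`, the expected number of detected unigenes is
#' `E[U(m)] = sum_i (1 - choose(T - c_i, m) / choose(T, m))`, computed in
#' log space for stability.
#'
#' @param counts Fragment count tibble (`unigene_id`, `fragment_count`).
#' @param sample_sizes Fragment counts `m` at which to evaluate; each must
#'   be at most the table total.
#' @return A tibble with columns `reads_sampled`, `expected_unigenes`.
#' @export
expected_titration_curve <- function(counts, sample_sizes) {
  counts <- counts |> filter(fragment_count > 0)
  ci <- counts$fragment_count
  total <- sum(ci)
  if (any(sample_sizes > total)) abort("sample size exceeds total fragments")
  if (any(sample_sizes < 0)) abort("negative sample size")
  expected <- vapply(sample_sizes, function(m) {
    if (m == 0) return(0)
    # P(unigene i undetected) = C(T - c_i, m) / C(T, m)
    log_p_miss <- ifelse(total - ci >= m,
                         lchoose(total - ci, m) - lchoose(total, m),
                         -Inf)
    sum(1 - exp(log_p_miss))
  }, numeric(1))
  tibble(reads_sampled = as.integer(sample_sizes),
         expected_unigenes = expected)
}

#' Correlate log-transformed per-gene counts between two assemblies
#'
#' Counts are joined on the shared gene universe (genes absent from one
#' table are imputed as 0), transformed as `log2(count + 1)`, and both the
#' Spearman rank and Pearson correlation coefficients are returned.
#'
#' @param counts_a,counts_b Tibbles with columns `gene_id` and `count` (a
#'   `fragment_count` column is also accepted).
#' @return A one-row tibble: `spearman_rho`, `pearson_r`, `n_genes`.
#' @export
log_count_correlation <- function(counts_a, counts_b) {
  norm <- function(df) {
    if (!"count" %in% names(df) && "fragment_count" %in% names(df)) {
      df <- df |> rename(count = fragment_count)
    }
    if (!"gene_id" %in% names(df) && "unigene_id" %in% names(df)) {
      df <- df |> rename(gene_id = unigene_id)
    }
    df[c("gene_id", "count")]
  }
  joined <- full_join(norm(counts_a), norm(counts_b), by = "gene_id",
                      suffix = c("_a", "_b")) |>
    mutate(count_a = dplyr::coalesce(count_a, 0),
           count_b = dplyr::coalesce(count_b, 0))
  if (nrow(joined) < 3) abort("need at least 3 shared genes to correlate")
  la <- log2(joined$count_a + 1)
  lb <- log2(joined$count_b + 1)
  tibble(
    spearman_rho = cor(la, lb, method = "spearman"),
    pearson_r = cor(la, lb, method = "pearson"),
    n_genes = nrow(joined)
  )
}

#' Superior-assembly checklist
#'
#' The composite reference-independent verdict: a superior de novo
#' transcriptome assembly shows (1) a high proportion of mappable reads,
#' (2) unigenes numbering roughly 150% or more of the expected transcript
#' count, (3) an N50 length in the expected range, and (4) high recovery of
#' conserved orthologs. Only the combination is informative; each flag is
#' reported with the threshold in effect.
#'
#' @param mappable_pct Percent of reads mapping to the assembly.
#' @param n_unigenes Number of unigenes in the assembly.
#' @param expected_transcripts Expected transcript count for the organism
#'   and tissue (> 0).
#' @param n50_length Assembly N50 in bases.
#' @param uco One-row tibble from [uco_recovery()] (its `frac_cov90` is
#'   used).
#' @param config An [eval_config()] list carrying the four thresholds.
#' @return A one-row tibble with the four metric values, four pass flags,
#'   and `overall` (all four pass).
#' @export
superior_checklist <- function(mappable_pct, n_unigenes, expected_transcripts,
                               n50_length, uco, config = eval_config()) {
  if (expected_transcripts <= 0) abort("expected_transcripts must be > 0")
  ratio <- n_unigenes / expected_transcripts
  flags <- c(
    pass_mappable = as.numeric(mappable_pct) > config$checklist_mappable_min,
    pass_unigene_ratio = ratio >= config$checklist_ratio_min,
    pass_n50 = n50_length >= config$checklist_n50_min,
    pass_uco = uco$frac_cov90 >= config$checklist_uco_min
  )
  tibble(
    mappable_pct = as.numeric(mappable_pct),
    unigene_ratio = ratio,
    n50_length = n50_length,
    uco_frac_cov90 = uco$frac_cov90,
    pass_mappable = flags[["pass_mappable"]],
    pass_unigene_ratio = flags[["pass_unigene_ratio"]],
    pass_n50 = flags[["pass_n50"]],
    pass_uco = flags[["pass_uco"]],
    overall = all(flags)
  )
}
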