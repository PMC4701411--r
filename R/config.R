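#' Evaluation configuration
#'
#' Bundles every tunable threshold used across the toolkit. Defaults follow
#' the conventions of k-mer (De Bruijn graph) transcriptome assembly
#' evaluation against an annotated reference: a k-mer of 31, the BS > 1.5
#' "long and accurate unigene" threshold, the SFB >= 0.1 expression floor,
#' the 99% identity / 80% overlap Type II definitions, and the 90% identity /
#' 1e-10 e-value chimera-adjudication filters.
#'
#' @param k Assembly k-mer value; the Type I Case II/III boundary is `k - 1`
#'   bases of alignment overlap.
#' @param bs_threshold Normalized bit score above which a unigene counts as a
#'   high-quality (long, accurate) reconstruction. Bits per reference base;
#'   the ideal full-length error-free value is 2.0.
#' @param sfb_threshold Sequenced fragments per reference base above which a
#'   gene counts as expressed at assemblable depth.
#' @param type2_identity_min Minimum percent identity for an alignment to
#'   participate in Type II classification.
#' @param type2_overlap_frac Query-overlap fraction of unigene length
#'   separating Type II Case IV (above) from Case V (at or below).
#' @param chimera_identity_min,chimera_evalue_max Filters applied to genome
#'   alignments before chimera adjudication; poorer alignments are discarded.
#' @param min_unigene_length Unigenes shorter than this are removed before
#'   length statistics.
#' @param titration_step Reads between recorded points on a titration curve.
#' @param crg_ks_max Ks ceiling defining closely related gene (CRG) pairs.
#' @param crg_max_pairs CRG subset cap: the lowest-Ks expressed pairs kept.
#' @param t2_seg_overlap_max Maximum query-segment overlap (bases) still
#'   treated as "non-overlapping" for Type II Case I, absorbing alignment end
#'   jitter; also the end-coordinate tolerance for Case II "equal" segments.
#' @param chimera_merge_gap Genome hits on the same chromosome and strand
#'   separated by at most this many bases are merged into one genomic window
#'   (intron-scale gap).
#' @param chimera_cover_frac Fraction of the unigene a genomic window must
#'   cover to count as a full-length placement.
#' @param checklist_mappable_min,checklist_ratio_min,checklist_n50_min,checklist_uco_min
#'   Superior-assembly checklist thresholds: percent mappable reads,
#'   unigene/expected-transcript ratio, N50 length (bases), and minimum
#'   fraction of conserved orthologs covered > 90%.
#' @param rng_seed Default seed for stochastic operations.
#'
#' @return A list with class `"asm_config"`.
#' @examples
#' cfg <- eval_config(k = 25)
#' cfg$bs_threshold
#' @export
eval_config <- function(k = 31L,
                        bs_threshold = 1.5,
                        sfb_threshold = 0.1,
                        type2_identity_min = 99,
                        type2_overlap_frac = 0.80,
                        chimera_identity_min = 90,
                        chimera_evalue_max = 1e-10,
                        min_unigene_length = 100L,
                        titration_step = 1000L,
                        crg_ks_max = 0.2,
                        crg_max_pairs = 300L,
                        t2_seg_overlap_max = 10L,
                        chimera_merge_gap = 10000L,
                        chimera_cover_frac = 0.9,
                        checklist_mappable_min = 65,
                        checklist_ratio_min = 1.5,
                        checklist_n50_min = 1200,
                        checklist_uco_min = 0.70,
                        rng_seed = 1L) {
  cfg <- list(
    k = as.integer(k),
    bs_threshold = bs_threshold,
    sfb_threshold = sfb_threshold,
    type2_identity_min = type2_identity_min,
    type2_overlap_frac = type2_overlap_frac,
    chimera_identity_min = chimera_identity_min,
    chimera_evalue_max = chimera_evalue_max,
    min_unigene_length = as.integer(min_unigene_length),
    titration_step = as.integer(titration_step),
    crg_ks_max = crg_ks_max,
    crg_max_pairs = as.integer(crg_max_pairs),
    t2_seg_overlap_max = as.integer(t2_seg_overlap_max),
    chimera_merge_gap = as.integer(chimera_merge_gap),
    chimera_cover_frac = chimera_cover_frac,
    checklist_mappable_min = checklist_mappable_min,
    checklist_ratio_min = checklist_ratio_min,
    checklist_n50_min = checklist_n50_min,
    checklist_uco_min = checklist_uco_min,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "asm_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$k >= 2L,
    cfg$bs_threshold >= 0,
    cfg$sfb_threshold >= 0,
    cfg$type2_identity_min >= 0, cfg$type2_identity_min <= 100,
    cfg$type2_overlap_frac > 0, cfg$type2_overlap_frac <= 1,
    cfg$chimera_identity_min >= 0, cfg$chimera_identity_min <= 100,
    cfg$chimera_evalue_max >= 0,
    cfg$min_unigene_length >= 0,
    cfg$titration_step >= 1L,
    cfg$crg_ks_max > 0,
    cfg$t2_seg_overlap_max >= 0L,
    cfg$chimera_merge_gap >= 0L,
    cfg$chimera_cover_frac > 0, cfg$chimera_cover_frac <= 1
  )
  invisible(cfg)
}

#' Read an evaluation configuration from a YAML file
#'
#' Keys mirror the arguments of [eval_config()]; absent keys keep defaults.
#'
#' @param path Path to a YAML file.
#' @return An `"asm_config"` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(eval_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown config keys: ", paste(unknown, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(eval_config, vals)
}

#' @export
print.asm_config <- function(x, ...) {
  cat("<asm_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
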