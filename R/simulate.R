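#' Simulation plan for a toy reference transcriptome
#'
#' Describes the synthetic study system: gene count, a truncated-normal
#' cDNA length distribution, a fraction of genes generated as diverged
#' paralog duplicates, an exponential intergenic-gap model laying the genes
#' on chromosomes, and a log-normal expression model whose dynamic range
#' spans several orders of magnitude (the dominant difficulty of real
#' transcriptome assembly).
#'
#' @param n_genes Number of reference genes (>= 2).
#' @param length_mean,length_sd,length_min cDNA length distribution (bases);
#'   lengths are drawn normal and floored at `length_min`.
#' @param paralog_fraction Fraction of genes belonging to a duplicated pair;
#'   the number of pairs is `round(n_genes * paralog_fraction / 2)`.
#' @param paralog_divergence Per-base substitution probability applied when
#'   copying a paralog mate.
#' @param min_paralog_separation Minimum genomic distance between paralog
#'   mates on the same chromosome (mates this close could merge into one
#'   genomic window during chimera adjudication).
#' @param n_chrom Number of chromosomes.
#' @param intergenic_mean,intergenic_min Intergenic gap model: gaps are
#'   `intergenic_min` plus an exponential draw with the given mean (bases).
#' @param expr_meanlog,expr_sdlog Log-normal fragment-count parameters; the
#'   defaults give a median of ~50 fragments per gene and roughly three
#'   orders of magnitude of dynamic range.
#' @param zero_fraction Fraction of genes set to zero fragments (undetected).
#' @param seed Integer seed; every generator in this module is a pure
#'   function of (plan, seed).
#' @return A list with class `"asm_sim_plan"`.
#' @export
simulation_plan <- function(n_genes = 200L,
                            length_mean = 1300,
                            length_sd = 400,
                            length_min = 300L,
                            paralog_fraction = 0.1,
                            paralog_divergence = 0.03,
                            min_paralog_separation = 20000L,
                            n_chrom = 2L,
                            intergenic_mean = 2000,
                            intergenic_min = 200L,
                            expr_meanlog = log(50),
                            expr_sdlog = 1.6,
                            zero_fraction = 0.05,
                            seed = 1L) {
  stopifnot(n_genes >= 2, length_min >= 1, n_chrom >= 1,
            paralog_fraction >= 0, paralog_fraction <= 1,
            paralog_divergence >= 0, paralog_divergence <= 1,
            zero_fraction >= 0, zero_fraction <= 1)
  if (length_min > length_mean + 6 * length_sd) {
    abort("infeasible plan: length_min exceeds mean + 6 sd")
  }
  structure(
    list(n_genes = as.integer(n_genes), length_mean = length_mean,
         length_sd = length_sd, length_min = as.integer(length_min),
         paralog_fraction = paralog_fraction,
         paralog_divergence = paralog_divergence,
         min_paralog_separation = as.integer(min_paralog_separation),
         n_chrom = as.integer(n_chrom), intergenic_mean = intergenic_mean,
         intergenic_min = as.integer(intergenic_min),
         expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
         zero_fraction = zero_fraction, seed = as.integer(seed)),
    class = "asm_sim_plan"
  )
}

dna_alphabet <- c("A", "C", "G", "T")

random_seq <- function(len) {
  paste(sample(dna_alphabet, len, replace = TRUE), collapse = "")
}

# substitute each base with probability `rate`, returning the mutated string
# and the number of substitutions made
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- which(runif(length(chars)) < rate)
  for (p in pos) {
    chars[p] <- sample(setdiff(dna_alphabet, chars[p]), 1)
  }
  list(seq = paste(chars, collapse = ""), n = length(pos))
}

#' Simulate a reference transcriptome, gene map and genome
#'
#' Generates random-composition gene sequences (paralog pairs by
#' copy-and-mutate at the plan's divergence), lays the genes on chromosomes
#' with exponential intergenic gaps, and assembles the implied genomic
#' sequence. Paralog mates are never placed adjacently nor within
#' `min_paralog_separation` bases of each other. Deterministic given the
#' plan seed.
#'
#' @param plan A [simulation_plan()].
#' @return A list with class `"asm_sim"`: `reference` (tibble as from
#'   [read_fasta()]), `loci` (gene annotation tibble), `genome` (tibble
#'   `chrom`, `sequence`, `length`), `paralog_pairs` (tibble `gene_a`,
#'   `gene_b`, `divergence`), and the `plan`.
#' @export
simulate_reference <- function(plan) {
  stopifnot(inherits(plan, "asm_sim_plan"))
  withr::with_seed(plan$seed, {
    n <- plan$n_genes
    ids <- sprintf("g%04d", seq_len(n))
    lengths <- pmax(plan$length_min, as.integer(round(
      rnorm(n, plan$length_mean, plan$length_sd))))
    n_pairs <- round(n * plan$paralog_fraction / 2)
    seqs <- character(n)
    divergence_n <- integer(n)
    pair_a <- pair_b <- character(0)
    i <- 1L
    made_pairs <- 0L
    while (i <= n) {
      seqs[i] <- random_seq(lengths[i])
      if (made_pairs < n_pairs && i < n) {
        # next gene is this one's diverged duplicate (equal length)
        lengths[i + 1L] <- lengths[i]
        mut <- mutate_seq(seqs[i], plan$paralog_divergence)
        seqs[i + 1L] <- mut$seq
        divergence_n[i + 1L] <- mut$n
        pair_a <- c(pair_a, ids[i])
        pair_b <- c(pair_b, ids[i + 1L])
        made_pairs <- made_pairs + 1L
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    reference <- tibble(seq_id = ids, sequence = seqs, length = lengths,
                        n_count = 0L)
    pairs <- tibble(gene_a = pair_a, gene_b = pair_b,
                    divergence = plan$paralog_divergence)

    # place genes: permute until no paralog mates are adjacent or closer
    # than the minimum separation on one chromosome
    chrom_of <- function(perm) {
      per <- ceiling(n / plan$n_chrom)
      paste0("chr", ((seq_len(n) - 1) %/% per) + 1L)
    }
    mate_idx <- match(pair_b, ids)
    src_idx <- match(pair_a, ids)
    for (try in 1:200) {
      perm <- sample(n)
      chrom <- chrom_of(perm)
      gaps <- plan$intergenic_min + as.integer(round(rexp(n, 1 / plan$intergenic_mean)))
      pos_in_perm <- match(seq_len(n), perm)
      starts <- integer(n); ends <- integer(n)
      cur_end <- setNames(rep(0L, plan$n_chrom), paste0("chr", seq_len(plan$n_chrom)))
      ord <- integer(n)
      ord_count <- setNames(rep(0L, plan$n_chrom), names(cur_end))
      for (j in seq_len(n)) {
        g <- perm[j]
        cj <- chrom[j]
        starts[g] <- cur_end[[cj]] + gaps[j] + 1L
        ends[g] <- starts[g] + lengths[g] - 1L
        cur_end[[cj]] <- ends[g]
        ord_count[[cj]] <- ord_count[[cj]] + 1L
        ord[g] <- ord_count[[cj]]
      }
      chrom_g <- chrom[pos_in_perm]
      ok <- TRUE
      if (length(src_idx) > 0) {
        same <- chrom_g[src_idx] == chrom_g[mate_idx]
        adj <- same & abs(ord[src_idx] - ord[mate_idx]) == 1L
        close <- same & abs(starts[src_idx] - starts[mate_idx]) <
          plan$min_paralog_separation
        ok <- !any(adj | close)
      }
      if (ok) break
      if (try == 200) abort("could not place paralog mates apart; lower paralog_fraction or n_chrom")
    }
    loci <- tibble(gene_id = ids, chrom = chrom_g, start = starts,
                   end = ends, strand = "+", order_index = ord) |>
      arrange(chrom, order_index)

    # genome sequence: spacer + gene sequence per chromosome, in order
    genome <- loci |>
      group_by(chrom) |>
      arrange(order_index, .by_group = TRUE) |>
      summarise(sequence = {
        out <- character(0); prev_end <- 0L
        for (r in seq_len(n())) {
          spacer <- random_seq(start[r] - prev_end - 1L)
          out <- c(out, spacer, reference$sequence[match(gene_id[r], reference$seq_id)])
          prev_end <- end[r]
        }
        paste(out, collapse = "")
      }, .groups = "drop") |>
      mutate(length = nchar(sequence))

    structure(list(reference = reference, loci = loci, genome = genome,
                   paralog_pairs = pairs, plan = plan),
              class = "asm_sim")
  })
}

#' Simulate per-gene fragment counts
#'
#' Draws log-normal fragment counts per gene (rounded to integers) and sets
#' a designated fraction of genes to zero (undetected). The RNG stream is
#' derived from the plan seed plus one so reference and expression draws do
#' not interact.
#'
#' @param plan A [simulation_plan()].
#' @param sim The [simulate_reference()] output.
#' @return A tibble `gene_id`, `fragment_count`, with attribute
#'   `zero_genes` listing genes whose final count is zero.
#' @export
simulate_expression <- function(plan, sim) {
  stopifnot(inherits(sim, "asm_sim"))
  withr::with_seed(plan$seed + 1L, {
    n <- plan$n_genes
    counts <- as.integer(round(rlnorm(n, plan$expr_meanlog, plan$expr_sdlog)))
    zero <- runif(n) < plan$zero_fraction
    counts[zero] <- 0L
    out <- tibble(gene_id = sim$reference$seq_id, fragment_count = counts)
    attr(out, "zero_genes") <- out$gene_id[out$fragment_count == 0]
    out
  })
}

directive_kinds <- c("t1_case1", "t1_case2", "t1_case3", "chimera",
                     "co_assembly", "duplicate", "t2_case3", "t2_case4",
                     "t2_case5", "trans_splice")

#' Draw a ground-truth error plan
#'
#' Selects disjoint sets of genes for each directive kind and draws the
#' geometric parameters (split points, overlap sizes relative to `k`). To
#' guarantee both boundary regimes are represented, the first insufficient-
#' overlap directive uses overlap exactly `k - 1` and the first conflicting-
#' overlap directive exactly `k`. Chimera directives always join genes on
#' different chromosomes; trans-splice directives join distant genes on one
#' chromosome; duplication directives use paralog pairs (equal-length
#' mates); co-assembly directives use genomically adjacent gene pairs.
#'
#' @param sim The [simulate_reference()] output.
#' @param n_t1_case1,n_t1_case2,n_t1_case3 Fragmentation directives: gap,
#'   insufficient overlap, conflicting overlap.
#' @param n_chimera Chimeric joins of two non-adjacent genes.
#' @param n_co_assembly Legitimate co-assemblies of adjacent gene pairs.
#' @param n_duplicate Ambiguous duplications (unigene matching both mates of
#'   a paralog pair equally).
#' @param n_t2_case3,n_t2_case4,n_t2_case5 Ambiguity directives with nested,
#'   heavily overlapping and moderately overlapping query segments.
#' @param n_trans_splice Trans-splice candidates (annotated as such).
#' @param noise_mismatch_rate Per-base substitution rate applied to
#'   background (directive-free) unigenes.
#' @param k Assembly k-mer value the overlaps are drawn around.
#' @param seed Seed; defaults to the plan seed plus two.
#' @return A list with class `"asm_error_plan"`: `directives` tibble
#'   (`kind`, `gene_a`, `gene_b`, `param`), plus the rates and seed.
#' @export
error_plan <- function(sim,
                       n_t1_case1 = 5L, n_t1_case2 = 5L, n_t1_case3 = 5L,
                       n_chimera = 5L, n_co_assembly = 5L, n_duplicate = 5L,
                       n_t2_case3 = 5L, n_t2_case4 = 5L, n_t2_case5 = 5L,
                       n_trans_splice = 0L,
                       noise_mismatch_rate = 0,
                       k = 31L,
                       seed = sim$plan$seed + 2L) {
  stopifnot(inherits(sim, "asm_sim"), k >= 2)
  withr::with_seed(seed, {
    loci <- sim$loci
    lens <- setNames(sim$reference$length, sim$reference$seq_id)
    used <- character(0)
    take_genes <- function(n_needed) {
      pool <- setdiff(sim$reference$seq_id, used)
      if (length(pool) < n_needed) abort("not enough unused genes for the error plan")
      g <- sample(pool, n_needed)
      used <<- c(used, g)
      g
    }
    directives <- list()
    add <- function(kind, gene_a, gene_b = NA_character_, param = NA_integer_) {
      directives[[length(directives) + 1L]] <<-
        tibble(kind = kind, gene_a = gene_a, gene_b = gene_b,
               param = as.integer(param))
    }

    # duplications need equal-length paralog mates
    if (n_duplicate > 0) {
      pp <- sim$paralog_pairs
      if (nrow(pp) < n_duplicate) abort("not enough paralog pairs for duplication directives")
      sel <- pp[sample(nrow(pp), n_duplicate), ]
      used <- c(used, sel$gene_a, sel$gene_b)
      for (r in seq_len(nrow(sel))) add("duplicate", sel$gene_a[r], sel$gene_b[r])
    }

    # co-assemblies need adjacent pairs whose members are unused
    if (n_co_assembly > 0) {
      adj <- loci |>
        group_by(chrom) |>
        arrange(order_index, .by_group = TRUE) |>
        mutate(nxt = lead(gene_id)) |>
        ungroup() |>
        filter(!is.na(nxt), !(gene_id %in% used), !(nxt %in% used))
      picked <- character(0)
      rows <- sample(nrow(adj))
      for (r in rows) {
        if (length(picked) / 2 >= n_co_assembly) break
        a <- adj$gene_id[r]; b <- adj$nxt[r]
        if (a %in% picked || b %in% picked) next
        picked <- c(picked, a, b)
        add("co_assembly", a, b)
      }
      if (length(picked) / 2 < n_co_assembly) {
        abort("not enough free adjacent pairs for co-assembly directives")
      }
      used <- c(used, picked)
    }

    chrom_of_gene <- setNames(loci$chrom, loci$gene_id)
    start_of_gene <- setNames(loci$start, loci$gene_id)

    # chimeras: two genes whose genomic windows cannot merge — different
    # chromosomes, or far apart on one chromosome
    for (i in seq_len(n_chimera)) {
      repeat {
        g <- take_genes(2L)
        diff_chrom <- chrom_of_gene[g[1]] != chrom_of_gene[g[2]]
        far <- abs(start_of_gene[g[1]] - start_of_gene[g[2]]) > 30000
        if (diff_chrom || far) break
        used <- setdiff(used, g)
      }
      g <- g[order(lens[g])]
      add("chimera", g[1], g[2])
    }

    # trans-splice candidates: distant genes on one chromosome
    for (i in seq_len(n_trans_splice)) {
      repeat {
        g <- take_genes(2L)
        same <- chrom_of_gene[g[1]] == chrom_of_gene[g[2]]
        far <- abs(start_of_gene[g[1]] - start_of_gene[g[2]]) > 30000
        if (same && far) break
        used <- setdiff(used, g)
      }
      g <- g[order(lens[g])]
      add("trans_splice", g[1], g[2])
    }

    # remaining ambiguity directives: any non-adjacent pair, shorter first
    non_adjacent_pair <- function() {
      repeat {
        g <- take_genes(2L)
        la <- loci[loci$gene_id == g[1], ]
        lb <- loci[loci$gene_id == g[2], ]
        adj <- la$chrom == lb$chrom && abs(la$order_index - lb$order_index) == 1
        if (!adj) return(g[order(lens[g])])
        used <<- setdiff(used, g)
      }
    }
    for (i in seq_len(n_t2_case3)) { g <- non_adjacent_pair(); add("t2_case3", g[1], g[2]) }
    for (i in seq_len(n_t2_case4)) { g <- non_adjacent_pair(); add("t2_case4", g[1], g[2]) }
    for (i in seq_len(n_t2_case5)) { g <- non_adjacent_pair(); add("t2_case5", g[1], g[2]) }

    # fragmentation directives with drawn gap/overlap sizes
    if (n_t1_case1 > 0) {
      for (g in take_genes(n_t1_case1)) {
        add("t1_case1", g, param = sample(5:50, 1))
      }
    }
    if (n_t1_case2 > 0) {
      ov <- c(k - 1L, sample(0:(k - 1L), max(0L, n_t1_case2 - 1L), replace = TRUE))
      for (j in seq_len(n_t1_case2)) add("t1_case2", take_genes(1L), param = ov[j])
    }
    if (n_t1_case3 > 0) {
      ov <- c(k, sample(k:(2L * k), max(0L, n_t1_case3 - 1L), replace = TRUE))
      for (j in seq_len(n_t1_case3)) add("t1_case3", take_genes(1L), param = ov[j])
    }

    empty_directives <- tibble(kind = character(), gene_a = character(),
                               gene_b = character(), param = integer())
    structure(list(directives = if (length(directives)) bind_rows(directives)
                                else empty_directives,
                   noise_mismatch_rate = noise_mismatch_rate,
                   k = as.integer(k), seed = as.integer(seed)),
              class = "asm_error_plan")
  })
}

#' Corrupt a simulated reference into an assembly with known errors
#'
#' Realises an [error_plan()] as unigene sequences plus a ground-truth
#' record: fragmentation directives emit two pieces whose reference
#' projections have exactly the intended gap or overlap; chimera and
#' trans-splice directives concatenate segments of two genes; co-assembly
#' directives excise the genomic span of an adjacent pair including the
#' true intergenic spacer; duplication directives copy one paralog mate;
#' nested/staggered ambiguity directives copy one gene and record the
#' implied two-gene alignment geometry. Background genes (no directive)
#' yield one full-length unigene each, with substitution noise at the
#' plan's rate. Alignment geometry is recorded directly so that
#' [derive_truth_alignments()] can emit the implied alignment tables with
#' no external aligner.
#'
#' @param sim The [simulate_reference()] output.
#' @param eplan An [error_plan()].
#' @param seed Seed for the noise draws; defaults to the error-plan seed.
#' @return A list with class `"asm_truth"`: `assembly` (unigene tibble as
#'   from [read_fasta()]), `geometry` (implied alignments), `labels` (list
#'   of intended Type I events, Type II events, chimera verdicts),
#'   `sources` (unigene to source-gene map), `trans_splice_ids`, `k`.
#' @export
corrupt_assembly <- function(sim, eplan, seed = eplan$seed) {
  stopifnot(inherits(sim, "asm_sim"), inherits(eplan, "asm_error_plan"))
  withr::with_seed(seed + 1L, {
    ref <- sim$reference
    loci <- sim$loci
    lens <- setNames(ref$length, ref$seq_id)
    seq_of <- setNames(ref$sequence, ref$seq_id)
    locus_of <- split(loci, loci$gene_id)
    genome_seq <- setNames(sim$genome$sequence, sim$genome$chrom)

    geometry <- list()
    seqs <- list()
    sources <- list()
    t1_events <- list()
    t2_events <- list()
    verdicts <- list()
    trans_ids <- character(0)

    emit_geom <- function(unigene, target, subject, qs, qe, ss, se,
                          mism = 0L, gaps = 0L) {
      geometry[[length(geometry) + 1L]] <<- tibble(
        unigene_id = unigene, target = target, subject_id = subject,
        q_start = as.integer(qs), q_end = as.integer(qe),
        s_start = as.integer(ss), s_end = as.integer(se),
        mismatches = as.integer(mism), gap_openings = as.integer(gaps))
    }
    emit_seq <- function(unigene, s, source_gene) {
      seqs[[unigene]] <<- s
      sources[[length(sources) + 1L]] <<-
        tibble(unigene_id = unigene, gene_id = source_gene,
               piece_length = nchar(s))
    }
    genome_span <- function(gene, offset_start, offset_end) {
      lc <- locus_of[[gene]]
      c(lc$chrom, lc$start + offset_start - 1L, lc$start + offset_end - 1L)
    }

    d <- eplan$directives
    for (r in seq_len(nrow(d))) {
      kind <- d$kind[r]; ga <- d$gene_a[r]; gb <- d$gene_b[r]
      La <- unname(lens[ga])
      if (kind %in% c("t1_case1", "t1_case2", "t1_case3")) {
        b <- as.integer(round(0.55 * La))
        if (kind == "t1_case1") {
          gap <- d$param[r]
          p2_start <- b + gap + 1L
        } else {
          ov <- d$param[r]
          p2_start <- b - ov + 1L
        }
        u1 <- paste0("u_", ga, "_1"); u2 <- paste0("u_", ga, "_2")
        emit_seq(u1, substr(seq_of[ga], 1L, b), ga)
        emit_seq(u2, substr(seq_of[ga], p2_start, La), ga)
        emit_geom(u1, "cdna", ga, 1L, b, 1L, b)
        emit_geom(u2, "cdna", ga, 1L, La - p2_start + 1L, p2_start, La)
        gs1 <- genome_span(ga, 1L, b)
        gs2 <- genome_span(ga, p2_start, La)
        emit_geom(u1, "genome", gs1[1], 1L, b, gs1[2], gs1[3])
        emit_geom(u2, "genome", gs2[1], 1L, La - p2_start + 1L, gs2[2], gs2[3])
        is_gap <- kind == "t1_case1"
        t1_events[[length(t1_events) + 1L]] <- tibble(
          kind = paste0("T1_case", match(kind, c("t1_case1", "t1_case2", "t1_case3"))),
          gene_id = ga, unigene_a = u1, unigene_b = u2,
          gap = if (is_gap) d$param[r] else NA_integer_,
          overlap = if (is_gap) NA_integer_ else d$param[r])
      } else if (kind %in% c("chimera", "trans_splice")) {
        Lb <- unname(lens[gb])
        x <- as.integer(round(0.5 * La))
        y <- min(as.integer(round(0.5 * Lb)), 4L * x)
        u <- paste0("u_chi_", ga, "_", gb)
        emit_seq(u, paste0(substr(seq_of[ga], 1L, x), substr(seq_of[gb], 1L, y)), ga)
        emit_geom(u, "cdna", ga, 1L, x, 1L, x)
        emit_geom(u, "cdna", gb, x + 1L, x + y, 1L, y)
        gsa <- genome_span(ga, 1L, x); gsb <- genome_span(gb, 1L, y)
        emit_geom(u, "genome", gsa[1], 1L, x, gsa[2], gsa[3])
        emit_geom(u, "genome", gsb[1], x + 1L, x + y, gsb[2], gsb[3])
        t2_events[[length(t2_events) + 1L]] <- tibble(
          kind = "T2_case1", unigene_id = u, gene_a = ga, gene_b = gb)
        if (kind == "trans_splice") {
          trans_ids <- c(trans_ids, u)
          verdicts[[length(verdicts) + 1L]] <-
            tibble(unigene_id = u, verdict = "trans_spliced_candidate")
        } else {
          verdicts[[length(verdicts) + 1L]] <-
            tibble(unigene_id = u, verdict = "chimera")
        }
      } else if (kind == "co_assembly") {
        la <- locus_of[[ga]]; lb <- locus_of[[gb]]
        u <- paste0("u_co_", ga, "_", gb)
        span <- substr(genome_seq[la$chrom], la$start, lb$end)
        L <- nchar(span)
        Lb <- unname(lens[gb])
        emit_seq(u, span, ga)
        emit_geom(u, "cdna", ga, 1L, La, 1L, La)
        emit_geom(u, "cdna", gb, L - Lb + 1L, L, 1L, Lb)
        emit_geom(u, "genome", la$chrom, 1L, L, la$start, lb$end)
        verdicts[[length(verdicts) + 1L]] <-
          tibble(unigene_id = u, verdict = "co_assembly")
      } else if (kind == "duplicate") {
        u <- paste0("u_dup_", ga, "_", gb)
        emit_seq(u, seq_of[ga], ga)
        emit_geom(u, "cdna", ga, 1L, La, 1L, La)
        emit_geom(u, "cdna", gb, 1L, La, 1L, La)
        la <- locus_of[[ga]]; lb <- locus_of[[gb]]
        emit_geom(u, "genome", la$chrom, 1L, La, la$start, la$end)
        emit_geom(u, "genome", lb$chrom, 1L, La, lb$start, lb$end)
        t2_events[[length(t2_events) + 1L]] <- tibble(
          kind = "T2_case2", unigene_id = u, gene_a = ga, gene_b = gb)
        verdicts[[length(verdicts) + 1L]] <-
          tibble(unigene_id = u, verdict = "ambiguous_duplicate")
      } else if (kind %in% c("t2_case3", "t2_case4", "t2_case5")) {
        u <- paste0("u_amb_", ga, "_", gb)
        emit_seq(u, seq_of[ga], ga)
        if (kind == "t2_case3") {
          s <- max(2L, as.integer(round(0.2 * La)))
          e <- as.integer(round(0.7 * La))
          emit_geom(u, "cdna", ga, 1L, La, 1L, La)
          emit_geom(u, "cdna", gb, s, e, 1L, e - s + 1L)
        } else if (kind == "t2_case4") {
          a_end <- as.integer(floor(0.9 * La))
          b_start <- as.integer(floor(0.05 * La)) + 1L
          emit_geom(u, "cdna", ga, 1L, a_end, 1L, a_end)
          emit_geom(u, "cdna", gb, b_start, La, 1L, La - b_start + 1L)
        } else {
          a_end <- as.integer(round(0.6 * La))
          b_start <- as.integer(round(0.4 * La)) + 1L
          emit_geom(u, "cdna", ga, 1L, a_end, 1L, a_end)
          emit_geom(u, "cdna", gb, b_start, La, 1L, La - b_start + 1L)
        }
        gsa <- genome_span(ga, 1L, La)
        emit_geom(u, "genome", gsa[1], 1L, La, gsa[2], gsa[3])
        t2_events[[length(t2_events) + 1L]] <- tibble(
          kind = paste0("T2_case", match(kind, c("t2_case3", "t2_case4", "t2_case5")) + 2L),
          unigene_id = u, gene_a = ga, gene_b = gb)
      }
    }

    # background genes: one clean full-length unigene each, optional noise
    background <- setdiff(ref$seq_id, unique(c(d$gene_a, d$gene_b)))
    for (g in background) {
      u <- paste0("u_", g)
      mut <- mutate_seq(seq_of[g], eplan$noise_mismatch_rate)
      emit_seq(u, mut$seq, g)
      L <- unname(lens[g])
      emit_geom(u, "cdna", g, 1L, L, 1L, L, mism = mut$n)
      gs <- genome_span(g, 1L, L)
      emit_geom(u, "genome", gs[1], 1L, L, gs[2], gs[3], mism = mut$n)
    }

    assembly <- tibble(
      seq_id = names(seqs),
      sequence = unlist(seqs, use.names = FALSE)
    ) |>
      mutate(length = nchar(sequence),
             n_count = as.integer(lengths(regmatches(sequence, gregexpr("N", sequence)))))

    structure(list(
      assembly = assembly,
      geometry = bind_rows(geometry),
      labels = list(
        type1 = if (length(t1_events)) bind_rows(t1_events) else
          tibble(kind = character(), gene_id = character(),
                 unigene_a = character(), unigene_b = character(),
                 gap = integer(), overlap = integer()),
        type2 = if (length(t2_events)) bind_rows(t2_events) else
          tibble(kind = character(), unigene_id = character(),
                 gene_a = character(), gene_b = character()),
        verdicts = if (length(verdicts)) bind_rows(verdicts) else
          tibble(unigene_id = character(), verdict = character())
      ),
      sources = bind_rows(sources),
      trans_splice_ids = trans_ids,
      k = eplan$k
    ), class = "asm_truth")
  })
}

#' Derive the alignment tables implied by a corrupted assembly
#'
#' Converts the recorded construction geometry into standard 12-column
#' alignment tibbles (versus the reference cDNAs and versus the genome),
#' with idealized scoring: +2 bits per matched base, -2 per mismatch, -5
#' per gap opening, e-value 0. These stand in for an aligner so every
#' evaluator can be exercised without external data; real aligner tables in
#' the same 12-column dialect are accepted everywhere the derived ones are.
#'
#' @param truth An `"asm_truth"` object from [corrupt_assembly()].
#' @return A list with tibbles `cdna` and `genome`.
#' @export
derive_truth_alignments <- function(truth) {
  stopifnot(inherits(truth, "asm_truth"))
  fmt <- function(g) {
    g |>
      mutate(
        aln_length = q_end - q_start + 1L,
        matches = aln_length - mismatches,
        pct_identity = 100 * matches / aln_length,
        e_value = 0,
        bit_score = pmax(0, 2 * matches - 2 * mismatches - 5 * gap_openings)
      ) |>
      transmute(query_id = unigene_id, subject_id, pct_identity, aln_length,
                mismatches, gap_openings, q_start, q_end, s_start, s_end,
                e_value, bit_score)
  }
  list(
    cdna = fmt(truth$geometry |> filter(target == "cdna")),
    genome = fmt(truth$geometry |> filter(target == "genome"))
  )
}

#' Distribute per-gene fragment counts over the unigenes derived from them
#'
#' Splits each gene's simulated fragment count among the unigenes whose
#' source is that gene, proportionally to piece length (largest-remainder
#' rounding, deterministic). Genes with no derived unigene keep their
#' fragments unassigned (dropped with a message).
#'
#' @param gene_counts Tibble `gene_id`, `fragment_count` from
#'   [simulate_expression()].
#' @param truth An `"asm_truth"` object.
#' @return A per-unigene count tibble (`unigene_id`, `fragment_count`).
#' @export
assign_fragments <- function(gene_counts, truth) {
  stopifnot(inherits(truth, "asm_truth"))
  src <- truth$sources
  merged <- src |> inner_join(gene_counts, by = "gene_id")
  dropped <- setdiff(gene_counts$gene_id[gene_counts$fragment_count > 0],
                     src$gene_id)
  if (length(dropped) > 0) {
    inform(paste0(length(dropped), " gene(s) have no derived unigene; ",
                  "their fragments are unassigned"))
  }
  merged |>
    group_by(gene_id) |>
    group_modify(function(df, key) {
      total <- df$fragment_count[1]
      w <- df$piece_length / sum(df$piece_length)
      base <- floor(total * w)
      rem <- total - sum(base)
      if (rem > 0) {
        extra <- order(total * w - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      tibble(unigene_id = df$unigene_id, fragment_count = as.integer(base))
    }) |>
    ungroup() |>
    select(unigene_id, fragment_count)
}

#' Subsample read pairs to a target number of bases
#'
#' Pairs are kept or dropped atomically, sampled without replacement until
#' the cumulative base count reaches the target; the last accepted pair may
#' overshoot. Accepts either a pair table (`pair_id`, `n_bases`) or a pair
#' of FASTQ files.
#'
#' @param pairs Tibble with columns `pair_id` and `n_bases`, or `NULL` when
#'   using FASTQ input.
#' @param target_bases Target cumulative bases (> 0).
#' @param seed Integer seed.
#' @param r1,r2 Optional FASTQ paths (read 1 / read 2); when given, the
#'   subsampled pairs are written to `out_r1` / `out_r2`.
#' @param out_r1,out_r2 Output FASTQ paths for FASTQ mode.
#' @return For table input, the subset of rows kept (in original order).
#'   For FASTQ input, the integer indices of pairs kept, invisibly, after
#'   writing the output files.
#' @export
subsample_reads <- function(pairs = NULL, target_bases, seed = 1L,
                            r1 = NULL, r2 = NULL,
                            out_r1 = NULL, out_r2 = NULL) {
  if (target_bases <= 0) abort("target_bases must be > 0")
  if (!is.null(r1)) {
    stopifnot(!is.null(r2), !is.null(out_r1), !is.null(out_r2))
    s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
    s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
    stopifnot(length(s1) == length(s2))
    nb <- Biostrings::width(s1) + Biostrings::width(s2)
    keep <- subsample_keep(nb, target_bases, seed)
    q1 <- S4Vectors::mcols(s1)$qualities
    q2 <- S4Vectors::mcols(s2)$qualities
    Biostrings::writeXStringSet(s1[keep], out_r1, format = "fastq",
                                qualities = q1[keep])
    Biostrings::writeXStringSet(s2[keep], out_r2, format = "fastq",
                                qualities = q2[keep])
    return(invisible(keep))
  }
  stopifnot(is.data.frame(pairs), all(c("pair_id", "n_bases") %in% names(pairs)))
  keep <- subsample_keep(pairs$n_bases, target_bases, seed)
  pairs[sort(keep), , drop = FALSE]
}

subsample_keep <- function(n_bases, target_bases, seed) {
  if (sum(n_bases) <= target_bases) return(seq_along(n_bases))
  perm <- withr::with_seed(seed, sample(length(n_bases)))
  cum <- cumsum(n_bases[perm])
  n_keep <- which(cum >= target_bases)[1]
  perm[seq_len(n_keep)]
}
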