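#' Read sequences from a FASTA file
#'
#' Reads reference transcripts or assembly unigenes. The sequence identifier
#' is the first whitespace-delimited token of the header; the ambiguous-base
#' count tallies `N` characters.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id`, `sequence`, `length`, `n_count`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 a gene", "ACGTN", ">g2", "GGGG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(seq_id = character(), sequence = character(),
                  length = integer(), n_count = integer()))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence identifier(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble(
    seq_id = ids,
    sequence = unname(as.character(seqs)),
    length = Biostrings::width(seqs),
    n_count = as.integer(Biostrings::letterFrequency(seqs, "N"))
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with `seq_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$seq_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

aln_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_openings", "q_start", "q_end",
              "s_start", "s_end", "e_value", "bit_score")

#' Read a 12-column tabular alignment file
#'
#' Parses the standard 12-column tab-separated alignment dialect (query,
#' subject, percent identity, alignment length, mismatches, gap openings,
#' query start/end, subject start/end, e-value, bit score). Lines starting
#' with `#` are skipped. Coordinates are 1-based inclusive; a subject start
#' greater than subject end encodes a minus-strand alignment and is passed
#' through unchanged (see [canonicalize_alignments()]).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the 12 standard columns.
#' @export
read_alignment_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    out <- as_tibble(setNames(rep(list(numeric()), 12), aln_cols))
    out$query_id <- character(); out$subject_id <- character()
    return(out[aln_cols])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    abort(sprintf("line %d: expected 12 tab-separated columns, found %d",
                  line_no[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    abort(sprintf("line %d: non-numeric value in a numeric column",
                  line_no[bad]))
  }
  tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num[, 1], aln_length = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gap_openings = as.integer(num[, 4]),
    q_start = as.integer(num[, 5]), q_end = as.integer(num[, 6]),
    s_start = as.integer(num[, 7]), s_end = as.integer(num[, 8]),
    e_value = num[, 9], bit_score = num[, 10]
  )
}

#' Write an alignment tibble as a 12-column TSV
#'
#' @param aln Alignment tibble (12 standard columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(aln, path) {
  readr::write_tsv(aln[aln_cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a per-unigene fragment count table
#'
#' Two tab-separated columns: unigene identifier and the non-negative count of
#' sequenced fragments (a read pair counts once; an orphan read counts once)
#' mapped to it. Repeated identifiers are summed. Fractional counts are
#' rejected: fragment counting retains one best alignment per fragment, so
#' multi-mapping weights never arise.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `unigene_id`, `fragment_count`.
#' @export
read_counts_table <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(path, col_names = c("unigene_id", "fragment_count"),
                        col_types = "cd", comment = "#", progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble(unigene_id = character(), fragment_count = integer()))
  }
  if (any(is.na(df$fragment_count))) abort("non-numeric fragment count")
  if (any(df$fragment_count < 0)) abort("negative fragment count")
  if (any(df$fragment_count != round(df$fragment_count))) {
    abort("fractional fragment count: counts must be integers")
  }
  df |>
    group_by(unigene_id) |>
    summarise(fragment_count = as.integer(sum(fragment_count)), .groups = "drop")
}

#' Read a gene annotation table
#'
#' Accepts a BED-like TSV (`chrom`, `start`, `end`, `gene_id`, `strand`) or
#' GFF3 `gene` lines (with an `ID=` attribute). Genes on each chromosome are
#' ranked by start coordinate into `order_index`; two genes are adjacent when
#' they share a chromosome and their order indices differ by one.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `order_index`.
#' @export
read_gene_annotation <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  order_index = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 9)) { # GFF3
    m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
    gene_rows <- m[, 3] == "gene"
    m <- m[gene_rows, , drop = FALSE]
    ids <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9])
    df <- tibble(gene_id = ids, chrom = m[, 1],
                 start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                 strand = m[, 7])
  } else if (all(nf >= 5)) { # BED-like
    m <- matrix(unlist(lapply(fields, `[`, 1:5)), ncol = 5, byrow = TRUE)
    df <- tibble(gene_id = m[, 4], chrom = m[, 1],
                 start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                 strand = m[, 5])
  } else {
    abort(sprintf("line %d: expected 5 BED-like or 9 GFF3 columns",
                  which(nf < 5)[1]))
  }
  if (anyNA(df$start) || anyNA(df$end)) abort("non-numeric gene coordinate")
  if (any(df$start >= df$end)) abort("gene with start >= end")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene identifier(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  df |>
    group_by(chrom) |>
    arrange(start, .by_group = TRUE) |>
    mutate(order_index = row_number()) |>
    ungroup() |>
    arrange(chrom, order_index)
}

#' Write a gene annotation tibble as BED-like TSV
#'
#' @param loci Gene annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(loci, path) {
  readr::write_tsv(loci[c("chrom", "start", "end", "gene_id", "strand")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Write evaluation reports to disk
#'
#' Writes each element of a named list of data frames (or scalars collected
#' into one-row data frames) to `out_dir`, one file per report section, in
#' TSV or JSON form. Field order is deterministic and numeric content is
#' identical across the two formats; TSV tables round-trip through
#' [readr::read_tsv()].
#'
#' @param results Named list of data frames (an `asm_eval` object also works).
#' @param out_dir Output directory, created if needed.
#' @param format `"tsv"` or `"json"`.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(results, out_dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "asm_eval")) results <- unclass(results)
  stopifnot(is.list(results), length(names(results)) == length(results))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.null(x)) next
    if (!is.data.frame(x)) x <- as_tibble(as.list(x))
    path <- file.path(out_dir, paste0(nm, ".", format))
    if (format == "tsv") {
      readr::write_tsv(x, path)
    } else {
      jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null")
    }
    files <- c(files, path)
  }
  invisible(files)
}
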