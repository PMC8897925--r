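# Writers for every external format the pipeline emits. All writers
# round-trip losslessly against the corresponding readers (tested).

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write gene models as GTF (1-based inclusive)
#'
#' Emits `gene`, `exon` and (when known) `five_prime_utr`/`three_prime_utr`
#' features. This conversion from internal 0-based half-open coordinates is
#' the only +1 boundary in the package.
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gtf <- function(genes, path) {
  fmt <- function(chrom, src, type, start0, end0, strand, gid) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            chrom, src, type, start0 + 1L, end0, strand, gid)
  }
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, fmt(g$chrom, "methylens", "gene", g$start, g$end,
                          g$strand, g$gene_id))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, fmt(g$chrom, "methylens", "exon", ex$start[j],
                            ex$end[j], g$strand, g$gene_id))
    }
    if (!is.na(g$utr5_start)) {
      lines <- c(lines, fmt(g$chrom, "methylens", "five_prime_utr",
                            g$utr5_start, g$utr5_end, g$strand, g$gene_id))
    }
    if (!is.na(g$utr3_start)) {
      lines <- c(lines, fmt(g$chrom, "methylens", "three_prime_utr",
                            g$utr3_start, g$utr3_end, g$strand, g$gene_id))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write gene models as BED12
#'
#' Exons become blocks; the thick range spans from the end of the 5' UTR to
#' the start of the 3' UTR when both are known, else the full gene.
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- arrange(g$exons[[1]], .data$start)
    have_utr <- !is.na(g$utr5_start) && !is.na(g$utr3_start)
    thick_start <- if (have_utr) {
      if (g$strand == "+") g$utr5_end else g$utr3_end
    } else g$start
    thick_end <- if (have_utr) {
      if (g$strand == "+") g$utr3_start else g$utr5_start
    } else g$end
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom, g$start, g$end, g$gene_id, g$strand,
            thick_start, thick_end, nrow(ex),
            paste0(ex$end - ex$start, collapse = ","),
            paste0(ex$start - g$start, collapse = ","))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write per-cytosine counts as Bismark-coverage-like TSVs
#'
#' One file per (group, replicate): chrom, start, end, percent methylated,
#' count methylated, count unmethylated; no header.
#'
#' @param records Per-cytosine record tibble.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Tibble `path`, `group`, `replicate` suitable for
#'   [read_methylation_counts()].
#' @export
write_methylation_counts <- function(records, dir, prefix = "meth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combos <- distinct(records, .data$group, .data$replicate) |>
    arrange(.data$group, .data$replicate)
  paths <- purrr::pmap_chr(combos, function(group, replicate) {
    sub <- records |> filter(.data$group == !!group, .data$replicate == !!replicate)
    path <- file.path(dir, sprintf("%s_%s_rep%d.cov", prefix, group, replicate))
    readr::write_tsv(
      tibble(
        chrom = sub$chrom, start = sub$pos, end = sub$pos + 1L,
        pct = round(100 * sub$n_methylated / sub$n_total, 4),
        n_methylated = sub$n_methylated,
        n_unmethylated = sub$n_total - sub$n_methylated
      ),
      path, col_names = FALSE, progress = FALSE
    )
    path
  })
  mutate(combos, path = paths, .before = 1)
}

#' Write a BED3 interval file
#' @param intervals Tibble `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(intervals, path) {
  readr::write_tsv(select(intervals, "chrom", "start", "end"), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write an expression table
#' @param expression Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Write ATAC peaks as BED6+2 (log2fc, qvalue)
#' @param peaks Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atac_peaks <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else
      sprintf("peak%05d", seq_len(nrow(peaks))),
    score = 0L, strand = ".",
    log2fc = peaks$log2fc, qvalue = peaks$qvalue
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write sequences as FASTA (e.g. DMR sequence sets for external motif tools)
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
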