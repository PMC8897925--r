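#' Read per-cytosine methylation count files
#'
#' Reads one Bismark-coverage-like TSV per replicate (columns: chrom, start,
#' end, percent methylated, count methylated, count unmethylated; no header)
#' and stacks them into a single per-cytosine record table. `pos` is taken
#' from the file's start column (0-based).
#'
#' @param paths Character vector of file paths.
#' @param group Group label per path (`"group1"` = epithelial-like reference,
#'   `"group2"` = fiber-like), recycled if length 1.
#' @param replicate Integer replicate index per path.
#' @param context Cytosine context label attached to every record
#'   (files of this dialect are usually pre-split by context).
#' @return Tibble sorted by (chrom, pos): `chrom`, `pos`, `context`,
#'   `group`, `replicate`, `n_methylated`, `n_total`.
#' @export
read_methylation_counts <- function(paths, group, replicate, context = "CG") {
  group <- rep_len(group, length(paths))
  replicate <- rep_len(as.integer(replicate), length(paths))
  out <- purrr::pmap(
    list(paths, group, replicate),
    function(path, grp, rep) {
      dat <- suppressWarnings(readr::read_tsv(
        path,
        col_names = c("chrom", "pos", "end", "pct", "n_methylated", "n_unmethylated"),
        col_types = "ciidii",
        progress = FALSE
      ))
      probs <- readr::problems(dat)
      if (nrow(probs) > 0) {
        abort(sprintf("Malformed methylation counts in %s at line %d.",
                      path, probs$row[1]))
      }
      if (nrow(dat) == 0) {
        warn(sprintf("Empty methylation counts file: %s", path))
      }
      tibble(
        chrom = dat$chrom, pos = dat$pos, context = context,
        group = grp, replicate = rep,
        n_methylated = dat$n_methylated,
        n_total = dat$n_methylated + dat$n_unmethylated
      )
    }
  ) |> list_rbind()
  if (any(out$n_methylated > out$n_total | out$n_methylated < 0)) {
    abort("Methylated counts exceed totals (or are negative).")
  }
  dup <- out |> count(.data$chrom, .data$pos, .data$group, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate cytosine records, e.g. %s:%d replicate %d.",
                  dup$chrom[1], dup$pos[1], dup$replicate[1]))
  }
  arrange(out, .data$chrom, .data$pos, .data$group, .data$replicate)
}

#' Read gene models from GTF or BED12
#'
#' Coordinates are normalised to 0-based half-open internally; GTF input
#' (1-based inclusive) is the only place the +/-1 conversion happens. Exons
#' are sorted; introns are the gaps between exons; UTRs are taken from
#' `five_prime_utr`/`three_prime_utr` features when present (GTF) or from
#' the thick/CDS region (BED12).
#'
#' @param path File path.
#' @param format `"gtf"` or `"bed12"`.
#' @return Gene-model tibble: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `exons` list-column, and `utr5_start`/`utr5_end`/`utr3_start`/`utr3_end`
#'   (NA when underivable).
#' @export
read_gene_models <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "gtf") read_genes_gtf(path) else read_genes_bed12(path)
}

read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr)) |>
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           # GTF is 1-based inclusive; internal is 0-based half-open
           start0 = .data$start - 1L, end0 = .data$end)
  genes <- df |> filter(.data$type == "gene")
  if (nrow(genes) == 0) {
    # tolerate exon-only GTFs by deriving gene spans from exons
    genes <- df |> filter(.data$type == "exon") |>
      group_by(.data$gene_id, .data$chrom, .data$strand) |>
      summarise(start0 = min(.data$start0), end0 = max(.data$end0), .groups = "drop")
  }
  purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$strand, genes$start0, genes$end0),
    function(gid, chrom, strand, g_start, g_end) {
      feats <- df |> filter(.data$gene_id == gid)
      exons <- feats |> filter(.data$type == "exon") |>
        transmute(start = .data$start0, end = .data$end0) |> arrange(.data$start)
      if (nrow(exons) == 0) exons <- tibble(start = g_start, end = g_end)
      if (any(exons$start < g_start | exons$end > g_end)) {
        abort(sprintf("Exon outside gene span for %s.", gid))
      }
      utr5 <- feats |> filter(.data$type == "five_prime_utr")
      utr3 <- feats |> filter(.data$type == "three_prime_utr")
      tibble(
        gene_id = gid, chrom = chrom, strand = strand,
        start = as.integer(g_start), end = as.integer(g_end),
        exons = list(exons),
        utr5_start = if (nrow(utr5)) as.integer(min(utr5$start0)) else NA_integer_,
        utr5_end = if (nrow(utr5)) as.integer(max(utr5$end0)) else NA_integer_,
        utr3_start = if (nrow(utr3)) as.integer(min(utr3$start0)) else NA_integer_,
        utr3_end = if (nrow(utr3)) as.integer(max(utr3$end0)) else NA_integer_
      )
    }
  ) |> list_rbind() |> arrange(.data$chrom, .data$start)
}

read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  n <- length(gr)
  blocks <- if (!is.null(gr$blocks)) gr$blocks else NULL
  purrr::map(seq_len(n), function(i) {
    g_start <- BiocGenerics::start(gr)[i] - 1L  # import() gives 1-based starts
    g_end <- BiocGenerics::end(gr)[i]
    chrom <- as.character(GenomeInfoDb::seqnames(gr))[i]
    strand <- as.character(BiocGenerics::strand(gr))[i]
    if (strand == "*") strand <- "+"
    exons <- if (!is.null(blocks)) {
      b <- blocks[[i]]
      # block starts are relative 1-based within the BED record after import
      tibble(start = g_start + BiocGenerics::start(b) - 1L,
             end = g_start + BiocGenerics::end(b))
    } else {
      tibble(start = g_start, end = g_end)
    }
    if (any(exons$start < g_start | exons$end > g_end)) {
      abort(sprintf("Exon outside gene span for %s.", gr$name[i]))
    }
    thick <- gr$thick
    utr <- list(utr5_start = NA_integer_, utr5_end = NA_integer_,
                utr3_start = NA_integer_, utr3_end = NA_integer_)
    if (!is.null(thick)) {
      t_start <- BiocGenerics::start(thick)[i] - 1L
      t_end <- BiocGenerics::end(thick)[i]
      if (t_end > t_start && (t_start > g_start || t_end < g_end)) {
        left <- c(g_start, t_start)
        right <- c(t_end, g_end)
        if (strand == "+") {
          utr <- list(utr5_start = left[1], utr5_end = left[2],
                      utr3_start = right[1], utr3_end = right[2])
        } else {
          utr <- list(utr5_start = right[1], utr5_end = right[2],
                      utr3_start = left[1], utr3_end = left[2])
        }
      }
    }
    tibble(
      gene_id = if (!is.null(gr$name)) gr$name[i] else sprintf("gene%04d", i),
      chrom = chrom, strand = strand,
      start = as.integer(g_start), end = as.integer(g_end),
      exons = list(mutate(exons, across(dplyr::everything(), as.integer))),
      utr5_start = as.integer(utr$utr5_start), utr5_end = as.integer(utr$utr5_end),
      utr3_start = as.integer(utr$utr3_start), utr3_end = as.integer(utr$utr3_end)
    )
  }) |> list_rbind() |> arrange(.data$chrom, .data$start)
}

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `fpkm_group1`, `fpkm_group2` and
#' optionally `log2fc` and `qvalue`. When `log2fc` is absent it is computed
#' as `log2(fpkm_group2 / fpkm_group1)` for genes with both FPKMs positive.
#' The fold-change orientation is group2/group1 (fiber/epithelial)
#' throughout. `qvalue` may contain NA; such records are retained but drop
#' out of significance-filtered sets downstream.
#'
#' @param path File path.
#' @return Tibble with one row per gene.
#' @export
read_expression_table <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("gene_id", "fpkm_group1", "fpkm_group2")
  missing <- setdiff(needed, names(dat))
  if (length(missing) > 0) {
    abort(paste0("Expression table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(dat$gene_id)) {
    abort("Duplicate gene_id in expression table.")
  }
  if (!"log2fc" %in% names(dat)) {
    dat$log2fc <- ifelse(dat$fpkm_group1 > 0 & dat$fpkm_group2 > 0,
                         log2(dat$fpkm_group2 / dat$fpkm_group1), NA_real_)
  }
  if (!"qvalue" %in% names(dat)) dat$qvalue <- NA_real_
  as_tibble(dat) |>
    select("gene_id", "fpkm_group1", "fpkm_group2", "log2fc", "qvalue",
           dplyr::any_of("true_avg_diff_methyl"))
}

#' Read an ATAC peak table
#'
#' BED6+2 dialect: chrom, start, end, name, score, strand, log2fc, qvalue
#' (headerless). Intervals are 0-based half-open as in BED; overlapping
#' peaks are preserved as-is.
#'
#' @param path File path.
#' @return Peak tibble: `chrom`, `start`, `end`, `name`, `log2fc`, `qvalue`.
#' @export
read_atac_peaks <- function(path) {
  dat <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "log2fc", "qvalue"),
    col_types = "ciicccdd", progress = FALSE
  )
  if (any(dat$start >= dat$end)) {
    abort("ATAC peak with start >= end.")
  }
  select(dat, "chrom", "start", "end", "name", "log2fc", "qvalue")
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a `>motif_id tf_name` header followed by
#' four rows of counts for A, C, G, T (optionally wrapped in
#' `A [ ... ]`-style brackets). Multiple motifs per file are supported.
#'
#' @param path File path.
#' @return List of motif models; each is a list with `motif_id`, `tf_name`
#'   and `counts`, a 4 x width matrix with rownames A, C, G, T.
#' @export
read_jaspar_pfms <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort("No JASPAR headers ('>') found.")
  purrr::map(seq_along(starts), function(k) {
    i <- starts[k]
    stop_at <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    body <- lines[(i + 1):stop_at]
    if (length(body) < 4) abort("JASPAR record with fewer than 4 count rows.")
    header <- sub("^>\\s*", "", lines[i])
    parts <- strsplit(header, "\\s+")[[1]]
    rows <- lapply(body[1:4], parse_jaspar_row)
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("PFM %s has count rows of unequal length.", parts[1]))
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) abort("Negative count in PFM.")
    zero_cols <- which(colSums(counts) == 0)
    if (length(zero_cols) > 0) {
      abort(sprintf("PFM %s has an all-zero column at position %d.",
                    parts[1], zero_cols[1]))
    }
    list(
      motif_id = parts[1],
      tf_name = if (length(parts) > 1) parts[2] else parts[1],
      counts = counts
    )
  })
}

parse_jaspar_row <- function(line) {
  line <- gsub("^[ACGTacgt]\\s*\\[|\\]\\s*$", "", trimws(line))
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(vals)) abort("Unparseable PFM count row.")
  vals
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
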