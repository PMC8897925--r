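#' Generate a toy genome with gene models, CpG islands and repeats
#'
#' Emits a random genome whose CpG dinucleotide density is controlled by
#' `cpg_rate` (bases are drawn i.i.d. with `P(C) = P(G) = sqrt(cpg_rate)`, so
#' the expected CpG density per bp is exactly `cpg_rate`), places
#' non-overlapping gene models on both strands with exon/intron structure and
#' UTRs, and overlays CpG islands (locally CpG-enriched sequence) and repeat
#' intervals. All coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_annotation` with elements `genome` (named
#'   character vector of chromosome sequences), `chrom_sizes` (tibble
#'   `chrom`, `size`), `genes` (tibble of gene models with an `exons`
#'   list-column), `cgi`, `shores` and `repeats` (interval tibbles), and the
#'   `config` used.
#' @export
#' @examples
#' ann <- make_annotation(sim_config(genome_length = 1e5, n_genes = 8,
#'                                   n_planted_dmrs = 4))
#' ann$chrom_sizes
make_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chrom_sizes <- split_genome(config$genome_length, config$n_chroms)
    letters_by_chrom <- lapply(chrom_sizes$size, random_bases,
                               cpg_rate = config$cpg_rate)
    names(letters_by_chrom) <- chrom_sizes$chrom

    genes <- place_genes(config, chrom_sizes)

    cgi <- random_intervals(
      chrom_sizes,
      n = max(1L, config$n_genes %/% 4L),
      span_range = c(300L, 800L)
    )
    # CpG islands carry genuinely CpG-enriched sequence
    cgi_rate <- min(4 * config$cpg_rate, 0.25)
    if (nrow(cgi) > 0) {
      for (i in seq_len(nrow(cgi))) {
        span <- cgi$end[i] - cgi$start[i]
        letters_by_chrom[[cgi$chrom[i]]][(cgi$start[i] + 1L):cgi$end[i]] <-
          random_bases(span, cpg_rate = cgi_rate)
      }
    }
    genome <- vapply(letters_by_chrom, paste, character(1), collapse = "")
    shores <- cgi_shores(cgi, chrom_sizes, flank = 2000L)

    repeats <- random_intervals(
      chrom_sizes,
      n = max(1L, config$n_genes %/% 4L),
      span_range = c(100L, 500L)
    )

    structure(
      list(
        genome = genome,
        chrom_sizes = chrom_sizes,
        genes = genes,
        cgi = cgi,
        shores = shores,
        repeats = repeats,
        config = config
      ),
      class = "sim_annotation"
    )
  })
}

split_genome <- function(total, n_chroms) {
  base <- total %/% n_chroms
  sizes <- rep(base, n_chroms)
  sizes[n_chroms] <- sizes[n_chroms] + total - sum(sizes)
  tibble(chrom = paste0("chr", seq_len(n_chroms)), size = as.integer(sizes))
}

# i.i.d. base draws with P(C) = P(G) = sqrt(rate): the chance that any fixed
# dinucleotide is "CG" is then exactly `rate`.
random_bases <- function(len, cpg_rate) {
  g <- sqrt(cpg_rate)
  if (2 * g > 1) abort("`cpg_rate` too high for the i.i.d. base model.")
  at <- (1 - 2 * g) / 2
  sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = c(at, g, g, at))
}

# Non-overlapping gene placement with promoter headroom on both sides.
place_genes <- function(config, chrom_sizes) {
  n <- config$n_genes
  empty <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), exons = list(),
    utr5_start = integer(), utr5_end = integer(),
    utr3_start = integer(), utr3_end = integer()
  )
  if (n == 0) return(empty)
  margin <- 2000L  # promoter headroom regardless of orientation
  rows <- vector("list", n)
  placed <- 0L
  for (ci in seq_len(nrow(chrom_sizes))) {
    pos <- margin + sample(200:800, 1)
    size <- chrom_sizes$size[ci]
    while (placed < n) {
      len <- as.integer(sample(1500:4000, 1))
      if (pos + len + margin > size) break
      placed <- placed + 1L
      strand <- sample(c("+", "-"), 1)
      exons <- make_exons(pos, pos + len)
      utr <- derive_utrs(exons, strand)
      rows[[placed]] <- tibble(
        gene_id = sprintf("gene%04d", placed),
        chrom = chrom_sizes$chrom[ci],
        strand = strand,
        start = as.integer(pos),
        end = as.integer(pos + len),
        exons = list(exons),
        utr5_start = utr$utr5_start, utr5_end = utr$utr5_end,
        utr3_start = utr$utr3_start, utr3_end = utr$utr3_end
      )
      pos <- pos + len + margin + sample(200:800, 1)
    }
    if (placed >= n) break
  }
  if (placed < n) {
    abort(sprintf(
      "Genome too short to place %d genes (placed %d); increase `genome_length`.",
      n, placed
    ))
  }
  bind_rows(rows)
}

# Alternating exon/intron segmentation of [start, end); >= 1 exon.
make_exons <- function(start, end) {
  len <- end - start
  n_ex <- sample(1:4, 1)
  n_seg <- 2L * n_ex - 1L
  # random positive segment lengths summing to len, each >= 30 bp
  w <- as.vector(stats::rmultinom(1, len - 30L * n_seg, rep(1, n_seg))) + 30L
  bounds <- start + c(0L, cumsum(w))
  idx <- seq(1L, n_seg, by = 2L)
  tibble(start = as.integer(bounds[idx]), end = as.integer(bounds[idx + 1L]))
}

# UTRs as the outermost stretch of the terminal exons, strand-aware: the
# 5' UTR sits at the TSS end, the 3' UTR at the opposite end.
derive_utrs <- function(exons, strand, max_len = 100L) {
  exons <- arrange(exons, .data$start)
  first_ex <- exons[1, ]
  last_ex <- exons[nrow(exons), ]
  left_len <- min(max_len, first_ex$end - first_ex$start)
  right_len <- min(max_len, last_ex$end - last_ex$start)
  left <- c(first_ex$start, first_ex$start + left_len)
  right <- c(last_ex$end - right_len, last_ex$end)
  if (strand == "+") {
    list(utr5_start = left[1], utr5_end = left[2],
         utr3_start = right[1], utr3_end = right[2])
  } else {
    list(utr5_start = right[1], utr5_end = right[2],
         utr3_start = left[1], utr3_end = left[2])
  }
}

random_intervals <- function(chrom_sizes, n, span_range) {
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  chrom <- sample(chrom_sizes$chrom, n, replace = TRUE,
                  prob = chrom_sizes$size)
  size <- chrom_sizes$size[match(chrom, chrom_sizes$chrom)]
  span <- sample_from(seq(span_range[1], span_range[2]), n)
  span <- pmin(span, size)
  start <- vapply(size - span, function(m) sample.int(m + 1L, 1) - 1L, integer(1))
  tibble(chrom = chrom, start = as.integer(start),
         end = as.integer(start + span)) |>
    arrange(.data$chrom, .data$start)
}

# 2 kb flanks either side of each island, clipped to the chromosome.
cgi_shores <- function(cgi, chrom_sizes, flank = 2000L) {
  if (nrow(cgi) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  size <- chrom_sizes$size[match(cgi$chrom, chrom_sizes$chrom)]
  bind_rows(
    tibble(chrom = cgi$chrom, start = pmax(0L, cgi$start - flank), end = cgi$start),
    tibble(chrom = cgi$chrom, start = cgi$end, end = pmin(size, cgi$end + flank))
  ) |>
    filter(.data$end > .data$start) |>
    arrange(.data$chrom, .data$start)
}

#' Locate CpG dinucleotides in a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble with `chrom` and 0-based `pos` of the C of each CpG on the
#'   forward strand, sorted by (chrom, pos).
#' @export
cpg_sites <- function(genome) {
  out <- imap(genome, function(seq, chrom) {
    m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    if (m[1] == -1) return(tibble(chrom = character(), pos = integer()))
    tibble(chrom = chrom, pos = as.integer(m) - 1L)
  })
  bind_rows(out) |> arrange(.data$chrom, .data$pos)
}
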