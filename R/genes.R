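#' Strand-aware promoter intervals for gene models
#'
#' The promoter is the `upstream` bp immediately 5' of the transcription
#' start site: `[start - upstream, start)` on the plus strand and
#' `[end, end + upstream)` on the minus strand, clipped to the chromosome
#' when sizes are supplied.
#'
#' @param genes Gene-model tibble with `chrom`, `strand`, `start`, `end`.
#' @param upstream Promoter extent in bp (default 2000).
#' @param chrom_sizes Optional tibble `chrom`, `size` used for clipping.
#' @return Tibble `chrom`, `start`, `end`, `gene_id` aligned with `genes`.
#' @export
promoter_interval <- function(genes, upstream = 2000L, chrom_sizes = NULL) {
  start <- if_else(genes$strand == "+",
                   genes$start - as.integer(upstream), genes$end)
  end <- if_else(genes$strand == "+",
                 genes$start, genes$end + as.integer(upstream))
  start <- pmax(0L, as.integer(start))
  if (!is.null(chrom_sizes)) {
    size <- chrom_sizes$size[match(genes$chrom, chrom_sizes$chrom)]
    end <- pmin(as.integer(size), as.integer(end))
  }
  tibble(chrom = genes$chrom, start = start, end = as.integer(end),
         gene_id = genes$gene_id)
}

#' Introns of a gene model
#'
#' Gaps between consecutive exons; a single-exon gene has none.
#'
#' @param exons Tibble with `start`, `end` (0-based half-open).
#' @return Tibble with `start`, `end`, possibly empty.
#' @export
gene_introns <- function(exons) {
  exons <- arrange(exons, .data$start)
  if (nrow(exons) < 2) return(tibble(start = integer(), end = integer()))
  tibble(
    start = exons$end[-nrow(exons)],
    end = exons$start[-1]
  ) |>
    filter(.data$end > .data$start)
}
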