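#' Classify ATAC peaks by differential accessibility
#'
#' `opening` when `log2fc > 0` and `q < 0.05`, `closing` when `log2fc < 0`
#' and `q < 0.05`, else `stable` (a boundary q of exactly 0.05, a zero fold
#' change, or a missing q all land in `stable`, keeping the partition
#' total).
#'
#' @param peaks Peak tibble with `log2fc` and `qvalue`.
#' @param q_cutoff Significance cutoff (default 0.05).
#' @return `peaks` with a `peak_class` column appended.
#' @export
classify_peaks <- function(peaks, q_cutoff = 0.05) {
  mutate(peaks, peak_class = dplyr::case_when(
    !is.na(.data$qvalue) & .data$qvalue < q_cutoff & .data$log2fc > 0 ~ "opening",
    !is.na(.data$qvalue) & .data$qvalue < q_cutoff & .data$log2fc < 0 ~ "closing",
    TRUE ~ "stable"
  ))
}

#' Match DMRs to their best-overlapping ATAC peak
#'
#' Records one row per DMR that overlaps at least one peak by >= 1 bp
#' (half-open intervals, so abutting features do not overlap). Among
#' candidate peaks the match is the one with the largest overlap, ties
#' broken by smaller q-value, then by leftmost peak start. DMRs without any
#' overlap are omitted from the records but counted.
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`, `diff_methyl`,
#'   `direction`).
#' @param peaks Classified peak tibble (from [classify_peaks()]).
#' @return List: `records` tibble (`dmr_idx`, `peak_idx`, `overlap_bp`,
#'   `peak_class`, `peak_log2fc`, `peak_qvalue`, `dmr_direction`,
#'   `diff_methyl`), `n_dmrs_total`, `n_dmrs_overlapping`.
#' @export
overlap_dmrs_with_peaks <- function(dmrs, peaks) {
  ov <- interval_overlaps(dmrs, peaks)
  records <- ov |>
    mutate(
      qvalue = peaks$qvalue[.data$idx_y],
      peak_start = peaks$start[.data$idx_y]
    ) |>
    arrange(.data$idx_x, dplyr::desc(.data$overlap_bp), .data$qvalue,
            .data$peak_start) |>
    distinct(.data$idx_x, .keep_all = TRUE) |>
    transmute(
      dmr_idx = .data$idx_x,
      peak_idx = .data$idx_y,
      overlap_bp = .data$overlap_bp,
      peak_class = peaks$peak_class[.data$idx_y],
      peak_log2fc = peaks$log2fc[.data$idx_y],
      peak_qvalue = peaks$qvalue[.data$idx_y],
      dmr_direction = dmrs$direction[.data$dmr_idx],
      diff_methyl = dmrs$diff_methyl[.data$dmr_idx]
    )
  list(
    records = records,
    n_dmrs_total = nrow(dmrs),
    n_dmrs_overlapping = nrow(records)
  )
}

#' Methylation-accessibility contingency and correlation
#'
#' From the DMR-peak overlap records: the 2 x 3 contingency of methylation
#' direction against peak class with a Pearson chi-square (no continuity
#' correction; skipped on degenerate margins), and the Pearson correlation
#' between `diff_methyl` and peak `log2fc` overall and within the
#' significant-peak stratum (`q < 0.05`).
#'
#' @param overlaps Output of [overlap_dmrs_with_peaks()].
#' @param q_cutoff Stratum cutoff (default 0.05).
#' @return Object of class `methylens_atac_stats`: `table`, `statistic`,
#'   `df`, `p_value`, `correlation_all`, `correlation_significant` (tibbles
#'   `r`, `p_value`, `n`; NULL when fewer than 3 records), and the `records`.
#' @export
methylation_accessibility_stats <- function(overlaps, q_cutoff = 0.05) {
  rec <- overlaps$records
  tab <- table(
    dmr_direction = factor(rec$dmr_direction, c("hyper", "hypo")),
    peak_class = factor(rec$peak_class, c("opening", "closing", "stable"))
  )
  chi <- chisq_or_skip(tab)
  cor_or_null <- function(df) {
    if (nrow(df) < 3) return(NULL)
    pearson_cor(df$diff_methyl, df$peak_log2fc)
  }
  structure(
    list(
      table = tab, statistic = chi$statistic, df = chi$df,
      p_value = chi$p_value,
      correlation_all = cor_or_null(rec),
      correlation_significant = cor_or_null(
        filter(rec, .data$peak_qvalue < q_cutoff)
      ),
      records = rec
    ),
    class = "methylens_atac_stats"
  )
}
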