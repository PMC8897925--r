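#' Classify differentially expressed genes
#'
#' Labels each gene `fiber_preferred` when `log2fc > log2fc_cutoff` and
#' `qvalue < q_cutoff`, `epithelial_preferred` when
#' `log2fc < -log2fc_cutoff` and `qvalue < q_cutoff`, else `not_de`.
#' Inequalities are strict, so boundary values (and NA q-values) fall in
#' `not_de`.
#'
#' @param expression Expression tibble with `log2fc` and `qvalue`.
#' @param log2fc_cutoff Absolute log2 fold-change cutoff (default 0.4).
#' @param q_cutoff q-value cutoff (default 0.05).
#' @return `expression` with a `deg_class` column appended.
#' @export
classify_degs <- function(expression, log2fc_cutoff = 0.4, q_cutoff = 0.05) {
  mutate(expression, deg_class = dplyr::case_when(
    !is.na(.data$qvalue) & .data$qvalue < q_cutoff &
      .data$log2fc > log2fc_cutoff ~ "fiber_preferred",
    !is.na(.data$qvalue) & .data$qvalue < q_cutoff &
      .data$log2fc < -log2fc_cutoff ~ "epithelial_preferred",
    TRUE ~ "not_de"
  ))
}

#' Average methylation change per gene
#'
#' For each gene with at least one in-scope DMR, the unweighted mean of the
#' linked DMRs' `diff_methyl` (fiber - epithelial). `promoter_only` scope
#' keeps only links whose location is the promoter. `n_cg`- or
#' length-weighted means are available but the unweighted mean is the
#' default.
#'
#' @param dmrs DMR tibble (rows indexed by `links$dmr_idx`).
#' @param links DMR-gene link tibble from [map_dmr_to_genes()].
#' @param scope `"promoter_and_genebody"` or `"promoter_only"`.
#' @param weights `"none"` (default), `"n_cg"` or `"length"`.
#' @return Tibble: `gene_id`, `scope`, `n_dmrs`, `avg_diff_methyl`,
#'   `meth_direction` (`increase`/`decrease`/`zero`).
#' @export
average_gene_methylation <- function(dmrs, links,
                                     scope = c("promoter_and_genebody",
                                               "promoter_only"),
                                     weights = c("none", "n_cg", "length")) {
  scope <- match.arg(scope)
  weights <- match.arg(weights)
  if (scope == "promoter_only") {
    links <- filter(links, .data$location == "promoter")
  }
  if (nrow(links) == 0) {
    return(tibble(gene_id = character(), scope = character(),
                  n_dmrs = integer(), avg_diff_methyl = double(),
                  meth_direction = character()))
  }
  w <- switch(weights,
    none = rep(1, nrow(links)),
    n_cg = dmrs$n_cg[links$dmr_idx],
    length = (dmrs$end - dmrs$start)[links$dmr_idx]
  )
  tibble(
    gene_id = links$gene_id,
    diff_methyl = dmrs$diff_methyl[links$dmr_idx],
    w = w
  ) |>
    group_by(.data$gene_id) |>
    summarise(
      n_dmrs = dplyr::n(),
      avg_diff_methyl = sum(.data$diff_methyl * .data$w) / sum(.data$w),
      .groups = "drop"
    ) |>
    mutate(
      scope = scope,
      meth_direction = dplyr::case_when(
        .data$avg_diff_methyl > 0 ~ "increase",
        .data$avg_diff_methyl < 0 ~ "decrease",
        TRUE ~ "zero"
      )
    ) |>
    select("gene_id", "scope", "n_dmrs", "avg_diff_methyl", "meth_direction")
}

#' Correlate per-gene methylation change with expression change
#'
#' Pearson correlation between `avg_diff_methyl` and `log2fc` over the genes
#' present in both tables, with the t-distribution p-value on n - 2 degrees
#' of freedom. Pass a DEG-filtered expression table to reproduce the
#' published design (only differentially expressed genes with at least one
#' in-scope DMR), or the full table to measure the raw coupling.
#'
#' @param summaries Output of [average_gene_methylation()].
#' @param expression Expression tibble (optionally filtered to DEGs).
#' @return Object of class `methylens_cor`: `r`, `p_value`, `n`, `scope`,
#'   and the joined `data` tibble.
#' @export
correlate_methylation_expression <- function(summaries, expression) {
  joined <- inner_join(summaries, expression, by = "gene_id")
  res <- pearson_cor(joined$avg_diff_methyl, joined$log2fc)
  structure(
    list(r = res$r, p_value = res$p_value, n = res$n,
         scope = if (nrow(summaries)) summaries$scope[1] else NA_character_,
         data = joined),
    class = "methylens_cor"
  )
}

#' Quadrant association between methylation and expression direction
#'
#' Cross-tabulates per-gene methylation direction (increase/decrease in
#' fiber) against DEG class (epithelial/fiber preferred) for differentially
#' expressed genes with at least one in-scope DMR, and applies a Pearson
#' chi-square without continuity correction. Genes whose average methylation
#' change is exactly zero are excluded from the table and counted
#' separately. With a zero margin the test is skipped but the table is still
#' returned.
#'
#' @param summaries Output of [average_gene_methylation()].
#' @param degs Expression tibble already passed through [classify_degs()];
#'   only rows with `deg_class != "not_de"` enter the table.
#' @return Object of class `methylens_assoc` with elements `table` (2 x 2),
#'   `statistic`, `df`, `p_value` (NA when skipped), `row_percent`,
#'   `n_zero`, `n`.
#' @export
methylation_expression_association <- function(summaries, degs) {
  joined <- inner_join(summaries, degs, by = "gene_id") |>
    filter(.data$deg_class != "not_de")
  n_zero <- sum(joined$meth_direction == "zero")
  joined <- filter(joined, .data$meth_direction != "zero")
  tab <- table(
    meth_direction = factor(joined$meth_direction, c("increase", "decrease")),
    deg_class = factor(joined$deg_class,
                       c("epithelial_preferred", "fiber_preferred"))
  )
  res <- chisq_or_skip(tab)
  row_percent <- prop.table(tab, 1) * 100
  structure(
    list(table = tab, statistic = res$statistic, df = res$df,
         p_value = res$p_value, row_percent = row_percent,
         n_zero = n_zero, n = sum(tab)),
    class = "methylens_assoc"
  )
}
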