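#' Joint classification of DMR sites by methylation, accessibility and
#' expression
#'
#' A site is a (DMR, gene) pair that (a) overlaps a differential ATAC peak
#' (`opening` or `closing`; stable peaks disqualify) and (b) lies in the
#' promoter or gene body of a differentially expressed gene. Each site falls
#' into one of four methylation-by-chromatin combinations
#' (hypo/hyper x opening/closing), crossed with the host gene's class.
#'
#' @param overlaps Output of [overlap_dmrs_with_peaks()].
#' @param links DMR-gene link tibble from [map_dmr_to_genes()].
#' @param degs Expression tibble through [classify_degs()].
#' @param scope `"promoter_and_genebody"` or `"promoter_only"`.
#' @return Site tibble: `dmr_idx`, `gene_id`, `location`, `meth_direction`,
#'   `chromatin_direction`, `deg_class`, `combo`.
#' @export
classify_triple_sites <- function(overlaps, links, degs,
                                  scope = c("promoter_and_genebody",
                                            "promoter_only")) {
  scope <- match.arg(scope)
  if (scope == "promoter_only") {
    links <- filter(links, .data$location == "promoter")
  }
  diff_peaks <- overlaps$records |>
    filter(.data$peak_class %in% c("opening", "closing"))
  deg_only <- degs |> filter(.data$deg_class != "not_de")
  links |>
    inner_join(diff_peaks, by = "dmr_idx") |>
    inner_join(select(deg_only, "gene_id", "deg_class"), by = "gene_id") |>
    transmute(
      dmr_idx = .data$dmr_idx,
      gene_id = .data$gene_id,
      location = .data$location,
      meth_direction = .data$dmr_direction,
      chromatin_direction = if_else(.data$peak_class == "opening",
                                    "increased", "decreased"),
      deg_class = .data$deg_class,
      combo = paste(.data$meth_direction,
                    if_else(.data$peak_class == "opening", "opening", "closing"),
                    if_else(.data$deg_class == "fiber_preferred",
                            "fiber", "epithelial"),
                    sep = "_")
    )
}

#' Concordance of triple-classified sites with the inverse-methylation model
#'
#' A site is concordant when it matches the canonical pattern: hypomethylated
#' with opening chromatin at a fiber-preferred gene, or hypermethylated with
#' closing chromatin at an epithelial-preferred gene. The 2 x 2 of gene
#' class against concordance is tested with a Pearson chi-square (no
#' continuity correction; skipped on an empty margin).
#'
#' @param sites Output of [classify_triple_sites()].
#' @return Object of class `methylens_assoc`: `table`, `statistic`, `df`,
#'   `p_value`, `concordant_fraction` tibble by gene class, `n`.
#' @export
triple_association <- function(sites) {
  if (nrow(sites) == 0) abort("No triple-classified sites.")
  concordant <- (sites$meth_direction == "hypo" &
                   sites$chromatin_direction == "increased" &
                   sites$deg_class == "fiber_preferred") |
    (sites$meth_direction == "hyper" &
       sites$chromatin_direction == "decreased" &
       sites$deg_class == "epithelial_preferred")
  tab <- table(
    deg_class = factor(sites$deg_class,
                       c("epithelial_preferred", "fiber_preferred")),
    concordance = factor(if_else(concordant, "concordant", "discordant"),
                         c("concordant", "discordant"))
  )
  res <- chisq_or_skip(tab)
  frac <- tibble(
    deg_class = rownames(tab),
    n_sites = as.integer(rowSums(tab)),
    concordant_fraction = as.numeric(tab[, "concordant"] / rowSums(tab))
  )
  structure(
    list(table = tab, statistic = res$statistic, df = res$df,
         p_value = res$p_value, concordant_fraction = frac, n = sum(tab)),
    class = "methylens_assoc"
  )
}

#' Per-gene rollup of triple-classified sites
#'
#' One row per gene with at least one qualifying site: site counts per
#' combination and a flag for whether any site is concordant
#' (hypo+opening at a fiber gene or hyper+closing at an epithelial gene).
#'
#' @param sites Output of [classify_triple_sites()].
#' @return Tibble: `gene_id`, `deg_class`, `n_sites`, one `n_<combo>` count
#'   column per observed combination, `has_concordant_site`.
#' @export
per_gene_rollup <- function(sites) {
  if (nrow(sites) == 0) {
    return(tibble(gene_id = character(), deg_class = character(),
                  n_sites = integer(), has_concordant_site = logical()))
  }
  concordant <- (sites$meth_direction == "hypo" &
                   sites$chromatin_direction == "increased" &
                   sites$deg_class == "fiber_preferred") |
    (sites$meth_direction == "hyper" &
       sites$chromatin_direction == "decreased" &
       sites$deg_class == "epithelial_preferred")
  counts <- sites |>
    count(.data$gene_id, .data$combo) |>
    tidyr::pivot_wider(names_from = "combo", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  sites |>
    mutate(concordant = concordant) |>
    group_by(.data$gene_id, .data$deg_class) |>
    summarise(n_sites = dplyr::n(),
              has_concordant_site = any(.data$concordant),
              .groups = "drop") |>
    left_join(counts, by = "gene_id") |>
    arrange(.data$gene_id)
}
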