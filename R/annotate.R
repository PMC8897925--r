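#' Parameters for genomic-feature annotation
#'
#' @param promoter_upstream Promoter extent upstream of the TSS in bp.
#' @param proximal_promoter Extent of the proximal promoter sub-zone in bp
#'   (the remainder up to `promoter_upstream` is distal).
#' @param cgi_shore Width of CpG-island shores in bp.
#' @param category_priority Ordered character vector of feature categories;
#'   an interval is labelled with the highest-priority category it overlaps
#'   by at least 1 bp, or `intergenic`.
#' @return List of class `annotation_params`.
#' @export
annotation_params <- function(promoter_upstream = 2000,
                              proximal_promoter = 1000,
                              cgi_shore = 2000,
                              category_priority = c(
                                "promoter", "utr5", "first_exon",
                                "first_intron", "other_exon", "other_intron",
                                "utr3", "cgi", "cgi_shore", "repeat"
                              )) {
  check_pos(promoter_upstream, "promoter_upstream")
  check_pos(proximal_promoter, "proximal_promoter")
  check_pos(cgi_shore, "cgi_shore")
  if (anyDuplicated(category_priority)) {
    abort("`category_priority` must list each category exactly once.")
  }
  structure(
    list(
      promoter_upstream = as.integer(promoter_upstream),
      proximal_promoter = as.integer(proximal_promoter),
      cgi_shore = as.integer(cgi_shore),
      category_priority = category_priority
    ),
    class = "annotation_params"
  )
}

#' Classify cytosine sequence context
#'
#' Examines the two bases 3' of a cytosine on its own strand: `CG` when the
#' next base is G, else `CHG` when the base after that is G, else `CHH`
#' (H = A, C or T). On the minus strand the reverse complement is read, so a
#' G on the forward sequence is the cytosine and its 3' neighbours lie at
#' decreasing positions. Positions that are not a cytosine on the requested
#' strand return `not_C`; a cytosine too close to the sequence edge for a
#' full 3' context returns `CHH_trunc`.
#'
#' @param sequence A single character string.
#' @param pos 0-based position vector.
#' @param strand `"+"` or `"-"`, recycled.
#' @return Character vector in
#'   `c("CG", "CHG", "CHH", "CHH_trunc", "not_C")`.
#' @export
#' @examples
#' classify_context("ACGT", 1, "+")  # "CG"
#' classify_context("CAG", 0, "+")   # "CHG"
classify_context <- function(sequence, pos, strand = "+") {
  n <- nchar(sequence)
  strand <- rep_len(strand, length(pos))
  base_at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- p >= 0 & p < n
    if (any(ok)) out[ok] <- substring(sequence, p[ok] + 1, p[ok] + 1)
    out
  }
  b0 <- base_at(pos)
  plus <- strand == "+"
  is_c <- !is.na(b0) & ((plus & b0 == "C") | (!plus & b0 == "G"))
  b1 <- ifelse(plus, base_at(pos + 1L), base_at(pos - 1L))
  b2 <- ifelse(plus, base_at(pos + 2L), base_at(pos - 2L))
  # on the minus strand the 3' neighbour is the complement of the forward base
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b1 <- ifelse(plus, b1, unname(comp[b1]))
  b2 <- ifelse(plus, b2, unname(comp[b2]))
  out <- rep("not_C", length(pos))
  out[is_c & !is.na(b1) & b1 == "G"] <- "CG"
  chg <- is_c & !is.na(b1) & b1 != "G" & !is.na(b2) & b2 == "G"
  out[chg] <- "CHG"
  chh <- is_c & !is.na(b1) & b1 != "G" & !is.na(b2) & b2 != "G"
  out[chh] <- "CHH"
  out[is_c & (is.na(b1) | (b1 != "G" & is.na(b2)))] <- "CHH_trunc"
  out
}

#' Build the genomic feature index
#'
#' Expands gene models, CpG islands, shores and repeats into one long
#' interval table with a `category` column matching
#' `annotation_params()$category_priority`. First exon/intron are
#' strand-aware (closest to the TSS). Promoter intervals carry a
#' `promoter_zone` of `proximal`/`distal` sub-intervals as separate rows
#' with category `promoter`.
#'
#' @param genes Gene-model tibble.
#' @param cgi,shores,repeats Interval tibbles (`chrom`, `start`, `end`);
#'   may be empty or NULL.
#' @param params An [annotation_params()].
#' @param chrom_sizes Optional `chrom`/`size` tibble for clipping promoters.
#' @return Feature tibble: `chrom`, `start`, `end`, `category`, `gene_id`
#'   (NA for non-genic features), `promoter_zone` (NA unless promoter).
#' @export
build_feature_index <- function(genes, cgi = NULL, shores = NULL,
                                repeats = NULL, params = annotation_params(),
                                chrom_sizes = NULL) {
  feats <- list()
  if (!is.null(genes) && nrow(genes) > 0) {
    prom <- promoter_interval(genes, params$promoter_upstream, chrom_sizes)
    # proximal = nearest `proximal_promoter` bp to the TSS, distal = the rest
    prox_start <- if_else(genes$strand == "+",
                          pmax(prom$start, prom$end - params$proximal_promoter),
                          prom$start)
    prox_end <- if_else(genes$strand == "+", prom$end,
                        pmin(prom$end, prom$start + params$proximal_promoter))
    feats$prox <- tibble(
      chrom = prom$chrom, start = as.integer(prox_start),
      end = as.integer(prox_end), category = "promoter",
      gene_id = genes$gene_id, promoter_zone = "proximal"
    )
    feats$dist <- tibble(
      chrom = prom$chrom,
      start = if_else(genes$strand == "+", prom$start, prox_end),
      end = if_else(genes$strand == "+", prox_start, prom$end),
      category = "promoter", gene_id = genes$gene_id,
      promoter_zone = "distal"
    ) |> filter(.data$end > .data$start)
    gene_feats <- purrr::pmap(
      list(genes$gene_id, genes$chrom, genes$strand, genes$exons,
           genes$utr5_start, genes$utr5_end, genes$utr3_start, genes$utr3_end),
      function(gid, chrom, strand, exons, u5s, u5e, u3s, u3e) {
        exons <- arrange(exons, .data$start)
        introns <- gene_introns(exons)
        first_ex_idx <- if (strand == "+") 1L else nrow(exons)
        first_in_idx <- if (nrow(introns) == 0) integer(0) else
          if (strand == "+") 1L else nrow(introns)
        rows <- list(
          tibble(start = exons$start, end = exons$end,
                 category = if_else(seq_len(nrow(exons)) == first_ex_idx,
                                    "first_exon", "other_exon"))
        )
        if (nrow(introns) > 0) {
          rows <- c(rows, list(
            tibble(start = introns$start, end = introns$end,
                   category = if_else(seq_len(nrow(introns)) == first_in_idx,
                                      "first_intron", "other_intron"))
          ))
        }
        if (!is.na(u5s)) {
          rows <- c(rows, list(tibble(start = u5s, end = u5e, category = "utr5")))
        }
        if (!is.na(u3s)) {
          rows <- c(rows, list(tibble(start = u3s, end = u3e, category = "utr3")))
        }
        bind_rows(rows) |>
          mutate(chrom = chrom, gene_id = gid, promoter_zone = NA_character_)
      }
    ) |> list_rbind()
    feats$genic <- gene_feats
  }
  add_plain <- function(df, category) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    tibble(chrom = df$chrom, start = df$start, end = df$end,
           category = category, gene_id = NA_character_,
           promoter_zone = NA_character_)
  }
  feats$cgi <- add_plain(cgi, "cgi")
  feats$shores <- add_plain(shores, "cgi_shore")
  feats$repeats <- add_plain(repeats, "repeat")
  bind_rows(feats) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$chrom, .data$start)
}

#' Assign intervals to their highest-priority feature category
#'
#' Each query interval is labelled with the highest-priority category (per
#' `params$category_priority`) among features it overlaps by at least 1 bp;
#' `intergenic` when it overlaps none. Promoter hits also report whether a
#' proximal or distal promoter zone was touched (proximal wins ties).
#'
#' @param intervals Tibble `chrom`, `start`, `end`.
#' @param feature_index Output of [build_feature_index()].
#' @param params An [annotation_params()].
#' @return `intervals` with `category` and `promoter_zone` columns appended.
#' @export
annotate_intervals <- function(intervals, feature_index,
                               params = annotation_params()) {
  levels <- c(params$category_priority, "intergenic")
  if (nrow(intervals) == 0) {
    return(mutate(intervals, category = character(0), promoter_zone = character(0)))
  }
  ov <- interval_overlaps(intervals, feature_index)
  category <- rep("intergenic", nrow(intervals))
  zone <- rep(NA_character_, nrow(intervals))
  if (nrow(ov) > 0) {
    best <- tibble(idx = ov$idx_x,
                   rank = match(feature_index$category[ov$idx_y], levels),
                   zone = feature_index$promoter_zone[ov$idx_y]) |>
      group_by(.data$idx) |>
      summarise(
        rank = min(.data$rank),
        promoter_zone = dplyr::if_else(
          levels[min(.data$rank)] == "promoter",
          dplyr::if_else(any(.data$zone == "proximal", na.rm = TRUE),
                         "proximal", "distal"),
          NA_character_
        ),
        .groups = "drop"
      )
    category[best$idx] <- levels[best$rank]
    zone[best$idx] <- best$promoter_zone
  }
  mutate(intervals, category = factor(category, levels = levels),
         promoter_zone = zone)
}

#' Link DMRs to genes via promoter or gene-body overlap
#'
#' Every (DMR, gene) pair overlapping by at least 1 bp of the gene's
#' strand-aware promoter or its body is recorded; when a DMR touches both
#' features of the same gene, the promoter location wins. A DMR may link to
#' several genes.
#'
#' @param dmrs DMR tibble (needs `chrom`, `start`, `end`; extra columns are
#'   carried through by `dmr_idx`).
#' @param genes Gene-model tibble.
#' @param params An [annotation_params()].
#' @param chrom_sizes Optional clipping sizes for promoters.
#' @return Link tibble: `dmr_idx` (row in `dmrs`), `gene_id`, `location`
#'   (`promoter`/`genebody`).
#' @export
map_dmr_to_genes <- function(dmrs, genes, params = annotation_params(),
                             chrom_sizes = NULL) {
  empty <- tibble(dmr_idx = integer(), gene_id = character(),
                  location = character())
  if (nrow(dmrs) == 0 || nrow(genes) == 0) return(empty)
  prom <- promoter_interval(genes, params$promoter_upstream, chrom_sizes)
  prom_hits <- interval_overlaps(dmrs, prom) |>
    transmute(dmr_idx = .data$idx_x, gene_id = prom$gene_id[.data$idx_y],
              location = "promoter")
  body_hits <- interval_overlaps(dmrs, genes) |>
    transmute(dmr_idx = .data$idx_x, gene_id = genes$gene_id[.data$idx_y],
              location = "genebody")
  bind_rows(prom_hits, body_hits) |>
    mutate(location = factor(.data$location, c("promoter", "genebody"))) |>
    arrange(.data$dmr_idx, .data$gene_id, .data$location) |>
    distinct(.data$dmr_idx, .data$gene_id, .keep_all = TRUE) |>
    mutate(location = as.character(.data$location))
}

#' Random-placement null for the DMR category distribution
#'
#' Draws `n_draws` random interval sets of the same size as the observed DMR
#' set, with lengths resampled (with replacement) from the observed length
#' multiset and placed uniformly over the genome. Each draw is annotated as
#' the observed set was; expected counts are the per-category means scaled
#' to the observed set size. A Pearson chi-square (no continuity correction)
#' compares observed to expected counts, pooling categories with expected
#' counts below 1, and per-category percentage-point differences are
#' reported.
#'
#' @param observed_categories Factor/character vector: the category of each
#'   observed DMR (from [annotate_intervals()]).
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param lengths Observed DMR lengths (bp) to resample from.
#' @param feature_index Output of [build_feature_index()].
#' @param params An [annotation_params()].
#' @param n_draws Number of random sets.
#' @param seed RNG seed.
#' @return List of class `methylens_null`: `comparison` tibble (category,
#'   observed, expected, pct_observed, pct_expected, pct_difference),
#'   `statistic`, `df`, `p_value`, `n_draws`.
#' @export
random_null_test <- function(observed_categories, chrom_sizes, lengths,
                             feature_index, params = annotation_params(),
                             n_draws = 50, seed = 1L) {
  stopifnot(length(observed_categories) == length(lengths), length(lengths) > 0)
  levels <- c(params$category_priority, "intergenic")
  n <- length(lengths)
  draws <- with_seed(seed, {
    random_placement(lengths, n_draws, chrom_sizes)
  })
  ann <- annotate_intervals(draws, feature_index, params)
  expected_counts <- table(factor(ann$category, levels)) / n_draws
  observed_counts <- table(factor(observed_categories, levels))
  comparison <- tibble(
    category = levels,
    observed = as.integer(observed_counts),
    expected = as.numeric(expected_counts),
    pct_observed = 100 * as.numeric(observed_counts) / n,
    pct_expected = 100 * as.numeric(expected_counts) / n
  ) |>
    mutate(pct_difference = .data$pct_observed - .data$pct_expected)
  # chi-square on categories with expected >= 1; smaller cells pooled
  keep <- comparison$expected >= 1
  obs <- c(comparison$observed[keep], sum(comparison$observed[!keep]))
  exp <- c(comparison$expected[keep], sum(comparison$expected[!keep]))
  if (sum(!keep) == 0) {
    obs <- comparison$observed
    exp <- comparison$expected
  }
  nonzero <- exp > 0
  stat <- sum((obs[nonzero] - exp[nonzero])^2 / exp[nonzero])
  df <- sum(nonzero) - 1L
  structure(
    list(
      comparison = comparison,
      statistic = stat,
      df = df,
      p_value = pchisq(stat, df, lower.tail = FALSE),
      n_draws = n_draws
    ),
    class = "methylens_null"
  )
}

# Uniform placement of len-resampled intervals over the genome; a draw whose
# chromosome is shorter than the resampled length is retried (capped).
random_placement <- function(lengths, n_draws, chrom_sizes) {
  total <- n_draws * length(lengths)
  len <- sample_from(lengths, total)
  chrom <- sample_from(chrom_sizes$chrom, total, prob = chrom_sizes$size)
  size <- chrom_sizes$size[match(chrom, chrom_sizes$chrom)]
  for (try in 1:100) {
    bad <- which(len > size)
    if (length(bad) == 0) break
    chrom[bad] <- sample(chrom_sizes$chrom, length(bad), replace = TRUE,
                         prob = chrom_sizes$size)
    size[bad] <- chrom_sizes$size[match(chrom[bad], chrom_sizes$chrom)]
  }
  if (any(len > size)) abort("A chromosome is shorter than the longest DMR.")
  start <- floor(runif(total, 0, size - len + 1))
  tibble(chrom = chrom, start = as.integer(start),
         end = as.integer(start + len))
}

#' Compare the genomic distributions of hyper- and hypomethylated regions
#'
#' Builds the category-by-direction contingency table, applies a Pearson
#' chi-square without continuity correction, and reports the per-category
#' percentage-point difference between the two directions' distributions.
#'
#' @param annotated_dmrs Tibble with `category` and `direction`
#'   (`hyper`/`hypo`) columns.
#' @return List of class `methylens_assoc`: `table`, `statistic`, `df`,
#'   `p_value`, `pct_difference` tibble.
#' @export
compare_hyper_hypo_distributions <- function(annotated_dmrs) {
  dirs <- unique(as.character(annotated_dmrs$direction))
  for (d in c("hyper", "hypo")) {
    if (!d %in% dirs) abort(sprintf("No DMRs with direction '%s'.", d))
  }
  tab <- table(
    category = droplevels(factor(annotated_dmrs$category)),
    direction = factor(annotated_dmrs$direction, c("hyper", "hypo"))
  )
  chi <- pearson_chisq(tab)
  pct <- tibble(
    category = rownames(tab),
    pct_hyper = 100 * tab[, "hyper"] / sum(tab[, "hyper"]),
    pct_hypo = 100 * tab[, "hypo"] / sum(tab[, "hypo"])
  ) |>
    mutate(pct_difference = .data$pct_hyper - .data$pct_hypo)
  structure(
    list(table = tab, statistic = chi$statistic, df = chi$df,
         p_value = chi$p_value, pct_difference = pct),
    class = "methylens_assoc"
  )
}
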