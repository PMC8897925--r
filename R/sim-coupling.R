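#' Simulate a differential-expression table coupled to planted methylation
#'
#' Each gene's true average methylation change is the mean signed effect of
#' the planted regions in its promoter or gene body (0 if none). The gene's
#' expression log2 fold change (group2/group1) is
#' `expr_coupling_slope * avg_diff_methyl + N(0, expr_noise_sd)`. Group-1
#' FPKMs are drawn log-normal and group-2 FPKMs back-computed so the table is
#' internally consistent with the fold change. q-values are assigned
#' truth-linked (differential fitting is outside this generator's scope):
#' genes with `|log2fc| > 0.4` receive `q < 0.05` with probability 0.95,
#' others with probability 0.05.
#'
#' @param config A [sim_config()].
#' @param genes Gene-model tibble from [make_annotation()].
#' @param truth Planted-region truth tibble from [simulate_methylomes()]
#'   (or [plant_dmrs] output embedded in it).
#' @return Tibble with `gene_id`, `fpkm_group1`, `fpkm_group2`, `log2fc`,
#'   `qvalue` and the latent `true_avg_diff_methyl` column.
#' @export
simulate_expression <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 202L, {
    n <- nrow(genes)
    truth_by_gene <- truth |>
      filter(!is.na(.data$gene_id)) |>
      group_by(.data$gene_id) |>
      summarise(avg = mean(.data$effect), .groups = "drop")
    avg_dm <- truth_by_gene$avg[match(genes$gene_id, truth_by_gene$gene_id)]
    avg_dm[is.na(avg_dm)] <- 0
    log2fc <- config$expr_coupling_slope * avg_dm +
      rnorm(n, 0, config$expr_noise_sd)
    fpkm1 <- rlnorm(n, meanlog = 1.5, sdlog = 1)
    fpkm2 <- fpkm1 * 2^log2fc
    tibble(
      gene_id = genes$gene_id,
      fpkm_group1 = fpkm1,
      fpkm_group2 = fpkm2,
      log2fc = log2fc,
      qvalue = assign_truth_qvalues(abs(log2fc) > 0.4),
      true_avg_diff_methyl = avg_dm
    )
  })
}

#' Simulate an ATAC peak table coupled to planted methylation
#'
#' One accessibility peak is placed over each planted region (the peak
#' extends the region by 50-300 bp on each side) with log2 fold change
#' `atac_coupling_slope * effect + N(0, atac_noise_sd)`; additional
#' background peaks are placed at least 500 bp away from every planted region
#' with noise-only fold changes. q-values are truth-linked: peaks over
#' planted regions get `q < 0.05` with probability 0.95, background peaks
#' with probability 0.05.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [make_annotation()].
#' @param truth Planted-region truth tibble.
#' @return Peak tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `log2fc`, `qvalue`, plus `planted` flag and the latent `true_effect`.
#' @export
simulate_atac <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 303L, {
    planted <- if (nrow(truth) > 0) {
      ext1 <- sample(50:300, nrow(truth), replace = TRUE)
      ext2 <- sample(50:300, nrow(truth), replace = TRUE)
      size <- annotation$chrom_sizes$size[
        match(truth$chrom, annotation$chrom_sizes$chrom)]
      tibble(
        chrom = truth$chrom,
        start = pmax(0L, truth$start - ext1),
        end = pmin(size, truth$end + ext2),
        log2fc = config$atac_coupling_slope * truth$effect +
          rnorm(nrow(truth), 0, config$atac_noise_sd),
        qvalue = assign_truth_qvalues(rep(TRUE, nrow(truth))),
        planted = TRUE,
        true_effect = truth$effect
      )
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             log2fc = double(), qvalue = double(), planted = logical(),
             true_effect = double())
    }
    bg <- random_intervals(annotation$chrom_sizes, config$n_background_peaks,
                           span_range = c(200L, 600L))
    if (nrow(bg) > 0 && nrow(truth) > 0) {
      pad <- mutate(truth, start = pmax(0L, .data$start - 500L),
                    end = .data$end + 500L)
      hit <- unique(interval_overlaps(bg, pad)$idx_x)
      if (length(hit) > 0) bg <- bg[-hit, ]
    }
    bg <- mutate(bg,
      log2fc = rnorm(nrow(bg), 0, config$atac_noise_sd),
      qvalue = assign_truth_qvalues(rep(FALSE, nrow(bg))),
      planted = FALSE,
      true_effect = 0
    )
    bind_rows(planted, bg) |> arrange(.data$chrom, .data$start)
  })
}

# Truth-linked q-value assignment: TRUE -> q < 0.05 with probability 0.95,
# FALSE -> q < 0.05 with probability 0.05.
assign_truth_qvalues <- function(is_signal) {
  n <- length(is_signal)
  sig <- runif(n) < if_else(is_signal, 0.95, 0.05)
  if_else(sig, runif(n, 1e-6, 0.049), runif(n, 0.051, 1))
}
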