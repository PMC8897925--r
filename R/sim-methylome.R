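#' Simulate replicate methylomes with planted differentially methylated regions
#'
#' Per CpG site and biological replicate, total read counts are drawn
#' `Poisson(coverage_mean)` (floored at one read) and methylated counts are
#' beta-binomial with site mean `mu` and across-replicate overdispersion
#' `phi` (`phi = 0` is exactly binomial). Outside planted regions
#' `mu = base_methylation` for both groups; inside a planted region the
#' group-2 mean is shifted by the region's signed effect and clamped to
#' `[0.02, 0.98]`. Planted regions are attached to distinct random genes
#' (promoter or gene body) while genes last; any excess is placed in
#' intergenic space.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [make_annotation()].
#' @return List with `records`, a per-cytosine tibble (`chrom`, `pos`,
#'   `context`, `group`, `replicate`, `n_methylated`, `n_total`) sorted by
#'   (chrom, pos), and `truth`, the planted-region tibble (`chrom`, `start`,
#'   `end`, `effect`, `gene_id`, `location`) listing every planted interval
#'   with its signed methylation effect.
#' @export
simulate_methylomes <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "sim_annotation"))
  sites <- cpg_sites(annotation$genome)
  truth <- simulate_truth(config, annotation, sites)
  with_seed(config$seed + 101L, {
    mu1 <- rep(config$base_methylation, nrow(sites))
    mu2 <- mu1
    if (nrow(truth) > 0 && nrow(sites) > 0) {
      ov <- interval_overlaps(
        tibble(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L),
        truth
      )
      mu2[ov$idx_x] <- pmin(0.98, pmax(0.02, mu2[ov$idx_x] + truth$effect[ov$idx_y]))
    }
    reps <- seq_len(config$n_replicates_per_group)
    grid <- tidyr::expand_grid(group = .methylens_groups, replicate = reps)
    records <- pmap(grid, function(group, replicate) {
      mu <- if (group == "group1") mu1 else mu2
      n_total <- pmax(1L, rpois(nrow(sites), config$coverage_mean))
      n_meth <- rbetabinom_mu_phi(nrow(sites), n_total, mu, config$dispersion_phi)
      tibble(
        chrom = sites$chrom, pos = sites$pos, context = "CG",
        group = group, replicate = as.integer(replicate),
        n_methylated = as.integer(n_meth), n_total = as.integer(n_total)
      )
    }) |>
      list_rbind() |>
      arrange(.data$chrom, .data$pos, .data$group, .data$replicate)
    list(records = records, truth = truth)
  })
}

#' Generate the planted-DMR truth table without simulating reads
#'
#' Deterministically reproduces the planted regions that
#' [simulate_methylomes()] would use for the same configuration and
#' annotation, which is all the expression/accessibility simulators need.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [make_annotation()].
#' @param sites Optional precomputed [cpg_sites()] table.
#' @return Planted-region tibble (`chrom`, `start`, `end`, `effect`,
#'   `gene_id`, `location`).
#' @export
simulate_truth <- function(config, annotation, sites = NULL) {
  if (is.null(sites)) sites <- cpg_sites(annotation$genome)
  with_seed(config$seed + 100L, plant_dmrs(config, annotation, sites))
}

# Anchor a planted region on the local CpG structure: among windows of
# `span` bp starting at each CpG inside [lo, hi), prefer one holding at
# least the expected CpG count (a differentially methylated region is
# defined by the CpGs it contains, so boundaries snap to CpG positions);
# fall back to the densest window, or to `lo` when the interval has no CpG.
snap_to_cpg_window <- function(cpg_pos, lo, hi, span, rate) {
  # cpg_pos must be sorted
  a_lo <- findInterval(lo - 0.5, cpg_pos) + 1L
  a_hi <- findInterval(hi - span, cpg_pos)
  if (a_hi < a_lo) return(as.integer(min(lo, hi - span)))
  anchors <- cpg_pos[a_lo:a_hi]
  counts <- findInterval(anchors + span - 0.5, cpg_pos) -
    findInterval(anchors - 0.5, cpg_pos)
  target <- max(5, round(span * rate))
  good <- anchors[counts >= target]
  if (length(good) > 0) return(sample_from(good, 1))
  anchors[which.max(counts)]
}

# Choose planted-DMR intervals: one per distinct random gene (promoter or
# body) while genes last, the remainder in intergenic space well away from
# genes and other planted regions.
plant_dmrs <- function(config, annotation, cpg = NULL) {
  n <- config$n_planted_dmrs
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    effect = double(), gene_id = character(), location = character()
  )
  if (n == 0) return(empty)
  genes <- annotation$genes
  spans <- sample_from(seq(config$dmr_span_range[1], config$dmr_span_range[2]), n)
  signs <- if_else(runif(n) < config$hyper_fraction, 1, -1)
  n_genic <- min(n, nrow(genes))
  rows <- vector("list", n)
  cpg_by_chrom <- if (is.null(cpg)) list() else split(cpg$pos, cpg$chrom)
  if (n_genic > 0) {
    host <- genes[sample.int(nrow(genes), n_genic), ]
    host_prom <- promoter_interval(host, upstream = 2000L,
                                   chrom_sizes = annotation$chrom_sizes)
    for (i in seq_len(n_genic)) {
      in_promoter <- runif(1) < 0.5
      lo <- if (in_promoter) host_prom$start[i] else host$start[i]
      hi <- if (in_promoter) host_prom$end[i] else host$end[i]
      span <- min(spans[i], hi - lo)
      chrom_cpg <- cpg_by_chrom[[host$chrom[i]]] %||% integer(0)
      start <- snap_to_cpg_window(chrom_cpg, lo, hi, span, config$cpg_rate)
      rows[[i]] <- tibble(
        chrom = host$chrom[i], start = as.integer(start),
        end = as.integer(start + span), effect = signs[i] * config$effect_size,
        gene_id = host$gene_id[i],
        location = if (in_promoter) "promoter" else "genebody"
      )
    }
  }
  if (n > n_genic) {
    # intergenic placements, rejected if within 500 bp of a gene/promoter or
    # an already-placed region
    blocked <- bind_rows(
      tibble(chrom = genes$chrom, start = genes$start - 2500L, end = genes$end + 2500L),
      bind_rows(rows[seq_len(n_genic)]) |> select("chrom", "start", "end")
    )
    for (i in seq(n_genic + 1L, n)) {
      for (try in 1:200) {
        ci <- sample.int(nrow(annotation$chrom_sizes), 1,
                         prob = annotation$chrom_sizes$size)
        size <- annotation$chrom_sizes$size[ci]
        span <- spans[i]
        start <- sample.int(size - span, 1) - 1L
        cand <- tibble(chrom = annotation$chrom_sizes$chrom[ci],
                       start = as.integer(start), end = as.integer(start + span))
        pad <- mutate(cand, start = pmax(0L, .data$start - 500L), end = .data$end + 500L)
        if (nrow(interval_overlaps(pad, blocked)) == 0) {
          rows[[i]] <- mutate(cand, effect = signs[i] * config$effect_size,
                              gene_id = NA_character_, location = "intergenic")
          blocked <- bind_rows(blocked, cand)
          break
        }
      }
      if (is.null(rows[[i]])) {
        abort("Could not place all intergenic planted regions; enlarge the genome.")
      }
    }
  }
  bind_rows(rows) |> arrange(.data$chrom, .data$start)
}
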