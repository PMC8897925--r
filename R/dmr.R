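#' Parameters of the smoothed beta-binomial DMR caller
#'
#' Defaults are the region-calling parameterisation the package is built
#' around: 200 bp smoothing span, no site-level effect-size filter
#' (`delta = 0`), site p-value threshold 1e-5, minimum region span 50 bp,
#' minimum 3 CpGs, merging of regions less than 100 bp apart, and at least
#' half the region's CpGs individually significant.
#'
#' @param smoothing_span Window width in bp; each site is smoothed over
#'   `pos +/- smoothing_span / 2`, including the site itself.
#' @param delta Minimum absolute smoothed methylation difference for a site
#'   to count as significant (0 disables the filter).
#' @param p_threshold Site-level two-sided p-value cutoff.
#' @param minlen Minimum region span in bp (inclusive last - first + 1).
#' @param minCG Minimum number of CpGs in a region.
#' @param dis_merge Regions closer than this many bp are merged (strict `<`),
#'   absorbing any intervening CpGs.
#' @param pct_sig Minimum fraction of significant CpGs in a region,
#'   evaluated after merging.
#' @param dispersion_prior_weight Pseudo-observations pulling per-site
#'   dispersion estimates toward the genome-wide median.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(smoothing_span = 200,
                       delta = 0,
                       p_threshold = 1e-5,
                       minlen = 50,
                       minCG = 3,
                       dis_merge = 100,
                       pct_sig = 0.5,
                       dispersion_prior_weight = 10) {
  check_pos(smoothing_span, "smoothing_span", strict = FALSE)
  check_pos(delta, "delta", strict = FALSE)
  check_prob(p_threshold, "p_threshold")
  check_pos(minlen, "minlen", strict = FALSE)
  check_pos(minCG, "minCG", strict = FALSE)
  check_pos(dis_merge, "dis_merge", strict = FALSE)
  if (pct_sig <= 0 || pct_sig > 1) abort("`pct_sig` must be in (0, 1].")
  check_pos(dispersion_prior_weight, "dispersion_prior_weight", strict = FALSE)
  structure(
    list(
      smoothing_span = smoothing_span, delta = delta,
      p_threshold = p_threshold, minlen = minlen, minCG = minCG,
      dis_merge = dis_merge, pct_sig = pct_sig,
      dispersion_prior_weight = dispersion_prior_weight
    ),
    class = "dmr_params"
  )
}

# Integer site ids (1..n_sites) for records sorted by (chrom, pos), plus
# the site coordinate table. C-level, no per-group R evaluation.
site_index <- function(records) {
  n <- nrow(records)
  new_site <- c(TRUE, records$pos[-1] != records$pos[-n] |
                  records$chrom[-1] != records$chrom[-n])
  id <- cumsum(new_site)
  list(id = id,
       sites = tibble(chrom = records$chrom[new_site],
                      pos = records$pos[new_site]))
}

# rowsum() onto a dense 1..n_sites vector.
rowsum_dense <- function(x, site_id, n_sites) {
  out <- numeric(n_sites)
  tmp <- rowsum(as.numeric(x), site_id)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

# Per-site, per-group window aggregates used by both the smoother and the
# Wald variance: pooled methylated/total reads and the sum of squared
# per-replicate totals over all replicate x window-CpG observations.
site_window_sums <- function(records, span) {
  half <- span / 2
  cg <- records |>
    filter(.data$context == "CG") |>
    arrange(.data$chrom, .data$pos)
  si <- site_index(cg)
  n_sites <- nrow(si$sites)
  per_site <- si$sites
  for (g in c(1, 2)) {
    sel <- cg$group == paste0("group", g)
    per_site[[paste0("meth_group", g)]] <-
      rowsum_dense(cg$n_methylated[sel], si$id[sel], n_sites)
    per_site[[paste0("total_group", g)]] <-
      rowsum_dense(cg$n_total[sel], si$id[sel], n_sites)
    per_site[[paste0("total_sq_group", g)]] <-
      rowsum_dense(as.numeric(cg$n_total[sel])^2, si$id[sel], n_sites)
  }
  chrom_ids <- cumsum(!duplicated(per_site$chrom))
  out <- vector("list", max(chrom_ids))
  for (ci in unique(chrom_ids)) {
    df <- per_site[chrom_ids == ci, ]
    pos <- df$pos
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    wsum <- function(x) {
      cs <- cumsum(as.numeric(x))
      cs[hi] - c(0, cs)[lo]
    }
    out[[ci]] <- mutate(df,
      w_meth1 = wsum(.data$meth_group1),
      w_total1 = wsum(.data$total_group1),
      w_totalsq1 = wsum(.data$total_sq_group1),
      w_meth2 = wsum(.data$meth_group2),
      w_total2 = wsum(.data$total_group2),
      w_totalsq2 = wsum(.data$total_sq_group2)
    )
  }
  bind_rows(out)
}

#' Smooth methylation proportions over a positional window
#'
#' For each CpG site and group, the smoothed proportion is the ratio of
#' methylated to total reads pooled across replicates over every CpG within
#' `smoothing_span / 2` bp of the site (the site itself included). A span of
#' 0 reduces to the per-site pooled proportion. Sites with zero pooled reads
#' in either group's window are dropped with a message.
#'
#' @param records Per-cytosine record tibble (CG context rows are used).
#' @param params A [dmr_params()].
#' @return Tibble `chrom`, `pos`, `mu1`, `mu2` plus the window read
#'   aggregates used by [site_wald_test()].
#' @export
smooth_methylation <- function(records, params = dmr_params()) {
  sums <- site_window_sums(records, params$smoothing_span)
  empty_window <- sums$w_total1 == 0 | sums$w_total2 == 0
  if (any(empty_window)) {
    rlang::inform(sprintf(
      "Dropping %d site(s) with zero-coverage smoothing windows.",
      sum(empty_window)
    ))
    sums <- sums[!empty_window, ]
  }
  mutate(sums,
    mu1 = .data$w_meth1 / .data$w_total1,
    mu2 = .data$w_meth2 / .data$w_total2
  ) |>
    select("chrom", "pos", "mu1", "mu2",
           "w_meth1", "w_total1", "w_totalsq1",
           "w_meth2", "w_total2", "w_totalsq2")
}

#' Estimate shrunken beta-binomial dispersion per site
#'
#' A method-of-moments dispersion is computed per site from the
#' across-replicate spread of methylation proportions (each group with at
#' least two informative replicates contributes; the group estimates are
#' averaged, then clamped to `[0, 0.99]`). Per-site estimates are shrunk
#' toward the genome-wide median `phi_bar` with
#' `phi_star = (k * phi_bar + m * phi_hat) / (k + m)` where `k` is
#' `dispersion_prior_weight` and `m` the number of replicates that informed
#' the site. Sites without an estimate receive `phi_bar`.
#'
#' @param records Per-cytosine record tibble.
#' @param params A [dmr_params()].
#' @return Tibble `chrom`, `pos`, `phi_hat`, `phi_star`, `m`.
#' @export
estimate_dispersion <- function(records, params = dmr_params()) {
  cg <- records |>
    filter(.data$context == "CG") |>
    arrange(.data$chrom, .data$pos)
  si <- site_index(cg)
  n_sites <- nrow(si$sites)
  p_all <- cg$n_methylated / cg$n_total
  phi_raw <- matrix(NA_real_, n_sites, 2)
  n_rep <- matrix(0L, n_sites, 2)
  for (g in c(1, 2)) {
    sel <- cg$group == paste0("group", g)
    k <- rowsum_dense(rep(1, sum(sel)), si$id[sel], n_sites)
    sp <- rowsum_dense(p_all[sel], si$id[sel], n_sites)
    spp <- rowsum_dense(p_all[sel]^2, si$id[sel], n_sites)
    sN <- rowsum_dense(cg$n_total[sel], si$id[sel], n_sites)
    mu <- ifelse(k > 0, sp / k, NA_real_)
    s2 <- ifelse(k >= 2, (spp - sp^2 / pmax(k, 1)) / pmax(k - 1, 1), NA_real_)
    nbar <- ifelse(k > 0, sN / k, NA_real_)
    ok <- !is.na(s2) & !is.na(mu) & mu > 0 & mu < 1 & nbar > 1
    phi_raw[ok, g] <- (nbar[ok] * s2[ok] / (mu[ok] * (1 - mu[ok])) - 1) /
      (nbar[ok] - 1)
    n_rep[, g] <- as.integer(k)
  }
  informative <- !is.na(phi_raw)
  any_info <- informative[, 1] | informative[, 2]
  phi_hat <- rep(NA_real_, n_sites)
  phi_hat[any_info] <- pmin(0.99, pmax(0, rowMeans(phi_raw, na.rm = TRUE)[any_info]))
  per_site <- si$sites |>
    mutate(
      phi_hat = phi_hat,
      m = as.integer(rowSums(n_rep * informative))
    )
  if (all(is.na(per_site$phi_hat))) {
    warn("No site had >= 2 informative replicates; using dispersion 0 everywhere.")
    phi_bar <- 0
  } else {
    phi_bar <- median(per_site$phi_hat, na.rm = TRUE)
  }
  k <- params$dispersion_prior_weight
  per_site |>
    mutate(
      phi_star = if_else(
        is.na(.data$phi_hat),
        phi_bar,
        (k * phi_bar + .data$m * .data$phi_hat) / (k + .data$m)
      )
    ) |>
    arrange(.data$chrom, .data$pos)
}

#' Two-group Wald test on smoothed methylation proportions
#'
#' The variance of each group's smoothed proportion treats every
#' replicate-by-window-CpG read total `N_j` that informed the pooled
#' estimate as a beta-binomial observation:
#' `Var_g = sum_j N_j^2 mu(1-mu)(1+(N_j-1)phi*)/N_j / (sum_j N_j)^2`,
#' which collapses to
#' `mu(1-mu) * ((1-phi*) W + phi* S2) / W^2` with `W = sum N_j` and
#' `S2 = sum N_j^2`. The Wald statistic is `(mu2 - mu1) / sqrt(V1 + V2)`
#' with a two-sided normal p-value. Degenerate sites (both variances zero)
#' get `p = 1` when the group means agree and are otherwise flagged
#' `unstable` and excluded from significance.
#'
#' @param smoothed Output of [smooth_methylation()].
#' @param dispersion Output of [estimate_dispersion()].
#' @param params A [dmr_params()].
#' @return Site-statistic tibble: `chrom`, `pos`, `mu1`, `mu2`, `phi_star`,
#'   `wald_stat`, `p_value`, `is_significant`, `unstable`.
#' @export
site_wald_test <- function(smoothed, dispersion, params = dmr_params()) {
  dat <- inner_join(smoothed, select(dispersion, "chrom", "pos", "phi_star"),
                    by = c("chrom", "pos"))
  v1 <- with(dat, mu1 * (1 - mu1) *
               ((1 - phi_star) * w_total1 + phi_star * w_totalsq1) / w_total1^2)
  v2 <- with(dat, mu2 * (1 - mu2) *
               ((1 - phi_star) * w_total2 + phi_star * w_totalsq2) / w_total2^2)
  vsum <- v1 + v2
  wald <- ifelse(vsum > 0, (dat$mu2 - dat$mu1) / sqrt(vsum), 0)
  p <- ifelse(vsum > 0, 2 * pnorm(-abs(wald)), ifelse(dat$mu1 == dat$mu2, 1, NA_real_))
  unstable <- vsum == 0 & dat$mu1 != dat$mu2
  out <- dat |>
    mutate(
      wald_stat = wald,
      p_value = p,
      unstable = unstable,
      is_significant = !unstable & .data$p_value < params$p_threshold &
        abs(.data$mu2 - .data$mu1) >= params$delta
    ) |>
    select("chrom", "pos", "mu1", "mu2", "phi_star", "wald_stat",
           "p_value", "is_significant", "unstable")
  filter(out, !.data$unstable) |>
    bind_rows(filter(out, .data$unstable)) |>
    arrange(.data$chrom, .data$pos)
}

#' Segment significant sites into differentially methylated regions
#'
#' Significant CpGs are chained into candidate regions: a new region starts
#' whenever the bp gap to the previous significant CpG is at least
#' `dis_merge` (so regions closer than `dis_merge` merge, absorbing any
#' non-significant CpGs in between). Regions are kept when span
#' (`last - first + 1` over CpG positions) is at least `minlen`, the region
#' holds at least `minCG` CpGs (significant or absorbed), and at least
#' `pct_sig` of those CpGs are individually significant (evaluated after
#' merging). `diff_methyl` is the mean of `mu2 - mu1` over all region CpGs.
#'
#' @param site_stats Output of [site_wald_test()], sorted by position.
#' @param params A [dmr_params()].
#' @return DMR tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `n_cg`, `frac_sig`, `mean_mu1`, `mean_mu2`, `diff_methyl`, `direction`.
#' @export
call_dmrs <- function(site_stats, params = dmr_params()) {
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cg = integer(), frac_sig = double(), mean_mu1 = double(),
    mean_mu2 = double(), diff_methyl = double(), direction = character()
  )
  if (nrow(site_stats) == 0) return(empty)
  site_stats |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      sig_idx <- which(df$is_significant)
      if (length(sig_idx) == 0) {
        return(mutate(empty[, -1], span = integer(0), .after = "end"))
      }
      sig_pos <- df$pos[sig_idx]
      new_region <- c(TRUE, diff(sig_pos) >= params$dis_merge)
      region_id <- cumsum(new_region)
      purrr::map(split(sig_idx, region_id), function(idx) {
        lo <- min(idx); hi <- max(idx)
        cpgs <- df[lo:hi, ]  # absorbed CpGs included
        span <- cpgs$pos[nrow(cpgs)] - cpgs$pos[1] + 1L
        diff <- mean(cpgs$mu2 - cpgs$mu1)
        tibble(
          start = cpgs$pos[1],
          end = cpgs$pos[nrow(cpgs)] + 1L,
          span = span,
          n_cg = nrow(cpgs),
          frac_sig = mean(cpgs$is_significant),
          mean_mu1 = mean(cpgs$mu1),
          mean_mu2 = mean(cpgs$mu2),
          diff_methyl = diff,
          direction = if (diff >= 0) "hyper" else "hypo"
        )
      }) |> list_rbind()
    }) |>
    ungroup() |>
    filter(.data$span >= params$minlen,
           .data$n_cg >= params$minCG,
           .data$frac_sig >= params$pct_sig) |>
    select(-"span") |>
    arrange(.data$chrom, .data$start)
}

#' Run the full DMR caller
#'
#' Convenience wrapper: smoothing, dispersion shrinkage, site Wald tests and
#' region segmentation in one call.
#'
#' @param records Per-cytosine record tibble.
#' @param params A [dmr_params()].
#' @return List with `sites` (site statistics) and `dmrs` (region calls).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 6e4, n_genes = 5, n_planted_dmrs = 3,
#'                   n_background_peaks = 10)
#' ann <- make_annotation(cfg)
#' sim <- simulate_methylomes(cfg, ann)
#' res <- dmr_pipeline(sim$records)
#' nrow(res$dmrs)
dmr_pipeline <- function(records, params = dmr_params()) {
  smoothed <- smooth_methylation(records, params)
  dispersion <- estimate_dispersion(records, params)
  sites <- site_wald_test(smoothed, dispersion, params)
  list(sites = sites, dmrs = call_dmrs(sites, params))
}

#' Genome-wide methylation summaries
#'
#' Two descriptive summaries: (1) per group, the share of methylated
#' cytosines by sequence context, where a cytosine counts as methylated
#' when its pooled methylated reads reach `methylated_min_reads`; (2) when a
#' feature table is supplied, the pooled mCG/CG level (methylated CG reads
#' over total CG reads) per feature category and group.
#'
#' @param records Per-cytosine record tibble (any context mix).
#' @param features Optional feature tibble `chrom`, `start`, `end`,
#'   `category`.
#' @param methylated_min_reads Pooled methylated-read threshold for calling
#'   a cytosine methylated (default 1).
#' @return List with `context_proportions` (tibble `group`, `context`,
#'   `n_methylated_cytosines`, `proportion`) and `feature_levels` (tibble
#'   `group`, `category`, `mcg_level`; NULL when `features` is missing).
#' @export
methylome_summary <- function(records, features = NULL, methylated_min_reads = 1) {
  pooled <- records |>
    group_by(.data$chrom, .data$pos, .data$context, .data$group) |>
    summarise(meth = sum(.data$n_methylated), total = sum(.data$n_total),
              .groups = "drop")
  context_proportions <- pooled |>
    filter(.data$meth >= methylated_min_reads) |>
    count(.data$group, .data$context, name = "n_methylated_cytosines") |>
    group_by(.data$group) |>
    mutate(proportion = .data$n_methylated_cytosines /
             sum(.data$n_methylated_cytosines)) |>
    ungroup()
  feature_levels <- NULL
  if (!is.null(features)) {
    cg <- filter(pooled, .data$context == "CG")
    ov <- interval_overlaps(
      tibble(chrom = cg$chrom, start = cg$pos, end = cg$pos + 1L),
      features
    )
    feature_levels <- tibble(
      group = cg$group[ov$idx_x],
      category = features$category[ov$idx_y],
      meth = cg$meth[ov$idx_x],
      total = cg$total[ov$idx_x]
    ) |>
      group_by(.data$group, .data$category) |>
      summarise(mcg_level = sum(.data$meth) / sum(.data$total), .groups = "drop")
  }
  list(context_proportions = context_proportions, feature_levels = feature_levels)
}
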