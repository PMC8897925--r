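test_that("sim_config validates its inputs", {
  expect_error(sim_config(dispersion_phi = 1), "dispersion_phi")
  expect_error(sim_config(base_methylation = 1.2), "base_methylation")
  expect_error(sim_config(dmr_span_range = c(300, 100)), "dmr_span_range")
  expect_error(coupling_noise_for_r(0.4, 0.4, -2), "share a sign")
})

test_that("a degenerate config with no genes still emits a genome", {
  cfg <- sim_config(genome_length = 5e4, n_genes = 0, n_planted_dmrs = 0)
  ann <- make_annotation(cfg)
  expect_equal(nrow(ann$genes), 0)
  expect_equal(sum(nchar(ann$genome)), 5e4)
})

test_that("a genome too short for the requested genes errors", {
  expect_error(make_annotation(sim_config(genome_length = 2e4, n_genes = 50)),
               "too short")
})

test_that("annotation output is byte-identical under a fixed seed", {
  cfg <- sim_config(genome_length = 8e4, n_genes = 6, n_planted_dmrs = 3)
  a1 <- make_annotation(cfg)
  a2 <- make_annotation(cfg)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$genes, a2$genes)
  td <- withr::local_tempdir()
  f1 <- write_genome_fasta(a1$genome, file.path(td, "a.fa"))
  f2 <- write_genome_fasta(a2$genome, file.path(td, "b.fa"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g1 <- write_genes_gtf(a1$genes, file.path(td, "a.gtf"))
  g2 <- write_genes_gtf(a2$genes, file.path(td, "b.gtf"))
  expect_identical(readLines(g1), readLines(g2))
})

test_that("background CpG density matches the configured rate", {
  cfg <- sim_config(genome_length = 1e6, n_genes = 0, n_planted_dmrs = 0,
                    cpg_rate = 0.05)
  ann <- make_annotation(cfg)
  sites <- cpg_sites(ann$genome)
  # direct count on the emitted sequence, excluding the CpG-boosted islands
  in_cgi <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(ann$cgi))) {
    in_cgi <- in_cgi | (sites$chrom == ann$cgi$chrom[i] &
                          sites$pos >= ann$cgi$start[i] - 1 &
                          sites$pos < ann$cgi$end[i])
  }
  bg_len <- sum(nchar(ann$genome)) - sum(ann$cgi$end - ann$cgi$start)
  observed <- sum(!in_cgi)
  expected <- 0.05 * bg_len
  sd3 <- 3 * sqrt(bg_len * 0.05 * 0.95)
  expect_lt(abs(observed - expected), sd3)
})

test_that("CpG islands are CpG-enriched relative to background", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 10, n_planted_dmrs = 0)
  ann <- make_annotation(cfg)
  sites <- cpg_sites(ann$genome)
  cgi_hits <- methylens:::interval_overlaps(
    tibble::tibble(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L),
    ann$cgi
  )
  cgi_len <- sum(ann$cgi$end - ann$cgi$start)
  dens_cgi <- nrow(cgi_hits) / cgi_len
  dens_bg <- (nrow(sites) - nrow(cgi_hits)) /
    (sum(nchar(ann$genome)) - cgi_len)
  expect_gt(dens_cgi, 1.5 * dens_bg)
})

test_that("gene models are well-formed and non-overlapping", {
  cfg <- sim_config(genome_length = 3e5, n_genes = 40, n_planted_dmrs = 0)
  ann <- make_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), 40)
  expect_true(all(g$end > g$start))
  # non-overlap within chromosome
  by_chrom <- split(g, g$chrom)
  for (df in by_chrom) {
    df <- df[order(df$start), ]
    if (nrow(df) > 1) expect_true(all(df$start[-1] >= df$end[-nrow(df)]))
  }
  for (i in seq_len(nrow(g))) {
    ex <- g$exons[[i]]
    expect_gte(nrow(ex), 1)
    expect_true(all(ex$start >= g$start[i] & ex$end <= g$end[i]))
    expect_true(g$utr5_end[i] > g$utr5_start[i])
    expect_true(g$utr3_end[i] > g$utr3_start[i])
  }
})

test_that("pooled methylation matches the binomial mean at phi = 0", {
  cfg <- sim_config(genome_length = 3e5, n_genes = 0, n_planted_dmrs = 0,
                    dispersion_phi = 0, coverage_mean = 50,
                    base_methylation = 0.5, n_replicates_per_group = 1)
  ann <- make_annotation(cfg)
  sim <- simulate_methylomes(cfg, ann)
  expect_gt(nrow(sim$records) / 2, 1e4)
  pooled <- sum(sim$records$n_methylated) / sum(sim$records$n_total)
  expect_gt(pooled, 0.49)
  expect_lt(pooled, 0.51)
})

test_that("zero effect size yields an all-zero truth table", {
  cfg <- sim_config(genome_length = 1e5, n_genes = 10, n_planted_dmrs = 5,
                    effect_size = 0)
  ann <- make_annotation(cfg)
  sim <- simulate_methylomes(cfg, ann)
  expect_equal(nrow(sim$truth), 5)
  expect_true(all(sim$truth$effect == 0))
})

test_that("beta-binomial replicate variance follows mu(1-mu)(1+(N-1)phi)/N", {
  n <- 2e4
  N <- 50
  mu <- 0.5
  for (phi in c(0, 0.3)) {
    draws <- withr::with_seed(42, {
      methylens:::rbetabinom_mu_phi(n, N, mu, phi) / N
    })
    v_expected <- mu * (1 - mu) * (1 + (N - 1) * phi) / N
    expect_lt(abs(var(draws) - v_expected), 5 * v_expected / sqrt(n / 2))
  }
  v0 <- withr::with_seed(1, var(methylens:::rbetabinom_mu_phi(2e3, N, mu, 0) / N))
  v3 <- withr::with_seed(1, var(methylens:::rbetabinom_mu_phi(2e3, N, mu, 0.3) / N))
  expect_gt(v3, v0)
})

test_that("expression coupling off gives near-zero correlation", {
  cfg <- sim_config(genome_length = 3.2e6, n_genes = 520, n_planted_dmrs = 500,
                    expr_coupling_slope = 0, expr_noise_sd = 1)
  ann <- make_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  expr <- simulate_expression(cfg, ann$genes, truth)
  coupled <- expr[expr$true_avg_diff_methyl != 0, ]
  expect_gte(nrow(coupled), 450)
  r <- cor(coupled$true_avg_diff_methyl, coupled$log2fc)
  expect_lt(abs(r), 0.1)
})

test_that("genes without planted regions have exactly zero methylation signal", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 20, n_planted_dmrs = 5)
  ann <- make_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  expr <- simulate_expression(cfg, ann$genes, truth)
  unplanted <- setdiff(ann$genes$gene_id, truth$gene_id)
  expect_true(all(expr$true_avg_diff_methyl[expr$gene_id %in% unplanted] == 0))
  expect_true(all(expr$fpkm_group2 ==
                    expr$fpkm_group1 * 2^expr$log2fc))
})

test_that("accessibility coupling off gives near-zero correlation", {
  cfg <- sim_config(genome_length = 3.2e6, n_genes = 520, n_planted_dmrs = 500,
                    atac_coupling_slope = 0, atac_noise_sd = 0.5)
  ann <- make_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  peaks <- simulate_atac(cfg, ann, truth)
  planted <- peaks[peaks$planted, ]
  expect_equal(nrow(planted), 500)
  expect_lt(abs(cor(planted$true_effect, planted$log2fc)), 0.1)
})

test_that("a background-only run yields no peak overlapping any planted region", {
  cfg <- sim_config(genome_length = 1e5, n_genes = 5, n_planted_dmrs = 0,
                    n_background_peaks = 40)
  ann <- make_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  peaks <- simulate_atac(cfg, ann, truth)
  expect_true(all(!peaks$planted))
  dmr_like <- tibble::tibble(chrom = character(), start = integer(),
                             end = integer(), diff_methyl = double(),
                             direction = character())
  ov <- overlap_dmrs_with_peaks(dmr_like, classify_peaks(peaks))
  expect_equal(nrow(ov$records), 0)
})
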