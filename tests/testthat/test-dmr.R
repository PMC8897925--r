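test_that("smoothing pools reads over the positional window", {
  # isolated CpG: window of one, 8/10 methylated pooled
  rec <- grid_records(pos = 500, meth1 = 8, total1 = 10, meth2 = 8, total2 = 10)
  sm <- smooth_methylation(rec, dmr_params(smoothing_span = 200))
  expect_equal(sm$mu1, 0.8)

  # 3 CpGs at 0/50/100 with pooled (5/10, 10/10, 0/10): middle = 15/30
  rec <- grid_records(pos = c(0, 50, 100), meth1 = c(5, 10, 0),
                      total1 = 10, meth2 = c(5, 10, 0), total2 = 10)
  sm <- smooth_methylation(rec, dmr_params(smoothing_span = 200))
  expect_equal(sm$mu1[2], 15 / 30)
  # the +/-100 bp window is inclusive, so site 0 also reaches site 100
  expect_equal(sm$mu1[1], 15 / 30)
  sm120 <- smooth_methylation(
    grid_records(pos = c(0, 50, 120), meth1 = c(5, 10, 0), total1 = 10,
                 meth2 = c(5, 10, 0), total2 = 10),
    dmr_params(smoothing_span = 200)
  )
  expect_equal(sm120$mu1[1], 15 / 20)  # site at 120 now out of reach

  # span 0 reduces to per-site pooled proportions
  sm0 <- smooth_methylation(rec, dmr_params(smoothing_span = 0))
  expect_equal(sm0$mu1, c(0.5, 1, 0))
})

test_that("the Wald statistic matches the direct variance arithmetic", {
  # mu1 = 0.8, mu2 = 0.2, one replicate per group, N = 100, phi* = 0
  rec <- grid_records(pos = 500, meth1 = 80, total1 = 100,
                      meth2 = 20, total2 = 100)
  sm <- smooth_methylation(rec, dmr_params())
  disp <- suppressWarnings(estimate_dispersion(rec, dmr_params()))
  expect_equal(disp$phi_star, 0)  # single-replicate groups fall back
  st <- site_wald_test(sm, disp, dmr_params())
  expect_equal(st$wald_stat, (0.2 - 0.8) / sqrt(0.0016 + 0.0016),
               tolerance = 1e-6)
  expect_equal(abs(st$wald_stat), 10.6066, tolerance = 1e-4)
})

test_that("equal group means give wald 0 and p 1", {
  rec <- grid_records(pos = 500, meth1 = 5, total1 = 10, meth2 = 5, total2 = 10)
  st <- site_wald_test(smooth_methylation(rec, dmr_params()),
                       suppressWarnings(estimate_dispersion(rec, dmr_params())),
                       dmr_params())
  expect_equal(st$wald_stat, 0)
  expect_equal(st$p_value, 1)
})

test_that("increasing the dispersion strictly shrinks the Wald statistic", {
  sm <- tibble::tibble(
    chrom = "chr1", pos = 100L, mu1 = 0.3, mu2 = 0.7,
    w_meth1 = 30, w_total1 = 100, w_totalsq1 = 100 * 20,
    w_meth2 = 70, w_total2 = 100, w_totalsq2 = 100 * 20
  )
  wald_at <- function(phi) {
    disp <- tibble::tibble(chrom = "chr1", pos = 100L, phi_star = phi)
    site_wald_test(sm, disp, dmr_params())$wald_stat
  }
  w1 <- wald_at(0.1)
  w2 <- wald_at(0.2)
  expect_lt(abs(w2), abs(w1))
})

test_that("degenerate zero-variance sites are handled per the contract", {
  rec <- grid_records(pos = 500, meth1 = 10, total1 = 10, meth2 = 0, total2 = 10)
  st <- site_wald_test(smooth_methylation(rec, dmr_params()),
                       suppressWarnings(estimate_dispersion(rec, dmr_params())),
                       dmr_params())
  expect_true(st$unstable)
  expect_false(st$is_significant)
})

test_that("dispersion shrinkage recovers the simulated overdispersion scale", {
  make_rec <- function(phi) {
    n_sites <- 1e4
    pos <- seq_len(n_sites) * 40L
    withr::with_seed(7, {
      dplyr::bind_rows(lapply(1:3, function(r) {
        dplyr::bind_rows(
          toy_records(pos, "group1", r,
                      methylens:::rbetabinom_mu_phi(n_sites, 50, 0.5, phi), 50),
          toy_records(pos, "group2", r,
                      methylens:::rbetabinom_mu_phi(n_sites, 50, 0.5, phi), 50)
        )
      }))
    })
  }
  d0 <- estimate_dispersion(make_rec(0), dmr_params())
  expect_lte(median(d0$phi_star), 0.02)
  d3 <- estimate_dispersion(make_rec(0.3), dmr_params())
  expect_gt(median(d3$phi_star), 0.2)
  expect_lt(median(d3$phi_star), 0.4)
})

test_that("identical replicate proportions give a zero raw dispersion", {
  rec <- grid_records(pos = 100, meth1 = 5, total1 = 10, meth2 = 7,
                      total2 = 10, reps = 3)
  d <- estimate_dispersion(rec, dmr_params())
  expect_equal(d$phi_hat, 0)
})

test_that("segmentation reproduces the worked examples", {
  p <- dmr_params()
  # two clusters, gap 160 >= 100; first spans 41 < 50 and is dropped
  st <- toy_sites(c(0, 20, 40, 200, 220, 260), sig = rep(TRUE, 6))
  d <- call_dmrs(st, p)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 200)
  expect_equal(d$end, 261)
  expect_equal(d$n_cg, 3)

  # all gaps below the merge window: one region over everything
  st <- toy_sites(c(0, 20, 40, 60, 120), sig = rep(TRUE, 5))
  d <- call_dmrs(st, p)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(0, 121))
  expect_equal(d$n_cg, 5)
  expect_equal(d$frac_sig, 1)

  # no significant sites at all
  st <- toy_sites(c(0, 60, 120), sig = rep(FALSE, 3))
  expect_equal(nrow(call_dmrs(st, p)), 0)
  expect_equal(nrow(call_dmrs(st[0, ], p)), 0)
})

test_that("segmentation equals the brute-force oracle on random instances", {
  p <- dmr_params()
  withr::with_seed(101, {
    for (i in 1:250) {
      n <- sample(1:30, 1)
      pos <- sort(sample.int(1200, n))
      sig <- runif(n) < 0.45
      mu2 <- runif(n)
      st <- toy_sites(pos, sig)
      st$mu2 <- mu2
      got <- call_dmrs(st, p)
      want <- oracle_call_dmrs(st, p)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$n_cg, want$n_cg)
        expect_equal(got$frac_sig, want$frac_sig)
        expect_equal(got$diff_methyl, want$diff_methyl)
      }
    }
  })
})

test_that("swapping group labels negates every region difference exactly", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 15, n_planted_dmrs = 8)
  ann <- make_annotation(cfg)
  sim <- simulate_methylomes(cfg, ann)
  swapped <- sim$records |>
    dplyr::mutate(group = ifelse(group == "group1", "group2", "group1"))
  d1 <- dmr_pipeline(sim$records)$dmrs
  d2 <- dmr_pipeline(swapped)$dmrs
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$start, d2$start)
  expect_equal(d2$diff_methyl, -d1$diff_methyl)
  expect_true(all(d1$direction != d2$direction | d1$diff_methyl == 0))
})

test_that("methylome summaries report context shares and feature levels", {
  rec <- dplyr::bind_rows(
    toy_records(seq(0, 80, 10), "group1", 1, 5, 10),             # 9 CG
    toy_records(95, "group1", 1, 3, 10, context = "CHH")         # 1 CHH
  )
  s <- methylome_summary(rec)
  cg_share <- s$context_proportions$proportion[
    s$context_proportions$context == "CG"]
  expect_equal(cg_share, 0.9)

  feats <- tibble::tibble(chrom = "chr1", start = c(0L, 50L),
                          end = c(50L, 100L),
                          category = c("left", "right"))
  s2 <- methylome_summary(rec, feats)
  lv <- s2$feature_levels
  # left: CpGs 0..40 -> 25/50; right: CpGs 50..80 -> 20/40
  expect_equal(lv$mcg_level[lv$category == "left"], 0.5)
  expect_equal(lv$mcg_level[lv$category == "right"], 0.5)

  rec_all_meth <- toy_records(c(0, 10), "group1", 1, c(1, 2), 10)
  s3 <- methylome_summary(rec_all_meth)
  expect_equal(s3$context_proportions$proportion, 1)
})

test_that("a null methylome produces essentially no region calls", {
  cfg <- sim_config(genome_length = 1.2e6, n_genes = 0, n_planted_dmrs = 0,
                    seed = 3)
  ann <- make_annotation(cfg)
  sim <- simulate_methylomes(cfg, ann)
  n_cpg <- nrow(sim$records) / 6
  expect_gt(n_cpg, 4e4)
  res <- dmr_pipeline(sim$records)
  expect_lte(nrow(res$dmrs), 1)
})
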