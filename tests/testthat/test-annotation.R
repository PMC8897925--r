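test_that("cytosine context classification follows the 3' definition", {
  expect_equal(classify_context("ACGT", 1, "+"), "CG")
  expect_equal(classify_context("CAG", 0, "+"), "CHG")
  expect_equal(classify_context("CAT", 0, "+"), "CHH")
  expect_equal(classify_context("ACGT", 0, "+"), "not_C")  # A, not a cytosine
  expect_equal(classify_context("ACGT", 2, "-"), "CG")     # G pairs with C
  expect_equal(classify_context("TTTT", 0, "+"), "not_C")
  # truncated 3' context is flagged distinctly
  expect_equal(classify_context("AAC", 2, "+"), "CHH_trunc")
  expect_equal(classify_context("CA", 0, "+"), "CHH_trunc")
})

test_that("strand classification matches a reverse-complement oracle", {
  seq <- withr::with_seed(11, random_dna(1000))
  rc <- methylens:::reverse_complement(seq)
  n <- nchar(seq)
  # classifying pos on the minus strand of seq must equal classifying the
  # mirrored position on the plus strand of the reverse complement
  pos <- 2:(n - 3)
  minus <- classify_context(seq, pos, "-")
  mirrored <- classify_context(rc, n - 1 - pos, "+")
  expect_equal(minus, mirrored)
})

test_that("interval annotation applies the priority order", {
  params <- annotation_params()
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "+"),
    start = c(5000L, 200L), end = c(8000L, 900L),
    exons = list(tibble::tibble(start = 5000L, end = 8000L),
                 tibble::tibble(start = 200L, end = 900L)),
    utr5_start = NA_integer_, utr5_end = NA_integer_,
    utr3_start = NA_integer_, utr3_end = NA_integer_
  )
  idx <- build_feature_index(genes, params = params)
  # inside gA's promoter [3000,5000) and gB's exon -> promoter wins
  got <- annotate_intervals(
    tibble::tibble(chrom = "chr1", start = 600L, end = 3200L), idx, params
  )
  expect_equal(as.character(got$category), "promoter")
  # overlapping nothing -> intergenic
  got2 <- annotate_intervals(
    tibble::tibble(chrom = "chr1", start = 20000L, end = 20100L), idx, params
  )
  expect_equal(as.character(got2$category), "intergenic")
})

test_that("interval annotation equals a brute-force scan on random cases", {
  params <- annotation_params()
  cfg <- sim_config(genome_length = 2e5, n_genes = 12, n_planted_dmrs = 0)
  ann <- make_annotation(cfg)
  idx <- build_feature_index(ann$genes, ann$cgi, ann$shores, ann$repeats,
                             params, ann$chrom_sizes)
  withr::with_seed(5, {
    q <- tibble::tibble(
      chrom = "chr1",
      start = sample.int(199000, 300),
      end = 0L
    )
    q$end <- q$start + sample.int(800, 300)
    got <- annotate_intervals(q, idx, params)
    want <- oracle_annotate(q, idx, params)
    expect_equal(as.character(got$category), want)
  })
})

test_that("DMR-gene links are strand-aware with promoter precedence", {
  params <- annotation_params()
  gene <- tibble::tibble(
    gene_id = "gM", chrom = "chr1", strand = "-",
    start = 5000L, end = 8000L,
    exons = list(tibble::tibble(start = 5000L, end = 8000L)),
    utr5_start = NA_integer_, utr5_end = NA_integer_,
    utr3_start = NA_integer_, utr3_end = NA_integer_
  )
  # minus-strand promoter is [8000, 10000)
  no_link <- map_dmr_to_genes(
    tibble::tibble(chrom = "chr1", start = 100L, end = 200L), gene, params)
  expect_equal(nrow(no_link), 0)
  linked <- map_dmr_to_genes(
    tibble::tibble(chrom = "chr1", start = 8100L, end = 8150L), gene, params)
  expect_equal(linked$location, "promoter")
  # a DMR crossing the gene end overlaps body and promoter: promoter wins
  both <- map_dmr_to_genes(
    tibble::tibble(chrom = "chr1", start = 7900L, end = 8100L), gene, params)
  expect_equal(nrow(both), 1)
  expect_equal(both$location, "promoter")
})

test_that("a DMR overlapping two gene bodies links to both genes", {
  params <- annotation_params()
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(1000L, 2000L), end = c(1900L, 3000L),
    exons = list(tibble::tibble(start = 1000L, end = 1900L),
                 tibble::tibble(start = 2000L, end = 3000L)),
    utr5_start = NA_integer_, utr5_end = NA_integer_,
    utr3_start = NA_integer_, utr3_end = NA_integer_
  )
  links <- map_dmr_to_genes(
    tibble::tibble(chrom = "chr1", start = 1800L, end = 2100L), genes, params)
  expect_equal(sort(links$gene_id), c("g1", "g2"))
})

test_that("mirroring a gene mirrors its promoter exactly", {
  L <- 50000L
  withr::with_seed(3, {
    for (i in 1:20) {
      start <- sample.int(L - 10000L, 1) + 3000L
      end <- start + sample.int(3000L, 1)
      strand <- sample(c("+", "-"), 1)
      g <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = strand,
                          start = start, end = end)
      m_start <- L - end
      m_end <- L - start
      mirrored <- tibble::tibble(
        gene_id = "g", chrom = "chr1",
        strand = ifelse(strand == "+", "-", "+"),
        start = m_start, end = m_end
      )
      p <- promoter_interval(g)
      pm <- promoter_interval(mirrored)
      expect_equal(pm$start, L - p$end)
      expect_equal(pm$end, L - p$start)
    }
  })
})

test_that("category counts partition any annotated DMR set", {
  params <- annotation_params()
  cfg <- sim_config(genome_length = 2e5, n_genes = 10, n_planted_dmrs = 0)
  ann <- make_annotation(cfg)
  idx <- build_feature_index(ann$genes, ann$cgi, ann$shores, ann$repeats,
                             params, ann$chrom_sizes)
  q <- withr::with_seed(9, tibble::tibble(
    chrom = "chr1", start = sample.int(190000, 150)
  ))
  q$end <- q$start + 200L
  got <- annotate_intervals(q, idx, params)
  expect_equal(sum(table(got$category)), nrow(q))
})

test_that("random placement resamples the observed length multiset", {
  cs <- tibble::tibble(chrom = c("chr1", "chr2"), size = c(5e4L, 3e4L))
  lengths <- c(120L, 250L, 300L)
  draws <- withr::with_seed(2, methylens:::random_placement(lengths, 20, cs))
  expect_equal(nrow(draws), 60)
  expect_true(all((draws$end - draws$start) %in% lengths))
  expect_true(all(draws$start >= 0))
  sizes <- cs$size[match(draws$chrom, cs$chrom)]
  expect_true(all(draws$end <= sizes))
  expect_error(
    withr::with_seed(2, methylens:::random_placement(2e5L, 5, cs)),
    "shorter"
  )
})

test_that("a single all-genome feature shows zero percent difference", {
  cs <- tibble::tibble(chrom = "chr1", size = 1e5L)
  idx <- tibble::tibble(chrom = "chr1", start = 0L, end = 1e5L,
                        category = "promoter", gene_id = NA_character_,
                        promoter_zone = NA_character_)
  res <- random_null_test(rep("promoter", 50), cs, rep(200L, 50), idx,
                          n_draws = 20, seed = 4)
  row <- res$comparison[res$comparison$category == "promoter", ]
  expect_equal(row$pct_difference, 0)
  expect_equal(row$observed, 50)
})

test_that("hyper/hypo distribution comparison matches closed forms", {
  same <- tibble::tibble(
    category = rep(c("promoter", "other_exon"), each = 20),
    direction = rep(c("hyper", "hypo"), 20)
  )
  res <- compare_hyper_hypo_distributions(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  perfect <- tibble::tibble(
    category = rep(c("promoter", "other_exon"), each = 10),
    direction = c(rep("hyper", 10), rep("hypo", 10))
  )
  res2 <- compare_hyper_hypo_distributions(perfect)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$p_value, 7.744216e-06, tolerance = 1e-5)
  expect_equal(unname(colSums(res2$table)), c(10, 10))

  only_hyper <- tibble::tibble(category = "promoter", direction = "hyper")
  expect_error(compare_hyper_hypo_distributions(only_hyper), "hypo")
})
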