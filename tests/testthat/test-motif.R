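test_that("log-odds construction matches direct arithmetic", {
  uni <- matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_true(all(abs(pfm_to_pwm(uni)) < 1e-12))

  col <- matrix(c(10, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  lo <- pfm_to_pwm(col, pseudocount = 0.25)
  expect_equal(unname(lo["A", 1]), log2((10.25 / 11) / 0.25), tolerance = 1e-9)
  expect_equal(unname(lo["A", 1]), 1.898, tolerance = 1e-3)

  # doubling all counts barely moves the log-odds at this pseudocount
  m <- matrix(c(8, 1, 1, 2, 3, 3, 3, 3), 4, 2,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  d <- abs(pfm_to_pwm(2 * m) - pfm_to_pwm(m))
  expect_lt(max(d), 0.1)

  expect_error(pfm_to_pwm(uni, background = c(0, 0.5, 0.25, 0.25)), "positive")
})

test_that("the score tail table matches hand enumeration for width 1", {
  lo <- matrix(c(2, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  tab <- pwm_score_pvalue_table(lo)
  expect_equal(methylens:::pwm_tail_p(tab, round(2 / 0.01)), 0.25)
  expect_equal(methylens:::pwm_tail_p(tab, 0L), 1)
  # minimum possible score always has p = 1
  expect_equal(methylens:::pwm_tail_p(tab, tab$offset), 1)
})

test_that("the DP tail equals brute-force enumeration up to width 8", {
  withr::with_seed(41, {
    for (w in c(2, 3, 5, 8)) {
      counts <- matrix(stats::rpois(4 * w, 5) + 0.0, 4, w,
                       dimnames = list(c("A", "C", "G", "T"), NULL))
      counts[1, ] <- counts[1, ] + 3  # break symmetry
      bg <- c(0.3, 0.2, 0.2, 0.3)
      lo <- pfm_to_pwm(counts, background = bg)
      tab <- pwm_score_pvalue_table(lo, background = bg)
      q <- tab$q
      probes <- quantile(seq(tab$offset, tab$offset + length(tab$tail) - 1),
                         c(0, 0.25, 0.5, 0.9, 1))
      for (s_int in as.integer(probes)) {
        dp <- methylens:::pwm_tail_p(tab, s_int)
        # oracle enumerates the same discretised matrix
        oracle <- oracle_pwm_tail(q, bg, s_int)
        expect_equal(dp, oracle, tolerance = 1e-9)
      }
    }
  })
})

test_that("tail probabilities are monotone non-increasing in score", {
  lo <- pfm_to_pwm(sharp_motif()$counts)
  tab <- pwm_score_pvalue_table(lo)
  expect_true(all(diff(tab$tail) <= 1e-12))
})

test_that("hit calling finds the consensus and respects thresholds", {
  # width 8: a perfect uniform-background match has p = 4^-8 < 1e-4
  m <- sharp_motif("ACGTACGT")
  hits <- call_motif_hits(c(s1 = "ACGTACGTTTTTTT"), m,
                          background = rep(0.25, 4))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$offset[1], 0L)

  # sequence shorter than the motif: no hits, no error
  none <- call_motif_hits(c(s = "ACG"), m, background = rep(0.25, 4))
  expect_equal(nrow(none), 0)

  # threshold 1 reports every offset on both strands
  all_hits <- call_motif_hits(c(s = "ACGTACGTACGT"), m, p_threshold = 1,
                              background = rep(0.25, 4))
  expect_equal(nrow(all_hits), 2 * (12 - 8 + 1))
})

test_that("hits mirror exactly between a sequence and its reverse complement", {
  m <- sharp_motif("ACGGT")
  w <- 5
  withr::with_seed(43, {
    for (i in 1:50) {
      seq <- random_dna(60)
      rc <- methylens:::reverse_complement(seq)
      h1 <- call_motif_hits(stats::setNames(seq, "s"), m, p_threshold = 0.05,
                            background = rep(0.25, 4))
      h2 <- call_motif_hits(stats::setNames(rc, "s"), m, p_threshold = 0.05,
                            background = rep(0.25, 4))
      # a + hit at offset o maps to a - hit at L - w - o on the complement
      m1 <- h1 |>
        dplyr::mutate(offset = 60 - w - offset,
                      strand = as.character(ifelse(strand == "+", "-", "+"))) |>
        dplyr::arrange(offset, strand)
      m2 <- h2 |> dplyr::arrange(offset, strand)
      expect_equal(m1$offset, m2$offset)
      expect_equal(m1$strand, as.character(m2$strand))
      expect_equal(sort(m1$score), sort(m2$score))
    }
  })
})

test_that("shuffles preserve composition (and adjacency in dinucleotide mode)", {
  expect_equal(unname(shuffle_sequences(c(h = "AAAA"), seed = 1)), "AAAA")
  expect_equal(unname(shuffle_sequences(c(h = "AAAA"), "dinucleotide", 1)),
               "AAAA")
  dicount <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  withr::with_seed(47, {
    for (i in 1:10) {
      s <- random_dna(1000)
      mono <- shuffle_sequences(stats::setNames(s, "x"), seed = i)
      expect_equal(sort(strsplit(mono, "")[[1]]), sort(strsplit(s, "")[[1]]))
      expect_false(unname(mono) == s)
      di <- shuffle_sequences(stats::setNames(s, "x"), "dinucleotide", i)
      expect_equal(dicount(unname(di)), dicount(s))
      expect_equal(unname(substr(di, 1, 1)), substr(s, 1, 1))
      expect_equal(unname(substr(di, 1000, 1000)), substr(s, 1000, 1000))
    }
  })
  # deterministic under seed
  s <- c(a = "ACGTGGCATGCA")
  expect_identical(shuffle_sequences(s, "dinucleotide", 9),
                   shuffle_sequences(s, "dinucleotide", 9))
})

test_that("enrichment reproduces the hypergeometric closed form", {
  m <- sharp_motif("ACGTACGT")
  withr::with_seed(53, {
    primary <- stats::setNames(
      paste0(replicate(10, random_dna(30)), "ACGTACGT"),
      paste0("p", 1:10)
    )
    control <- stats::setNames(replicate(10, random_dna(38)), paste0("c", 1:10))
  })
  res <- motif_enrichment(primary, control, list(m),
                          background = rep(0.25, 4))
  expect_equal(res$n_primary_with_hit, 10)
  expect_equal(res$n_control_with_hit, 0)
  expect_equal(res$fisher_p, 1 / choose(20, 10), tolerance = 1e-9)
  expect_equal(res$adjusted_p, res$fisher_p)

  # identical hit counts cannot be enriched
  res2 <- motif_enrichment(primary, primary, list(m),
                           background = rep(0.25, 4))
  expect_gte(res2$fisher_p, 0.5)
})

test_that("TF expression filtering maps names and keeps unmapped motifs", {
  res <- tibble::tibble(
    motif_id = c("M1", "M2", "M3", "M4"),
    tf_name = c("LOWTF", "HIGHTF", "ARNT::HIF1A", "GHOST"),
    n_primary_with_hit = 5L, n_primary = 10L,
    n_control_with_hit = 1L, n_control = 10L,
    fisher_p = 0.01, adjusted_p = 0.02, n_target_genes = 3L
  )
  expr <- classify_degs(tibble::tibble(
    gene_id = c("LowTF", "HighTF", "HIF1A"),
    fpkm_group1 = c(0.3, 5, 2), fpkm_group2 = c(0.4, 3, 1),
    log2fc = c(0.4, -0.7, -1), qvalue = c(0.5, 0.01, 0.01)
  ))
  out <- annotate_tf_expression(res, expr, fpkm_cutoff = 1)
  expect_false("M1" %in% out$motif_id)       # 0.7 FPKM < 1: dropped
  expect_true(all(c("M2", "M3") %in% out$motif_id))
  expect_true(out$tf_unmapped[out$motif_id == "M4"])
  expect_equal(out$tf_deg_class[out$motif_id == "M2"], "epithelial_preferred")
  expect_equal(out$tf_total_fpkm[out$motif_id == "M3"], 3)
  expect_true(all(out$motif_id %in% res$motif_id))
})

test_that("DMR sequence groups follow direction and gene class", {
  genome <- c(chr1 = paste(rep("ACGT", 300), collapse = ""))
  dmrs <- tibble::tibble(chrom = "chr1", start = c(0L, 100L, 200L),
                         end = c(40L, 140L, 240L),
                         diff_methyl = c(-0.3, 0.3, 0.3),
                         direction = c("hypo", "hyper", "hyper"))
  links <- tibble::tibble(dmr_idx = 1:3, gene_id = c("gF", "gE", "gN"),
                          location = "promoter")
  degs <- classify_degs(tibble::tibble(
    gene_id = c("gF", "gE", "gN"), fpkm_group1 = 1, fpkm_group2 = 1,
    log2fc = c(1, -1, 0), qvalue = c(0.01, 0.01, 0.01)
  ))
  grp <- dmr_sequence_groups(dmrs, links, degs, genome)
  expect_length(grp$hypo_fiber, 1)
  expect_length(grp$hyper_epithelial, 1)
  expect_equal(unname(nchar(grp$hypo_fiber)), 40)
  # extraction equals a direct genome slice
  expect_equal(as.character(grp$hypo_fiber),
               substr(genome[["chr1"]], 1, 40))
  expect_error(extract_dmr_sequences(
    tibble::tibble(chrom = "chr1", start = 1190L, end = 1300L), genome),
    "outside")
})
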