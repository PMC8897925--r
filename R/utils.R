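# Internal helpers shared across modules.

# Draw beta-binomial counts parameterised by (mu, phi).
# phi = 0 falls back to binomial exactly; alpha = mu (1 - phi) / phi,
# beta = (1 - mu) (1 - phi) / phi, so Var(p) = mu (1 - mu) (1 + (N - 1) phi) / N.
rbetabinom_mu_phi <- function(n, size, mu, phi) {
  stopifnot(all(mu >= 0 & mu <= 1), all(phi >= 0 & phi < 1))
  mu <- rep_len(mu, n)
  size <- rep_len(size, n)
  phi <- rep_len(phi, n)
  out <- integer(n)
  bin <- phi == 0 | mu == 0 | mu == 1
  if (any(bin)) out[bin] <- rbinom(sum(bin), size[bin], mu[bin])
  if (any(!bin)) {
    a <- mu[!bin] * (1 - phi[!bin]) / phi[!bin]
    b <- (1 - mu[!bin]) * (1 - phi[!bin]) / phi[!bin]
    p <- rbeta(sum(!bin), a, b)
    out[!bin] <- rbinom(sum(!bin), size[!bin], p)
  }
  out
}

# Pearson chi-square without continuity correction on a contingency matrix.
# Returns statistic, df and p; does not error on zero margins (caller decides).
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  ok <- expected > 0
  stat <- sum((tab[ok] - expected[ok])^2 / expected[ok])
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(
    statistic = stat,
    df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE),
    observed = tab,
    expected = expected
  )
}

has_zero_margin <- function(tab) {
  any(rowSums(tab) == 0) || any(colSums(tab) == 0)
}

# Chi-square after dropping all-zero rows/columns (unobserved classes);
# degenerate when fewer than 2 informative levels remain on either margin.
chisq_or_skip <- function(tab) {
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  sub <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(sub) < 2 || ncol(sub) < 2) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  pearson_chisq(sub)
}

# Pearson correlation with the t-distribution p-value, returned as a tibble row.
pearson_cor <- function(x, y) {
  if (length(x) < 3) {
    abort("Need at least 3 pairs for a correlation.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance in one of the correlated columns.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x)
  )
}

# Overlap width of interval sets given as 0-based half-open tibbles with
# chrom/start/end. Returns a tibble of (idx_x, idx_y, overlap_bp) for pairs
# overlapping by at least 1 bp, using IRanges for the join.
interval_overlaps <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(idx_x = integer(), idx_y = integer(), overlap_bp = integer()))
  }
  # IRanges is 1-based inclusive: [start+1, end]
  rx <- IRanges::IRanges(x$start + 1L, x$end)
  ry <- IRanges::IRanges(y$start + 1L, y$end)
  hits <- IRanges::findOverlaps(rx, ry, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same_chrom <- x$chrom[qi] == y$chrom[si]
  qi <- qi[same_chrom]
  si <- si[same_chrom]
  ov <- pmin(x$end[qi], y$end[si]) - pmax(x$start[qi], y$start[si])
  tibble(idx_x = qi, idx_y = si, overlap_bp = as.integer(ov))
}

# sample() without the scalar-x surprise: always samples elements of x.
sample_from <- function(x, n, replace = TRUE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must be a probability in [0, 1]."))
  }
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(paste0("`", name, "` must be ", if (strict) "positive." else "non-negative."))
  }
  invisible(x)
}
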