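# In-code fixtures shared across test files.

# A per-cytosine record tibble from parallel vectors.
toy_records <- function(pos, group, replicate, n_meth, n_total,
                        chrom = "chr1", context = "CG") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), context = context,
    group = group, replicate = as.integer(replicate),
    n_methylated = as.integer(n_meth), n_total = as.integer(n_total)
  ) |>
    dplyr::arrange(chrom, pos, group, replicate)
}

# Records for a set of sites with identical per-replicate counts in a group.
grid_records <- function(pos, meth1, total1, meth2, total2, reps = 1) {
  dplyr::bind_rows(lapply(seq_len(reps), function(r) {
    dplyr::bind_rows(
      toy_records(pos, "group1", r, meth1, total1),
      toy_records(pos, "group2", r, meth2, total2)
    )
  })) |> dplyr::arrange(chrom, pos, group, replicate)
}

# A site-statistic tibble where significance is set directly (for
# segmentation tests); mu values default to a fixed contrast.
toy_sites <- function(pos, sig, mu1 = 0.2, mu2 = 0.7, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    mu1 = rep_len(mu1, length(pos)), mu2 = rep_len(mu2, length(pos)),
    phi_star = 0.05, wald_stat = ifelse(sig, 10, 0),
    p_value = ifelse(sig, 1e-10, 0.5),
    is_significant = sig, unstable = FALSE
  )
}

# Brute-force segmentation oracle implementing the stated region semantics
# directly: chain significant CpGs while the bp gap to the previous
# significant CpG is < dis_merge; the region covers all CpGs between the
# first and last chained significant site; then filter on span, CpG count
# and significant fraction.
oracle_call_dmrs <- function(sites, params) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    df <- sites[sites$chrom == ch, ]
    df <- df[order(df$pos), ]
    sig <- which(df$is_significant)
    if (length(sig) == 0) next
    groups <- list()
    current <- sig[1]
    if (length(sig) > 1) {
      for (k in 2:length(sig)) {
        if (df$pos[sig[k]] - df$pos[sig[k - 1]] < params$dis_merge) {
          current <- c(current, sig[k])
        } else {
          groups <- c(groups, list(current))
          current <- sig[k]
        }
      }
    }
    groups <- c(groups, list(current))
    for (g in groups) {
      lo <- min(g); hi <- max(g)
      cpgs <- df[lo:hi, ]
      span <- max(cpgs$pos) - min(cpgs$pos) + 1
      n_cg <- nrow(cpgs)
      frac <- mean(cpgs$is_significant)
      if (span >= params$minlen && n_cg >= params$minCG &&
          frac >= params$pct_sig) {
        d <- mean(cpgs$mu2 - cpgs$mu1)
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start = min(cpgs$pos), end = max(cpgs$pos) + 1L,
          n_cg = n_cg, frac_sig = frac, diff_methyl = d,
          direction = if (d >= 0) "hyper" else "hypo"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_cg = integer(),
                          frac_sig = double(), diff_methyl = double(),
                          direction = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# Brute-force highest-priority feature annotation.
oracle_annotate <- function(intervals, feature_index, params) {
  levels <- c(params$category_priority, "intergenic")
  vapply(seq_len(nrow(intervals)), function(i) {
    best <- length(levels)
    for (j in seq_len(nrow(feature_index))) {
      if (feature_index$chrom[j] != intervals$chrom[i]) next
      if (feature_index$start[j] < intervals$end[i] &&
          intervals$start[i] < feature_index$end[j]) {
        best <- min(best, match(feature_index$category[j], levels))
      }
    }
    levels[best]
  }, character(1))
}

# Brute-force best-peak overlap join with the stated tie-breaks.
oracle_overlap <- function(dmrs, peaks) {
  rows <- list()
  for (i in seq_len(nrow(dmrs))) {
    best <- NULL
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != dmrs$chrom[i]) next
      ov <- min(dmrs$end[i], peaks$end[j]) - max(dmrs$start[i], peaks$start[j])
      if (ov < 1) next
      cand <- list(peak_idx = j, overlap_bp = ov, q = peaks$qvalue[j],
                   start = peaks$start[j])
      if (is.null(best) ||
          cand$overlap_bp > best$overlap_bp ||
          (cand$overlap_bp == best$overlap_bp && cand$q < best$q) ||
          (cand$overlap_bp == best$overlap_bp && cand$q == best$q &&
             cand$start < best$start)) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        dmr_idx = i, peak_idx = best$peak_idx, overlap_bp = best$overlap_bp
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(dmr_idx = integer(), peak_idx = integer(),
                          overlap_bp = integer()))
  }
  dplyr::bind_rows(rows)
}

# Brute-force PWM tail probability by enumerating all 4^w words
# (cross-sums via outer products; independent of the DP convolution).
oracle_pwm_tail <- function(log_odds, background, score) {
  w <- ncol(log_odds)
  scores <- 0
  probs <- 1
  for (j in seq_len(w)) {
    scores <- as.vector(outer(scores, log_odds[, j], "+"))
    probs <- as.vector(outer(probs, background, "*"))
  }
  sum(probs[scores >= score - 1e-9])
}

# A near-deterministic PFM whose consensus is the given word.
sharp_motif <- function(consensus = "ACGTAC") {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(0, 4, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) counts[bases[j], j] <- 100
  list(motif_id = "SHARP", tf_name = "SHARP", counts = counts)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
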