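#' Extract DMR sequences grouped for motif enrichment
#'
#' Builds the two sequence groups used for transcription-factor motif
#' enrichment: (1) sequences of hypomethylated (demethylated-in-fiber)
#' regions linked to fiber-preferred genes and (2) sequences of
#' hypermethylated regions linked to epithelial-preferred genes. Sequences
#' are uppercase; names record coordinates, the linked gene and direction.
#'
#' @param dmrs DMR tibble.
#' @param links DMR-gene links from [map_dmr_to_genes()].
#' @param degs Expression tibble through [classify_degs()].
#' @param genome Named character vector of chromosome sequences.
#' @return List with character vectors `hypo_fiber` and `hyper_epithelial`,
#'   each carrying a `gene_id` attribute aligned with the sequences.
#' @export
dmr_sequence_groups <- function(dmrs, links, degs, genome) {
  pick <- function(direction, class) {
    sel <- links |>
      inner_join(
        degs |> filter(.data$deg_class == class) |> select("gene_id"),
        by = "gene_id"
      ) |>
      filter(dmrs$direction[.data$dmr_idx] == direction) |>
      distinct(.data$dmr_idx, .data$gene_id)
    seqs <- extract_dmr_sequences(dmrs[sel$dmr_idx, ], genome)
    names(seqs) <- sprintf("%s|%s|%s", names(seqs), sel$gene_id, direction)
    attr(seqs, "gene_id") <- sel$gene_id
    seqs
  }
  list(
    hypo_fiber = pick("hypo", "fiber_preferred"),
    hyper_epithelial = pick("hyper", "epithelial_preferred")
  )
}

#' Slice DMR sequences out of the genome
#'
#' @param dmrs Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param genome Named character vector of chromosome sequences.
#' @return Uppercase character vector named `chrom:start-end`.
#' @export
extract_dmr_sequences <- function(dmrs, genome) {
  if (nrow(dmrs) == 0) return(stats::setNames(character(0), character(0)))
  bad <- !(dmrs$chrom %in% names(genome)) |
    dmrs$end > nchar(genome)[match(dmrs$chrom, names(genome))] |
    dmrs$start < 0
  if (any(bad)) abort("DMR outside the supplied genome contigs.")
  seqs <- toupper(substring(genome[dmrs$chrom], dmrs$start + 1L, dmrs$end))
  stats::setNames(seqs, sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end))
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' `log_odds[b, j] = log2(((counts[b, j] + pseudocount) /
#' (colsum_j + 4 * pseudocount)) / background[b])`, in bits.
#'
#' @param counts 4 x width non-negative matrix, rows A, C, G, T.
#' @param pseudocount Added to every cell (default 0.25).
#' @param background Base frequencies (A, C, G, T) summing to 1.
#' @return 4 x width log-odds matrix (bits), rownames A, C, G, T.
#' @export
pfm_to_pwm <- function(counts, pseudocount = 0.25,
                       background = rep(0.25, 4)) {
  stopifnot(nrow(counts) == 4)
  if (any(background <= 0)) abort("Background frequencies must be positive.")
  background <- background / sum(background)
  col_total <- colSums(counts)
  probs <- sweep(counts + pseudocount, 2, col_total + 4 * pseudocount, "/")
  lo <- log2(probs / background)
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

#' Exact tail distribution of PWM scores under the background model
#'
#' Discretises each log-odds cell to `bin_width`-bit units and convolves the
#' per-column score distributions under the (independent-base) background
#' model by dynamic programming. The returned object maps any score to
#' `P(background word scores >= score)` under the same discretisation, so
#' scanning and p-value lookup are exactly consistent.
#'
#' @param log_odds 4 x width matrix from [pfm_to_pwm()].
#' @param background Base frequencies (A, C, G, T).
#' @param bin_width Discretisation step in bits (default 0.01).
#' @return Object of class `pwm_pvalue_table`: integer-binned matrix `q`,
#'   `offset`, `tail` (monotone non-increasing), `bin_width`.
#' @export
pwm_score_pvalue_table <- function(log_odds, background = rep(0.25, 4),
                                   bin_width = 0.01) {
  stopifnot(all(is.finite(log_odds)))
  background <- background / sum(background)
  q <- round(log_odds / bin_width)
  w <- ncol(q)
  lo_total <- sum(apply(q, 2, min))
  hi_total <- sum(apply(q, 2, max))
  # probability vector over integer scores lo_total..hi_total
  probs <- numeric(hi_total - lo_total + 1)
  probs[1] <- 1
  for (j in seq_len(w)) {
    col_lo <- min(q[, j])
    new <- numeric(length(probs))
    for (b in 1:4) {
      shift <- q[b, j] - col_lo
      if (background[b] > 0) {
        n_old <- length(probs) - shift
        new[(1 + shift):length(probs)] <-
          new[(1 + shift):length(probs)] + background[b] * probs[1:n_old]
      }
    }
    probs <- new
  }
  tail <- rev(cumsum(rev(probs)))
  structure(
    list(q = q, offset = lo_total, tail = tail, bin_width = bin_width),
    class = "pwm_pvalue_table"
  )
}

# P(background word >= score) for integer-binned scores.
pwm_tail_p <- function(table, score_int) {
  idx <- score_int - table$offset + 1
  idx <- pmin(pmax(idx, 1), length(table$tail) + 1)
  out <- rep(0, length(score_int))
  in_range <- idx <= length(table$tail)
  out[in_range] <- table$tail[idx[in_range]]
  out[score_int < table$offset] <- 1
  out
}

#' Scan sequences for PWM hits with exact p-values
#'
#' Every offset (and strand, when `scan_both_strands`) whose discretised
#' log-odds score has a background tail probability below `p_threshold` is
#' reported. Reverse-strand scores are computed on the reverse complement;
#' offsets are reported in forward-sequence coordinates. Sequences shorter
#' than the motif yield no hits.
#'
#' @param sequences Named character vector.
#' @param motif Motif model (list with `motif_id`, `tf_name`, `counts`).
#' @param p_threshold Hit p-value cutoff (default 1e-4).
#' @param scan_both_strands Scan the reverse complement too (default TRUE).
#' @param pseudocount Passed to [pfm_to_pwm()].
#' @param background Base frequencies; `NULL` estimates a zero-order
#'   background from the scanned sequences.
#' @param bin_width Score discretisation in bits.
#' @return Hit tibble: `sequence_id`, `offset` (0-based), `strand`, `score`
#'   (bits), `p_value`.
#' @export
call_motif_hits <- function(sequences, motif, p_threshold = 1e-4,
                            scan_both_strands = TRUE, pseudocount = 0.25,
                            background = NULL, bin_width = 0.01) {
  if (is.null(background)) background <- zero_order_background(sequences)
  pwm <- pfm_to_pwm(motif$counts, pseudocount, background)
  tab <- pwm_score_pvalue_table(pwm, background, bin_width)
  w <- ncol(pwm)
  hits <- purrr::imap(sequences, function(seq, sid) {
    L <- nchar(seq)
    if (L < w) return(NULL)
    fwd <- scan_one(seq, tab)
    out <- list(tibble(
      sequence_id = sid, offset = seq_along(fwd$score) - 1L, strand = "+",
      score = fwd$score * tab$bin_width, p_value = fwd$p
    ))
    if (scan_both_strands) {
      rc <- reverse_complement(seq)
      rev <- scan_one(rc, tab)
      out <- c(out, list(tibble(
        sequence_id = sid,
        offset = L - w - (seq_along(rev$score) - 1L),
        strand = "-",
        score = rev$score * tab$bin_width, p_value = rev$p
      )))
    }
    bind_rows(out)
  }) |> list_rbind()
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(sequence_id = character(), offset = integer(),
                  strand = character(), score = double(), p_value = double()))
  }
  # a threshold of 1 is the degenerate "report every offset" setting
  hits |>
    filter(!is.na(.data$p_value),
           .data$p_value < p_threshold | p_threshold >= 1) |>
    arrange(.data$sequence_id, .data$offset, .data$strand)
}

# Integer-binned scores and p-values at every offset of one sequence.
scan_one <- function(seq, tab) {
  q <- tab$q
  w <- ncol(q)
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  L <- length(code)
  n_off <- L - w + 1
  if (n_off <= 0) return(list(score = numeric(0), p = numeric(0)))
  score <- rep(0L, n_off)
  valid <- rep(TRUE, n_off)
  for (j in seq_len(w)) {
    b <- code[j:(j + n_off - 1)]
    valid <- valid & !is.na(b)
    contrib <- q[cbind(ifelse(is.na(b), 1L, b), j)]
    score <- score + ifelse(is.na(b), 0L, contrib)
  }
  p <- pwm_tail_p(tab, score)
  p[!valid] <- NA_real_
  list(score = score, p = p)
}

zero_order_background <- function(sequences) {
  chars <- unlist(strsplit(toupper(paste(sequences, collapse = "")), ""))
  counts <- table(factor(chars, c("A", "C", "G", "T")))
  if (any(counts == 0)) {
    counts <- counts + 1  # avoid zero background on tiny sets
  }
  as.numeric(counts / sum(counts))
}

reverse_complement <- function(seq) {
  comp <- chartr("ACGTacgt", "TGCAtgca", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Shuffle sequences preserving composition
#'
#' Mononucleotide mode permutes the letters of each sequence (preserving
#' 1-mer counts); dinucleotide mode performs an Euler-path shuffle that
#' additionally preserves all 16 adjacency counts. Deterministic under
#' `seed`.
#'
#' @param sequences Named character vector.
#' @param mode `"mononucleotide"` (default) or `"dinucleotide"`.
#' @param seed RNG seed.
#' @return Shuffled sequences, same names and lengths.
#' @export
shuffle_sequences <- function(sequences,
                              mode = c("mononucleotide", "dinucleotide"),
                              seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    out <- vapply(sequences, function(seq) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      if (length(chars) < 2) return(seq)
      if (mode == "mononucleotide") {
        paste(sample(chars), collapse = "")
      } else {
        paste(euler_shuffle(chars), collapse = "")
      }
    }, character(1))
    stats::setNames(out, names(sequences))
  })
}

# Altschul-Erikson dinucleotide shuffle: pick a random "last edge" out of
# each non-terminal vertex; accept when following last edges reaches the
# terminal vertex from everywhere; shuffle the remaining edges per vertex.
euler_shuffle <- function(chars) {
  n <- length(chars)
  s_last <- chars[n]
  verts <- unique(chars)
  edges <- split(chars[-1], factor(chars[-n], levels = verts))
  if (length(verts) == 1) return(chars)
  for (attempt in 1:1000) {
    last_edge <- stats::setNames(rep(NA_character_, length(verts)), verts)
    for (v in setdiff(verts, s_last)) {
      es <- edges[[v]]
      if (length(es) == 0) next
      last_edge[v] <- es[sample.int(length(es), 1)]
    }
    # connectivity: from every vertex with edges, last-edge chain reaches s_last
    ok <- TRUE
    for (v in setdiff(verts, s_last)) {
      if (length(edges[[v]]) == 0) next
      cur <- v
      seen <- character(0)
      while (cur != s_last && !is.na(last_edge[cur]) && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- last_edge[cur]
      }
      if (cur != s_last) { ok <- FALSE; break }
    }
    if (!ok) next
    # build per-vertex edge stacks: shuffled non-last edges, then the last edge
    stacks <- lapply(verts, function(v) {
      es <- edges[[v]]
      if (is.na(last_edge[v])) return(sample(es))
      drop_idx <- match(last_edge[v], es)
      rest <- es[-drop_idx]
      c(if (length(rest)) sample(rest) else character(0), last_edge[v])
    })
    names(stacks) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- chars[1]
    cur <- chars[1]
    for (i in 2:n) {
      nxt <- stacks[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    return(out)
  }
  abort("Dinucleotide shuffle failed to find an Euler path.")
}

#' Motif enrichment in primary versus control sequences
#'
#' For each motif, counts the sequences with at least one hit in the primary
#' and control sets, applies a one-sided Fisher's exact test (primary
#' enriched) and a Benjamini-Hochberg adjustment across motifs. When
#' `sequence_genes` maps primary sequence names to gene ids, the number of
#' distinct target genes with a hit is reported.
#'
#' @param primary,control Named character vectors of sequences.
#' @param motifs List of motif models (from [read_jaspar_pfms()]).
#' @param p_threshold Hit p-value cutoff (default 1e-4).
#' @param sequence_genes Optional named character vector
#'   (primary sequence name -> gene id).
#' @param background `NULL` to estimate zero-order background from the
#'   combined sets.
#' @return Tibble sorted by adjusted p: `motif_id`, `tf_name`,
#'   `n_primary_with_hit`, `n_primary`, `n_control_with_hit`, `n_control`,
#'   `fisher_p`, `adjusted_p`, `n_target_genes`.
#' @export
motif_enrichment <- function(primary, control, motifs, p_threshold = 1e-4,
                             sequence_genes = NULL, background = NULL) {
  if (length(primary) == 0 || length(control) == 0) {
    abort("Both sequence sets must be non-empty.")
  }
  if (is.null(background)) {
    background <- zero_order_background(c(primary, control))
  }
  rows <- purrr::map(motifs, function(motif) {
    hp <- call_motif_hits(primary, motif, p_threshold, background = background)
    hc <- call_motif_hits(control, motif, p_threshold, background = background)
    a <- dplyr::n_distinct(hp$sequence_id)
    b <- dplyr::n_distinct(hc$sequence_id)
    mat <- matrix(c(a, length(primary) - a, b, length(control) - b), 2)
    n_genes <- if (!is.null(sequence_genes) && nrow(hp) > 0) {
      dplyr::n_distinct(sequence_genes[unique(hp$sequence_id)], na.rm = TRUE)
    } else if (nrow(hp) > 0) NA_integer_ else 0L
    tibble(
      motif_id = motif$motif_id, tf_name = motif$tf_name,
      n_primary_with_hit = a, n_primary = length(primary),
      n_control_with_hit = b, n_control = length(control),
      fisher_p = fisher.test(mat, alternative = "greater")$p.value,
      n_target_genes = n_genes
    )
  }) |> list_rbind()
  rows |>
    mutate(adjusted_p = p.adjust(.data$fisher_p, method = "BH")) |>
    arrange(.data$adjusted_p, .data$fisher_p) |>
    select("motif_id", "tf_name", "n_primary_with_hit", "n_primary",
           "n_control_with_hit", "n_control", "fisher_p", "adjusted_p",
           "n_target_genes")
}

#' Filter and annotate enriched motifs by TF expression
#'
#' Maps each motif's transcription-factor name to a gene (case-insensitive;
#' heterodimer names like `"ARNT::HIF1A"` map via each part, kept when any
#' part passes), drops motifs whose TF gene's summed FPKM
#' (`fpkm_group1 + fpkm_group2`) falls below `fpkm_cutoff`, and annotates
#' survivors with the TF gene's DEG class and total FPKM. TFs without a
#' matching gene are retained and flagged unmapped.
#'
#' @param results Enrichment tibble from [motif_enrichment()].
#' @param expression Expression tibble through [classify_degs()].
#' @param fpkm_cutoff Minimum summed FPKM (default 1).
#' @param aliases Optional named character vector mapping TF names to
#'   gene ids (case-insensitive keys).
#' @return Filtered tibble with `tf_gene_id`, `tf_total_fpkm`,
#'   `tf_deg_class`, `tf_unmapped` appended.
#' @export
annotate_tf_expression <- function(results, expression, fpkm_cutoff = 1,
                                   aliases = NULL) {
  expr_key <- stats::setNames(seq_len(nrow(expression)),
                              toupper(expression$gene_id))
  alias_key <- if (!is.null(aliases)) {
    stats::setNames(as.character(aliases), toupper(names(aliases)))
  } else character(0)
  lookup <- function(tf_name) {
    parts <- toupper(strsplit(tf_name, "::", fixed = TRUE)[[1]])
    mapped <- ifelse(parts %in% names(alias_key),
                     toupper(alias_key[parts]), parts)
    hits <- expr_key[mapped[mapped %in% names(expr_key)]]
    if (length(hits) == 0) return(NULL)
    expression[unname(hits), ]
  }
  annotated <- purrr::pmap(results, function(...) {
    row <- tibble(...)
    genes <- lookup(row$tf_name)
    if (is.null(genes)) {
      return(mutate(row, tf_gene_id = NA_character_, tf_total_fpkm = NA_real_,
                    tf_deg_class = NA_character_, tf_unmapped = TRUE))
    }
    total <- genes$fpkm_group1 + genes$fpkm_group2
    best <- which.max(total)
    mutate(row,
      tf_gene_id = paste(genes$gene_id, collapse = ";"),
      tf_total_fpkm = max(total),
      tf_deg_class = genes$deg_class[best],
      tf_unmapped = FALSE
    )
  }) |> list_rbind()
  annotated |>
    filter(.data$tf_unmapped | .data$tf_total_fpkm >= fpkm_cutoff)
}
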