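#' Pipeline configuration
#'
#' Collects input paths, parameters and thresholds for [run_pipeline()].
#' Can also be loaded from a YAML file with [read_pipeline_config()]; every
#' run writes its resolved configuration beside the outputs for provenance.
#'
#' @param methylation_paths Tibble or data frame with `path`, `group`,
#'   `replicate` (as returned by [write_methylation_counts()]).
#' @param genome_path Genome FASTA.
#' @param genes_path Gene models (GTF).
#' @param cgi_path,repeats_path Optional BED3 annotations.
#' @param expression_path Expression TSV.
#' @param atac_path Optional ATAC peak BED6+2; when `NULL` the chromatin and
#'   triple-integration stages are skipped.
#' @param pfm_path Optional JASPAR PFM file; when `NULL` the motif stage is
#'   skipped.
#' @param dmr A [dmr_params()].
#' @param annotation An [annotation_params()].
#' @param log2fc_cutoff,q_cutoff DEG thresholds (defaults 0.4, 0.05).
#' @param atac_q_cutoff Peak significance threshold (default 0.05).
#' @param tf_fpkm_cutoff TF expression filter (default 1 FPKM).
#' @param motif_p_threshold Motif hit p-value cutoff (default 1e-4).
#' @param null_draws Random-placement draws for the distribution null.
#' @param seed Seed for every stochastic stage (null draws, shuffles).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(methylation_paths, genome_path, genes_path,
                            expression_path, atac_path = NULL,
                            cgi_path = NULL, repeats_path = NULL,
                            pfm_path = NULL,
                            dmr = dmr_params(),
                            annotation = annotation_params(),
                            log2fc_cutoff = 0.4, q_cutoff = 0.05,
                            atac_q_cutoff = 0.05, tf_fpkm_cutoff = 1,
                            motif_p_threshold = 1e-4,
                            null_draws = 50, seed = 1L) {
  structure(
    list(
      methylation_paths = as_tibble(methylation_paths),
      genome_path = genome_path, genes_path = genes_path,
      expression_path = expression_path, atac_path = atac_path,
      cgi_path = cgi_path, repeats_path = repeats_path, pfm_path = pfm_path,
      dmr = dmr, annotation = annotation,
      log2fc_cutoff = log2fc_cutoff, q_cutoff = q_cutoff,
      atac_q_cutoff = atac_q_cutoff, tf_fpkm_cutoff = tf_fpkm_cutoff,
      motif_p_threshold = motif_p_threshold,
      null_draws = null_draws, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()] (parameter blocks `dmr` and `annotation` are nested
#'   maps).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$methylation_paths <- bind_rows(lapply(raw$methylation_paths, as_tibble))
  if (!is.null(raw$dmr)) raw$dmr <- do.call(dmr_params, raw$dmr)
  if (!is.null(raw$annotation)) {
    raw$annotation <- do.call(annotation_params, raw$annotation)
  }
  do.call(pipeline_config, raw)
}

#' Write a synthetic dataset to disk
#'
#' Materialises a full synthetic study (genome FASTA, gene GTF, CGI/repeat
#' BEDs, per-replicate methylation count files, expression TSV, ATAC BED6+2
#' and planted-truth TSV) and returns a ready [pipeline_config()] pointing
#' at the files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param ... Extra arguments passed to [pipeline_config()] (e.g.
#'   `pfm_path`).
#' @return A `pipeline_config` with an extra `truth_path` element recorded
#'   in its `atac_path` sibling list.
#' @export
simulate_dataset <- function(config, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- make_annotation(config)
  sim <- simulate_methylomes(config, ann)
  expr <- simulate_expression(config, ann$genes, sim$truth)
  peaks <- simulate_atac(config, ann, sim$truth)
  write_genome_fasta(ann$genome, file.path(dir, "genome.fa"))
  write_genes_gtf(ann$genes, file.path(dir, "genes.gtf"))
  write_bed3(ann$cgi, file.path(dir, "cgi.bed"))
  write_bed3(ann$repeats, file.path(dir, "repeats.bed"))
  meth <- write_methylation_counts(sim$records, dir)
  write_expression_table(
    select(expr, -"true_avg_diff_methyl"),
    file.path(dir, "expression.tsv")
  )
  write_atac_peaks(peaks, file.path(dir, "atac_peaks.bed"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  pipeline_config(
    methylation_paths = meth,
    genome_path = file.path(dir, "genome.fa"),
    genes_path = file.path(dir, "genes.gtf"),
    cgi_path = file.path(dir, "cgi.bed"),
    repeats_path = file.path(dir, "repeats.bed"),
    expression_path = file.path(dir, "expression.tsv"),
    atac_path = file.path(dir, "atac_peaks.bed"),
    seed = config$seed,
    ...
  )
}

#' Run the integrative methylation pipeline
#'
#' Executes every stage on the configured inputs: DMR calling, genomic
#' annotation with the random-placement null and the hyper/hypo distribution
#' comparison, expression integration (correlation and quadrant association
#' at both scopes), chromatin integration, triple integration and motif
#' enrichment. All output tables, a JSON summary of every headline statistic
#' and the resolved configuration are written under `outdir`. Stages whose
#' inputs are not configured are skipped with a notice; an error in any
#' stage aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with every stage result and `summary`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  summary <- list(seed = config$seed)

  inputs <- stage("read_inputs", {
    mp <- config$methylation_paths
    list(
      records = read_methylation_counts(mp$path, mp$group, mp$replicate),
      genome = read_genome_fasta(config$genome_path),
      genes = read_gene_models(config$genes_path, "gtf"),
      cgi = if (!is.null(config$cgi_path)) {
        readr::read_tsv(config$cgi_path, col_names = c("chrom", "start", "end"),
                        col_types = "cii", progress = FALSE)
      },
      repeats = if (!is.null(config$repeats_path)) {
        readr::read_tsv(config$repeats_path, col_names = c("chrom", "start", "end"),
                        col_types = "cii", progress = FALSE)
      },
      expression = read_expression_table(config$expression_path),
      peaks = if (!is.null(config$atac_path)) read_atac_peaks(config$atac_path),
      pfms = if (!is.null(config$pfm_path)) read_jaspar_pfms(config$pfm_path)
    )
  })
  chrom_sizes <- tibble(chrom = names(inputs$genome),
                        size = nchar(inputs$genome))

  dmr_res <- stage("dmr_calling", dmr_pipeline(inputs$records, config$dmr))
  dmrs <- dmr_res$dmrs
  summary$n_dmrs <- nrow(dmrs)
  summary$n_hyper <- sum(dmrs$direction == "hyper")
  summary$n_hypo <- sum(dmrs$direction == "hypo")

  ann_res <- stage("genome_annotation", {
    shores <- if (!is.null(inputs$cgi)) {
      cgi_shores(inputs$cgi, chrom_sizes, config$annotation$cgi_shore)
    }
    index <- build_feature_index(inputs$genes, inputs$cgi, shores,
                                 inputs$repeats, config$annotation, chrom_sizes)
    annotated <- annotate_intervals(dmrs, index, config$annotation)
    null_test <- if (nrow(dmrs) > 0) {
      random_null_test(annotated$category, chrom_sizes,
                       dmrs$end - dmrs$start, index, config$annotation,
                       n_draws = config$null_draws, seed = config$seed + 11L)
    }
    hyper_hypo <- if (nrow(dmrs) > 0 &&
                      all(c("hyper", "hypo") %in% annotated$direction)) {
      compare_hyper_hypo_distributions(annotated)
    }
    list(index = index, annotated = annotated, null_test = null_test,
         hyper_hypo = hyper_hypo)
  })
  if (!is.null(ann_res$null_test)) {
    summary$null_chisq <- ann_res$null_test$statistic
    summary$null_p <- ann_res$null_test$p_value
  }
  if (!is.null(ann_res$hyper_hypo)) {
    summary$hyper_hypo_chisq <- ann_res$hyper_hypo$statistic
    summary$hyper_hypo_p <- ann_res$hyper_hypo$p_value
  }

  expr_res <- stage("expression_integration", {
    degs <- classify_degs(inputs$expression, config$log2fc_cutoff,
                          config$q_cutoff)
    links <- map_dmr_to_genes(dmrs, inputs$genes, config$annotation,
                              chrom_sizes)
    per_scope <- lapply(
      c(promoter_and_genebody = "promoter_and_genebody",
        promoter_only = "promoter_only"),
      function(scope) {
        summaries <- average_gene_methylation(dmrs, links, scope)
        deg_only <- filter(degs, .data$deg_class != "not_de")
        correlation <- tryCatch(
          correlate_methylation_expression(summaries, deg_only),
          error = function(e) NULL
        )
        association <- methylation_expression_association(summaries, degs)
        list(summaries = summaries, correlation = correlation,
             association = association)
      }
    )
    list(degs = degs, links = links, scopes = per_scope)
  })
  for (scope in names(expr_res$scopes)) {
    sc <- expr_res$scopes[[scope]]
    if (!is.null(sc$correlation)) {
      summary[[paste0("expr_r_", scope)]] <- sc$correlation$r
      summary[[paste0("expr_r_p_", scope)]] <- sc$correlation$p_value
      summary[[paste0("expr_n_", scope)]] <- sc$correlation$n
    }
    summary[[paste0("expr_chisq_", scope)]] <- sc$association$statistic
    summary[[paste0("expr_chisq_p_", scope)]] <- sc$association$p_value
  }

  atac_res <- NULL
  triple_res <- NULL
  if (is.null(inputs$peaks)) {
    rlang::inform("No ATAC peaks configured; skipping chromatin and triple integration.")
  } else {
    atac_res <- stage("chromatin_integration", {
      peaks <- classify_peaks(inputs$peaks, config$atac_q_cutoff)
      overlaps <- overlap_dmrs_with_peaks(dmrs, peaks)
      stats <- methylation_accessibility_stats(overlaps, config$atac_q_cutoff)
      list(peaks = peaks, overlaps = overlaps, stats = stats)
    })
    summary$n_dmrs_in_open_chromatin <- atac_res$overlaps$n_dmrs_overlapping
    summary$atac_chisq <- atac_res$stats$statistic
    summary$atac_chisq_p <- atac_res$stats$p_value
    if (!is.null(atac_res$stats$correlation_all)) {
      summary$atac_r <- atac_res$stats$correlation_all$r
      summary$atac_r_p <- atac_res$stats$correlation_all$p_value
    }
    if (!is.null(atac_res$stats$correlation_significant)) {
      summary$atac_r_significant <- atac_res$stats$correlation_significant$r
    }

    triple_res <- stage("triple_integration", {
      lapply(
        c(promoter_and_genebody = "promoter_and_genebody",
          promoter_only = "promoter_only"),
        function(scope) {
          sites <- classify_triple_sites(atac_res$overlaps, expr_res$links,
                                         expr_res$degs, scope)
          assoc <- if (nrow(sites) > 0) triple_association(sites)
          list(sites = sites, association = assoc,
               rollup = per_gene_rollup(sites))
        }
      )
    })
    for (scope in names(triple_res)) {
      tr <- triple_res[[scope]]
      summary[[paste0("triple_n_sites_", scope)]] <- nrow(tr$sites)
      summary[[paste0("triple_n_genes_", scope)]] <- nrow(tr$rollup)
      if (!is.null(tr$association)) {
        summary[[paste0("triple_chisq_", scope)]] <- tr$association$statistic
        summary[[paste0("triple_chisq_p_", scope)]] <- tr$association$p_value
      }
    }
  }

  motif_res <- NULL
  if (is.null(inputs$pfms)) {
    rlang::inform("No PFM file configured; skipping motif analysis.")
  } else {
    motif_res <- stage("motif_analysis", {
      groups <- dmr_sequence_groups(dmrs, expr_res$links, expr_res$degs,
                                    inputs$genome)
      lapply(groups, function(seqs) {
        if (length(seqs) == 0) return(NULL)
        control <- shuffle_sequences(seqs, seed = config$seed + 21L)
        enr <- motif_enrichment(
          seqs, control, inputs$pfms, config$motif_p_threshold,
          sequence_genes = stats::setNames(attr(seqs, "gene_id"), names(seqs))
        )
        annotate_tf_expression(enr, expr_res$degs, config$tf_fpkm_cutoff)
      })
    })
    for (grp in names(motif_res)) {
      if (!is.null(motif_res[[grp]]) && nrow(motif_res[[grp]]) > 0) {
        summary[[paste0("motif_top_", grp)]] <- motif_res[[grp]]$motif_id[1]
        summary[[paste0("motif_top_adjp_", grp)]] <- motif_res[[grp]]$adjusted_p[1]
      }
    }
  }

  stage("write_outputs", {
    readr::write_tsv(bind_cols(dmrs, select(ann_res$annotated, "category")),
                     file.path(outdir, "dmrs_annotated.tsv"), progress = FALSE)
    if (!is.null(ann_res$null_test)) {
      readr::write_tsv(ann_res$null_test$comparison,
                       file.path(outdir, "dmr_distribution_vs_random.tsv"),
                       progress = FALSE)
    }
    for (scope in names(expr_res$scopes)) {
      readr::write_tsv(expr_res$scopes[[scope]]$summaries,
                       file.path(outdir, paste0("gene_methylation_", scope, ".tsv")),
                       progress = FALSE)
    }
    if (!is.null(atac_res)) {
      readr::write_tsv(atac_res$stats$records,
                       file.path(outdir, "dmr_atac_overlaps.tsv"),
                       progress = FALSE)
    }
    if (!is.null(triple_res)) {
      readr::write_tsv(triple_res$promoter_and_genebody$sites,
                       file.path(outdir, "triple_sites.tsv"), progress = FALSE)
      readr::write_tsv(triple_res$promoter_and_genebody$rollup,
                       file.path(outdir, "triple_gene_rollup.tsv"),
                       progress = FALSE)
    }
    if (!is.null(motif_res)) {
      for (grp in names(motif_res)) {
        if (!is.null(motif_res[[grp]])) {
          readr::write_tsv(motif_res[[grp]],
                           file.path(outdir, paste0("motif_enrichment_", grp, ".tsv")),
                           progress = FALSE)
        }
      }
    }
    write_resolved_config(config, file.path(outdir, "resolved_config.yaml"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  })

  invisible(list(
    inputs = inputs, dmr = dmr_res, annotation = ann_res,
    expression = expr_res, chromatin = atac_res, triple = triple_res,
    motif = motif_res, summary = summary
  ))
}

write_resolved_config <- function(config, path) {
  out <- unclass(config)
  out$methylation_paths <- purrr::transpose(as.list(out$methylation_paths))
  out$dmr <- unclass(out$dmr)
  out$annotation <- unclass(out$annotation)
  yaml::write_yaml(out, path)
}
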