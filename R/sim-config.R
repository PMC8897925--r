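#' Configuration for the synthetic multi-omics generator
#'
#' Bundles every knob of the toy-data generator: a Mb-scale genome with a
#' controlled CpG density, non-overlapping gene models, CpG islands and
#' repeats, replicate methylomes with planted differentially methylated
#' regions (DMRs), and expression/accessibility tables coupled to the planted
#' methylation effects. Defaults encode the study conditions the package is
#' validated under: 0.4 methylation-proportion effects over 200 bp spans,
#' 30x mean coverage, three replicates per group, beta-binomial
#' overdispersion phi = 0.1, and coupling slopes/noise calibrated by closed
#' form so that the generated methylation/expression correlation targets
#' r = -0.4 and the methylation/accessibility correlation targets r = -0.86.
#'
#' @param genome_length Total genome length in bp.
#' @param n_chroms Number of pseudo-chromosomes the genome is split into.
#' @param cpg_rate Target CpG dinucleotide density per bp of genome.
#' @param n_genes Number of non-overlapping gene models to place.
#' @param n_planted_dmrs Number of planted DMRs. Each is attached to a
#'   distinct random gene (promoter or gene body) while genes last; any
#'   excess is placed in intergenic space.
#' @param dmr_span_range Length-2 numeric, min/max span (bp) of planted DMRs.
#' @param effect_size Methylation-proportion shift of group 2 inside a
#'   planted DMR; sign is drawn per DMR with probability `hyper_fraction`.
#' @param hyper_fraction Probability a planted DMR is hypermethylated
#'   (positive effect) in group 2.
#' @param base_methylation Background CpG methylation proportion.
#' @param dispersion_phi Beta-binomial overdispersion across replicates,
#'   in `[0, 1)`; 0 is exactly binomial.
#' @param coverage_mean Mean Poisson read coverage per CpG per replicate
#'   (floored at 1 read).
#' @param n_replicates_per_group Biological replicates per group.
#' @param expr_coupling_slope log2 fold-change units of expression per unit of
#'   average methylation difference for genes hosting planted DMRs.
#' @param expr_noise_sd Gaussian noise sd added to gene log2 fold changes.
#' @param atac_coupling_slope Accessibility log2 fold-change units per unit of
#'   planted methylation effect.
#' @param atac_noise_sd Gaussian noise sd added to peak log2 fold changes.
#' @param n_background_peaks Accessibility peaks placed away from planted
#'   DMRs, with noise-only fold changes.
#' @param seed Integer seed; with a fixed seed all generator outputs are
#'   reproducible byte for byte.
#'
#' @return A list of class `sim_config`.
#' @seealso [coupling_noise_for_r()] for the closed form behind the default
#'   coupling noise values.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 2e5, n_genes = 20, n_planted_dmrs = 8)
#' ann <- make_annotation(cfg)
#' nrow(ann$genes)
sim_config <- function(genome_length = 1e6,
                       n_chroms = 1,
                       cpg_rate = 0.04,
                       n_genes = 200,
                       n_planted_dmrs = 40,
                       dmr_span_range = c(200, 200),
                       effect_size = 0.4,
                       hyper_fraction = 0.5,
                       base_methylation = 0.5,
                       dispersion_phi = 0.1,
                       coverage_mean = 30,
                       n_replicates_per_group = 3,
                       expr_coupling_slope = -2,
                       expr_noise_sd = NULL,
                       atac_coupling_slope = -1,
                       atac_noise_sd = NULL,
                       n_background_peaks = 200,
                       seed = 1L) {
  check_pos(genome_length, "genome_length")
  check_pos(n_chroms, "n_chroms")
  check_prob(cpg_rate, "cpg_rate")
  check_pos(n_genes, "n_genes", strict = FALSE)
  check_pos(n_planted_dmrs, "n_planted_dmrs", strict = FALSE)
  if (length(dmr_span_range) != 2 || any(dmr_span_range <= 0) ||
      dmr_span_range[1] > dmr_span_range[2]) {
    abort("`dmr_span_range` must be an increasing pair of positive spans.")
  }
  check_prob(base_methylation, "base_methylation")
  check_prob(hyper_fraction, "hyper_fraction")
  if (dispersion_phi < 0 || dispersion_phi >= 1) {
    abort("`dispersion_phi` must lie in [0, 1).")
  }
  check_pos(coverage_mean, "coverage_mean")
  check_pos(n_replicates_per_group, "n_replicates_per_group")
  # Default coupling noise targets r = -0.4 (expression) and r = -0.86
  # (accessibility) via the closed form; a zero slope means no coupling and
  # the noise sd is then just the marginal log2FC spread.
  if (is.null(expr_noise_sd)) {
    expr_noise_sd <- if (expr_coupling_slope == 0) 1 else
      coupling_noise_for_r(0.4 * sign(expr_coupling_slope),
                           effect_size, expr_coupling_slope)
  }
  if (is.null(atac_noise_sd)) {
    atac_noise_sd <- if (atac_coupling_slope == 0) 0.5 else
      coupling_noise_for_r(0.86 * sign(atac_coupling_slope),
                           effect_size, atac_coupling_slope)
  }
  check_pos(expr_noise_sd, "expr_noise_sd", strict = FALSE)
  check_pos(atac_noise_sd, "atac_noise_sd", strict = FALSE)
  structure(
    list(
      genome_length = as.integer(genome_length),
      n_chroms = as.integer(n_chroms),
      cpg_rate = cpg_rate,
      n_genes = as.integer(n_genes),
      n_planted_dmrs = as.integer(n_planted_dmrs),
      dmr_span_range = as.integer(dmr_span_range),
      effect_size = effect_size,
      hyper_fraction = hyper_fraction,
      base_methylation = base_methylation,
      dispersion_phi = dispersion_phi,
      coverage_mean = coverage_mean,
      n_replicates_per_group = as.integer(n_replicates_per_group),
      expr_coupling_slope = expr_coupling_slope,
      expr_noise_sd = expr_noise_sd,
      atac_coupling_slope = atac_coupling_slope,
      atac_noise_sd = atac_noise_sd,
      n_background_peaks = as.integer(n_background_peaks),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Noise level that yields a target correlation under linear coupling
#'
#' For responses `y = slope * x + e` with `e ~ N(0, sd^2)` and predictor
#' values `x = +/- effect_size` (balanced signs, so `sd(x) = effect_size`),
#' the population Pearson correlation is
#' `r = sign(slope) / sqrt(1 + sd^2 / (slope^2 * effect_size^2))`. Inverting
#' for `sd` gives the noise level at which the generated columns correlate at
#' `target_r` in expectation.
#'
#' @param target_r Target Pearson correlation (sign must match `slope`).
#' @param effect_size Magnitude of the planted methylation effects.
#' @param slope Coupling slope.
#' @return Gaussian noise standard deviation.
#' @export
#' @examples
#' coupling_noise_for_r(-0.4, effect_size = 0.4, slope = -2)
coupling_noise_for_r <- function(target_r, effect_size, slope) {
  if (abs(target_r) <= 0 || abs(target_r) >= 1) {
    abort("`target_r` must have magnitude in (0, 1).")
  }
  if (sign(target_r) != sign(slope)) {
    abort("`target_r` and `slope` must share a sign.")
  }
  abs(slope) * effect_size * sqrt(1 / target_r^2 - 1)
}
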