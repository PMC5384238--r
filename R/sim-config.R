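#' Simulation configuration for the synthetic multi-tumour cohort
#'
#' Parameterizes \code{\link{generate_cohort}}.  Defaults describe the
#' study conditions the pipeline is validated under: 15 tumour types, 500
#' genes, 150 miRNAs, negative-binomial counts with dispersion 0.1 around
#' a log2 baseline of 5, planted differential expression of +/-2 log2
#' units recurring in 10 tumour types, 30 planted repressive pairs with
#' slope -0.5, copy-number and methylation confounding, and stage-linked
#' exponential survival with a per-unit log hazard ratio of 0.7 on
#' selected genes.
#'
#' @param n_tumour_types number of tumour types (>= 1).
#' @param n_genes,n_mirnas feature counts.
#' @param n_controls_per_type,n_tumours_per_type samples per type.
#' @param baseline_mean_log2 log2 of the mean count at a nominal 1e6
#'   library; per-feature baselines scatter around it.
#' @param dispersion NB dispersion phi (var = mu + phi mu^2), >= 0.
#' @param planted_de_fraction fraction of features carrying planted DE,
#'   in [0, 1).
#' @param planted_lfc planted log2 fold change (tumour vs control).
#' @param n_planted_pairs number of planted repressive miRNA-gene pairs.
#' @param pair_slope log2-RPKM gene change per centred log2-RPKM miRNA
#'   unit; must be <= 0 (repression).
#' @param planted_recurrence number of tumour types each planted feature
#'   is DE in (<= n_tumour_types).
#' @param cna_effect log2 expression shift per copy-number level.
#' @param met_effect log2 expression shift per mean M-value unit.
#' @param probes_per_gene methylation probes simulated per gene (>= 0).
#' @param survival_gene_loghr true per-unit (log2 expression z-score)
#'   natural-log hazard ratio planted on the survival genes.
#' @param censor_rate expected censoring fraction, in (0, 1).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration including the seed.
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_tumour_types = 15,
                       n_genes = 500,
                       n_mirnas = 150,
                       n_controls_per_type = 12,
                       n_tumours_per_type = 40,
                       baseline_mean_log2 = 5,
                       dispersion = 0.1,
                       planted_de_fraction = 0.15,
                       planted_lfc = 2,
                       n_planted_pairs = 30,
                       pair_slope = -0.5,
                       planted_recurrence = 10,
                       cna_effect = 0.3,
                       met_effect = 0.2,
                       probes_per_gene = 3,
                       survival_gene_loghr = 0.7,
                       censor_rate = 0.4,
                       seed = 1L) {
  cfg <- list(n_tumour_types = n_tumour_types, n_genes = n_genes,
              n_mirnas = n_mirnas,
              n_controls_per_type = n_controls_per_type,
              n_tumours_per_type = n_tumours_per_type,
              baseline_mean_log2 = baseline_mean_log2,
              dispersion = dispersion,
              planted_de_fraction = planted_de_fraction,
              planted_lfc = planted_lfc,
              n_planted_pairs = n_planted_pairs,
              pair_slope = pair_slope,
              planted_recurrence = planted_recurrence,
              cna_effect = cna_effect, met_effect = met_effect,
              probes_per_gene = probes_per_gene,
              survival_gene_loghr = survival_gene_loghr,
              censor_rate = censor_rate, seed = as.integer(seed))

  count_fields <- c("n_tumour_types", "n_genes", "n_mirnas",
                    "n_controls_per_type", "n_tumours_per_type")
  for (f in count_fields)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("invalid configuration field '", f, "': must be a count >= 1")
  for (f in c("n_planted_pairs", "probes_per_gene", "planted_recurrence"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("invalid configuration field '", f, "': must be a count >= 0")
  if (cfg$dispersion < 0)
    stop("invalid configuration field 'dispersion': must be >= 0")
  if (cfg$planted_de_fraction < 0 || cfg$planted_de_fraction >= 1)
    stop("invalid configuration field 'planted_de_fraction': ",
         "must lie in [0, 1)")
  if (cfg$pair_slope > 0)
    stop("invalid configuration field 'pair_slope': planted pairs are ",
         "repressive, so pair_slope must be <= 0")
  if (cfg$planted_recurrence > cfg$n_tumour_types)
    stop("invalid configuration field 'planted_recurrence': cannot ",
         "exceed n_tumour_types")
  if (cfg$censor_rate <= 0 || cfg$censor_rate >= 1)
    stop("invalid configuration field 'censor_rate': must lie in (0, 1)")
  if (cfg$n_planted_pairs > 0 && cfg$planted_de_fraction == 0)
    stop("invalid configuration field 'n_planted_pairs': planted pairs ",
         "require planted_de_fraction > 0")
  class(cfg) <- "sim_config"
  cfg
}
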