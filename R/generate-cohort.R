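#' Generate a synthetic multi-tumour cohort with planted ground truth
#'
#' Simulates, per tumour type, gene and miRNA count matrices (controls and
#' tumours), copy-number levels, methylation beta-values, and clinical
#' tables, plus the shared target catalogue, pathway gene sets and known
#' feature/pair lists, with the statistical structure the downstream
#' pipeline assumes:
#'
#' \itemize{
#'   \item counts are negative binomial around a log-linear mean: a
#'     per-feature baseline, a planted differential-expression shift
#'     (+/- \code{planted_lfc} in the tumour samples of the types a
#'     feature is planted in), \code{cna_effect} per copy-number level,
#'     \code{met_effect} per unit of the gene's mean methylation M-value,
#'     and, for planted pair genes, \code{pair_slope} times the partner
#'     miRNA's centred log2-RPKM;
#'   \item library sizes are log-normal (sigma 0.3) around 1e6, so the
#'     CPM/TMM steps have real work to do;
#'   \item copy-number levels are drawn symmetrically in -2..2 and
#'     methylation from a logit-normal per probe, both for tumour samples
#'     only (control samples carry the expected value of these effects, so
#'     confounders shift expression without faking group differences);
#'   \item survival times are exponential with hazard scaled by a stage
#'     effect and the planted genes' expression z-scores, with independent
#'     exponential censoring tuned to \code{censor_rate}; one tumour type
#'     is "PRAD-like" and carries Gleason scores instead of stages;
#'   \item the target catalogue holds every planted pair at genomic
#'     agreement >= 2, plus 10x as many decoy edges: half at agreement 1
#'     (rejected by the agreement filter) and half non-interacting at
#'     agreement >= 2 (candidates the statistics must reject).
#' }
#'
#' The cohort is a deterministic function of the configuration: the master
#' seed drives one RNG stream from which per-tumour-type sub-seeds are
#' derived.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{cohort} and \code{truth}.
#'   \code{cohort}: \code{types} (named list with per-type
#'   \code{genes}/\code{mirnas} count matrices, \code{cna}, \code{met_beta},
#'   \code{probe_map}, \code{clinical}), \code{gene_lengths},
#'   \code{mirna_lengths}, \code{targets}, \code{pathways},
#'   \code{known_pairs}, \code{known_genes}, \code{known_mirnas},
#'   \code{prad_like}.  \code{truth}: \code{de_genes_by_type},
#'   \code{de_mirnas_by_type} (data.frames with directions),
#'   \code{planted_pairs}, \code{survival_genes} (named log-HR vector).
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)

  type_names <- sprintf("TT%02d", seq_len(cfg$n_tumour_types))
  prad_like <- type_names[1]
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  mir_ids <- sprintf("hsa-miR-%d", 1000 + seq_len(cfg$n_mirnas))

  gene_lengths <- setNames(round(runif(cfg$n_genes, 500, 5000)), gene_ids)
  mirna_lengths <- setNames(rep(22, cfg$n_mirnas), mir_ids)

  gene_base <- setNames(rnorm(cfg$n_genes, cfg$baseline_mean_log2, 1.5),
                        gene_ids)
  mir_base <- setNames(rnorm(cfg$n_mirnas, cfg$baseline_mean_log2 + 3, 1.5),
                       mir_ids)

  plan <- .plant_truth(cfg, gene_ids, mir_ids, type_names)
  pathways <- .make_pathways(gene_ids, plan)
  targets <- .make_targets(cfg, gene_ids, mir_ids, plan)
  surv_genes <- plan$survival_genes

  type_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_tumour_types)
  stage_effect <- 0.8    # log-hazard increment for bad prognosis
  h0 <- 1 / 730          # baseline hazard (events on a ~2-year scale, days)

  types <- list()
  for (ti in seq_along(type_names)) {
    tt <- type_names[ti]
    set.seed(type_seeds[ti])
    types[[tt]] <- .simulate_type(cfg, tt, ti, gene_ids, mir_ids,
                                  gene_base, mir_base, gene_lengths,
                                  mirna_lengths, plan, surv_genes,
                                  stage_effect, h0,
                                  gleason = tt == prad_like)
  }

  truth <- list(
    de_genes_by_type = plan$de_genes_by_type,
    de_mirnas_by_type = plan$de_mirnas_by_type,
    planted_pairs = plan$planted_pairs,
    survival_genes = surv_genes,
    survival_types = plan$survival_types)

  cohort <- list(types = types, gene_lengths = gene_lengths,
                 mirna_lengths = mirna_lengths, targets = targets,
                 pathways = pathways, known_pairs = plan$known_pairs,
                 known_genes = plan$known_genes,
                 known_mirnas = plan$known_mirnas,
                 prad_like = prad_like, config = cfg)
  list(cohort = cohort, truth = truth)
}

## Decide which features are planted DE, in which types, with which
## directions, and which of them form repressive pairs / survival genes /
## known lists.  Uses the master RNG stream.
.plant_truth <- function(cfg, gene_ids, mir_ids, type_names) {
  n_pg <- round(cfg$planted_de_fraction * cfg$n_genes)
  n_pm <- round(cfg$planted_de_fraction * cfg$n_mirnas)
  if (cfg$n_planted_pairs > 0) {
    n_pg <- max(n_pg, cfg$n_planted_pairs)
    n_pm <- max(n_pm, min(cfg$n_planted_pairs, cfg$n_mirnas))
  }
  planted_genes <- if (n_pg > 0) sample(gene_ids, n_pg) else character(0)
  planted_mirs <- if (n_pm > 0) sample(mir_ids, n_pm) else character(0)

  pair_genes <- head(planted_genes, cfg$n_planted_pairs)
  pair_mirs <- if (cfg$n_planted_pairs > 0)
    planted_mirs[(seq_len(cfg$n_planted_pairs) - 1) %% n_pm + 1]
  else character(0)
  planted_pairs <- data.frame(mirna = pair_mirs, gene = pair_genes,
                              stringsAsFactors = FALSE)

  # direction per planted feature; pair members get opposite directions
  gene_dir <- setNames(sample(c("up", "down"), n_pg, replace = TRUE),
                       planted_genes)
  mir_dir <- setNames(sample(c("up", "down"), n_pm, replace = TRUE),
                      planted_mirs)
  if (cfg$n_planted_pairs > 0) {
    half <- seq_len(cfg$n_planted_pairs) %% 2 == 0
    mir_dir[pair_mirs] <- ifelse(half, "down", "up")[
      match(pair_mirs, pair_mirs)]
    gene_dir[pair_genes] <- ifelse(mir_dir[pair_mirs] == "up",
                                   "down", "up")
  }

  # tumour-type sets: pair members share one set so both recur together
  pick_types <- function() sample(type_names, cfg$planted_recurrence)
  gene_types <- lapply(planted_genes, function(g) pick_types())
  names(gene_types) <- planted_genes
  mir_types <- lapply(planted_mirs, function(m) pick_types())
  names(mir_types) <- planted_mirs
  if (cfg$n_planted_pairs > 0) {
    for (i in seq_len(cfg$n_planted_pairs)) {
      shared <- pick_types()
      gene_types[[pair_genes[i]]] <- shared
      mir_types[[pair_mirs[i]]] <- shared
    }
  }

  to_by_type <- function(ids, dirs, type_sets) {
    out <- lapply(type_names, function(tt) {
      sel <- vapply(ids, function(f) tt %in% type_sets[[f]], logical(1))
      data.frame(feature_id = ids[sel], direction = unname(dirs[ids[sel]]),
                 stringsAsFactors = FALSE)
    })
    names(out) <- type_names
    out
  }

  # survival effects are tumour-type-specific (each gene drives hazard in
  # a handful of types), mirroring the type-restricted survival
  # associations seen in practice and keeping per-type hazards from being
  # dominated by many simultaneous gene effects
  n_surv <- min(8, cfg$n_planted_pairs)
  survival_genes <- setNames(rep(cfg$survival_gene_loghr, n_surv),
                             head(pair_genes, n_surv))
  survival_types <- lapply(names(survival_genes), function(g)
    sample(type_names, min(5, cfg$n_tumour_types)))
  names(survival_types) <- names(survival_genes)

  known_genes <- unique(c(pair_genes,
                          sample(planted_genes,
                                 min(n_pg, max(0, n_pg - 5))),
                          sample(setdiff(gene_ids, planted_genes),
                                 min(10, cfg$n_genes - n_pg))))
  known_mirs <- unique(c(pair_mirs,
                         sample(setdiff(mir_ids, planted_mirs),
                                min(5, cfg$n_mirnas - n_pm))))
  known_pairs <- planted_pairs[seq_len(floor(cfg$n_planted_pairs / 2)), ,
                               drop = FALSE]

  list(planted_genes = planted_genes, planted_mirs = planted_mirs,
       gene_dir = gene_dir, mir_dir = mir_dir,
       gene_types = gene_types, mir_types = mir_types,
       planted_pairs = planted_pairs,
       pair_of_gene = setNames(pair_mirs, pair_genes),
       de_genes_by_type = to_by_type(planted_genes, gene_dir, gene_types),
       de_mirnas_by_type = to_by_type(planted_mirs, mir_dir, mir_types),
       survival_genes = survival_genes, survival_types = survival_types,
       known_genes = known_genes, known_mirnas = known_mirs,
       known_pairs = known_pairs)
}

## Seven hallmark pathways; planted pair genes are always members so the
## pathway-restricted pairing universe contains them, planted DE genes are
## over-represented, and overlap between pathways is allowed.
.make_pathways <- function(gene_ids, plan) {
  nm <- c("apoptosis", "necrosis", "senescence", "ddr", "cell_cycle",
          "dna_replication", "telomere_elongation")
  n <- length(gene_ids)
  size <- max(5, round(n * 0.12))
  planted <- plan$planted_genes
  w <- ifelse(gene_ids %in% planted, 4, 1)
  sets <- lapply(seq_along(nm), function(i)
    sample(gene_ids, size, prob = w))
  names(sets) <- nm
  pair_genes <- plan$planted_pairs$gene
  if (length(pair_genes) > 0) {
    slot <- (seq_along(pair_genes) - 1) %% length(nm) + 1
    for (i in seq_along(pair_genes))
      sets[[slot[i]]] <- unique(c(sets[[slot[i]]], pair_genes[i]))
  }
  sets
}

## Target catalogue: planted pairs at agreement 2..5 plus 10x decoys,
## half at agreement 1 (any edge) and half non-interacting at >= 2.
.make_targets <- function(cfg, gene_ids, mir_ids, plan) {
  planted <- plan$planted_pairs
  n_planted <- nrow(planted)
  planted_df <- if (n_planted > 0)
    data.frame(mirna = planted$mirna, gene = planted$gene,
               agreement = sample(2:5, n_planted, replace = TRUE),
               stringsAsFactors = FALSE)
  else data.frame(mirna = character(0), gene = character(0),
                  agreement = integer(0), stringsAsFactors = FALSE)

  n_decoy <- 10 * max(n_planted, 5)
  decoys <- data.frame(
    mirna = sample(mir_ids, n_decoy, replace = TRUE),
    gene = sample(gene_ids, n_decoy, replace = TRUE),
    stringsAsFactors = FALSE)
  planted_key <- pair_key(planted_df$mirna, planted_df$gene)
  decoys <- decoys[!pair_key(decoys$mirna, decoys$gene) %in% planted_key, ,
                   drop = FALSE]
  decoys <- decoys[!duplicated(pair_key(decoys$mirna, decoys$gene)), ,
                   drop = FALSE]
  half <- seq_len(nrow(decoys)) <= nrow(decoys) / 2
  decoys$agreement <- ifelse(half, 1L,
                             sample(2:4, nrow(decoys), replace = TRUE))
  out <- rbind(planted_df, decoys)
  rownames(out) <- NULL
  out
}

## Simulate one tumour type under its own sub-seed.
.simulate_type <- function(cfg, tt, ti, gene_ids, mir_ids, gene_base,
                           mir_base, gene_lengths, mirna_lengths, plan,
                           surv_genes, stage_effect, h0, gleason) {
  n_c <- cfg$n_controls_per_type
  n_t <- cfg$n_tumours_per_type
  n <- n_c + n_t
  sample_ids <- sprintf("%s_S%03d", tt, seq_len(n))
  groups <- c(rep("control", n_c), rep("tumour", n_t))
  is_tum <- groups == "tumour"

  draw_counts <- function(eta, lib) {
    mu <- 2^eta * rep(lib, each = nrow(eta)) / 1e6
    y <- if (cfg$dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    else rpois(length(mu), lambda = mu)
    matrix(y, nrow = nrow(eta), dimnames = dimnames(eta))
  }

  # --- miRNAs ---
  lib_m <- rlnorm(n, log(1e6), 0.3)
  eta_m <- matrix(mir_base[mir_ids], nrow = cfg$n_mirnas, ncol = n,
                  dimnames = list(mir_ids, sample_ids))
  de_m <- plan$de_mirnas_by_type[[tt]]
  if (nrow(de_m) > 0) {
    shift <- ifelse(de_m$direction == "up", cfg$planted_lfc,
                    -cfg$planted_lfc)
    eta_m[de_m$feature_id, is_tum] <- eta_m[de_m$feature_id, is_tum] + shift
  }
  mir_counts <- draw_counts(eta_m, lib_m)
  mir_log_rpkm <- log_expr(rpkm(mir_counts, mirna_lengths))
  mir_centred <- mir_log_rpkm - rowMeans(mir_log_rpkm)

  # --- confounders (tumour samples only) ---
  cna <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), cfg$n_genes * n_t,
                       replace = TRUE,
                       prob = c(0.03, 0.10, 0.74, 0.10, 0.03)),
                cfg$n_genes, n_t,
                dimnames = list(gene_ids, sample_ids[is_tum]))

  n_probes <- cfg$probes_per_gene * cfg$n_genes
  if (cfg$probes_per_gene > 0) {
    probe_ids <- sprintf("cg%07d", (ti - 1) * n_probes + seq_len(n_probes))
    probe_map <- data.frame(
      probe = probe_ids,
      gene = rep(gene_ids, each = cfg$probes_per_gene),
      stringsAsFactors = FALSE)
    probe_mu <- rnorm(n_probes, 0, 1.5)
    met_m <- matrix(probe_mu, n_probes, n_t) +
      matrix(rnorm(n_probes * n_t, 0, 0.6), n_probes, n_t)
    dimnames(met_m) <- list(probe_ids, sample_ids[is_tum])
    met_beta <- 2^met_m / (1 + 2^met_m)
    # per-gene mean M per tumour sample; controls take the expected value
    gene_mean_m <- rowsum(met_m, probe_map$gene) / cfg$probes_per_gene
    gene_mean_m <- gene_mean_m[gene_ids, , drop = FALSE]
    gene_expected_m <- rowsum(probe_mu, probe_map$gene)[gene_ids, 1] /
      cfg$probes_per_gene
  } else {
    probe_map <- data.frame(probe = character(0), gene = character(0),
                            stringsAsFactors = FALSE)
    met_beta <- matrix(numeric(0), 0, n_t,
                       dimnames = list(NULL, sample_ids[is_tum]))
    gene_mean_m <- matrix(0, cfg$n_genes, n_t,
                          dimnames = list(gene_ids, sample_ids[is_tum]))
    gene_expected_m <- setNames(rep(0, cfg$n_genes), gene_ids)
  }

  # --- genes ---
  lib_g <- rlnorm(n, log(1e6), 0.3)
  eta_g <- matrix(gene_base[gene_ids], nrow = cfg$n_genes, ncol = n,
                  dimnames = list(gene_ids, sample_ids))
  de_g <- plan$de_genes_by_type[[tt]]
  if (nrow(de_g) > 0) {
    shift <- ifelse(de_g$direction == "up", cfg$planted_lfc,
                    -cfg$planted_lfc)
    eta_g[de_g$feature_id, is_tum] <- eta_g[de_g$feature_id, is_tum] + shift
  }
  met_term <- matrix(cfg$met_effect * gene_expected_m[gene_ids],
                     cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))
  met_term[, is_tum] <- cfg$met_effect * gene_mean_m
  eta_g <- eta_g + met_term
  eta_g[, is_tum] <- eta_g[, is_tum] + cfg$cna_effect * cna
  if (nrow(plan$planted_pairs) > 0) {
    pg <- plan$planted_pairs$gene
    pm <- plan$planted_pairs$mirna
    eta_g[pg, ] <- eta_g[pg, ] + cfg$pair_slope * mir_centred[pm, ]
  }
  gene_counts <- draw_counts(eta_g, lib_g)

  # --- clinical (tumour samples only) ---
  bad <- rbinom(n_t, 1, 0.4)
  lp <- stage_effect * bad
  active <- names(surv_genes)[vapply(names(surv_genes), function(g)
    tt %in% plan$survival_types[[g]], logical(1))]
  if (length(active) > 0) {
    glr <- log_expr(rpkm(gene_counts, gene_lengths))[active, is_tum,
                                                     drop = FALSE]
    z <- (glr - rowMeans(glr)) / pmax(apply(glr, 1, sd), 1e-8)
    lp <- lp + colSums(surv_genes[active] * z)
  }
  t_event <- rexp(n_t, rate = h0 * exp(lp))
  t_cens <- rexp(n_t, rate = h0 * cfg$censor_rate / (1 - cfg$censor_rate))
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  stage_raw <- if (gleason) {
    ifelse(bad == 1, sample(c("8", "9", "10"), n_t, replace = TRUE),
           sample(c("6", "7"), n_t, replace = TRUE))
  } else {
    ifelse(bad == 1,
           sample(c("Stage III", "Stage IIIA", "Stage IV", "Stage X"),
                  n_t, replace = TRUE),
           sample(c("Stage I", "Stage IB", "Stage II", "Stage IIA"),
                  n_t, replace = TRUE))
  }
  clinical <- data.frame(sample_id = sample_ids[is_tum], time = time,
                         event = event, stage_or_gleason = stage_raw,
                         stringsAsFactors = FALSE)

  list(genes = count_matrix(gene_counts, groups, tt),
       mirnas = count_matrix(mir_counts, groups, tt),
       cna = cna, met_beta = met_beta, probe_map = probe_map,
       clinical = clinical)
}
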