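#' Validate cohort inclusion rules on sample sheets
#'
#' A tumour type enters the analysis only when its control arm is large
#' enough for a reliable two-group comparison: at least 10 control
#' (healthy) samples and controls making up at least 5\% of the type's
#' total samples.  Types failing either rule are excluded with the reason
#' recorded.
#'
#' @param sample_sheets named list (tumour type -> data.frame with columns
#'   \code{sample_id}, \code{group}) or a single row-bound data.frame with
#'   a \code{tumour_type} column.
#' @param min_controls minimum control count, default 10.
#' @param min_control_frac minimum control fraction, default 0.05.
#' @return list with \code{accepted} (character vector of tumour types)
#'   and \code{report} (data.frame: type, n_control, n_total, accepted,
#'   reason).
#' @export
validate_cohort <- function(sample_sheets, min_controls = 10,
                            min_control_frac = 0.05) {
  if (is.data.frame(sample_sheets))
    sample_sheets <- split(sample_sheets, sample_sheets$tumour_type)
  rows <- lapply(names(sample_sheets), function(tt) {
    sh <- sample_sheets[[tt]]
    if (anyDuplicated(sh$sample_id))
      stop("duplicate sample ids within tumour type ", tt)
    n_control <- sum(sh$group == "control")
    n_total <- nrow(sh)
    ok_n <- n_control >= min_controls
    ok_f <- n_control / n_total >= min_control_frac
    reason <- if (ok_n && ok_f) "" else paste(
      c(if (!ok_n) sprintf("fewer than %d controls", min_controls),
        if (!ok_f) sprintf("controls below %.0f%% of samples",
                           100 * min_control_frac)),
      collapse = "; ")
    data.frame(tumour_type = tt, n_control = n_control, n_total = n_total,
               accepted = ok_n && ok_f, reason = reason,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(accepted = report$tumour_type[report$accepted], report = report)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or plain list) configuration for
#' \code{\link{run_pipeline}}: \code{input_dir} (a cohort directory for
#' \code{\link{read_cohort}}) or nothing (cohort passed in memory), plus
#' any of the threshold arguments of \code{run_pipeline} and an optional
#' \code{out_dir} and \code{seed}.  Unknown keys and out-of-range
#' thresholds are rejected by name.
#'
#' @param path YAML file path, or a named list already parsed.
#' @return validated named list of \code{run_pipeline} arguments plus
#'   optional \code{input_dir} and \code{seed}.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  allowed <- c("input_dir", "out_dir", "seed", "fdr_max", "lfc_min",
               "cpm_threshold", "min_agreement", "recurrence_threshold",
               "scan_range", "optimize_recurrence")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  chk <- function(key, lo, hi) {
    if (!is.null(cfg[[key]]) && (cfg[[key]] < lo || cfg[[key]] > hi))
      stop("configuration key '", key, "' out of range [", lo, ", ", hi, "]")
  }
  chk("fdr_max", 0, 1); chk("cpm_threshold", 0, Inf)
  chk("lfc_min", 0, Inf); chk("min_agreement", 1, Inf)
  chk("recurrence_threshold", 1, Inf)
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    stop("configuration key 'input_dir' does not exist: ", cfg$input_dir)
  cfg
}

.log_stage <- function(log, stage, n_in, n_out) {
  entry <- data.frame(stage = stage, n_in = n_in, n_out = n_out,
                      stringsAsFactors = FALSE)
  message(sprintf("[oncopair] %-28s in=%6d out=%6d", stage, n_in, n_out))
  rbind(log, entry)
}

#' Run the full integrative pipeline on a cohort
#'
#' Sequences every stage on an in-memory cohort (from
#' \code{\link{generate_cohort}} or \code{\link{read_cohort}}): cohort
#' validation, per-type differential expression of genes and miRNAs,
#' per-type pathway enrichment, cross-tumour recurrence with optional
#' threshold optimization against the known cancer feature lists,
#' inverse-expression pairing (conserved, exclusive and specificity
#' calls, novelty flags), covariate-adjusted per-type and joint pair
#' regression with global FDR, negative-pair selection, and the
#' stage-adjusted survival combination.  A structured log records the
#' in/out count of every filtering step so the full funnel can be
#' reconstructed.
#'
#' @param cohort cohort list.
#' @param fdr_max,lfc_min,cpm_threshold,min_agreement the pipeline's
#'   standard thresholds (0.05, 1, 1, 2).
#' @param recurrence_threshold recurrence cut-off; the default 8 can be
#'   replaced by the optimizer's choice with
#'   \code{optimize_recurrence = TRUE}.
#' @param scan_range thresholds scanned when optimizing, default 5:10.
#' @param optimize_recurrence when TRUE, choose the cut-off by enrichment
#'   against the known gene list (falls back to
#'   \code{recurrence_threshold} when no scanned cut-off is significant).
#' @param out_dir optional directory; when given, every stage's table is
#'   written as TSV and a manifest of output hashes is included.
#' @return list with every stage's results: \code{validation}, \code{de}
#'   (per type, genes and mirnas), \code{enrichment}, \code{recurrence}
#'   (tables, scan, thresholds), \code{pairs} (instances, conserved,
#'   exclusive, specificity, annotated), \code{regression} (all rows +
#'   selected), \code{survival} (scan + combined), \code{log},
#'   and \code{manifest} when \code{out_dir} is set.
#' @export
run_pipeline <- function(cohort,
                         fdr_max = 0.05, lfc_min = 1, cpm_threshold = 1,
                         min_agreement = 2, recurrence_threshold = 8,
                         scan_range = 5:10, optimize_recurrence = FALSE,
                         out_dir = NULL) {
  log <- data.frame(stage = character(0), n_in = integer(0),
                    n_out = integer(0), stringsAsFactors = FALSE)

  # --- validation ---
  sheets <- lapply(cohort$types, function(ty)
    data.frame(sample_id = colnames(ty$genes$counts),
               group = as.character(ty$genes$groups),
               stringsAsFactors = FALSE))
  validation <- validate_cohort(sheets)
  log <- .log_stage(log, "validate_cohort", length(cohort$types),
                    length(validation$accepted))
  types <- validation$accepted

  # --- per-type DE ---
  de_genes <- list(); de_mirnas <- list()
  de_gene_tables <- list(); de_mirna_tables <- list()
  expressed <- list()
  for (tt in types) {
    ty <- cohort$types[[tt]]
    dg <- de_analysis(ty$genes, cpm_threshold)
    dm <- de_analysis(ty$mirnas, cpm_threshold)
    de_gene_tables[[tt]] <- dg
    de_mirna_tables[[tt]] <- dm
    de_genes[[tt]] <- select_de(dg, fdr_max, lfc_min)
    de_mirnas[[tt]] <- select_de(dm, fdr_max, lfc_min)
    expressed[[tt]] <- attr(dg, "expressed")
  }
  log <- .log_stage(log, "de_genes",
                    sum(vapply(de_gene_tables, nrow, integer(1))),
                    sum(vapply(de_genes, nrow, integer(1))))
  log <- .log_stage(log, "de_mirnas",
                    sum(vapply(de_mirna_tables, nrow, integer(1))),
                    sum(vapply(de_mirnas, nrow, integer(1))))

  # --- pathway enrichment per type ---
  enrichment <- lapply(types, function(tt)
    enrich_pathways(intersect(de_genes[[tt]]$feature_id, expressed[[tt]]),
                    expressed[[tt]], cohort$pathways))
  names(enrichment) <- types

  # --- recurrence + threshold ---
  gene_rec <- recurrence_table(de_genes)
  mir_rec <- recurrence_table(de_mirnas)
  gene_scan <- NULL; mir_scan <- NULL
  thr_gene <- recurrence_threshold
  thr_mir <- recurrence_threshold
  if (optimize_recurrence) {
    gene_universe <- unique(unlist(expressed))
    opt_g <- tryCatch(
      optimize_threshold(gene_rec,
                         intersect(cohort$known_genes, gene_universe),
                         gene_universe, scan_range),
      error = function(e) NULL)
    if (!is.null(opt_g)) { thr_gene <- opt_g$threshold; gene_scan <- opt_g$scan }
    mir_universe <- unique(unlist(lapply(de_mirna_tables,
                                         function(d) d$feature_id)))
    opt_m <- tryCatch(
      optimize_threshold(mir_rec,
                         intersect(cohort$known_mirnas, mir_universe),
                         mir_universe, scan_range),
      error = function(e) NULL)
    if (!is.null(opt_m)) { thr_mir <- opt_m$threshold; mir_scan <- opt_m$scan }
  }
  rec_genes <- select_recurrent(gene_rec, thr_gene)
  rec_mirs <- select_recurrent(mir_rec, thr_mir)
  log <- .log_stage(log, "recurrent_genes", nrow(gene_rec), nrow(rec_genes))
  log <- .log_stage(log, "recurrent_mirnas", nrow(mir_rec), nrow(rec_mirs))

  # --- pairing ---
  pathway_universe <- unique(unlist(cohort$pathways))
  instances <- candidate_pairs(de_genes, de_mirnas, cohort$targets,
                               min_agreement, pathway_universe)
  conserved <- conserved_pairs(instances, rec_genes$feature_id,
                               rec_mirs$feature_id)
  log <- .log_stage(log, "conserved_pairs",
                    length(unique(pair_key(instances$mirna,
                                           instances$gene))),
                    nrow(conserved))
  exclusive <- exclusive_pairs(instances)
  specificity <- if (nrow(instances) > 0) specificity_test(instances)
                 else NULL
  annotated <- flag_novel(conserved, cohort$known_pairs)

  # --- covariate-adjusted regression ---
  regression <- pair_regression(cohort, conserved, types)
  regression <- adjust_pair_pvalues(regression)
  selected <- select_significant_negative(regression, fdr_max)
  log <- .log_stage(log, "significant_negative_pairs", nrow(conserved),
                    nrow(selected))

  # --- survival ---
  sel_key <- pair_key(selected$mirna, selected$gene)
  sel_genes <- unique(selected$gene)
  surv <- NULL; combined <- NULL
  if (length(sel_genes) > 0) {
    clin_by_type <- lapply(types, function(tt) {
      cl <- cohort$types[[tt]]$clinical
      cl$prognosis <- encode_prognosis(cl$stage_or_gleason,
                                       gleason = tt == cohort$prad_like)
      cl
    })
    names(clin_by_type) <- types
    expr_by_type <- lapply(types, function(tt) {
      ty <- cohort$types[[tt]]
      tum <- colnames(ty$genes$counts)[ty$genes$groups == "tumour"]
      log_expr(rpkm(ty$genes$counts, cohort$gene_lengths))[, tum,
                                                           drop = FALSE]
    })
    names(expr_by_type) <- types
    surv <- survival_scan(clin_by_type, expr_by_type, sel_genes)
    reg_sel <- regression[pair_key(regression$mirna,
                                   regression$gene) %in% sel_key, ,
                          drop = FALSE]
    combined <- combine_correlation_survival(reg_sel, surv, fdr_max)
    log <- .log_stage(log, "survival_supported_pairs", nrow(selected),
                      length(unique(pair_key(
                        combined$mirna,
                        combined$gene)[combined$n_supported_types > 0])))
  }

  out <- list(validation = validation,
              de = list(gene_tables = de_gene_tables,
                        mirna_tables = de_mirna_tables,
                        de_genes = de_genes, de_mirnas = de_mirnas,
                        expressed = expressed),
              enrichment = enrichment,
              recurrence = list(genes = gene_rec, mirnas = mir_rec,
                                gene_scan = gene_scan, mir_scan = mir_scan,
                                gene_threshold = thr_gene,
                                mir_threshold = thr_mir,
                                recurrent_genes = rec_genes,
                                recurrent_mirnas = rec_mirs),
              pairs = list(instances = instances, conserved = conserved,
                           exclusive = exclusive,
                           specificity = specificity,
                           annotated = annotated),
              regression = list(all = regression, selected = selected),
              survival = list(scan = surv, combined = combined),
              log = log)
  if (!is.null(out_dir)) out$manifest <- .write_stage_outputs(out, out_dir)
  out
}

#' Per-type and joint covariate-adjusted regression for a set of pairs
#'
#' Assembles, for every pair, the tumour-sample covariate bundle of each
#' tumour type (gene and miRNA log2(RPKM+1), CNA level, methylation
#' M-values of the gene's probes) and fits the per-type models plus the
#' joint model across types.  Pairs whose gene or miRNA is absent from a
#' type's expression data get a \code{nonexistent} row for that dataset.
#'
#' @param cohort cohort list.
#' @param pairs data.frame with \code{mirna}, \code{gene} columns.
#' @param types tumour types to use (default: all in the cohort).
#' @return row-bound PairModelResult data.frame (no FDR yet; see
#'   \code{\link{adjust_pair_pvalues}}).
#' @export
pair_regression <- function(cohort, pairs, types = names(cohort$types)) {
  if (nrow(pairs) == 0)
    return(data.frame(mirna = character(0), gene = character(0),
                      dataset = character(0), n_samples = integer(0),
                      correlation = numeric(0), t_stat = numeric(0),
                      pvalue = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  bundles <- lapply(types, function(tt) {
    ty <- cohort$types[[tt]]
    tum <- colnames(ty$genes$counts)[ty$genes$groups == "tumour"]
    gene_log <- log_expr(rpkm(ty$genes$counts, cohort$gene_lengths))[, tum,
                                                                     drop = FALSE]
    mir_log <- log_expr(rpkm(ty$mirnas$counts,
                             cohort$mirna_lengths))[, tum, drop = FALSE]
    met_m <- if (nrow(ty$met_beta) > 0)
      beta_to_m(ty$met_beta[, tum, drop = FALSE]) else NULL
    list(tt = tt, tum = tum, gene_log = gene_log, mir_log = mir_log,
         cna = ty$cna[, tum, drop = FALSE], met_m = met_m,
         probe_map = ty$probe_map)
  })
  names(bundles) <- types

  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]; m <- pairs$mirna[i]
    m_norm <- normalize_mirna_id(m)
    joint_parts <- list()
    for (b in bundles) {
      mir_row <- match(m_norm, normalize_mirna_id(rownames(b$mir_log)))
      if (!g %in% rownames(b$gene_log) || is.na(mir_row)) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna = m, gene = g, dataset = b$tt, n_samples = 0L,
          correlation = 0, t_stat = NA_real_, pvalue = NA_real_,
          status = "nonexistent", stringsAsFactors = FALSE)
        next
      }
      probes <- b$probe_map$probe[b$probe_map$gene == g]
      met <- if (!is.null(b$met_m) && length(probes) > 0)
        t(b$met_m[probes, , drop = FALSE]) else NULL
      cna <- if (g %in% rownames(b$cna)) b$cna[g, ] else NULL
      rows[[length(rows) + 1]] <- fit_pair_model(
        b$gene_log[g, ], b$mir_log[mir_row, ], cna = cna, met = met,
        mirna_id = m, gene_id = g, dataset = b$tt)
      # probe sets differ across types, so the joint model carries the
      # gene-level mean M-value as its methylation covariate
      met_mean <- if (is.null(met)) NA_real_ else rowMeans(met)
      joint_parts[[b$tt]] <- data.frame(
        gene = b$gene_log[g, ], mir = b$mir_log[mir_row, ],
        cna = if (is.null(cna)) NA else cna, met_mean = met_mean,
        cancer_type = b$tt, stringsAsFactors = FALSE)
    }
    if (length(joint_parts) >= 2) {
      jd <- do.call(rbind, joint_parts)
      met_j <- if (all(is.na(jd$met_mean))) NULL
               else matrix(jd$met_mean, ncol = 1)
      rows[[length(rows) + 1]] <- fit_joint_model(
        jd$gene, jd$mir, jd$cancer_type, cna = jd$cna, met = met_j,
        mirna_id = m, gene_id = g)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        mirna = m, gene = g, dataset = "joint", n_samples = 0L,
        correlation = 0, t_stat = NA_real_, pvalue = NA_real_,
        status = "nonexistent", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Write every stage table under out_dir and return a hash manifest.
.write_stage_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  save_tsv <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }
  save_tsv(res$validation$report, "validation.tsv")
  for (tt in names(res$de$gene_tables)) {
    save_tsv(res$de$gene_tables[[tt]], sprintf("de_genes_%s.tsv", tt))
    save_tsv(res$de$mirna_tables[[tt]], sprintf("de_mirnas_%s.tsv", tt))
    save_tsv(res$enrichment[[tt]], sprintf("enrichment_%s.tsv", tt))
  }
  save_tsv(res$recurrence$genes, "recurrence_genes.tsv")
  save_tsv(res$recurrence$mirnas, "recurrence_mirnas.tsv")
  save_tsv(res$recurrence$gene_scan, "threshold_scan_genes.tsv")
  save_tsv(res$recurrence$mir_scan, "threshold_scan_mirnas.tsv")
  save_tsv(res$pairs$instances, "pair_instances.tsv")
  save_tsv(res$pairs$annotated, "conserved_pairs.tsv")
  save_tsv(res$pairs$specificity, "pair_specificity.tsv")
  save_tsv(res$regression$all, "pair_models.tsv")
  save_tsv(res$regression$selected, "selected_pairs.tsv")
  save_tsv(res$survival$scan, "survival.tsv")
  save_tsv(res$survival$combined, "pair_survival_matrix.tsv")
  save_tsv(res$log, "pipeline_log.tsv")
  data.frame(file = basename(files),
             md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}
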