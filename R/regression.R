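#' Methylation beta-value to M-value transform
#'
#' \code{M = log2(beta / (1 - beta))}: the logit-2 transform that maps the
#' bounded methylation fraction onto the real line and stabilizes its
#' variance before linear modelling.  Values are clamped away from 0 and 1
#' by \code{eps} so the transform is always finite; NA/NaN propagate with a
#' warning.
#'
#' @param beta numeric vector/matrix of beta-values.
#' @param eps clamp margin, default 1e-6.
#' @return M-values of the same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(is.na(beta))) warning("NA beta-values propagate as NA M-values")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Log-transform of expression used across the pipeline
#'
#' \code{log2(x + 1)}: the pseudocount guards zero RPKM values.
#' @param x RPKM (or other non-negative expression) values.
#' @param base logarithm base, default 2.
#' @param pseudocount added before the log, default 1.
#' @return transformed values.
#' @export
log_expr <- function(x, base = 2, pseudocount = 1) {
  log(x + pseudocount, base = base)
}

## Build the model frame for one pair in one dataset.  met is a samples x
## probes matrix of M-values (may have 0 columns); cna a vector of levels.
## Constant or aliased columns are dropped before Type-III ANOVA.
.pair_model_frame <- function(gene_log, mir_log, cna = NULL, met = NULL,
                              cancer_type = NULL) {
  df <- data.frame(gene = gene_log, mir = mir_log)
  if (!is.null(cna)) df$cna <- factor(cna)
  if (!is.null(cancer_type)) df$cancer_type <- factor(cancer_type)
  if (!is.null(met) && NCOL(met) > 0) {
    met <- as.matrix(met)
    colnames(met) <- paste0("met_", seq_len(ncol(met)))
    df <- cbind(df, met)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  # drop constant methylation probes and single-level factors
  drop <- vapply(names(df), function(nm) {
    v <- df[[nm]]
    if (nm %in% c("gene", "mir")) return(FALSE)
    if (is.factor(v)) length(unique(v)) < 2 else var(v) < 1e-12
  }, logical(1))
  df[, !drop, drop = FALSE]
}

.fit_terms <- function(df, joint = FALSE) {
  covars <- setdiff(names(df), c("gene", "mir", "cancer_type"))
  rhs <- c("mir", covars)
  if (joint) rhs <- c(rhs, "cancer_type", "mir:cancer_type")
  as.formula(paste("gene ~", paste(rhs, collapse = " + ")))
}

## Shared core: OLS fit + Type-III ANOVA; returns the PairModelResult row.
.fit_model_core <- function(df, mirna_id, gene_id, dataset, joint) {
  nonexistent <- data.frame(
    mirna = mirna_id, gene = gene_id, dataset = dataset,
    n_samples = nrow(df), correlation = 0, t_stat = NA_real_,
    pvalue = NA_real_, status = "nonexistent", stringsAsFactors = FALSE)
  if (nrow(df) == 0 || var(df$gene) < 1e-12 || var(df$mir) < 1e-12)
    return(nonexistent)

  form <- .fit_terms(df, joint)
  contr <- lapply(Filter(is.factor, df), function(f) "contr.sum")
  fit <- lm(form, data = df, contrasts = if (length(contr)) contr else NULL)
  # aliased columns: refit after removing offending methylation probes
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    bad_probes <- unique(sub("^(met_[0-9]+).*", "\\1", bad))
    bad_probes <- intersect(bad_probes, names(df))
    if (length(bad_probes) > 0) {
      warning("dropping aliased covariate(s): ",
              paste(bad_probes, collapse = ", "))
      df <- df[, setdiff(names(df), bad_probes), drop = FALSE]
      form <- .fit_terms(df, joint)
      fit <- lm(form, data = df,
                contrasts = if (length(contr)) contr else NULL)
    }
    if (any(is.na(coef(fit)))) return(nonexistent)
  }
  p_model <- length(coef(fit))
  if (nrow(df) < p_model + 2) return(nonexistent)

  a3 <- car::Anova(fit, type = 3)
  ss_mir <- a3["mir", "Sum Sq"]
  ss_resid <- a3["Residuals", "Sum Sq"]
  sm <- summary(fit)$coefficients
  beta_mir <- sm["mir", "Estimate"]
  data.frame(
    mirna = mirna_id, gene = gene_id, dataset = dataset,
    n_samples = nrow(df),
    # variance fraction after accounting for the other model terms
    # (partial eta^2); reduces to R^2 in simple regression
    correlation = sign(beta_mir) * sqrt(min(1, ss_mir / (ss_mir + ss_resid))),
    t_stat = sm["mir", "t value"], pvalue = sm["mir", "Pr(>|t|)"],
    status = "fit", stringsAsFactors = FALSE)
}

#' Covariate-adjusted pair model for one tumour type
#'
#' Ordinary least squares of the gene's log expression on the miRNA's log
#' expression, adjusting for the gene's copy-number level (entered as a
#' categorical factor over the observed levels) and each of its
#' methylation probes (M-values, independent columns).  The signed
#' gene-miRNA correlation is
#' \code{sign(miRNA coefficient) * sqrt(SS_miRNA / (SS_miRNA + SS_resid))}
#' with \code{SS_miRNA} the Type-III sum of squares of the miRNA term: the
#' square root of the fraction of expression variance attributable to the
#' miRNA after accounting for the other factors.  With no covariates this
#' reduces exactly to the Pearson correlation.
#'
#' @param gene_log,mir_log per-sample log2(RPKM+1) vectors, same samples.
#' @param cna optional per-sample copy-number level in -2..2.
#' @param met optional samples x probes matrix of methylation M-values for
#'   the gene's probes.
#' @param mirna_id,gene_id,dataset identifiers carried into the result.
#' @return one-row data.frame (a PairModelResult): \code{mirna},
#'   \code{gene}, \code{dataset}, \code{n_samples}, \code{correlation},
#'   \code{t_stat}, \code{pvalue}, \code{status} (\code{"fit"} or
#'   \code{"nonexistent"} when the model cannot be estimated; such rows
#'   carry correlation 0 and are excluded from FDR correction).
#' @export
fit_pair_model <- function(gene_log, mir_log, cna = NULL, met = NULL,
                           mirna_id = "mir", gene_id = "gene",
                           dataset = "dataset") {
  df <- .pair_model_frame(gene_log, mir_log, cna, met)
  .fit_model_core(df, mirna_id, gene_id, dataset, joint = FALSE)
}

#' Joint pair model across all tumour types
#'
#' As \code{\link{fit_pair_model}} but pooling the samples of every tumour
#' type, with cancer type (sum-to-zero contrasts) and its interaction with
#' miRNA expression added as factors.  The miRNA main effect under sum
#' contrasts is the average within-type slope, so its Type-III sum of
#' squares measures the shared (cross-tumour) component of the
#' association after cancer type, the interaction, CNA and methylation.
#'
#' @inheritParams fit_pair_model
#' @param cancer_type per-sample tumour-type labels (>= 2 distinct).
#' @return one-row data.frame with \code{dataset = "joint"}.
#' @export
fit_joint_model <- function(gene_log, mir_log, cancer_type, cna = NULL,
                            met = NULL, mirna_id = "mir", gene_id = "gene") {
  if (length(unique(cancer_type)) < 2)
    stop("joint model needs >= 2 cancer types; use fit_pair_model")
  df <- .pair_model_frame(gene_log, mir_log, cna, met, cancer_type)
  joint <- "cancer_type" %in% names(df)
  .fit_model_core(df, mirna_id, gene_id, "joint", joint = joint)
}

#' FDR over the full pair x dataset family
#'
#' BH adjustment across every fitted (pair, dataset) test: each pair is
#' analysed in all per-type datasets plus the joint one, and the correction
#' spans the whole collection.  Rows with status \code{"nonexistent"} are
#' excluded from the family and get NA.
#'
#' @param results row-bound PairModelResult data.frame.
#' @param per_pair when TRUE, adjust within each pair's own datasets
#'   instead of globally (default FALSE).
#' @return \code{results} with an \code{fdr} column.
#' @export
adjust_pair_pvalues <- function(results, per_pair = FALSE) {
  results$fdr <- NA_real_
  ok <- results$status == "fit" & !is.na(results$pvalue)
  if (per_pair) {
    key <- pair_key(results$mirna, results$gene)
    for (k in unique(key[ok])) {
      idx <- ok & key == k
      results$fdr[idx] <- bh_adjust(results$pvalue[idx])
    }
  } else {
    results$fdr[ok] <- bh_adjust(results$pvalue[ok])
  }
  results
}

#' Final selection: significant negative joint correlation
#'
#' Keeps the pairs whose joint-analysis correlation is negative (the
#' repressive direction expected of miRNA targeting) with FDR < 0.05.
#'
#' @param results FDR-adjusted PairModelResult data.frame (must contain
#'   \code{dataset == "joint"} rows).
#' @param fdr_max threshold, default 0.05.
#' @return the selected joint rows.
#' @export
select_significant_negative <- function(results, fdr_max = 0.05) {
  joint <- results[results$dataset == "joint", , drop = FALSE]
  if (nrow(joint) == 0) stop("no joint-analysis rows present")
  keep <- joint$status == "fit" & !is.na(joint$fdr) &
    joint$correlation < 0 & joint$fdr < fdr_max
  out <- joint[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
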