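#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment.  Thin validating wrapper around
#' \code{stats::p.adjust(method = "BH")} so every stage of the pipeline
#' shares one entry point with input checking.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NA allowed).
#' @return vector of BH-adjusted p-values (q-values).
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed features
#'
#' Applies the selection rule used throughout the pipeline: a feature is
#' called differentially expressed when its FDR is strictly below
#' \code{fdr_max} and its absolute log2 fold change is strictly above
#' \code{lfc_min}.  Both comparisons are strict, so a feature sitting
#' exactly at either threshold is excluded.
#'
#' @param results data.frame with columns \code{feature_id}, \code{log2fc},
#'   \code{fdr} (as produced by \code{\link{de_analysis}}).
#' @param fdr_max FDR threshold, default 0.05.
#' @param lfc_min absolute log2 fold-change threshold, default 1.
#' @return data.frame of selected features with a \code{direction} column
#'   (\code{"up"} / \code{"down"}, tumour relative to control).
#' @export
select_de <- function(results, fdr_max = 0.05, lfc_min = 1) {
  stopifnot(all(c("feature_id", "log2fc", "fdr") %in% names(results)))
  keep <- !is.na(results$fdr) & results$fdr < fdr_max &
    abs(results$log2fc) > lfc_min
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Per-tumour differential expression analysis
#'
#' The full two-group testing stage for one tumour type: CPM filtering of
#' weakly expressed features, TMM normalization, the negative-binomial
#' exact test, and BH adjustment.  Selection by threshold is left to
#' \code{\link{select_de}} so the complete table can be inspected.
#'
#' @param counts a \code{count_matrix}.
#' @param cpm_threshold CPM filter threshold (features kept when CPM >=
#'   this in at least \code{min_samples} samples), default 1.
#' @param min_samples see \code{\link{filter_low_expression}}.
#' @param dispersion optional fixed NB dispersion (estimated by default).
#' @return data.frame with columns \code{feature_id}, \code{log2fc},
#'   \code{avg_log2cpm}, \code{pvalue}, \code{fdr}, \code{direction};
#'   attributes \code{dispersion} and \code{expressed} (ids surviving the
#'   CPM filter, the enrichment universe for this tumour type).
#' @export
de_analysis <- function(counts, cpm_threshold = 1, min_samples = NULL,
                        dispersion = NULL) {
  filtered <- filter_low_expression(counts, cpm_threshold, min_samples)
  if (nrow(filtered$counts) == 0)
    stop("no features survive the CPM filter")
  f <- tmm_factors(filtered)
  res <- nb_exact_test(filtered, factors = f, dispersion = dispersion)
  res$fdr <- bh_adjust(res$pvalue)
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  attr(res, "expressed") <- rownames(filtered$counts)
  res
}
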