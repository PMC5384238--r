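#' Encode tumour stage (or Gleason score) as a binary prognosis
#'
#' Stages I and II (with any sub-letter, e.g. "Stage IIA") are coded good
#' prognosis; stages III, IV and X bad.  For the prostate-like tumour type,
#' where grade replaces stage, Gleason 6-7 is good and Gleason >= 8 bad.
#' Unparseable values give NA with a warning (the record is then excluded
#' from modelling).
#'
#' @param stage_raw character vector of raw stage / Gleason annotations.
#' @param gleason logical (scalar or vector): interpret the value as a
#'   Gleason score instead of a stage.
#' @return factor with levels \code{good}, \code{bad}.
#' @export
encode_prognosis <- function(stage_raw, gleason = FALSE) {
  gleason <- rep_len(gleason, length(stage_raw))
  out <- rep(NA_character_, length(stage_raw))
  s <- toupper(trimws(as.character(stage_raw)))

  gl_num <- suppressWarnings(as.numeric(sub(".*?([0-9]+).*", "\\1", s)))
  out[gleason & !is.na(gl_num) & gl_num >= 6 & gl_num <= 7] <- "good"
  out[gleason & !is.na(gl_num) & gl_num >= 8] <- "bad"

  st <- sub("^STAGE\\s*", "", s[!gleason])
  roman <- regmatches(st, regexpr("^(IV|III|II|I|X)", st))
  stage_code <- rep(NA_character_, length(st))
  stage_code[attr(regexpr("^(IV|III|II|I|X)", st), "match.length") > 0] <-
    roman
  out[!gleason] <- ifelse(stage_code %in% c("I", "II"), "good",
                          ifelse(stage_code %in% c("III", "IV", "X"),
                                 "bad", NA))
  bad_parse <- is.na(out) & !is.na(stage_raw) & nzchar(s)
  if (any(bad_parse))
    warning(sum(bad_parse), " stage value(s) could not be parsed; ",
            "records excluded")
  factor(out, levels = c("good", "bad"))
}

#' Stage-adjusted Cox model for one feature in one tumour type
#'
#' Cox proportional-hazards fit (Efron tie handling) of survival on the
#' binary prognosis plus the feature's log2-expression.  The expression
#' effect is therefore adjusted for tumour stage: its Wald p-value
#' measures association with survival independent of stage.  The hazard
#' ratio is reported per unit of log2-expression, both as the natural-log
#' coefficient and as log2(HR).
#'
#' @param time,event numeric survival time (> 0) and 0/1 event indicator.
#' @param expr_log per-sample log2(RPKM+1) expression.
#' @param prognosis factor from \code{\link{encode_prognosis}}; when it has
#'   a single observed level it is dropped from the model with a warning.
#' @param ties tie-handling method passed to \code{coxph}, default
#'   \code{"efron"}.
#' @return one-row data.frame: \code{loghr} (natural log HR per unit
#'   log2-expression), \code{log2_hr}, \code{se}, \code{pvalue}, \code{n},
#'   \code{n_events}, \code{converged}.  Non-convergent or degenerate fits
#'   return \code{converged = FALSE} with NA estimates (excluded from the
#'   FDR family downstream).
#' @export
cox_fit <- function(time, event, expr_log, prognosis = NULL,
                    ties = "efron") {
  df <- data.frame(time = time, event = event, expr = expr_log)
  if (!is.null(prognosis)) df$prognosis <- prognosis
  df <- df[complete.cases(df), , drop = FALSE]
  failed <- data.frame(loghr = NA_real_, log2_hr = NA_real_, se = NA_real_,
                       pvalue = NA_real_, n = nrow(df),
                       n_events = sum(df$event), converged = FALSE)
  if (nrow(df) < 3 || sum(df$event) < 2) return(failed)
  if (var(df$expr) < 1e-12) {
    warning("expression is constant; Cox fit skipped")
    return(failed)
  }
  use_prog <- !is.null(prognosis) && length(unique(df$prognosis)) >= 2
  if (!is.null(prognosis) && !use_prog)
    warning("prognosis has a single observed level; covariate dropped")
  form <- if (use_prog) Surv(time, event) ~ prognosis + expr
          else Surv(time, event) ~ expr
  fit <- tryCatch(coxph(form, data = df, ties = ties),
                  warning = function(w) NULL, error = function(e) NULL)
  if (is.null(fit) || is.na(coef(fit)["expr"])) return(failed)
  beta <- coef(fit)["expr"]
  se <- sqrt(vcov(fit)["expr", "expr"])
  data.frame(loghr = unname(beta), log2_hr = unname(beta / log(2)),
             se = unname(se),
             pvalue = unname(2 * pnorm(-abs(beta / se))),
             n = nrow(df), n_events = sum(df$event), converged = TRUE)
}

#' Survival scan over features within tumour types
#'
#' Runs \code{\link{cox_fit}} for each requested feature in each tumour
#' type and BH-corrects the Wald p-values across the whole
#' (feature x tumour type) family.
#'
#' @param clinical_by_type named list (tumour type -> data.frame with
#'   \code{sample_id}, \code{time}, \code{event}, \code{prognosis}).
#' @param expr_by_type named list (tumour type -> features x samples
#'   matrix of log2(RPKM+1)).
#' @param features feature ids to test (default: all shared features).
#' @return data.frame: \code{feature_id}, \code{tumour_type},
#'   \code{loghr}, \code{log2_hr}, \code{pvalue}, \code{fdr}, \code{n},
#'   \code{n_events}, \code{converged}.
#' @export
survival_scan <- function(clinical_by_type, expr_by_type, features = NULL) {
  rows <- list()
  for (tt in names(clinical_by_type)) {
    clin <- clinical_by_type[[tt]]
    expr <- expr_by_type[[tt]]
    if (is.null(expr)) next
    ids <- intersect(clin$sample_id, colnames(expr))
    clin <- clin[match(ids, clin$sample_id), , drop = FALSE]
    feats <- if (is.null(features)) rownames(expr)
             else intersect(features, rownames(expr))
    for (f in feats) {
      r <- suppressWarnings(
        cox_fit(clin$time, clin$event, expr[f, ids], clin$prognosis))
      r <- cbind(data.frame(feature_id = f, tumour_type = tt,
                            stringsAsFactors = FALSE), r)
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no (feature, tumour type) combinations to test")
  out$fdr <- NA_real_
  ok <- out$converged & !is.na(out$pvalue)
  out$fdr[ok] <- bh_adjust(out$pvalue[ok])
  rownames(out) <- NULL
  out
}

#' Combine pair correlations with gene survival associations
#'
#' The final pair-survival call: a pair is "supported" in a tumour type
#' when its per-type expression correlation and its gene's stage-adjusted
#' survival association are both significant (FDR < 0.05).  Such pairs are
#' consistent with the miRNA regulating the gene and the gene's expression
#' affecting survival.  Pairs supported in two or more tumour types form
#' the strongest, multi-type stratum.
#'
#' @param pair_results FDR-adjusted per-type PairModelResult rows (the
#'   joint rows are ignored here).
#' @param surv survival scan results from \code{\link{survival_scan}}.
#' @param fdr_max significance threshold for both components, default 0.05.
#' @return data.frame with one row per (pair, tumour type) where both
#'   results exist: correlation and survival estimates with their FDRs, a
#'   logical \code{supported} flag, and \code{n_supported_types} repeated
#'   per pair.
#' @export
combine_correlation_survival <- function(pair_results, surv,
                                         fdr_max = 0.05) {
  per_type <- pair_results[pair_results$dataset != "joint", , drop = FALSE]
  merged <- merge(
    per_type,
    surv[, c("feature_id", "tumour_type", "log2_hr", "pvalue", "fdr",
             "converged")],
    by.x = c("gene", "dataset"), by.y = c("feature_id", "tumour_type"),
    suffixes = c("_corr", "_surv"))
  merged$supported <- merged$status == "fit" & merged$converged &
    !is.na(merged$fdr_corr) & merged$fdr_corr < fdr_max &
    !is.na(merged$fdr_surv) & merged$fdr_surv < fdr_max
  key <- pair_key(merged$mirna, merged$gene)
  n_sup <- tapply(merged$supported, key, sum)
  merged$n_supported_types <- as.integer(n_sup[key])
  merged <- merged[order(-merged$n_supported_types, merged$mirna,
                         merged$gene, merged$dataset), , drop = FALSE]
  names(merged)[names(merged) == "dataset"] <- "tumour_type"
  rownames(merged) <- NULL
  merged
}
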