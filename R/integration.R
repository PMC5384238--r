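#' Cross-tumour recurrence table
#'
#' Collects, for every feature, the tumour types in which it is
#' differentially expressed and the direction in each.  A feature may be up
#' in some types and down in others; both are recorded and either counts
#' toward recurrence.
#'
#' @param per_tumour_de named list (tumour type -> data.frame with columns
#'   \code{feature_id}, \code{direction}), e.g. \code{\link{select_de}}
#'   output per type.
#' @return data.frame with columns \code{feature_id}, \code{recurrence}
#'   (number of distinct tumour types), \code{types} and \code{directions}
#'   (comma-joined, aligned), sorted by decreasing recurrence.
#' @export
recurrence_table <- function(per_tumour_de) {
  if (length(per_tumour_de) == 0)
    return(data.frame(feature_id = character(0), recurrence = integer(0),
                      types = character(0), directions = character(0),
                      stringsAsFactors = FALSE))
  if (anyDuplicated(names(per_tumour_de)))
    stop("tumour types must be distinct")
  long <- do.call(rbind, lapply(names(per_tumour_de), function(tt) {
    de <- per_tumour_de[[tt]]
    if (is.null(de) || nrow(de) == 0) return(NULL)
    data.frame(feature_id = de$feature_id, tumour_type = tt,
               direction = de$direction, stringsAsFactors = FALSE)
  }))
  if (is.null(long))
    return(recurrence_table(list()))
  split_f <- split(long, long$feature_id)
  out <- do.call(rbind, lapply(split_f, function(d) {
    d <- d[order(d$tumour_type), , drop = FALSE]
    data.frame(feature_id = d$feature_id[1],
               recurrence = length(unique(d$tumour_type)),
               types = paste(d$tumour_type, collapse = ","),
               directions = paste(d$direction, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$recurrence, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose the recurrence cut-off by enrichment in known cancer features
#'
#' Scans candidate recurrence thresholds; at each threshold T the features
#' recurring in at least T tumour types are cross-tabulated against a list
#' of known cancer genes (or miRNAs) over the full universe, scored with a
#' right-tailed Fisher exact test, and BH-corrected across the scanned
#' thresholds.  The chosen cut-off is the one with the highest odds ratio
#' among thresholds significant at FDR < 0.05, with ties broken toward the
#' smaller (more inclusive) threshold.
#'
#' @param table recurrence table from \code{\link{recurrence_table}}.
#' @param known character vector of known cancer feature ids (subset of
#'   \code{universe}).
#' @param universe all candidate feature ids the selection is drawn from.
#' @param t_range integer vector of thresholds to scan, default 5:10.
#' @param fdr_max significance requirement on the scan rows, default 0.05.
#' @return list with \code{threshold} (chosen T) and \code{scan}
#'   (data.frame: \code{threshold}, \code{n_selected}, \code{overlap},
#'   \code{odds_ratio} (ad/bc), \code{odds_ratio_h} (zero-cell corrected,
#'   used for ranking), \code{pvalue}, \code{fdr}).
#' @export
optimize_threshold <- function(table, known, universe, t_range = 5:10,
                               fdr_max = 0.05) {
  known <- unique(known)
  universe <- unique(universe)
  stray <- setdiff(known, universe)
  if (length(stray) > 0)
    stop("known features missing from the universe: ",
         paste(head(stray, 5), collapse = ", "))
  rows <- lapply(t_range, function(tt) {
    sel <- table$feature_id[table$recurrence >= tt]
    a <- length(intersect(sel, known))
    b <- length(sel) - a
    cc <- length(known) - a
    d <- length(universe) - a - b - cc
    if (length(sel) == 0) {
      or <- NaN; or_h <- NaN; p <- NA_real_
    } else {
      ft <- fisher_2x2(a, b, cc, d, alternative = "greater")
      or <- ft$odds_ratio; or_h <- ft$odds_ratio_h; p <- ft$p_value
    }
    data.frame(threshold = tt, n_selected = length(sel), overlap = a,
               odds_ratio = or, odds_ratio_h = or_h, pvalue = p,
               stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, rows)
  scan$fdr <- NA_real_
  ok <- !is.na(scan$pvalue)
  scan$fdr[ok] <- bh_adjust(scan$pvalue[ok])
  eligible <- ok & !is.nan(scan$odds_ratio) &
    !is.na(scan$fdr) & scan$fdr < fdr_max
  if (!any(eligible))
    stop("no enrichable threshold: no scanned cut-off reaches FDR < ",
         fdr_max)
  cand <- scan[eligible, , drop = FALSE]
  # rank on the zero-cell-corrected OR so that thresholds at which every
  # known feature is captured (raw OR infinite) are still ordered by how
  # tight the selection is; remaining ties go to the smaller threshold
  best <- cand$threshold[order(-cand$odds_ratio_h, cand$threshold)][1]
  list(threshold = best, scan = scan)
}

#' Features recurring in at least a given number of tumour types
#'
#' @param table recurrence table from \code{\link{recurrence_table}}.
#' @param threshold minimum number of distinct tumour types (>= 1).
#' @return the rows of \code{table} whose recurrence meets the threshold,
#'   directions retained.
#' @export
select_recurrent <- function(table, threshold) {
  stopifnot(threshold >= 1)
  out <- table[table$recurrence >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
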