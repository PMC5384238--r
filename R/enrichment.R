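#' Read a GMT pathway file
#'
#' Standard tab-separated gene-set format: one set per line, fields are
#' name, description, then member ids.
#'
#' @param path file path.
#' @return named list of character vectors (pathway -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write a GMT pathway file
#' @param catalog named list of character vectors.
#' @param path output file path.
#' @param descriptions optional per-set description strings.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(catalog))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(catalog), descriptions, catalog)
  writeLines(lines, path)
  invisible(path)
}

#' Directional pathway enrichment of DE genes
#'
#' For each pathway, tests whether differentially expressed genes are over-
#' or under-represented among the pathway's expressed members, relative to
#' all genes expressed in the experiment.  The 2x2 table is
#' \code{[[DE in pathway, DE outside], [non-DE in pathway, non-DE outside]]}
#' with a two-sided Fisher exact p-value; the sample odds ratio ad/bc
#' quantifies the direction: OR > 1 means the pathway is enriched in
#' altered genes, OR < 1 that it is depleted (it behaves more like healthy
#' tissue).  P-values are BH-adjusted across the pathways tested.
#'
#' @param de_genes character vector of DE gene ids (must be a subset of
#'   \code{expressed_genes}).
#' @param expressed_genes the universe: all genes expressed (surviving the
#'   CPM filter) in this tumour type.
#' @param catalog named list of pathway gene sets (e.g. from
#'   \code{\link{read_gmt}}).
#' @return data.frame with one row per pathway: cell counts \code{a..d},
#'   \code{odds_ratio} (ad/bc; may be Inf/NaN), \code{odds_ratio_h}
#'   (zero-cell corrected, for display), \code{pvalue}, \code{fdr},
#'   \code{direction} (\code{enriched} / \code{depleted}).
#' @export
enrich_pathways <- function(de_genes, expressed_genes, catalog) {
  de_genes <- unique(de_genes)
  expressed_genes <- unique(expressed_genes)
  stray <- setdiff(de_genes, expressed_genes)
  if (length(stray) > 0)
    stop("DE genes not in the expressed universe: ",
         paste(head(stray, 5), collapse = ", "))
  rows <- lapply(names(catalog), function(nm) {
    path_genes <- intersect(catalog[[nm]], expressed_genes)
    a <- length(intersect(de_genes, path_genes))
    b <- length(de_genes) - a
    cc <- length(path_genes) - a
    d <- length(expressed_genes) - a - b - cc
    ft <- fisher_2x2(a, b, cc, d, alternative = "two.sided")
    data.frame(pathway = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, odds_ratio_h = ft$odds_ratio_h,
               pvalue = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out$direction <- ifelse(is.nan(out$odds_ratio), NA_character_,
                          ifelse(out$odds_ratio > 1, "enriched", "depleted"))
  rownames(out) <- NULL
  out
}

#' Random size-matched enrichment control
#'
#' Draws \code{n_reps} random gene sets of a pathway's size from the
#' expressed universe and computes the same 2x2 odds ratio against the DE
#' genes, giving the null distribution an observed pathway OR can be
#' compared with.
#'
#' @param de_genes,expressed_genes as in \code{\link{enrich_pathways}}.
#' @param pathway_size size of the random sets.
#' @param n_reps number of random draws.
#' @param seed RNG seed for reproducibility.
#' @param observed_or optional observed pathway OR; when given, the result
#'   carries a \code{nonrandom} flag set when it falls outside the
#'   [2.5\%, 97.5\%] interval of the control ORs.
#' @return list with \code{or} (vector of control ORs, length
#'   \code{n_reps}), \code{ci} (2.5/97.5 percentiles, NA when empty) and
#'   \code{nonrandom} (logical or NA).
#' @export
random_control <- function(de_genes, expressed_genes, pathway_size,
                           n_reps = 1000, seed = 1, observed_or = NULL) {
  expressed_genes <- unique(expressed_genes)
  if (pathway_size > length(expressed_genes))
    stop("pathway_size exceeds the size of the expressed universe")
  if (n_reps == 0)
    return(list(or = numeric(0), ci = c(NA_real_, NA_real_), nonrandom = NA))
  de_genes <- unique(de_genes)
  ors <- local_seed(seed, vapply(seq_len(n_reps), function(i) {
    fake <- sample(expressed_genes, pathway_size)
    a <- length(intersect(de_genes, fake))
    b <- length(de_genes) - a
    cc <- pathway_size - a
    d <- length(expressed_genes) - a - b - cc
    fisher_2x2(a, b, cc, d)$odds_ratio_h
  }, numeric(1)))
  ci <- quantile(ors, c(0.025, 0.975), na.rm = TRUE)
  nonrandom <- if (is.null(observed_or)) NA
               else observed_or < ci[1] || observed_or > ci[2]
  list(or = ors, ci = unname(ci), nonrandom = nonrandom)
}

## evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
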