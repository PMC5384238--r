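#' Normalize miRNA identifiers
#'
#' Target catalogues mix naming conventions; for matching, miRNA ids are
#' lower-cased and any "hsa-" species prefix is stripped.  Gene symbols are
#' left as-is.
#'
#' @param x character vector of miRNA ids.
#' @return normalized ids.
#' @export
normalize_mirna_id <- function(x) {
  sub("^hsa-", "", tolower(x))
}

pair_key <- function(mirna, gene) {
  paste(normalize_mirna_id(mirna), gene, sep = "|")
}

#' Inverse-expression candidate pair instances
#'
#' Emits one instance per (tumour type, catalogue edge) where the miRNA and
#' the gene are differentially expressed in opposite directions in that
#' tumour type and the edge's genomic agreement (number of independent
#' prediction methods supporting the same 3' UTR position) meets the
#' cut-off.  Down-regulated genes pair with up-regulated miRNAs and vice
#' versa, reflecting miRNA-mediated repression.  Genes can be restricted to
#' a pathway universe so that pairing stays within the cancer pathways
#' under study.
#'
#' @param de_genes_by_type,de_mirnas_by_type named lists (tumour type ->
#'   data.frame with \code{feature_id}, \code{direction}).
#' @param catalog data.frame with columns \code{mirna}, \code{gene},
#'   \code{agreement}.
#' @param min_agreement minimum genomic agreement, default 2.
#' @param gene_universe optional character vector; when given, only genes
#'   in it can form pairs (e.g. the union of the pathway gene sets).
#' @return data.frame of pair instances: \code{mirna}, \code{gene},
#'   \code{tumour_type}, \code{orientation} (\code{"miR-up/gene-down"} or
#'   \code{"miR-down/gene-up"}).
#' @export
candidate_pairs <- function(de_genes_by_type, de_mirnas_by_type, catalog,
                            min_agreement = 2, gene_universe = NULL) {
  stopifnot(all(c("mirna", "gene", "agreement") %in% names(catalog)))
  cat_ok <- catalog[catalog$agreement >= min_agreement, , drop = FALSE]
  if (!is.null(gene_universe))
    cat_ok <- cat_ok[cat_ok$gene %in% gene_universe, , drop = FALSE]
  cat_ok$mirna_norm <- normalize_mirna_id(cat_ok$mirna)

  types <- intersect(names(de_genes_by_type), names(de_mirnas_by_type))
  rows <- lapply(types, function(tt) {
    dg <- de_genes_by_type[[tt]]
    dm <- de_mirnas_by_type[[tt]]
    if (is.null(dg) || is.null(dm) || nrow(dg) == 0 || nrow(dm) == 0)
      return(NULL)
    gdir <- setNames(dg$direction, dg$feature_id)
    mdir <- setNames(dm$direction, normalize_mirna_id(dm$feature_id))
    hit <- cat_ok[cat_ok$gene %in% names(gdir) &
                    cat_ok$mirna_norm %in% names(mdir), , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    g <- gdir[hit$gene]
    m <- mdir[hit$mirna_norm]
    inverse <- (m == "up" & g == "down") | (m == "down" & g == "up")
    hit <- hit[inverse, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    data.frame(mirna = hit$mirna, gene = hit$gene, tumour_type = tt,
               orientation = ifelse(mdir[hit$mirna_norm] == "up",
                                    "miR-up/gene-down", "miR-down/gene-up"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna = character(0), gene = character(0),
                      tumour_type = character(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  # one instance per (pair, tumour type)
  out <- out[!duplicated(paste(pair_key(out$mirna, out$gene),
                               out$tumour_type)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairs whose both members recur across tumour types
#'
#' Restricts the pair instances to those whose gene and miRNA both belong
#' to the recurrent (cross-tumour) feature sets, then aggregates the
#' instances per pair.
#'
#' @param instances pair instances from \code{\link{candidate_pairs}}.
#' @param recurrent_genes,recurrent_mirnas character vectors of recurrent
#'   feature ids (from \code{\link{select_recurrent}}).
#' @return data.frame with one row per pair: \code{mirna}, \code{gene},
#'   \code{n_tumours}, \code{tumour_types} (comma-joined),
#'   \code{orientations} (comma-joined, aligned with the types).
#' @export
conserved_pairs <- function(instances, recurrent_genes, recurrent_mirnas) {
  keep <- instances$gene %in% recurrent_genes &
    normalize_mirna_id(instances$mirna) %in%
      normalize_mirna_id(recurrent_mirnas)
  aggregate_pairs(instances[keep, , drop = FALSE])
}

aggregate_pairs <- function(instances) {
  if (nrow(instances) == 0)
    return(data.frame(mirna = character(0), gene = character(0),
                      n_tumours = integer(0), tumour_types = character(0),
                      orientations = character(0), stringsAsFactors = FALSE))
  key <- pair_key(instances$mirna, instances$gene)
  out <- do.call(rbind, lapply(split(instances, key), function(d) {
    d <- d[order(d$tumour_type), , drop = FALSE]
    data.frame(mirna = d$mirna[1], gene = d$gene[1],
               n_tumours = length(unique(d$tumour_type)),
               tumour_types = paste(d$tumour_type, collapse = ","),
               orientations = paste(d$orientation, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_tumours, out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumour-type-exclusive pairs
#'
#' A pair is exclusive to a tumour type when its inverse differential
#' expression occurs in that type and in no other.  With \code{group}, the
#' query generalizes to a named set of types: pairs whose instances all
#' fall within the group are returned (optionally requiring presence in
#' every member of the group), e.g. pairs seen only in the two lung tumour
#' types.
#'
#' @param instances pair instances from \code{\link{candidate_pairs}}.
#' @param group optional character vector of tumour types for a
#'   group-exclusivity query.
#' @param require_all with \code{group}: demand an instance in every type
#'   of the group (default FALSE).
#' @return without \code{group}: named list (tumour type -> data.frame of
#'   pairs exclusive to it); with \code{group}: one data.frame of
#'   group-exclusive pairs.
#' @export
exclusive_pairs <- function(instances, group = NULL, require_all = FALSE) {
  if (nrow(instances) == 0) {
    empty <- aggregate_pairs(instances)
    if (is.null(group)) return(list()) else return(empty)
  }
  key <- pair_key(instances$mirna, instances$gene)
  types_by_pair <- lapply(split(instances$tumour_type, key), unique)

  if (!is.null(group)) {
    sel <- vapply(types_by_pair, function(tt) {
      all(tt %in% group) && (!require_all || all(group %in% tt))
    }, logical(1))
    keep_keys <- names(types_by_pair)[sel]
    return(aggregate_pairs(instances[key %in% keep_keys, , drop = FALSE]))
  }

  solo <- vapply(types_by_pair, function(tt) length(tt) == 1, logical(1))
  solo_type <- vapply(types_by_pair[solo], identity, character(1))
  out <- lapply(split(names(solo_type), solo_type), function(keys)
    aggregate_pairs(instances[key %in% keys, , drop = FALSE]))
  out
}

#' Pair specificity test
#'
#' Scores how exclusive an interaction is: a pair that recurs across
#' tumour types while its miRNA and gene each have few other partners is
#' "highly specific".  Over all pair instances, each distinct pair (m, g)
#' is tested with a right-tailed Fisher exact test on the 2x2 table
#' \code{[[#(m,g), #(m, other gene)], [#(other miRNA, g), #(neither)]]},
#' and BH-corrected over all tested pairs.  Low p means the pair's
#' recurrence is concentrated in each other rather than spread over
#' co-interactors.
#'
#' The table construction is pluggable through \code{margin}: the default
#' \code{"pooled"} uses the single table above, crossing the miRNA margin
#' with the gene margin over all instances.  \code{"mirna"} compares the
#' miRNA's own split between this gene and its co-interactors against the
#' gene's overall instance frequency, i.e.
#' \code{[[#(m,g), #(m, other)], [#(g anywhere), #(not g)]]}; \code{"gene"}
#' is the mirror image.  These one-sided variants probe promiscuity of one
#' partner at a time and are exposed for sensitivity analysis.
#'
#' @param instances pair instances from \code{\link{candidate_pairs}}.
#' @param margin \code{"pooled"} (default), \code{"mirna"} or
#'   \code{"gene"}.
#' @return data.frame with one row per distinct pair: \code{mirna},
#'   \code{gene}, cells \code{a..d}, \code{odds_ratio}, \code{pvalue},
#'   \code{fdr}, sorted by p-value.
#' @export
specificity_test <- function(instances,
                             margin = c("pooled", "mirna", "gene")) {
  margin <- match.arg(margin)
  if (nrow(instances) == 0) stop("no pair instances to test")
  mir <- normalize_mirna_id(instances$mirna)
  gene <- instances$gene
  key <- paste(mir, gene, sep = "|")
  n_total <- length(key)

  pair_count <- table(key)
  mir_count <- table(mir)
  gene_count <- table(gene)
  uniq <- !duplicated(key)
  rows <- data.frame(mirna = instances$mirna[uniq], gene = gene[uniq],
                     key = key[uniq], stringsAsFactors = FALSE)
  rows$mir_norm <- normalize_mirna_id(rows$mirna)

  a <- as.integer(pair_count[rows$key])
  b <- as.integer(mir_count[rows$mir_norm]) - a   # same miRNA, other genes
  cc <- as.integer(gene_count[rows$gene]) - a     # same gene, other miRNAs
  d <- n_total - a - b - cc                       # neither partner involved
  if (margin == "mirna") {
    cc <- as.integer(gene_count[rows$gene])       # gene frequency overall
    d <- n_total - cc
  } else if (margin == "gene") {
    b <- cc                                       # gene's other miRNAs
    cc <- as.integer(mir_count[rows$mir_norm])    # miRNA frequency overall
    d <- n_total - cc
  }

  res <- mapply(function(a, b, cc, d) {
    ft <- fisher_2x2(a, b, cc, d, alternative = "greater")
    c(ft$p_value, ft$odds_ratio_h)
  }, a, b, cc, d)
  out <- data.frame(mirna = rows$mirna, gene = rows$gene,
                    a = a, b = b, c = cc, d = d,
                    odds_ratio = res[2, ], pvalue = res[1, ],
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag pairs as novel or validated
#'
#' Marks each pair as validated when it appears in a list of known
#' (database-described) interactions, after miRNA id normalization, and as
#' novel otherwise.
#'
#' @param pairs data.frame with columns \code{mirna}, \code{gene}.
#' @param known_pairs data.frame with columns \code{mirna}, \code{gene} of
#'   known interactions (may be empty).
#' @return \code{pairs} with an added \code{status} column
#'   (\code{"validated"} / \code{"novel"}).
#' @export
flag_novel <- function(pairs, known_pairs) {
  known_keys <- if (is.null(known_pairs) || nrow(known_pairs) == 0)
    character(0) else pair_key(known_pairs$mirna, known_pairs$gene)
  pairs$status <- ifelse(pair_key(pairs$mirna, pairs$gene) %in% known_keys,
                         "validated", "novel")
  pairs
}
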