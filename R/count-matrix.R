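#' Count matrix with sample metadata
#'
#' Bundles a features x samples matrix of non-negative integer read counts
#' with the per-sample group labels (\code{"control"} / \code{"tumour"}) and
#' a tumour-type tag.  This is the unit on which differential expression is
#' run, one object per tumour type per feature class (genes or miRNAs).
#'
#' @param counts numeric matrix, features x samples, non-negative integers.
#'   Must have rownames (feature ids); colnames are taken as sample ids.
#' @param groups character or factor of length \code{ncol(counts)} with
#'   values in \code{c("control", "tumour")}.
#' @param tumour_type single string tagging the cohort.
#'
#' @return an object of class \code{"count_matrix"}: a list with elements
#'   \code{counts}, \code{groups} (factor with levels control, tumour) and
#'   \code{tumour_type}.
#' @export
count_matrix <- function(counts, groups, tumour_type = "unknown") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have rownames (feature ids)")
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(groups) != ncol(counts))
    stop("length(groups) must equal ncol(counts)")
  groups <- factor(as.character(groups), levels = c("control", "tumour"))
  if (anyNA(groups)) stop("groups must be 'control' or 'tumour'")
  structure(
    list(counts = counts, groups = groups,
         tumour_type = as.character(tumour_type)[1]),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s; %d control, %d tumour)\n",
              nrow(x$counts), ncol(x$counts), x$tumour_type,
              sum(x$groups == "control"), sum(x$groups == "tumour")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

as_count_input <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Counts per million
#'
#' Library-size scaling of a count matrix: each entry is multiplied by 1e6
#' and divided by its column (library) total, so each column sums to one
#' million over the features present.
#'
#' @param counts a \code{count_matrix} or a plain numeric matrix.
#' @param lib_sizes optional per-sample library sizes; defaults to column
#'   sums of \code{counts}.
#' @return numeric matrix of the same dimension.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  m <- as_count_input(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0)) {
    bad <- colnames(m)[lib_sizes <= 0]
    if (is.null(bad)) bad <- which(lib_sizes <= 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(m, 2, lib_sizes, "/") * 1e6
}

#' Remove weakly expressed features
#'
#' Keeps features whose CPM is at or above \code{cpm_threshold} in at least
#' \code{min_samples} samples; everything below is treated as unexpressed
#' noise.  The retention rule is inclusive (CPM exactly at the threshold is
#' kept) because filtering removes features with CPM strictly below it.
#'
#' @param counts a \code{count_matrix}.
#' @param cpm_threshold minimum CPM, default 1.
#' @param min_samples number of samples that must reach the threshold;
#'   defaults to the size of the smaller group.
#' @return a \code{count_matrix} restricted to the surviving features, in
#'   their original order.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  min_samples = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(min_samples)) min_samples <- min(table(counts$groups))
  keep <- rowSums(cpm(counts) >= cpm_threshold) >= min_samples
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  out
}

#' Reads per kilobase per million
#'
#' Length- and depth-normalized expression:
#' \code{count * 1e9 / (library_size * length_bp)}.
#'
#' @param counts a \code{count_matrix} or numeric matrix.
#' @param lengths named vector of feature lengths in bp covering every
#'   feature in \code{counts}.
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(counts, lengths) {
  m <- as_count_input(counts)
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing) > 0)
    stop("missing length for feature(s): ",
         paste(head(missing, 5), collapse = ", "))
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("feature lengths must be > 0")
  sweep(cpm(m), 1, len / 1e3, "/")
}
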