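#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors for count libraries.  For each sample k
#' against a reference sample r, over features with positive counts in
#' both, the log-ratio \eqn{M_g = \log_2((y_{gk}/N_k)/(y_{gr}/N_r))} and
#' abundance \eqn{A_g = \tfrac12 \log_2((y_{gk}/N_k)(y_{gr}/N_r))} are
#' doubly trimmed (30\% of M, 5\% of A by default) and the factor is the
#' weighted mean of the surviving M-values, with inverse asymptotic
#' variance weights
#' \eqn{w_g = (N_k-y_{gk})/(N_k y_{gk}) + (N_r-y_{gr})/(N_r y_{gr})^{-1}}
#' (delta-method binomial variance of M).  Factors are rescaled so their
#' geometric mean is 1, so multiplying library sizes by the factors leaves
#' total depth comparable.
#'
#' @param counts a \code{count_matrix} or numeric matrix with >= 2 samples.
#' @param ref_sample optional column index or name of the reference sample;
#'   by default the sample whose upper quartile of CPM is closest to the
#'   mean upper quartile.
#' @param trim_m two-sided trim fraction on M-values (default 0.30).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return named numeric vector of per-sample normalization factors with
#'   geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        trim_m = 0.30, trim_a = 0.05) {
  m <- as_count_input(counts)
  if (ncol(m) < 2) stop("tmm_factors needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("every library size must be > 0")

  if (is.null(ref_sample)) {
    uq <- apply(cpm(m), 2, quantile, probs = 0.75)
    ref_sample <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    ref_sample <- match(ref_sample, colnames(m))
    if (is.na(ref_sample)) stop("ref_sample not found among sample ids")
  }

  yr <- m[, ref_sample]
  nr <- lib[ref_sample]
  f <- vapply(seq_len(ncol(m)), function(k) {
    if (k == ref_sample) return(1)
    .tmm_pair(m[, k], lib[k], yr, nr, trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

## one sample against the reference; returns an unscaled factor
.tmm_pair <- function(yk, nk, yr, nr, trim_m, trim_a) {
  pos <- yk > 0 & yr > 0
  yk <- yk[pos]; yr <- yr[pos]
  if (length(yk) == 0) {
    warning("no features shared with the reference; factor set to 1")
    return(1)
  }
  pk <- yk / nk
  pr <- yr / nr
  M <- log2(pk / pr)
  A <- 0.5 * log2(pk * pr)

  n <- length(M)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  keep <- rank(M, ties.method = "first") >= loM &
    rank(M, ties.method = "first") <= hiM &
    rank(A, ties.method = "first") >= loA &
    rank(A, ties.method = "first") <= hiA
  if (!any(keep)) {
    warning("no features survive the TMM trim; factor set to 1")
    return(1)
  }
  w <- 1 / ((nk - yk[keep]) / (nk * yk[keep]) + (nr - yr[keep]) / (nr * yr[keep]))
  2^(sum(w * M[keep]) / sum(w))
}
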