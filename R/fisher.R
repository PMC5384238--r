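#' Fisher exact test for a 2x2 table
#'
#' Exact inference on a 2x2 contingency table via the hypergeometric
#' distribution, conditioning on both margins.  The two-sided p-value sums
#' the probabilities of all tables (with the observed margins) at most as
#' probable as the observed one, with the conventional relative tolerance
#' for ties; \code{"greater"} is the right tail of the first cell.  This is
#' the same definition as \code{stats::fisher.test} but computed directly
#' from \code{dhyper}, which keeps the very large number of pair
#' specificity tests cheap.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   rows = condition 1 (yes/no), columns = condition 2 (yes/no).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return list with \code{p_value}, the sample odds ratio
#'   \code{odds_ratio} = ad/bc (Inf when bc = 0 and ad > 0, NaN when both
#'   products are 0), and \code{odds_ratio_h} with the Haldane-Anscombe
#'   0.5 correction applied when any cell is zero (the p-value always comes
#'   from the uncorrected table).
#' @export
fisher_2x2 <- function(a, b, c, d,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")

  m <- a + b        # row 1 margin
  n <- c + d        # row 2 margin
  k <- a + c        # column 1 margin
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  obs <- probs[a - lo + 1]
  p <- switch(alternative,
    greater   = sum(probs[support >= a]),
    less      = sum(probs[support <= a]),
    two.sided = sum(probs[probs <= obs * (1 + 1e-7)]))
  p <- min(1, p)

  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf
        else NaN
  or_h <- if (any(cells == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)) else or
  list(p_value = p, odds_ratio = or, odds_ratio_h = or_h)
}
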