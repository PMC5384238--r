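## Negative-binomial exact test for two-group count data.
##
## Parameterization throughout: var = mu + phi * mu^2, i.e. NB size = 1/phi.
## phi = 0 is the Poisson limit, in which the conditional test reduces to a
## binomial exact test on the group totals.

#' Quantile-to-quantile adjustment of counts to a common library size
#'
#' Maps each observed count to the equivalent quantile of a negative
#' binomial with the same expression proportion but the common (geometric
#' mean) library size.  The percentile is computed under both a normal and
#' a gamma approximation to the NB and the two mapped values are averaged,
#' which is accurate across the count range while remaining smooth in the
#' non-integer output ("pseudo-counts").
#'
#' @param y count vector or matrix.
#' @param input_mean expected value of each count under its own library.
#' @param output_mean expected value under the common library.
#' @param dispersion NB dispersion phi (var = mu + phi mu^2).
#' @return pseudo-counts on the common-library scale (non-negative reals).
#' @keywords internal
q2q_nbinom <- function(y, input_mean, output_mean, dispersion) {
  eps <- 1e-10
  input_mean <- pmax(input_mean, eps)
  output_mean <- pmax(output_mean, eps)
  ri <- input_mean + dispersion * input_mean^2
  ro <- output_mean + dispersion * output_mean^2

  # work in the nearer tail for numerical accuracy
  lower <- y < input_mean
  p <- ifelse(lower,
              pnorm(y, mean = input_mean, sd = sqrt(ri)),
              pnorm(y, mean = input_mean, sd = sqrt(ri), lower.tail = FALSE))
  q1 <- ifelse(lower,
               qnorm(p, mean = output_mean, sd = sqrt(ro)),
               qnorm(p, mean = output_mean, sd = sqrt(ro), lower.tail = FALSE))

  shape_i <- input_mean^2 / ri
  shape_o <- output_mean^2 / ro
  p2 <- ifelse(lower,
               pgamma(y, shape = shape_i, scale = ri / input_mean),
               pgamma(y, shape = shape_i, scale = ri / input_mean,
                      lower.tail = FALSE))
  q2 <- ifelse(lower,
               qgamma(p2, shape = shape_o, scale = ro / output_mean),
               qgamma(p2, shape = shape_o, scale = ro / output_mean,
                      lower.tail = FALSE))
  q <- (q1 + q2) / 2
  # tail underflow on extreme outliers: fall back to linear scaling
  bad <- !is.finite(q)
  if (any(bad)) q[bad] <- (y * output_mean / input_mean)[bad]
  pmax(q, 0)
}

## Conditional (quantile-adjusted) log-likelihood of a common dispersion,
## summed over features and groups, for pseudo-counts at equal library
## sizes.  r = 1/phi; lgamma handles non-integer pseudo-counts.
.cond_loglik <- function(phi, pseudo, groups) {
  r <- 1 / phi
  ll <- 0
  for (g in levels(groups)) {
    yg <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(yg)
    if (n == 0) next
    z <- rowSums(yg)
    ll <- ll + sum(lgamma(yg + r)) + sum(lgamma(n * r) - lgamma(z + n * r)) -
      nrow(yg) * n * lgamma(r)
  }
  if (!is.finite(ll)) -Inf else ll
}

#' Common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the quantile-adjusted conditional likelihood over features
#' (libraries assumed equalized), profiling over
#' \code{delta = phi / (1 + phi)}.  Falls back to a method-of-moments
#' estimate from pooled CPM when optimization fails or is degenerate.
#'
#' @param pseudo matrix of (pseudo-)counts at a common library size.
#' @param groups two-level factor over columns.
#' @return scalar dispersion estimate phi >= 0.
#' @keywords internal
estimate_common_dispersion <- function(pseudo, groups) {
  mom <- function() {
    mu <- rowMeans(pseudo)
    v <- apply(pseudo, 1, var)
    ok <- is.finite(mu) & is.finite(v) & mu > 0
    if (!any(ok)) return(0)
    max(0, mean((v[ok] - mu[ok]) / mu[ok]^2))
  }
  opt <- tryCatch(
    optimize(function(delta) .cond_loglik(delta / (1 - delta), pseudo, groups),
             interval = c(1e-6, 0.95), maximum = TRUE),
    error = function(e) NULL)
  if (is.null(opt)) return(mom())
  delta <- opt$maximum
  # boundary solutions indicate a flat likelihood; use moments instead
  if (delta >= 0.949) return(mom())
  if (delta <= 2e-6) return(0)
  delta / (1 - delta)
}

## Exact conditional two-sided p-value for one feature, given the rounded
## group sums of pseudo-counts at equalized libraries.  Under a common phi
## the group sums are NB(n_j * lambda, size n_j / phi); conditional on the
## total, the p-value sums the probabilities of all splits at most as
## probable as the observed one.  phi = 0 uses the Poisson (binomial) limit.
.exact_split_pvalue <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  x <- 0:s
  if (phi <= 1e-12) {
    logp <- dbinom(x, size = s, prob = n1 / (n1 + n2), log = TRUE)
  } else {
    lambda <- s / (n1 + n2)
    logp <- dnbinom(x, size = n1 / phi, mu = n1 * lambda, log = TRUE) +
      dnbinom(s - x, size = n2 / phi, mu = n2 * lambda, log = TRUE)
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  obs <- p[s1 + 1]
  min(1, sum(p[p <= obs * (1 + 1e-10)]) / sum(p))
}

#' Negative-binomial exact test between two groups
#'
#' Per-feature exact test of differential abundance between the control and
#' tumour groups of a count matrix.  A common dispersion is estimated
#' across features by conditional maximum likelihood; libraries are
#' equalized to the geometric mean effective library size by quantile
#' adjustment; each feature's p-value is the exact conditional probability
#' of group-sum splits at most as probable as the one observed.  Log2 fold
#' changes (tumour vs control) use normalized group means with a small
#' prior count so zeros give finite estimates.
#'
#' @param counts a \code{count_matrix} with both groups present.
#' @param factors per-sample normalization factors (e.g. from
#'   \code{\link{tmm_factors}}); default all 1.
#' @param dispersion optional fixed dispersion phi; estimated when NULL.
#' @param prior_count prior added to each group mean for the fold change,
#'   default 0.125.
#' @return data.frame with columns \code{feature_id}, \code{log2fc},
#'   \code{avg_log2cpm}, \code{pvalue}, plus the estimated common
#'   \code{dispersion} as an attribute.
#' @export
nb_exact_test <- function(counts, factors = NULL, dispersion = NULL,
                          prior_count = 0.125) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  groups <- droplevels(counts$groups)
  if (nlevels(groups) != 2)
    stop("nb_exact_test needs both a control and a tumour group")
  if (is.null(factors)) factors <- rep(1, ncol(m))
  lib <- colSums(m)
  eff <- lib * factors
  if (any(eff <= 0)) stop("effective library sizes must be > 0")
  if (any(vapply(levels(groups),
                 function(g) sum(m[, groups == g]) == 0, logical(1))))
    stop("a group has zero total count for every feature")
  n_star <- exp(mean(log(eff)))

  # iterate pseudo-counts and common dispersion (two passes suffice)
  phi <- if (is.null(dispersion)) 0.1 else dispersion
  pseudo <- m
  for (it in 1:2) {
    prop <- rowSums(m) / sum(eff)
    mu_in <- outer(prop, eff)
    pseudo <- q2q_nbinom(m, mu_in, outer(prop, rep(n_star, ncol(m))), phi)
    if (is.null(dispersion)) {
      phi <- estimate_common_dispersion(pseudo, groups)
    } else break
  }

  g1 <- groups == "control"
  g2 <- groups == "tumour"
  n1 <- sum(g1); n2 <- sum(g2)
  s1 <- round(rowSums(pseudo[, g1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, g2, drop = FALSE]))
  pvals <- vapply(seq_len(nrow(m)), function(i)
    .exact_split_pvalue(s1[i], s2[i], n1, n2, phi), numeric(1))

  cpm1 <- s1 / (n1 * n_star) * 1e6
  cpm2 <- s2 / (n2 * n_star) * 1e6
  log2fc <- log2((cpm2 + prior_count) / (cpm1 + prior_count))
  avg <- log2((s1 + s2) / ((n1 + n2) * n_star) * 1e6 + prior_count)

  out <- data.frame(feature_id = rownames(m), log2fc = log2fc,
                    avg_log2cpm = avg, pvalue = pvals,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- phi
  out
}
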