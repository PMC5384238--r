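# Independent oracle implementations used to check package results.
# These are deliberately written from first principles (choose/factorial
# arithmetic, explicit enumeration, direct formula transcription) and
# share no code with the implementation under test.

# Hypergeometric probability of a 2x2 table [[a,b],[c,d]] with fixed
# margins, via log-binomial coefficients.
oracle_table_prob <- function(a, b, c, d) {
  exp(lchoose(a + b, a) + lchoose(c + d, c) - lchoose(a + b + c + d, a + c))
}

# Exhaustive-enumeration Fisher p-values for a 2x2 table.
oracle_fisher <- function(a, b, c, d, alternative) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x)
    oracle_table_prob(x, m - x, k - x, n - k + x), numeric(1))
  obs <- probs[xs == a]
  switch(alternative,
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]),
         two.sided = min(1, sum(probs[probs <= obs * (1 + 1e-7)])))
}

# Sorted step-up cummin BH oracle.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(n / (n:1) * p[o]))
  q[order(o)]
}

# Literal-formula TMM oracle: straightforward transcription with
# order()-based double trimming and inverse-variance weighting.
oracle_tmm <- function(counts, ref, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f <- rep(1, ncol(counts))
  for (k in seq_len(ncol(counts))) {
    if (k == ref) next
    ok <- counts[, k] > 0 & counts[, ref] > 0
    yk <- counts[ok, k]; yr <- counts[ok, ref]
    M <- log2((yk / lib[k]) / (yr / lib[ref]))
    A <- 0.5 * log2((yk / lib[k]) * (yr / lib[ref]))
    nn <- length(M)
    cutM <- floor(nn * trim_m)
    cutA <- floor(nn * trim_a)
    keepM <- order(M)[(cutM + 1):(nn - cutM)]
    keepA <- order(A)[(cutA + 1):(nn - cutA)]
    keep <- intersect(keepM, keepA)
    v <- (lib[k] - yk[keep]) / (lib[k] * yk[keep]) +
      (lib[ref] - yr[keep]) / (lib[ref] * yr[keep])
    f[k] <- 2^(sum(M[keep] / v) / sum(1 / v))
  }
  f / exp(mean(log(f)))
}

# Exhaustive conditional binomial two-sided p-value: all splits of the
# total s between n1 and n2 samples, summing probabilities at most the
# observed one.
oracle_binom_split <- function(s1, s2, n1, n2) {
  s <- s1 + s2
  pr <- n1 / (n1 + n2)
  probs <- vapply(0:s, function(x) choose(s, x) * pr^x * (1 - pr)^(s - x),
                  numeric(1))
  obs <- probs[s1 + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

# Exhaustive Cox partial likelihood for a single covariate, no ties:
# direct product over event times, maximized by grid + optimize.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_fit <- function(time, event, x) {
  optimize(oracle_cox_loglik, c(-10, 10), time = time, event = event,
           x = x, maximum = TRUE, tol = 1e-10)$maximum
}

# small fast simulation configuration shared by unit tests
small_config <- function(seed = 1, ...) {
  args <- list(n_tumour_types = 3, n_genes = 60, n_mirnas = 24,
               n_controls_per_type = 10, n_tumours_per_type = 15,
               n_planted_pairs = 4, planted_recurrence = 2,
               probes_per_gene = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

pk <- function(m, g) paste(sub("^hsa-", "", tolower(m)), g, sep = "|")
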