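test_that("beta-to-M transform closed forms and antisymmetry hold", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  b <- c(0.01, 0.2, 0.37, 0.5, 0.9)
  expect_equal(beta_to_m(b) + beta_to_m(1 - b), rep(0, 5))
  # clamping keeps boundary values finite
  expect_true(is.finite(beta_to_m(0)))
  expect_true(is.finite(beta_to_m(1)))
  expect_warning(mm <- beta_to_m(c(0.5, NA)), "NA")
  expect_true(is.na(mm[2]))
})

test_that("single-predictor correlation equals signed Pearson r", {
  set.seed(21)
  for (slope in c(-0.7, 0.4)) {
    x <- rnorm(40)
    y <- slope * x + rnorm(40)
    fit <- fit_pair_model(y, x)
    expect_equal(fit$correlation, cor(y, x), tolerance = 1e-10)
    expect_equal(fit$status, "fit")
  }
})

test_that("expression driven purely by CNA yields a null miRNA effect", {
  set.seed(22)
  pvals <- replicate(200, {
    cna <- sample(c(-1, 0, 1), 60, replace = TRUE)
    gene <- 0.8 * cna + rnorm(60)
    mir <- rnorm(60)
    fit_pair_model(gene, mir, cna = cna)$pvalue
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.1)
})

test_that("confounded repressive pairs are recovered with covariates", {
  set.seed(23)
  hits <- 0
  for (rep in 1:20) {
    n <- 60
    mir <- rnorm(n, 8, 1)
    cna <- sample(-2:2, n, replace = TRUE, prob = c(.05, .15, .6, .15, .05))
    met <- matrix(rnorm(n * 2), n, 2)
    gene <- 5 - 0.5 * mir + 0.4 * cna + 0.3 * rowMeans(met) + rnorm(n, 0, 0.4)
    fit <- fit_pair_model(gene, mir, cna = cna, met = met)
    if (fit$pvalue < 0.05 && fit$correlation < 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Type-III miRNA share is invariant to covariate entry order", {
  set.seed(24)
  n <- 50
  mir <- rnorm(n); cna <- sample(-1:1, n, TRUE)
  met <- matrix(rnorm(n * 3), n, 3)
  gene <- -0.4 * mir + 0.5 * cna + met %*% c(0.2, -0.3, 0.1) + rnorm(n)
  f1 <- fit_pair_model(gene, mir, cna = cna, met = met)
  f2 <- fit_pair_model(gene, mir, cna = cna, met = met[, 3:1])
  expect_equal(f1$correlation, f2$correlation, tolerance = 1e-10)
  expect_equal(f1$pvalue, f2$pvalue, tolerance = 1e-10)
})

test_that("joint model pools within-type slopes and flags cancellation", {
  set.seed(25)
  n <- 80
  type <- rep(c("A", "B"), each = n / 2)
  mir <- rnorm(n)
  # identical slope across types, no confounders
  gene <- -0.6 * mir + ifelse(type == "A", 2, -1) + rnorm(n, 0, 0.5)
  jf <- fit_joint_model(gene, mir, type)
  within_r <- mean(c(cor(gene[type == "A"], mir[type == "A"]),
                     cor(gene[type == "B"], mir[type == "B"])))
  expect_equal(sign(jf$correlation), sign(within_r))
  expect_equal(abs(jf$correlation), abs(within_r), tolerance = 0.15)

  # slopes of opposite sign cancel in the main effect
  gene2 <- ifelse(type == "A", 1, -1) * mir + rnorm(n, 0, 0.2)
  jf2 <- fit_joint_model(gene2, mir, type)
  expect_lt(abs(jf2$correlation), 0.15)

  expect_error(fit_joint_model(gene, mir, rep("A", n)), "fit_pair_model")
})

test_that("degenerate designs downgrade to nonexistent status", {
  out <- fit_pair_model(rep(1, 10), rnorm(10))
  expect_equal(out$status, "nonexistent")
  expect_equal(out$correlation, 0)
  tiny <- suppressWarnings(
    fit_pair_model(rnorm(3), rnorm(3), met = matrix(rnorm(9), 3, 3)))
  expect_equal(tiny$status, "nonexistent")
})

test_that("the FDR family spans pair x dataset and skips nonexistent rows", {
  set.seed(26)
  res <- data.frame(
    mirna = "m", gene = "g",
    dataset = c(paste0("T", 1:15), "joint"),
    n_samples = 30, correlation = runif(16, -1, 1),
    t_stat = 0, pvalue = runif(16), status = "fit",
    stringsAsFactors = FALSE)
  res$pvalue[3] <- NA; res$status[3] <- "nonexistent"
  adj <- adjust_pair_pvalues(res)
  ok <- adj$status == "fit"
  expect_equal(adj$fdr[ok], oracle_bh(res$pvalue[ok]))
  expect_true(is.na(adj$fdr[3]))
  # all-1 p-values stay 1
  res1 <- res; res1$pvalue <- 1; res1$status <- "fit"
  expect_true(all(adjust_pair_pvalues(res1)$fdr == 1))
})

test_that("final selection requires negative sign and joint significance", {
  res <- data.frame(
    mirna = c("m1", "m2", "m3"), gene = c("g1", "g2", "g3"),
    dataset = "joint", n_samples = 100,
    correlation = c(0.5, -0.3, -0.4), t_stat = 0,
    pvalue = c(1e-8, 0.01, 0.2), status = "fit",
    fdr = c(1e-6, 0.04, 0.3), stringsAsFactors = FALSE)
  sel <- select_significant_negative(res)
  expect_equal(sel$mirna, "m2")   # positive and non-significant excluded
})
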