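equal_lib_cm <- function(counts, groups) {
  # pad with a filler feature so all column sums are equal, which makes
  # the pseudo-count adjustment the identity
  total <- max(colSums(counts)) + 50
  filler <- total - colSums(counts)
  m <- rbind(counts, filler = filler)
  rownames(m) <- c(rownames(counts), "filler")
  count_matrix(m, groups)
}

test_that("poisson limit reproduces exhaustive conditional binomial", {
  set.seed(3)
  groups <- rep(c("control", "tumour"), c(3, 2))
  for (rep in 1:10) {
    counts <- matrix(rpois(5 * 4, 4), 4, 5,
                     dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
    cm <- equal_lib_cm(counts, groups)
    res <- nb_exact_test(cm, dispersion = 0)
    for (i in 1:4) {
      s1 <- sum(counts[i, 1:3]); s2 <- sum(counts[i, 4:5])
      if (s1 + s2 > 50) next
      expect_equal(res$pvalue[res$feature_id == paste0("g", i)],
                   oracle_binom_split(s1, s2, 3, 2), tolerance = 1e-10)
    }
  }
})

test_that("a feature with identical group means carries no signal", {
  groups <- rep(c("control", "tumour"), each = 4)
  counts <- matrix(20, 1, 8, dimnames = list("flat", paste0("s", 1:8)))
  cm <- equal_lib_cm(counts, groups)
  res <- nb_exact_test(cm, dispersion = 1e-13)
  p <- res$pvalue[res$feature_id == "flat"]
  expect_gte(p, 0.9)
  expect_lte(p, 1.0)
  expect_equal(res$log2fc[res$feature_id == "flat"], 0, tolerance = 1e-6)
})

test_that("p-values are invariant to feature order and group swap", {
  set.seed(11)
  m <- matrix(rnbinom(50 * 8, mu = 60, size = 10), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  g <- rep(c("control", "tumour"), each = 4)
  r1 <- nb_exact_test(count_matrix(m, g))
  perm <- sample(nrow(m))
  r2 <- nb_exact_test(count_matrix(m[perm, ], g))
  expect_equal(r1$pvalue[match(r2$feature_id, r1$feature_id)], r2$pvalue)

  r3 <- nb_exact_test(count_matrix(m, rev(g)))
  expect_equal(r1$pvalue, r3$pvalue, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r3$log2fc, tolerance = 1e-9)
})

test_that("common dispersion estimation recovers the truth", {
  set.seed(5)
  m <- matrix(rnbinom(1000 * 12, mu = 80, size = 1 / 0.15), 1000, 12,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:12)))
  cm <- count_matrix(m, rep(c("control", "tumour"), each = 6))
  res <- nb_exact_test(cm)
  expect_equal(attr(res, "dispersion"), 0.15, tolerance = 0.03)
})

test_that("degenerate inputs error clearly", {
  m <- matrix(0, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  m[, 3:4] <- 5
  cm <- count_matrix(m, rep(c("control", "tumour"), each = 2))
  expect_error(nb_exact_test(cm), "library|zero total")
  one_group <- count_matrix(m[, 3:4] + 1, c("tumour", "tumour"))
  expect_error(nb_exact_test(one_group), "group")
})
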