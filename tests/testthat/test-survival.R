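test_that("stage and Gleason coding reproduce the prognosis rules", {
  expect_equal(as.character(encode_prognosis(
    c("Stage I", "Stage IB", "Stage II", "Stage IIA"))),
    rep("good", 4))
  expect_equal(as.character(encode_prognosis(
    c("Stage III", "Stage IIIA", "Stage IV", "Stage X"))),
    rep("bad", 4))
  gl <- encode_prognosis(c("6", "7", "8", "10"), gleason = TRUE)
  expect_equal(as.character(gl), c("good", "good", "bad", "bad"))
  expect_warning(out <- encode_prognosis("Stage ???"), "parsed")
  expect_true(is.na(out))
})

test_that("cox estimates match an exhaustive partial-likelihood oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 10
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    time <- sort(rexp(n, 0.1)) + seq(0, 1e-3, length.out = n)  # no ties
    event <- rbinom(n, 1, 0.8)
    event[1:2] <- 1
    fit <- cox_fit(time, event, x)
    if (!fit$converged) next
    expect_equal(fit$loghr, oracle_cox_fit(time, event, x),
                 tolerance = 1e-6)
  }
})

test_that("log HR scales inversely with the expression unit", {
  set.seed(32)
  n <- 120
  x <- rnorm(n)
  haz <- 0.02 * exp(0.6 * x)
  time <- rexp(n, haz)
  event <- as.integer(time < quantile(time, 0.7))
  f1 <- cox_fit(time, event, x)
  f2 <- cox_fit(time, event, 2 * x)
  expect_equal(f1$loghr, 2 * f2$loghr, tolerance = 1e-6)
  expect_equal(f1$log2_hr, f1$loghr / log(2))
})

test_that("degenerate survival inputs are flagged not fit", {
  expect_warning(out <- cox_fit(rexp(20), rbinom(20, 1, 0.8),
                                rep(2, 20)), "constant")
  expect_false(out$converged)
  few <- cox_fit(rexp(5), c(1, 0, 0, 0, 0), rnorm(5))
  expect_false(few$converged)
  prog <- factor(rep("good", 30), levels = c("good", "bad"))
  expect_warning(one <- cox_fit(rexp(30), rbinom(30, 1, 0.9), rnorm(30),
                                prog), "single")
  expect_true(one$converged)   # expression effect still estimable
})

test_that("pair support requires both correlation and survival calls", {
  pair_results <- data.frame(
    mirna = "m", gene = "g", dataset = c("A", "B", "joint"),
    n_samples = 40, correlation = c(-0.5, -0.5, -0.5), t_stat = 0,
    pvalue = c(0.001, 0.001, 0.001), status = "fit",
    fdr = c(0.01, 0.01, 0.01), stringsAsFactors = FALSE)
  surv <- data.frame(
    feature_id = "g", tumour_type = c("A", "B"),
    loghr = 0.5, log2_hr = 0.7, se = 0.1,
    pvalue = c(0.001, 0.5), n = 40, n_events = 20, converged = TRUE,
    fdr = c(0.01, 0.8), stringsAsFactors = FALSE)
  comb <- combine_correlation_survival(pair_results, surv)
  expect_equal(nrow(comb), 2)
  expect_equal(comb$supported[comb$tumour_type == "A"], TRUE)
  expect_equal(comb$supported[comb$tumour_type == "B"], FALSE)
  expect_true(all(comb$n_supported_types == 1))
})

test_that("planted survival effects are recovered end to end", {
  # a gene with a real hazard effect in a cohort-sized single-type setting
  set.seed(33)
  n <- 300
  expr <- rnorm(n, 8, 1)
  bad <- rbinom(n, 1, 0.4)
  z <- (expr - mean(expr)) / sd(expr)
  t_event <- rexp(n, (1 / 500) * exp(0.8 * bad + 0.7 * z))
  t_cens <- rexp(n, (1 / 500) * 0.65)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  prog <- factor(ifelse(bad == 1, "bad", "good"), c("good", "bad"))
  fit <- cox_fit(time, event, z, prog)
  expect_true(fit$converged)
  expect_equal(fit$loghr, 0.7, tolerance = 0.25)
  expect_lt(fit$pvalue, 0.001)
})
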