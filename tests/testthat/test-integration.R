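de_row <- function(ids, dir = "up")
  data.frame(feature_id = ids, direction = dir, stringsAsFactors = FALSE)

test_that("recurrence bookkeeping counts distinct types with directions", {
  per_type <- list(
    A = de_row(c("f1", "f2")),
    B = rbind(de_row("f1"), de_row("f3", "down")),
    C = de_row("f3", "down"))
  tab <- recurrence_table(per_type)
  expect_equal(tab$recurrence[tab$feature_id == "f1"], 2)
  expect_equal(tab$recurrence[tab$feature_id == "f2"], 1)
  expect_false("f4" %in% tab$feature_id)

  # a feature up in one type and down in another keeps both directions
  mixed <- list(A = de_row("rb1", "up"), B = de_row("rb1", "down"))
  tm <- recurrence_table(mixed)
  expect_equal(tm$recurrence, 2)
  expect_equal(tm$directions, "up,down")

  expect_equal(nrow(recurrence_table(list())), 0)
  expect_error(recurrence_table(list(A = de_row("x"), A = de_row("y"))),
               "distinct")
})

test_that("threshold scan picks the designed cut-off", {
  # known features planted at recurrence >= 8; background spread uniformly
  build_table <- function(seed) {
    set.seed(seed)
    known <- paste0("k", 1:40)
    other <- paste0("o", 1:200)
    data.frame(
      feature_id = c(known, other),
      recurrence = c(sample(8:10, 40, replace = TRUE),
                     sample(1:10, 200, replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  universe <- c(paste0("k", 1:40), paste0("o", 1:200), paste0("u", 1:200))
  hits <- 0
  for (seed in 1:10) {
    tab <- build_table(seed)
    out <- optimize_threshold(tab, paste0("k", 1:40), universe, 5:10)
    expect_equal(nrow(out$scan), 6)
    expect_true(all(diff(out$scan$n_selected) <= 0))
    if (out$threshold == 8) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("degenerate scans are rejected", {
  tab <- data.frame(feature_id = c("a", "b"), recurrence = c(9, 9))
  # known set = universe: no enrichment is possible
  expect_error(optimize_threshold(tab, c("a", "b"), c("a", "b"), 5:10),
               "no enrichable threshold")
  expect_error(optimize_threshold(tab, "z", c("a", "b"), 5:10), "missing")
})

test_that("recurrent selection respects the threshold bounds", {
  tab <- recurrence_table(list(A = de_row("f1"), B = de_row("f1"),
                               C = de_row("f2")))
  expect_equal(nrow(select_recurrent(tab, 1)), 2)
  expect_equal(select_recurrent(tab, 2)$feature_id, "f1")
  expect_equal(nrow(select_recurrent(tab, 4)), 0)
})

test_that("planted features reach the recurrence cut-off in simulation", {
  sim <- generate_cohort(small_config(seed = 4, planted_recurrence = 3))
  de_g <- lapply(sim$truth$de_genes_by_type, identity)
  tab <- recurrence_table(de_g)
  planted <- unique(unlist(lapply(de_g, function(d) d$feature_id)))
  sel <- select_recurrent(tab, 3)
  expect_true(all(planted %in% sel$feature_id))
})
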