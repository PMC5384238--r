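test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(pair_slope = 0.2), "pair_slope")
  expect_error(sim_config(planted_recurrence = 20, n_tumour_types = 10),
               "planted_recurrence")
  expect_error(sim_config(censor_rate = 1.2), "censor_rate")
  expect_error(sim_config(planted_de_fraction = 1), "planted_de_fraction")
  expect_error(sim_config(planted_de_fraction = 0, n_planted_pairs = 3),
               "n_planted_pairs")
})

test_that("a null configuration plants nothing", {
  sim <- generate_cohort(small_config(seed = 3, planted_de_fraction = 1e-9,
                                      n_planted_pairs = 0))
  expect_true(all(vapply(sim$truth$de_genes_by_type, nrow,
                         integer(1)) == 0))
  expect_equal(nrow(sim$truth$planted_pairs), 0)
})

test_that("the same configuration and seed reproduce the cohort exactly", {
  a <- generate_cohort(small_config(seed = 5))
  b <- generate_cohort(small_config(seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(small_config(seed = 6))
  expect_false(identical(a$cohort$types[[1]]$genes$counts,
                         c$cohort$types[[1]]$genes$counts))
})

test_that("generated values respect their domains", {
  sim <- generate_cohort(small_config(seed = 7))
  for (ty in sim$cohort$types) {
    expect_true(all(ty$genes$counts >= 0))
    expect_true(all(ty$genes$counts == round(ty$genes$counts)))
    expect_true(all(ty$met_beta > 0 & ty$met_beta < 1))
    expect_true(all(ty$cna %in% -2:2))
    expect_true(all(ty$clinical$time > 0))
    expect_true(all(ty$clinical$event %in% 0:1))
  }
  expect_true(all(sim$cohort$targets$agreement >= 1))
  # planted pairs always carry agreement >= 2 in the catalogue
  tk <- pk(sim$cohort$targets$mirna, sim$cohort$targets$gene)
  planted <- pk(sim$truth$planted_pairs$mirna, sim$truth$planted_pairs$gene)
  ag <- sim$cohort$targets$agreement[match(planted, tk)]
  expect_true(all(ag >= 2))
  # decoys at agreement 1 exist, and decoy edges dominate 10:1
  expect_gte(sum(sim$cohort$targets$agreement == 1), 1)
  expect_gte(nrow(sim$cohort$targets), 10 * length(planted))
})

test_that("planted pair members are DE with opposite directions in the
           planted number of types", {
  sim <- generate_cohort(small_config(seed = 9))
  tr <- sim$truth
  cfg_rec <- 2
  for (i in seq_len(nrow(tr$planted_pairs))) {
    g <- tr$planted_pairs$gene[i]
    m <- tr$planted_pairs$mirna[i]
    g_types <- names(Filter(function(d) g %in% d$feature_id,
                            tr$de_genes_by_type))
    m_types <- names(Filter(function(d) m %in% d$feature_id,
                            tr$de_mirnas_by_type))
    expect_gte(length(g_types), cfg_rec)
    expect_gte(length(m_types), cfg_rec)
    shared <- intersect(g_types, m_types)
    expect_gte(length(shared), 1)
    for (tt in shared) {
      dg <- tr$de_genes_by_type[[tt]]
      dm <- tr$de_mirnas_by_type[[tt]]
      expect_false(dg$direction[dg$feature_id == g] ==
                     dm$direction[dm$feature_id == m])
    }
  }
})

test_that("written cohorts round-trip through the readers", {
  sim <- generate_cohort(small_config(seed = 11))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(sim$cohort, dir)
  expect_true(all(c("gene_counts", "mirna_counts", "cna", "met_beta",
                    "clinical", "targets", "pathways") %in% manifest$kind))
  back <- read_cohort(dir)
  for (tt in names(sim$cohort$types)) {
    orig <- sim$cohort$types[[tt]]
    got <- back$types[[tt]]
    expect_equal(got$genes$counts, orig$genes$counts)
    expect_equal(got$mirnas$counts, orig$mirnas$counts)
    expect_identical(as.character(got$genes$groups),
                     as.character(orig$genes$groups))
    expect_equal(got$cna, orig$cna)
    expect_equal(got$met_beta, orig$met_beta)
    expect_equal(got$clinical$time, orig$clinical$time)
    expect_identical(got$clinical$stage_or_gleason,
                     orig$clinical$stage_or_gleason)
  }
  expect_equal(back$pathways, sim$cohort$pathways)
  expect_equal(back$targets, sim$cohort$targets)
  expect_equal(back$gene_lengths, sim$cohort$gene_lengths)
})

test_that("a cohort without methylation omits the MET files", {
  sim <- generate_cohort(small_config(seed = 13, probes_per_gene = 0))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(sim$cohort, dir)
  expect_true("met_absent" %in% manifest$kind)
  expect_false(file.exists(file.path(dir, names(sim$cohort$types)[1],
                                     "met_beta.tsv")))
  back <- read_cohort(dir)
  expect_equal(nrow(back$types[[1]]$met_beta), 0)
})

test_that("null pairs with zero confounders carry no partial correlation", {
  # pair_slope 0, cna/met effects 0: planted "pairs" are independent given
  # the group structure, so the per-type (tumour-only) model must stay null
  passes <- logical(6)
  for (s in 1:6) {
    sim <- generate_cohort(small_config(
      seed = 100 + s, pair_slope = 0, cna_effect = 0, met_effect = 0))
    reg <- pair_regression(sim$cohort, sim$truth$planted_pairs)
    reg <- adjust_pair_pvalues(reg)
    sel <- select_significant_negative(reg)
    passes[s] <- nrow(sel) > 0
  }
  expect_lte(mean(passes), 1 / 3)  # small-sample bound on the ~5% rate
})
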