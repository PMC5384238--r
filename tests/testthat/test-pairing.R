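de_tbl <- function(ids, dirs)
  data.frame(feature_id = ids, direction = dirs, stringsAsFactors = FALSE)

basic_catalog <- data.frame(
  mirna = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
  gene = c("G1", "G2", "G1", "G3"),
  agreement = c(2, 1, 3, 2),
  stringsAsFactors = FALSE)

test_that("candidate pairs require inverse DE and genomic agreement >= 2", {
  genes <- list(A = de_tbl(c("G1", "G2", "G3"), c("down", "down", "up")))
  mirs <- list(A = de_tbl(c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
                          c("up", "up", "up")))
  inst <- candidate_pairs(genes, mirs, basic_catalog)
  keys <- paste(inst$mirna, inst$gene)
  # agreement 2, inverse: emitted
  expect_true("hsa-miR-1 G1" %in% keys)
  # agreement 1: dropped even though inverse
  expect_false("hsa-miR-1 G2" %in% keys)
  # both up: not inverse
  expect_false("hsa-miR-3 G3" %in% keys)
  expect_true(all(inst$orientation == "miR-up/gene-down"))

  # pathway universe restriction
  inst2 <- candidate_pairs(genes, mirs, basic_catalog,
                           gene_universe = "G9")
  expect_equal(nrow(inst2), 0)
})

test_that("conserved pairs demand both members recurrent", {
  inst <- data.frame(mirna = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2"),
                     gene = c("G1", "G1", "G2"),
                     tumour_type = c("A", "B", "A"),
                     orientation = "miR-up/gene-down",
                     stringsAsFactors = FALSE)
  out <- conserved_pairs(inst, recurrent_genes = c("G1", "G2"),
                         recurrent_mirnas = "hsa-miR-1")
  expect_equal(nrow(out), 1)
  expect_equal(out$n_tumours, 2)
  expect_equal(out$tumour_types, "A,B")
  expect_equal(nrow(conserved_pairs(inst[0, ], "G1", "hsa-miR-1")), 0)
})

test_that("exclusivity is exact: one type, or a named type group", {
  inst <- data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3", "m3", "m3"),
    gene = c("G1", "G1", "G2", "G2", "G3", "G3", "G3"),
    tumour_type = c("LUAD", "LUSC", "LUAD", "BRCA", "LUAD", "LUSC", "BRCA"),
    orientation = "miR-up/gene-down", stringsAsFactors = FALSE)
  solo <- data.frame(mirna = "m4", gene = "G4", tumour_type = "LUAD",
                     orientation = "miR-down/gene-up",
                     stringsAsFactors = FALSE)
  inst <- rbind(inst, solo)

  excl <- exclusive_pairs(inst)
  expect_equal(excl$LUAD$gene, "G4")       # only the single-type pair
  expect_false("G1" %in% unlist(lapply(excl, `[[`, "gene")))

  lung <- exclusive_pairs(inst, group = c("LUAD", "LUSC"))
  expect_setequal(lung$gene, c("G1", "G4"))  # within the group only
  lung_both <- exclusive_pairs(inst, group = c("LUAD", "LUSC"),
                               require_all = TRUE)
  expect_equal(lung_both$gene, "G1")
  # a pair in 3 types is in no exclusive set
  expect_false("G3" %in% c(lung$gene, unlist(lapply(excl, `[[`, "gene"))))
})

test_that("specificity ranks a faithful pair above promiscuous ones", {
  # m targets only g across 10 tumours; background partners are spread
  faithful <- data.frame(mirna = "hsa-miR-9", gene = "GX",
                         tumour_type = paste0("T", 1:10),
                         orientation = "miR-up/gene-down",
                         stringsAsFactors = FALSE)
  set.seed(8)
  noise <- data.frame(mirna = paste0("m", sample(1:20, 60, replace = TRUE)),
                      gene = paste0("G", sample(1:20, 60, replace = TRUE)),
                      tumour_type = paste0("T", sample(1:10, 60, TRUE)),
                      orientation = "miR-up/gene-down",
                      stringsAsFactors = FALSE)
  inst <- rbind(faithful, noise)
  inst <- inst[!duplicated(paste(inst$mirna, inst$gene, inst$tumour_type)), ]
  res <- specificity_test(inst)
  top <- res[1, ]
  expect_equal(top$gene, "GX")
  expect_equal(top$a, 10)
  # p agrees with enumeration on its own table
  expect_equal(top$pvalue,
               oracle_fisher(top$a, top$b, top$c, top$d, "greater"),
               tolerance = 1e-12)

  # a one-off pair between promiscuous partners is unremarkable
  hub <- rbind(
    data.frame(mirna = "hub", gene = paste0("HG", 1:8),
               tumour_type = "T1", orientation = "miR-up/gene-down"),
    data.frame(mirna = paste0("hm", 1:8), gene = "HGX",
               tumour_type = "T1", orientation = "miR-up/gene-down"),
    data.frame(mirna = "hub", gene = "HGX", tumour_type = "T1",
               orientation = "miR-up/gene-down"))
  rh <- specificity_test(hub)
  expect_gt(rh$pvalue[rh$mirna == "hub" & rh$gene == "HGX"], 0.5)

  # invariance under tumour relabelling
  relab <- inst
  relab$tumour_type <- chartr("0123456789", "abcdefghij", relab$tumour_type)
  res2 <- specificity_test(relab)
  expect_equal(res$pvalue, res2$pvalue)
})

test_that("adding co-interactors never decreases a pair's specificity p", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    inst <- data.frame(
      mirna = paste0("m", sample(1:8, n, replace = TRUE)),
      gene = paste0("G", sample(1:8, n, replace = TRUE)),
      tumour_type = paste0("T", sample(1:6, n, replace = TRUE)),
      orientation = "miR-up/gene-down", stringsAsFactors = FALSE)
    inst <- inst[!duplicated(paste(inst$mirna, inst$gene,
                                   inst$tumour_type)), ]
    res <- specificity_test(inst)
    target <- res[sample(nrow(res), 1), ]
    # add a co-interactor instance for the target's miRNA (new gene)
    extra <- data.frame(mirna = target$mirna, gene = "NEWGENE",
                        tumour_type = "T1",
                        orientation = "miR-up/gene-down",
                        stringsAsFactors = FALSE)
    res2 <- specificity_test(rbind(inst, extra))
    p_before <- target$pvalue
    p_after <- res2$pvalue[res2$mirna == target$mirna &
                             res2$gene == target$gene]
    expect_gte(p_after, p_before - 1e-12)
  }
})

test_that("novelty flags come from the known-pair list", {
  pairs <- data.frame(mirna = c("hsa-miR-1", "hsa-miR-2"),
                      gene = c("G1", "G2"), stringsAsFactors = FALSE)
  known <- data.frame(mirna = "miR-1", gene = "G1",
                      stringsAsFactors = FALSE)  # different id convention
  out <- flag_novel(pairs, known)
  expect_equal(out$status, c("validated", "novel"))
  all_novel <- flag_novel(pairs, known[0, ])
  expect_true(all(all_novel$status == "novel"))
})
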