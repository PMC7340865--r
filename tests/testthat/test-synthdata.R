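test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(n_smokers = 125, n_samples = 125), "n_smokers")
  expect_error(synth_config(planted_cpg_ids = c(1, 99999)), "range")
  expect_error(synth_config(set_size_range = c(1, 5)), "set_size_range")
  expect_error(synth_config(frac_intergenic = 1.2), "frac_intergenic")
  expect_error(synth_config(noise_sd_m = -1), "non-negative")
})

test_that("generation is deterministic given config and seed", {
  cfg <- tiny_config(seed = 17)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset$beta, g2$dataset$beta)
  expect_identical(g1$dataset$sample_sheet, g2$dataset$sample_sheet)
  expect_identical(g1$genesets, g2$genesets)
  # GMT bytes identical across seeded runs
  f1 <- tempfile(); f2 <- tempfile()
  generate_genesets(cfg, a1, path = f1)
  generate_genesets(cfg, a2, path = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("annotation respects intergenic fraction and label vocabularies", {
  cfg_all_inter <- tiny_config(frac_intergenic = 1)
  ann <- generate_annotation(cfg_all_inter)
  expect_true(all(ann$UCSC_RefGene_Name == ""))
  expect_true(all(ann$Relation_to_UCSC_CpG_Island == "OpenSea"))

  cfg_one_gene <- synth_config(n_probes = 30, n_genes = 1, probes_per_gene = 3,
                               frac_intergenic = 0, n_sets = 0,
                               planted_cpg_ids = integer(0),
                               planted_set_name = NULL, n_samples = 10,
                               n_smokers = 2)
  ann1 <- generate_annotation(cfg_one_gene)
  expect_true(any(grepl("GENE0001", ann1$UCSC_RefGene_Name)))

  cfg <- tiny_config()
  ann2 <- generate_annotation(cfg)
  expect_true(all(ann2$CHR %in% as.character(1:22)))
  groups <- setdiff(unique(unlist(
    strsplit(ann2$UCSC_RefGene_Group, ";", fixed = TRUE))), "")
  expect_true(all(groups %in% c("TSS200", "TSS1500", "5'UTR", "1stExon",
                                "Body", "3'UTR")))
  gene_per_probe <- lengths(strsplit(ann2$UCSC_RefGene_Name, ";", fixed = TRUE))
  grp_per_probe <- lengths(strsplit(ann2$UCSC_RefGene_Group, ";", fixed = TRUE))
  expect_identical(gene_per_probe, grp_per_probe)
})

test_that("generated betas live strictly inside (0,1) and round-trip through M", {
  gen <- generate_dataset(tiny_config(seed = 9))
  b <- gen$dataset$beta
  expect_gt(min(b), 0)
  expect_lt(max(b), 1)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-10)
})

test_that("cell proportions are a valid composition", {
  gen <- generate_dataset(tiny_config(seed = 2))
  props <- as.matrix(gen$dataset$sample_sheet[, c("CD8T", "CD4T", "NK",
                                                  "Bcell", "Mono", "Gran")])
  expect_true(all(props >= 0))
  expect_equal(unname(rowSums(props)), rep(1, nrow(props)), tolerance = 1e-9)
})

test_that("ground truth marks exactly the planted probes", {
  cfg0 <- tiny_config(planted_cpg_ids = integer(0), planted_set_name = NULL)
  gen0 <- generate_dataset(cfg0)
  expect_true(all(gen0$ground_truth$true_effect == 0))
  expect_length(gen0$ground_truth$causal_probe_ids, 0)

  cfg <- tiny_config(seed = 4, planted_set_name = NULL)
  gen <- generate_dataset(cfg)
  gt <- gen$ground_truth
  expect_false(anyDuplicated(gt$causal_probe_ids) > 0)
  expect_setequal(gt$causal_probe_ids,
                  names(gt$true_effect)[gt$true_effect != 0])
  planted <- gen$dataset$probe_ids[cfg$planted_cpg_ids]
  expect_equal(unname(gt$true_effect[planted]),
               rep(cfg$planted_cpg_delta_m, length(planted)))
})

test_that("noiseless construction reproduces the planted M difference exactly", {
  cfg <- tiny_config(n_probes = 40, planted_cpg_ids = 3,
                     planted_cpg_delta_m = 0.6, noise_sd_m = 0,
                     covariate_effect_scale = 0, chip_effect_sd = 0,
                     planted_set_name = NULL)
  gen <- generate_dataset(cfg)
  m <- beta_to_m(gen$dataset$beta)
  smok <- gen$dataset$sample_sheet$smoking == 1
  diff3 <- rowMeans(m[, smok]) - rowMeans(m[, !smok])
  planted <- gen$dataset$probe_ids[3]
  expect_equal(unname(diff3[planted]), 0.6, tolerance = 1e-10)
  expect_true(all(abs(diff3[setdiff(names(diff3), planted)]) < 1e-10))
})

test_that("gene sets have requested sizes and survive a GMT round trip", {
  cfg <- synth_config(n_probes = 400, n_genes = 60, n_sets = 3,
                      set_size_range = c(5, 5), planted_cpg_ids = integer(0),
                      planted_set_name = NULL, n_samples = 10, n_smokers = 2)
  ann <- generate_annotation(cfg)
  path <- tempfile(fileext = ".gmt")
  sets <- generate_genesets(cfg, ann, path = path)
  expect_identical(unname(lengths(sets)), rep(5L, 3))
  expect_identical(read_gmt(path), sets, ignore_attr = TRUE)

  cfg_big <- synth_config(n_probes = 50, n_genes = 4, n_sets = 2,
                          set_size_range = c(5, 30),
                          planted_cpg_ids = integer(0),
                          planted_set_name = NULL, n_samples = 10,
                          n_smokers = 2)
  ann_small <- generate_annotation(cfg_big)
  expect_error(generate_genesets(cfg_big, ann_small), "universe")
})

test_that("an unknown planted set name is rejected", {
  cfg <- tiny_config(planted_set_name = "NOT_A_SET")
  expect_error(generate_dataset(cfg), "NOT_A_SET")
})

test_that("chip structure is recoverable from the control probes", {
  cfg <- tiny_config(seed = 13)
  gen <- generate_dataset(cfg)
  pcs <- control_probe_pcs(gen$control, k = 2)
  chips <- gen$dataset$sample_sheet$chip
  # PC1 separates chips: between-chip variance dominates within-chip
  fit <- stats::aov(pcs[, 1] ~ chips)
  expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 1e-6)
})

test_that("written synthetic inputs read back identically", {
  gen <- generate_dataset(tiny_config(n_probes = 200, seed = 6))
  dir <- tempfile()
  paths <- write_synth_dataset(gen, dir)
  expect_true(all(file.exists(paths)))
  beta_back <- read_matrix_tsv(paths["beta"])
  expect_equal(beta_back, gen$dataset$beta, tolerance = 1e-12)
  ann_back <- read_annotation(paths["annotation"])
  expect_identical(ann_back$IlmnID, gen$annotation$IlmnID)
  expect_identical(ann_back$UCSC_RefGene_Name, gen$annotation$UCSC_RefGene_Name)
  sheet_back <- read_sample_sheet(paths["sample_sheet"])
  expect_identical(sheet_back$sample_id, gen$dataset$sample_sheet$sample_id)
  expect_equal(sheet_back$alcohol, gen$dataset$sample_sheet$alcohol)
})
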