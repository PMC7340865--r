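test_that("island-relation collapse is total and strand labels pool", {
  x <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
  expect_identical(collapse_island_relation(x),
                   c("Island", "Shore", "Shore", "Shelf", "Shelf", "OpenSea"))
  expect_error(collapse_island_relation("Lagoon"), "unknown island relation")
})

region_fixture <- function() {
  # 4 probes x 2 samples with hand-checkable means:
  #   cg1 Body      N_Shore   beta 0.2 / 0.4
  #   cg2 Body;5'UTR S_Shore  beta 0.4 / 0.6
  #   cg3 TSS200    Island    beta 0.6 / 0.8
  #   cg4 (none)    OpenSea   beta 0.5 / 0.5
  beta <- matrix(c(0.2, 0.4, 0.6, 0.5,
                   0.4, 0.6, 0.8, 0.5), 4, 2,
                 dimnames = list(paste0("cg", 1:4), c("A", "B")))
  ann <- data.frame(
    IlmnID = rownames(beta), CHR = "1", MAPINFO = 1:4 * 10L,
    UCSC_RefGene_Name = c("G1", "G1;G2", "G3", ""),
    UCSC_RefGene_Group = c("Body", "Body;5'UTR", "TSS200", ""),
    Relation_to_UCSC_CpG_Island = c("N_Shore", "S_Shore", "Island", "OpenSea"),
    stringsAsFactors = FALSE
  )
  sheet <- data.frame(
    sample_id = c("A", "B"), smoking = c(1, 0), age = 44, sex = 0, bmi = 25,
    CD8T = 0.1, CD4T = 0.2, NK = 0.1, Bcell = 0.1, Mono = 0.1, Gran = 0.4,
    chip = "c1", array_pos = "p1", stringsAsFactors = FALSE
  )
  methyl_dataset(beta, ann, sheet)
}

test_that("region means pool strand shores and multi-group probes correctly", {
  ds <- region_fixture()
  expect_warning(means <- region_means(ds), "no probes")
  # Shore pools cg1 + cg2; Body pools cg1 + cg2; 5'UTR is cg2 alone
  expect_equal(means["Shore", ], c(A = 0.3, B = 0.5))
  expect_equal(means["Body", ], c(A = 0.3, B = 0.5))
  expect_equal(means["5'UTR", ], c(A = 0.4, B = 0.6))
  expect_equal(means["TSS200", ], c(A = 0.6, B = 0.8))
  expect_equal(means["Island", ], c(A = 0.6, B = 0.8))
  expect_equal(means["OpenSea", ], c(A = 0.5, B = 0.5))
  expect_false("Shelf" %in% rownames(means))      # zero probes, omitted
  expect_identical(unname(attr(means, "n_probes")["Shore"]), 2L)
  # single-probe regions equal that probe's beta
  expect_equal(means["TSS200", ], ds$beta["cg3", ])
})

test_that("region means are invariant to probe order and constant where flat", {
  ds <- region_fixture()
  suppressWarnings(m1 <- region_means(ds))
  perm <- c(3, 1, 4, 2)
  ds2 <- methyl_dataset(ds$beta[perm, ], ds$annotation[perm, ],
                        ds$sample_sheet)
  suppressWarnings(m2 <- region_means(ds2))
  expect_equal(m2[rownames(m1), ], m1[rownames(m1), ], ignore_attr = TRUE)
  expect_equal(unname(m1["OpenSea", ]), c(0.5, 0.5))  # all-0.5 region
})

test_that("Wilcoxon rank-sum: exact enumeration, degenerate and tied cases", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 0.1)                  # most extreme split of C(6,3) = 20
  expect_identical(w$method, "exact")
  expect_identical(w$W, 6)                # ranks 1+2+3

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  allsame <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5))
  expect_equal(allsame$p, 1)
  expect_identical(allsame$method, "degenerate")

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("tied data match a brute-force permutation oracle", {
  set.seed(8)
  x <- sample(1:6, 10, replace = TRUE)    # ties guaranteed
  y <- sample(2:7, 10, replace = TRUE)
  got <- wilcoxon_rank_sum(x, y, mode = "normal")
  pooled <- c(x, y)
  nA <- length(x)
  EW <- nA * (length(pooled) + 1) / 2
  obs_dev <- abs(sum(rank(pooled)[1:nA]) - EW)
  devs <- replicate(1e5, {
    idx <- sample.int(length(pooled), nA)
    abs(sum(rank(pooled)[idx]) - EW)
  })
  p_perm <- mean(devs >= obs_dev)
  expect_lt(abs(got$p - p_perm), 0.01)
})

test_that("exact and normal modes agree within 10% for n >= 10 per group", {
  # relative agreement is assessed away from the far tail, where a normal
  # approximation's relative error necessarily diverges
  set.seed(14)
  for (rep in 1:50) {
    x <- rnorm(12)
    y <- rnorm(12)
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p
    pn <- wilcoxon_rank_sum(x, y, mode = "normal")$p
    expect_lt(abs(pe - pn) / pe, 0.1)
  }
})

test_that("a planted Shore-wide shift is detected with negative direction", {
  cfg <- tiny_config(n_probes = 2000, planted_cpg_ids = integer(0),
                     planted_set_name = NULL, planted_region = "Shore",
                     planted_region_delta_m = -0.3, noise_sd_m = 0.2,
                     seed = 21)
  gen <- generate_dataset(cfg)
  res <- region_analysis(gen$dataset)
  shore <- res[res$region == "Shore", ]
  expect_lt(shore$p, 0.05)
  expect_identical(shore$direction, -1)
  expect_equal(res$q_bh, bh_adjust(res$p), tolerance = 1e-12)
})

test_that("with no planted effects no region is extreme", {
  cfg <- tiny_config(n_probes = 1500, planted_cpg_ids = integer(0),
                     planted_set_name = NULL, seed = 33)
  gen <- generate_dataset(cfg)
  res <- region_analysis(gen$dataset)
  expect_identical(nrow(res), 10L)
  expect_gt(min(res$p), 1e-4)
  expect_true(all(res$median_smoker > 0 & res$median_smoker < 1))
})

test_that("region analysis requires both groups", {
  ds <- region_fixture()
  ds$sample_sheet$smoking <- c(1, 1)
  expect_error(region_analysis(ds), "both smokers and never")
})
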