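test_that("running moments reproduce the hand-enumerated N=4 case", {
  mom <- running_moments(c(3, 2, 1, 0), m = 2)
  expect_equal(mom$E[2], 2.5)   # mean of X_2 over all C(4,2) placements
  expect_equal(mom$V[2], 2.25)  # population variance over the 6 placements
})

test_that("running moments agree with exhaustive enumeration for all N <= 8", {
  set.seed(31)
  for (N in 4:8) {
    scores <- round(rnorm(N), 2)
    for (m in 2:(N - 1)) {
      mom <- running_moments(scores, m)
      ref <- moments_brute(scores, m)
      expect_equal(mom$E, ref$E, tolerance = 1e-12)
      expect_equal(mom$V, ref$V, tolerance = 1e-10)
    }
  }
})

test_that("constant scores make the full-list running sum deterministic", {
  mom <- running_moments(rep(3, 6), m = 3)
  expect_equal(mom$E[6], 9)
  expect_equal(mom$V[6], 0, tolerance = 1e-10)
  expect_error(running_moments(1:4, m = 4), "2 <= m < N")
  expect_error(running_moments(1:4, m = 1), "2 <= m < N")
})

test_that("toy GSZ equals the independent enumeration-based reference", {
  params <- gsz_params(min_set_size = 2, n_perm = 20)
  set.seed(17)
  for (rep in 1:5) {
    N <- 8
    s <- setNames(round(rnorm(N), 2), sprintf("g%02d", 1:N))
    members <- sample(names(s), 3)
    got <- gsz_score(s, members, params)
    expect_equal(got$gsz, gsz_brute(s, members, params), tolerance = 1e-10)
    expect_identical(got$size, 3L)
  }
})

test_that("degenerate and extreme configurations behave as documented", {
  params <- gsz_params(min_set_size = 2, n_perm = 20)
  s_const <- setNames(rep(1, 10), paste0("g", 1:10))
  expect_warning(res <- gsz_score(s_const, paste0("g", 1:3), params),
                 "all gene scores are equal")
  expect_equal(res$gsz, 0)

  # members are exactly the top-m genes of a strictly decreasing score list
  s <- setNames(seq(10, 1), paste0("g", 1:10))
  res_top <- gsz_score(s, paste0("g", 1:3), params)
  expect_identical(res_top$direction, "high-scoring end")
  expect_gt(res_top$gsz, 0)

  expect_error(gsz_score(s, paste0("g", 1:2), gsz_params(min_set_size = 5)),
               "outside")
})

test_that("permutation p-values honor their bounds", {
  null <- 1:50 / 10
  expect_equal(perm_pvalue(100, null), 1 / 51)   # above every null score
  expect_equal(perm_pvalue(-1, null), 1)         # below every null score
  params <- gsz_params(min_set_size = 2, n_perm = 30)
  s <- setNames(rnorm(40), paste0("g", 1:40))
  null1 <- permutation_null(s, paste0("g", 1:5), params, seed = 4)
  null2 <- permutation_null(s, paste0("g", 1:5), params, seed = 4)
  expect_identical(null1, null2)
  expect_length(null1, 30)
})

test_that("Gumbel fit recovers known parameters and the location maps to 1-1/e", {
  set.seed(12)
  # inverse-CDF draws from Gumbel(location 2, scale 1)
  x <- 2 - 1 * log(-log(runif(5000)))
  p0 <- evd_pvalue(3, x)
  expect_equal(attr(p0, "location"), 2, tolerance = 0.05)
  expect_equal(attr(p0, "scale"), 1, tolerance = 0.05)
  p_loc <- evd_pvalue(attr(p0, "location"), x)
  expect_equal(as.numeric(p_loc), 1 - exp(-1), tolerance = 1e-6)
  expect_gt(as.numeric(evd_pvalue(-50, x)), 0.999999)
  expect_error(evd_pvalue(1, rnorm(10)), ">= 20")
  expect_warning(pna <- evd_pvalue(1, rep(2, 25)), "degenerate")
  expect_true(is.na(pna))
})

test_that("asymptotic and empirical p-values are rank-concordant under the null", {
  set.seed(23)
  s <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  sets <- lapply(1:60, function(i) sample(names(s), 12))
  names(sets) <- sprintf("S%02d", 1:60)
  res <- analyze_collection(s, sets, gsz_params(n_perm = 200), seed = 6)
  rho <- cor(res$p_perm, res$p_asym, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("collection bookkeeping: universe intersection, q, order invariance", {
  set.seed(41)
  s <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  params <- gsz_params(min_set_size = 5, max_set_size = 30, n_perm = 40)

  sets <- list(
    all_outside = paste0("x", 1:10),            # no member scored
    ok = sample(names(s), 10),
    too_big = sample(names(s), 60),
    whole = names(s)                            # universe > max_set_size
  )
  kept <- intersect_universe(sets, s, params)
  expect_identical(names(kept), "ok")
  expect_identical(attr(kept, "n_excluded"), 3L)
  expect_error(intersect_universe(list(a = paste0("x", 1:3)), s, params),
               "no gene set")

  single <- analyze_collection(s, sets["ok"], params, seed = 2)
  expect_equal(single$q, single$p_asym)

  many <- lapply(1:15, function(i) sample(names(s), 8))
  names(many) <- sprintf("S%02d", 1:15)
  r1 <- analyze_collection(s, many, params, seed = 9)
  r2 <- analyze_collection(s, many[sample(15)], params, seed = 9)
  expect_identical(r1[order(r1$set), ], r2[order(r2$set), ])
})

test_that("per-category FDR adjusts each collection separately", {
  set.seed(55)
  s <- setNames(rnorm(120), sprintf("g%03d", 1:120))
  sets <- lapply(1:12, function(i) sample(names(s), 10))
  names(sets) <- sprintf("S%02d", 1:12)
  cats <- setNames(rep(c("GO-MF", "curated"), each = 6), names(sets))
  params <- gsz_params(n_perm = 40)
  res <- analyze_collection(s, sets, params, seed = 3, categories = cats)
  for (cc in unique(res$category)) {
    sub <- res[res$category == cc, ]
    expect_equal(sub$q, bh_adjust(sub$p_asym), tolerance = 1e-12)
  }
})
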