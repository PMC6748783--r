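test_that("median-of-ratios size factors match the hand-derived cases", {
  m <- matrix(rpois(40, 100), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m[m == 0] <- 1
  same <- count_matrix(cbind(m[, 1], m[, 1], m[, 1]))
  expect_equal(unname(size_factors(same)), rep(1, 3))

  two <- count_matrix(matrix(c(m[, 1], 2 * m[, 1]), 10, 2,
                             dimnames = list(paste0("g", 1:10), c("a", "b"))))
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)))

  single <- count_matrix(matrix(c(4, 9), 1, 2,
                                dimnames = list("g", c("a", "b"))))
  expect_equal(unname(size_factors(single)), c(2 / 3, 3 / 2))

  zeroes <- count_matrix(matrix(c(0, 5, 5, 0), 2, 2))
  expect_error(size_factors(zeroes), "filter")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  cm <- rand_cm(300, 6, lambda = 80, seed = 12)
  ours <- size_factors(cm)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts(cm))
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("common dispersion vanishes on Poisson data and constant columns", {
  A <- rand_cm(2000, 6, lambda = 100, seed = 3, prefix = c("g", "a"))
  B <- rand_cm(2000, 6, lambda = 100, seed = 4, prefix = c("g", "b"))
  expect_lt(estimate_common_dispersion(A, B), 0.02)

  flatA <- count_matrix(matrix(50, 20, 3, dimnames = list(NULL, paste0("a", 1:3))))
  flatB <- count_matrix(matrix(50, 20, 3, dimnames = list(NULL, paste0("b", 1:3))))
  expect_equal(estimate_common_dispersion(flatA, flatB), 0)
})

test_that("callers are label-symmetric and null on identical groups", {
  cm <- rand_cm(400, 8, lambda = 60, seed = 21)
  A <- cm[, 1:4]
  B <- cm[, 5:8]
  dup <- count_matrix(cbind(counts(A),
                            `colnames<-`(counts(A), paste0("d", 1:4))))
  Ad <- dup[, 1:4]; Bd <- dup[, 5:8]

  for (f in list(function(a, b) nb_exact_caller(a, b, phi = 0.1),
                 lognormal_caller, poisson_caller, binomial_caller)) {
    r_id <- f(Ad, Bd)
    expect_true(all(r_id$p[!is.na(r_id$p)] == 1))
    r_ab <- f(A, B)
    r_ba <- f(B, A)
    expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
  }

  # the rank caller thins stochastically when depths differ, so its exact
  # identical-groups tie requires equal effective depths (no thinning)
  x <- counts(cm)[, 1]
  flat <- count_matrix(matrix(rep(x, 8), ncol = 8,
                              dimnames = list(cm$gene_ids, paste0("c", 1:8))))
  r_rank <- rank_caller(flat[, 1:4], flat[, 5:8], seed = 7)
  expect_true(all(r_rank$p[!is.na(r_rank$p)] == 1))
  expect_equal(rank_caller(A, B, seed = 7)$p,
               rank_caller(B, A, seed = 7)$p, tolerance = 1e-12)
})

test_that("zero-total genes are filtered, not tested", {
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m[3, ] <- 0
  cm <- count_matrix(m)
  r <- nb_exact_caller(cm[, 1:3], cm[, 4:6], phi = 0.05)
  expect_true(is.na(r$p[3]))
  expect_false(r$significant[3])
  expect_equal(attr(r, "genes_filtered"), 1)
  expect_equal(attr(r, "genes_tested"), 9)
})

test_that("pooled exact tests reproduce enumeration on the 3-vs-1 fixture", {
  # gene g1 pools to A = 3, B = 1 at equal depths: two-sided binomial
  # p = P(|X - 2| >= 1 | X ~ Bin(4, 1/2)) = 1 - P(X = 2) = 0.625
  m <- rbind(g0 = c(1000, 1000, 1000, 1000),
             g1 = c(2, 1, 1, 0))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  cm <- count_matrix(m)
  A <- cm[, 1:2]; B <- cm[, 3:4]

  r_pois <- poisson_caller(A, B)
  expect_equal(r_pois$p[2], 0.625, tolerance = 1e-9)
  r_nb0 <- nb_exact_caller(A, B, phi = 0)
  expect_equal(r_nb0$p[2], 0.625, tolerance = 1e-9)

  # Fisher caller agrees with fisher.test on its own 2x2 table
  r_fish <- binomial_caller(A, B)
  tab <- matrix(c(3, sum(counts(A)) - 3, 1, sum(counts(B)) - 1), 2)
  expect_equal(r_fish$p[2], fisher.test(tab)$p.value, tolerance = 1e-7)
})

test_that("unmoderated log-normal caller equals the pooled t-test", {
  cm <- rand_cm(100, 8, lambda = 200, seed = 33)
  A <- cm[, 1:4]; B <- cm[, 5:8]
  r <- lognormal_caller(A, B, n_prior = 0)
  sf <- size_factors(countgof:::bind_groups(A, B))
  yA <- log(sweep(counts(A), 2, sf[1:4], `/`) + 0.5)
  yB <- log(sweep(counts(B), 2, sf[5:8], `/`) + 0.5)
  for (g in c(1, 17, 50)) {
    ref <- t.test(yA[g, ], yB[g, ], var.equal = TRUE)$p.value
    expect_equal(r$p[g], ref, tolerance = 1e-10)
  }
})

test_that("rank caller honours the exact rank-distribution floor at n = 3", {
  # a fully separated gene at 3 vs 3 can reach at best the smallest
  # achievable two-sided exact p, 2 * (1/20) = 0.1
  m <- rbind(g0 = rep(500, 6),
             sep = c(1, 2, 3, 400, 500, 600))
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  cm <- count_matrix(m)
  r <- rank_caller(cm[, 1:3], cm[, 4:6], seed = 1)
  expect_equal(r$p[2], 0.1)
  expect_false(any(r$significant))   # 0.1 can never pass FDR < 0.05 alone

  expect_error(rank_caller(cm[, 1:2], cm[, 3:6], seed = 1), "at least 3")
})

test_that("de_result invariants hold: q from p, significance from q", {
  cm <- rand_cm(500, 10, lambda = 30, seed = 44)
  r <- lognormal_caller(cm[, 1:5], cm[, 6:10], fdr = 0.2)
  tested <- !is.na(r$p)
  expect_equal(r$q[tested], bh_adjust(r$p[tested]))
  expect_equal(r$significant, !is.na(r$q) & r$q < 0.2)
  expect_true(all(r$p[tested] > 0 & r$p[tested] <= 1))
})
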