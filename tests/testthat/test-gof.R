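test_that("NB moment fit matches the closed-form parameter algebra", {
  # mean 10, unbiased variance 30: r = 100/20 = 5, p = 10/30, phi = 20/100
  x <- c(3, 3, 12, 14, 14, 14)
  expect_equal(mean(x), 10)
  expect_equal(var(x), 30)
  fit <- fit_nb_moments(x)
  expect_equal(fit$status, "ok")
  expect_equal(fit$r, 5)
  expect_equal(fit$p, 1 / 3)
  expect_equal(fit$phi, 0.2)

  expect_equal(fit_nb_moments(c(4, 4, 4))$status, "degenerate")
  expect_equal(fit_nb_moments(c(0, 1, 2))$status, "degenerate")  # var == mean
  expect_equal(fit_nb_moments(c(0, 0, 0))$status, "degenerate")
})

test_that("K-squared statistic reproduces reference values", {
  # reference statistics computed independently with scipy.stats
  # (normaltest / skewtest / kurtosistest), frozen here; for the exactly
  # symmetric vector the skewness z is 0 by definition so K^2 reduces to
  # the kurtosis component (-1.4352592385)^2
  r1 <- normal_gof(1:16)
  expect_equal(r1$statistic, 1.4352592385^2, tolerance = 1e-9)
  expect_equal(r1$p, 0.3570124796, tolerance = 1e-8)

  x2 <- c(1, 1, 1, 1, 2, 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233)
  r2 <- normal_gof(x2)
  expect_equal(r2$statistic, 18.7909215299, tolerance = 1e-8)
  expect_equal(r2$p, 0.0000831004, tolerance = 1e-6)

  x3 <- c(-3.1, -2.2, -1.5, -0.9, -0.4, -0.1, 0.0, 0.1, 0.2, 0.5, 0.8,
          1.3, 1.9, 2.4, 3.0, 3.3)
  r3 <- normal_gof(x3)
  expect_equal(r3$statistic, 0.0338050131, tolerance = 1e-8)
  expect_equal(r3$p, 0.9832395394, tolerance = 1e-8)

  # heavier tails -> larger statistic
  expect_gt(r2$statistic, r3$statistic)

  expect_equal(normal_gof(rep(2, 16))$status, "degenerate")
  expect_equal(normal_gof(rnorm(5))$status, "too_few")
})

test_that("log-normal test excludes zeroes and otherwise tests log counts", {
  expect_equal(lognormal_gof(c(0, 5, 8, 9, 10, 11, 12, 13))$status,
               "excluded_zeroes")
  expect_equal(lognormal_gof(rep(7, 10))$status, "degenerate")
  x <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  expect_equal(lognormal_gof(x)$p, normal_gof(log(x))$p)
})

test_that("Poisson dispersion test matches closed forms and detects NB", {
  r <- poisson_gof(c(1, 2, 3))
  expect_equal(r$statistic, 1)
  expect_equal(r$p, exp(-0.5))
  expect_equal(poisson_gof(c(5, 5, 5, 5))$p, 1)
  expect_equal(poisson_gof(c(0, 0, 0))$status, "too_few")

  set.seed(4)
  rej <- mean(replicate(1000, poisson_gof(rnbinom(16, mu = 100, size = 2))$p) < 0.05)
  expect_gt(rej, 0.9)   # overdispersion phi = 0.5 is essentially always caught
})

test_that("NB GOF p-values are floored, seeded and permutation-invariant", {
  cfg <- nb_gof_config(n_bootstrap = 99, seed = 5)
  x <- c(8, 12, 9, 15, 22, 5, 30, 11, 14, 19, 7, 25, 10, 13, 18, 21)
  r <- nb_gof(x, cfg)
  expect_gte(r$p, 1 / 100)
  expect_equal(nb_gof(x, cfg)$p, r$p)                 # same seed, same p
  set.seed(99)
  expect_equal(nb_gof(sample(x), cfg)$p, r$p)          # order-invariant
  expect_equal(nb_gof(rep(4, 10), cfg)$status, "degenerate")
})

test_that("BH adjustment matches the hand step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), p.adjust(c(0.5, NA, 0.01), "BH"))
})

test_that("the battery assigns coherent statuses and per-distribution BH", {
  m <- rbind(c(5, 9, 14, 3, 8, 12, 7, 10),   # ordinary gene
             c(0, 2, 1, 3, 0, 2, 1, 2),      # contains zeroes
             rep(6, 8),                      # constant
             rep(0, 8))                      # silent
  rownames(m) <- paste0("g", 1:4)
  colnames(m) <- paste0("r", 1:8)
  gt <- gof_battery(count_matrix(m), nb_gof_config(n_bootstrap = 99, seed = 1))

  expect_s3_class(gt, "gof_table")
  expect_equal(nrow(gt), 16)
  ln <- gt[gt$distribution == "lognormal", ]
  expect_equal(ln$status[ln$gene %in% c("g2", "g4")],
               rep("excluded_zeroes", 2))
  expect_equal(gt$status[gt$distribution == "normal" & gt$gene == "g3"],
               "degenerate")
  expect_equal(gt$status[gt$distribution == "poisson" & gt$gene == "g4"],
               "too_few")
  # invariants: adjusted >= raw; reject only when tested and below alpha
  tested <- gt$status == "tested"
  expect_true(all(gt$padj[tested] >= gt$p[tested]))
  expect_true(all(gt$reject == (tested & !is.na(gt$padj) & gt$padj < 0.05)))
  expect_true(all(is.na(gt$padj[!tested])))

  # one-gene matrix: BH is the identity
  one <- count_matrix(matrix(c(5, 9, 14, 3, 8, 12, 7, 10), 1, 8,
                             dimnames = list("g1", paste0("r", 1:8))))
  g1 <- gof_battery(one, nb_gof_config(n_bootstrap = 99, seed = 1))
  expect_equal(g1$padj[g1$status == "tested"], g1$p[g1$status == "tested"])
})

test_that("rejection summaries report fractions over tested genes only", {
  mk <- function(status, reject) {
    n <- length(status)
    data.frame(gene = paste0("g", seq_len(n)),
               distribution = rep("poisson", n),
               p = ifelse(status == "tested", 0.5, NA),
               padj = ifelse(status == "tested", 0.5, NA),
               reject = reject, status = status, stringsAsFactors = FALSE)
  }
  tab <- mk(rep("tested", 10), c(rep(TRUE, 7), rep(FALSE, 3)))
  class(tab) <- c("gof_table", "data.frame")
  s <- rejection_summary(tab)
  expect_equal(s$fraction, 0.7)
  expect_equal(s$percent, 70)

  tab2 <- rbind(mk(rep("tested", 7), rep(FALSE, 7)),
                mk(rep("excluded_zeroes", 3), rep(FALSE, 3)))
  tab2$distribution <- "lognormal"
  tab2$gene <- paste0("g", 1:10)
  class(tab2) <- c("gof_table", "data.frame")
  s2 <- rejection_summary(tab2)
  expect_equal(s2$fraction, 0)
  expect_equal(s2$tested, 7)
  expect_equal(s2$excluded_zeroes, 3)
})
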