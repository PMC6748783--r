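#' Method-of-moments negative binomial fit
#'
#' Fits NB(r, p) to one gene's cross-replicate counts by matching the sample
#' mean m and unbiased sample variance v: \eqn{r = m^2/(v - m)},
#' \eqn{p = m/v}, dispersion \eqn{\phi = 1/r} (variance \eqn{\mu + \phi\mu^2}).
#' The moment fit only exists for overdispersed data; when \eqn{v \le m}
#' (including constant and all-zero vectors) the fit is degenerate and the
#' NB goodness-of-fit test cannot be evaluated.
#'
#' @param x integer vector of counts, length >= 2.
#' @return object of class \code{"nb_fit"}: list with \code{mean},
#'   \code{variance}, \code{status} ("ok" or "degenerate") and, when ok,
#'   \code{r}, \code{p}, \code{phi}.
#' @examples
#' fit_nb_moments(c(6, 8, 12, 14))  # mean 10, variance > mean
#' @export
fit_nb_moments <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  m <- mean(x)
  v <- stats::var(x)
  if (v > m && m > 0) {
    fit <- list(mean = m, variance = v,
                r = m^2 / (v - m), p = m / v, phi = (v - m) / m^2,
                status = "ok")
  } else {
    fit <- list(mean = m, variance = v, r = NA_real_, p = NA_real_,
                phi = NA_real_, status = "degenerate")
  }
  class(fit) <- "nb_fit"
  fit
}

#' @export
print.nb_fit <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("nb_fit: mean %.4g, variance %.4g -> r = %.4g, p = %.4g, phi = %.4g\n",
                x$mean, x$variance, x$r, x$p, x$phi))
  else
    cat(sprintf("nb_fit: degenerate (mean %.4g, variance %.4g <= mean)\n",
                x$mean, x$variance))
  invisible(x)
}

# ---- D'Agostino-Pearson K^2 omnibus normality test -------------------------

# z-transform of sample skewness (D'Agostino 1970).
dagostino_skew_z <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

# z-transform of sample kurtosis (Anscombe & Glynn 1983).
dagostino_kurt_z <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  b2 <- mean((x - m)^4) / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  z <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  num <- 1 - 2 / a
  den <- 1 + z * sqrt(2 / (a - 4))
  (1 - 2 / (9 * a) - sign(den) * abs(num / den)^(1 / 3)) * sqrt(9 * a / 2)
}

#' Normality goodness-of-fit (D'Agostino-Pearson K-squared)
#'
#' Omnibus test combining the z-transforms of sample skewness and kurtosis:
#' \eqn{K^2 = Z_1^2 + Z_2^2}, referred to a chi-squared distribution with 2
#' degrees of freedom.  The kurtosis transform is unreliable for very small
#' samples, so at least \code{n_min} observations are required.
#'
#' @param x numeric vector.
#' @param n_min minimum sample size (default 8).
#' @return list with \code{statistic}, \code{p} and \code{status}
#'   ("tested", "too_few" or "degenerate"); \code{p} is \code{NA} unless
#'   status is "tested".
#' @export
normal_gof <- function(x, n_min = 8L) {
  if (length(x) < n_min)
    return(list(statistic = NA_real_, p = NA_real_, status = "too_few"))
  if (stats::var(x) == 0)
    return(list(statistic = NA_real_, p = NA_real_, status = "degenerate"))
  k2 <- dagostino_skew_z(x)^2 + dagostino_kurt_z(x)^2
  list(statistic = k2,
       p = max(stats::pchisq(k2, df = 2, lower.tail = FALSE),
               .Machine$double.xmin),   # guard against underflow to 0
       status = "tested")
}

#' Log-normality goodness-of-fit
#'
#' Applies \code{\link{normal_gof}} to \code{log(x)}.  The log transform is
#' undefined at zero, so any vector containing a zero count is excluded from
#' this test (status \code{"excluded_zeroes"}) rather than imputed.
#'
#' @inheritParams normal_gof
#' @return as \code{\link{normal_gof}}, with the additional status
#'   \code{"excluded_zeroes"}.
#' @export
lognormal_gof <- function(x, n_min = 8L) {
  if (any(x == 0))
    return(list(statistic = NA_real_, p = NA_real_, status = "excluded_zeroes"))
  normal_gof(log(x), n_min = n_min)
}

#' Poisson goodness-of-fit (dispersion index)
#'
#' Chi-squared dispersion test: \eqn{D = \sum_i (x_i - \bar x)^2 / \bar x}
#' referred to the upper tail of a chi-squared distribution with n - 1
#' degrees of freedom.  Under the Poisson null the conditional distribution
#' of the counts given their total makes D approximately chi-squared;
#' overdispersion inflates D.
#'
#' @param x integer vector of counts, length >= 2.
#' @return list with \code{statistic}, \code{p}, \code{status} ("tested" or
#'   "too_few" when the mean is zero).
#' @examples
#' poisson_gof(c(1, 2, 3))  # D = 1, p = exp(-1/2)
#' @export
poisson_gof <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (m == 0)
    return(list(statistic = NA_real_, p = NA_real_, status = "too_few"))
  d <- sum((x - m)^2) / m
  list(statistic = d,
       p = max(stats::pchisq(d, df = length(x) - 1, lower.tail = FALSE),
               .Machine$double.xmin),   # guard against underflow to 0
       status = "tested")
}

# ---- PGF-based NB goodness-of-fit ------------------------------------------

#' Configuration of the NB goodness-of-fit bootstrap
#'
#' The NB test statistic has no closed-form null distribution, so p-values
#' come from a parametric bootstrap: \code{n_bootstrap} samples are drawn
#' from the fitted NB, the statistic recomputed (re-estimating the
#' parameters each time), and the p-value is the +1-corrected exceedance
#' fraction, bounded below by \code{1/(n_bootstrap + 1)}.  At the default
#' \code{n_bootstrap = 1000} the floor is about 1e-3; 1e7 bootstraps push it
#' to about 1e-7 at proportional cost.
#'
#' @param n_bootstrap number of parametric bootstrap samples B.
#' @param weight_exponent exponent a >= 0 of the weight \eqn{t^a} in the
#'   statistic's integral; moderate values damp the region near t = 1 where
#'   the empirical PGF derivative is steep for large counts.
#' @param quadrature_order order of the Gauss-Legendre rule on [0, 1].
#' @param seed integer seed for the bootstrap draws.
#' @return object of class \code{"nb_gof_config"}.
#' @export
nb_gof_config <- function(n_bootstrap = 1000L, weight_exponent = 5,
                          quadrature_order = 64L, seed = 1L) {
  stopifnot(n_bootstrap >= 1, weight_exponent >= 0, quadrature_order >= 2)
  obj <- list(n_bootstrap = as.integer(n_bootstrap),
              weight_exponent = weight_exponent,
              quadrature_order = as.integer(quadrature_order),
              seed = as.integer(seed))
  class(obj) <- "nb_gof_config"
  obj
}

# Gauss-Legendre nodes/weights on [0,1], cached per order.
gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(order) {
  key <- as.character(order)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(order, 0, 1)
  }
  gl_cache[[key]]
}

# PGF statistic T_n for rows of a count matrix X (rows = samples of size n).
# The NB PGF G(t) = (p/(1-(1-p)t))^r satisfies (1-(1-p)t) G'(t) = r(1-p) G(t).
# With c1 = (v-m)/v = 1-p and c2 = m^2/v = r(1-p) (Poisson limit c1=0, c2=m
# when v <= m), the empirical defect is
#   D_n(t) = (1 - c1 t) G_n'(t) - c2 G_n(t),
# and T_n = n * int_0^1 D_n(t)^2 t^a dt by Gauss-Legendre quadrature.
nb_pgf_stat_rows <- function(X, a, rule) {
  n <- ncol(X)
  B <- nrow(X)
  t <- rule$x
  w <- rule$w
  mns <- rowMeans(X)
  vars <- rowSums((X - mns)^2) / (n - 1)
  c1 <- ifelse(vars > mns & vars > 0, (vars - mns) / vars, 0)
  c2 <- ifelse(vars > mns & vars > 0, mns^2 / vars, mns)
  xv <- as.vector(t(X))                      # sample-major within row blocks
  grp <- rep(seq_len(B), each = n)
  P <- exp(outer(xv, log(t)))                # t^x, (B*n) x K
  G <- rowsum(P, grp, reorder = FALSE) / n   # empirical PGF
  Gp <- sweep(rowsum(xv * P, grp, reorder = FALSE) / n, 2, t, `/`)  # x t^(x-1)
  D <- (1 - outer(c1, t)) * Gp - c2 * G
  wa <- w * t^a
  n * as.vector(D^2 %*% wa)
}

#' Negative binomial goodness-of-fit test
#'
#' Tests whether one gene's cross-replicate counts are compatible with a
#' negative binomial distribution, using a statistic built on the
#' probability generating function: the NB PGF satisfies the differential
#' identity \eqn{(1-(1-p)t)G'(t) = r(1-p)G(t)}, and the statistic integrates
#' the squared empirical defect of that identity over \eqn{t \in [0,1]}
#' with weight \eqn{t^a}.  The null distribution is obtained by parametric
#' bootstrap from the method-of-moments fit (parameters re-estimated for
#' every bootstrap sample).  The returned p-value is bounded below by
#' \code{1/(B+1)} and is invariant to reordering of \code{x}.
#'
#' @param x integer vector of counts, length >= 2.
#' @param cfg a \code{\link{nb_gof_config}}.
#' @return list with \code{statistic}, \code{p} and \code{status} ("tested"
#'   or "degenerate" when the moment fit does not exist).
#' @export
nb_gof <- function(x, cfg = nb_gof_config()) {
  stopifnot(inherits(cfg, "nb_gof_config"))
  fit <- fit_nb_moments(x)
  if (fit$status != "ok")
    return(list(statistic = NA_real_, p = NA_real_, status = "degenerate"))
  set.seed(cfg$seed)
  res <- nb_gof_fitted(sort(x), fit, cfg)
  list(statistic = res$statistic, p = res$p, status = "tested")
}

# Core bootstrap given an ok moment fit; assumes RNG state already seeded.
nb_gof_fitted <- function(x, fit, cfg) {
  rule <- gl_rule(cfg$quadrature_order)
  a <- cfg$weight_exponent
  n <- length(x)
  t_obs <- nb_pgf_stat_rows(matrix(x, nrow = 1), a, rule)
  B <- cfg$n_bootstrap
  exceed <- 0L
  chunk <- max(1L, min(B, floor(2e6 / (n * cfg$quadrature_order))))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    Xb <- matrix(stats::rnbinom(b * n, size = fit$r, prob = fit$p), nrow = b)
    tb <- nb_pgf_stat_rows(Xb, a, rule)
    exceed <- exceed + sum(tb >= t_obs)
    done <- done + b
  }
  list(statistic = t_obs, p = (1 + exceed) / (B + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate; a
#' validating wrapper around \code{stats::p.adjust(method = "BH")}.  Inputs
#' must lie in (0, 1]; \code{NA}s are tolerated and propagated (useful for
#' untested genes).
#'
#' @param p vector of raw p-values in (0, 1] (NAs allowed).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Cross-replicate goodness-of-fit battery
#'
#' Tests every gene's counts across replicates against four candidate
#' distributions: normal, log-normal, Poisson and negative binomial.  Raw
#' p-values are Benjamini-Hochberg adjusted separately within each
#' distribution over the genes actually tested for it, and a gene rejects a
#' model when its adjusted p-value falls below \code{alpha}.  Genes a test
#' cannot evaluate are carried with an explanatory status instead of a
#' p-value: \code{excluded_zeroes} (log-normal with zero counts),
#' \code{degenerate} (constant data; NB moment fit with variance <= mean)
#' or \code{too_few} (sample size below the normality test's minimum; mean
#' zero for the Poisson test).
#'
#' @param cm a \code{count_matrix}.
#' @param cfg a \code{\link{nb_gof_config}} for the NB bootstrap.
#' @param alpha critical adjusted p-value (default 0.05).
#' @param distributions subset of
#'   \code{c("normal", "lognormal", "poisson", "negbin")}.
#' @param n_min minimum replicates for the normality-based tests.
#' @return object of class \code{"gof_table"}: a long data.frame with
#'   columns \code{gene}, \code{distribution}, \code{p}, \code{padj},
#'   \code{reject}, \code{status}, with the battery parameters as
#'   attributes.  Summarise with \code{\link{rejection_summary}}.
#' @export
gof_battery <- function(cm, cfg = nb_gof_config(), alpha = 0.05,
                        distributions = c("normal", "lognormal",
                                          "poisson", "negbin"),
                        n_min = 8L) {
  stopifnot(inherits(cm, "count_matrix"))
  distributions <- match.arg(distributions, several.ok = TRUE)
  m <- cm$counts
  ng <- nrow(m)
  if (ncol(m) < 2) stop("need at least 2 replicates", call. = FALSE)
  res <- list()
  run_simple <- function(fun) {
    p <- numeric(ng); status <- character(ng)
    for (g in seq_len(ng)) {
      r <- fun(m[g, ])
      p[g] <- r$p; status[g] <- r$status
    }
    list(p = p, status = status)
  }
  if ("normal" %in% distributions)
    res$normal <- run_simple(function(x) normal_gof(x, n_min = n_min))
  if ("lognormal" %in% distributions)
    res$lognormal <- run_simple(function(x) lognormal_gof(x, n_min = n_min))
  if ("poisson" %in% distributions)
    res$poisson <- run_simple(poisson_gof)
  if ("negbin" %in% distributions) {
    p <- numeric(ng); status <- character(ng)
    rule <- gl_rule(cfg$quadrature_order)
    set.seed(cfg$seed)
    for (g in seq_len(ng)) {
      fit <- fit_nb_moments(m[g, ])
      if (fit$status != "ok") {
        p[g] <- NA_real_; status[g] <- "degenerate"
      } else {
        r <- nb_gof_fitted(sort(m[g, ]), fit, cfg)
        p[g] <- r$p; status[g] <- "tested"
      }
    }
    res$negbin <- list(p = p, status = status)
  }
  tab <- do.call(rbind, lapply(names(res), function(d) {
    p <- res[[d]]$p
    status <- res[[d]]$status
    padj <- rep(NA_real_, ng)
    tested <- status == "tested"
    padj[tested] <- bh_adjust(p[tested])
    data.frame(gene = cm$gene_ids, distribution = d, p = p, padj = padj,
               reject = !is.na(padj) & padj < alpha, status = status,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  attr(tab, "alpha") <- alpha
  attr(tab, "config") <- cfg
  class(tab) <- c("gof_table", "data.frame")
  tab
}

#' Per-distribution rejection summary
#'
#' Collapses a \code{\link{gof_battery}} result into one row per
#' distribution: genes tested, rejected, the rejected fraction (denominator
#' = genes tested; excluded/degenerate genes are reported separately), and
#' counts of each non-tested status.
#'
#' @param gt a \code{gof_table}.
#' @return object of class \code{"gof_summary"}: data.frame with columns
#'   \code{distribution}, \code{tested}, \code{rejected}, \code{fraction},
#'   \code{percent} (rounded to whole percent), \code{excluded_zeroes},
#'   \code{degenerate}, \code{too_few}.
#' @export
rejection_summary <- function(gt) {
  stopifnot(inherits(gt, "gof_table"), nrow(gt) > 0)
  out <- do.call(rbind, lapply(split(gt, gt$distribution), function(d) {
    tested <- sum(d$status == "tested")
    rejected <- sum(d$reject)
    data.frame(distribution = d$distribution[1],
               tested = tested, rejected = rejected,
               fraction = if (tested > 0) rejected / tested else 0,
               percent = if (tested > 0) round(100 * rejected / tested) else 0,
               excluded_zeroes = sum(d$status == "excluded_zeroes"),
               degenerate = sum(d$status == "degenerate"),
               too_few = sum(d$status == "too_few"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  ord <- match(c("poisson", "normal", "lognormal", "negbin"), out$distribution)
  out <- out[ord[!is.na(ord)], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gof_summary", "data.frame")
  out
}

#' @export
summary.gof_table <- function(object, ...) rejection_summary(object)

#' @export
print.gof_summary <- function(x, ...) {
  cat("Cross-replicate goodness-of-fit rejection summary\n")
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  df$fraction <- sprintf("%.3f", df$fraction)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.gof_table <- function(x, ...) {
  cat(sprintf("gof_table: %d genes x %d distributions (alpha = %g)\n",
              length(unique(x$gene)), length(unique(x$distribution)),
              attr(x, "alpha")))
  print(rejection_summary(x))
  invisible(x)
}

#' Histogram of goodness-of-fit p-values per distribution
#'
#' @param x a \code{gof_table}.
#' @param ... passed to \code{hist}.
#' @export
plot.gof_table <- function(x, ...) {
  dists <- unique(x$distribution)
  old <- graphics::par(mfrow = c(1, length(dists)))
  on.exit(graphics::par(old))
  for (d in dists) {
    p <- x$p[x$distribution == d & x$status == "tested"]
    graphics::hist(p, breaks = 20, main = d, xlab = "p-value",
                   col = "grey80", ...)
  }
  invisible(x)
}
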