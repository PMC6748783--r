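#' Median-of-ratios size factors
#'
#' Robust per-sample scaling factors in the DESeq lineage: for each sample,
#' the median over genes (restricted to genes positive in every sample) of
#' the ratio of its count to the gene's geometric mean across samples,
#' rescaled so the factors have geometric mean 1.
#'
#' @param cm a \code{count_matrix} with at least one gene positive in every
#'   sample.
#' @return named numeric vector of positive factors with geometric mean 1.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has positive counts in every sample; filter samples or genes first",
         call. = FALSE)
  lg <- log(m[pos, , drop = FALSE])
  gm <- rowMeans(lg)
  sf <- exp(apply(lg - gm, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- cm$sample_ids
  sf
}

#' Common NB dispersion by moments
#'
#' Averages per-gene method-of-moments dispersion estimates
#' \eqn{\hat\phi_g = \max(0, (s_g^2 - \bar x_g)/\bar x_g^2)} computed within
#' each group on size-factor-scaled counts, over all (gene, group) cells
#' whose scaled mean exceeds \code{mean_floor} (low-mean genes carry almost
#' no information about \eqn{\phi} and their truncated estimates are badly
#' biased).
#'
#' @param cmA,cmB \code{count_matrix} objects for the two groups (same
#'   genes, >= 2 samples each).
#' @param mean_floor minimum scaled group mean for a gene to contribute.
#' @return a single dispersion estimate \eqn{\hat\phi \ge 0}.
#' @export
estimate_common_dispersion <- function(cmA, cmB, mean_floor = 5) {
  stopifnot(inherits(cmA, "count_matrix"), inherits(cmB, "count_matrix"),
            ncol(cmA$counts) >= 2, ncol(cmB$counts) >= 2,
            identical(cmA$gene_ids, cmB$gene_ids))
  sf <- size_factors(bind_groups(cmA, cmB))
  nA <- ncol(cmA$counts)
  sA <- sweep(cmA$counts, 2, sf[seq_len(nA)], `/`)
  sB <- sweep(cmB$counts, 2, sf[-seq_len(nA)], `/`)
  phis <- c(group_phis(sA, mean_floor), group_phis(sB, mean_floor))
  if (length(phis) == 0) {
    warning("no gene exceeds the mean floor; returning phi = 0", call. = FALSE)
    return(0)
  }
  mean(phis)
}

group_phis <- function(s, mean_floor) {
  m <- rowMeans(s)
  v <- rowSums((s - m)^2) / (ncol(s) - 1)
  keep <- m > mean_floor
  pmax(0, (v[keep] - m[keep]) / m[keep]^2)
}

bind_groups <- function(cmA, cmB) {
  ids <- c(cmA$sample_ids, cmB$sample_ids)
  if (anyDuplicated(ids))
    stop("groups share sample ids", call. = FALSE)
  count_matrix(cbind(cmA$counts, cmB$counts))
}

# ---- shared exact-test engine ----------------------------------------------

# Two-sided exact p-values by the "sum of outcome probabilities <= observed
# outcome's probability" convention.  The three exact families used by the
# callers all have a log pmf on support 0..tot of the form
#   tabA[s] + tabB[tot - s] + lconst[gene]
# (conditional NB via the convolution identity NB(rA,q) + NB(rB,q) =
# NB(rA+rB,q); binomial; central hypergeometric), which the compiled kernel
# scans on a window mean_hint +/- (8 sd_hint + pad) extended to include the
# observed value.  For a unimodal pmf, any mass outside such a window lies
# in the tails and is at least as extreme as the observed value, so it is
# counted as extreme; the window bounds make that correction ~1e-13.
exact_two_sided_tables <- function(obs, tot, tabA, tabB, lconst,
                                   mean_hint, sd_hint, pad = 20) {
  if (length(obs) == 0) return(numeric(0))
  lo <- pmax(0, floor(pmin(mean_hint - 8 * sd_hint, obs) - pad))
  hi <- pmin(tot, ceiling(pmax(mean_hint + 8 * sd_hint, obs) + pad))
  cpp_exact_two_sided(as.integer(obs), as.integer(tot), as.integer(lo),
                      as.integer(hi), tabA, tabB,
                      rep_len(lconst, length(obs)))
}

# table construction for the conditional binomial (known success prob p0)
binom_tables <- function(tot, p0) {
  kmax <- max(tot)
  lf <- lgamma(0:kmax + 1)
  list(tabA = (0:kmax) * log(p0) - lf,
       tabB = (0:kmax) * log1p(-p0) - lf,
       lconst = lgamma(tot + 1))
}

# Assemble a de_result from per-gene raw p-values (NA = filtered).
de_result <- function(gene_ids, p, fdr, caller) {
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- bh_adjust(p[tested])
  out <- data.frame(gene = gene_ids, p = p, q = q,
                    significant = !is.na(q) & q < fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "caller") <- caller
  attr(out, "fdr") <- fdr
  attr(out, "genes_tested") <- sum(tested)
  attr(out, "genes_filtered") <- sum(!tested)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result [%s]: %d genes tested, %d filtered, %d significant at FDR < %g\n",
              attr(x, "caller"), attr(x, "genes_tested"),
              attr(x, "genes_filtered"), sum(x$significant), attr(x, "fdr")))
  invisible(x)
}

caller_prep <- function(cmA, cmB) {
  stopifnot(inherits(cmA, "count_matrix"), inherits(cmB, "count_matrix"),
            identical(cmA$gene_ids, cmB$gene_ids))
  comb <- bind_groups(cmA, cmB)
  sf <- size_factors(comb)
  nA <- ncol(cmA$counts)
  list(comb = comb, sf = sf, nA = nA, nB = ncol(cmB$counts),
       sfA = sf[seq_len(nA)], sfB = sf[-seq_len(nA)],
       genes = cmA$gene_ids)
}

#' NB exact-test caller
#'
#' Minimal caller matching the negative binomial assumption with a
#' conditional exact test (the edgeR-style construction): counts are scaled
#' to a common effective library by the size factors and rounded, each
#' group's sum is modelled as NB with size \eqn{n_g/\phi}, and the
#' two-sided p-value sums the conditional probabilities of all group-A sums
#' as or less probable than the observed one given the total.  \eqn{\phi =
#' 0} reduces to the conditional binomial test.  Genes with pooled total 0
#' are filtered, not tested.
#'
#' @param cmA,cmB \code{count_matrix} objects for the two groups (same genes).
#' @param phi common NB dispersion; \code{NULL} estimates it with
#'   \code{\link{estimate_common_dispersion}}.
#' @param fdr BH significance threshold.
#' @return a \code{de_result} data.frame (gene, p, q, significant).
#' @export
nb_exact_caller <- function(cmA, cmB, phi = NULL, fdr = 0.05) {
  prep <- caller_prep(cmA, cmB)
  if (is.null(phi)) phi <- estimate_common_dispersion(cmA, cmB)
  stopifnot(phi >= 0)
  scA <- round(sweep(cmA$counts, 2, prep$sfA, `/`))
  scB <- round(sweep(cmB$counts, 2, prep$sfB, `/`))
  SA <- rowSums(scA)
  S <- SA + rowSums(scB)
  tested <- S > 0
  p <- rep(NA_real_, length(S))
  if (any(tested)) {
    nA <- prep$nA; nB <- prep$nB
    obs <- SA[tested]; tot <- S[tested]
    if (phi < 1e-8) {
      p0 <- nA / (nA + nB)
      tb <- binom_tables(tot, p0)
      p[tested] <- exact_two_sided_tables(
        obs, tot, tb$tabA, tb$tabB, tb$lconst,
        mean_hint = tot * p0, sd_hint = sqrt(tot * p0 * (1 - p0)))
    } else {
      rA <- nA / phi; rB <- nB / phi
      fA <- rA / (rA + rB)
      overd <- (rA + rB + tot) / (rA + rB + 1)
      kmax <- max(tot)
      lf <- lgamma(0:kmax + 1)
      p[tested] <- exact_two_sided_tables(
        obs, tot,
        tabA = lgamma(0:kmax + rA) - lf,
        tabB = lgamma(0:kmax + rB) - lf,
        lconst = -(lgamma(tot + rA + rB) - lgamma(tot + 1) -
                     lgamma(rA + rB)) - lgamma(rA) - lgamma(rB),
        mean_hint = tot * fA,
        sd_hint = sqrt(pmax(tot * fA * (1 - fA) * overd, 0.25)))
    }
  }
  de_result(prep$genes, p, fdr, "nb")
}

#' Log-normal (moderated t) caller
#'
#' Minimal caller matching the log-normal assumption (the limma-style
#' construction): a two-sample pooled t-test on \code{log(scaled count +
#' 0.5)} with the per-gene variance shrunk toward the mean variance across
#' genes with a prior weight of \code{n_prior} pseudo-samples.  With
#' \code{n_prior = 0} this is the ordinary pooled t-test.  Genes with
#' pooled total 0, or constant within both groups, are filtered.
#'
#' @inheritParams nb_exact_caller
#' @param n_prior prior pseudo-sample weight of the variance moderation.
#' @return a \code{de_result}.
#' @export
lognormal_caller <- function(cmA, cmB, fdr = 0.05, n_prior = 4) {
  prep <- caller_prep(cmA, cmB)
  yA <- log(sweep(cmA$counts, 2, prep$sfA, `/`) + 0.5)
  yB <- log(sweep(cmB$counts, 2, prep$sfB, `/`) + 0.5)
  nA <- prep$nA; nB <- prep$nB
  S <- rowSums(cmA$counts) + rowSums(cmB$counts)
  mA <- rowMeans(yA); mB <- rowMeans(yB)
  ssA <- rowSums((yA - mA)^2); ssB <- rowSums((yB - mB)^2)
  df <- nA + nB - 2
  s2 <- (ssA + ssB) / df
  tested <- S > 0 & (s2 > 0 | mA != mB)
  p <- rep(NA_real_, length(S))
  if (any(tested)) {
    s2bar <- mean(s2[tested])
    s2mod <- (n_prior * s2bar + df * s2[tested]) / (n_prior + df)
    tt <- (mA[tested] - mB[tested]) / sqrt(s2mod * (1 / nA + 1 / nB))
    p[tested] <- 2 * stats::pt(-abs(tt), df = df + n_prior)
  }
  de_result(prep$genes, p, fdr, "lognormal")
}

#' Pooled Poisson caller
#'
#' Minimal caller matching the Poisson assumption: counts are pooled within
#' each group and the group-A pool is tested against a binomial with
#' success probability equal to group A's share of the effective depth
#' (exact conditional test).  Biological overdispersion is deliberately
#' ignored -- this caller exists to demonstrate the Poisson failure mode on
#' replicated data.
#'
#' @inheritParams nb_exact_caller
#' @return a \code{de_result}.
#' @export
poisson_caller <- function(cmA, cmB, fdr = 0.05) {
  prep <- caller_prep(cmA, cmB)
  SA <- rowSums(cmA$counts)
  S <- SA + rowSums(cmB$counts)
  p0 <- sum(prep$sfA) / sum(prep$sf)
  tested <- S > 0
  p <- rep(NA_real_, length(S))
  if (any(tested)) {
    obs <- SA[tested]; tot <- S[tested]
    tb <- binom_tables(tot, p0)
    p[tested] <- exact_two_sided_tables(
      obs, tot, tb$tabA, tb$tabB, tb$lconst,
      mean_hint = tot * p0, sd_hint = sqrt(tot * p0 * (1 - p0)))
  }
  de_result(prep$genes, p, fdr, "poisson")
}

#' Binomial (Fisher's exact) caller
#'
#' Minimal caller matching the binomial assumption (the DEGseq-style
#' construction): per gene, a 2x2 table of the gene's pooled count against
#' the rest of the library in each pooled group, tested with Fisher's exact
#' test on raw counts (no normalisation, mirroring the tool it represents).
#'
#' @inheritParams nb_exact_caller
#' @return a \code{de_result}.
#' @export
binomial_caller <- function(cmA, cmB, fdr = 0.05) {
  stopifnot(inherits(cmA, "count_matrix"), inherits(cmB, "count_matrix"),
            identical(cmA$gene_ids, cmB$gene_ids))
  SA <- rowSums(cmA$counts)
  SB <- rowSums(cmB$counts)
  libA <- sum(cmA$counts)
  libB <- sum(cmB$counts)
  S <- SA + SB
  tested <- S > 0
  p <- rep(NA_real_, length(S))
  if (any(tested)) {
    obs <- SA[tested]; tot <- S[tested]
    fr <- libA / (libA + libB)
    kmax <- max(tot)
    p[tested] <- exact_two_sided_tables(
      obs, tot,
      tabA = lchoose(libA, 0:kmax),
      tabB = lchoose(libB, 0:kmax),
      lconst = -lchoose(libA + libB, tot),
      mean_hint = tot * fr, sd_hint = sqrt(pmax(tot * fr * (1 - fr), 0.25)))
  }
  de_result(cmA$gene_ids, p, fdr, "binomial")
}

# Row-wise midranks of a genes x samples matrix, vectorised over genes.
row_midranks <- function(X) {
  n <- ncol(X)
  R <- matrix(0, nrow(X), n)
  for (j in seq_len(n)) {
    less <- integer(nrow(X))
    eq <- integer(nrow(X))
    for (k in seq_len(n)) {
      less <- less + (X[, k] < X[, j])
      eq <- eq + (X[, k] == X[, j])
    }
    R[, j] <- less + (eq + 1) / 2
  }
  R
}

#' Rank-based caller with Poisson resampling
#'
#' Minimal caller matching the non-parametric approach (the SAM-seq-style
#' construction): each sample's counts are down-sampled to the minimum
#' effective depth by Poisson thinning, the Mann-Whitney U statistic is
#' computed with midranks, and U is averaged over \code{n_resample}
#' thinnings.  The two-sided p-value refers the averaged statistic's
#' nearest achievable value to the exact null distribution of U.  With 3
#' samples per group the smallest achievable two-sided p is 0.1, so no
#' single gene can reach FDR < 0.05 on its own.
#'
#' @inheritParams nb_exact_caller
#' @param n_resample number of Poisson thinnings averaged per gene.
#' @param seed integer seed for the thinning draws.
#' @return a \code{de_result}.
#' @export
rank_caller <- function(cmA, cmB, fdr = 0.05, n_resample = 20, seed = 1L) {
  prep <- caller_prep(cmA, cmB)
  nA <- prep$nA; nB <- prep$nB
  if (nA < 3 || nB < 3)
    stop("rank_caller needs at least 3 samples per group (exact rank p-values are vacuous below that)",
         call. = FALSE)
  X <- prep$comb$counts
  ratio <- min(prep$sf) / prep$sf
  S <- rowSums(X)
  tested <- S > 0
  p <- rep(NA_real_, length(S))
  if (any(tested)) {
    Xt <- X[tested, , drop = FALSE]
    set.seed(seed)
    Ubar <- numeric(nrow(Xt))
    # thin columns in sorted-sample-id order so the draws do not depend on
    # group labelling: swapping groups then gives identical p-values
    col_order <- order(prep$comb$sample_ids)
    for (r in seq_len(n_resample)) {
      Xs <- Xt
      for (j in col_order[ratio[col_order] < 1])
        Xs[, j] <- stats::rpois(nrow(Xt), lambda = Xt[, j] * ratio[j])
      R <- row_midranks(Xs)
      Ubar <- Ubar + rowSums(R[, seq_len(nA), drop = FALSE]) - nA * (nA + 1) / 2
    }
    Ubar <- Ubar / n_resample
    u0 <- round(Ubar)
    lo <- pmin(u0, nA * nB - u0)
    p[tested] <- pmin(1, 2 * stats::pwilcox(lo, nA, nB))
  }
  de_result(prep$genes, p, fdr, "rank")
}
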