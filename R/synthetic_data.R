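#' Specification of a synthetic replicated count dataset
#'
#' Describes the generative model used by \code{\link{simulate_null_matrix}}:
#' a single biological condition measured in \code{n_samples} replicates.  A
#' fraction of genes is silent (true mean zero); each expressed gene g has a
#' mean \eqn{\mu_g} drawn log-uniformly from \code{mean_range} and counts
#' \eqn{X_{gj} \sim NB(s_j \mu_g, \phi(\mu_g))} with variance
#' \eqn{s_j\mu_g + \phi (s_j\mu_g)^2}, sampled as a gamma-Poisson mixture.
#' The dispersion follows \eqn{\phi(\mu) = \phi_0 + \phi_1/\mu}.  Optional
#' homogeneous Poisson background contamination emulates low-level genomic
#' DNA carry-over that makes silent genes appear lowly expressed.
#'
#' Defaults mirror the scale of a deeply sequenced Arabidopsis-style
#' experiment: 33,851 annotated genes of which about 18\% are silent, and 16
#' clean replicates.  Library-size factors default to mild lognormal
#' variation (sd 0.15 on the log scale, geometric mean 1) drawn once from the
#' spec's seed.
#'
#' @param n_genes,n_samples dimensions of the simulated matrix.
#' @param silent_fraction fraction of genes with true mean zero.
#' @param mean_range length-2 positive vector; expressed-gene means are
#'   log-uniform on this interval.
#' @param phi0,phi1 dispersion trend \eqn{\phi(\mu)=\phi_0+\phi_1/\mu}; both
#'   must be >= 0.  Set \code{phi1 = 0} for a constant dispersion.
#' @param libsize_factors per-sample positive multipliers of the gene means,
#'   or \code{NULL} to draw them (lognormal, sdlog 0.15, normalised to
#'   geometric mean 1).
#' @param contamination_rate expected background counts per gene per sample
#'   (Poisson, homogeneous across genes); 0 disables contamination.
#' @param outlier_sample optional sample index to corrupt with
#'   \code{\link{corrupt_outlier}} (noise_sd 0.5) after simulation.
#' @param seed integer seed; the same spec always yields the same matrix.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_genes = 33851L, n_samples = 16L,
                           silent_fraction = 6000 / 33851,
                           mean_range = c(10, 1000),
                           phi0 = 0.05, phi1 = 2,
                           libsize_factors = NULL,
                           contamination_rate = 0,
                           outlier_sample = NULL,
                           seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 1,
            silent_fraction >= 0, silent_fraction <= 1,
            length(mean_range) == 2, all(mean_range > 0),
            mean_range[1] <= mean_range[2],
            phi0 >= 0, phi1 >= 0, contamination_rate >= 0)
  if (!is.null(libsize_factors)) {
    stopifnot(length(libsize_factors) == n_samples, all(libsize_factors > 0))
  }
  if (!is.null(outlier_sample))
    stopifnot(outlier_sample >= 1, outlier_sample <= n_samples)
  obj <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              silent_fraction = silent_fraction, mean_range = mean_range,
              phi0 = phi0, phi1 = phi1, libsize_factors = libsize_factors,
              contamination_rate = contamination_rate,
              outlier_sample = outlier_sample, seed = as.integer(seed))
  class(obj) <- "synthetic_spec"
  obj
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d genes x %d samples, silent fraction %.3f\n",
    x$n_genes, x$n_samples, x$silent_fraction))
  cat(sprintf("  means log-uniform on [%g, %g]; phi(mu) = %g + %g/mu\n",
              x$mean_range[1], x$mean_range[2], x$phi0, x$phi1))
  cat(sprintf("  contamination rate %g; seed %d\n",
              x$contamination_rate, x$seed))
  invisible(x)
}

#' Simulate a null (single-condition) count matrix
#'
#' Draws a genes x samples matrix from the generative model described in
#' \code{\link{synthetic_spec}}.  All samples share the same gene means up to
#' library-size factors, so any two-group comparison within the matrix is a
#' true null.  The gene means, silent flags and library-size factors used
#' are attached as attribute \code{"truth"} for downstream checks.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a \code{count_matrix}.
#' @export
simulate_null_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  ns <- spec$n_samples
  n_silent <- round(spec$silent_fraction * ng)
  silent <- rep(FALSE, ng)
  if (n_silent > 0) silent[sample.int(ng, n_silent)] <- TRUE
  mu <- numeric(ng)
  n_expr <- ng - n_silent
  if (n_expr > 0) {
    lr <- log(spec$mean_range)
    mu[!silent] <- exp(stats::runif(n_expr, lr[1], lr[2]))
  }
  s <- spec$libsize_factors
  if (is.null(s)) {
    s <- exp(stats::rnorm(ns, 0, 0.15))
    s <- s / exp(mean(log(s)))
  }
  m <- matrix(0, ng, ns)
  if (n_expr > 0) {
    phi <- spec$phi0 + spec$phi1 / mu[!silent]
    mu_mat <- outer(mu[!silent], s)
    if (all(phi == 0)) {
      m[!silent, ] <- stats::rpois(n_expr * ns, lambda = mu_mat)
    } else {
      size <- ifelse(phi > 0, 1 / phi, Inf)
      m[!silent, ] <- stats::rnbinom(n_expr * ns, mu = mu_mat,
                                     size = rep(size, ns))
    }
  }
  if (spec$contamination_rate > 0)
    m <- m + stats::rpois(ng * ns, spec$contamination_rate)
  rownames(m) <- sprintf("gene%05d", seq_len(ng))
  colnames(m) <- sprintf("rep%02d", seq_len(ns))
  cm <- count_matrix(m)
  if (!is.null(spec$outlier_sample))
    cm <- corrupt_outlier(cm, colnames(m)[spec$outlier_sample],
                          noise_sd = 0.5, seed = spec$seed + 1L)
  attr(cm, "truth") <- list(mu = mu, silent = silent, libsize_factors = s)
  cm
}

#' Corrupt one sample with multiplicative noise
#'
#' Emulates a degraded replicate that correlates poorly with all others:
#' every count in the named column is multiplied by an independent lognormal
#' factor \eqn{e^{N(0,\sigma^2)}} and rounded.  Only that column changes;
#' \code{noise_sd = 0} is the identity.
#'
#' @param cm a \code{count_matrix}.
#' @param sample sample identifier of the column to corrupt.
#' @param noise_sd standard deviation of the log-normal noise (log scale).
#' @param seed integer seed.
#' @return a new \code{count_matrix}.
#' @export
corrupt_outlier <- function(cm, sample, noise_sd, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"), noise_sd >= 0)
  j <- match(sample, cm$sample_ids)
  if (is.na(j)) stop("unknown sample id: ", sample, call. = FALSE)
  m <- cm$counts
  if (noise_sd > 0) {
    set.seed(seed)
    m[, j] <- round(m[, j] * exp(stats::rnorm(nrow(m), 0, noise_sd)))
  }
  count_matrix(m)
}

#' Spike differential expression into one group
#'
#' Utility for power/sanity checks of the callers (the mock-comparison
#' experiment itself uses no spiked signal).  A random fraction of genes has
#' its counts in \code{groupB_samples} rescaled by \eqn{2^{log2fc}}:
#' binomial thinning for negative fold changes, added Poisson counts for
#' positive ones, identity for \code{log2fc = 0}.
#'
#' @param cm a \code{count_matrix}.
#' @param groupB_samples sample identifiers forming the perturbed group.
#' @param fraction fraction of genes to perturb.
#' @param log2fc log2 fold change applied to group B.
#' @param seed integer seed.
#' @return a list with elements \code{counts} (new \code{count_matrix}) and
#'   \code{spiked} (character vector of perturbed gene ids).
#' @export
spike_de <- function(cm, groupB_samples, fraction, log2fc, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"), fraction >= 0, fraction <= 1)
  jb <- match(groupB_samples, cm$sample_ids)
  if (length(jb) == 0 || anyNA(jb))
    stop("groupB_samples must be a non-empty subset of the sample ids", call. = FALSE)
  n_spike <- round(fraction * nrow(cm$counts))
  if (fraction > 0 && n_spike < 1)
    stop("fraction * n_genes must be >= 1 (or fraction = 0)", call. = FALSE)
  m <- cm$counts
  spiked <- character(0)
  if (n_spike > 0) {
    set.seed(seed)
    idx <- sample.int(nrow(m), n_spike)
    spiked <- rownames(m)[idx]
    f <- 2^log2fc
    block <- m[idx, jb, drop = FALSE]
    if (f < 1) {
      block[] <- stats::rbinom(length(block), size = block, prob = f)
    } else if (f > 1) {
      block[] <- block + stats::rpois(length(block), lambda = (f - 1) * block)
    }
    m[idx, jb] <- block
  }
  list(counts = count_matrix(m), spiked = spiked)
}
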