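#' Pairwise replicate correlation matrix
#'
#' Pearson correlation of gene expression between every pair of samples,
#' computed across all genes on \code{log(count + log_offset)} (the standard
#' scale for expression concordance) or on raw counts with \code{log =
#' FALSE}.  All genes are included; all-zero rows are constant on both
#' scales and contribute nothing to the covariance.
#'
#' @param cm a \code{count_matrix} with at least 2 samples.
#' @param log_offset positive pseudo-count added before the log transform.
#' @param log logical; transform to log scale first (default) or correlate
#'   raw counts.
#' @return a symmetric samples x samples matrix with unit diagonal.  A
#'   sample with zero variance across genes yields \code{NA} entries and a
#'   warning naming it.
#' @export
correlation_matrix <- function(cm, log_offset = 1, log = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (log) {
    stopifnot(log_offset > 0)
    m <- log(m + log_offset)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("sample(s) with zero variance across genes: ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}

#' Flag outlier replicates by median correlation
#'
#' A replicate is flagged when its median off-diagonal correlation with the
#' other replicates falls below \code{threshold}.  The default 0.95 sits in
#' the gap between a typical degraded replicate (R around 0.83-0.87) and
#' healthy replicates (R > 0.99).
#'
#' @param corr symmetric correlation matrix with sample ids as dimnames.
#' @param threshold flagging threshold in [0, 1].
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(corr, threshold = 0.95) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            threshold >= 0, threshold <= 1)
  if (nrow(corr) < 2) return(character(0))
  med <- vapply(seq_len(nrow(corr)),
                function(i) stats::median(corr[i, -i], na.rm = TRUE),
                numeric(1))
  ids <- colnames(corr)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(corr)))
  ids[!is.na(med) & med < threshold]
}

#' Down-sample every column to a common depth
#'
#' Draws, for each sample, a without-replacement subsample of its reads:
#' the vector of per-gene retained counts follows the multivariate
#' hypergeometric distribution with the column's counts as urn composition.
#' Every column sum equals \code{target_depth} exactly and every cell is at
#' most its original value.  This is the count-level analogue of
#' down-sampling read pairs to the shallowest replicate before realignment.
#'
#' @param cm a \code{count_matrix}.
#' @param target_depth positive integer, or \code{"min"} for the smallest
#'   library size; must not exceed any library size.
#' @param seed integer seed.
#' @return a \code{count_matrix} with equal column sums.
#' @export
downsample <- function(cm, target_depth = "min", seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  ls <- lib_sizes(cm)
  if (identical(target_depth, "min")) target_depth <- min(ls)
  stopifnot(length(target_depth) == 1, target_depth > 0,
            target_depth == round(target_depth))
  if (any(ls < target_depth))
    stop("target_depth exceeds the library size of sample(s): ",
         paste(names(ls)[ls < target_depth], collapse = ", "), call. = FALSE)
  set.seed(seed)
  m <- cm$counts
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- rmvhyper(m[, j], target_depth)
  }
  count_matrix(out)
}

# Multivariate hypergeometric draw: sequential conditional univariate
# hypergeometrics.  x: urn composition; k: number drawn (k <= sum(x)).
rmvhyper <- function(x, k) {
  total <- sum(x)
  if (k == total) return(x)
  res <- numeric(length(x))
  remaining <- total
  for (i in seq_along(x)) {
    if (k == 0) break
    if (remaining == k) {           # must take everything left
      res[i:length(x)] <- x[i:length(x)]
      return(res)
    }
    if (x[i] > 0) {
      d <- stats::rhyper(1, m = x[i], n = remaining - x[i], k = k)
      res[i] <- d
      k <- k - d
    }
    remaining <- remaining - x[i]
  }
  res
}
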