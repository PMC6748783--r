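#' Configuration of the mock-comparison false-positive experiment
#'
#' The experiment repeatedly splits one condition's replicate pool into two
#' disjoint groups of \code{nr} samples each and calls differential
#' expression between them.  Because both groups come from the same
#' condition the null hypothesis is true by construction and every
#' significant gene is a false positive.
#'
#' @param nr_range integer vector of per-group replicate numbers (default
#'   3:7).
#' @param n_iterations random splits per replicate number (default 100).
#' @param fdr BH significance threshold applied by every caller.
#' @param pool sample ids to draw from; \code{NULL} uses all samples minus
#'   any replicates flagged by \code{\link{flag_outliers}}.
#' @param callers character vector naming built-in callers (any of
#'   \code{"nb"}, \code{"lognormal"}, \code{"poisson"}, \code{"binomial"},
#'   \code{"rank"}) or a named list of functions
#'   \code{function(cmA, cmB, fdr)} returning a \code{de_result}.
#' @param seed integer seed; the full experiment (splits, thinnings,
#'   bootstraps) is reproducible from it.
#' @return object of class \code{"fp_config"}.
#' @export
fp_experiment_config <- function(nr_range = 3:7, n_iterations = 100L,
                                 fdr = 0.05, pool = NULL,
                                 callers = c("nb", "lognormal", "poisson",
                                             "binomial"),
                                 seed = 1L) {
  stopifnot(all(nr_range >= 1), n_iterations >= 1, fdr > 0, fdr < 1)
  obj <- list(nr_range = as.integer(nr_range),
              n_iterations = as.integer(n_iterations), fdr = fdr,
              pool = pool, callers = callers, seed = as.integer(seed))
  class(obj) <- "fp_config"
  obj
}

#' Draw one null split
#'
#' Samples \code{2 * nr} ids without replacement from the pool and assigns
#' the first \code{nr} to group A, the rest to group B: uniform over all
#' ordered disjoint pairs of nr-sets.
#'
#' @param pool character vector of sample ids.
#' @param nr per-group size; \code{2 * nr} must not exceed the pool size.
#' @return list with character vectors \code{A} and \code{B}.
#' @export
draw_null_split <- function(pool, nr) {
  if (2 * nr > length(pool))
    stop(sprintf("2*nr = %d exceeds pool size %d", 2 * nr, length(pool)),
         call. = FALSE)
  sel <- sample(pool, 2 * nr)
  list(A = sel[seq_len(nr)], B = sel[nr + seq_len(nr)])
}

builtin_callers <- function(names, phi = NULL) {
  funs <- list(
    nb = function(cmA, cmB, fdr) nb_exact_caller(cmA, cmB, phi = phi, fdr = fdr),
    lognormal = function(cmA, cmB, fdr) lognormal_caller(cmA, cmB, fdr = fdr),
    poisson = function(cmA, cmB, fdr) poisson_caller(cmA, cmB, fdr = fdr),
    binomial = function(cmA, cmB, fdr) binomial_caller(cmA, cmB, fdr = fdr),
    rank = function(cmA, cmB, fdr)
      rank_caller(cmA, cmB, fdr = fdr,
                  seed = sample.int(.Machine$integer.max, 1))
  )
  unknown <- setdiff(names, names(funs))
  if (length(unknown))
    stop("unknown caller(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  funs[names]
}

#' Run the mock-comparison false-positive experiment
#'
#' For every replicate number and iteration, one null split is drawn and
#' shared by all callers (a paired design, so caller differences are not
#' confounded by sampling), each caller produces per-gene q-values, and the
#' false-positive fraction (significant / tested genes) is recorded.  A
#' caller error in one iteration is recorded as \code{NA} and skipped, not
#' fatal.  Per-gene recurrence counts (how often each gene was called, per
#' caller and replicate number) are accumulated and available via
#' \code{\link{gene_recurrence}}.
#'
#' @param cm a \code{count_matrix} of same-condition replicates.
#' @param cfg an \code{\link{fp_experiment_config}}.
#' @return object of class \code{"fp_result"}: a data.frame with one row
#'   per (caller, nr, iteration) and columns \code{caller}, \code{nr},
#'   \code{iteration}, \code{fp_fraction}, \code{n_significant},
#'   \code{n_tested}, \code{set_a}, \code{set_b}.
#' @export
run_fp_experiment <- function(cm, cfg = fp_experiment_config()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(cfg, "fp_config"))
  pool <- cfg$pool
  if (is.null(pool)) {
    flagged <- if (ncol(cm$counts) >= 3)
      flag_outliers(correlation_matrix(cm)) else character(0)
    pool <- setdiff(cm$sample_ids, flagged)
  }
  stopifnot(all(pool %in% cm$sample_ids))
  if (2 * max(cfg$nr_range) > length(pool))
    stop("pool too small for the largest nr", call. = FALSE)
  callers <- if (is.list(cfg$callers)) cfg$callers else builtin_callers(cfg$callers)
  if (is.null(names(callers)) || any(!nzchar(names(callers))))
    stop("callers must be named", call. = FALSE)
  set.seed(cfg$seed)
  rows <- vector("list", length(cfg$nr_range) * cfg$n_iterations * length(callers))
  recur <- lapply(callers, function(f)
    matrix(0L, nrow(cm$counts), length(cfg$nr_range),
           dimnames = list(cm$gene_ids, as.character(cfg$nr_range))))
  ri <- 0L
  for (ni in seq_along(cfg$nr_range)) {
    nr <- cfg$nr_range[ni]
    for (it in seq_len(cfg$n_iterations)) {
      split <- draw_null_split(pool, nr)
      cmA <- cm[, split$A]
      cmB <- cm[, split$B]
      for (cn in names(callers)) {
        res <- tryCatch(callers[[cn]](cmA, cmB, cfg$fdr),
                        error = function(e) e)
        ri <- ri + 1L
        if (inherits(res, "error")) {
          warning(sprintf("caller '%s' failed at nr=%d iteration %d: %s",
                          cn, nr, it, conditionMessage(res)), call. = FALSE)
          rows[[ri]] <- data.frame(
            caller = cn, nr = nr, iteration = it, fp_fraction = NA_real_,
            n_significant = NA_integer_, n_tested = NA_integer_,
            set_a = paste(split$A, collapse = ","),
            set_b = paste(split$B, collapse = ","),
            stringsAsFactors = FALSE)
          next
        }
        nt <- attr(res, "genes_tested")
        ns <- sum(res$significant)
        rows[[ri]] <- data.frame(
          caller = cn, nr = nr, iteration = it,
          fp_fraction = if (nt > 0) ns / nt else 0,
          n_significant = ns, n_tested = nt,
          set_a = paste(split$A, collapse = ","),
          set_b = paste(split$B, collapse = ","),
          stringsAsFactors = FALSE)
        if (ns > 0)
          recur[[cn]][res$gene[res$significant], ni] <-
            recur[[cn]][res$gene[res$significant], ni] + 1L
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  attr(out, "config") <- cfg
  attr(out, "pool") <- pool
  attr(out, "recurrence") <- recur
  class(out) <- c("fp_result", "data.frame")
  out
}

#' Per-gene recurrence of false-positive calls
#'
#' Supplementary view of an \code{fp_result}: for each caller, a genes x nr
#' matrix counting in how many iterations each gene was called significant.
#'
#' @param res an \code{fp_result}.
#' @return named list of integer matrices, one per caller.
#' @export
gene_recurrence <- function(res) {
  stopifnot(inherits(res, "fp_result"))
  attr(res, "recurrence")
}

#' Summarise false-positive fractions
#'
#' Order statistics of the per-iteration FP fractions for each (caller,
#' nr): median, quartiles, 2.5\%/97.5\% limits (all with the type-7 linear
#' interpolation convention of \code{stats::quantile}) and the outliers
#' beyond the 95\% limits.
#'
#' @param res an \code{fp_result}.
#' @return object of class \code{"fp_summary"}: data.frame with columns
#'   \code{caller}, \code{nr}, \code{n}, \code{median}, \code{q25},
#'   \code{q75}, \code{lo95}, \code{hi95}, \code{n_outliers}; the outlier
#'   values are kept in attribute \code{"outliers"}.
#' @export
summarize_fp <- function(res) {
  stopifnot(inherits(res, "fp_result"))
  cells <- split(res, list(res$caller, res$nr), drop = TRUE)
  outliers <- list()
  out <- do.call(rbind, lapply(cells, function(d) {
    v <- d$fp_fraction[!is.na(d$fp_fraction)]
    qs <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975),
                          names = FALSE, type = 7)
    key <- sprintf("%s.nr%d", d$caller[1], d$nr[1])
    outliers[[key]] <<- v[v < qs[1] | v > qs[5]]
    data.frame(caller = d$caller[1], nr = d$nr[1], n = length(v),
               median = qs[3], q25 = qs[2], q75 = qs[4],
               lo95 = qs[1], hi95 = qs[5],
               n_outliers = sum(v < qs[1] | v > qs[5]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out <- out[order(out$caller, out$nr), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "outliers") <- outliers
  attr(out, "fdr") <- attr(res, "config")$fdr
  class(out) <- c("fp_summary", "data.frame")
  out
}

#' @export
summary.fp_result <- function(object, ...) summarize_fp(object)

#' @export
print.fp_summary <- function(x, ...) {
  cat("False-positive fractions in mock (null) comparisons\n")
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  for (col in c("median", "q25", "q75", "lo95", "hi95"))
    df[[col]] <- sprintf("%.4f", df[[col]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Box-plot style display of FP fractions by replicate number
#'
#' One panel per caller: boxes span the quartiles, whiskers the 95\% data
#' limits, points mark outliers beyond them.
#'
#' @param x an \code{fp_summary}.
#' @param ... ignored.
#' @export
plot.fp_summary <- function(x, ...) {
  callers <- unique(x$caller)
  old <- graphics::par(mfrow = c(1, length(callers)))
  on.exit(graphics::par(old))
  outl <- attr(x, "outliers")
  for (cn in callers) {
    d <- x[x$caller == cn, , drop = FALSE]
    ylim <- range(0, d$hi95, unlist(outl[sprintf("%s.nr%d", cn, d$nr)]),
                  na.rm = TRUE)
    graphics::plot(NA, xlim = range(d$nr) + c(-0.5, 0.5), ylim = ylim,
                   xlab = "replicates per group", ylab = "FP fraction",
                   main = cn)
    graphics::abline(h = attr(x, "fdr"), col = "red", lty = 2)
    for (i in seq_len(nrow(d))) {
      nr <- d$nr[i]
      graphics::rect(nr - 0.3, d$q25[i], nr + 0.3, d$q75[i], col = "lightblue")
      graphics::segments(nr - 0.3, d$median[i], nr + 0.3, d$median[i], lwd = 2)
      graphics::segments(nr, d$hi95[i], nr, d$q75[i])
      graphics::segments(nr, d$lo95[i], nr, d$q25[i])
      graphics::segments(nr - 0.15, d$hi95[i], nr + 0.15, d$hi95[i])
      graphics::segments(nr - 0.15, d$lo95[i], nr + 0.15, d$lo95[i])
      ov <- outl[[sprintf("%s.nr%d", cn, nr)]]
      if (length(ov)) graphics::points(rep(nr, length(ov)), ov, pch = 16, cex = 0.6)
    }
  }
  invisible(x)
}
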