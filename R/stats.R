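#' Welch's unequal-variance t-test
#'
#' Thin wrapper around \code{\link[stats]{t.test}} with
#' \code{var.equal = FALSE} (Welch-Satterthwaite degrees of freedom),
#' returning a uniform test-result structure. Welch's form is used for all
#' group comparisons because it stays valid under unequal variances and
#' sample sizes.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param alternative \code{"two.sided"}, \code{"greater"} (b tends larger
#'   than a is \code{"less"}; alternatives refer to \code{a} relative to
#'   \code{b} as in \code{t.test(a, b)}).
#' @return List of class \code{fivepsol_test}: \code{statistic}, \code{p},
#'   \code{alternative}, \code{n} (per-group sizes), \code{df}.
#' @export
welch_t <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t requires at least 2 observations per group")
  ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  test_result(unname(ht$statistic), ht$p.value, alternative,
              c(length(a), length(b)), df = unname(ht$parameter),
              method = "welch_t")
}

#' Wilcoxon rank-sum test
#'
#' Wrapper around \code{\link[stats]{wilcox.test}}. Exact enumeration is
#' used when both groups have at most 20 observations and the pooled data
#' are tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric vectors.
#' @param alternative As in \code{wilcox.test}; \code{"greater"} means
#'   \code{a} stochastically larger than \code{b}.
#' @param exact Force exact (TRUE) / approximate (FALSE); default NULL
#'   applies the small-sample tie-free rule.
#' @return A \code{fivepsol_test} (statistic is the rank-sum W).
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided", exact = NULL) {
  if (is.null(exact))
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = !exact))
  test_result(unname(ht$statistic), ht$p.value, alternative,
              c(length(a), length(b)), method = "wilcoxon_rank_sum")
}

#' Pearson correlation test
#'
#' Wrapper around \code{\link[stats]{cor.test}} (t statistic on n - 2
#' degrees of freedom). By default refuses groups smaller than 30, the floor
#' below which the t reference for r is not trusted here; set
#' \code{allow_small = TRUE} to override.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alternative As in \code{cor.test}.
#' @param allow_small Allow n < 30 (default FALSE).
#' @return A \code{fivepsol_test} with extra element \code{estimate} (r).
#' @export
pearson_test <- function(x, y, alternative = "two.sided",
                         allow_small = FALSE) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 30 && !allow_small)
    stop("pearson_test requires n >= 30 (got ", sum(ok),
         "); set allow_small = TRUE to override")
  ht <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = alternative)
  out <- test_result(unname(ht$statistic), ht$p.value, alternative,
                     sum(ok), df = unname(ht$parameter),
                     method = "pearson_test")
  out$estimate <- unname(ht$estimate)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment via
#' \code{\link[stats]{p.adjust}(method = "BH")}; NA entries are preserved in
#' place and excluded from the adjustment.
#'
#' @param pvalues Numeric vector of p-values (NA allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  bh_adjust_na(pvalues)
}

test_result <- function(statistic, p, alternative, n, df = NULL,
                        method = "test") {
  structure(list(statistic = statistic, p = p, alternative = alternative,
                 n = n, df = df, method = method),
            class = "fivepsol_test")
}

#' @export
print.fivepsol_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), n = %s\n",
              x$method, x$statistic, x$p, x$alternative,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric test per gene set for over-representation of a
#' hit list within a universe, with Benjamini-Hochberg adjustment across
#' sets. The p-value is P(X >= observed overlap).
#'
#' @param hits Character vector of hit gene ids (e.g. one solubility
#'   category); must be unique and contained in \code{universe}.
#' @param gene_sets Named list of character vectors (the gene sets).
#' @param universe Character vector of all testable gene ids (unique).
#' @return data.frame: set, set_size (within universe), overlap, expected,
#'   fold enrichment, p, fdr.
#' @export
hypergeometric_enrichment <- function(hits, gene_sets, universe) {
  if (anyDuplicated(universe)) stop("duplicated gene ids in universe")
  if (anyDuplicated(hits)) stop("duplicated gene ids in hits")
  hits <- intersect(hits, universe)
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(hits, set))
    expected <- n * K / N
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out
}
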