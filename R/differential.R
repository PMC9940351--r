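#' Median-of-ratios size factors
#'
#' DESeq-style size factors: per sample, the median over usable genes of the
#' ratio of that gene's count to its geometric mean across samples. Genes
#' with a zero count in any sample are excluded from the reference. Computed
#' on spike-in counts this anchors absolute normalization (the spike-in is a
#' constant amount of foreign RNA per sample); computed on target counts it
#' gives compositional library-size factors.
#'
#' @param counts Gene x sample count matrix (>= 2 columns).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  counts <- as.matrix(counts)
  usable <- rowSums(counts <= 0) == 0
  if (!any(usable))
    stop("no usable reference gene: every gene has a zero count")
  lgm <- rowMeans(log(counts[usable, , drop = FALSE]))
  sf <- apply(counts[usable, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - lgm)))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Negative-binomial Wald contrast
#'
#' A minimal two-group differential test on counts: normalized group means
#' are compared as \code{log2FC = log2(meanB + pc) - log2(meanA + pc)}, with
#' a delta-method standard error under a negative-binomial variance
#' (\code{mu + alpha * mu^2}) whose dispersion alpha is estimated per gene by
#' method of moments, pooled across the two groups and floored. The Wald
#' statistic \code{LFC/SE} is referred to a t distribution on
#' \code{nA + nB - 2} degrees of freedom (the dispersion is itself estimated
#' from few replicates; the t reference keeps the test close to nominal at
#' triplicate scale). Genes whose summed normalized counts fall below
#' \code{count_floor} get NA statistics; FDR is Benjamini-Hochberg over the
#' tested genes.
#'
#' @param counts_A,counts_B Count matrices (genes x replicates) sharing row
#'   order (and rownames, if set). The reported LFC is B relative to A.
#' @param size_factors Optional per-sample factors, columns of A then B;
#'   defaults to median-of-ratios on the combined matrix.
#' @param count_floor Minimum summed normalized count for a gene to be
#'   tested (default 10).
#' @param pseudocount Added on the normalized-mean scale before log2
#'   (default 0.5).
#' @param dispersion_floor Lower bound for alpha (default 0.01).
#' @return data.frame: gene, base_mean, lfc, se, p, fdr.
#' @export
nb_contrast <- function(counts_A, counts_B, size_factors = NULL,
                        count_floor = 10, pseudocount = 0.5,
                        dispersion_floor = 0.01) {
  counts_A <- as.matrix(counts_A); counts_B <- as.matrix(counts_B)
  if (nrow(counts_A) != nrow(counts_B))
    stop("counts_A and counts_B must have the same genes")
  nA <- ncol(counts_A); nB <- ncol(counts_B)
  if (nA < 1 || nB < 1) stop("each group needs at least one replicate")
  if (is.null(size_factors))
    size_factors <- size_factors_median_ratio(cbind(counts_A, counts_B))
  if (length(size_factors) != nA + nB)
    stop("need one size factor per sample (A columns first)")
  sfA <- size_factors[seq_len(nA)]
  sfB <- size_factors[nA + seq_len(nB)]
  qA <- sweep(counts_A, 2, sfA, "/")
  qB <- sweep(counts_B, 2, sfB, "/")
  muA <- rowMeans(qA); muB <- rowMeans(qB)
  lfc <- log2(muB + pseudocount) - log2(muA + pseudocount)

  alpha <- mom_dispersion(qA, qB, sfA, sfB, muA, muB, dispersion_floor)
  varA <- (muA * mean(1 / sfA) + alpha * muA^2) / nA
  varB <- (muB * mean(1 / sfB) + alpha * muB^2) / nB
  log2sq <- log(2)^2
  se <- sqrt(varA / ((muA + pseudocount)^2 * log2sq) +
             varB / ((muB + pseudocount)^2 * log2sq))
  stat <- lfc / se
  df <- max(nA + nB - 2, 1)
  p <- 2 * stats::pt(-abs(stat), df = df)

  tested <- (rowSums(qA) + rowSums(qB)) >= count_floor & is.finite(se) &
    se > 0
  out <- data.frame(
    gene = rownames(counts_A) %||% as.character(seq_len(nrow(counts_A))),
    base_mean = (muA + muB) / 2,
    lfc = ifelse(tested, lfc, NA_real_),
    se = ifelse(tested, se, NA_real_),
    p = ifelse(tested, p, NA_real_),
    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust_na(out$p)
  rownames(out) <- NULL
  out
}

# pooled method-of-moments NB dispersion, floored; groups with a single
# replicate contribute no variance information
mom_dispersion <- function(qA, qB, sfA, sfB, muA, muB, floor) {
  est <- function(q, sf, mu) {
    n <- ncol(q)
    if (n < 2) return(list(a = rep(NA_real_, length(mu)), w = 0))
    v <- apply(q, 1, stats::var)
    a <- (v - mu * mean(1 / sf)) / mu^2
    a[!is.finite(a)] <- NA_real_
    list(a = a, w = n - 1)
  }
  eA <- est(qA, sfA, muA); eB <- est(qB, sfB, muB)
  wsum <- function(a1, w1, a2, w2) {
    num <- ifelse(is.na(a1), 0, a1 * w1) + ifelse(is.na(a2), 0, a2 * w2)
    den <- ifelse(is.na(a1), 0, w1) + ifelse(is.na(a2), 0, w2)
    ifelse(den > 0, num / den, NA_real_)
  }
  a <- wsum(eA$a, eA$w, eB$a, eB$w)
  pmax(ifelse(is.na(a), floor, a), floor)
}

# pull the count submatrix for given sample mask from a SummarizedExperiment
se_counts <- function(se, mask) {
  SummarizedExperiment::assay(se, "counts")[, mask, drop = FALSE]
}

se_col <- function(se, name) {
  as.character(SummarizedExperiment::colData(se)[[name]])
}

#' Per-gene mRNA solubility
#'
#' Solubility is the log2 fold change of a gene's RNA-Seq counts in the
#' soluble fraction over the total fraction within the same condition,
#' computed with \code{\link{nb_contrast}}. The default normalization uses
#' median-of-ratios factors on target-species genes (solubility is a
#' within-species compositional ratio); \code{normalization = "spike"}
#' switches to spike-in factors and \code{"none"} uses raw counts.
#'
#' @param se Count experiment from \code{\link{aggregate_counts}} or
#'   \code{\link{count_experiment}} (target + spike rows).
#' @param conditions Conditions to analyze (default: all present).
#' @param normalization \code{"library"} (default), \code{"spike"} or
#'   \code{"none"}.
#' @param ... Passed to \code{\link{nb_contrast}}.
#' @return data.frame: condition, gene, base_mean, lfc (soluble/total), se,
#'   p, fdr (FDR within condition, target genes).
#' @export
solubility <- function(se, conditions = NULL,
                       normalization = c("library", "spike", "none"), ...) {
  normalization <- match.arg(normalization)
  cond <- se_col(se, "condition"); frac <- se_col(se, "fraction")
  assay_ <- se_col(se, "assay")
  if (is.null(conditions)) conditions <- unique(cond)
  parts <- split_spike(se)
  out <- lapply(conditions, function(cc) {
    selA <- cond == cc & frac == "total" & assay_ == "RNA"
    selB <- cond == cc & frac == "soluble" & assay_ == "RNA"
    if (!any(selA) || !any(selB))
      stop("condition '", cc, "' lacks soluble or total RNA samples")
    sf <- contrast_size_factors(parts, selA, selB, normalization)
    res <- nb_contrast(se_counts(parts$target, selA),
                       se_counts(parts$target, selB),
                       size_factors = sf, ...)
    cbind(condition = cc, res)
  })
  do.call(rbind, out)
}

#' Per-gene relative degradation
#'
#' Relative degradation is the spike-in normalized log2 fold change of 5'P
#' decay-intermediate counts over RNA-Seq counts for the same condition and
#' fraction: a proxy for the fraction of a gene's molecules undergoing 5'->3'
#' decay. Size factors are median-of-ratios on the spike-in genes of the
#' contrasted libraries (the spike-in amount is constant per sample, so it
#' anchors the 5'P/RNA comparison across library types).
#'
#' @param se Count experiment with 5P and RNA assays (target + spike rows).
#' @param conditions,fractions Subsets to analyze (default: all present).
#' @param ... Passed to \code{\link{nb_contrast}}.
#' @return data.frame: condition, fraction, gene, base_mean,
#'   lfc (5P/RNA), se, p, fdr.
#' @export
relative_degradation <- function(se, conditions = NULL, fractions = NULL,
                                 ...) {
  cond <- se_col(se, "condition"); frac <- se_col(se, "fraction")
  assay_ <- se_col(se, "assay")
  if (is.null(conditions)) conditions <- unique(cond)
  if (is.null(fractions)) fractions <- unique(frac)
  parts <- split_spike(se)
  grid <- expand.grid(condition = conditions, fraction = fractions,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cc <- grid$condition[i]; ff <- grid$fraction[i]
    selA <- cond == cc & frac == ff & assay_ == "RNA"
    selB <- cond == cc & frac == ff & assay_ == "5P"
    if (!any(selA) || !any(selB))
      stop("condition '", cc, "' fraction '", ff,
           "' lacks RNA or 5P samples")
    sf <- contrast_size_factors(parts, selA, selB, "spike")
    res <- nb_contrast(se_counts(parts$target, selA),
                       se_counts(parts$target, selB),
                       size_factors = sf, ...)
    cbind(condition = cc, fraction = ff, res)
  })
  do.call(rbind, out)
}

contrast_size_factors <- function(parts, selA, selB, normalization) {
  sel <- c(which(selA), which(selB))
  switch(normalization,
    library = size_factors_median_ratio(
      SummarizedExperiment::assay(parts$target, "counts")[, sel,
                                                          drop = FALSE]),
    spike = size_factors_median_ratio(
      SummarizedExperiment::assay(parts$spike, "counts")[, sel,
                                                         drop = FALSE]),
    none = rep(1, length(sel)))
}

#' Ratio-of-ratios interaction test
#'
#' Tests, per gene, whether two log fold changes differ: the estimate is
#' \code{lfc_a - lfc_b}, its standard error \code{sqrt(se_a^2 + se_b^2)}
#' (the two contrasts use independent samples), with a normal Wald p-value
#' and Benjamini-Hochberg FDR. Used to find genes whose solubility responds
#' differently to two depletions.
#'
#' @param res_a,res_b data.frames from \code{\link{nb_contrast}} /
#'   \code{\link{solubility}} (columns gene, lfc, se); joined on gene.
#' @return data.frame: gene, estimate (lfc_a - lfc_b), se, p, fdr.
#' @export
ratio_of_ratios <- function(res_a, res_b) {
  m <- merge(res_a[, c("gene", "lfc", "se")],
             res_b[, c("gene", "lfc", "se")],
             by = "gene", suffixes = c("_a", "_b"))
  est <- m$lfc_a - m$lfc_b
  se <- sqrt(m$se_a^2 + m$se_b^2)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(gene = m$gene, estimate = est, se = se, p = p,
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust_na(out$p)
  out
}

#' Solubility-category classification
#'
#' Assigns each gene to one of five categories from its solubility changes
#' upon two depletions (mutant vs WT solubility LFC differences) and the
#' interaction test between them:
#' \itemize{
#'   \item \code{red}: interaction FDR < \code{fdr_cutoff} AND
#'     \code{delta_not1 < -lfc_cutoff} AND \code{delta_not4 > lfc_cutoff}
#'     (less soluble upon Not1 depletion, more upon Not4 depletion);
#'   \item \code{green}: interaction significant AND
#'     \code{delta_not1 > lfc_cutoff} AND \code{delta_not4 < -lfc_cutoff};
#'   \item \code{orange}: interaction not significant AND both deltas > 0;
#'   \item \code{blue}: interaction not significant AND both deltas < 0;
#'   \item \code{none}: everything else (including genes with missing
#'     values, flagged \code{incomplete}).
#' }
#'
#' @param delta_not1,delta_not4 data.frames with columns gene, estimate (the
#'   solubility change mutant - WT, e.g. from \code{\link{ratio_of_ratios}}
#'   of mutant vs WT solubility).
#' @param interaction data.frame with columns gene, fdr (the not1-vs-not4
#'   interaction test).
#' @param fdr_cutoff Interaction significance threshold (default 0.05).
#' @param lfc_cutoff Fold-change cutoff on each delta (default 0.5).
#' @return data.frame: gene, delta_not1, delta_not4, interaction_fdr,
#'   category, incomplete.
#' @export
classify_categories <- function(delta_not1, delta_not4, interaction,
                                fdr_cutoff = 0.05, lfc_cutoff = 0.5) {
  genes <- unique(c(delta_not1$gene, delta_not4$gene, interaction$gene))
  d1 <- stats::setNames(delta_not1$estimate, delta_not1$gene)[genes]
  d4 <- stats::setNames(delta_not4$estimate, delta_not4$gene)[genes]
  fi <- stats::setNames(interaction$fdr, interaction$gene)[genes]
  incomplete <- is.na(d1) | is.na(d4) | is.na(fi)
  sig <- !incomplete & fi < fdr_cutoff
  cat <- rep("none", length(genes))
  cat[sig & d1 < -lfc_cutoff & d4 > lfc_cutoff] <- "red"
  cat[sig & d1 > lfc_cutoff & d4 < -lfc_cutoff] <- "green"
  notsig <- !incomplete & fi >= fdr_cutoff
  cat[notsig & d1 > 0 & d4 > 0] <- "orange"
  cat[notsig & d1 < 0 & d4 < 0] <- "blue"
  data.frame(gene = genes, delta_not1 = unname(d1), delta_not4 = unname(d4),
             interaction_fdr = unname(fi), category = cat,
             incomplete = incomplete, stringsAsFactors = FALSE)
}

#' High/low solubility flags
#'
#' Flags genes as high or low solubility from a solubility result using the
#' disjunctive rule: high iff (LFC > 0 and FDR < \code{fdr_cutoff}) or
#' (LFC > \code{strong_lfc} and p < \code{p_cutoff}); low symmetrically with
#' negated signs; otherwise neither.
#'
#' @param result data.frame with columns gene, lfc, p, fdr.
#' @param fdr_cutoff,p_cutoff,strong_lfc Rule thresholds (defaults 0.05,
#'   0.05, 1).
#' @return data.frame: gene, flag in \{high, low, neither\}.
#' @export
solubility_flags <- function(result, fdr_cutoff = 0.05, p_cutoff = 0.05,
                             strong_lfc = 1) {
  high <- (result$lfc > 0 & result$fdr < fdr_cutoff) |
    (result$lfc > strong_lfc & result$p < p_cutoff)
  low <- (result$lfc < 0 & result$fdr < fdr_cutoff) |
    (result$lfc < -strong_lfc & result$p < p_cutoff)
  flag <- rep("neither", nrow(result))
  flag[which(high)] <- "high"
  flag[which(low)] <- "low"
  data.frame(gene = result$gene, flag = flag, stringsAsFactors = FALSE)
}
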