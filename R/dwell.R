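#' Per-codon ribosome dwelling occupancy from 5'P ends (5'P-RDO)
#'
#' During co-translational 5'->3' decay the exonuclease trails the last
#' translating ribosome, leaving 5'P ends about 17 nt upstream of the
#' ribosome A-site codon. The RDO of a sense codon is therefore the mean 5'P
#' depth \code{offset_nt} upstream of that codon's occurrences, normalized
#' to the mean depth over all codon occurrences, so that the
#' position-weighted mean occupancy is exactly 1. A 5' end at transcript
#' position x supports the codon starting at x + offset; codons starting at
#' positions < offset contribute no eligible positions. The terminal stop
#' codon is excluded (occupancy is defined over the 61 sense codons).
#'
#' @param trackset A \code{\link{five_prime_tracks}}.
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param offset_nt A-site offset in nt (default 17).
#' @param transcripts Optional gene ids to restrict to (default: all target
#'   genes).
#' @param cds_window Optional fractional CDS window \code{c(lo, hi)} (e.g.
#'   \code{c(0, 0.5)} for the first half). A codon is eligible only if both
#'   its start and the offset position fall inside the window (half-open in
#'   fraction space).
#' @return data.frame of class rows: codon, occupancy (NA when no eligible
#'   position), n_positions, mean_depth; attribute \code{meta} records
#'   sample, offset, transcripts used and total positions.
#' @export
rdo <- function(trackset, catalog, offset_nt = 17, transcripts = NULL,
                cds_window = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  transcripts <- intersect(transcripts, names(trackset$tracks))
  if (length(transcripts) == 0) stop("empty transcript filter")
  if (offset_nt < 0) stop("offset_nt must be >= 0")
  codons61 <- sense_codons()
  sums <- stats::setNames(numeric(61), codons61)
  npos <- stats::setNames(integer(61), codons61)
  for (g in transcripts) {
    track <- trackset$tracks[[g]]
    L <- length(track)
    cod <- gene_codons(catalog, g)
    cod <- cod[-length(cod)]                      # drop terminal stop
    starts <- 3L * (seq_along(cod) - 1L)
    keep <- starts >= offset_nt & cod %in% codons61
    if (!is.null(cds_window)) {
      lo <- cds_window[1] * L; hi <- cds_window[2] * L
      keep <- keep & starts >= lo & starts < hi &
        (starts - offset_nt) >= lo & (starts - offset_nt) < hi
    }
    if (!any(keep)) next
    d <- track[starts[keep] - offset_nt + 1L]
    cc <- cod[keep]
    agg <- rowsum(d, cc)
    sums[rownames(agg)] <- sums[rownames(agg)] + agg[, 1]
    tab <- table(cc)
    npos[names(tab)] <- npos[names(tab)] + as.integer(tab)
  }
  total_n <- sum(npos)
  if (total_n == 0) stop("no eligible codon positions under this filter")
  overall <- sum(sums) / total_n
  mean_depth <- ifelse(npos > 0, sums / npos, NA_real_)
  occupancy <- if (overall > 0) mean_depth / overall else
    ifelse(npos > 0, 0, NA_real_)
  out <- data.frame(codon = codons61, occupancy = unname(occupancy),
                    n_positions = unname(npos),
                    mean_depth = unname(mean_depth),
                    stringsAsFactors = FALSE)
  attr(out, "meta") <- list(sample = trackset$sample_id,
                            offset_nt = offset_nt,
                            transcripts = length(transcripts),
                            total_positions = total_n)
  out
}

#' Differential RDO between two samples or conditions
#'
#' Per-codon log2 fold change of normalized occupancies,
#' \code{log2(occupancy_b / occupancy_a)}; NA occupancies propagate.
#'
#' @param rdo_a,rdo_b data.frames from \code{\link{rdo}}.
#' @return data.frame: codon, lfc, occupancy_a, occupancy_b.
#' @export
differential_rdo <- function(rdo_a, rdo_b) {
  m <- merge(rdo_a[, c("codon", "occupancy")],
             rdo_b[, c("codon", "occupancy")],
             by = "codon", suffixes = c("_a", "_b"))
  m$lfc <- log2(m$occupancy_b / m$occupancy_a)
  m[, c("codon", "lfc", "occupancy_a", "occupancy_b")]
}

#' Codon-optimality analysis of differential RDOs
#'
#' Correlates per-codon differential RDOs with a codon-optimality scale
#' (tAI) and compares the most versus least optimal codons. The Pearson
#' correlation is tested with a t reference; the extreme groups (top and
#' bottom \code{n_extreme} codons by tAI) are compared with a one-sided
#' Wilcoxon rank-sum test under the alternative that non-optimal codons have
#' larger differential RDO (more dwelling).
#'
#' @param diff_rdo data.frame from \code{\link{differential_rdo}}.
#' @param tai Named numeric vector over sense codons (see
#'   \code{\link{read_tai}}).
#' @param n_extreme Number of codons in each extreme group (default 15).
#' @return List: \code{pearson} (a \code{fivepsol_test} with estimate r),
#'   \code{wilcoxon} (one-sided \code{fivepsol_test}), \code{optimal},
#'   \code{nonoptimal} (codon sets).
#' @export
tai_analysis <- function(diff_rdo, tai, n_extreme = 15) {
  x <- stats::setNames(diff_rdo$lfc, diff_rdo$codon)
  codons <- intersect(names(tai), names(x))
  codons <- codons[is.finite(x[codons])]
  ord <- codons[order(tai[codons], decreasing = TRUE)]
  optimal <- utils::head(ord, n_extreme)
  nonoptimal <- utils::tail(ord, n_extreme)
  pear <- pearson_test(x[codons], tai[codons])
  wil <- wilcoxon_rank_sum(x[nonoptimal], x[optimal],
                           alternative = "greater")
  list(pearson = pear, wilcoxon = wil, optimal = optimal,
       nonoptimal = nonoptimal)
}
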