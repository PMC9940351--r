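#' Anchored metagene profile of 5' ends
#'
#' Aggregates 5'-end depth at each nt offset relative to the start codon or
#' to the stop codon (offset 0 = first nt of the start codon, or first nt of
#' the stop codon), after shifting ends \code{shift_nt} downstream to the
#' A-site-equivalent position, and scales to depth per million mapped 5'
#' ends. Offsets falling outside a transcript's CDS are simply not covered
#' by that transcript (tracks span the CDS only).
#'
#' @param tracksets A \code{\link{five_prime_tracks}} or list thereof (per-
#'   million profiles are averaged across samples).
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param anchor \code{"start"} or \code{"stop"}.
#' @param shift_nt Downstream shift applied to 5' ends (default 17; use 0
#'   for unshifted profiles).
#' @param flank \code{c(upstream, downstream)} nt around the anchor.
#' @param transcripts Optional gene ids (default: all target genes).
#' @return data.frame: offset, value (mean depth per million), n_genes
#'   (transcripts covering that offset); attribute \code{meta}.
#' @export
metagene_anchored <- function(tracksets, catalog,
                              anchor = c("start", "stop"), shift_nt = 17,
                              flank = c(50, 200), transcripts = NULL) {
  anchor <- match.arg(anchor)
  if (methods::is(tracksets, "five_prime_tracks"))
    tracksets <- list(tracksets)
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  offsets <- seq(-flank[1], flank[2])
  lens <- cds_lengths(catalog)
  profs <- lapply(tracksets, function(ts) {
    val <- numeric(length(offsets)); ng <- integer(length(offsets))
    for (g in intersect(transcripts, names(ts$tracks))) {
      L <- lens[[g]]
      apos <- if (anchor == "start") 0L else L - 3L
      src <- apos + offsets - shift_nt        # unshifted source position
      ok <- src >= 0 & src < L
      val[ok] <- val[ok] + ts$tracks[[g]][src[ok] + 1L]
      ng[ok] <- ng[ok] + 1L
    }
    list(val = val * 1e6 / ts$library_size, ng = ng)
  })
  value <- Reduce(`+`, lapply(profs, `[[`, "val")) / length(profs)
  n_genes <- profs[[1]]$ng
  out <- data.frame(offset = offsets, value = value, n_genes = n_genes)
  attr(out, "meta") <- list(anchor = anchor, shift_nt = shift_nt,
                            samples = vapply(tracksets, `[[`, "",
                                             "sample_id"))
  out
}

#' CDS-scaled metagene profile
#'
#' Splits every CDS into \code{n_bins} equal bins, takes the mean 5'-end
#' depth per bin per transcript, averages bins across transcripts, and
#' normalizes by the mean depth over all nucleotides of the transcript
#' group (a uniform library is a flat profile of 1s).
#'
#' @param tracksets A \code{\link{five_prime_tracks}} or list thereof
#'   (normalized profiles averaged across samples).
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param n_bins Number of bins (20 or 100 are the usual choices).
#' @param transcripts Optional gene ids (default: all target genes).
#' @return data.frame: bin (1..n_bins), value; attribute \code{meta}.
#' @export
metagene_scaled <- function(tracksets, catalog, n_bins = 100,
                            transcripts = NULL) {
  if (methods::is(tracksets, "five_prime_tracks"))
    tracksets <- list(tracksets)
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  lens <- cds_lengths(catalog)
  profs <- lapply(tracksets, function(ts) {
    use <- intersect(transcripts, names(ts$tracks))
    if (length(use) == 0) stop("no transcripts to profile")
    binmat <- t(vapply(use, function(g) {
      v <- ts$tracks[[g]]
      L <- lens[[g]]
      bin <- pmin(floor((seq_len(L) - 1) * n_bins / L), n_bins - 1) + 1L
      as.numeric(tapply(v, bin, mean)[as.character(seq_len(n_bins))])
    }, numeric(n_bins)))
    binmat[is.na(binmat)] <- 0
    prof <- colMeans(binmat)
    overall <- sum(vapply(ts$tracks[use], sum, numeric(1))) /
      sum(lens[use])
    if (overall > 0) prof / overall else prof
  })
  value <- Reduce(`+`, profs) / length(profs)
  out <- data.frame(bin = seq_len(n_bins), value = value)
  attr(out, "meta") <- list(n_bins = n_bins,
                            transcripts = length(intersect(
                              transcripts, names(tracksets[[1]]$tracks))))
  out
}

#' Windowed CDS read proportions (soluble vs total)
#'
#' For each gene covered by at least \code{min_reads} 5'P ends in BOTH the
#' soluble and the total library, computes the proportion of that gene's
#' reads whose 5' ends fall into fractional CDS windows (default 10-30%,
#' 40-60%, 70-90%; half-open in fraction space), per fraction, plus the
#' log2 total/soluble ratio of the proportions.
#'
#' @param trackset_soluble,trackset_total \code{\link{five_prime_tracks}}
#'   for the paired soluble and total libraries.
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param windows List of fractional intervals \code{c(lo, hi)}.
#' @param min_reads Inclusion threshold on CDS-wide reads in both samples
#'   (default 20; a gene with exactly 20 reads in both is included).
#' @param transcripts Optional gene ids (default: all target genes).
#' @return data.frame: gene, window label, prop_soluble, prop_total,
#'   log2_ratio (total over soluble); attribute \code{excluded} counts genes
#'   below the threshold.
#' @export
window_ratio <- function(trackset_soluble, trackset_total, catalog,
                         windows = list(c(0.1, 0.3), c(0.4, 0.6),
                                        c(0.7, 0.9)),
                         min_reads = 20, transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  lens <- cds_lengths(catalog)
  labs <- vapply(windows, function(w)
    sprintf("%g-%g%%", 100 * w[1], 100 * w[2]), character(1))
  rows <- list(); excluded <- 0L
  for (g in transcripts) {
    vs <- trackset_soluble$tracks[[g]]; vt <- trackset_total$tracks[[g]]
    if (is.null(vs) || is.null(vt)) next
    ns <- sum(vs); nt <- sum(vt)
    if (ns < min_reads || nt < min_reads) {
      excluded <- excluded + 1L
      next
    }
    L <- lens[[g]]
    frac <- (seq_len(L) - 1) / L
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      inw <- frac >= w[1] & frac < w[2]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, window = labs[i],
        prop_soluble = sum(vs[inw]) / ns,
        prop_total = sum(vt[inw]) / nt,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), window = character(0),
               prop_soluble = numeric(0), prop_total = numeric(0))
  out$log2_ratio <- log2(out$prop_total / out$prop_soluble)
  attr(out, "excluded") <- excluded
  out
}

#' Reading-frame fractions of unshifted 5' ends
#'
#' Percentage of 5'P end counts in each reading frame over entire ORFs,
#' where frame k means transcript position mod 3 = k (position 0 at the A of
#' ATG). Co-translational decay intermediates sit ~17 nt upstream of codon
#' starts, and -17 = 1 (mod 3), so ribosome-protected decay enriches frame
#' 1; computed on unshifted ends.
#'
#' @param trackset A \code{\link{five_prime_tracks}}.
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param transcripts Optional gene ids (default: all target genes).
#' @return Named numeric vector \code{c(frame0, frame1, frame2)} of
#'   percentages summing to 100 (NaN if no counted ends).
#' @export
frame_fractions <- function(trackset, catalog, transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  counts <- c(0, 0, 0)
  for (g in intersect(transcripts, names(trackset$tracks))) {
    v <- trackset$tracks[[g]]
    fr <- (seq_along(v) - 1) %% 3
    counts <- counts + as.numeric(rowsum(as.numeric(v),
                                         factor(fr, levels = 0:2)))
  }
  stats::setNames(100 * counts / sum(counts),
                  c("frame0", "frame1", "frame2"))
}
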