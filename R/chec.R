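#' Promoter windows around +1 nucleosome positions
#'
#' Builds, per gene, the promoter binding window spanning 400 bp upstream
#' and 100 bp downstream of the +1 nucleosome position, strand-aware
#' (upstream means 5' of the gene). Windows extending past contig bounds
#' are clipped and flagged. Input and output coordinates are 1-based closed
#' (GFF convention); an unclipped window has width 501.
#'
#' @param plus1 data.frame with columns \code{gene}, \code{chrom},
#'   \code{pos} (1-based +1 nucleosome position) and \code{strand}.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param upstream,downstream Window extents in bp (defaults 400 and 100).
#' @return data.frame: gene, chrom, start, end, strand, width, clipped.
#' @export
promoter_windows <- function(plus1, contig_lengths, upstream = 400,
                             downstream = 100) {
  need <- c("gene", "chrom", "pos", "strand")
  if (!all(need %in% names(plus1)))
    stop("plus1 must have columns ", paste(need, collapse = ", "))
  if (!all(plus1$chrom %in% names(contig_lengths)))
    stop("contig length missing for some chromosomes")
  plus <- plus1$strand == "+"
  start <- ifelse(plus, plus1$pos - upstream, plus1$pos - downstream)
  end <- ifelse(plus, plus1$pos + downstream, plus1$pos + upstream)
  clen <- contig_lengths[plus1$chrom]
  cstart <- pmax(start, 1L)
  cend <- pmin(end, clen)
  data.frame(gene = plus1$gene, chrom = plus1$chrom,
             start = as.integer(cstart), end = as.integer(cend),
             strand = plus1$strand,
             width = as.integer(cend - cstart + 1),
             clipped = cstart != start | cend != end,
             stringsAsFactors = FALSE)
}

#' Count MNase cut sites in promoter windows
#'
#' Collapses sequencing reads of a ChEC library to cut positions and counts
#' them per promoter window, strand-blind (MNase cuts both strands). With
#' \code{ends = "five_prime"} (default) the cut is the 5' end of each
#' alignment — the position adjacent to the MNase cleavage for a
#' standard directional library; \code{ends = "both"} counts both alignment
#' ends, for protocols where each fragment boundary is a cut.
#'
#' @param reads Alignments: a \link[GenomicRanges]{GRanges} of spans, a
#'   data.frame with \code{chrom,start,end,strand} (1-based closed), a BED
#'   path, or a BAM path (primary alignments only).
#' @param windows data.frame from \code{\link{promoter_windows}}.
#' @param ends \code{"five_prime"} (default) or \code{"both"}.
#' @return Named integer vector of cut counts, one per window, suitable for
#'   \code{\link{chec_signal}}.
#' @export
count_mnase_cuts <- function(reads, windows, ends = c("five_prime", "both")) {
  ends <- match.arg(ends)
  gr <- as_read_granges(reads)
  cuts <- if (ends == "five_prime") five_prime_positions(gr) else
    c(GenomicRanges::resize(gr, 1, fix = "start", ignore.strand = TRUE),
      GenomicRanges::resize(gr, 1, fix = "end", ignore.strand = TRUE))
  win <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(windows$start, windows$end))
  n <- GenomicRanges::countOverlaps(win, cuts, ignore.strand = TRUE)
  stats::setNames(as.integer(n), windows$gene)
}

#' ChEC promoter signal over a free-MNase control
#'
#' Per promoter window: RPKM (counts per kb of window per million library
#' reads) in the fusion-MNase sample and the free-MNase control, the log2
#' fold change of the two RPKMs (with pseudocount), and the mode-centered
#' LFC — the bulk of promoters carry only background cleavage, so the mode
#' of the LFC distribution estimates the background offset and is
#' subtracted.
#'
#' @param sample_counts,control_counts Named numeric vectors of MNase-cut
#'   counts per promoter window (names matching \code{regions$gene}) for the
#'   fusion sample and free-MNase control.
#' @param regions data.frame from \code{\link{promoter_windows}}.
#' @param library_sizes Optional \code{c(sample, control)} total mapped
#'   reads; default: sums of the supplied counts.
#' @param pseudocount RPKM pseudocount in the LFC (default 0.5).
#' @param mode_method Passed to \code{\link{estimate_mode}}.
#' @return data.frame: gene, rpkm_sample, rpkm_control, lfc, centered_lfc;
#'   attribute \code{mode} holds the subtracted mode estimate.
#' @export
chec_signal <- function(sample_counts, control_counts, regions,
                        library_sizes = NULL, pseudocount = 0.5,
                        mode_method = c("lognormal", "kde")) {
  mode_method <- match.arg(mode_method)
  s <- sample_counts[regions$gene]
  c0 <- control_counts[regions$gene]
  if (anyNA(s) || anyNA(c0))
    stop("counts missing for some promoter windows")
  if (is.null(library_sizes))
    library_sizes <- c(sum(sample_counts), sum(control_counts))
  if (any(library_sizes <= 0)) stop("zero-library input")
  kb <- regions$width / 1e3
  rpkm_s <- s / (kb * library_sizes[1] / 1e6)
  rpkm_c <- c0 / (kb * library_sizes[2] / 1e6)
  lfc <- log2((rpkm_s + pseudocount) / (rpkm_c + pseudocount))
  mode_est <- estimate_mode(lfc, method = mode_method)
  out <- data.frame(gene = regions$gene, rpkm_sample = unname(rpkm_s),
                    rpkm_control = unname(rpkm_c), lfc = unname(lfc),
                    centered_lfc = unname(lfc - mode_est),
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode_est
  out
}

#' Mode of a log2 fold-change distribution
#'
#' Primary method: fit a log-normal distribution (via
#' \code{\link[MASS]{fitdistr}}) to \code{2^values} — strictly positive by
#' construction — and return the log2 of the fitted mode
#' \code{exp(mu - sigma^2)}. Fallback / alternative: the argmax of a
#' Gaussian kernel density estimate. A constant vector returns its value.
#'
#' @param values Numeric vector (log2 scale).
#' @param method \code{"lognormal"} (default) or \code{"kde"}.
#' @return Scalar mode estimate on the log2 scale.
#' @export
estimate_mode <- function(values, method = c("lognormal", "kde")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values")
  if (length(unique(values)) == 1) return(values[1])
  if (method == "lognormal") {
    x <- 2^values
    fit <- tryCatch(MASS::fitdistr(x, "lognormal"),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      mu <- fit$estimate[["meanlog"]]; sg <- fit$estimate[["sdlog"]]
      return((mu - sg^2) / log(2))
    }
    method <- "kde"            # degenerate fit: fall through to KDE
  }
  d <- stats::density(values)
  d$x[which.max(d$y)]
}
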