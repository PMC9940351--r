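#' Per-transcript 5'-end track set
#'
#' Holds, for one library, an integer vector per gene giving the number of
#' read 5' ends at each CDS nucleotide. Positions are 0-based transcript
#' coordinates with 0 at the first nucleotide of the start codon (element
#' \code{i} of the vector is transcript position \code{i - 1}).
#'
#' @param sample_id Library identifier.
#' @param tracks Named list of non-negative integer vectors, one per gene,
#'   each of length equal to the gene's CDS length.
#' @param library_size Total mapped 5' ends of the target species; defaults
#'   to the sum of the supplied tracks.
#' @return Object of class \code{five_prime_tracks}.
#' @export
five_prime_tracks <- function(sample_id, tracks, library_size = NULL) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  for (v in tracks) if (any(v < 0)) stop("track counts must be >= 0")
  total <- sum(vapply(tracks, sum, numeric(1)))
  if (is.null(library_size)) library_size <- total
  if (total > library_size + 1e-9)
    stop("sum of track counts exceeds library_size")
  structure(list(sample_id = sample_id,
                 tracks = lapply(tracks, as.integer),
                 library_size = as.numeric(library_size)),
            class = "five_prime_tracks")
}

#' @export
print.five_prime_tracks <- function(x, ...) {
  cat(sprintf("five_prime_tracks '%s': %d genes, %.0f mapped 5' ends\n",
              x$sample_id, length(x$tracks), x$library_size))
  invisible(x)
}

# Coerce read input (GRanges, data.frame, BED path, BAM path) to a GRanges
# of alignment spans with strand.
as_read_granges <- function(reads) {
  if (methods::is(reads, "GRanges")) return(reads)
  if (is.character(reads) && length(reads) == 1) {
    if (grepl("\\.bam$", reads, ignore.case = TRUE))
      return(read_bam_alignments(reads))
    return(rtracklayer::import(reads, format = "bed"))
  }
  if (is.data.frame(reads)) {
    stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
    return(GenomicRanges::GRanges(
      seqnames = reads$chrom,
      ranges = IRanges::IRanges(reads$start, reads$end),
      strand = reads$strand))
  }
  stop("unsupported read input; give a GRanges, data.frame, BED or BAM")
}

# reference-space width from a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Primary mapped alignments from a BAM as GRanges spans. Unmapped and
# secondary/supplementary records are dropped (counted in a message).
read_bam_alignments <- function(bam_path) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "strand", "cigar"))
  res <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  all_n <- Rsamtools::countBam(bam_path)$records
  keep <- !is.na(res$pos)
  if (all_n > sum(keep))
    message(all_n - sum(keep), " unmapped/secondary records skipped")
  w <- cigar_ref_width(res$cigar[keep])
  GenomicRanges::GRanges(
    seqnames = as.character(res$rname[keep]),
    ranges = IRanges::IRanges(res$pos[keep], width = w),
    strand = as.character(res$strand[keep]))
}

#' Build 5'-end tracks from alignments
#'
#' Collapses alignments to their 5' ends (leftmost aligned base on the plus
#' strand, rightmost on the minus strand) and counts, per gene, the ends
#' falling inside the spliced CDS in transcript coordinates. Only sense-strand
#' ends are counted; antisense ends are ignored. A 5' end inside two
#' overlapping same-strand CDSs counts toward both.
#'
#' @param reads Alignments: a \link[GenomicRanges]{GRanges} of spans, a
#'   data.frame with \code{chrom,start,end,strand} (1-based closed), a BED
#'   path, or a coordinate-sorted BAM path.
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param sample_id Library identifier stored in the track set.
#' @return A \code{\link{five_prime_tracks}}; \code{library_size} is the
#'   number of mapped 5' ends on target-species contigs.
#' @export
build_5p_tracks <- function(reads, catalog, sample_id = "sample") {
  gr <- as_read_granges(reads)
  ends <- five_prime_positions(gr)
  tx <- map_to_transcript(ends, catalog)
  tracks <- empty_tracks(catalog)
  if (nrow(tx) > 0) {
    tab <- tapply(tx$pos, tx$gene_id, function(p) p, simplify = FALSE)
    for (g in names(tab))
      tracks[[g]] <- tracks[[g]] +
        tabulate(tab[[g]] + 1L, nbins = length(tracks[[g]]))
  }
  spike_chroms <- unique(catalog$genes$chrom[catalog$genes$species == "spike"])
  lib <- sum(!(as.character(GenomicRanges::seqnames(gr)) %in% spike_chroms))
  five_prime_tracks(sample_id, tracks, library_size = max(lib, sum(
    vapply(tracks, sum, numeric(1)))))
}

# width-1 GRanges of read 5' ends, preserving strand
five_prime_positions <- function(gr) {
  pos <- ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                GenomicRanges::end(gr), GenomicRanges::start(gr))
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(pos, width = 1),
    strand = BiocGenerics::strand(gr))
}

# map width-1 genomic positions to (gene_id, transcript position 0-based);
# strand-aware (sense only); a position in two CDSs yields two rows
map_to_transcript <- function(pos_gr, catalog) {
  hits <- GenomicRanges::findOverlaps(pos_gr, catalog$parts,
                                      ignore.strand = FALSE)
  if (length(hits) == 0)
    return(data.frame(gene_id = character(0), pos = integer(0)))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  part <- catalog$parts[s]
  gpos <- GenomicRanges::start(pos_gr)[q]
  minus <- as.character(BiocGenerics::strand(part)) == "-"
  tx <- ifelse(minus,
               part$tx_offset + (GenomicRanges::end(part) - gpos),
               part$tx_offset + (gpos - GenomicRanges::start(part)))
  data.frame(gene_id = part$gene_id, pos = as.integer(tx),
             stringsAsFactors = FALSE)
}

empty_tracks <- function(catalog) {
  lens <- cds_lengths(catalog)
  stats::setNames(lapply(lens, function(L) integer(L)), names(lens))
}

#' Write / read 5'-end tracks as bedGraph
#'
#' Tracks are serialized in transcript coordinates (contig = gene id,
#' 0-based half-open intervals, run-length encoded over nonzero counts).
#' \code{read_trackset_bedgraph} reconstructs full-length vectors from the
#' catalog, so a write/read round trip reproduces counts exactly.
#'
#' @param trackset A \code{\link{five_prime_tracks}}.
#' @param path Output/input bedGraph path.
#' @param catalog A \code{\link{transcript_catalog}} (for lengths on read).
#' @param sample_id Sample id to assign on read.
#' @return \code{write_trackset_bedgraph} invisibly returns \code{path};
#'   \code{read_trackset_bedgraph} returns a \code{five_prime_tracks}.
#' @export
write_trackset_bedgraph <- function(trackset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fivepsol bedGraph; sample=%s; library_size=%.10g",
                     trackset$sample_id, trackset$library_size), con)
  for (g in names(trackset$tracks)) {
    v <- trackset$tracks[[g]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", g, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' @rdname write_trackset_bedgraph
#' @export
read_trackset_bedgraph <- function(path, catalog, sample_id = NULL) {
  first <- readLines(path, n = 1)
  lib <- NULL
  if (grepl("^# fivepsol bedGraph", first)) {
    if (is.null(sample_id))
      sample_id <- sub(".*sample=([^;]+);.*", "\\1", first)
    lib <- as.numeric(sub(".*library_size=([0-9.eE+-]+).*", "\\1", first))
  }
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("gene", "start", "end", "count"),
                           stringsAsFactors = FALSE)
  tracks <- empty_tracks(catalog)
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene[i]
    if (is.null(tracks[[g]])) next
    tracks[[g]][(tab$start[i] + 1):tab$end[i]] <- tab$count[i]
  }
  five_prime_tracks(sample_id %||% "sample", tracks, library_size = lib)
}

#' Aggregate CDS-overlapping counts into a gene x sample matrix
#'
#' For a 5'P library the gene count is the number of read 5' ends within the
#' CDS (the sum of its track); for an RNA library it is the number of reads
#' overlapping the spliced CDS by at least one nucleotide (sense strand).
#'
#' @param samples Named list; each element is either a
#'   \code{\link{five_prime_tracks}} (counted as 5' ends) or a read input
#'   accepted by \code{\link{build_5p_tracks}} (counted as overlapping
#'   reads).
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param sample_info data.frame with one row per sample (rownames matching
#'   \code{names(samples)}) and columns \code{condition}, \code{fraction},
#'   \code{assay} (5P/RNA), \code{replicate}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts}, \code{colData} from \code{sample_info} and a per-gene
#'   \code{species} column in \code{rowData}.
#' @export
aggregate_counts <- function(samples, catalog, sample_info) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  if (!all(names(samples) %in% rownames(sample_info)))
    stop("sample_info must have a row for every sample")
  need <- c("condition", "fraction", "assay", "replicate")
  if (!all(need %in% colnames(sample_info)))
    stop("sample_info must have columns ", paste(need, collapse = ", "))
  genes <- catalog$genes$id
  counts <- matrix(0L, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, names(samples)))
  for (nm in names(samples)) {
    x <- samples[[nm]]
    if (methods::is(x, "five_prime_tracks")) {
      counts[, nm] <- vapply(x$tracks[genes], sum, integer(1))
    } else {
      gr <- as_read_granges(x)
      hits <- GenomicRanges::findOverlaps(gr, catalog$parts,
                                          ignore.strand = FALSE,
                                          minoverlap = 1L)
      pg <- catalog$parts$gene_id[S4Vectors::subjectHits(hits)]
      # a read spanning two parts of one gene counts once
      key <- paste(S4Vectors::queryHits(hits), pg)
      pg <- pg[!duplicated(key)]
      tab <- table(factor(pg, levels = genes))
      counts[, nm] <- as.integer(tab)
    }
    tgt <- sum(counts[catalog$genes$species == "target", nm])
    if (tgt == 0)
      stop("sample '", nm, "' has zero target-species reads")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sample_info[names(samples), , drop = FALSE]),
    rowData = S4Vectors::DataFrame(species = catalog$genes$species,
                                   row.names = genes))
  se
}

#' Build a count experiment directly from a matrix
#'
#' Convenience constructor used by the simulator and for counts read from
#' TSV: wraps a gene x sample integer matrix plus metadata into the same
#' \link[SummarizedExperiment]{SummarizedExperiment} layout as
#' \code{\link{aggregate_counts}}.
#'
#' @param counts Integer matrix, genes x samples (dimnames required).
#' @param sample_info data.frame with columns \code{condition},
#'   \code{fraction}, \code{assay}, \code{replicate}; rownames matching
#'   \code{colnames(counts)}.
#' @param species Character vector (target/spike) per gene.
#' @return A \code{SummarizedExperiment}.
#' @export
count_experiment <- function(counts, sample_info, species) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            length(species) == nrow(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = matrix(as.integer(counts), nrow = nrow(counts),
                                  dimnames = dimnames(counts))),
    colData = S4Vectors::DataFrame(
      sample_info[colnames(counts), , drop = FALSE]),
    rowData = S4Vectors::DataFrame(species = species,
                                   row.names = rownames(counts)))
}

#' Split a count experiment into target and spike-in parts
#'
#' @param se A \code{SummarizedExperiment} from
#'   \code{\link{aggregate_counts}} or \code{\link{count_experiment}}.
#' @return \code{list(target = ..., spike = ...)}.
#' @export
split_spike <- function(se) {
  sp <- SummarizedExperiment::rowData(se)$species
  if (is.null(sp)) stop("rowData lacks a 'species' column")
  if (!any(sp == "spike"))
    stop("spike-in required for relative degradation: no spike genes found")
  if (!any(sp == "target")) stop("no target-species genes found")
  list(target = se[sp == "target", ], spike = se[sp == "spike", ])
}
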