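#' Transcript catalog
#'
#' The coordinate backbone of all analyses: one entry per protein-coding
#' gene, holding the (spliced) CDS parts in genomic coordinates, the CDS
#' sequence read 5'->3', and a species tag separating target genes from
#' spike-in genes. Codon k (0-based) occupies CDS nucleotides
#' \code{[3k, 3k+3)}; transcript coordinate 0 is the first nucleotide of the
#' start codon.
#'
#' @param genes data.frame with columns \code{id}, \code{chrom},
#'   \code{strand} (+/-), \code{species} (target/spike), \code{cds_length}.
#' @param parts_gr \link[GenomicRanges]{GRanges} of CDS parts with metadata
#'   columns \code{gene_id} and \code{tx_offset} (transcript coordinate of
#'   the part's first transcribed base).
#' @param seqs Named character vector of CDS sequences (5'->3').
#' @param spike_prefix Chromosome-name prefix identifying spike-in contigs.
#' @param skipped Number of records dropped during loading.
#' @return Object of class \code{transcript_catalog}.
#' @export
transcript_catalog <- function(genes, parts_gr, seqs, spike_prefix = "SPIKE_",
                               skipped = 0L) {
  stopifnot(is.data.frame(genes),
            all(c("id", "chrom", "strand", "species", "cds_length") %in%
                  names(genes)))
  if (anyDuplicated(genes$id)) stop("duplicate gene ids in catalog")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  seqs <- seqs[genes$id]
  if (any(is.na(seqs))) stop("missing CDS sequence for some genes")
  if (!all(nchar(seqs) == genes$cds_length))
    stop("cds_length does not match sequence length")
  if (any(genes$cds_length %% 3 != 0) || any(genes$cds_length <= 0))
    stop("every CDS length must be a positive multiple of 3")
  structure(
    list(genes = genes, parts = parts_gr, seqs = seqs,
         spike_prefix = spike_prefix, skipped = as.integer(skipped)),
    class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf(
    "transcript_catalog: %d genes (%d target, %d spike-in), %d skipped\n",
    nrow(x$genes), sum(x$genes$species == "target"),
    sum(x$genes$species == "spike"), x$skipped))
  invisible(x)
}

#' @export
length.transcript_catalog <- function(x) nrow(x$genes)

#' CDS lengths of a catalog
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param ids Optional subset of gene ids.
#' @return Named integer vector of CDS lengths (nt).
#' @export
cds_lengths <- function(catalog, ids = NULL) {
  out <- stats::setNames(as.integer(catalog$genes$cds_length),
                         catalog$genes$id)
  if (!is.null(ids)) out <- out[ids]
  out
}

#' Load a transcript catalog from GFF3 + FASTA
#'
#' Builds one entry per protein-coding gene from the CDS features of a GFF3
#' annotation and the genome FASTA. Multiple CDS parts per transcript are
#' spliced in transcription order; on the minus strand the assembled
#' sequence is reverse-complemented so \code{cds_sequence} reads 5'->3'.
#' When several transcripts share a gene the longest CDS is kept. Records
#' whose spliced CDS length is not a positive multiple of 3 are skipped with
#' a warning and counted in the catalog's \code{skipped} field. A gene is
#' tagged \code{species = "spike"} iff its chromosome name starts with
#' \code{spike_prefix}.
#'
#' GFF3 coordinates (1-based, closed) are converted at this boundary;
#' internally all transcript coordinates are 0-based half-open.
#'
#' @param gff3_path Path to a GFF3 file with CDS features.
#' @param fasta_path Path to the genome FASTA (must cover every chromosome
#'   referenced by a CDS).
#' @param spike_prefix Chromosome-name prefix identifying spike-in contigs
#'   (default \code{"SPIKE_"}).
#' @return A \code{\link{transcript_catalog}}.
#' @export
load_annotation <- function(gff3_path, fasta_path, spike_prefix = "SPIKE_") {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  cds <- gff[tolower(as.character(gff$type)) == "cds"]
  if (length(cds) == 0) stop("no CDS features in ", gff3_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  # group CDS parts by transcript (Parent when present, else ID)
  parent <- rep(NA_character_, length(cds))
  if ("Parent" %in% names(S4Vectors::mcols(cds))) {
    pl <- cds$Parent
    has <- lengths(pl) > 0
    parent[has] <- vapply(pl[has], function(x) x[[1]], character(1))
  }
  if ("ID" %in% names(S4Vectors::mcols(cds)))
    parent[is.na(parent)] <- cds$ID[is.na(parent)]
  if (anyNA(parent)) stop("CDS features lack both Parent and ID attributes")
  parent <- sub("^transcript:", "", parent)

  # map transcript -> gene via mRNA/transcript features when available
  tx2gene <- stats::setNames(parent, parent)
  txf <- gff[tolower(as.character(gff$type)) %in%
               c("mrna", "transcript")]
  if (length(txf) > 0 && all(c("ID", "Parent") %in%
                             names(S4Vectors::mcols(txf)))) {
    tid <- sub("^transcript:", "", txf$ID)
    gid <- vapply(txf$Parent, function(x)
      if (length(x)) sub("^gene:", "", x[[1]]) else NA_character_,
      character(1))
    ok <- !is.na(tid) & !is.na(gid)
    tx2gene[tid[ok]] <- gid[ok]
  }

  missing_chrom <- setdiff(unique(as.character(GenomicRanges::seqnames(cds))),
                           names(genome))
  if (length(missing_chrom) > 0)
    stop("sequence missing from FASTA for chromosome(s): ",
         paste(missing_chrom, collapse = ", "))

  ord <- order(parent, GenomicRanges::start(cds))
  cds <- cds[ord]; parent <- parent[ord]
  split_idx <- split(seq_along(cds), parent)

  skipped <- 0L
  rows <- list(); part_list <- list(); seq_list <- character(0)
  for (tx in names(split_idx)) {
    idx <- split_idx[[tx]]
    parts <- cds[idx]
    chrom <- as.character(GenomicRanges::seqnames(parts))[1]
    strand <- as.character(BiocGenerics::strand(parts))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    L <- sum(GenomicRanges::width(parts))
    if (L <= 0 || L %% 3 != 0) {
      warning("skipping transcript '", tx, "': CDS length ", L,
              " is not a positive multiple of 3", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    # transcription order: ascending starts on +, descending on -
    parts <- parts[order(GenomicRanges::start(parts),
                         decreasing = (strand == "-"))]
    # assemble the genomic-forward sequence in ascending coordinate order,
    # then reverse-complement once; reverse-complementing a concatenation
    # reverses the segment order, which is exactly what the minus strand
    # needs (rightmost exon is transcribed first)
    asc <- if (strand == "-") rev(seq_along(parts)) else seq_along(parts)
    seq <- do.call(Biostrings::xscat, lapply(asc, function(i)
      Biostrings::subseq(genome[[chrom]],
                         GenomicRanges::start(parts)[i],
                         GenomicRanges::end(parts)[i])))
    if (strand == "-") seq <- Biostrings::reverseComplement(seq)
    gene <- unname(tx2gene[tx])
    if (is.na(gene)) gene <- tx
    rows[[tx]] <- data.frame(
      id = gene, tx = tx, chrom = chrom, strand = strand,
      species = if (startsWith(chrom, spike_prefix)) "spike" else "target",
      cds_length = L, stringsAsFactors = FALSE)
    part_list[[tx]] <- data.frame(
      chrom = chrom,
      start = GenomicRanges::start(parts),
      end = GenomicRanges::end(parts),
      strand = strand,
      tx_offset = cumsum(c(0L, utils::head(GenomicRanges::width(parts), -1))),
      stringsAsFactors = FALSE)
    seq_list[[tx]] <- as.character(seq)
  }
  if (length(rows) == 0) stop("no usable CDS records in ", gff3_path)
  genes <- do.call(rbind, rows)

  # longest CDS wins on duplicate gene ids
  genes <- genes[order(genes$id, -genes$cds_length), ]
  keep <- !duplicated(genes$id)
  genes <- genes[keep, ]
  part_list <- part_list[genes$tx]
  seq_list <- seq_list[genes$tx]
  names(part_list) <- names(seq_list) <- genes$id
  rownames(genes) <- NULL
  genes$tx <- NULL

  parts_df <- do.call(rbind, lapply(names(part_list), function(g) {
    df <- part_list[[g]]; df$gene_id <- g; df
  }))
  parts_gr <- GenomicRanges::GRanges(
    seqnames = parts_df$chrom,
    ranges = IRanges::IRanges(parts_df$start, parts_df$end),
    strand = parts_df$strand,
    gene_id = parts_df$gene_id,
    tx_offset = parts_df$tx_offset)

  transcript_catalog(genes, parts_gr, unlist(seq_list),
                     spike_prefix = spike_prefix, skipped = skipped)
}

#' Extract the codon sequence of a gene
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param id Gene id.
#' @return Character vector of codons (includes start and terminal stop).
#' @export
gene_codons <- function(catalog, id) {
  if (!id %in% names(catalog$seqs)) stop("unknown gene id: ", id)
  s <- catalog$seqs[[id]]
  substring(s, seq(1, nchar(s) - 2, by = 3), seq(3, nchar(s), by = 3))
}

#' Write a catalog (plus genome) to FASTA and GFF3
#'
#' Companion writer for simulated annotations: emits the genome FASTA and a
#' gene/mRNA/CDS GFF3 that \code{\link{load_annotation}} can read back.
#'
#' @param catalog A \code{\link{transcript_catalog}}.
#' @param genome Named \link[Biostrings]{DNAStringSet} of contig sequences.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(catalog, genome, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(genome, fasta_path)
  con <- file(gff3_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  parts <- catalog$parts
  for (i in seq_len(nrow(catalog$genes))) {
    g <- catalog$genes[i, ]
    p <- parts[parts$gene_id == g$id]
    p <- p[order(GenomicRanges::start(p))]
    gs <- min(GenomicRanges::start(p)); ge <- max(GenomicRanges::end(p))
    writeLines(sprintf(
      "%s\tfivepsol\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
      g$chrom, gs, ge, g$strand, g$id), con)
    writeLines(sprintf(
      "%s\tfivepsol\tmRNA\t%d\t%d\t.\t%s\t.\tID=transcript:%s_t;Parent=gene:%s",
      g$chrom, gs, ge, g$strand, g$id, g$id), con)
    for (j in seq_along(p)) {
      writeLines(sprintf(
        "%s\tfivepsol\tCDS\t%d\t%d\t.\t%s\t0\tID=CDS:%s_%d;Parent=transcript:%s_t",
        g$chrom, GenomicRanges::start(p)[j], GenomicRanges::end(p)[j],
        g$strand, g$id, j, g$id), con)
    }
  }
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}
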