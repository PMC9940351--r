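# Hand-built fixtures and independent brute-force oracles. The oracles are
# written position-by-position in the most literal way possible so that they
# share no code or vectorization tricks with the package implementations.

GRanges <- GenomicRanges::GRanges
IRanges <- IRanges::IRanges
DNAString <- Biostrings::DNAString
DNAStringSet <- Biostrings::DNAStringSet
reverseComplement <- Biostrings::reverseComplement

# --- toy catalog -----------------------------------------------------------
# Three single-exon genes on their own contigs:
#   g1: + strand, 10 codons, CDS at chrA:11-40 (contig 50 nt)
#   g2: - strand,  7 codons, CDS at chrB:11-31 (contig 41 nt)
#   s1: spike,     3 codons, CDS at SPIKE_1:6-14 (contig 20 nt)
toy_seqs <- c(
  g1 = "ATGGGGCCCAAATTTGGGGATCATTGGTAA",
  g2 = "ATGAAACCCGGGTTTACGTAA",
  s1 = "ATGGCGTAA")

toy_catalog <- function() {
  genes <- data.frame(
    id = c("g1", "g2", "s1"),
    chrom = c("chrA", "chrB", "SPIKE_1"),
    strand = c("+", "-", "+"),
    species = c("target", "target", "spike"),
    cds_length = c(30L, 21L, 9L),
    stringsAsFactors = FALSE)
  parts <- GRanges(
    seqnames = genes$chrom,
    ranges = IRanges(start = c(11L, 11L, 6L), end = c(40L, 31L, 14L)),
    strand = genes$strand,
    gene_id = genes$id,
    tx_offset = c(0L, 0L, 0L))
  transcript_catalog(genes, parts, toy_seqs)
}

# genome matching toy_catalog (minus-strand CDS stored reverse-complemented)
toy_genome <- function() {
  rc <- function(s) as.character(reverseComplement(DNAString(s)))
  DNAStringSet(c(
    chrA = paste0("ACGTACGTAC", toy_seqs[["g1"]], "TTTTACGTAC"),
    chrB = paste0("ACGTACGTAC", rc(toy_seqs[["g2"]]), "ACGTACGTAC"),
    SPIKE_1 = paste0("ACGTA", toy_seqs[["s1"]], "GTACGT")))
}

# single long plus-strand gene with a caller-chosen codon sequence,
# for dwell tests (codons must include the terminal stop)
long_gene_catalog <- function(codons) {
  cds <- paste(codons, collapse = "")
  L <- nchar(cds)
  genes <- data.frame(id = "gl", chrom = "chrL", strand = "+",
                      species = "target", cds_length = L,
                      stringsAsFactors = FALSE)
  parts <- GRanges("chrL", IRanges(start = 11L, end = 10L + L),
                   strand = "+", gene_id = "gl", tx_offset = 0L)
  transcript_catalog(genes, parts, c(gl = cds))
}

# two-exon genes (one per strand) for splice-aware mapping tests:
#   e1: + strand on chrE, exons chrE:11-19 and chrE:31-42 (9 + 12 = 21 nt)
#   e2: - strand on chrF, exons chrF:31-42 (first transcribed) and chrF:11-19
two_exon_catalog <- function() {
  rc <- function(s) as.character(reverseComplement(DNAString(s)))
  ex1 <- "ATGAAACCC"; ex2 <- "GGGTTTACGTAA"
  # chrF (minus strand): the first transcribed exon is the RIGHTMOST one
  # (chrF:31-42, 12 nt, mRNA "ATGAAACCCGGG"), the second is chrF:11-19
  # (9 nt, mRNA "TTTACGTAA")
  exF1 <- "ATGAAACCCGGG"; exF2 <- "TTTACGTAA"
  genes <- data.frame(
    id = c("e1", "e2"), chrom = c("chrE", "chrF"), strand = c("+", "-"),
    species = c("target", "target"), cds_length = c(21L, 21L),
    stringsAsFactors = FALSE)
  parts <- GRanges(
    seqnames = c("chrE", "chrE", "chrF", "chrF"),
    ranges = IRanges(start = c(11L, 31L, 31L, 11L),
                     end = c(19L, 42L, 42L, 19L)),
    strand = c("+", "+", "-", "-"),
    gene_id = c("e1", "e1", "e2", "e2"),
    tx_offset = c(0L, 9L, 0L, 12L))
  seqs <- c(e1 = paste0(ex1, ex2), e2 = paste0(ex1, ex2))
  genome <- DNAStringSet(c(
    chrE = paste0("ACGTACGTAC", ex1, "ACGTACGTACG", ex2, "ACGTACGT"),
    chrF = paste0("ACGTACGTAC", rc(exF2), "ACGTACGTACG", rc(exF1),
                  "ACGTACGT")))
  list(catalog = transcript_catalog(genes, parts, seqs), genome = genome)
}

# deterministic non-trivial tracks over a catalog (values 0..4 cycling,
# phase-shifted per gene)
toy_trackset <- function(catalog, sample_id = "toy") {
  lens <- cds_lengths(catalog)
  tracks <- lapply(seq_along(lens), function(i)
    as.integer((seq_len(lens[i]) + i) %% 5))
  names(tracks) <- names(lens)
  five_prime_tracks(sample_id, tracks)
}

split_codons <- function(s)
  substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))

# --- brute-force oracles ---------------------------------------------------

bf_rdo <- function(trackset, catalog, offset = 17, transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  codon_of <- character(0); depth_of <- numeric(0)
  for (g in transcripts) {
    track <- trackset$tracks[[g]]
    cod <- split_codons(catalog$seqs[[g]])
    cod <- cod[-length(cod)]
    for (k in seq_along(cod)) {
      start0 <- 3 * (k - 1)
      src <- start0 - offset
      if (src >= 0 && cod[k] %in% sense_codons()) {
        codon_of <- c(codon_of, cod[k])
        depth_of <- c(depth_of, track[src + 1])
      }
    }
  }
  overall <- mean(depth_of)
  means <- vapply(split(depth_of, codon_of), mean, numeric(1))
  means / overall
}

bf_metagene_anchored <- function(trackset, catalog, anchor = "start",
                                 shift = 17, flank = c(50, 200),
                                 transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  offsets <- seq(-flank[1], flank[2])
  value <- numeric(length(offsets)); n_genes <- integer(length(offsets))
  for (g in transcripts) {
    track <- trackset$tracks[[g]]
    L <- length(track)
    apos <- if (anchor == "start") 0 else L - 3
    for (j in seq_along(offsets)) {
      src <- apos + offsets[j] - shift
      if (src >= 0 && src < L) {
        value[j] <- value[j] + track[src + 1]
        n_genes[j] <- n_genes[j] + 1L
      }
    }
  }
  list(value = value * 1e6 / trackset$library_size, n_genes = n_genes)
}

bf_metagene_scaled <- function(trackset, catalog, n_bins,
                               transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  acc <- matrix(0, nrow = length(transcripts), ncol = n_bins)
  total_depth <- 0; total_len <- 0
  for (gi in seq_along(transcripts)) {
    g <- transcripts[gi]
    track <- trackset$tracks[[g]]
    L <- length(track)
    for (b in seq_len(n_bins)) {
      pos <- which(floor((seq_len(L) - 1) * n_bins / L) == b - 1)
      acc[gi, b] <- if (length(pos) > 0) mean(track[pos]) else 0
    }
    total_depth <- total_depth + sum(track)
    total_len <- total_len + L
  }
  prof <- colMeans(acc)
  overall <- total_depth / total_len
  if (overall > 0) prof / overall else prof
}

bf_frame_fractions <- function(trackset, catalog, transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  counts <- c(0, 0, 0)
  for (g in transcripts) {
    track <- trackset$tracks[[g]]
    for (pos0 in seq_along(track) - 1)
      counts[pos0 %% 3 + 1] <- counts[pos0 %% 3 + 1] + track[pos0 + 1]
  }
  100 * counts / sum(counts)
}

bf_window_ratio <- function(ts_sol, ts_tot, catalog, windows, min_reads,
                            transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- catalog$genes$id[catalog$genes$species == "target"]
  rows <- list()
  for (g in transcripts) {
    vs <- ts_sol$tracks[[g]]; vt <- ts_tot$tracks[[g]]
    if (is.null(vs) || is.null(vt)) next
    if (sum(vs) < min_reads || sum(vt) < min_reads) next
    L <- length(vs)
    for (w in windows) {
      pos <- which((seq_len(L) - 1) / L >= w[1] & (seq_len(L) - 1) / L < w[2])
      rows[[length(rows) + 1]] <- data.frame(
        gene = g,
        prop_soluble = sum(vs[pos]) / sum(vs),
        prop_total = sum(vt[pos]) / sum(vt),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

bf_size_factors <- function(counts) {
  keep <- which(apply(counts, 1, function(r) all(r > 0)))
  ref <- vapply(keep, function(i) prod(counts[i, ])^(1 / ncol(counts)),
                numeric(1))
  # the median is taken on the log scale (with an even number of usable
  # genes the two middle ratios are averaged geometrically)
  vapply(seq_len(ncol(counts)), function(j)
    2^stats::median(log2(counts[keep, j] / ref)), numeric(1))
}

bf_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p)); pv <- p[ok]; n <- length(pv)
  for (i in seq_len(n)) {
    cands <- vapply(which(pv >= pv[i]), function(j)
      n * pv[j] / sum(pv <= pv[j]), numeric(1))
    out[ok[i]] <- min(1, cands)
  }
  out
}
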