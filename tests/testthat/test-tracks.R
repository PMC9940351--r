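test_that("5' ends map to transcript coordinates on both strands", {
  cat0 <- toy_catalog()
  reads <- data.frame(
    chrom = c("chrA", "chrB", "chrA", "chrA", "SPIKE_1"),
    start = c(13L, 15L, 13L, 2L, 6L),
    end   = c(22L, 20L, 22L, 8L, 10L),
    strand = c("+", "-", "-", "+", "+"),
    stringsAsFactors = FALSE)
  ts <- build_5p_tracks(reads, cat0, sample_id = "s")
  # plus strand: 5' end = start 13 -> transcript position 13 - 11 = 2
  exp_g1 <- integer(30); exp_g1[3] <- 1L
  expect_identical(ts$tracks$g1, exp_g1)
  # minus strand: 5' end = end 20 -> transcript position 31 - 20 = 11
  exp_g2 <- integer(21); exp_g2[12] <- 1L
  expect_identical(ts$tracks$g2, exp_g2)
  # the antisense chrA read and the read upstream of the CDS count nowhere
  expect_identical(sum(ts$tracks$g1), 1L)
  # spike read maps to the spike track but not to library_size
  exp_s1 <- integer(9); exp_s1[1] <- 1L
  expect_identical(ts$tracks$s1, exp_s1)
  expect_identical(ts$library_size, 4)   # all chrA/chrB ends, incl. unmapped
})

test_that("minus-strand mapping mirrors plus-strand mapping", {
  cds <- toy_seqs[["g1"]]
  genes <- data.frame(id = c("m1", "m2"), chrom = c("chrM1", "chrM2"),
                      strand = c("+", "-"), species = "target",
                      cds_length = 30L, stringsAsFactors = FALSE)
  parts <- GenomicRanges::GRanges(
    c("chrM1", "chrM2"), IRanges::IRanges(21L, 50L), strand = c("+", "-"),
    gene_id = c("m1", "m2"), tx_offset = c(0L, 0L))
  cat0 <- transcript_catalog(genes, parts, c(m1 = cds, m2 = cds))
  set.seed(7)
  t_pos <- sample(0:29, 60, replace = TRUE)
  reads <- rbind(
    data.frame(chrom = "chrM1", start = 21L + t_pos, end = 21L + t_pos + 9L,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(chrom = "chrM2", start = 50L - t_pos - 9L, end = 50L - t_pos,
               strand = "-", stringsAsFactors = FALSE))
  ts <- build_5p_tracks(reads, cat0)
  expect_identical(ts$tracks$m1, ts$tracks$m2)
  expect_identical(sum(ts$tracks$m1), 60L)
})

test_that("bedGraph serialization round-trips exactly", {
  cat0 <- toy_catalog()
  ts <- toy_trackset(cat0, sample_id = "lib_A")
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_trackset_bedgraph(ts, path)
  back <- read_trackset_bedgraph(path, cat0)
  expect_identical(back$tracks, ts$tracks)
  expect_identical(back$library_size, ts$library_size)
  expect_identical(back$sample_id, "lib_A")
})

test_that("BAM input reproduces data.frame input", {
  cat0 <- toy_catalog()
  tmp <- withr::local_tempdir()
  sam <- file.path(tmp, "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrA\tLN:50",
    "@SQ\tSN:chrB\tLN:41",
    "@SQ\tSN:SPIKE_1\tLN:20",
    "r1\t0\tchrA\t13\t60\t10M\t*\t0\t0\t*\t*",
    "r2\t16\tchrB\t15\t60\t6M\t*\t0\t0\t*\t*"),
    sam)
  bam <- Rsamtools::asBam(sam, file.path(tmp, "toy"),
                          indexDestination = FALSE, overwrite = TRUE)
  ts_bam <- build_5p_tracks(bam, cat0, sample_id = "s")
  reads <- data.frame(chrom = c("chrA", "chrB"), start = c(13L, 15L),
                      end = c(22L, 20L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  ts_df <- build_5p_tracks(reads, cat0, sample_id = "s")
  expect_identical(ts_bam$tracks, ts_df$tracks)
  expect_identical(ts_bam$library_size, ts_df$library_size)
})

test_that("aggregate_counts counts 5'P ends and >=1 nt RNA overlaps", {
  cat0 <- toy_catalog()
  ts <- toy_trackset(cat0, "lib5p")
  rna <- GenomicRanges::GRanges(
    c("chrA", "chrA", "chrA", "chrB", "SPIKE_1"),
    IRanges::IRanges(start = c(5L, 1L, 38L, 28L, 1L),
                     end = c(11L, 10L, 45L, 35L, 20L)),
    strand = c("+", "+", "+", "-", "+"))
  si <- data.frame(condition = "WT", fraction = "total",
                   assay = c("5P", "RNA"), replicate = 1L,
                   row.names = c("lib5p", "libRNA"))
  se <- aggregate_counts(list(lib5p = ts, libRNA = rna), cat0, si)
  cm <- SummarizedExperiment::assay(se, "counts")
  # 5'P library: per-gene sums of the track
  expect_identical(cm[, "lib5p"],
                   vapply(ts$tracks, sum, integer(1)))
  # RNA: 1-nt overlap at the CDS boundary counts, a read ending 1 nt
  # before it does not; sense only
  expect_identical(unname(cm[, "libRNA"]), c(2L, 1L, 1L))
})

test_that("a read spanning two exons of one gene counts once", {
  tec <- two_exon_catalog()
  rna <- GenomicRanges::GRanges("chrE", IRanges::IRanges(15L, 35L),
                                strand = "+")
  si <- data.frame(condition = "WT", fraction = "total", assay = "RNA",
                   replicate = 1L, row.names = "r")
  se <- aggregate_counts(list(r = rna), tec$catalog, si)
  expect_identical(unname(SummarizedExperiment::assay(se)[, "r"]),
                   c(1L, 0L))
})

test_that("samples without target reads are rejected by name", {
  cat0 <- toy_catalog()
  rna <- GenomicRanges::GRanges("SPIKE_1", IRanges::IRanges(6L, 14L),
                                strand = "+")
  si <- data.frame(condition = "WT", fraction = "total", assay = "RNA",
                   replicate = 1L, row.names = "only_spike")
  expect_error(aggregate_counts(list(only_spike = rna), cat0, si),
               "only_spike")
})

test_that("count_experiment and split_spike validate their inputs", {
  cm <- matrix(c(1L, 2L, 3L, 4L), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  si <- data.frame(condition = "WT", fraction = "total", assay = "RNA",
                   replicate = 1:2, row.names = c("s1", "s2"))
  expect_error(count_experiment(cm - 2L, si, c("target", "spike")),
               "non-negative")
  se <- count_experiment(cm, si, c("target", "target"))
  expect_error(split_spike(se), "spike")
  se2 <- count_experiment(cm, si, c("target", "spike"))
  parts <- split_spike(se2)
  expect_identical(rownames(parts$target), "a")
  expect_identical(rownames(parts$spike), "b")
})
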