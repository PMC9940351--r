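test_that("median-of-ratios size factors match the hand example", {
  counts <- matrix(c(2, 8, 4, 16), nrow = 2,
                   dimnames = list(c("gA", "gB"), c("s1", "s2")))
  sf <- size_factors_median_ratio(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # genes with a zero anywhere are excluded from the reference
  counts2 <- rbind(counts, gC = c(0, 1000))
  expect_equal(size_factors_median_ratio(counts2), sf)
  expect_error(size_factors_median_ratio(rbind(c(0, 5), c(3, 0))),
               "no usable reference gene")
})

test_that("size factors match the brute-force oracle and DESeq2", {
  set.seed(31)
  counts <- matrix(rpois(300 * 6, lambda = rep(exp(rnorm(300, 5, 1)), 6)) + 1,
                   nrow = 300,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   sprintf("s%d", 1:6)))
  counts <- sweep(counts, 2, c(1, 2, 0.5, 1.5, 0.8, 1.2), "*")
  counts <- round(counts)
  counts[counts == 0] <- 1
  sf <- size_factors_median_ratio(counts)
  expect_equal(unname(sf), bf_size_factors(counts), tolerance = 1e-10)
  dsf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(dsf), tolerance = 1e-8)
})

test_that("nb_contrast is null on identical groups and floors low counts", {
  set.seed(5)
  cm <- matrix(rpois(60, 50), nrow = 20,
               dimnames = list(sprintf("g%02d", 1:20), NULL))
  cm[1, ] <- 0L   # below the count floor
  res <- nb_contrast(cm, cm, size_factors = rep(1, 6))
  expect_true(all(res$lfc[-1] == 0))
  expect_true(all(res$p[-1] == 1))
  expect_true(is.na(res$lfc[1]) && is.na(res$p[1]) && is.na(res$fdr[1]))
})

test_that("nb_contrast agrees with DESeq2 on planted effects", {
  set.seed(77)
  n <- 300
  mu <- exp(rnorm(n, log(200), 1))
  lfc_true <- c(rep(0, 200), rnorm(100, 0, 1.5))
  simg <- function(m) matrix(rnbinom(n * 3, mu = rep(m, 3), size = 1 / 0.02),
                             nrow = n)
  cmA <- simg(mu); cmB <- simg(mu * 2^lfc_true)
  rownames(cmA) <- rownames(cmB) <- sprintf("g%03d", 1:n)
  res <- nb_contrast(cmA, cmB)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cbind(cmA, cmB),
    S4Vectors::DataFrame(group = factor(rep(c("A", "B"), each = 3))),
    design = ~group)
  dres <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)),
                          contrast = c("group", "B", "A"))
  ok <- !is.na(res$lfc) & !is.na(dres$log2FoldChange)
  expect_gt(cor(res$lfc[ok], dres$log2FoldChange[ok]), 0.98)
  # strong calls agree in direction
  strong <- ok & !is.na(dres$padj) & dres$padj < 1e-4 &
    abs(dres$log2FoldChange) > 1
  expect_true(all(sign(res$lfc[strong]) ==
                    sign(dres$log2FoldChange[strong])))
  expect_gt(mean(res$fdr[strong] < 0.05), 0.9)
})

make_sol_se <- function(counts_sol, counts_tot, species) {
  stopifnot(ncol(counts_sol) == ncol(counts_tot))
  cm <- cbind(counts_sol, counts_tot)
  colnames(cm) <- c(sprintf("WT_soluble_RNA_rep%d", seq_len(ncol(counts_sol))),
                    sprintf("WT_total_RNA_rep%d", seq_len(ncol(counts_tot))))
  si <- data.frame(
    condition = "WT",
    fraction = rep(c("soluble", "total"), each = ncol(counts_sol)),
    assay = "RNA",
    replicate = rep(seq_len(ncol(counts_sol)), 2),
    row.names = colnames(cm))
  count_experiment(cm, si, species)
}

test_that("solubility is zero for identical pools and antisymmetric", {
  set.seed(11)
  n <- 40
  base <- matrix(rpois(n * 3, 120), nrow = n,
                 dimnames = list(c(sprintf("g%02d", 1:(n - 4)),
                                   sprintf("spk%d", 1:4)), NULL))
  species <- c(rep("target", n - 4), rep("spike", 4))
  se_same <- make_sol_se(base, base, species)
  res_same <- solubility(se_same)
  expect_true(all(res_same$lfc[!is.na(res_same$lfc)] == 0))

  other <- matrix(rpois(n * 3, 120), nrow = n, dimnames = dimnames(base))
  se <- make_sol_se(other, base, species)
  res <- solubility(se)
  # swapping the fraction labels exactly negates the LFCs
  se_sw <- se
  SummarizedExperiment::colData(se_sw)$fraction <-
    ifelse(SummarizedExperiment::colData(se)$fraction == "soluble",
           "total", "soluble")
  res_sw <- solubility(se_sw)
  m <- merge(res, res_sw, by = "gene")
  expect_equal(m$lfc.x, -m$lfc.y)
  expect_equal(m$p.x, m$p.y)
})

test_that("relative_degradation requires spike-ins", {
  cm <- matrix(rpois(20 * 4, 100), nrow = 20,
               dimnames = list(sprintf("g%02d", 1:20),
                               c("a5p", "arna", "b5p", "brna")))
  si <- data.frame(condition = "WT", fraction = "total",
                   assay = c("5P", "RNA", "5P", "RNA"),
                   replicate = c(1, 1, 2, 2),
                   row.names = colnames(cm))
  se <- count_experiment(cm, si, rep("target", 20))
  expect_error(relative_degradation(se), "spike")
})

test_that("ratio_of_ratios is null on identical inputs and antisymmetric", {
  res <- data.frame(gene = c("a", "b", "c"), lfc = c(1, -0.5, 0.2),
                    se = c(0.1, 0.2, 0.3))
  rr <- ratio_of_ratios(res, res)
  expect_equal(rr$estimate, rep(0, 3))
  expect_equal(rr$p, rep(1, 3))
  res2 <- data.frame(gene = c("a", "b", "c"), lfc = c(0, 1, -1),
                     se = c(0.1, 0.1, 0.1))
  expect_equal(ratio_of_ratios(res, res2)$estimate,
               -ratio_of_ratios(res2, res)$estimate)
})

test_that("category rules follow the published definitions", {
  genes <- LETTERS[1:7]
  d1 <- data.frame(gene = genes,
                   estimate = c(-1, 1, 0.3, -0.3, -1, NA, -0.5))
  d4 <- data.frame(gene = genes,
                   estimate = c(1, -1, 0.2, -0.2, 1, 0.4, 1))
  fi <- data.frame(gene = genes,
                   fdr = c(0.01, 0.01, 0.5, 0.5, 0.2, 0.01, 0.01))
  res <- classify_categories(d1, d4, fi)
  expect_identical(res$category[match(genes, res$gene)],
                   c("red", "green", "orange", "blue", "none", "none",
                     "none"))
  expect_identical(res$incomplete[match("F", res$gene)], TRUE)
})

test_that("solubility flags apply the disjunctive rule", {
  res <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    lfc = c(0.5, 1.2, -1.2, 0.5, -0.2),
    p = c(0.001, 0.03, 0.03, 0.2, 0.01),
    fdr = c(0.01, 0.2, 0.2, 0.2, 0.01))
  flags <- solubility_flags(res)
  expect_identical(flags$flag, c("high", "high", "low", "neither", "low"))
})
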