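small_cfg <- function(...) {
  sim_config(n_genes_target = 12, n_genes_spike = 3,
             cds_length_range = c(120, 300),
             conditions = c("WT", "not1d", "not4d"),
             replicates = 1, seed = 5, ...)
}

test_that("simulation is deterministic and leaves the caller's RNG alone", {
  cfg <- small_cfg()
  set.seed(99); before <- .Random.seed
  sim1 <- simulate_experiment(cfg)
  expect_identical(.Random.seed, before)
  sim2 <- simulate_experiment(cfg)
  expect_identical(SummarizedExperiment::assay(sim1$counts),
                   SummarizedExperiment::assay(sim2$counts))
  s <- names(sim1$tracksets_5p)[1]
  expect_identical(sim1$tracksets_5p[[s]]$tracks,
                   sim2$tracksets_5p[[s]]$tracks)
  expect_identical(sim1$truth$genes, sim2$truth$genes)
})

test_that("the transcriptome respects the codon-usage model", {
  usage <- setNames(rep(0, 61), sense_codons()); usage[["CAA"]] <- 1
  cfg <- small_cfg(codon_usage = usage)
  tg <- generate_transcriptome(cfg)
  cod <- gene_codons(tg$catalog, tg$catalog$genes$id[1])
  expect_identical(cod[1], "ATG")
  expect_identical(cod[length(cod)], "TAA")
  expect_true(all(cod[2:(length(cod) - 1)] == "CAA"))
  # spike genes live on SPIKE_ contigs and are tagged spike
  expect_true(all(startsWith(
    tg$catalog$genes$chrom[tg$catalog$genes$species == "spike"], "SPIKE_")))
  expect_true(all(tg$catalog$genes$cds_length %% 3 == 0))
})

test_that("planted categories move solubility symmetrically by the set fold", {
  cfg <- sim_config(n_genes_target = 20, n_genes_spike = 3,
                    planted = list(red_frac = 0.1, green_frac = 0.1,
                                   lfc = 1),
                    conditions = c("WT", "not1d", "not4d"), seed = 2)
  tg <- generate_transcriptome(cfg)
  p <- gene_params(tg$catalog, cfg)
  red <- names(p$category)[p$category == "red"]
  green <- names(p$category)[p$category == "green"]
  expect_length(red, 2); expect_length(green, 2)
  expect_equal(unname(log2(p$solubility[red, "not1d"] /
                             p$solubility[red, "WT"])), rep(-1, 2))
  expect_equal(unname(log2(p$solubility[red, "not4d"] /
                             p$solubility[red, "WT"])), rep(1, 2))
  expect_equal(unname(log2(p$solubility[green, "not1d"] /
                             p$solubility[green, "WT"])), rep(1, 2))
  # null genes keep their WT solubility in every condition
  null <- names(p$category)[p$category == "null"]
  expect_equal(p$solubility[null, "not1d"], p$solubility[null, "WT"])
})

test_that("explicit solubility grids are planted verbatim", {
  cfg <- small_cfg(s_values = c(0.25, 0.5, 0.75),
                   planted = list(red_frac = 0, green_frac = 0, lfc = 1))
  tg <- generate_transcriptome(cfg)
  p <- gene_params(tg$catalog, cfg)
  tgt <- tg$catalog$genes$id[tg$catalog$genes$species == "target"]
  expect_equal(unname(p$solubility[tgt, "WT"]),
               rep(c(0.25, 0.5, 0.75), length.out = length(tgt)))
  expect_error(sim_config(s_values = c(0.5, 1.2)))
})

test_that("RNA tracks conserve the drawn counts", {
  cfg <- small_cfg()
  tg <- generate_transcriptome(cfg)
  rs <- simulate_rna_sample(tg$catalog, cfg, "WT", "total", seed = 42)
  expect_equal(vapply(rs$trackset$tracks, sum, numeric(1)),
               as.numeric(rs$counts), ignore_attr = TRUE)
  rs2 <- simulate_rna_sample(tg$catalog, cfg, "WT", "total", seed = 42,
                             tracks = FALSE)
  expect_equal(rs2$counts, rs$counts)
  expect_null(rs2$trackset)
})

test_that("fully periodic 5'P libraries put every end in frame 1", {
  cfg <- small_cfg(periodic_fraction = c(soluble = 1, total = 1))
  tg <- generate_transcriptome(cfg)
  ts <- simulate_5p_sample(tg$catalog, cfg, "WT", "total", seed = 9)
  fr <- frame_fractions(ts, tg$catalog)
  expect_equal(unname(fr), c(0, 100, 0))
  # spike-in genes are never periodic
  spk <- tg$catalog$genes$id[tg$catalog$genes$species == "spike"]
  fr_spk <- frame_fractions(ts, tg$catalog, transcripts = spk)
  expect_true(all(fr_spk < 50))
})

test_that("ground truth is internally consistent", {
  cfg <- small_cfg()
  sim <- simulate_experiment(cfg)
  tr <- sim$truth$genes
  expect_equal(tr$dsol_not1d,
               log2(tr$s_not1d / tr$s_WT))
  expect_true(all(tr$reldeg_WT_total[tr$species == "spike"] == 0))
  p <- gene_params(sim$catalog, cfg)
  tgt <- tr$species == "target"
  expect_equal(tr$reldeg_WT_total[tgt],
               unname(log2(cfg$five_p_rate[["total"]] *
                             p$deg_gene[tr$gene[tgt]] /
                             cfg$spike_5p_rate)))
  expect_identical(colnames(sim$counts), sim$manifest$sample)
})

test_that("sim_config round-trips through YAML", {
  cfg <- sim_config(n_genes_target = 15, n_genes_spike = 3,
                    periodic_fraction = c(soluble = 0.2, total = 0.7),
                    conditions = c("WT", "not1d"),
                    condition_deg = list(WT = c(soluble = 1, total = 1),
                                         not1d = c(soluble = 0.6,
                                                   total = 1.2)),
                    seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_genes_target = 15, n_genes_spike = 3,
    periodic_fraction = list(soluble = 0.2, total = 0.7),
    conditions = c("WT", "not1d"),
    condition_deg = list(WT = list(soluble = 1, total = 1),
                         not1d = list(soluble = 0.6, total = 1.2)),
    seed = 4), path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$periodic_fraction, cfg$periodic_fraction)
  expect_equal(cfg2$condition_deg, cfg$condition_deg)
  expect_identical(cfg2$conditions, cfg$conditions)
  expect_identical(cfg2$seed, cfg$seed)
  expect_equal(cfg2$tai, cfg$tai)
})

test_that("auxiliary simulators expose their planted truth", {
  chec <- simulate_chec(n_promoters = 200, seed = 3)
  expect_true(all(chec$windows$width[!chec$windows$clipped] == 501L))
  expect_identical(sum(chec$truth$bound), 20L)
  expect_true(all(chec$truth$enrichment[chec$truth$bound] == 4))
  pc <- simulate_parclip(n_regions = 400, seed = 3)
  expect_identical(sum(pc$truth$class == "higher"), 40L)
  expect_identical(sum(pc$truth$class == "lower"), 20L)
  expect_true(all(pc$regions$t_count >= 200 & pc$regions$t_count <= 1500))
})
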