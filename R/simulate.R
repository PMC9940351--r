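#' Simulation configuration
#'
#' Defines a complete synthetic fractionation experiment: a two-species
#' transcriptome (target + spike-in), per-gene expression and solubility,
#' planted solubility-category genes, codon-dependent ribosome dwelling with
#' the 17-nt 5'P offset, per-condition degradation effects, and sequencing
#' depth/noise. All downstream estimators can be validated against the
#' ground truth the generator emits.
#'
#' The generative model: each mRNA molecule undergoing decay leaves one 5'P
#' end. With probability \code{periodic_fraction[fraction]} the end is
#' co-translational: it sits 17 nt upstream of a ribosome A-site codon
#' sampled proportionally to \code{exp(-dwell_a * tai)} times a positional
#' ramp (decay-onset delay); otherwise the end is uniform over the CDS. The
#' soluble pool is a binomial thinning of the total pool by the gene's
#' solubility fraction s. Spike-in genes have condition-invariant expression
#' and no co-translational signal.
#'
#' @param n_genes_target,n_genes_spike Number of target / spike-in genes.
#' @param cds_length_range CDS length range in nt (rounded to codons).
#' @param codon_usage Named probability vector over the 61 sense codons
#'   (default uniform).
#' @param tai Codon-optimality scale used as dwell ground truth (default
#'   \code{\link{synthetic_tai}()}).
#' @param dwell_a Strength of the dwell-optimality coupling;
#'   dwell multiplier = \code{exp(-dwell_a * tai)} (default 2).
#' @param dwell_perturbation Named list condition -> named multiplier vector
#'   per codon, applied on top of the base dwell (default none).
#' @param periodic_fraction Named \code{c(soluble=, total=)} mixture weight
#'   of co-translational (periodic) ends (defaults 0.3 and 0.6: periodicity
#'   is visible in the total pool, weak in the soluble pool).
#' @param positional_amp Named \code{c(soluble=, total=)} amplitude of the
#'   linear dwell ramp across the CDS, from 1-amp at the start to 1+amp at
#'   the end (defaults 0 and 0.5: total-pool 5'P ends pile up late in the
#'   CDS, modeling delayed decay onset).
#' @param expression_sdlog Log-normal sd of per-gene expression (mean 1).
#' @param s_range Range of wild-type solubility fractions s (default
#'   0.2-0.8).
#' @param s_values Optional explicit wild-type solubility fractions
#'   (values in (0,1)), recycled over target genes in catalog order;
#'   overrides \code{s_range}. Useful for planting a known grid of
#'   solubilities for recovery studies.
#' @param planted List \code{(red_frac, green_frac, lfc)}: fractions of
#'   target genes planted in the red / green categories and the solubility
#'   log2 change magnitude upon depletion (default 0.1, 0.1, 1).
#' @param five_p_rate Named \code{c(soluble=, total=)} baseline decay rate:
#'   expected 5'P molecules per RNA (defaults 0.4 and 0.1, so relative
#'   degradation is ~2 log2 units higher in the soluble pool).
#' @param spike_5p_rate Decay rate of spike-in genes (default 0.2).
#' @param condition_deg Matrix-like list condition -> \code{c(soluble=,
#'   total=)} multipliers on the 5'P rate (defaults encode lower soluble
#'   relative degradation upon Not1 depletion, higher upon Not4/Not5
#'   depletion, mildly higher total degradation for all depletions).
#' @param deg_sdlog Log-normal sd of the per-gene degradation factor.
#' @param rna_mean_count Mean RNA-Seq count of a target gene in the total
#'   fraction (default 300).
#' @param nb_dispersion Negative-binomial dispersion of counts (default
#'   0.01, an asymptotic dispersion typical of tightly controlled yeast
#'   triplicates; 0 gives Poisson).
#' @param replicates Replicates per condition x fraction x assay (default
#'   3).
#' @param conditions Condition names (default WT, not1d, not4d, not5d).
#' @param seed Integer master seed; fixed seed gives byte-identical outputs.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes_target = 120, n_genes_spike = 20,
                       cds_length_range = c(300, 1500),
                       codon_usage = NULL, tai = synthetic_tai(),
                       dwell_a = 2, dwell_perturbation = list(),
                       periodic_fraction = c(soluble = 0.3, total = 0.6),
                       positional_amp = c(soluble = 0, total = 0.5),
                       expression_sdlog = 0.8,
                       s_range = c(0.2, 0.8), s_values = NULL,
                       planted = list(red_frac = 0.1, green_frac = 0.1,
                                      lfc = 1),
                       five_p_rate = c(soluble = 0.4, total = 0.1),
                       spike_5p_rate = 0.2,
                       condition_deg = list(
                         WT = c(soluble = 1, total = 1),
                         not1d = c(soluble = 0.6, total = 1.2),
                         not4d = c(soluble = 1.8, total = 1.2),
                         not5d = c(soluble = 1.4, total = 1.2)),
                       deg_sdlog = 0.25,
                       rna_mean_count = 300, nb_dispersion = 0.01,
                       replicates = 3,
                       conditions = c("WT", "not1d", "not4d", "not5d"),
                       seed = 1L) {
  codons <- sense_codons()
  if (is.null(codon_usage))
    codon_usage <- stats::setNames(rep(1 / 61, 61), codons)
  if (!setequal(names(codon_usage), codons))
    stop("codon_usage must cover exactly the 61 sense codons")
  codon_usage <- codon_usage[codons] / sum(codon_usage)
  stopifnot(all(codon_usage >= 0),
            all(tai[codons] > 0),
            all(periodic_fraction >= 0 & periodic_fraction <= 1),
            all(positional_amp >= 0 & positional_amp < 1),
            s_range[1] > 0, s_range[2] < 1, s_range[1] <= s_range[2],
            all(five_p_rate > 0), spike_5p_rate > 0,
            is.null(s_values) ||
              all(s_values > 0 & s_values < 1),
            nb_dispersion >= 0, replicates >= 1,
            n_genes_target >= 2, n_genes_spike >= 2)
  if (!all(conditions %in% names(condition_deg)))
    stop("condition_deg must name every condition")
  cfg <- list(
    n_genes_target = as.integer(n_genes_target),
    n_genes_spike = as.integer(n_genes_spike),
    cds_length_range = cds_length_range,
    codon_usage = codon_usage, tai = tai[codons], dwell_a = dwell_a,
    dwell_perturbation = dwell_perturbation,
    periodic_fraction = periodic_fraction,
    positional_amp = positional_amp,
    expression_sdlog = expression_sdlog, s_range = s_range,
    s_values = s_values,
    planted = planted, five_p_rate = five_p_rate,
    spike_5p_rate = spike_5p_rate, condition_deg = condition_deg,
    deg_sdlog = deg_sdlog, rna_mean_count = rna_mean_count,
    nb_dispersion = nb_dispersion, replicates = as.integer(replicates),
    conditions = conditions, seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys are \code{\link{sim_config}} arguments
#'   (vectors with names supported via YAML maps).
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("periodic_fraction", "positional_amp", "five_p_rate",
               "codon_usage", "tai"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$condition_deg))
    y$condition_deg <- lapply(y$condition_deg, unlist)
  do.call(sim_config, y)
}

#' Generate the synthetic two-species transcriptome
#'
#' Samples one single-exon protein-coding gene per contig: an ATG start,
#' internal codons drawn from \code{codon_usage}, a single terminal TAA
#' stop, and random flanking sequence. Strands alternate between + and -
#' (minus-strand CDSs are stored reverse-complemented in the genome).
#' Spike-in genes live on contigs named \code{SPIKE_*}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{catalog} (a \code{\link{transcript_catalog}}) and
#'   \code{genome} (named \link[Biostrings]{DNAStringSet}).
#' @export
generate_transcriptome <- function(config) {
  with_preserved_seed(config$seed, {
    n_t <- config$n_genes_target; n_s <- config$n_genes_spike
    ids <- c(sprintf("gene%04d", seq_len(n_t)),
             sprintf("spike%03d", seq_len(n_s)))
    species <- c(rep("target", n_t), rep("spike", n_s))
    chroms <- ifelse(species == "spike", paste0("SPIKE_", ids),
                     paste0("chr_", ids))
    strands <- rep(c("+", "-"), length.out = n_t + n_s)
    lo <- config$cds_length_range[1]; hi <- config$cds_length_range[2]
    n_cod <- pmax(round(stats::runif(n_t + n_s, lo, hi) / 3), 10)
    codons <- sense_codons()
    flank <- 50L
    seqs <- character(n_t + n_s)
    parts <- vector("list", n_t + n_s)
    genome <- character(n_t + n_s)
    for (i in seq_len(n_t + n_s)) {
      internal <- sample(codons, n_cod[i] - 2L, replace = TRUE,
                         prob = config$codon_usage)
      cds <- paste0("ATG", paste(internal, collapse = ""), "TAA")
      L <- nchar(cds)
      fl5 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                   collapse = "")
      fl3 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                   collapse = "")
      cds_genomic <- if (strands[i] == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds))) else cds
      genome[i] <- paste0(fl5, cds_genomic, fl3)
      seqs[i] <- cds
      parts[[i]] <- data.frame(chrom = chroms[i], start = flank + 1L,
                               end = flank + L, strand = strands[i],
                               tx_offset = 0L, gene_id = ids[i],
                               stringsAsFactors = FALSE)
    }
    pdf_ <- do.call(rbind, parts)
    parts_gr <- GenomicRanges::GRanges(
      seqnames = pdf_$chrom,
      ranges = IRanges::IRanges(pdf_$start, pdf_$end),
      strand = pdf_$strand, gene_id = pdf_$gene_id,
      tx_offset = pdf_$tx_offset)
    genes <- data.frame(id = ids, chrom = chroms, strand = strands,
                        species = species, cds_length = nchar(seqs),
                        stringsAsFactors = FALSE)
    gen <- Biostrings::DNAStringSet(stats::setNames(genome, chroms))
    list(catalog = transcript_catalog(genes, parts_gr,
                                      stats::setNames(seqs, ids)),
         genome = gen)
  })
}

#' Ground-truth per-gene simulation parameters
#'
#' Recomputes, deterministically from the config seed, the per-gene
#' parameters underlying a simulated experiment: relative expression,
#' solubility (fraction soluble) per condition, the planted solubility
#' category, and the per-gene degradation factor. Calling this on the
#' catalog returned by \code{\link{generate_transcriptome}} with the same
#' config gives exactly the values used by the library simulators, so
#' estimator output can be compared against truth without running
#' \code{\link{simulate_experiment}}.
#'
#' @param catalog Catalog from \code{\link{generate_transcriptome}}.
#' @param config The \code{\link{sim_config}} used to generate it.
#' @return List: \code{expression}, \code{solubility} (gene x condition
#'   matrix), \code{category}, \code{deg_gene}; all indexed by gene id.
#' @export
gene_params <- function(catalog, config) {
  # derived seed kept inside the 32-bit integer range for any master seed
  with_preserved_seed(as.integer((as.double(config$seed) + 7) %% 2147483647), {
    g <- catalog$genes
    n <- nrow(g)
    tgt <- which(g$species == "target")
    expr <- exp(stats::rnorm(n, -config$expression_sdlog^2 / 2,
                             config$expression_sdlog))
    expr[g$species == "spike"] <-
      exp(stats::rnorm(sum(g$species == "spike"), 0, 0.3))
    n_red <- round(config$planted$red_frac * length(tgt))
    n_green <- round(config$planted$green_frac * length(tgt))
    category <- rep("null", n)
    if (n_red > 0) category[tgt[seq_len(n_red)]] <- "red"
    if (n_green > 0) category[tgt[n_red + seq_len(n_green)]] <- "green"
    s_wt <- stats::runif(n, config$s_range[1], config$s_range[2])
    if (!is.null(config$s_values))
      s_wt[tgt] <- rep_len(config$s_values, length(tgt))
    pl <- category != "null"
    # planted genes start low enough that doubling solubility stays < 1
    s_wt[pl] <- stats::runif(sum(pl), 0.2, 0.45)
    fold <- 2^config$planted$lfc
    s <- sapply(config$conditions, function(cc) {
      si <- s_wt
      if (cc == "not1d") {
        si[category == "red"] <- pmax(s_wt[category == "red"] / fold, 0.02)
        si[category == "green"] <- pmin(s_wt[category == "green"] * fold,
                                        0.95)
      } else if (cc == "not4d") {
        si[category == "red"] <- pmin(s_wt[category == "red"] * fold, 0.95)
        si[category == "green"] <- pmax(s_wt[category == "green"] / fold,
                                        0.02)
      }
      si
    })
    rownames(s) <- g$id
    deg <- exp(stats::rnorm(n, -config$deg_sdlog^2 / 2, config$deg_sdlog))
    list(expression = stats::setNames(expr, g$id), solubility = s,
         category = stats::setNames(category, g$id),
         deg_gene = stats::setNames(deg, g$id))
  })
}

# per-codon dwell weights for a condition (ground-truth A-site dwell)
dwell_weights <- function(config, condition) {
  w <- exp(-config$dwell_a * config$tai)
  pert <- config$dwell_perturbation[[condition]]
  if (!is.null(pert)) w[names(pert)] <- w[names(pert)] * pert
  w
}

#' Simulate one 5'P-Seq library
#'
#' Draws, per gene, a negative-binomial number of decay intermediates and
#' places each 5' end either co-translationally (probability
#' \code{periodic_fraction[fraction]}: 17 nt upstream of an A-site codon
#' sampled proportionally to dwell weight times the positional ramp; codons
#' starting before nt 17 and the stop codon are ineligible) or uniformly
#' over the CDS. The soluble library is thinned by the gene's solubility;
#' spike-in genes are condition-invariant with uniform ends.
#'
#' @param catalog Catalog from \code{\link{generate_transcriptome}}.
#' @param config A \code{\link{sim_config}}.
#' @param condition,fraction Library condition and fraction.
#' @param seed Integer seed for this library.
#' @param depth_scale Multiplier on expected molecule counts (default 1).
#' @return A \code{\link{five_prime_tracks}}.
#' @export
simulate_5p_sample <- function(catalog, config, condition = "WT",
                               fraction = "total", seed = 1L,
                               depth_scale = 1) {
  params <- gene_params(catalog, config)
  w_codon <- dwell_weights(config, condition)
  pi_frac <- config$periodic_fraction[[fraction]]
  amp <- config$positional_amp[[fraction]]
  rate <- config$five_p_rate[[fraction]] *
    config$condition_deg[[condition]][[fraction]]
  with_preserved_seed(seed, {
    tracks <- empty_tracks(catalog)
    for (i in seq_len(nrow(catalog$genes))) {
      g <- catalog$genes$id[i]
      spike <- catalog$genes$species[i] == "spike"
      L <- catalog$genes$cds_length[i]
      s_eff <- if (fraction == "soluble" && !spike)
        params$solubility[g, condition] else 1
      mu <- config$rna_mean_count * params$expression[g] * s_eff *
        depth_scale *
        (if (spike) config$spike_5p_rate else rate * params$deg_gene[g])
      N <- if (config$nb_dispersion > 0)
        stats::rnbinom(1, mu = mu, size = 1 / config$nb_dispersion)
      else stats::rpois(1, mu)
      if (N == 0) next
      pi_g <- if (spike) 0 else pi_frac
      n_per <- stats::rbinom(1, N, pi_g)
      v <- integer(L)
      if (n_per > 0) {
        cod <- gene_codons(catalog, g)
        K <- length(cod)
        k_all <- seq_len(K - 1)                 # codon indices 1..K-1 (sense)
        elig <- k_all[3 * (k_all - 1) >= 17]
        if (length(elig) > 0) {
          ramp <- 1 + amp * (2 * (elig - 1) / max(K - 2, 1) - 1)
          wts <- w_codon[cod[elig]] * ramp
          ks <- elig[sample.int(length(elig), n_per, replace = TRUE,
                                prob = wts)]
          pos <- 3L * (ks - 1L) - 17L
          v <- v + tabulate(pos + 1L, nbins = L)
        } else n_per <- 0L
      }
      n_uni <- N - n_per
      if (n_uni > 0)
        v <- v + tabulate(sample.int(L, n_uni, replace = TRUE), nbins = L)
      tracks[[g]] <- v
    }
    if (sum(vapply(tracks, sum, numeric(1))) == 0)
      warning("simulated 5'P library is empty", call. = FALSE)
    five_prime_tracks(
      sprintf("%s_%s_5P", condition, fraction), tracks)
  })
}

#' Simulate one RNA-Seq library
#'
#' Per-gene negative-binomial read counts with mean proportional to
#' expression times the fraction weight (solubility for the soluble pool),
#' and read 5' ends uniform over the CDS.
#'
#' @inheritParams simulate_5p_sample
#' @param tracks Build positional 5'-end tracks (default TRUE); FALSE
#'   returns counts only (faster when only count statistics are needed).
#' @return List: \code{trackset} (a \code{\link{five_prime_tracks}}, NULL
#'   when \code{tracks = FALSE}) and \code{counts} (named integer vector of
#'   CDS read counts).
#' @export
simulate_rna_sample <- function(catalog, config, condition = "WT",
                                fraction = "total", seed = 1L,
                                depth_scale = 1, tracks = TRUE) {
  params <- gene_params(catalog, config)
  with_preserved_seed(seed, {
    g <- catalog$genes
    s_eff <- ifelse(g$species == "spike" | fraction == "total", 1,
                    params$solubility[cbind(g$id, condition)])
    mu <- config$rna_mean_count * params$expression[g$id] * s_eff *
      depth_scale
    counts <- if (config$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    else stats::rpois(length(mu), mu)
    names(counts) <- g$id
    if (!tracks)
      return(list(trackset = NULL, counts = counts))
    tr <- empty_tracks(catalog)
    for (i in seq_along(counts)) {
      if (counts[i] == 0) next
      L <- g$cds_length[i]
      tr[[g$id[i]]] <- tabulate(
        sample.int(L, counts[i], replace = TRUE), nbins = L)
    }
    list(trackset = five_prime_tracks(
      sprintf("%s_%s_RNA", condition, fraction), tr),
      counts = counts)
  })
}

#' Simulate the full multi-condition experiment
#'
#' Generates the transcriptome, then every library of the design
#' (conditions x \{soluble, total\} x \{5P, RNA\} x replicates), aggregates
#' counts, and returns the ground truth for every downstream estimator. Two
#' runs with the same config are identical.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{catalog}, \code{genome}, \code{counts} (a
#'   \code{SummarizedExperiment}), \code{tracksets_5p},
#'   \code{tracksets_rna} (named lists of \code{five_prime_tracks}),
#'   \code{truth} (see Details), \code{manifest} (data.frame of libraries).
#'   \code{truth$genes} holds per-gene expression, solubility per condition,
#'   the true solubility change (log2 s_cond/s_WT), the planted category and
#'   the true relative-degradation LFC (log2 of the gene's 5'P rate over the
#'   spike-in rate, the quantity the spike-anchored 5P/RNA contrast
#'   estimates); \code{truth$codons} holds the dwell ground truth.
#' @export
simulate_experiment <- function(config) {
  tg <- generate_transcriptome(config)
  catalog <- tg$catalog
  params <- gene_params(catalog, config)
  design <- expand.grid(replicate = seq_len(config$replicates),
                        assay = c("5P", "RNA"),
                        fraction = c("soluble", "total"),
                        condition = config$conditions,
                        stringsAsFactors = FALSE)
  design <- design[, c("condition", "fraction", "assay", "replicate")]
  design$sample <- sprintf("%s_%s_%s_rep%d", design$condition,
                           design$fraction, design$assay, design$replicate)
  tracksets_5p <- list(); tracksets_rna <- list()
  counts <- matrix(0L, nrow = nrow(catalog$genes), ncol = nrow(design),
                   dimnames = list(catalog$genes$id, design$sample))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    seed_i <- as.integer((as.double(config$seed) * 10007 + i) %% 2147483647)
    if (d$assay == "5P") {
      ts <- simulate_5p_sample(catalog, config, d$condition, d$fraction,
                               seed = seed_i)
      ts$sample_id <- d$sample
      tracksets_5p[[d$sample]] <- ts
      counts[, i] <- vapply(ts$tracks, sum, numeric(1))
    } else {
      rs <- simulate_rna_sample(catalog, config, d$condition, d$fraction,
                                seed = seed_i)
      rs$trackset$sample_id <- d$sample
      tracksets_rna[[d$sample]] <- rs$trackset
      counts[, i] <- rs$counts
    }
  }
  sample_info <- design[, c("condition", "fraction", "assay", "replicate")]
  rownames(sample_info) <- design$sample
  se <- count_experiment(counts, sample_info, catalog$genes$species)

  sol <- params$solubility
  truth_genes <- data.frame(
    gene = catalog$genes$id, species = catalog$genes$species,
    expression = unname(params$expression),
    category = unname(params$category),
    deg_gene = unname(params$deg_gene), stringsAsFactors = FALSE)
  for (cc in config$conditions) {
    truth_genes[[paste0("s_", cc)]] <- unname(sol[, cc])
    truth_genes[[paste0("dsol_", cc)]] <- log2(sol[, cc] / sol[, "WT"])
    for (ff in c("soluble", "total"))
      truth_genes[[paste0("reldeg_", cc, "_", ff)]] <- ifelse(
        catalog$genes$species == "spike", 0,
        log2(config$five_p_rate[[ff]] * config$condition_deg[[cc]][[ff]] *
               params$deg_gene / config$spike_5p_rate))
  }
  truth_codons <- data.frame(
    codon = names(config$tai), tai = unname(config$tai),
    dwell_multiplier = unname(exp(-config$dwell_a * config$tai)),
    stringsAsFactors = FALSE)

  list(catalog = catalog, genome = tg$genome, counts = se,
       tracksets_5p = tracksets_5p, tracksets_rna = tracksets_rna,
       truth = list(genes = truth_genes, codons = truth_codons),
       manifest = design)
}

#' Write a simulated experiment to disk
#'
#' Emits FASTA + GFF3 annotation, the gene x sample counts TSV, per-library
#' bedGraph tracks, ground-truth TSVs, and a manifest TSV with an md5 digest
#' per file. All outputs are plain text; identical configs give
#' byte-identical files.
#'
#' @param sim Result of \code{\link{simulate_experiment}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a data.frame of (file, md5).
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  write_annotation(sim$catalog, sim$genome,
                   file.path(dir, "genome.fa"),
                   file.path(dir, "annotation.gff3"))
  cm <- SummarizedExperiment::assay(sim$counts, "counts")
  utils::write.table(
    data.frame(gene = rownames(cm), cm, check.names = FALSE),
    file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  si <- as.data.frame(SummarizedExperiment::colData(sim$counts))
  utils::write.table(data.frame(sample = rownames(si), si),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ts in c(sim$tracksets_5p, sim$tracksets_rna))
    write_trackset_bedgraph(
      ts, file.path(dir, "tracks", paste0(ts$sample_id, ".bedgraph")))
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$codons, file.path(dir, "truth_codons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$manifest, file.path(dir, "libraries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.tsv"]
  digest <- data.frame(
    file = sub(paste0("^", dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  utils::write.table(digest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(digest)
}

#' Simulate a ChEC promoter experiment
#'
#' Promoter windows (400 bp upstream / 100 bp downstream of a +1 nucleosome
#' position on a virtual contig) with Poisson cut counts: the control
#' (free MNase) sees length-proportional background with per-promoter
#' abundance jitter; the fusion sample sees the same background multiplied
#' by the planted enrichment (1 for unbound promoters).
#'
#' @param n_promoters Number of promoters (default 1000).
#' @param bound_frac Fraction of promoters bound (default 0.1).
#' @param enrichment Fold enrichment at bound promoters (default 4, i.e.
#'   true centered LFC = 2).
#' @param mean_coverage Expected control counts per promoter (default 200).
#' @param jitter_sdlog Log-normal sd of shared abundance jitter (default
#'   0.3).
#' @param seed Integer seed.
#' @return List: \code{plus1} (+1 positions table), \code{contig_lengths},
#'   \code{windows} (from \code{\link{promoter_windows}}), \code{counts}
#'   (data.frame gene, count_sample, count_control), \code{truth}
#'   (data.frame gene, enrichment, bound).
#' @export
simulate_chec <- function(n_promoters = 1000, bound_frac = 0.1,
                          enrichment = 4, mean_coverage = 200,
                          jitter_sdlog = 0.3, seed = 1L) {
  with_preserved_seed(seed, {
    genes <- sprintf("prom%04d", seq_len(n_promoters))
    contig_len <- 1000L * n_promoters + 2000L
    pos <- sort(sample(500:(contig_len - 500), n_promoters))
    strand <- rep(c("+", "-"), length.out = n_promoters)
    plus1 <- data.frame(gene = genes, chrom = "chrSim", pos = pos,
                        strand = strand, stringsAsFactors = FALSE)
    windows <- promoter_windows(plus1, c(chrSim = contig_len))
    bound <- seq_len(n_promoters) %in%
      sample.int(n_promoters, round(bound_frac * n_promoters))
    enr <- ifelse(bound, enrichment, 1)
    bg <- mean_coverage * (windows$width / 501) *
      exp(stats::rnorm(n_promoters, -jitter_sdlog^2 / 2, jitter_sdlog))
    counts <- data.frame(
      gene = genes,
      count_sample = stats::rpois(n_promoters, bg * enr),
      count_control = stats::rpois(n_promoters, bg),
      stringsAsFactors = FALSE)
    list(plus1 = plus1, contig_lengths = c(chrSim = contig_len),
         windows = windows, counts = counts,
         truth = data.frame(gene = genes, enrichment = enr, bound = bound,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a PAR-CLIP cross-linking experiment
#'
#' Regions with a T-base count and Poisson T-to-C transition counts for a
#' factor of interest and a reference factor sharing a per-region
#' cross-link rate; a planted subset deviates from the reference-predicted
#' rate by \code{high_bias} (more cross-linking) or \code{low_bias} (less).
#'
#' @param n_regions Number of regions (default 2000).
#' @param t_count_range Range of T counts per region (default 200-1500).
#' @param base_rate Mean transitions per T in the reference (default 0.05).
#' @param rate_sdlog Log-normal sd of the shared per-region rate (default
#'   0.5).
#' @param high_frac,low_frac Fractions of regions planted high / low
#'   (defaults 0.10 and 0.05).
#' @param high_bias,low_bias Fold deviation of the planted subsets
#'   (defaults 4 and 0.25; both beyond the twofold calling cutoff).
#' @param seed Integer seed.
#' @return List: \code{regions} (data.frame region, t_count,
#'   transitions_not4, transitions_rnapii), \code{truth} (region, bias,
#'   class in \{higher, lower, expected\}).
#' @export
simulate_parclip <- function(n_regions = 2000,
                             t_count_range = c(200, 1500),
                             base_rate = 0.05, rate_sdlog = 0.5,
                             high_frac = 0.10, low_frac = 0.05,
                             high_bias = 4, low_bias = 0.25, seed = 1L) {
  with_preserved_seed(seed, {
    region <- sprintf("region%04d", seq_len(n_regions))
    t_count <- as.integer(round(stats::runif(n_regions, t_count_range[1],
                                             t_count_range[2])))
    rate <- base_rate * exp(stats::rnorm(n_regions, -rate_sdlog^2 / 2,
                                         rate_sdlog))
    n_high <- round(high_frac * n_regions)
    n_low <- round(low_frac * n_regions)
    bias <- rep(1, n_regions)
    idx <- sample.int(n_regions, n_high + n_low)
    bias[idx[seq_len(n_high)]] <- high_bias
    if (n_low > 0) bias[idx[n_high + seq_len(n_low)]] <- low_bias
    regions <- data.frame(
      region = region, t_count = t_count,
      transitions_not4 = stats::rpois(n_regions, t_count * rate * bias),
      transitions_rnapii = stats::rpois(n_regions, t_count * rate),
      stringsAsFactors = FALSE)
    cls <- ifelse(bias > 1, "higher", ifelse(bias < 1, "lower", "expected"))
    list(regions = regions,
         truth = data.frame(region = region, bias = bias, class = cls,
                            stringsAsFactors = FALSE))
  })
}
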