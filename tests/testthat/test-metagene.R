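test_that("anchored metagene places single ends at the right offset", {
  cat0 <- toy_catalog()
  track <- integer(30); track[13] <- 1L   # transcript position 12
  ts <- five_prime_tracks("a", list(g1 = track, g2 = integer(21),
                                    s1 = integer(9)))
  prof0 <- metagene_anchored(ts, cat0, anchor = "start", shift_nt = 0,
                             flank = c(5, 25))
  expect_equal(prof0$value[prof0$offset == 12], 1e6)
  expect_equal(sum(prof0$value), 1e6)
  # +17 shift moves the same end to offset 29
  prof17 <- metagene_anchored(ts, cat0, anchor = "start", shift_nt = 17,
                              flank = c(0, 40))
  expect_equal(prof17$value[prof17$offset == 29], 1e6)
  # stop anchor: offset 0 is the first nt of the stop codon (position 27)
  track2 <- integer(30); track2[28] <- 1L
  ts2 <- five_prime_tracks("b", list(g1 = track2, g2 = integer(21),
                                     s1 = integer(9)))
  profs <- metagene_anchored(ts2, cat0, anchor = "stop", shift_nt = 0,
                             flank = c(10, 5))
  expect_equal(profs$value[profs$offset == 0], 1e6)
})

test_that("metagene profiles match the brute-force oracles", {
  cat0 <- toy_catalog()
  ts <- toy_trackset(cat0)
  for (anchor in c("start", "stop")) {
    got <- metagene_anchored(ts, cat0, anchor = anchor, shift_nt = 17,
                             flank = c(20, 60))
    bf <- bf_metagene_anchored(ts, cat0, anchor = anchor, shift = 17,
                               flank = c(20, 60))
    expect_equal(got$value, bf$value, tolerance = 1e-12)
    expect_identical(got$n_genes, bf$n_genes)
  }
  for (nb in c(20, 100)) {
    got <- metagene_scaled(ts, cat0, n_bins = nb)
    bf <- bf_metagene_scaled(ts, cat0, n_bins = nb)
    expect_equal(got$value, unname(bf), tolerance = 1e-12)
  }
  expect_equal(unname(frame_fractions(ts, cat0)),
               bf_frame_fractions(ts, cat0), tolerance = 1e-12)
})

test_that("a uniform library gives a flat scaled profile of ones", {
  internal <- rep("CAA", 58)
  cat0 <- long_gene_catalog(c("ATG", internal, "TAA"))
  ts <- five_prime_tracks("u", list(gl = rep(3L, 180)))
  prof <- metagene_scaled(ts, cat0, n_bins = 20)
  expect_equal(prof$value, rep(1, 20))
})

test_that("averaging across samples is per-million then mean", {
  cat0 <- toy_catalog()
  t1 <- integer(30); t1[4] <- 2L
  t2 <- integer(30); t2[4] <- 6L
  mk <- function(tr, id) five_prime_tracks(
    id, list(g1 = tr, g2 = integer(21), s1 = integer(9)))
  p <- metagene_anchored(list(mk(t1, "x"), mk(t2, "y")), cat0,
                         anchor = "start", shift_nt = 0, flank = c(0, 10))
  # both libraries have all reads at position 3: each contributes 1e6
  expect_equal(p$value[p$offset == 3], 1e6)
})

test_that("frame fractions follow position mod 3", {
  cat0 <- toy_catalog()
  track <- integer(30)
  track[1] <- 1L; track[2] <- 2L; track[3] <- 1L  # positions 0, 1, 2
  ts <- five_prime_tracks("f", list(g1 = track, g2 = integer(21),
                                    s1 = integer(9)))
  expect_equal(unname(frame_fractions(ts, cat0)), c(25, 50, 25))
})

test_that("window proportions use half-open fractional windows", {
  cat0 <- toy_catalog()
  # g1 (L = 30): fraction of position i (1-based) is (i-1)/30
  sol <- integer(30); sol[4] <- 20L              # frac 0.10 -> in 10-30%
  tot <- integer(30); tot[7] <- 10L; tot[10] <- 10L  # frac 0.20 in, 0.30 out
  mk <- function(tr, id) five_prime_tracks(
    id, list(g1 = tr, g2 = integer(21), s1 = integer(9)))
  res <- window_ratio(mk(sol, "s"), mk(tot, "t"), cat0)
  w1 <- res[res$window == "10-30%", ]
  expect_equal(w1$prop_soluble, 1)
  expect_equal(w1$prop_total, 0.5)
  expect_equal(w1$log2_ratio, -1)
  # g2 has zero reads -> excluded
  expect_identical(attr(res, "excluded"), 1L)

  # threshold boundary: exactly min_reads reads in both is included
  sol19 <- integer(30); sol19[4] <- 19L
  res19 <- window_ratio(mk(sol19, "s"), mk(tot, "t"), cat0,
                        transcripts = "g1")
  expect_identical(nrow(res19), 0L)
  res20 <- window_ratio(mk(sol, "s"), mk(tot, "t"), cat0,
                        transcripts = "g1", min_reads = 20)
  expect_identical(nrow(res20), 3L)
})

test_that("window_ratio matches the brute-force oracle", {
  cat0 <- toy_catalog()
  ts1 <- toy_trackset(cat0, "s")
  tracks2 <- lapply(toy_trackset(cat0, "t")$tracks,
                    function(v) as.integer(rev(v)))
  ts2 <- five_prime_tracks("t", tracks2)
  wins <- list(c(0.1, 0.3), c(0.4, 0.6), c(0.7, 0.9))
  got <- window_ratio(ts1, ts2, cat0, windows = wins, min_reads = 20)
  bf <- bf_window_ratio(ts1, ts2, cat0, wins, 20)
  expect_equal(got$prop_soluble, bf$prop_soluble, tolerance = 1e-12)
  expect_equal(got$prop_total, bf$prop_total, tolerance = 1e-12)
})
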