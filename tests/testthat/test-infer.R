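test_that("consensus binarization maps minority residues to 1 and handles gaps/ties", {
  aln <- timepoint_alignment(list(c("AAC-G", "AAC-G", "AACTG", "GACTA", "GACTA")),
                             times = 1)
  bin <- consensus_binarize(aln)
  # column 4 contains gaps in two sequences: dropped, index recorded
  expect_equal(bin$dropped_columns, 4)
  expect_equal(bin$column_map, c(1, 2, 3, 5))
  # column 1 (A,A,A,G,G): consensus A, binary 0,0,0,1,1
  expect_equal(bin$matrices[[1]][, 1], c(0, 0, 0, 1, 1))
  # all-identical columns are all zero
  expect_true(all(bin$matrices[[1]][, 2:3] == 0))
  expect_equal(bin$consensus[1], "A")

  # modal tie resolved by character order and flagged
  aln2 <- timepoint_alignment(list(c("AG", "GG", "AG", "GG")), times = 1)
  bin2 <- consensus_binarize(aln2)
  expect_equal(bin2$tied_columns, 1)
  expect_equal(bin2$consensus[1], "A")
})

test_that("estimates only depend on the consensus/minority partition", {
  seqs_nt <- c("AAG", "AAG", "ACG", "CCG")
  seqs_aa <- c("MKW", "MKW", "MRW", "LRW")  # same partition, other alphabet
  b1 <- consensus_binarize(timepoint_alignment(list(seqs_nt), 1))
  b2 <- consensus_binarize(timepoint_alignment(list(seqs_aa), 1))
  expect_equal(b1$matrices[[1]], b2$matrices[[1]], ignore_attr = TRUE)
})

test_that("minority frequencies support both replicate pooling strategies", {
  m <- matrix("A", 40, 1)
  m[1, 1] <- "G"                            # replicate 1: n=10, f=0.1
  m[11:19, 1] <- "G"                        # replicate 2: n=30, f=0.3
  aln <- timepoint_alignment(list(m), times = 5,
                             replicates = list(rep(c(1, 2), c(10, 30))))
  bin <- consensus_binarize(aln)
  expect_equal(minority_frequency(bin, 5, "pooled"), 0.25)
  expect_equal(minority_frequency(bin, 5, "mean"), 0.2)
  expect_error(minority_frequency(bin, 99), "no such time point")
})

test_that("the relative-selection estimator is -log(f/f_norm) with exclusions", {
  expect_equal(relative_selection(0.5, 0.5), 0)
  expect_equal(relative_selection(0.05, 0.5), log(10), tolerance = 1e-12)
  expect_equal(log(10), 2.3026, tolerance = 1e-4)
  expect_equal(relative_selection(0.6, 0.5), -0.1823, tolerance = 1e-3)
  expect_true(is.na(relative_selection(0, 0.5)))
  # linear in -log f; a change of f_norm shifts all estimates uniformly
  f <- c(0.02, 0.1, 0.44)
  expect_equal(relative_selection(f, 0.4) - relative_selection(f, 0.4 * 1.7),
               rep(-log(1.7), 3), tolerance = 1e-12)
})

test_that("ranking is descending with index tie-break and invertible", {
  rc <- rank_sites(c(0.5, 2.3, 1.2))
  expect_equal(rc$site_index, c(2, 3, 1))
  expect_equal(rc$s_rank, c(2.3, 1.2, 0.5))
  back <- rc$s_rank[rc$rank_of_site]
  expect_equal(back, c(0.5, 2.3, 1.2))

  rc2 <- rank_sites(c(1, 1, 1))
  expect_equal(rc2$site_index, 1:3)

  rc3 <- rank_sites(c(NA, 0.2, NA, 0.1))
  expect_equal(rc3$site_index, c(2, 4))
  expect_true(all(is.na(rc3$rank_of_site[c(1, 3)])))
})

test_that("f_norm is recovered from the ranked-curve fixed point", {
  s <- c(-0.02, 0, 0.01, 0.03)
  res <- fnorm_from_frequencies(0.4 * exp(-10 * s), 0.4 * exp(-20 * s))
  expect_lt(abs(res$f_norm / 0.4 - 1), 0.01)
  # the intersection sits at the rank of the s = 0 site (rank 3 descending)
  expect_equal(res$intersection_rank, 3, tolerance = 1e-6)

  # uniform-shift identity: the crossing rank does not move with f_norm
  res2 <- fnorm_from_frequencies(0.2 * exp(-10 * s), 0.2 * exp(-20 * s))
  expect_equal(res2$intersection_rank, res$intersection_rank, tolerance = 1e-9)
  expect_lt(abs(res2$f_norm / 0.2 - 1), 0.01)

  # degenerate pair: identical curves cannot cross transversally
  expect_error(fnorm_from_frequencies(0.4 * exp(-10 * s), 0.4 * exp(-10 * s)),
               "degenerate|cross")
  # all-positive s: curves never cross
  sp <- c(0.01, 0.02, 0.05, 0.08)
  expect_error(fnorm_from_frequencies(0.4 * exp(-10 * sp), 0.4 * exp(-20 * sp)),
               "cross")
})

test_that("the inverse rank-curve derivative recovers the intrinsic density", {
  # linear ranked curve with slope -delta: constant density 1/delta
  d <- estimate_intrinsic_density(seq(2, 0.5, by = -0.05))
  expect_equal(unique(round(d$g_estimate, 9)), 1 / 0.05)

  # doubling the number of sites on a fixed s-range doubles the density
  d2 <- estimate_intrinsic_density(seq(2, 0.5, by = -0.025))
  expect_equal(mean(d2$g_estimate) / mean(d$g_estimate), 2, tolerance = 1e-9)

  # tied runs are merged before inversion
  d3 <- estimate_intrinsic_density(c(3, 2, 2, 2, 1))
  expect_true(all(is.finite(d3$g_estimate)))
  expect_error(estimate_intrinsic_density(rep(1, 5)), "tied")

  # half-normal landscape, exact exponential frequencies: the recovered
  # density matches the half-normal shape (KS on the implied sample)
  set.seed(8)
  s <- as.numeric(sample_selection_profile(500, intrinsic_dfe(0.05), seed = 8))
  beta <- 30
  est <- relative_selection(0.3 * exp(-beta * s), f_norm = 0.3)
  expect_equal(est, beta * s, tolerance = 1e-9)  # estimator is exact here
  ks <- suppressWarnings(
    stats::ks.test(est / beta, phalfnorm_mean, mean = mean(est) / beta))
  expect_gt(ks$p.value, 0.01)
})

test_that("the full pipeline factorizes across time points on exact input", {
  set.seed(9)
  # negative-s sites kept mild so no site's minority frequency crosses 1/2
  # (which would flip the pooled consensus and re-reference those sites)
  s <- c(seq(-0.012, -0.003, length.out = 5), 0,
         seq(0.004, 0.08, length.out = 24))
  f_t1 <- 0.4 * exp(-8 * s)
  f_t2 <- 0.4 * exp(-16 * s)
  # frequencies representable exactly at n = 4000 to 1 part in 1e3
  aln <- alignment_from_frequencies(list(f_t1, f_t2), n = 4000)
  out <- run_inference(aln)
  expect_lt(abs(out$fnorm$f_norm / 0.4 - 1), 0.02)

  est <- out$estimates
  ratio <- est$beta_s_t20 / est$beta_s_t10
  ratio <- ratio[abs(est$beta_s_t10) > 0.05]   # away from the s = 0 pivot
  expect_lt(sd(ratio) / mean(ratio), 0.2)      # constant beta(t2)/beta(t1)
  expect_equal(mean(ratio), 2, tolerance = 0.05)
})

test_that("a single time point falls back to f_norm = max(f) with a warning", {
  aln <- alignment_from_frequencies(list(c(0.4, 0.2, 0.1, 0.05, 0.3)), n = 100)
  expect_warning(out <- run_inference(aln), "single time point")
  expect_equal(out$fnorm$f_norm, 0.4)
  expect_equal(out$estimates$beta_s_t10[1], 0)
})
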