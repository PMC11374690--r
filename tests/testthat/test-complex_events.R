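test_that("oscillation detection follows the 4/2 and 5/3 rules", {
  expect_true(detect_oscillation(c(2, 1, 2, 1))$found)
  r <- detect_oscillation(c(2, 1, 2, 1))
  expect_equal(r$run_length, 4L)
  expect_equal(r$n_states, 2L)
  expect_false(detect_oscillation(c(2, 1, 2))$found)
  r <- detect_oscillation(c(4, 2, 3, 2, 4))
  expect_true(r$found)
  expect_equal(r$run_length, 5L)
  expect_equal(r$n_states, 3L)
  # adjacent equal values break the run
  expect_false(detect_oscillation(c(2, 1, 1, 2, 1))$found)
  # 4 segments with 3 states is not enough
  expect_false(detect_oscillation(c(1, 2, 3, 1))$found)
  expect_error(detect_oscillation(numeric()), "at least one")
})

test_that("interleave counting matches the crossing definition", {
  two <- rbind(sv_row("chr1", 100, "+", "chr1", 500, "-"),
               sv_row("chr1", 300, "+", "chr1", 700, "-"))
  expect_equal(count_interleaved(two), 2L)
  nested <- rbind(sv_row("chr1", 100, "+", "chr1", 700, "-"),
                  sv_row("chr1", 200, "+", "chr1", 300, "-"))
  expect_equal(count_interleaved(nested), 0L)
  ladder <- do.call(rbind, lapply(0:5, function(i)
    sv_row("chr1", 100 + i * 200, "+", "chr1", 400 + i * 200, "-")))
  expect_equal(count_interleaved(ladder), 6L)
})

test_that("interleave counting equals brute force on random fixtures", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    p1 <- sample(1e6, n)
    svs <- sv_row(rep("chr1", n), p1, "+", "chr1", p1 + sample(1e5, n), "-")
    # mix in another chromosome and interchromosomal junctions
    svs$chrom1[seq_len(n) %% 5 == 0] <- "chr2"
    svs$chrom2[seq_len(n) %% 5 == 0] <- "chr2"
    svs$chrom2[seq_len(n) %% 7 == 0] <- "chr3"
    expect_equal(count_interleaved(svs), interleaved_oracle(svs))
  }
})

test_that("exact multinomial p values", {
  expect_equal(multinomial_test_p(c(3, 3, 3, 3)), 1.0)
  expect_equal(multinomial_test_p(c(12, 0, 0, 0)), 4 * (1 / 4)^12,
               tolerance = 1e-12)
  expect_equal(multinomial_test_p(c(0, 0, 0, 0)), 1)
  # single cluster: BH FDR equals p
  r <- orientation_multinomial_fdr(matrix(c(5, 1, 0, 0), nrow = 1))
  expect_equal(r$fdr, r$p)
  # chi-square fallback for large totals is a valid p value
  p <- multinomial_test_p(c(40, 20, 20, 20))
  expect_true(p > 0 && p <= 1)
})

test_that("chromothripsis calls require all three criteria", {
  fix <- make_chromothripsis_cluster(seed = 3)
  r <- call_chromothripsis(fix$svs, fix$cn_segments, orientation_fdr = 1)
  expect_equal(r$call, "chromothripsis")
  expect_true(r$interleaved >= 6)
  # too few interleaved
  small <- make_chromothripsis_cluster(n_sv = 5, seed = 3)
  r <- call_chromothripsis(small$svs, small$cn_segments, orientation_fdr = 1)
  expect_equal(r$call, "complex_unclassified")
  # orientation FDR at or below 0.2 vetoes the call
  r <- call_chromothripsis(fix$svs, fix$cn_segments, orientation_fdr = 0.1)
  expect_equal(r$call, "complex_unclassified")
  # flat copy number vetoes the call
  flat <- make_chromothripsis_cluster(positive = FALSE,
                                      defect = "no_oscillation", seed = 3)
  r <- call_chromothripsis(flat$svs, flat$cn_segments, orientation_fdr = 1)
  expect_equal(r$call, "complex_unclassified")
  expect_error(call_chromothripsis(fix$svs[1:2, ], fix$cn_segments, 1),
               ">= 3")
})

test_that("chromoplexy calls require chain, balance and size criteria", {
  fix <- make_chromoplexy_cluster(seed = 5)
  r <- call_chromoplexy(fix$svs)
  expect_equal(r$call, "chromoplexy")
  expect_true(r$chain_chromosomes >= 3)
  two <- make_chromoplexy_cluster(positive = FALSE, defect = "two_chroms",
                                  seed = 5)
  expect_equal(nrow(two$svs), 3)
  expect_equal(call_chromoplexy(two$svs)$chain_chromosomes, 2)
  expect_equal(call_chromoplexy(two$svs)$call, "complex_unclassified")
  many <- make_chromoplexy_cluster(positive = FALSE, defect = "too_many",
                                   seed = 5)
  expect_equal(nrow(many$svs), 31)
  expect_equal(call_chromoplexy(many$svs)$call, "complex_unclassified")
  unbal <- make_chromoplexy_cluster(positive = FALSE, defect = "unbalanced",
                                    seed = 5)
  expect_equal(call_chromoplexy(unbal$svs)$call, "complex_unclassified")
})

test_that("cluster-level classification routes chromothripsis first", {
  ct <- make_chromothripsis_cluster(seed = 2)
  cp <- make_chromoplexy_cluster(chroms = c("chr4", "chr5", "chr6"), seed = 2)
  svs <- rbind(cbind(ct$svs, cluster_id = 1L), cbind(cp$svs, cluster_id = 2L))
  calls <- classify_complex_clusters(svs, ct$cn_segments)
  expect_equal(calls$call[calls$cluster_id == 1], "chromothripsis")
  expect_equal(calls$call[calls$cluster_id == 2], "chromoplexy")
})

test_that("complex enrichment flags stacked footprints and caps FDR", {
  lay <- tiny_layout(2, 1e7)
  grid <- build_bins(lay, 1e6)
  # 8 tumours, all with a footprint on the same bin; 4 with an extra random one
  fps <- lapply(1:8, function(i) {
    fp <- data.frame(chrom = "chr1", start = 3.2e6, end = 3.4e6)
    if (i > 4) fp <- rbind(fp, data.frame(chrom = "chr2",
                                          start = i * 1e6, end = i * 1e6 + 2e5))
    fp
  })
  res <- complex_enrichment(fps, lay, grid, n_perm = 200, seed = 9)
  top <- res[which.max(res$beta), ]
  expect_equal(top$chrom, "chr1")
  expect_equal(top$start, 3e6)
  expect_equal(top$g_obs, 8)
  expect_true(all(res$fdr > 0 & res$fdr <= 1))
  expect_true(top$fdr == min(res$fdr))
  expect_error(
    complex_enrichment(list(data.frame(chrom = "chr1", start = 0, end = 2e7)),
                       lay, grid, n_perm = 5, seed = 1), "longer")
})

test_that("uniformly placed footprints give beta near 1", {
  set.seed(31)
  lay <- tiny_layout(2, 1e7)
  grid <- build_bins(lay, 1e6)
  fps <- lapply(1:30, function(i) {
    st <- floor(runif(3, 0, 1e7 - 2e5))
    data.frame(chrom = sample(c("chr1", "chr2"), 3, replace = TRUE),
               start = st, end = st + 2e5)
  })
  res <- complex_enrichment(fps, lay, grid, n_perm = 400, seed = 13)
  # mean enrichment across bins concentrates at 1 under the null
  expect_lt(abs(mean(res$beta) - 1), 3 * sd(res$beta) / sqrt(nrow(res)))
})

test_that("empirical FDR values follow the exceedance formula", {
  obs <- c(1, 2, 3, 4)
  nulls <- list(c(1.5), numeric(), c(2.5), c(1.2, 3.5))
  fdr <- empirical_fdr_values(obs, nulls)
  # at v = 1: mean null exceedances (1+0+1+2)/4 = 1; obs exceedances 4
  expect_equal(fdr[1], 0.25)
  # at v = 4: no null reaches it -> zero replaced by smallest non-zero
  expect_equal(fdr[4], min(fdr[fdr > 0]))
  # cap at 1
  fdr2 <- empirical_fdr_values(c(1), list(c(2, 3), c(4)))
  expect_equal(fdr2, 1)
})
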