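test_that("IMD series is log10 of successive gaps with a 1 bp floor", {
  expect_equal(imd_series(c(100, 1100)), 3.0)
  expect_equal(imd_series(c(500, 500)), 0.0)
  expect_equal(imd_series(c(42)), numeric())
  expect_equal(imd_series(c(10, 1010, 11010)), c(3, 4))
})

test_that("PCF handles constant and stepped series", {
  cst <- pcf(rep(2.5, 30), gamma = 5, kmin = 2)
  expect_equal(nrow(cst), 1)
  stp <- pcf(c(0, 0, 0, 5, 5, 5), gamma = 1, kmin = 2)
  expect_equal(nrow(stp), 2)
  expect_equal(stp$end[1], 3)
  expect_equal(stp$mean, c(0, 5))
  expect_warning(one <- pcf(c(1, 2), gamma = 1, kmin = 3), "single segment")
  expect_equal(nrow(one), 1)
})

test_that("PCF DP equals exhaustive enumeration on random series", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:16, 1)
    x <- round(rnorm(n, sd = 2), 2) + rep(c(0, 4), each = ceiling(n / 2))[1:n]
    for (gamma in c(1, 10)) {
      for (kmin in c(2, 3)) {
        got <- pcf(x, gamma, kmin)
        want <- pcf_oracle(x, gamma, kmin)
        expect_equal(attr(got, "cost"), want$cost, tolerance = 1e-9)
        expect_equal(got$end, want$ends)
      }
    }
  }
})

test_that("segment statistics follow the density formulas", {
  lay <- genome_layout("chr1", 1e7)
  grid <- build_bins(lay, 1e6)
  grid$b <- 3  # every bin expects 3 breakends
  # 12 breakends spanning 100 kb: a = 12, s = 1e5
  pos <- seq(2e6, 2e6 + 99999, length.out = 12)
  segs <- data.frame(start = 1, end = 11)  # single PCF segment over all IMDs
  st <- segment_stats(segs, pos, "chr1", grid)
  expect_equal(st$a, 12)
  expect_equal(st$s, 1e5)
  expect_equal(st$d_obs, 12 / 1e5)
  expect_equal(st$d_exp, 3 / 1e6)  # one overlapping bin, b = 3
  expect_equal(st$beta, (12 / 1e5) / (3 / 1e6))
})

test_that("empirical FDR on segments: formula, cap and zero replacement", {
  obs <- data.frame(beta = c(10, 5, 2, 1))
  sims <- list(data.frame(beta = c(1.5)), data.frame(beta = numeric()),
               data.frame(beta = c(2.5)), data.frame(beta = c(1.2, 6)))
  out <- empirical_fdr(obs, sims)
  expect_equal(out$fdr[4], 0.25)   # (1+0+1+2)/4 / 4
  expect_equal(out$fdr[1], min(out$fdr[out$fdr > 0]))  # zero replaced
  expect_true(all(out$fdr <= 1))
  expect_equal(nrow(empirical_fdr(obs[0, , drop = FALSE], sims)), 0)
})

test_that("raising a segment's beta never raises its FDR", {
  sims <- lapply(1:20, function(r) data.frame(beta = rexp(50) * 2))
  set.seed(12)
  base <- data.frame(beta = c(rexp(19) * 2, 3))
  f1 <- empirical_fdr(base, sims)$fdr[20]
  base$beta[20] <- 8
  f2 <- empirical_fdr(base, sims)$fdr[20]
  expect_lte(f2, f1)
})

test_that("hotspot_segments pools per-chromosome PCF segments", {
  set.seed(33)
  lay <- tiny_layout(2, 2e7)
  grid <- build_bins(lay, 1e6)
  grid$b <- 1
  svs <- sv_row(rep(c("chr1", "chr2"), each = 30),
                floor(runif(60, 0, 1.9e7)), "+", "chr1", 0, "-")
  svs$chrom2 <- svs$chrom1
  svs$pos2 <- svs$pos1 + 5e4
  segs <- hotspot_segments(svs, grid, gamma = 10, kmin = 5)
  expect_true(all(c("chr1", "chr2") %in% segs$chrom))
  expect_true(all(segs$a >= 6))  # kmin + 1 breakends
  expect_true(all(segs$beta >= 0))
})

test_that("parameter selection maximizes hotspots with documented tie-break", {
  set.seed(44)
  s_lay <- tiny_layout(2, 2e7)
  grid <- build_bins(s_lay, 1e6)
  grid$b <- 1
  svs <- sv_row("chr1", floor(runif(40, 0, 1.9e7)), "+", "chr1", 0, "-")
  svs$chrom2 <- svs$chrom1; svs$pos2 <- svs$pos1 + 1e4
  reps <- run_replicates(svs, grid, s_lay, n_reps = 5, seed = 2)
  one <- select_parameters(svs, reps, grid, gamma_grid = 10, kmin_grid = 5)
  expect_equal(one$gamma, 10)
  expect_equal(one$kmin, 5)
  # null data: no hotspots anywhere, tie-break -> lowest gamma, lowest kmin
  nul <- select_parameters(svs, reps, grid, gamma_grid = c(5, 10),
                           kmin_grid = c(4, 8), fdr_threshold = 1e-6)
  expect_equal(nul$n_hotspots, 0)
  expect_equal(nul$gamma, 5)
  expect_equal(nul$kmin, 4)
})

test_that("filter_and_collapse merges overlaps and applies support rules", {
  segs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(1e6, 1.5e6, 3e6), end = c(2e6, 2.5e6, 4e6),
                     beta = c(10, 12, 7), fdr = c(0.01, 0.02, 0.2))
  svs <- rbind(sv_row("chr1", 1.2e6, "+", "chr1", 1.9e6, "-", sample = "T1"),
               sv_row("chr1", 2.2e6, "+", "chr1", 2.4e6, "-", sample = "T2"))
  hs <- filter_and_collapse(segs, svs, fdr_threshold = 0.05)
  expect_equal(nrow(hs), 1)  # chr2 fails FDR; chr1 pair merged
  expect_equal(hs$start, 1e6)
  expect_equal(hs$end, 2.5e6)
  expect_equal(hs$beta, 12)
  expect_equal(hs$fdr, 0.01)
  expect_equal(hs$n_samples, 2L)
  # CNA support: T1 has a boundary 1 kb from a breakend, T2 has none
  bnd <- data.frame(sample = "T1", chrom = "chr1", pos = 1.9e6 + 1000)
  hs2 <- filter_and_collapse(segs, svs, cn_boundaries = bnd,
                             fdr_threshold = 0.05)
  expect_equal(nrow(hs2), 1)
  bnd_none <- data.frame(sample = "T9", chrom = "chr9", pos = 1)
  hs3 <- filter_and_collapse(segs, svs, cn_boundaries = bnd_none,
                             fdr_threshold = 0.05)
  expect_equal(nrow(hs3), 0)
})

test_that("candidate genes respect the focal SV size cutoff", {
  segs <- data.frame(chrom = "chr1", start = 1e6, end = 3e6,
                     beta = 10, fdr = 0.001)
  svs <- rbind(
    sv_row("chr1", 1.2e6, "+", "chr1", 5.5e6, "-", sample = "T1"),  # 4.3 Mb
    sv_row("chr1", 1.3e6, "+", "chr1", 3.3e6, "-", sample = "T2"))  # 2.0 Mb
  genes <- data.frame(gene = "APC", chrom = "chr1", start = 1.4e6, end = 1.6e6)
  hs <- filter_and_collapse(segs, svs, genes = genes, drivers = "APC")
  expect_equal(hs$candidate_genes, "APC(1)")  # only the 2 Mb deletion counts
})

test_that("fragile-site rules need three criteria and no driver", {
  ann <- list(mean_repli = -1, genes_per_mb = 8, largest_gene_bp = 4e5,
              density_ratio = 6, known1 = FALSE, known2 = FALSE)
  r <- classify_fragile(ann)
  expect_true(r$fragile)  # criteria 1, 3, 4
  expect_equal(sum(r$criteria), 3)
  ann2 <- ann; ann2$density_ratio <- 1
  expect_false(classify_fragile(ann2)$fragile)  # only 2 criteria
  expect_false(classify_fragile(ann, contains_driver = TRUE)$fragile)
  # missing annotation counts as unmet
  ann3 <- ann; ann3$mean_repli <- NA
  expect_false(classify_fragile(ann3)$fragile)
})

test_that("fragile annotation computes densities from tracks", {
  hs <- data.frame(chrom = "chr1", start = 2e6, end = 4e6)
  genes <- data.frame(gene = c("BIG", "SMALL"), chrom = "chr1",
                      start = c(2.2e6, 3.8e6), end = c(2.9e6, 3.85e6))
  be <- data.frame(chrom = "chr1",
                   pos = c(seq(2.3e6, 2.8e6, by = 5e4), 1.5e6, 5e6))
  repli <- data.frame(chrom = "chr1", start = 0, end = 1e7, value = -2)
  known <- data.frame(chrom = "chr1", start = 3.9e6, end = 4.5e6)
  ann <- fragile_annotation(hs, be, repli = repli, genes = genes,
                            known1 = known)
  expect_equal(ann$mean_repli, -2)
  expect_equal(ann$genes_per_mb, 1)  # 2 genes / 2 Mb
  expect_equal(ann$largest_gene_bp, 7e5)
  expect_true(ann$known1)
  expect_false(ann$known2)
  expect_gt(ann$density_ratio, 5)  # 11 breakends in BIG, 2 in the flanks
})
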