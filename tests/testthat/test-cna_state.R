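test_that("psi_ave and LOH fraction follow the length-weighted formulas", {
  whole <- seg_df(list("chr1", 0, 100e6, 1, 1))
  r <- compute_psi_ave(whole)
  expect_equal(r$psi_ave, 2.0)
  expect_equal(r$h_frac, 0)

  mix <- seg_df(list("chr1", 0, 75e6, 2, 1), list("chr1", 75e6, 100e6, 1, 0))
  r <- compute_psi_ave(mix)
  expect_equal(r$psi_ave, 2.5)
  expect_equal(r$h_frac, 0.25)

  expect_error(compute_psi_ave(mix[0, ]), "empty")
})

test_that("subclonal segments expose the largest-fraction state", {
  s <- seg_df(list("chr1", 0, 10e6, 1, 1))
  s$frac <- 0.4
  s$n_maj2 <- 2; s$n_min2 <- 2; s$frac2 <- 0.6
  r <- compute_psi_ave(s)
  expect_equal(r$psi_ave, 4)  # counted as 2+2
})

test_that("WGD calls use the strict 2.9 - 2H inequality", {
  dip <- seg_df(list("chr1", 0, 100e6, 1, 1))
  expect_false(call_wgd(dip)$is_wgd)
  tet <- seg_df(list("chr1", 0, 100e6, 2, 2))
  expect_true(call_wgd(tet)$is_wgd)
  mix <- seg_df(list("chr1", 0, 75e6, 2, 1), list("chr1", 75e6, 100e6, 1, 0))
  expect_true(call_wgd(mix)$is_wgd)  # threshold 2.4 < 2.5
  # boundary: psi_ave exactly 2.9 - 2H -> non-WGD
  # 45% at (2,0), 55% at (1,1): psi = 2.0, H = 0.45, threshold = 2.0
  bnd <- seg_df(list("chr1", 0, 45e6, 2, 0), list("chr1", 45e6, 100e6, 1, 1))
  w <- call_wgd(bnd)
  expect_equal(w$psi_ave, 2.9 - 2 * w$h_frac)
  expect_false(w$is_wgd)
})

test_that("six-category classification matches the stated rules", {
  expect_equal(classify_segment(1, 0, FALSE), "LOH")
  expect_equal(classify_segment(2, 2, TRUE), "NOC")
  expect_equal(classify_segment(6, 1, FALSE), "AMP")
  expect_equal(classify_segment(0, 0, TRUE), "HD")
  expect_equal(classify_segment(2, 1, TRUE), "OLOSS")
  expect_equal(classify_segment(6, 0, TRUE), "Gain")  # t > 4, not LOH
  # non-WGD never yields OLOSS
  for (maj in 0:8) for (mn in 0:maj) {
    expect_false(classify_segment(maj, mn, FALSE) == "OLOSS")
  }
})

test_that("SegCN formulas and clipping", {
  expect_equal(seg_cn(3, 2, FALSE), 2)        # 3 clipped to 2
  expect_equal(seg_cn(2, 1, TRUE), -0.5)
  expect_equal(seg_cn(1, 1, FALSE), 0)
  expect_equal(seg_cn(1, 0, FALSE, male_x = TRUE), 0)
  expect_equal(seg_cn(2, 0, TRUE, male_x = TRUE), 0)
  expect_equal(seg_cn(0, 0, TRUE), -2)
  # bounds + monotone non-decreasing in t before clipping
  for (wgd in c(TRUE, FALSE)) {
    v <- seg_cn(0:20, 0, wgd)
    expect_true(all(v >= -2 & v <= 2))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("purity/ploidy update formulas", {
  r <- update_purity_ploidy(0.8, 2, 1)
  expect_equal(r$rho_new, 0.8)
  expect_equal(r$psi_new, 2)
  r <- update_purity_ploidy(0.8, 2, 0.9)
  expect_equal(r$rho_new, 0.72)
  expect_equal(r$psi_new, 2.0)
  r <- update_purity_ploidy(0.5, 4, 0.8)
  expect_equal(r$rho_new, 0.4)
  expect_equal(r$psi_new, 4.5)
  expect_error(update_purity_ploidy(0.5, 4, 0), "ccf_top")
})

test_that("CNA pass/fail decision logic", {
  cl <- data.frame(ccf = c(1.0, 0.4), n_snvs = c(600, 400))
  expect_true(evaluate_cna_pass(cl, 0.70, 0.68)$pass)
  r <- evaluate_cna_pass(data.frame(ccf = c(0.8, 0.5),
                                    n_snvs = c(500, 500)), 0.7, 0.7)
  expect_false(r$pass)
  expect_true("no clonal cluster" %in% r$reasons)
  r <- evaluate_cna_pass(cl, 0.70, 0.77)
  expect_false(r$pass)
  expect_true("purity discordance" %in% r$reasons)
  # tiny clusters (<1% of SNVs) are removed before assessment: here the only
  # in-window cluster has 0.5% of SNVs, so it cannot rescue the sample
  cl2 <- data.frame(ccf = c(1.0, 0.6), n_snvs = c(5, 995))
  expect_false(evaluate_cna_pass(cl2, 0.7, 0.7)$pass)
  # a clonal cluster that has max n_snvs but not max ccf still passes
  cl3 <- data.frame(ccf = c(1.0, 1.08), n_snvs = c(900, 100))
  expect_true(evaluate_cna_pass(cl3, 0.7, 0.7)$pass)
})

test_that("arm-level events sum per-category coverage against 50%", {
  lay <- tiny_layout(1, 1e7)  # chr1, arms 0-5e6, 5e6-1e7
  gain60 <- seg_df(list("chr1", 0, 3e6, 2, 1), list("chr1", 3e6, 1e7, 1, 1))
  ev <- arm_level_events(gain60, lay, FALSE)
  expect_true(ev$called[ev$arm == "chr1p" & ev$category == "Gain"])
  gain40 <- seg_df(list("chr1", 0, 2e6, 2, 1), list("chr1", 2e6, 1e7, 1, 1))
  ev <- arm_level_events(gain40, lay, FALSE)
  expect_false(any(ev$called[ev$category == "Gain"]))
  # two disjoint LOH segments of 30% + 25% sum to 55% -> called
  loh2 <- seg_df(list("chr1", 0, 1.5e6, 1, 0), list("chr1", 2e6, 3.25e6, 1, 0),
                 list("chr1", 3.25e6, 1e7, 1, 1))
  ev <- arm_level_events(loh2, lay, FALSE)
  got <- ev[ev$arm == "chr1p" & ev$category == "LOH", ]
  expect_equal(got$frac, (1.5e6 + 1.25e6) / 5e6)
  expect_true(got$called)
})

test_that("fraction_loh is length weighted and excludes HD", {
  expect_equal(fraction_loh(seg_df(list("chr1", 0, 1e6, 1, 1))), 0)
  expect_equal(fraction_loh(seg_df(list("chr1", 0, 1e6, 1, 0))), 1)
  expect_equal(fraction_loh(seg_df(list("chr1", 0, 1e6, 1, 0),
                                   list("chr1", 1e6, 2e6, 1, 1))), 0.5)
  expect_equal(fraction_loh(seg_df(list("chr1", 0, 1e6, 0, 0),
                                   list("chr1", 1e6, 2e6, 1, 1))), 0)
})

test_that("segment TSV reading converts coordinates and GISTIC output is sane", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tchr\tstartpos\tendpos\tnMaj1_A\tnMin1_A\tfrac1_A\tnMaj2_A\tnMin2_A\tfrac2_A",
               "T1\tchr1\t1\t1000000\t2\t1\t0.3\t1\t1\t0.7",
               "T1\tchr1\t1000001\t2000000\t3\t2\t1\tNA\tNA\tNA"), tf)
  s <- read_segments(tf)
  expect_equal(s$start, c(0, 1e6))
  expect_equal(s$end, c(1e6, 2e6))
  st <- clonal_state(s)
  expect_equal(st$n_maj[1], 1)  # subclonal 1+1 has the larger fraction
  out <- tempfile(fileext = ".tsv")
  g <- write_gistic_input(s, is_wgd = FALSE, path = out)
  expect_true(all(g$seg_cn >= -2 & g$seg_cn <= 2))
  expect_equal(g$seg_cn, c(0, 2))  # (1,1) -> 0; (3,2) -> 3, clipped to 2
  expect_equal(g$start, c(1, 1000001))
})
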