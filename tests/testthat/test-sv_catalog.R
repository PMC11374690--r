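make_call <- function(pos1, pos2, strand1 = "+", strand2 = "-",
                      chrom1 = "chr1", chrom2 = "chr1", support = 0.3,
                      normal = 0) {
  sv_row(chrom1, pos1, strand1, chrom2, pos2, strand2,
         tumour_support_frac = support, normal_support = normal)
}

test_that("consensus merge applies the two-caller and CN-rescue rules", {
  a <- make_call(1e6, 1.2e6)
  b <- make_call(1e6 + 150, 1.2e6 + 150)
  lone_near <- make_call(5e6, 5.4e6)           # 2 kb from a CN boundary
  lone_far <- make_call(8e6, 8.2e6)            # nearest boundary 10 kb+
  bnd <- data.frame(sample = "s1", chrom = "chr1", pos = c(5e6 + 2000, 8.21e6))
  res <- merge_consensus(list(delly = rbind(a, lone_near, lone_far),
                              manta = b),
                         cn_boundaries = bnd)
  expect_equal(nrow(res), 2)
  expect_true(any(res$n_callers == 2))          # merged pair kept
  expect_true(any(res$pos1 == 5e6))             # rescued single-caller call
  expect_false(any(res$pos1 == 8e6))            # unsupported call dropped
})

test_that("consensus merge pre-filters support and mask", {
  germ <- make_call(1e6, 1.2e6, normal = 3)
  weak <- make_call(2e6, 2.2e6, support = 0.01)
  masked <- make_call(100, 1.2e6)
  lay <- tiny_layout(2, 1e7, mask = data.frame(chrom = "chr1", start = 0,
                                               end = 1000))
  res <- merge_consensus(list(delly = rbind(germ, weak, masked),
                              manta = rbind(germ, weak, masked)),
                         layout = lay)
  expect_equal(nrow(res), 0)
  expect_error(merge_consensus(list(rbind(germ))), "named")
})

test_that("consensus merge is independent of callset order", {
  set.seed(4)
  calls <- lapply(1:8, function(i)
    make_call(1e6 * i, 1e6 * i + 2e5 + sample(0:300, 1)))
  c1 <- do.call(rbind, calls[1:5])
  c2 <- do.call(rbind, lapply(calls[3:8], function(x) {
    x$pos1 <- x$pos1 + 100; x$pos2 <- x$pos2 - 100; x
  }))
  r1 <- merge_consensus(list(delly = c1, manta = c2))
  r2 <- merge_consensus(list(manta = c2, delly = c1))
  expect_equal(r1, r2)
})

test_that("cluster grouping partitions SVs by breakend proximity", {
  far <- rbind(make_call(1e6, 1.1e6), make_call(11e6, 11.1e6))
  g <- group_clusters(far, d_cl = 1e6)
  expect_equal(length(unique(g$cluster_id)), 2)

  near3 <- rbind(make_call(1e6, 1.3e6), make_call(1.1e6, 1.4e6),
                 make_call(1.2e6, 1.5e6))
  g <- group_clusters(near3, d_cl = 1e6)
  expect_equal(length(unique(g$cluster_id)), 1)
  expect_equal(sum(table(g$cluster_id)), nrow(near3))  # partition

  lone <- group_clusters(make_call(1e6, 1.1e6))
  expect_equal(nrow(lone), 1)
  expect_equal(classify_simple(lone), "deletion")
})

test_that("simple classification by orientation and reciprocity", {
  expect_equal(classify_simple(sv_row("chr5", 1e6, "+", "chr5", 1.2e6, "-")),
               "deletion")
  expect_equal(classify_simple(sv_row("chr5", 1e6, "-", "chr5", 1.2e6, "+")),
               "tandem_duplication")
  expect_equal(classify_simple(sv_row("chr5", 1e6, "+", "chr5", 1.2e6, "+")),
               "simple_unclassified")  # lone inversion junction
  bal_inv <- rbind(sv_row("chr5", 1e6, "+", "chr5", 2e6, "+"),
                   sv_row("chr5", 1.001e6, "-", "chr5", 2.001e6, "-"))
  expect_equal(classify_simple(bal_inv), "balanced_inversion")
  recip <- rbind(sv_row("chr1", 1e6, "+", "chr3", 5e6, "-"),
                 sv_row("chr1", 1.002e6, "-", "chr3", 5.002e6, "+"))
  expect_equal(classify_simple(recip), "balanced_translocation")
  # same pair but breakends far apart on chr1: unbalanced
  nonrec <- rbind(sv_row("chr1", 1e6, "+", "chr3", 5e6, "-"),
                  sv_row("chr1", 3e6, "-", "chr3", 5.002e6, "+"))
  expect_equal(classify_simple(nonrec), "unbalanced_translocation")
  # lone interchromosomal junction: CN step decides
  lone <- sv_row("chr1", 1e6, "+", "chr3", 5e6, "-")
  expect_equal(classify_simple(lone), "simple_unclassified")
  bnd <- data.frame(chrom = "chr1", pos = 1e6 + 1500)
  expect_equal(classify_simple(lone, cn_boundaries = bnd),
               "unbalanced_translocation")
  expect_error(classify_simple(rbind(lone, lone, lone)), "complex")
})

test_that("classification is invariant to breakend record order", {
  fwd <- sv_row("chr5", 1e6, "+", "chr5", 1.2e6, "-")
  rev <- sv_row("chr5", 1.2e6, "-", "chr5", 1e6, "+")
  expect_equal(classify_simple(fwd), classify_simple(rev))
  expect_equal(orientation_counts(fwd), orientation_counts(rev))
})

test_that("orientation counts tabulate intrachromosomal junctions only", {
  dels <- do.call(rbind, lapply(1:4, function(i)
    sv_row("chr1", i * 1e6, "+", "chr1", i * 1e6 + 5e4, "-")))
  expect_equal(unname(orientation_counts(dels)), c(4, 0, 0, 0))
  tr <- sv_row("chr1", 1e6, "+", "chr2", 1e6, "-")
  expect_equal(unname(orientation_counts(tr)), c(0, 0, 0, 0))
  mixed <- rbind(sv_row("chr1", 1e6, "+", "chr1", 2e6, "-"),
                 sv_row("chr1", 3e6, "-", "chr1", 4e6, "+"),
                 sv_row("chr1", 5e6, "+", "chr1", 6e6, "+"),
                 sv_row("chr1", 7e6, "-", "chr1", 8e6, "-"))
  expect_equal(unname(orientation_counts(mixed)), c(1, 1, 1, 1))
})

test_that("kinase fusions require a 3' kinase domain and compatible strands", {
  genes <- data.frame(
    gene = c("NTRK1", "PART1", "NEG1"),
    chrom = c("chr1", "chr2", "chr1"),
    start = c(10e6, 5e6, 30e6), end = c(10.1e6, 5.1e6, 30.1e6),
    strand = c("+", "+", "-"),
    kd_start = c(10.06e6, NA, NA), kd_end = c(10.09e6, NA, NA),
    is_kinase = c(TRUE, FALSE, FALSE))
  # partner 5' end joined upstream of the + strand kinase domain:
  # kinase breakend retains the high side (-), partner retains low side (+)
  fus <- sv_row("chr2", 5.05e6, "+", "chr1", 10.02e6, "-")
  hit <- detect_kinase_fusions(fus, genes)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$kinase_gene, "NTRK1")
  expect_equal(hit$partner_gene, "PART1")
  # junction 3' of (after) the domain: no fusion
  after <- sv_row("chr2", 5.05e6, "+", "chr1", 10.095e6, "-")
  expect_equal(nrow(detect_kinase_fusions(after, genes)), 0)
  # incompatible strand at the kinase end: no fusion
  bad <- sv_row("chr2", 5.05e6, "+", "chr1", 10.02e6, "+")
  expect_equal(nrow(detect_kinase_fusions(bad, genes)), 0)
  # kinase gene without domain annotation: warning, skipped
  genes2 <- genes
  genes2$is_kinase[3] <- TRUE
  expect_warning(detect_kinase_fusions(fus, genes2), "NEG1")
})

test_that("BEDPE round trip preserves breakends and orientations", {
  svs <- rbind(sv_row("chr1", 1e6, "+", "chr1", 1.5e6, "-"),
               sv_row("chr2", 2e6, "-", "chr1", 9e6, "+"))
  svs$id <- c("a", "b")
  svs$class <- c("deletion", "translocation")
  tf <- tempfile(fileext = ".bedpe")
  write_bedpe(svs, tf)
  back <- read_bedpe(tf)
  expect_equal(nrow(back), 2)
  canon <- canonical_svs(svs)
  expect_equal(back$pos1, canon$pos1)
  expect_equal(back$strand1, canon$strand1)
  expect_equal(back$class, canon$class)
})
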