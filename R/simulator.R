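#' Simulate one null SV catalogue
#'
#' For each observed rearrangement, draws a first breakend by sampling a bin
#' with probability proportional to the expected breakend count `b`, placing
#' the breakend uniformly within the bin. Intrachromosomal junctions keep
#' their observed length exactly: the partner breakend is placed at that
#' distance upstream or downstream with equal probability. Interchromosomal
#' partners are drawn proportionally to `b` over bins on other chromosomes.
#' The whole junction is redrawn whenever either breakend falls off the
#' chromosome, in the layout mask or in an uncallable bin. Counts per class
#' and intrachromosomal lengths are conserved by construction.
#'
#' @param observed rearrangement data.frame (orientations and `class` labels
#'   are carried over).
#' @param grid a `bin_grid` with `b` filled (see [expected_breakends()]).
#' @param layout a [genome_layout()].
#' @param seed RNG seed.
#' @param max_rejects maximum redraw rounds before erroring (default 10000).
#' @return simulated rearrangement data.frame with attributes `seed`.
#' @export
simulate_catalog <- function(observed, grid, layout, seed,
                             max_rejects = 10000) {
  observed <- canonical_svs(observed)
  b <- grid$b
  if (is.null(b) || all(is.na(b))) stop("grid has no expected counts; run expected_breakends()")
  b[is.na(b) | !grid$callable] <- 0
  if (sum(b) <= 0) stop("sum of expected counts must be > 0")
  set.seed(seed)
  n <- nrow(observed)
  lens <- layout$chrom_lengths
  intra <- observed$chrom1 == observed$chrom2
  sv_len <- observed$pos2 - observed$pos1
  if (any(intra & sv_len > max(lens)))
    stop("an intrachromosomal SV is longer than every chromosome")
  chrom_of_bin <- grid$chrom
  ok_pos <- function(chrom, pos) {
    inside <- pos >= 0 & pos < lens[chrom]
    res <- inside
    if (any(inside)) {
      idx <- bin_index(grid, chrom[inside], pos[inside])
      call_ok <- !is.na(idx) & grid$callable[idx]
      call_ok[call_ok] <- !in_mask(layout, chrom[inside][call_ok],
                                   pos[inside][call_ok])
      res[inside] <- call_ok
    }
    res
  }
  out_chrom1 <- character(n); out_pos1 <- numeric(n)
  out_chrom2 <- character(n); out_pos2 <- numeric(n)
  pending <- seq_len(n)
  rounds <- 0L
  while (length(pending)) {
    rounds <- rounds + 1L
    if (rounds > max_rejects) stop("too many consecutive rejections in SV simulation")
    k <- length(pending)
    bin1 <- sample.int(nrow(grid), k, replace = TRUE, prob = b)
    p1 <- floor(stats::runif(k, grid$start[bin1], grid$end[bin1]))
    c1 <- chrom_of_bin[bin1]
    is_intra <- intra[pending]
    c2 <- character(k); p2 <- numeric(k)
    if (any(is_intra)) {
      dir <- ifelse(stats::runif(sum(is_intra)) < 0.5, 1, -1)
      p2[is_intra] <- p1[is_intra] + dir * sv_len[pending[is_intra]]
      c2[is_intra] <- c1[is_intra]
    }
    if (any(!is_intra)) {
      # partner bin proportional to b over bins on other chromosomes:
      # rejection-sample from the full distribution until the chromosome
      # differs (exactly the excluded-chromosome distribution)
      need <- which(!is_intra)
      guard <- 0L
      while (length(need)) {
        guard <- guard + 1L
        if (guard > max_rejects) stop("no eligible bins on other chromosomes")
        bin2 <- sample.int(nrow(grid), length(need), replace = TRUE, prob = b)
        ok2 <- chrom_of_bin[bin2] != c1[need]
        sel <- need[ok2]
        c2[sel] <- chrom_of_bin[bin2[ok2]]
        p2[sel] <- floor(stats::runif(length(sel), grid$start[bin2[ok2]],
                                      grid$end[bin2[ok2]]))
        need <- need[!ok2]
      }
    }
    good <- ok_pos(c1, p1) & ok_pos(c2, p2)
    acc <- pending[good]
    out_chrom1[acc] <- c1[good]; out_pos1[acc] <- p1[good]
    out_chrom2[acc] <- c2[good]; out_pos2[acc] <- p2[good]
    pending <- pending[!good]
  }
  sim <- observed
  sim$chrom1 <- out_chrom1; sim$pos1 <- out_pos1
  sim$chrom2 <- out_chrom2; sim$pos2 <- out_pos2
  sim <- canonical_svs(sim)
  attr(sim, "seed") <- seed
  sim
}

#' Generate independent null replicates
#'
#' Replicate `r` uses a sub-seed derived deterministically from `(seed, r)`,
#' so single replicates are reproducible and independent of evaluation order.
#'
#' @inheritParams simulate_catalog
#' @param n_reps number of replicates (analysis default 1000).
#' @return list of simulated catalogues (see [simulate_catalog()]).
#' @export
run_replicates <- function(observed, grid, layout, n_reps = 1000, seed = 1) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(r) {
    simulate_catalog(observed, grid, layout, seed = derive_seed(seed, r))
  })
}

## deterministic 32-bit sub-seed from (seed, r)
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r * 9973) %% 2147483629)
}
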