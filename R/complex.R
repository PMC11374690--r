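#' Copy-number oscillation detection
#'
#' Scans an ordered series of total copy-number values (segments overlapped by
#' a rearrangement cluster) for a contiguous run of at least 4 segments
#' oscillating between at most 2 states, or at least 5 segments oscillating
#' between at most 3 states. Within a run every adjacent pair of values must
#' differ.
#'
#' @param cn_values ordered numeric vector of total copy numbers.
#' @return list `found`, `run_length`, `n_states` (of the longest qualifying
#'   run; 0/NA when none).
#' @export
detect_oscillation <- function(cn_values) {
  n <- length(cn_values)
  if (n < 1L) stop("need at least one copy-number value")
  best <- list(found = FALSE, run_length = 0L, n_states = NA_integer_)
  if (n < 4L) return(best)
  for (i in seq_len(n - 3L)) {
    j <- i
    while (j < n && cn_values[j + 1L] != cn_values[j]) j <- j + 1L
    # [i, j] is a maximal adjacent-differing run starting at i
    len <- j - i + 1L
    if (len < 4L) next
    for (a in i:(j - 3L)) {
      for (b in (a + 3L):j) {
        w <- b - a + 1L
        k <- length(unique(cn_values[a:b]))
        ok <- (w >= 4L && k <= 2L) || (w >= 5L && k <= 3L)
        if (ok && w > best$run_length) {
          best <- list(found = TRUE, run_length = w, n_states = k)
        }
      }
    }
  }
  best
}

#' Interleaved intrachromosomal rearrangement count
#'
#' Counts intrachromosomal rearrangements whose span (a1, a2) crosses the span
#' of at least one other rearrangement on the same chromosome:
#' a1 < b1 < a2 < b2 or b1 < a1 < b2 < a2 (crossing; nested or disjoint pairs
#' do not count).
#'
#' @param cluster rearrangement data.frame.
#' @return integer count.
#' @export
count_interleaved <- function(cluster) {
  cluster <- canonical_svs(cluster)
  intra <- cluster[cluster$chrom1 == cluster$chrom2, , drop = FALSE]
  n <- nrow(intra)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (i in seq_len(n)) {
    a1 <- intra$pos1[i]; a2 <- intra$pos2[i]
    hit <- FALSE
    for (j in seq_len(n)) {
      if (i == j || intra$chrom1[i] != intra$chrom1[j]) next
      b1 <- intra$pos1[j]; b2 <- intra$pos2[j]
      if ((a1 < b1 && b1 < a2 && a2 < b2) || (b1 < a1 && a1 < b2 && b2 < a2)) {
        hit <- TRUE; break
      }
    }
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

#' Exact multinomial goodness-of-fit p value
#'
#' Probability, under equal cell probabilities, of observing an outcome no
#' more probable than the observed one. Exact (full enumeration over
#' compositions) for totals up to `exact_max`; chi-square approximation above.
#'
#' @param counts integer vector of category counts (length 4 for junction
#'   orientations).
#' @param exact_max largest total for which the exact test is used
#'   (default 60).
#' @return p value in (0, 1]; all-zero counts give 1.
#' @export
multinomial_test_p <- function(counts, exact_max = 60) {
  k <- length(counts)
  n <- sum(counts)
  if (n == 0L) return(1)
  if (n > exact_max) {
    return(suppressWarnings(
      stats::chisq.test(counts, p = rep(1 / k, k))$p.value))
  }
  lp_obs <- stats::dmultinom(counts, prob = rep(1 / k, k), log = TRUE)
  outs <- compositions(n, k)
  lp <- lgamma(n + 1) - rowSums(lgamma(outs + 1)) - n * log(k)
  sum(exp(lp[lp <= lp_obs + 1e-9]))
}

## all compositions of n into k non-negative parts, as a matrix
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1L)
    out[[i + 1L]] <- cbind(i, sub)
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

#' Orientation multinomial test with BH FDR across clusters
#'
#' @param counts_matrix matrix (clusters x 4 orientation categories) or a list
#'   of count vectors.
#' @return data.frame with `p` and `fdr` (Benjamini-Hochberg) per cluster.
#' @export
orientation_multinomial_fdr <- function(counts_matrix) {
  if (is.list(counts_matrix) && !is.data.frame(counts_matrix))
    counts_matrix <- do.call(rbind, counts_matrix)
  counts_matrix <- as.matrix(counts_matrix)
  if (nrow(counts_matrix) < 1L) stop("need at least one cluster")
  p <- apply(counts_matrix, 1, multinomial_test_p)
  data.frame(p = p, fdr = stats::p.adjust(p, method = "BH"))
}

#' Chromothripsis call for a complex cluster
#'
#' A cluster (>= 3 rearrangements) is chromothripsis when all three criteria
#' hold: (1) a contiguous oscillating copy-number run (4 segments / 2 states
#' or 5 segments / 3 states) among the segments overlapped by the cluster;
#' (2) at least 6 interleaved intrachromosomal rearrangements; (3) no evidence
#' (FDR > 0.2) that the intrachromosomal junction orientations diverge from an
#' equal-probability multinomial.
#'
#' @param cluster rearrangement data.frame (one cluster).
#' @param cn_segments copy-number segments (`chrom`, `start`, `end`, `total_cn`
#'   or `n_maj`+`n_min`); segments between the cluster's outermost breakends
#'   on each involved chromosome supply the oscillation series.
#' @param orientation_fdr FDR for this cluster from
#'   [orientation_multinomial_fdr()] computed across candidate clusters.
#' @param min_interleaved interleave threshold (default 6).
#' @param fdr_threshold orientation FDR threshold (default 0.2).
#' @return list: `call` ("chromothripsis" or "complex_unclassified") and the
#'   evidence fields.
#' @export
call_chromothripsis <- function(cluster, cn_segments, orientation_fdr,
                                min_interleaved = 6, fdr_threshold = 0.2) {
  if (nrow(cluster) < 3L) stop("chromothripsis calling requires cluster size >= 3")
  cn_segments <- as.data.frame(cn_segments)
  if (is.null(cn_segments$total_cn))
    cn_segments$total_cn <- cn_segments$n_maj + cn_segments$n_min
  osc <- list(found = FALSE, run_length = 0L, n_states = NA_integer_)
  for (ch in unique(c(cluster$chrom1, cluster$chrom2))) {
    pos <- c(cluster$pos1[cluster$chrom1 == ch],
             cluster$pos2[cluster$chrom2 == ch])
    if (!length(pos)) next
    span <- range(pos)
    seg <- cn_segments[cn_segments$chrom == ch &
                         cn_segments$end > span[1] &
                         cn_segments$start < span[2], , drop = FALSE]
    if (nrow(seg) == 0L) next
    seg <- seg[order(seg$start), ]
    o <- detect_oscillation(seg$total_cn)
    if (o$found && o$run_length > osc$run_length) osc <- o
  }
  inter <- count_interleaved(cluster)
  ok <- osc$found && inter >= min_interleaved &&
    orientation_fdr > fdr_threshold
  list(call = if (ok) "chromothripsis" else "complex_unclassified",
       oscillation_found = osc$found, run_length = osc$run_length,
       n_states = osc$n_states, interleaved = inter,
       orientation_fdr = orientation_fdr, n_rearrangements = nrow(cluster))
}

#' Chromoplexy call for a complex cluster
#'
#' Builds a breakpoint graph (nodes are breakends; the two ends of a junction
#' are connected, and breakends of different rearrangements are connected when
#' they lie on the same chromosome within `d_chain`). A cluster is chromoplexy
#' when a connected chain touches at least 3 chromosomes, at least 50% of its
#' footprints look like balanced-translocation footprints (all member
#' breakends from interchromosomal junctions, both orientations present,
#' within the deletion-bridge tolerance), and the cluster holds between 3 and
#' 30 rearrangements.
#'
#' @param cluster rearrangement data.frame (one cluster).
#' @param d_chain chain edge distance in bp (default 1 Mb).
#' @param d_fp footprint gap (default 10 kb; also the deletion-bridge
#'   tolerance).
#' @param max_size maximum rearrangement count (default 30).
#' @return list: `call` ("chromoplexy" or "complex_unclassified") and evidence.
#' @export
call_chromoplexy <- function(cluster, d_chain = 1e6, d_fp = 1e4,
                             max_size = 30) {
  n <- nrow(cluster)
  if (n < 3L) stop("chromoplexy calling requires cluster size >= 3")
  cluster <- canonical_svs(cluster)
  be <- data.frame(chrom = c(cluster$chrom1, cluster$chrom2),
                   pos = c(cluster$pos1, cluster$pos2),
                   sv = rep(seq_len(n), 2))
  m <- nrow(be)
  edges <- cbind(seq_len(n), n + seq_len(n))  # junction edges bnd1--bnd2
  for (ch in unique(be$chrom)) {
    idx <- which(be$chrom == ch)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq(a + 1, length(idx))) {
        i <- idx[a]; j <- idx[b]
        if (be$sv[i] != be$sv[j] && abs(be$pos[i] - be$pos[j]) <= d_chain)
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  chain_chroms <- max(tapply(be$chrom, memb,
                             function(x) length(unique(x))))
  fp <- cluster_footprints(cluster, d_fp = d_fp)
  balanced <- fp$all_inter & fp$n_breakends >= 2 & fp$n_strands == 2
  frac_bal <- mean(balanced)
  ok <- chain_chroms >= 3 && frac_bal >= 0.5 && n >= 3 && n <= max_size
  list(call = if (ok) "chromoplexy" else "complex_unclassified",
       chain_chromosomes = chain_chroms, balanced_footprint_frac = frac_bal,
       n_rearrangements = n)
}

#' Classify all complex clusters of a sample set
#'
#' Orientation multinomial FDRs are computed jointly across the candidate
#' clusters (as the FDR is a cross-cluster quantity), then each cluster is
#' tested for chromothripsis and chromoplexy; chromothripsis takes precedence
#' when both pass.
#'
#' @param svs rearrangement data.frame with `cluster_id` (see
#'   [group_clusters()]).
#' @param cn_segments per-sample copy-number segments (with `sample` column
#'   when `svs` has one).
#' @return data.frame, one row per complex cluster, with call and evidence.
#' @export
classify_complex_clusters <- function(svs, cn_segments) {
  ids <- unique(svs$cluster_id)
  sizes <- table(svs$cluster_id)
  complex_ids <- as.integer(names(sizes)[sizes >= 3])
  if (!length(complex_ids)) {
    return(data.frame(cluster_id = integer(), call = character()))
  }
  counts <- t(vapply(complex_ids, function(cid)
    orientation_counts(svs[svs$cluster_id == cid, ]), numeric(4)))
  fdrs <- orientation_multinomial_fdr(counts)$fdr
  out <- lapply(seq_along(complex_ids), function(k) {
    cid <- complex_ids[k]
    cl <- svs[svs$cluster_id == cid, ]
    seg <- cn_segments
    if (!is.null(seg$sample) && !is.null(cl$sample))
      seg <- seg[seg$sample == cl$sample[1], ]
    ct <- call_chromothripsis(cl, seg, fdrs[k])
    cp <- call_chromoplexy(cl)
    call <- if (ct$call == "chromothripsis") "chromothripsis"
      else if (cp$call == "chromoplexy") "chromoplexy"
      else "complex_unclassified"
    data.frame(cluster_id = cid, call = call,
               oscillation_found = ct$oscillation_found,
               run_length = ct$run_length, n_states = ct$n_states,
               interleaved = ct$interleaved,
               orientation_fdr = fdrs[k],
               chain_chromosomes = cp$chain_chromosomes,
               balanced_footprint_frac = cp$balanced_footprint_frac,
               n_rearrangements = nrow(cl), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Complex-SV enrichment by footprint permutation
#'
#' Counts, per genome bin, the tumours with at least one overlapping complex
#' footprint (g_obs), estimates the expectation g_exp as the mean of the same
#' count over permutations that re-place every footprint uniformly on the
#' genome (equal length, redrawn when crossing a chromosome end), and reports
#' the enrichment factor beta = g_obs / g_exp with an empirical FDR: for each
#' observed beta, the mean number of permuted bins with beta at least as large
#' divided by the number of observed bins with beta at least as large, capped
#' at 1, zeros replaced by the smallest non-zero FDR.
#'
#' @param footprints_by_tumour list (one element per tumour) of data.frames
#'   `chrom`, `start`, `end`.
#' @param layout a [genome_layout()].
#' @param grid a `bin_grid` from [build_bins()].
#' @param n_perm number of permutations (analysis default 1e5; use fewer for
#'   testing).
#' @param seed RNG seed.
#' @return data.frame per bin with `g_obs`, `g_exp`, `beta`, `fdr` (bins with
#'   `g_exp` 0 are dropped).
#' @export
complex_enrichment <- function(footprints_by_tumour, layout, grid,
                               n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  nb <- nrow(grid)
  lens <- layout$chrom_lengths
  count_tumours <- function(fps_list) {
    g <- integer(nb)
    for (fp in fps_list) {
      hit <- unique(unlist(lapply(seq_len(nrow(fp)), function(i)
        bins_overlapping(grid, fp$chrom[i], fp$start[i], fp$end[i]))))
      g[hit] <- g[hit] + 1L
    }
    g
  }
  for (fp in footprints_by_tumour) {
    if (any(fp$end - fp$start > max(lens)))
      stop("footprint longer than the longest chromosome")
  }
  g_obs <- count_tumours(footprints_by_tumour)
  set.seed(seed)
  chr_prob <- lens / sum(lens)
  place_uniform <- function(len) {
    repeat {
      ch <- sample(names(lens), 1, prob = chr_prob)
      if (len > lens[[ch]]) next
      st <- floor(stats::runif(1, 0, lens[[ch]]))
      if (st + len <= lens[[ch]])
        return(list(chrom = ch, start = st, end = st + len))
    }
  }
  g_exp_sum <- numeric(nb)
  perm_g <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    permuted <- lapply(footprints_by_tumour, function(fp) {
      plc <- lapply(fp$end - fp$start, place_uniform)
      data.frame(chrom = vapply(plc, `[[`, "", "chrom"),
                 start = vapply(plc, `[[`, 0, "start"),
                 end = vapply(plc, `[[`, 0, "end"))
    })
    g <- count_tumours(permuted)
    g_exp_sum <- g_exp_sum + g
    perm_g[[r]] <- g
  }
  g_exp <- g_exp_sum / n_perm
  keep <- g_exp > 0
  beta_obs <- g_obs[keep] / g_exp[keep]
  # empirical FDR over the observed beta values
  perm_beta <- lapply(perm_g, function(g) g[keep] / g_exp[keep])
  fdr <- empirical_fdr_values(beta_obs, perm_beta)
  out <- data.frame(chrom = grid$chrom[keep], start = grid$start[keep],
                    end = grid$end[keep], g_obs = g_obs[keep],
                    g_exp = g_exp[keep], beta = beta_obs, fdr = fdr)
  rownames(out) <- NULL
  out
}

#' Empirical FDR from observed and per-replicate null statistics
#'
#' `FDR(v) = mean_r #\{null_r >= v\} / #\{obs >= v\}`, capped at 1. Zero FDRs
#' are replaced by the lowest non-zero FDR value observed, where the FDR
#' curve is evaluated at every candidate statistic value (observed and
#' simulated); with no simulated values at all the floor is `1 / (R + 1)`.
#' Evaluating the curve on the pooled value set makes the replacement scale
#' with the number of replicates instead of collapsing to a coarse
#' observed-segment FDR when observed statistics are few.
#'
#' @param obs numeric vector of observed statistics.
#' @param null_list list of numeric vectors, one per replicate/permutation.
#' @return numeric vector of FDRs aligned with `obs`.
#' @export
empirical_fdr_values <- function(obs, null_list) {
  if (!length(obs)) return(numeric())
  R <- length(null_list)
  all_null <- sort(unlist(null_list))
  obs_sorted <- sort(obs)
  fdr_at <- function(v) {
    n_null_ge <- length(all_null) -
      findInterval(v, all_null, left.open = TRUE)
    n_obs_ge <- length(obs_sorted) -
      findInterval(v, obs_sorted, left.open = TRUE)
    pmin(1, (n_null_ge / R) / n_obs_ge)  # n_obs_ge >= 1 for v in obs range
  }
  fdr <- fdr_at(obs)
  if (any(fdr == 0)) {
    # lowest non-zero FDR over the full evaluation grid: all candidate values
    # with at least one observed exceedance
    grid_v <- c(obs_sorted, all_null[all_null <= max(obs_sorted)])
    curve <- fdr_at(grid_v)
    nz <- curve[curve > 0]
    fdr[fdr == 0] <- if (length(nz)) min(nz) else 1 / (R + 1)
  }
  fdr
}
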