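#' Inter-mutational distance series
#'
#' Log10 distances between consecutive sorted breakend positions on one
#' chromosome; coincident breakends are floored at 1 bp (log10 = 0).
#'
#' @param positions numeric vector of breakend positions (one chromosome).
#' @return numeric vector of length `length(positions) - 1` (empty for fewer
#'   than 2 positions).
#' @export
imd_series <- function(positions) {
  positions <- sort(positions)
  if (length(positions) < 2L) return(numeric())
  log10(pmax(diff(positions), 1))
}

#' Piecewise constant fitting (exact DP)
#'
#' Exact minimizer of the penalized least-squares segmentation cost
#' (within-segment sum of squared deviations plus `gamma` per segment) with a
#' hard minimum of `kmin` points per segment, via dynamic programming.
#' Ties are broken toward fewer segments, then earliest boundaries.
#'
#' @param values numeric series.
#' @param gamma segmentation penalty (> 0).
#' @param kmin minimum points per segment (>= 2).
#' @return data.frame `start`, `end` (1-based point indices), `mean`; the
#'   total cost is in `attr(, "cost")`.
#' @export
pcf <- function(values, gamma, kmin) {
  stopifnot(gamma > 0, kmin >= 2)
  n <- length(values)
  if (n < kmin) {
    warning("series shorter than kmin; returning a single segment")
    out <- data.frame(start = 1L, end = n, mean = mean(values))
    attr(out, "cost") <- sum((values - mean(values))^2) + gamma
    return(out)
  }
  res <- .pcf_dp(as.numeric(values), gamma, as.integer(kmin))
  out <- data.frame(start = res$start, end = res$end, mean = res$mean)
  attr(out, "cost") <- res$cost
  out
}

#' Per-segment hotspot statistics
#'
#' Maps a PCF segment over IMD indices `[j, k]` to breakends `[j, k + 1]` and
#' computes the observed breakend density `d_obs = a / s` (a = breakend count,
#' s = first-to-last breakend span + 1), the expected density
#' `d_exp = sum(b_j) / (n * s_bin)` over the `n` grid bins overlapping the
#' span, and the enrichment factor `beta = d_obs / d_exp`.
#'
#' @param segments PCF segment data.frame from [pcf()].
#' @param positions sorted breakend positions used to build the IMD series.
#' @param chrom chromosome of the series.
#' @param grid a `bin_grid` with `b` filled.
#' @return data.frame `chrom`, `start`, `end`, `a`, `s`, `d_obs`, `d_exp`,
#'   `beta`.
#' @export
segment_stats <- function(segments, positions, chrom, grid) {
  positions <- sort(positions)
  s_bin <- attr(grid, "s_bin")
  info <- grid_chrom_info(grid)
  if (!(chrom %in% names(info$offset)))
    stop("segment span outside the bin grid")
  off <- info$offset[[chrom]]
  nb <- info$n_bins[[chrom]]
  bsum <- c(0, cumsum(grid$b[off + seq_len(nb)]))
  j <- segments$start
  k <- segments$end
  first <- positions[j]
  last <- positions[k + 1L]
  a <- k - j + 2L
  s <- last - first + 1
  fb <- floor(first / s_bin)
  lb <- floor(last / s_bin)
  if (any(fb < 0 | lb > nb - 1)) stop("segment span outside the bin grid")
  n <- lb - fb + 1
  d_obs <- a / s
  d_exp <- (bsum[lb + 2] - bsum[fb + 1]) / (n * s_bin)
  data.frame(chrom = chrom, start = first, end = last + 1, a = a, s = s,
             d_obs = d_obs, d_exp = d_exp,
             beta = ifelse(d_exp > 0, d_obs / d_exp, Inf),
             stringsAsFactors = FALSE)
}

#' PCF hotspot segments for a whole catalogue
#'
#' Runs [imd_series()], [pcf()] and [segment_stats()] per chromosome over the
#' breakends of a rearrangement table and pools the segments genome-wide.
#' Chromosomes with fewer than 2 breakends are skipped; series shorter than
#' `kmin` yield one segment.
#'
#' @param svs rearrangement data.frame.
#' @param grid a `bin_grid` with `b` filled.
#' @param gamma,kmin PCF parameters.
#' @return data.frame of segment statistics (see [segment_stats()]).
#' @export
hotspot_segments <- function(svs, grid, gamma = 10, kmin = 10) {
  be <- data.frame(chrom = c(svs$chrom1, svs$chrom2),
                   pos = c(svs$pos1, svs$pos2))
  out <- list()
  for (ch in unique(be$chrom)) {
    pos <- sort(be$pos[be$chrom == ch])
    y <- imd_series(pos)
    if (!length(y)) next
    segs <- suppressWarnings(pcf(y, gamma, kmin))
    out[[ch]] <- segment_stats(segs, pos, ch, grid)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      a = integer(), s = numeric(), d_obs = numeric(),
                      d_exp = numeric(), beta = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Empirical FDR for observed PCF segments
#'
#' For each observed segment's beta value v, the FDR is the mean count of
#' simulated segments (per replicate, processed with identical PCF parameters)
#' with beta >= v, divided by the count of observed segments with beta >= v;
#' capped at 1, zeros replaced by the smallest non-zero FDR.
#'
#' @param observed segment data.frame from [hotspot_segments()].
#' @param simulated list of segment data.frames, one per replicate.
#' @return `observed` with an `fdr` column.
#' @export
empirical_fdr <- function(observed, simulated) {
  if (nrow(observed) == 0L) { observed$fdr <- numeric(); return(observed) }
  if (!length(simulated)) stop("need at least one simulated replicate")
  null_list <- lapply(simulated, function(s) s$beta)
  observed$fdr <- empirical_fdr_values(observed$beta, null_list)
  observed
}

#' Select PCF parameters over a grid
#'
#' Evaluates every (gamma, kmin) combination on the observed catalogue and the
#' simulated replicates and returns the pair maximizing the number of segments
#' with FDR below `fdr_threshold`; ties are broken by lower median FDR, then
#' lower gamma, then lower kmin.
#'
#' @param svs observed rearrangement data.frame.
#' @param replicates list of simulated catalogues (see [run_replicates()]).
#' @param grid a `bin_grid` with `b` filled.
#' @param gamma_grid,kmin_grid candidate values (defaults 1..20 and 2..20).
#' @param fdr_threshold hotspot FDR threshold (default 0.05).
#' @return list `gamma`, `kmin`, `n_hotspots`, plus the full search `table`.
#' @export
select_parameters <- function(svs, replicates, grid,
                              gamma_grid = 1:20, kmin_grid = 2:20,
                              fdr_threshold = 0.05) {
  stopifnot(length(gamma_grid) > 0, length(kmin_grid) > 0)
  rows <- list()
  for (g in gamma_grid) {
    for (k in kmin_grid) {
      obs <- hotspot_segments(svs, grid, gamma = g, kmin = k)
      sims <- lapply(replicates, hotspot_segments, grid = grid,
                     gamma = g, kmin = k)
      obs <- empirical_fdr(obs, sims)
      rows[[length(rows) + 1L]] <- data.frame(
        gamma = g, kmin = k,
        n_hotspots = sum(obs$fdr < fdr_threshold),
        median_fdr = if (nrow(obs)) stats::median(obs$fdr) else 1)
    }
  }
  tab <- do.call(rbind, rows)
  o <- order(-tab$n_hotspots, tab$median_fdr, tab$gamma, tab$kmin)
  best <- tab[o[1], ]
  list(gamma = best$gamma, kmin = best$kmin, n_hotspots = best$n_hotspots,
       table = tab)
}

#' Filter, support-check and collapse hotspot segments
#'
#' Keeps segments with FDR below `fdr_threshold`; drops hotspots in which no
#' contributing SV has a breakend within `cn_tol` of a copy-number segment
#' boundary in its own sample (skipped when `cn_boundaries` is NULL); merges
#' overlapping kept segments of the same class (union span, minimum FDR,
#' maximum beta); annotates contributing sample counts, overlapping genes and
#' per-gene focal SV counts restricted to SVs shorter than `focal_max` bp;
#' flags candidate genes that are supplied drivers or the sole expressed gene
#' in the region.
#'
#' @param segments segment data.frame with `fdr` (see [empirical_fdr()]).
#' @param svs contributing rearrangement data.frame (with `sample` column).
#' @param cn_boundaries data.frame `sample`, `chrom`, `pos` or NULL.
#' @param genes optional gene table (`gene`, `chrom`, `start`, `end`,
#'   optional `expressed` logical).
#' @param drivers optional character vector of driver gene names.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param cn_tol CNA-support distance (default 3 kb).
#' @param focal_max focal SV length cutoff (default 3 Mb).
#' @return data.frame of collapsed hotspots.
#' @export
filter_and_collapse <- function(segments, svs, cn_boundaries = NULL,
                                genes = NULL, drivers = character(),
                                fdr_threshold = 0.05, cn_tol = 3000,
                                focal_max = 3e6) {
  keep <- segments[segments$fdr < fdr_threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      beta = numeric(), fdr = numeric(), n_samples = integer(),
                      cna_supported = logical(), candidate_genes = character(),
                      stringsAsFactors = FALSE)
  if (nrow(keep) == 0L) return(empty)
  if (is.null(svs$sample)) svs$sample <- "sample1"
  contributing <- function(chrom, start, end) {
    hit1 <- svs$chrom1 == chrom & svs$pos1 >= start & svs$pos1 < end
    hit2 <- svs$chrom2 == chrom & svs$pos2 >= start & svs$pos2 < end
    svs[hit1 | hit2, , drop = FALSE]
  }
  if (!is.null(cn_boundaries)) {
    supported <- vapply(seq_len(nrow(keep)), function(i) {
      sv <- contributing(keep$chrom[i], keep$start[i], keep$end[i])
      if (nrow(sv) == 0L) return(FALSE)
      any(vapply(seq_len(nrow(sv)), function(r) {
        bnd <- cn_boundaries[cn_boundaries$sample == sv$sample[r], ]
        d1 <- bnd$pos[bnd$chrom == sv$chrom1[r]]
        d2 <- bnd$pos[bnd$chrom == sv$chrom2[r]]
        (length(d1) && min(abs(d1 - sv$pos1[r])) <= cn_tol) ||
          (length(d2) && min(abs(d2 - sv$pos2[r])) <= cn_tol)
      }, logical(1)))
    }, logical(1))
    keep <- keep[supported, , drop = FALSE]
    if (nrow(keep) == 0L) return(empty)
  }
  # collapse overlapping segments per chromosome
  keep <- keep[order(keep$chrom, keep$start), ]
  merged <- list()
  cur <- keep[1, ]
  flush <- function(cur) {
    merged[[length(merged) + 1L]] <<- cur
  }
  for (i in seq_len(nrow(keep))[-1]) {
    if (keep$chrom[i] == cur$chrom && keep$start[i] < cur$end) {
      cur$end <- max(cur$end, keep$end[i])
      cur$fdr <- min(cur$fdr, keep$fdr[i])
      cur$beta <- max(cur$beta, keep$beta[i])
    } else {
      flush(cur); cur <- keep[i, ]
    }
  }
  flush(cur)
  hs <- do.call(rbind, merged)
  hs$n_samples <- vapply(seq_len(nrow(hs)), function(i)
    length(unique(contributing(hs$chrom[i], hs$start[i], hs$end[i])$sample)),
    0L)
  hs$cna_supported <- !is.null(cn_boundaries)
  hs$candidate_genes <- ""
  if (!is.null(genes)) {
    genes <- as.data.frame(genes)
    for (i in seq_len(nrow(hs))) {
      ov <- genes[genes$chrom == hs$chrom[i] & genes$end > hs$start[i] &
                    genes$start < hs$end[i], , drop = FALSE]
      if (nrow(ov) == 0L) next
      sv <- contributing(hs$chrom[i], hs$start[i], hs$end[i])
      focal <- sv[sv$chrom1 == sv$chrom2 &
                    (sv$pos2 - sv$pos1) < focal_max, , drop = FALSE]
      ov$focal_n <- vapply(seq_len(nrow(ov)), function(g)
        sum(focal$pos2 > ov$start[g] & focal$pos1 < ov$end[g]), 0L)
      expressed <- if (!is.null(ov$expressed)) ov$expressed else
        rep(TRUE, nrow(ov))
      cand <- ov$gene %in% drivers |
        (expressed & sum(expressed) == 1L)
      hs$candidate_genes[i] <- paste(
        sprintf("%s(%d)", ov$gene[cand], ov$focal_n[cand]), collapse = ",")
    }
  }
  rownames(hs) <- NULL
  hs[, c("chrom", "start", "end", "beta", "fdr", "n_samples",
         "cna_supported", "candidate_genes")]
}

#' Fragile-site classification of a hotspot
#'
#' Six criteria: (1) late replication (mean replication timing <= 0);
#' (2) gene density below 5 per Mb; (3) overlaps a gene longer than 300 kb;
#' (4) breakpoint density in the largest overlapping gene exceeds 5 times the
#' density in the 1 Mb flanks; (5)/(6) overlaps either of two supplied known
#' fragile-site lists. A hotspot is a fragile site when at least 3 criteria
#' are met and it contains no driver gene. Missing annotations count the
#' criterion as unmet.
#'
#' @param ann list/1-row data.frame with fields `mean_repli`, `genes_per_mb`,
#'   `largest_gene_bp`, `density_ratio`, `known1`, `known2` (any may be NA).
#' @param contains_driver logical; hotspot contains an identified driver gene.
#' @return list `fragile` (logical) and `criteria` (named logical vector).
#' @export
classify_fragile <- function(ann, contains_driver = FALSE) {
  met <- function(x) !is.null(x) && !is.na(x) && x
  criteria <- c(
    late_replicating = met(ann$mean_repli <= 0),
    low_gene_density = met(ann$genes_per_mb < 5),
    large_gene = met(ann$largest_gene_bp > 3e5),
    gene_focused = met(ann$density_ratio > 5),
    known_list_1 = met(isTRUE(ann$known1)),
    known_list_2 = met(isTRUE(ann$known2)))
  list(fragile = sum(criteria) >= 3 && !contains_driver,
       criteria = criteria)
}

#' Build a fragile-site annotation for a hotspot
#'
#' @param hotspot 1-row data.frame (`chrom`, `start`, `end`).
#' @param breakends data.frame `chrom`, `pos` of the contributing breakends.
#' @param repli optional data.frame `chrom`, `start`, `end`, `value`
#'   (replication timing track).
#' @param genes optional gene table (`gene`, `chrom`, `start`, `end`).
#' @param known1,known2 optional BED-like data.frames of known fragile sites.
#' @param flank flank width for the density ratio (default 1 Mb).
#' @return annotation list suitable for [classify_fragile()].
#' @export
fragile_annotation <- function(hotspot, breakends, repli = NULL, genes = NULL,
                               known1 = NULL, known2 = NULL, flank = 1e6) {
  ch <- hotspot$chrom; s <- hotspot$start; e <- hotspot$end
  ov <- function(tbl) !is.null(tbl) &&
    any(tbl$chrom == ch & tbl$end > s & tbl$start < e)
  mean_repli <- NA_real_
  if (!is.null(repli)) {
    r <- repli[repli$chrom == ch & repli$end > s & repli$start < e, ]
    if (nrow(r)) {
      w <- pmin(r$end, e) - pmax(r$start, s)
      mean_repli <- sum(w * r$value) / sum(w)
    }
  }
  genes_per_mb <- NA_real_; largest_gene_bp <- NA_real_
  density_ratio <- NA_real_
  if (!is.null(genes)) {
    g <- genes[genes$chrom == ch & genes$end > s & genes$start < e, ]
    genes_per_mb <- nrow(g) / ((e - s) / 1e6)
    if (nrow(g)) {
      g$len <- g$end - g$start
      big <- g[which.max(g$len), ]
      largest_gene_bp <- big$len
      bp <- breakends[breakends$chrom == ch, ]
      n_in <- sum(bp$pos >= big$start & bp$pos < big$end)
      fl_left <- c(big$start - flank, big$start)
      fl_right <- c(big$end, big$end + flank)
      n_fl <- sum(bp$pos >= fl_left[1] & bp$pos < fl_left[2]) +
        sum(bp$pos >= fl_right[1] & bp$pos < fl_right[2])
      d_in <- n_in / big$len
      d_fl <- n_fl / (2 * flank)
      density_ratio <- if (d_fl > 0) d_in / d_fl else
        if (n_in > 0) Inf else NA_real_
    } else {
      largest_gene_bp <- 0
    }
  }
  list(mean_repli = mean_repli, genes_per_mb = genes_per_mb,
       largest_gene_bp = largest_gene_bp, density_ratio = density_ratio,
       known1 = ov(known1), known2 = ov(known2))
}
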