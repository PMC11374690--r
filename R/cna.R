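#' Allele-specific copy-number segments
#'
#' Segments are data.frames with columns `chrom`, `start`, `end` (0-based
#' half-open), `n_maj`, `n_min` (major/minor allele copy number of the clonal
#' state), `frac` (clonal fraction, in (0, 1]) and optionally `n_maj2`,
#' `n_min2`, `frac2` describing a second, subclonal state. Whenever a second
#' state is present and has the larger fraction, the exposed state used by all
#' downstream computations is that of the largest tumour cell fraction.
#'
#' @param segments segment data.frame.
#' @return data.frame with `n_maj`, `n_min` replaced by the largest-fraction
#'   state, plus a `length` column.
#' @export
clonal_state <- function(segments) {
  s <- as.data.frame(segments)
  if (nrow(s) == 0L) stop("empty segment list")
  if (is.null(s$frac)) s$frac <- 1
  if (!is.null(s$frac2) && !is.null(s$n_maj2)) {
    swap <- !is.na(s$frac2) & s$frac2 > s$frac
    if (any(swap)) {
      s$n_maj[swap] <- segments$n_maj2[swap]
      s$n_min[swap] <- segments$n_min2[swap]
      s$frac[swap] <- segments$frac2[swap]
    }
  }
  if (any(s$n_maj < s$n_min)) stop("n_maj must be >= n_min")
  s$length <- s$end - s$start
  if (any(s$length <= 0)) stop("segments must have positive length")
  s
}

#' Mean genome copy number and LOH fraction
#'
#' Computes the length-weighted average total copy number
#' \eqn{\psi_{ave} = \sum_i L_i (C_{Maj} + C_{Min}) / \sum_i L_i} and the
#' fraction `H` of the profiled genome with minor allele copy number 0.
#' Subclonal segments contribute the state of the largest cell fraction.
#'
#' @param segments segment data.frame (see [clonal_state()]).
#' @return list with `psi_ave` and `h_frac`.
#' @export
compute_psi_ave <- function(segments) {
  s <- clonal_state(segments)
  tot <- sum(s$length)
  psi_ave <- sum(s$length * (s$n_maj + s$n_min)) / tot
  h_frac <- sum(s$length[s$n_min == 0]) / tot
  list(psi_ave = psi_ave, h_frac = h_frac)
}

#' Whole-genome duplication call
#'
#' A tumour is called WGD when `2.9 - 2 * H < psi_ave` (strict inequality),
#' where `psi_ave` is the mean genome copy number and `H` the fraction of the
#' genome with minor allele copy number 0.
#'
#' @inheritParams compute_psi_ave
#' @return list with `psi_ave`, `h_frac`, `is_wgd`.
#' @export
call_wgd <- function(segments) {
  st <- compute_psi_ave(segments)
  st$is_wgd <- (2.9 - 2 * st$h_frac) < st$psi_ave
  st
}

#' Six-category CNA classification
#'
#' Classifies allele-specific copy-number states into HD (homozygous
#' deletion), LOH (including copy-neutral LOH), OLOSS (other loss; WGD tumours
#' only), NOC (no change), Gain and AMP, with WGD-dependent total copy number
#' thresholds:
#' \itemize{
#'   \item HD: total copy number 0.
#'   \item LOH: minor allele 0 and total \eqn{\le} 2 (non-WGD) or \eqn{\le} 4
#'     (WGD).
#'   \item NOC: 1+1 (non-WGD) or 2+2 (WGD).
#'   \item Gain: 2 < t \eqn{\le} 5 (non-WGD) or 4 < t \eqn{\le} 10 (WGD).
#'   \item AMP: t > 5 (non-WGD) or t > 10 (WGD).
#'   \item OLOSS: WGD only; minor allele \eqn{\ge} 1, t \eqn{\le} 4, not 2+2.
#' }
#' Precedence HD > LOH > NOC > Gain > AMP > OLOSS makes the category unique.
#'
#' @param n_maj,n_min major/minor allele copy numbers (vectors recycle).
#' @param is_wgd logical; tumour WGD status.
#' @return character vector of categories.
#' @export
classify_segment <- function(n_maj, n_min, is_wgd) {
  stopifnot(all(n_maj >= n_min), all(n_min >= 0))
  t_cn <- n_maj + n_min
  loh_max <- if (is_wgd) 4 else 2
  gain_max <- if (is_wgd) 10 else 5
  noc_cn <- if (is_wgd) 2 else 1
  out <- rep(NA_character_, length(t_cn))
  out[t_cn == 0] <- "HD"
  sel <- is.na(out) & n_min == 0 & t_cn <= loh_max
  out[sel] <- "LOH"
  sel <- is.na(out) & n_maj == noc_cn & n_min == noc_cn
  out[sel] <- "NOC"
  sel <- is.na(out) & t_cn > loh_max & t_cn <= gain_max
  # Gain lower bound is 2 (non-WGD) / 4 (WGD) == loh_max by construction
  out[sel] <- "Gain"
  sel <- is.na(out) & t_cn > gain_max
  out[sel] <- "AMP"
  if (is_wgd) {
    sel <- is.na(out) & n_min >= 1 & t_cn <= 4
    out[sel] <- "OLOSS"
  }
  if (anyNA(out)) stop("unclassifiable copy-number state (internal error)")
  out
}

#' Normalized per-segment copy number (SegCN) for GISTIC-style input
#'
#' SegCN is total copy number recentred on the assumed ploidy (2 for non-WGD,
#' 4 for WGD, halved), with male X handled separately, and clipped to
#' \[-2, 2\]:
#' non-WGD `t - 2` (male X `t - 1`); WGD `(t - 4) / 2` (male X `t - 2`).
#'
#' @param n_maj,n_min allele copy numbers (vectors).
#' @param is_wgd logical WGD status.
#' @param male_x logical vector; TRUE for X-chromosome segments of male
#'   tumours (default FALSE).
#' @return numeric vector of SegCN values in \[-2, 2\].
#' @export
seg_cn <- function(n_maj, n_min, is_wgd, male_x = FALSE) {
  t_cn <- n_maj + n_min
  male_x <- rep_len(male_x, length(t_cn))
  if (is_wgd) {
    v <- ifelse(male_x, t_cn - 2, (t_cn - 4) / 2)
  } else {
    v <- ifelse(male_x, t_cn - 1, t_cn - 2)
  }
  pmin(2, pmax(-2, v))
}

#' Purity and ploidy re-estimation from the top SNV cluster
#'
#' After a failed copy-number QC round, purity and ploidy are re-estimated
#' from the cancer cell fraction of the highest-CCF SNV cluster:
#' `rho_new = rho * ccf_top`;
#' `psi_new = (rho * psi + 2 * (rho_new - rho)) / rho_new`.
#'
#' @param rho current purity in (0, 1].
#' @param psi current tumour ploidy (> 0).
#' @param ccf_top CCF of the highest-CCF SNV cluster (> 0).
#' @return list with `rho_new`, `psi_new`.
#' @export
update_purity_ploidy <- function(rho, psi, ccf_top) {
  stopifnot(rho > 0, rho <= 1, psi > 0, ccf_top > 0)
  rho_new <- rho * ccf_top
  if (rho_new <= 0) stop("updated purity is non-positive")
  psi_new <- (rho * psi + 2 * (rho_new - rho)) / rho_new
  list(rho_new = rho_new, psi_new = psi_new)
}

#' Copy-number profile pass/fail decision
#'
#' A sample passes when (a) after removing SNV clusters holding < 1% of all
#' sample SNVs, a clonal cluster with 0.95 <= CCF <= 1.05 exists that has
#' either the highest CCF or the largest number of SNVs, and (b) the two
#' purity estimates differ by less than 0.05.
#'
#' @param clusters data.frame with columns `ccf` and `n_snvs`.
#' @param purity_a,purity_b purity estimates from two independent methods.
#' @return list with `pass` (logical) and `reasons` (character, empty on pass).
#' @export
evaluate_cna_pass <- function(clusters, purity_a, purity_b) {
  reasons <- character()
  cl <- as.data.frame(clusters)
  if (nrow(cl) > 0L) {
    tot <- sum(cl$n_snvs)
    if (tot > 0) cl <- cl[cl$n_snvs >= 0.01 * tot, , drop = FALSE]
  }
  clonal_ok <- FALSE
  if (nrow(cl) > 0L) {
    in_win <- cl$ccf >= 0.95 & cl$ccf <= 1.05
    top <- cl$ccf == max(cl$ccf) | cl$n_snvs == max(cl$n_snvs)
    clonal_ok <- any(in_win & top)
  }
  if (!clonal_ok) reasons <- c(reasons, "no clonal cluster")
  if (!(abs(purity_a - purity_b) < 0.05))
    reasons <- c(reasons, "purity discordance")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Arm-level CNA events
#'
#' For each chromosome arm and CNA category, calls an arm-level event when
#' segments of that category sum to more than half of the arm length.
#'
#' @param segments segment data.frame (see [clonal_state()]).
#' @param layout a [genome_layout()] with `arm_boundaries`.
#' @param is_wgd logical WGD status of the tumour.
#' @return data.frame `chrom`, `arm`, `category`, `frac`, `called`.
#' @export
arm_level_events <- function(segments, layout, is_wgd) {
  if (is.null(layout$arm_boundaries)) stop("layout lacks arm boundaries")
  s <- clonal_state(segments)
  s$category <- classify_segment(s$n_maj, s$n_min, is_wgd)
  out <- list()
  for (ch in intersect(layout$chrom_names, names(layout$arm_boundaries))) {
    cen <- layout$arm_boundaries[[ch]]
    len <- layout$chrom_lengths[[ch]]
    arms <- data.frame(arm = c("p", "q"), start = c(0, cen), end = c(cen, len))
    si <- s[s$chrom == ch, , drop = FALSE]
    for (a in seq_len(2)) {
      ov <- pmax(0, pmin(si$end, arms$end[a]) - pmax(si$start, arms$start[a]))
      keep <- ov > 0
      if (!any(keep)) next
      by_cat <- tapply(ov[keep], si$category[keep], sum)
      arm_len <- arms$end[a] - arms$start[a]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, arm = paste0(ch, arms$arm[a]),
        category = names(by_cat),
        frac = as.numeric(by_cat) / arm_len,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), arm = character(),
                      category = character(), frac = numeric(),
                      called = logical()))
  }
  res <- do.call(rbind, out)
  res$called <- res$frac > 0.5
  rownames(res) <- NULL
  res
}

#' Fraction of the genome under LOH
#'
#' Length-weighted fraction of segments with minor allele copy number 0 and
#' total copy number at least 1 (homozygous deletions are excluded).
#'
#' @inheritParams compute_psi_ave
#' @return numeric fraction in \[0, 1\].
#' @export
fraction_loh <- function(segments) {
  s <- clonal_state(segments)
  sum(s$length[s$n_min == 0 & (s$n_maj + s$n_min) >= 1]) / sum(s$length)
}

#' Read an allele-specific segment table
#'
#' Expects 1-based inclusive columns `sample`, `chr`, `startpos`, `endpos`,
#' `nMaj1_A`, `nMin1_A`, `frac1_A` and optionally `nMaj2_A`, `nMin2_A`,
#' `frac2_A`; converts to the package's 0-based half-open convention.
#'
#' @param path TSV path.
#' @return data.frame in internal segment format, with a `sample` column.
#' @export
read_segments <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  out <- data.frame(sample = as.character(x$sample),
                    chrom = as.character(x$chr),
                    start = x$startpos - 1,
                    end = x$endpos,
                    n_maj = x$nMaj1_A, n_min = x$nMin1_A, frac = x$frac1_A,
                    stringsAsFactors = FALSE)
  if ("nMaj2_A" %in% names(x)) {
    out$n_maj2 <- x$nMaj2_A; out$n_min2 <- x$nMin2_A; out$frac2 <- x$frac2_A
  }
  out
}

#' Write a GISTIC-style segmented copy-number table
#'
#' Emits sample, chrom, 1-based inclusive start/end, a synthetic marker count
#' (one per 10 kb, minimum 5) and SegCN.
#'
#' @param segments segment data.frame with a `sample` column.
#' @param is_wgd logical WGD status (single tumour) or named logical vector
#'   keyed by sample.
#' @param path output TSV path.
#' @param male_x logical vector as in [seg_cn()].
#' @return invisibly, the written data.frame.
#' @export
write_gistic_input <- function(segments, is_wgd, path, male_x = FALSE) {
  s <- clonal_state(segments)
  if (is.null(s$sample)) s$sample <- "sample1"
  wgd <- if (length(is_wgd) > 1L) is_wgd[s$sample] else rep(is_wgd, nrow(s))
  segcn <- numeric(nrow(s))
  for (w in unique(wgd)) {
    sel <- wgd == w
    segcn[sel] <- seg_cn(s$n_maj[sel], s$n_min[sel], w,
                         rep_len(male_x, nrow(s))[sel])
  }
  out <- data.frame(sample = s$sample, chrom = s$chrom,
                    start = s$start + 1, end = s$end,
                    n_markers = pmax(5, round(s$length / 1e4)),
                    seg_cn = segcn)
  data.table::fwrite(out, path, sep = "\t")
  invisible(out)
}
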