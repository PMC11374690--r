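# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive results by brute force / direct rules and must
# stay independent of the package implementation paths they check.

tiny_layout <- function(n_chroms = 2, len = 1e7, mask = NULL) {
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  genome_layout(chroms, rep(len, n_chroms),
                arm_boundaries = stats::setNames(rep(len / 2, n_chroms),
                                                 chroms),
                mask = mask)
}

# --- PCF brute force ---------------------------------------------------------

# all compositions of n into parts >= kmin, as segment-end vectors (cached)
.comp_cache <- new.env(parent = emptyenv())
compositions_kmin <- function(n, kmin) {
  key <- paste(n, kmin)
  if (!is.null(.comp_cache[[key]])) return(.comp_cache[[key]])
  res <- list()
  rec <- function(start, ends) {
    for (e in seq(start + kmin - 1, n)) {
      tail <- n - e
      if (tail != 0 && tail < kmin) next
      if (e == n) res[[length(res) + 1L]] <<- c(ends, e)
      else rec(e + 1, c(ends, e))
    }
  }
  if (n >= kmin) rec(1, integer())
  .comp_cache[[key]] <- res
  res
}

# exhaustive-enumeration PCF: min cost, then fewest segments, then
# lexicographically earliest boundaries
pcf_oracle <- function(x, gamma, kmin) {
  n <- length(x)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- x[i:j]
      S[i, j] <- sum((v - mean(v))^2)
    }
  }
  comps <- compositions_kmin(n, kmin)
  sse_of <- vapply(comps, function(ends) {
    starts <- c(1, utils::head(ends, -1) + 1)
    sum(S[cbind(starts, ends)])
  }, 0)
  m_of <- lengths(comps)
  cost <- sse_of + gamma * m_of
  tol <- 1e-9 * (1 + abs(min(cost)))
  cand <- which(cost <= min(cost) + tol)
  cand <- cand[m_of[cand] == min(m_of[cand])]
  if (length(cand) > 1L) {
    # lexicographic smallest boundary vector (all have equal length)
    bm <- do.call(rbind, comps[cand])
    for (col in seq_len(ncol(bm))) {
      cand <- cand[bm[, col] == min(bm[, col])]
      bm <- bm[bm[, col] == min(bm[, col]), , drop = FALSE]
      if (length(cand) == 1L) break
    }
  }
  list(cost = cost[cand[1]], ends = comps[[cand[1]]])
}

# --- interleave brute force --------------------------------------------------

interleaved_oracle <- function(svs) {
  svs <- canonical_svs(svs)
  intra <- svs[svs$chrom1 == svs$chrom2, , drop = FALSE]
  n <- nrow(intra)
  if (n < 2) return(0L)
  crosses <- function(i, j) {
    if (intra$chrom1[i] != intra$chrom1[j]) return(FALSE)
    a1 <- intra$pos1[i]; a2 <- intra$pos2[i]
    b1 <- intra$pos1[j]; b2 <- intra$pos2[j]
    (a1 < b1 && b1 < a2 && a2 < b2) || (b1 < a1 && a1 < b2 && b2 < a2)
  }
  sum(vapply(seq_len(n), function(i)
    any(vapply(setdiff(seq_len(n), i), crosses, FALSE, i = i)), FALSE))
}

# --- exact multinomial enumeration ------------------------------------------

multinomial_oracle <- function(counts) {
  n <- sum(counts)
  k <- length(counts)
  p_obs <- stats::dmultinom(counts, prob = rep(1 / k, k))
  total <- 0
  rec <- function(rem, left, acc) {
    if (left == 1L) {
      pr <- stats::dmultinom(c(acc, rem), prob = rep(1 / k, k))
      if (pr <= p_obs * (1 + 1e-9)) total <<- total + pr
      return()
    }
    for (i in 0:rem) rec(rem - i, left - 1L, c(acc, i))
  }
  rec(n, k, integer())
  total
}

# --- hand-coded CNA rule table ----------------------------------------------

# direct restatement of the six-category rules, written without reference to
# classify_segment's control flow
cna_rule_oracle <- function(maj, mn, wgd) {
  t <- maj + mn
  if (t == 0) return("HD")
  if (!wgd) {
    if (mn == 0 && t <= 2) return("LOH")
    if (maj == 1 && mn == 1) return("NOC")
    if (t > 2 && t <= 5) return("Gain")
    return("AMP")
  }
  if (mn == 0 && t <= 4) return("LOH")
  if (maj == 2 && mn == 2) return("NOC")
  if (t > 4 && t <= 10) return("Gain")
  if (t > 10) return("AMP")
  "OLOSS"
}

# --- misc --------------------------------------------------------------------

seg_df <- function(...) {
  # seg_df(c(chrom, start, end, n_maj, n_min), ...)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) data.frame(
    chrom = as.character(r[[1]]), start = as.numeric(r[[2]]),
    end = as.numeric(r[[3]]), n_maj = as.numeric(r[[4]]),
    n_min = as.numeric(r[[5]]), frac = 1, stringsAsFactors = FALSE)))
}

sv_row <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                   sample = "s1", ...) {
  data.frame(sample = sample, chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2, ...,
             stringsAsFactors = FALSE)
}
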