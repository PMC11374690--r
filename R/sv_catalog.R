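#' Rearrangement tables
#'
#' Rearrangements (SV junctions) are data.frames with one row per junction and
#' columns `id`, `sample`, `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#' `strand2`, plus optional `caller`, `tumour_support_frac`, `normal_support`
#' and `class`. Breakend orientation follows the BEDPE strand convention used
#' here throughout: `+` means the retained fragment extends toward lower
#' coordinates from the breakend; `-` the converse. With breakends ordered
#' (bnd1 <= bnd2), intrachromosomal junctions read: (+,-) deletion-like,
#' (-,+) duplication-like, (+,+) head-to-head inversion, (-,-) tail-to-tail
#' inversion.
#'
#' @param svs rearrangement data.frame.
#' @return the same data.frame with breakends ordered so that bnd1 <= bnd2
#'   (by chromosome name, then position).
#' @export
canonical_svs <- function(svs) {
  svs <- as.data.frame(svs)
  if (nrow(svs) == 0L) return(svs)
  swap <- (as.character(svs$chrom1) > as.character(svs$chrom2)) |
    (svs$chrom1 == svs$chrom2 & svs$pos1 > svs$pos2)
  if (any(swap)) {
    tmp <- svs[swap, c("chrom1", "pos1", "strand1")]
    svs[swap, c("chrom1", "pos1", "strand1")] <-
      svs[swap, c("chrom2", "pos2", "strand2")]
    svs[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  svs
}

#' Consensus merging of per-caller SV callsets
#'
#' Pre-filters every callset (any normal-read support, tumour support fraction
#' below 2%, or a breakend inside the layout mask or on an unknown
#' chromosome), then joins calls from different callers whose breakends both
#' lie within `tol` bp and whose orientations agree, and keeps merged variants
#' supported by at least two callers, or by one caller when a breakend falls
#' within `boundary_tol` of a copy-number segment boundary.
#'
#' @param callsets named list of rearrangement data.frames, one per caller.
#' @param cn_boundaries data.frame `chrom`, `pos` of copy-number segment
#'   boundaries (optionally per `sample`), or NULL to disable the rescue rule.
#' @param tol breakpoint matching tolerance in bp (default 400).
#' @param boundary_tol CN-boundary rescue distance in bp (default 3000).
#' @param layout optional [genome_layout()] used for mask/contig filtering.
#' @param min_support_frac minimum tumour-read support fraction (default 0.02).
#' @return merged rearrangement data.frame with `callers` (comma-separated)
#'   and `n_callers` columns.
#' @export
merge_consensus <- function(callsets, cn_boundaries = NULL, tol = 400,
                            boundary_tol = 3000, layout = NULL,
                            min_support_frac = 0.02) {
  if (is.null(names(callsets)) || any(names(callsets) == ""))
    stop("callsets must be a named list (caller names)")
  all_calls <- list()
  for (caller in names(callsets)) {
    x <- canonical_svs(callsets[[caller]])
    if (nrow(x) == 0L) next
    keep <- rep(TRUE, nrow(x))
    if (!is.null(x$normal_support)) keep <- keep & x$normal_support == 0
    if (!is.null(x$tumour_support_frac))
      keep <- keep & x$tumour_support_frac >= min_support_frac
    if (!is.null(layout)) {
      known <- x$chrom1 %in% layout$chrom_names & x$chrom2 %in% layout$chrom_names
      keep <- keep & known
      masked <- rep(FALSE, nrow(x))
      masked[known] <- in_mask(layout, x$chrom1[known], x$pos1[known]) |
        in_mask(layout, x$chrom2[known], x$pos2[known])
      keep <- keep & !masked
    }
    x <- x[keep, , drop = FALSE]
    if (nrow(x) == 0L) next
    x$caller <- caller
    all_calls[[caller]] <- x
  }
  cols <- c("sample", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "caller")
  empty <- data.frame(id = character(), sample = character(),
                      chrom1 = character(), pos1 = numeric(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = numeric(), strand2 = character(),
                      callers = character(), n_callers = integer(),
                      stringsAsFactors = FALSE)
  if (!length(all_calls)) return(empty)
  calls <- do.call(rbind, lapply(all_calls, function(x) {
    if (is.null(x$sample)) x$sample <- "sample1"
    x[, cols]
  }))
  rownames(calls) <- NULL
  n <- nrow(calls)
  # sort for reproducibility independent of callset order
  o <- order(calls$sample, calls$chrom1, calls$pos1, calls$chrom2,
             calls$pos2, calls$strand1, calls$strand2, calls$caller)
  calls <- calls[o, ]
  # match calls within tol: group by (sample, chrom pair, strand pair)
  key <- paste(calls$sample, calls$chrom1, calls$chrom2, calls$strand1,
               calls$strand2)
  comp <- seq_len(n)  # union-find roots
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (grp in split(seq_len(n), key)) {
    if (length(grp) < 2L) next
    for (a in seq_along(grp)[-length(grp)]) {
      i <- grp[a]
      for (b in seq((a + 1), length(grp))) {
        j <- grp[b]
        if (abs(calls$pos1[i] - calls$pos1[j]) <= tol &&
            abs(calls$pos2[i] - calls$pos2[j]) <= tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  merged <- lapply(split(seq_len(n), roots), function(idx) {
    g <- calls[idx, ]
    data.frame(sample = g$sample[1],
               chrom1 = g$chrom1[1], pos1 = round(stats::median(g$pos1)),
               strand1 = g$strand1[1],
               chrom2 = g$chrom2[1], pos2 = round(stats::median(g$pos2)),
               strand2 = g$strand2[1],
               callers = paste(sort(unique(g$caller)), collapse = ","),
               n_callers = length(unique(g$caller)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  keep <- res$n_callers >= 2
  if (!is.null(cn_boundaries) && any(!keep)) {
    single <- which(!keep)
    near <- vapply(single, function(i) {
      bnd <- cn_boundaries
      if (!is.null(bnd$sample)) bnd <- bnd[bnd$sample == res$sample[i], ]
      d1 <- bnd$pos[bnd$chrom == res$chrom1[i]]
      d2 <- bnd$pos[bnd$chrom == res$chrom2[i]]
      (length(d1) && min(abs(d1 - res$pos1[i])) <= boundary_tol) ||
        (length(d2) && min(abs(d2 - res$pos2[i])) <= boundary_tol)
    }, logical(1))
    keep[single] <- near
  }
  res <- res[keep, , drop = FALSE]
  if (nrow(res)) {
    o <- order(res$sample, res$chrom1, res$pos1, res$chrom2, res$pos2)
    res <- res[o, , drop = FALSE]
    res$id <- sprintf("sv%05d", seq_len(nrow(res)))
    res <- res[, c("id", setdiff(names(res), "id"))]
  } else {
    res <- empty
  }
  rownames(res) <- NULL
  res
}

#' Group rearrangements into footprints and clusters
#'
#' Clusters are connected components of rearrangements linked whenever any two
#' of their breakends lie on the same chromosome within `d_cl` bp. Footprints
#' are maximal runs of cluster breakends with successive gaps of at most
#' `d_fp` bp. This is a distance-threshold approximation to likelihood-based
#' footprint/cluster grouping; see the package vignette.
#'
#' @param svs rearrangement data.frame.
#' @param d_fp footprint gap threshold in bp (default 10 kb).
#' @param d_cl cluster linkage distance in bp (default 1 Mb).
#' @return the input with a `cluster_id` column; cluster sizes and footprints
#'   are available via [cluster_footprints()].
#' @export
group_clusters <- function(svs, d_fp = 1e4, d_cl = 1e6) {
  if (d_fp > d_cl) stop("d_fp must be <= d_cl")
  svs <- canonical_svs(svs)
  n <- nrow(svs)
  if (n == 0L) { svs$cluster_id <- integer(); return(svs) }
  # breakend table
  be <- data.frame(sv = rep(seq_len(n), 2),
                   chrom = c(svs$chrom1, svs$chrom2),
                   pos = c(svs$pos1, svs$pos2))
  edges <- list()
  for (ch in unique(be$chrom)) {
    bi <- be[be$chrom == ch, ]
    bi <- bi[order(bi$pos), ]
    if (nrow(bi) < 2L) next
    # successive breakends within d_cl chain their rearrangements together
    link <- which(diff(bi$pos) <= d_cl)
    if (length(link))
      edges[[ch]] <- cbind(bi$sv[link], bi$sv[link + 1L])
  }
  el <- do.call(rbind, edges)
  if (is.null(el)) el <- matrix(integer(), ncol = 2)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  svs$cluster_id <- as.integer(factor(memb, levels = unique(memb)))
  svs
}

#' Footprints of one cluster
#'
#' @param cluster rearrangement data.frame (rows of one cluster).
#' @param d_fp footprint gap threshold in bp.
#' @return data.frame `chrom`, `start`, `end`, `n_breakends`, `footprint_id`.
#' @export
cluster_footprints <- function(cluster, d_fp = 1e4) {
  be <- data.frame(chrom = c(cluster$chrom1, cluster$chrom2),
                   pos = c(cluster$pos1, cluster$pos2),
                   strand = c(cluster$strand1, cluster$strand2),
                   sv = rep(seq_len(nrow(cluster)), 2),
                   inter = rep(cluster$chrom1 != cluster$chrom2, 2))
  out <- list()
  for (ch in unique(be$chrom)) {
    bi <- be[be$chrom == ch, ]
    bi <- bi[order(bi$pos), ]
    brk <- c(0, cumsum(diff(bi$pos) > d_fp))
    for (grp in split(seq_len(nrow(bi)), brk)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(bi$pos[grp]), end = max(bi$pos[grp]) + 1,
        n_breakends = length(grp),
        n_strands = length(unique(bi$strand[grp])),
        all_inter = all(bi$inter[grp]),
        n_svs = length(unique(bi$sv[grp])),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$footprint_id <- seq_len(nrow(res))
  res
}

#' Classify a simple (size <= 2) cluster
#'
#' Size-1 intrachromosomal junctions map by orientation to deletion, tandem
#' duplication or (lone inversion junction) simple unclassified. Size-2
#' intrachromosomal clusters with one head-to-head and one tail-to-tail
#' inversion junction whose corresponding breakends co-locate within
#' `bridge_tol` are balanced inversions. Size-1 interchromosomal junctions are
#' unbalanced translocations when a copy-number boundary lies within
#' `cn_tol` of either breakend, else simple unclassified. Size-2 reciprocal
#' interchromosomal pairs are balanced translocations when the paired
#' breakends on each chromosome have opposite orientations and co-locate
#' within `bridge_tol` (no copy-number change or only a short deletion
#' bridge), else unbalanced translocations.
#'
#' @param cluster rearrangement data.frame with 1 or 2 rows.
#' @param cn_boundaries optional data.frame `chrom`, `pos` (see
#'   [merge_consensus()]).
#' @param bridge_tol deletion-bridge tolerance in bp (default 10 kb).
#' @param cn_tol CN-step detection distance in bp (default 3 kb).
#' @return character label.
#' @export
classify_simple <- function(cluster, cn_boundaries = NULL, bridge_tol = 1e4,
                            cn_tol = 3000) {
  cluster <- canonical_svs(cluster)
  n <- nrow(cluster)
  if (n >= 3L) stop("cluster of size >= 3 is complex; use the complex-event classifiers")
  near_cn <- function(chrom, pos) {
    if (is.null(cn_boundaries)) return(FALSE)
    p <- cn_boundaries$pos[cn_boundaries$chrom == chrom]
    length(p) > 0 && min(abs(p - pos)) <= cn_tol
  }
  if (n == 1L) {
    r <- cluster[1, ]
    if (r$chrom1 == r$chrom2) {
      ori <- paste0(r$strand1, r$strand2)
      return(switch(ori,
                    "+-" = "deletion",
                    "-+" = "tandem_duplication",
                    "simple_unclassified"))
    }
    if (near_cn(r$chrom1, r$pos1) || near_cn(r$chrom2, r$pos2))
      return("unbalanced_translocation")
    return("simple_unclassified")
  }
  a <- cluster[1, ]; b <- cluster[2, ]
  intra <- a$chrom1 == a$chrom2 && b$chrom1 == b$chrom2 &&
    a$chrom1 == b$chrom1
  if (intra) {
    oris <- sort(c(paste0(a$strand1, a$strand2), paste0(b$strand1, b$strand2)))
    shared <- abs(a$pos1 - b$pos1) <= bridge_tol &&
      abs(a$pos2 - b$pos2) <= bridge_tol
    if (identical(oris, c("++", "--")) && shared)
      return("balanced_inversion")
    return("simple_unclassified")
  }
  inter <- a$chrom1 != a$chrom2 && b$chrom1 != b$chrom2
  same_pair <- inter && a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2
  if (same_pair) {
    recip <- a$strand1 != b$strand1 && a$strand2 != b$strand2
    close1 <- abs(a$pos1 - b$pos1) <= bridge_tol
    close2 <- abs(a$pos2 - b$pos2) <= bridge_tol
    if (recip && close1 && close2) return("balanced_translocation")
    if (recip) return("unbalanced_translocation")
  }
  if (inter) {
    # two non-reciprocal translocation junctions
    if (near_cn(a$chrom1, a$pos1) || near_cn(a$chrom2, a$pos2) ||
        near_cn(b$chrom1, b$pos1) || near_cn(b$chrom2, b$pos2))
      return("unbalanced_translocation")
  }
  "simple_unclassified"
}

#' Intrachromosomal junction orientation counts
#'
#' Tabulates deletion-like (+,-), duplication-like (-,+), head-to-head (+,+)
#' and tail-to-tail (-,-) orientations over the intrachromosomal members of a
#' cluster; interchromosomal junctions are excluded.
#'
#' @param cluster rearrangement data.frame.
#' @return named integer vector `c(del_like, dup_like, hh_inv, tt_inv)`.
#' @export
orientation_counts <- function(cluster) {
  cluster <- canonical_svs(cluster)
  intra <- cluster$chrom1 == cluster$chrom2
  ori <- paste0(cluster$strand1[intra], cluster$strand2[intra])
  c(del_like = sum(ori == "+-"), dup_like = sum(ori == "-+"),
    hh_inv = sum(ori == "++"), tt_inv = sum(ori == "--"))
}

#' Kinase-domain fusion detection
#'
#' Reports junctions that join a partner gene to a kinase gene such that the
#' kinase domain lies 3' of the junction within the kinase gene (the retained
#' fragment contains the whole domain) and the predicted transcription strands
#' are compatible: the partner gene transcribes into the junction and the
#' kinase gene away from it.
#'
#' @param svs rearrangement data.frame.
#' @param genes gene-model data.frame with columns `gene`, `chrom`, `start`,
#'   `end`, `strand` and, for kinase genes, `kd_start`, `kd_end` (kinase
#'   domain interval) and `is_kinase` (logical).
#' @return data.frame of fusion records (`sv_id`, `kinase_gene`,
#'   `partner_gene`).
#' @export
detect_kinase_fusions <- function(svs, genes) {
  svs <- canonical_svs(svs)
  genes <- as.data.frame(genes)
  kin <- genes[isTRUE_v(genes$is_kinase), , drop = FALSE]
  nodom <- is.na(kin$kd_start) | is.na(kin$kd_end)
  if (any(nodom)) {
    warning("kinase gene(s) lacking domain annotation skipped: ",
            paste(kin$gene[nodom], collapse = ", "))
    kin <- kin[!nodom, , drop = FALSE]
  }
  hit_gene <- function(chrom, pos, tbl) {
    which(tbl$chrom == chrom & tbl$start <= pos & pos < tbl$end)
  }
  out <- list()
  for (i in seq_len(nrow(svs))) {
    ends <- list(list(chrom = svs$chrom1[i], pos = svs$pos1[i],
                      strand = svs$strand1[i]),
                 list(chrom = svs$chrom2[i], pos = svs$pos2[i],
                      strand = svs$strand2[i]))
    for (k in 1:2) {
      ke <- ends[[k]]; pe <- ends[[3 - k]]
      for (gi in hit_gene(ke$chrom, ke$pos, kin)) {
        g <- kin[gi, ]
        # retained fragment of the 3' (kinase) gene must contain the domain,
        # with the junction 5' of the domain in transcription direction
        dom_3prime <- if (g$strand == "+") {
          ke$pos < g$kd_start && ke$strand == "-"  # retains higher side
        } else {
          ke$pos >= g$kd_end && ke$strand == "+"   # retains lower side
        }
        if (!dom_3prime) next
        for (pj in hit_gene(pe$chrom, pe$pos, genes)) {
          p <- genes[pj, ]
          if (p$gene == g$gene) next
          # partner transcribes toward the junction on its retained side
          partner_5prime <- (p$strand == "+" && pe$strand == "+") ||
            (p$strand == "-" && pe$strand == "-")
          if (partner_5prime) {
            out[[length(out) + 1L]] <- data.frame(
              sv_id = if (!is.null(svs$id)) svs$id[i] else as.character(i),
              kinase_gene = g$gene, partner_gene = p$gene,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sv_id = character(), kinase_gene = character(),
                      partner_gene = character(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

isTRUE_v <- function(x) !is.null(x) & !is.na(x) & x

#' Read/write BEDPE rearrangement files
#'
#' BEDPE columns chrom1, start1, end1, chrom2, start2, end2, name, score,
#' strand1, strand2 plus optional extra columns (`sample`, `caller`,
#' `tumour_support_frac`, `normal_support`, `class`). Breakend positions are
#' taken as the BEDPE start coordinates (0-based).
#'
#' @param path file path.
#' @return rearrangement data.frame.
#' @export
read_bedpe <- function(path) {
  x <- as.data.frame(data.table::fread(path, header = TRUE))
  out <- data.frame(id = as.character(x$name),
                    chrom1 = as.character(x$chrom1), pos1 = x$start1,
                    strand1 = as.character(x$strand1),
                    chrom2 = as.character(x$chrom2), pos2 = x$start2,
                    strand2 = as.character(x$strand2),
                    stringsAsFactors = FALSE)
  for (cc in c("sample", "caller", "tumour_support_frac", "normal_support",
               "class")) {
    if (cc %in% names(x)) out[[cc]] <- x[[cc]]
  }
  canonical_svs(out)
}

#' @rdname read_bedpe
#' @param svs rearrangement data.frame to write.
#' @export
write_bedpe <- function(svs, path) {
  svs <- canonical_svs(svs)
  out <- data.frame(chrom1 = svs$chrom1, start1 = svs$pos1,
                    end1 = svs$pos1 + 1,
                    chrom2 = svs$chrom2, start2 = svs$pos2,
                    end2 = svs$pos2 + 1,
                    name = if (!is.null(svs$id)) svs$id else
                      sprintf("sv%05d", seq_len(nrow(svs))),
                    score = ".",
                    strand1 = svs$strand1, strand2 = svs$strand2)
  for (cc in c("sample", "class")) if (!is.null(svs[[cc]])) out[[cc]] <- svs[[cc]]
  data.table::fwrite(out, path, sep = "\t")
  invisible(out)
}
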