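#' Genome layout
#'
#' A genome layout holds the ordered chromosome names and lengths, optional
#' per-chromosome arm boundaries (centromere positions) and a set of
#' uncallable intervals (telomeres, centromeres or custom masks). All
#' coordinates are 0-based, half-open.
#'
#' @param chrom_names character vector of chromosome identifiers, in order.
#' @param chrom_lengths integer/numeric vector of chromosome lengths (bp).
#' @param arm_boundaries optional named numeric vector of centromere positions,
#'   one per chromosome, each strictly inside `(0, length)`.
#' @param mask optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of uncallable intervals.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chrom_names, chrom_lengths, arm_boundaries = NULL,
                          mask = NULL) {
  if (length(chrom_names) == 0L) stop("empty genome layout")
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths lengths differ")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  chrom_lengths <- as.numeric(chrom_lengths)
  names(chrom_lengths) <- chrom_names
  if (!is.null(arm_boundaries)) {
    if (is.null(names(arm_boundaries)))
      stop("arm_boundaries must be named by chromosome")
    bad <- names(arm_boundaries)[!(names(arm_boundaries) %in% chrom_names)]
    if (length(bad)) stop("unknown chromosome in arm_boundaries: ", bad[1])
    ab <- arm_boundaries
    ln <- chrom_lengths[names(ab)]
    if (any(ab <= 0 | ab >= ln))
      stop("arm boundaries must lie strictly within (0, chromosome length)")
  }
  if (is.null(mask)) {
    mask <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  } else {
    mask <- as.data.frame(mask)[, c("chrom", "start", "end")]
    if (any(!(mask$chrom %in% chrom_names)))
      stop("mask interval on unknown chromosome")
    if (any(mask$start < 0 | mask$end > chrom_lengths[mask$chrom] |
              mask$start >= mask$end))
      stop("mask intervals must be within chromosome bounds")
    mask <- merge_intervals(mask)
  }
  structure(list(chrom_names = as.character(chrom_names),
                 chrom_lengths = chrom_lengths,
                 arm_boundaries = arm_boundaries,
                 mask = mask),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.1f Mb total, %d mask intervals\n",
              length(x$chrom_names), sum(x$chrom_lengths) / 1e6, nrow(x$mask)))
  invisible(x)
}

#' Merge overlapping or adjacent intervals
#'
#' @param x data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame of disjoint intervals, sorted by chrom and start.
#' @export
merge_intervals <- function(x) {
  x <- as.data.frame(x)
  if (nrow(x) == 0L) return(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- vector("list", nrow(x))
  k <- 0L
  cur <- x[1, ]
  for (i in seq_len(nrow(x))[-1]) {
    if (x$chrom[i] == cur$chrom && x$start[i] <= cur$end) {
      cur$end <- max(cur$end, x$end[i])
    } else {
      k <- k + 1L; out[[k]] <- cur
      cur <- x[i, ]
    }
  }
  k <- k + 1L; out[[k]] <- cur
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

## total masked width falling inside each of a set of bins on one chromosome
masked_width <- function(bin_start, bin_end, mask_start, mask_end) {
  w <- numeric(length(bin_start))
  for (i in seq_along(mask_start)) {
    w <- w + pmax(0, pmin(bin_end, mask_end[i]) - pmax(bin_start, mask_start[i]))
  }
  w
}

#' Tile the genome into non-overlapping bins
#'
#' Divides every chromosome into consecutive bins of `bin_size` bp; the final
#' bin of a chromosome may be shorter. Bins whose overlap with the layout mask
#' exceeds `mask_frac` of their width are flagged not callable.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp (default 1 Mb).
#' @param mask_frac fraction of a bin that must be masked for the bin to be
#'   flagged uncallable (default 0.5).
#' @return A `bin_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `bin_id`, `callable` and (once filled by the background model) `b`, the
#'   expected breakend count per bin. The bin size is kept in `attr(, "s_bin")`.
#' @export
build_bins <- function(layout, bin_size = 1e6, mask_frac = 0.5) {
  stopifnot(inherits(layout, "genome_layout"))
  if (bin_size <= 0) stop("bin_size must be > 0")
  pieces <- lapply(layout$chrom_names, function(ch) {
    len <- layout$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  grid$bin_id <- seq_len(nrow(grid))
  grid$callable <- TRUE
  if (nrow(layout$mask) > 0L) {
    for (ch in unique(layout$mask$chrom)) {
      m <- layout$mask[layout$mask$chrom == ch, ]
      sel <- grid$chrom == ch
      mw <- masked_width(grid$start[sel], grid$end[sel], m$start, m$end)
      frac <- mw / (grid$end[sel] - grid$start[sel])
      grid$callable[sel] <- frac <= mask_frac
    }
  }
  grid$b <- NA_real_
  attr(grid, "s_bin") <- bin_size
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Bin index lookup
#'
#' Maps genomic positions to row indices of a regular [build_bins()] grid.
#' Positions outside the chromosome return `NA`.
#'
#' @param grid a `bin_grid`.
#' @param chrom,pos vectors of positions (0-based).
#' @return integer vector of row indices into `grid`.
#' @export
bin_index <- function(grid, chrom, pos) {
  s_bin <- attr(grid, "s_bin")
  info <- grid_chrom_info(grid)
  off <- info$offset[chrom]
  nb <- info$n_bins[chrom]
  len <- info$length[chrom]
  idx <- off + floor(pos / s_bin) + 1
  idx[is.na(off) | pos < 0 | pos >= len | floor(pos / s_bin) >= nb] <- NA
  as.integer(idx)
}

## per-chromosome offsets into a bin grid (memoised via attribute)
grid_chrom_info <- function(grid) {
  info <- attr(grid, "chrom_info")
  if (!is.null(info)) return(info)
  chroms <- unique(grid$chrom)
  n_bins <- vapply(chroms, function(ch) sum(grid$chrom == ch), 0)
  offset <- cumsum(c(0, n_bins[-length(n_bins)]))
  length <- vapply(chroms, function(ch) max(grid$end[grid$chrom == ch]), 0)
  names(offset) <- names(length) <- names(n_bins) <- chroms
  list(offset = offset, n_bins = n_bins, length = length)
}

#' Row indices of bins overlapping an interval
#'
#' @param grid a `bin_grid`.
#' @param chrom chromosome; `start`,`end` 0-based half-open interval.
#' @return integer vector of grid row indices.
#' @export
bins_overlapping <- function(grid, chrom, start, end) {
  s_bin <- attr(grid, "s_bin")
  info <- grid_chrom_info(grid)
  if (!(chrom %in% names(info$offset))) return(integer())
  off <- info$offset[[chrom]]
  nb <- info$n_bins[[chrom]]
  first <- max(0, floor(start / s_bin))
  last <- min(nb - 1, floor((end - 1) / s_bin))
  if (last < first) return(integer())
  as.integer(off + seq(first, last) + 1)
}

#' Is a position inside the uncallable mask?
#'
#' @param layout a [genome_layout()].
#' @param chrom,pos position vectors.
#' @return logical vector.
#' @export
in_mask <- function(layout, chrom, pos) {
  res <- logical(length(pos))
  m <- layout$mask
  if (nrow(m) == 0L) return(res)
  for (ch in unique(chrom)) {
    mi <- m[m$chrom == ch, ]
    if (nrow(mi) == 0L) next
    sel <- which(chrom == ch)
    for (j in seq_len(nrow(mi))) {
      res[sel] <- res[sel] | (pos[sel] >= mi$start[j] & pos[sel] < mi$end[j])
    }
  }
  res
}

#' Read a chrom/length table (FASTA-index-like TSV)
#'
#' Only the first two columns (chromosome, length) are used.
#' @param path file path.
#' @return data.frame with `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- data.table::fread(path, header = FALSE)
  data.frame(chrom = as.character(x[[1]]), length = as.numeric(x[[2]]),
             stringsAsFactors = FALSE)
}

#' Read a BED file (first three columns)
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  x <- data.table::fread(path, header = FALSE)
  data.frame(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
             end = as.numeric(x[[3]]), stringsAsFactors = FALSE)
}
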