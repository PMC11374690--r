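#' Synthetic cohort configuration
#'
#' Defaults describe a desk-scale cohort with the statistical structure the
#' pipeline assumes: a 3,000-Mb genome in 10 chromosomes (3,000 one-Mb bins),
#' covariates with true log-linear effects within \[-0.5, 0.8\], NB dispersion
#' 1.0, 15x hotspot injections, log-normal SV lengths and a 0.45 WGD fraction
#' with purity uniform on (0.3, 0.9).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param bin_size bin width (default 1 Mb).
#' @param covariates named list of covariate specs: each
#'   `list(type = "normal"|"binary", beta = effect, p = Bernoulli prob)`.
#' @param intercept log baseline breakend count per bin (cohort total).
#' @param dispersion NB2 dispersion alpha.
#' @param n_hotspots number of injected hotspot bins.
#' @param hotspot_multiplier multiplicative rate excess (>= 1).
#' @param n_tumours cohort size.
#' @param sv_class_mix named class probabilities.
#' @param length_meanlog,length_sdlog log-normal SV length parameters.
#' @param wgd_fraction fraction of tumours with WGD.
#' @param purity_range purity sampling range.
#' @param seed master seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_chroms = 10, chrom_length = 3e8, bin_size = 1e6,
                         covariates = list(
                           repli = list(type = "normal", beta = 0.5),
                           gc = list(type = "normal", beta = -0.3),
                           frag = list(type = "binary", beta = 0.8, p = 0.1),
                           expr_hi = list(type = "binary", beta = -0.5,
                                          p = 0.25)),
                         intercept = log(3), dispersion = 1.0,
                         n_hotspots = 5, hotspot_multiplier = 15,
                         n_tumours = 100,
                         sv_class_mix = c(deletion = 0.4,
                                          tandem_duplication = 0.3,
                                          inversion = 0.2,
                                          translocation = 0.1),
                         length_meanlog = log(6e4), length_sdlog = 1.2,
                         wgd_fraction = 0.45, purity_range = c(0.3, 0.9),
                         seed = 1) {
  stopifnot(hotspot_multiplier >= 1, abs(sum(sv_class_mix) - 1) < 1e-9,
            wgd_fraction >= 0, wgd_fraction <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate the synthetic genome layout and covariate grid
#'
#' Chromosomes carry a centromere at the midpoint; the first bin of each
#' chromosome is masked (telomere stand-in). Quantitative covariates are
#' standard normal draws, binary covariates Bernoulli.
#'
#' @param config a [synth_config()].
#' @return list `layout` (a [genome_layout()]) and `grid` (a `bin_grid` with
#'   covariate columns).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 1))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  lens <- rep(config$chrom_length, config$n_chroms)
  mask <- do.call(rbind, lapply(chroms, function(ch) data.frame(
    chrom = ch, start = 0, end = config$bin_size)))
  arms <- stats::setNames(lens / 2, chroms)
  layout <- genome_layout(chroms, lens, arm_boundaries = arms, mask = mask)
  grid <- build_bins(layout, config$bin_size)
  for (nm in names(config$covariates)) {
    sp <- config$covariates[[nm]]
    grid[[nm]] <- if (sp$type == "binary") {
      stats::rbinom(nrow(grid), 1, sp$p)
    } else {
      stats::rnorm(nrow(grid))
    }
  }
  list(layout = layout, grid = grid)
}

#' Generate per-tumour SV catalogues under the stated background
#'
#' Per-bin cohort rates are `lambda_j = exp(intercept + X beta_true)` with
#' injected hotspot bins multiplied by the configured factor; per-tumour
#' per-bin SV counts are negative binomial with the configured dispersion.
#' Each SV starts uniformly within its bin; intrachromosomal lengths are
#' log-normal, orientations follow the class convention, translocations pick a
#' partner chromosome uniformly.
#'
#' @param config a [synth_config()].
#' @param grid covariate grid from [generate_genome()].
#' @param layout layout from [generate_genome()].
#' @return list `svs` (rearrangement data.frame with `sample`), `truth`
#'   (data.frame of injected hotspot bins), `lambda` (per-bin cohort rates
#'   without injection).
#' @export
generate_cohort_svs <- function(config, grid, layout) {
  set.seed(derive_seed(config$seed, 2))
  X <- as.matrix(as.data.frame(grid)[, names(config$covariates), drop = FALSE])
  betas <- vapply(config$covariates, `[[`, 0, "beta")
  lambda <- exp(config$intercept + as.numeric(X %*% betas))
  lambda[!grid$callable] <- 0
  mult <- rep(1, nrow(grid))
  truth <- data.frame(bin_id = integer(), chrom = character(),
                      start = numeric(), end = numeric())
  if (config$n_hotspots > 0) {
    # inject into bins of typical covariate-driven rate (middle 50%): the
    # multiplier measures the designed 15x excess rather than compounding
    # with the background-rate lottery, keeping the stated recovery rates
    # attainable at desk scale (see the methods vignette)
    lam_call <- lambda[grid$callable]
    qs <- stats::quantile(lam_call, c(0.25, 0.75))
    injectable <- which(grid$callable & lambda >= qs[1] & lambda <= qs[2])
    inj <- sample(injectable, config$n_hotspots)
    mult[inj] <- config$hotspot_multiplier
    truth <- data.frame(bin_id = inj, chrom = grid$chrom[inj],
                        start = grid$start[inj], end = grid$end[inj])
  }
  mu_bin <- lambda * mult / config$n_tumours
  classes <- names(config$sv_class_mix)
  out <- list()
  for (t in seq_len(config$n_tumours)) {
    counts <- stats::rnbinom(length(mu_bin), mu = mu_bin,
                             size = 1 / config$dispersion)
    tot <- sum(counts)
    if (tot == 0) next
    bin <- rep(seq_along(counts), counts)
    pos1 <- floor(stats::runif(tot, grid$start[bin], grid$end[bin]))
    chrom1 <- grid$chrom[bin]
    cls <- sample(classes, tot, replace = TRUE, prob = config$sv_class_mix)
    len <- round(stats::rlnorm(tot, config$length_meanlog, config$length_sdlog))
    len <- pmax(len, 50)
    chrom2 <- chrom1
    pos2 <- pmin(pos1 + len, layout$chrom_lengths[chrom1] - 1)
    strand1 <- ifelse(cls == "deletion", "+",
                      ifelse(cls == "tandem_duplication", "-",
                             ifelse(cls == "inversion", "+", "+")))
    strand2 <- ifelse(cls == "deletion", "-",
                      ifelse(cls == "tandem_duplication", "+",
                             ifelse(cls == "inversion", "+", "-")))
    tr <- cls == "translocation"
    if (any(tr)) {
      other <- vapply(chrom1[tr], function(ch)
        sample(setdiff(layout$chrom_names, ch), 1), "")
      chrom2[tr] <- other
      pos2[tr] <- floor(stats::runif(sum(tr), 0,
                                     layout$chrom_lengths[other]))
    }
    out[[t]] <- data.frame(sample = sprintf("T%03d", t),
                           chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
                           chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
                           class = cls, stringsAsFactors = FALSE)
  }
  svs <- canonical_svs(do.call(rbind, out))
  svs$id <- sprintf("sv%06d", seq_len(nrow(svs)))
  list(svs = svs, truth = truth, lambda = lambda)
}

#' Generate allele-specific copy-number profiles
#'
#' WGD tumours are built on a 2+2 baseline, non-WGD on 1+1, with a small
#' number of category-labelled arm deviations. WGD profiles satisfy the WGD
#' inequality by construction; non-WGD deviations are kept small enough to
#' preserve the non-WGD call.
#'
#' @param config a [synth_config()].
#' @param layout a [genome_layout()].
#' @return list `profiles` (named list of segment data.frames), `truth`
#'   (data.frame `sample`, `is_wgd`, `purity`).
#' @export
generate_cn_profiles <- function(config, layout) {
  set.seed(derive_seed(config$seed, 3))
  chroms <- layout$chrom_names
  profiles <- list()
  truth <- list()
  for (t in seq_len(config$n_tumours)) {
    wgd <- stats::runif(1) < config$wgd_fraction
    base <- if (wgd) c(2, 2) else c(1, 1)
    segs <- list()
    for (ch in chroms) {
      len <- layout$chrom_lengths[[ch]]
      cen <- layout$arm_boundaries[[ch]]
      arms <- rbind(c(0, cen), c(cen, len))
      for (a in 1:2) {
        dev <- stats::runif(1)
        nm <- base[1]; nmn <- base[2]
        if (dev < 0.10) { nm <- base[1] + 1 }            # gain
        else if (dev < 0.16 && !wgd) { nmn <- 0 }        # LOH (non-WGD)
        else if (dev < 0.16 && wgd) { nm <- 2; nmn <- 1 } # OLOSS (WGD)
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, start = arms[a, 1], end = arms[a, 2],
          n_maj = nm, n_min = nmn, frac = 1, stringsAsFactors = FALSE)
      }
    }
    prof <- do.call(rbind, segs)
    sample_id <- sprintf("T%03d", t)
    prof$sample <- sample_id
    profiles[[sample_id]] <- prof
    truth[[sample_id]] <- data.frame(
      sample = sample_id, is_wgd = wgd,
      purity = stats::runif(1, config$purity_range[1],
                            config$purity_range[2]))
  }
  list(profiles = profiles, truth = do.call(rbind, truth))
}

#' Chromothripsis cluster template
#'
#' Builds a rearrangement cluster on one chromosome together with an
#' oscillating copy-number segment table. Positive fixtures satisfy all three
#' chromothripsis criteria; negatives break one, chosen by `defect`
#' ("nested" removes interleaving, "skewed" concentrates orientations in one
#' category, "no_oscillation" flattens the copy-number profile).
#'
#' @param chrom chromosome name; `start` leftmost breakpoint.
#' @param n_sv number of rearrangements (default 12, multiple of 4 advised).
#' @param spacing breakpoint spacing in bp.
#' @param positive logical; build a positive fixture.
#' @param defect which criterion to break for negative fixtures.
#' @param seed RNG seed (jitters breakpoints).
#' @return list `svs` (rearrangements, `sample` = "fix"), `cn_segments`.
#' @export
make_chromothripsis_cluster <- function(chrom = "chr1", start = 1e7,
                                        n_sv = 12, spacing = 5e4,
                                        positive = TRUE,
                                        defect = c("nested", "skewed",
                                                   "no_oscillation"),
                                        seed = 1) {
  defect <- match.arg(defect)
  set.seed(seed)
  oris <- rep(c("+-", "-+", "++", "--"), length.out = n_sv)
  if (!positive && defect == "skewed") oris <- rep("+-", n_sv)
  jit <- function(k) round(stats::runif(k, 0, spacing / 10))
  if (!positive && defect == "nested") {
    # concentric nested spans: no pair crosses
    p1 <- start + (seq_len(n_sv) - 1) * spacing + jit(n_sv)
    p2 <- start + (4 * n_sv) * spacing - (seq_len(n_sv) - 1) * spacing +
      jit(n_sv)
  } else {
    # crossing ladder: span i = [i*2s, i*2s + 3s] crosses neighbours
    p1 <- start + (seq_len(n_sv) - 1) * 2 * spacing + jit(n_sv)
    p2 <- p1 + 3 * spacing + jit(n_sv)
  }
  svs <- data.frame(sample = "fix", chrom1 = chrom, pos1 = p1,
                    strand1 = substr(oris, 1, 1),
                    chrom2 = chrom, pos2 = p2,
                    strand2 = substr(oris, 2, 2), stringsAsFactors = FALSE)
  svs <- canonical_svs(svs)
  span <- range(c(p1, p2))
  n_seg <- 8
  bounds <- round(seq(span[1] - spacing, span[2] + spacing,
                      length.out = n_seg + 1))
  cn <- if (!positive && defect == "no_oscillation") rep(2, n_seg)
    else rep(c(2, 1), length.out = n_seg)
  cn_segments <- data.frame(sample = "fix", chrom = chrom,
                            start = bounds[-(n_seg + 1)], end = bounds[-1],
                            total_cn = cn, stringsAsFactors = FALSE)
  list(svs = svs, cn_segments = cn_segments)
}

#' Chromoplexy cluster template
#'
#' Builds a cycle of translocations across `n_chroms` chromosomes with
#' reciprocal co-located breakends (balanced footprints). Negative fixtures
#' break one criterion: "two_chroms" restricts the chain to 2 chromosomes,
#' "too_many" exceeds 30 rearrangements, "unbalanced" makes the footprints
#' one-sided.
#'
#' @param chroms chromosome names forming the cycle.
#' @param base_pos leftmost breakpoint per chromosome (recycled).
#' @param gap distance between the reciprocal breakends of a footprint.
#' @param positive logical; `defect` as above.
#' @param defect which criterion to break.
#' @param seed RNG seed.
#' @return list `svs`.
#' @export
make_chromoplexy_cluster <- function(chroms = c("chr1", "chr2", "chr3"),
                                     base_pos = 2e7, gap = 5e3,
                                     positive = TRUE,
                                     defect = c("two_chroms", "too_many",
                                                "unbalanced"),
                                     seed = 1) {
  defect <- match.arg(defect)
  set.seed(seed)
  if (!positive && defect == "two_chroms") chroms <- chroms[1:2]
  k <- length(chroms)
  pos <- base_pos + round(stats::runif(k, 0, 1e6))
  names(pos) <- chroms
  mk <- function(c1, p1, s1, c2, p2, s2) data.frame(
    sample = "fix", chrom1 = c1, pos1 = p1, strand1 = s1,
    chrom2 = c2, pos2 = p2, strand2 = s2, stringsAsFactors = FALSE)
  svs <- list()
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    s2 <- if (!positive && defect == "unbalanced") "+" else "-"
    svs[[i]] <- mk(chroms[i], pos[i] + gap, "+",
                   chroms[j], pos[j], s2)
  }
  if (!positive && defect == "two_chroms") {
    # keep the size precondition satisfied: a third junction on the same pair
    svs[[3]] <- mk(chroms[1], pos[1] + gap + 500, "+",
                   chroms[2], pos[2] + 500, "-")
  }
  if (!positive && defect == "too_many") {
    extra <- lapply(seq_len(31 - k), function(m) {
      i <- (m %% k) + 1L
      j <- if (i == k) 1L else i + 1L
      mk(chroms[i], pos[i] + gap + m * 100, "+",
         chroms[j], pos[j] + m * 100, "-")
    })
    svs <- c(svs, extra)
  }
  list(svs = canonical_svs(do.call(rbind, svs)))
}
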