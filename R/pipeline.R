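#' Validate and resolve a run configuration
#'
#' Configurations are JSON files (or lists) with either a `synthetic` block
#' (passed to [synth_config()]) or paths to a chrom-sizes TSV (`layout`), a
#' mask BED (`mask`), a BEDPE catalogue (`bedpe`) and covariate tracks
#' (`tracks`, named bedGraph/BED paths); plus `gamma`, `kmin`, `n_reps`,
#' `fdr`, `seed` and `out_dir`. Referenced files must exist at validation.
#'
#' @param config path to a JSON file or a list.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(gamma = 10, kmin = 10, n_reps = 100, fdr = 0.05,
                   seed = 1, out_dir = "svhotspots_out", bin_size = 1e6)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$synthetic)) {
    for (f in c("layout", "bedpe")) {
      if (is.null(config[[f]])) stop("config lacks '", f, "' and no synthetic block")
      if (!file.exists(config[[f]])) stop("missing input file: ", config[[f]])
    }
    if (!is.null(config$mask) && !file.exists(config$mask))
      stop("missing input file: ", config$mask)
    for (tr in unlist(config$tracks)) {
      if (!file.exists(tr)) stop("missing covariate track: ", tr)
    }
  }
  class(config) <- c("run_config", "list")
  config
}

#' Run the hotspot pipeline end to end
#'
#' Stages: bin the genome, summarize covariates, fit the negative binomial
#' background, fill expected breakend counts, simulate null replicates,
#' segment inter-mutational distances by PCF, compute empirical FDRs, filter
#' and collapse hotspots. Outputs (`bins.tsv`, `model.txt`, `segments.tsv`,
#' `hotspots.tsv`, `config.json`, `log.txt`) are written to `out_dir` and are
#' bitwise reproducible from the config and seed.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   sprintf(...))
    log_lines <<- c(log_lines, msg)
  }
  say("svhotspots run, seed %d", config$seed)
  if (!is.null(config$synthetic)) {
    sc <- do.call(synth_config, c(config$synthetic,
                                  list(seed = config$seed)))
    gen <- generate_genome(sc)
    layout <- gen$layout; grid <- gen$grid
    cohort <- generate_cohort_svs(sc, grid, layout)
    svs <- cohort$svs
    say("synthetic cohort: %d SVs, %d injected hotspot bins",
        nrow(svs), nrow(cohort$truth))
    if (nrow(cohort$truth)) {
      data.table::fwrite(cohort$truth,
                         file.path(config$out_dir, "truth_hotspots.tsv"),
                         sep = "\t")
    }
  } else {
    sizes <- read_chrom_sizes(config$layout)
    mask <- if (!is.null(config$mask)) read_bed(config$mask) else NULL
    layout <- genome_layout(sizes$chrom, sizes$length, mask = mask)
    grid <- build_bins(layout, config$bin_size)
    if (!is.null(config$tracks)) {
      tracks <- lapply(config$tracks, function(p) {
        x <- as.data.frame(data.table::fread(p, header = FALSE))
        names(x)[1:3] <- c("chrom", "start", "end")
        if (ncol(x) >= 4) names(x)[4] <- "value"
        x
      })
      grid <- bin_covariates(grid, tracks)
    }
    svs <- read_bedpe(config$bedpe)
    say("loaded %d SVs", nrow(svs))
  }
  counts <- count_breakends(svs, grid)
  cov <- tryCatch(normalize_covariates(grid), error = function(e) NULL)
  model <- fit_nb(counts, cov)
  say("background model: dispersion %.4g, loglik %.2f", model$dispersion,
      model$loglik)
  grid <- expected_breakends(model, cov, grid)
  reps <- run_replicates(svs, grid, layout, n_reps = config$n_reps,
                         seed = config$seed)
  say("simulated %d replicates", length(reps))
  obs <- hotspot_segments(svs, grid, gamma = config$gamma,
                          kmin = config$kmin)
  sims <- lapply(reps, hotspot_segments, grid = grid, gamma = config$gamma,
                 kmin = config$kmin)
  obs <- empirical_fdr(obs, sims)
  hotspots <- filter_and_collapse(obs, svs, cn_boundaries = NULL,
                                  fdr_threshold = config$fdr)
  say("%d segments, %d hotspots at FDR < %g", nrow(obs), nrow(hotspots),
      config$fdr)
  fmt <- function(x) {
    num <- vapply(x, is.numeric, TRUE)
    x[num] <- lapply(x[num], function(v) signif(v, 10))
    x
  }
  data.table::fwrite(fmt(as.data.frame(grid)),
                     file.path(config$out_dir, "bins.tsv"), sep = "\t")
  data.table::fwrite(fmt(obs), file.path(config$out_dir, "segments.tsv"),
                     sep = "\t")
  data.table::fwrite(fmt(hotspots),
                     file.path(config$out_dir, "hotspots.tsv"), sep = "\t")
  writeLines(c(sprintf("coef\t%s\t%.10g", names(model$coefficients),
                       model$coefficients),
               sprintf("dispersion\t%.10g", model$dispersion)),
             file.path(config$out_dir, "model.txt"))
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, logf)
  invisible(list(layout = layout, grid = grid, model = model,
                 segments = obs, hotspots = hotspots, svs = svs))
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline from a config), `synth` (write a
#' synthetic cohort BEDPE plus truth tables), `bins` (tile a genome),
#' `cna` (WGD call and six-category classification of a segment TSV) and
#' `classify` (simple/complex classification of a BEDPE). Flags:
#' `--config`, `--seed`, `--n-reps`, `--gamma`, `--kmin`, `--fdr`, `--out`.
#' Returns 0 on success, 1 on validation error, 2 on runtime error.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly.
#' @export
sv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: svhotspots <run|synth|bins|cna|classify> [--config F] [--seed N] [--n-reps N] [--gamma G] [--kmin K] [--fdr Q] [--out DIR] [--input F]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) { message("missing value for --", key); return(invisible(1L)) }
    opt[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  status <- tryCatch({
    switch(cmd,
      run = {
        cfg <- run_config(opt$config)
        if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
        if (!is.null(opt$n_reps)) cfg$n_reps <- as.integer(opt$n_reps)
        if (!is.null(opt$gamma)) cfg$gamma <- num(opt$gamma)
        if (!is.null(opt$kmin)) cfg$kmin <- as.integer(opt$kmin)
        if (!is.null(opt$fdr)) cfg$fdr <- num(opt$fdr)
        if (!is.null(opt$out)) cfg$out_dir <- opt$out
        run_pipeline(cfg)
        0L
      },
      synth = {
        sc <- synth_config(seed = if (is.null(opt$seed)) 1L else
          as.integer(opt$seed))
        gen <- generate_genome(sc)
        cohort <- generate_cohort_svs(sc, gen$grid, gen$layout)
        out <- if (is.null(opt$out)) "." else opt$out
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_bedpe(cohort$svs, file.path(out, "cohort.bedpe"))
        data.table::fwrite(cohort$truth,
                           file.path(out, "truth_hotspots.tsv"), sep = "\t")
        0L
      },
      bins = {
        sizes <- read_chrom_sizes(opt$input)
        layout <- genome_layout(sizes$chrom, sizes$length)
        grid <- build_bins(layout)
        out <- if (is.null(opt$out)) "bins.tsv" else opt$out
        data.table::fwrite(as.data.frame(grid), out, sep = "\t")
        0L
      },
      cna = {
        segs <- read_segments(opt$input)
        out_rows <- lapply(split(segs, segs$sample), function(s) {
          w <- call_wgd(s)
          s2 <- clonal_state(s)
          data.frame(sample = s$sample, chrom = s$chrom,
                     start = s$start + 1, end = s$end,
                     category = classify_segment(s2$n_maj, s2$n_min, w$is_wgd),
                     is_wgd = w$is_wgd, psi_ave = w$psi_ave)
        })
        res <- do.call(rbind, out_rows)
        out <- if (is.null(opt$out)) "cna_categories.tsv" else opt$out
        data.table::fwrite(res, out, sep = "\t")
        0L
      },
      classify = {
        svs <- read_bedpe(opt$input)
        svs <- group_clusters(svs)
        lab <- vapply(split(seq_len(nrow(svs)), svs$cluster_id), function(ix) {
          cl <- svs[ix, ]
          if (nrow(cl) <= 2) classify_simple(cl) else "complex"
        }, "")
        svs$label <- lab[as.character(svs$cluster_id)]
        out <- if (is.null(opt$out)) "sv_classes.tsv" else opt$out
        data.table::fwrite(svs, out, sep = "\t")
        0L
      },
      { message("unknown subcommand: ", cmd); message(usage); 1L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config|missing|not found|lacks", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}
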