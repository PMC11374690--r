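#' Normalize genome covariates over callable bins
#'
#' Z-scores each covariate column over the callable bins of the grid (mean 0,
#' standard deviation 1 with the n-1 denominator). Zero-variance columns are
#' dropped with a warning. Means and standard deviations are stored so values
#' can be de-normalized.
#'
#' @param grid a `bin_grid` whose covariate columns are every column other
#'   than `chrom`, `start`, `end`, `bin_id`, `callable`, `b` (or pass
#'   `columns`).
#' @param columns optional character vector naming the covariate columns.
#' @return object of class `covariate_matrix`: list with `X` (matrix over all
#'   bins, standardized by callable-bin moments), `means`, `sds`, `columns`,
#'   `callable`.
#' @export
normalize_covariates <- function(grid, columns = NULL) {
  reserved <- c("chrom", "start", "end", "bin_id", "callable", "b")
  if (is.null(columns)) columns <- setdiff(names(grid), reserved)
  if (!length(columns)) stop("no covariate columns found")
  callable <- grid$callable
  if (sum(callable) < 2L) stop("need at least two callable bins")
  X <- as.matrix(as.data.frame(grid)[, columns, drop = FALSE])
  means <- apply(X[callable, , drop = FALSE], 2, mean)
  sds <- apply(X[callable, , drop = FALSE], 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (all(zero)) stop("all covariate columns have zero variance")
  if (any(zero)) {
    warning("dropping zero-variance covariate(s): ",
            paste(columns[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
    columns <- columns[!zero]; means <- means[!zero]; sds <- sds[!zero]
  }
  X <- sweep(sweep(X, 2, means), 2, sds, "/")
  structure(list(X = X, means = means, sds = sds, columns = columns,
                 callable = callable),
            class = "covariate_matrix")
}

#' Negative binomial regression of per-bin breakend counts
#'
#' Fits an NB2 model (variance mu + dispersion * mu^2) with log link by
#' maximum likelihood via [MASS::glm.nb()]. When the data show no
#' overdispersion (the size estimate diverges) the fit falls back to the
#' Poisson limit with dispersion 0. Collinear covariates are detected by rank
#' deficiency of the design matrix and dropped with a warning.
#'
#' @param counts non-negative integer counts, one per callable bin (a vector
#'   over all bins is subset by `covariates$callable`).
#' @param covariates a `covariate_matrix` from [normalize_covariates()], or
#'   NULL for an intercept-only fit.
#' @return object of class `nb_model`: list with `coefficients`, `se`,
#'   `dispersion` (NB2 alpha; 0 = Poisson), `loglik`, `converged`, `n`,
#'   `sum_counts`, `columns`.
#' @export
fit_nb <- function(counts, covariates = NULL) {
  if (is.null(covariates)) {
    X <- matrix(numeric(0), nrow = length(counts), ncol = 0)
    columns <- character()
  } else {
    X <- covariates$X
    if (length(counts) == nrow(X)) {
      counts <- counts[covariates$callable]
    }
    X <- X[covariates$callable, , drop = FALSE]
    columns <- covariates$columns
  }
  y <- counts
  if (length(y) != nrow(X) && ncol(X) > 0)
    stop("counts length does not match the number of callable bins")
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  if (ncol(X) > 0) {
    M <- cbind(`(Intercept)` = 1, X)
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
      keep <- qrM$pivot[seq_len(qrM$rank)]
      dropped <- setdiff(colnames(M), colnames(M)[keep])
      warning("dropping collinear covariate(s): ",
              paste(dropped, collapse = ", "))
      X <- M[, setdiff(colnames(M)[keep], "(Intercept)"), drop = FALSE]
      columns <- colnames(X)
    }
  }
  dat <- data.frame(y = y)
  form <- if (ncol(X) > 0) {
    for (j in seq_len(ncol(X))) dat[[colnames(X)[j]]] <- X[, j]
    stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)),
                                         collapse = " + ")))
  } else {
    y ~ 1
  }
  poisson_fit <- function() {
    f <- stats::glm(form, data = dat, family = stats::poisson())
    list(coef = stats::coef(f),
         se = sqrt(diag(stats::vcov(f))),
         dispersion = 0,
         loglik = as.numeric(stats::logLik(f)),
         converged = f$converged)
  }
  res <- tryCatch({
    f <- withCallingHandlers(
      MASS::glm.nb(form, data = dat),
      warning = function(w) invokeRestart("muffleWarning"))
    theta <- f$theta
    if (!is.finite(theta) || theta > 1e6) {
      poisson_fit()
    } else {
      list(coef = stats::coef(f),
           se = sqrt(diag(stats::vcov(f))),
           dispersion = 1 / theta,
           loglik = as.numeric(stats::logLik(f)),
           converged = f$converged)
    }
  }, error = function(e) poisson_fit())
  if (!isTRUE(res$converged))
    stop("negative binomial fit did not converge (loglik ",
         format(res$loglik), ")")
  structure(list(coefficients = res$coef, se = res$se,
                 dispersion = res$dispersion, loglik = res$loglik,
                 converged = res$converged, n = length(y),
                 sum_counts = sum(y), columns = columns),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("nb_model: %d bins, dispersion %.4g, loglik %.2f\n",
              x$n, x$dispersion, x$loglik))
  print(x$coefficients)
  invisible(x)
}

#' Negative binomial log-likelihood (NB2, dispersion 0 = Poisson)
#'
#' @param y counts; `mu` means; `dispersion` NB2 alpha (variance mu +
#'   alpha mu^2).
#' @return total log-likelihood.
#' @export
nb_loglik <- function(y, mu, dispersion) {
  if (dispersion == 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / dispersion, mu = mu, log = TRUE))
}

#' Expected breakend counts per bin
#'
#' Fills `b`, the model-expected breakend count, for every callable bin
#' (fitted mean under the log link); uncallable bins get `b = 0`. Warns when
#' the fitted total deviates from the observed total by more than 2%.
#'
#' @param model an `nb_model` from [fit_nb()].
#' @param covariates the `covariate_matrix` the model was fitted on (or NULL
#'   for intercept-only models).
#' @param grid the `bin_grid`.
#' @return `grid` with the `b` column filled.
#' @export
expected_breakends <- function(model, covariates, grid) {
  if (!isTRUE(model$converged)) stop("model did not converge")
  if (is.null(covariates)) {
    eta <- rep(model$coefficients[["(Intercept)"]], nrow(grid))
    callable <- grid$callable
  } else {
    if (!all(model$columns %in% covariates$columns))
      stop("covariate keys do not match the fitted model")
    X <- covariates$X[, model$columns, drop = FALSE]
    eta <- model$coefficients[["(Intercept)"]] +
      as.numeric(X %*% model$coefficients[model$columns])
    callable <- covariates$callable
  }
  b <- exp(eta)
  b[!callable] <- 0
  tot <- sum(b)
  if (abs(tot - model$sum_counts) > 0.02 * max(1, model$sum_counts))
    warning(sprintf("fitted total %.1f deviates >2%% from observed %d",
                    tot, model$sum_counts))
  grid$b <- b
  grid
}

#' Per-bin breakend counts from a rearrangement table
#'
#' Each junction contributes its two breakends; breakends outside the grid are
#' ignored.
#'
#' @param svs rearrangement data.frame.
#' @param grid a `bin_grid`.
#' @return integer vector of counts, one per grid row.
#' @export
count_breakends <- function(svs, grid) {
  idx <- c(bin_index(grid, svs$chrom1, svs$pos1),
           bin_index(grid, svs$chrom2, svs$pos2))
  idx <- idx[!is.na(idx)]
  tabulate(idx, nbins = nrow(grid))
}

#' Summarize covariate tracks over bins
#'
#' Quantitative tracks (bedGraph: chrom, start, end, value) contribute the
#' coverage-weighted mean value per bin; binary tracks (BED) contribute the
#' fraction of the bin overlapped.
#'
#' @param grid a `bin_grid`.
#' @param tracks named list; each element a data.frame with `chrom`, `start`,
#'   `end` and optionally `value` (present = quantitative).
#' @return `grid` with one new column per track.
#' @export
bin_covariates <- function(grid, tracks) {
  for (nm in names(tracks)) {
    tr <- as.data.frame(tracks[[nm]])
    quant <- "value" %in% names(tr)
    acc <- numeric(nrow(grid))
    wsum <- numeric(nrow(grid))
    for (i in seq_len(nrow(tr))) {
      hit <- bins_overlapping(grid, tr$chrom[i], tr$start[i], tr$end[i])
      if (!length(hit)) next
      ow <- pmin(grid$end[hit], tr$end[i]) - pmax(grid$start[hit], tr$start[i])
      if (quant) {
        acc[hit] <- acc[hit] + ow * tr$value[i]
        wsum[hit] <- wsum[hit] + ow
      } else {
        acc[hit] <- acc[hit] + ow
      }
    }
    grid[[nm]] <- if (quant) ifelse(wsum > 0, acc / pmax(wsum, 1), 0)
      else acc / (grid$end - grid$start)
  }
  grid
}
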