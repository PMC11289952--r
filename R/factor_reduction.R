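#' Drop images with any missing or infinite statistic
#'
#' Pattern statistics on backgrounds with fewer than 2 pattern elements are
#' undefined (NaN / Inf), so such rows are excluded before factor analysis.
#' Exclusion counts per viewing distance are attached so the filtering is
#' reportable.
#'
#' @param stats Data frame of stat records (metadata columns plus the
#'   [stat_registry()] columns).
#' @return The complete-case data frame with attribute `exclusions`, a data
#'   frame of per-distance excluded-row counts.
#' @export
filter_complete_cases <- function(stats) {
  if (nrow(stats) == 0) stop("empty statistic table")
  num <- stats[, intersect(stat_registry(), names(stats)), drop = FALSE]
  bad <- apply(num, 1L, function(r) any(!is.finite(r)))
  excl <- stats[bad, , drop = FALSE]
  counts <- if ("distance_cm" %in% names(stats)) {
    stats::aggregate(list(n_excluded = bad),
                     by = list(distance_cm = stats$distance_cm), FUN = sum)
  } else data.frame(distance_cm = NA_real_, n_excluded = sum(bad))
  out <- stats[!bad, , drop = FALSE]
  if (nrow(out) == 0)
    stop("all rows contained missing values; nothing left to analyze")
  attr(out, "exclusions") <- counts
  attr(out, "excluded_images") <-
    if ("image_id" %in% names(excl)) excl$image_id else character(0)
  out
}

#' Greedy correlation filter over statistic columns
#'
#' Scans the statistic columns in fixed registry order and keeps a column
#' only if its absolute Pearson correlation with every already-kept column is
#' below the threshold; the surviving set is therefore mutually less
#' correlated than the threshold. Zero-variance columns are dropped with a
#' warning. The scan order matters (a different order gives a different but
#' equally valid survivor set), which is why it is pinned to the registry
#' order.
#'
#' @param stats Complete-case statistic table.
#' @param threshold Absolute Pearson correlation cutoff (default 0.6).
#' @param order Column scan order; defaults to [stat_registry()] restricted
#'   to the available columns.
#' @return The table restricted to metadata plus surviving columns, with
#'   attribute `dropped_stats`.
#' @export
correlation_filter <- function(stats, threshold = 0.6, order = NULL) {
  cols <- intersect(if (is.null(order)) stat_registry() else order,
                    names(stats))
  if (nrow(stats) < 2) stop("need at least 2 rows to correlate")
  x <- as.matrix(stats[, cols, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance columns: ",
            paste(cols[sds == 0], collapse = ", "))
    cols <- cols[sds > 0]
    x <- x[, cols, drop = FALSE]
  }
  kept <- character(0)
  for (cn in cols) {
    if (length(kept) == 0) {
      kept <- cn
      next
    }
    r <- abs(stats::cor(x[, cn], x[, kept, drop = FALSE]))
    if (all(r < threshold)) kept <- c(kept, cn)
  }
  meta <- setdiff(names(stats), stat_registry())
  out <- stats[, c(meta, kept), drop = FALSE]
  attr(out, "kept_stats") <- kept
  attr(out, "dropped_stats") <- setdiff(cols, kept)
  out
}

#' Parallel analysis for factor retention
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' position-wise median eigenvalues of `n_sims` standard-normal datasets of
#' identical shape; the retained factor count is the number of observed
#' eigenvalues strictly greater than the corresponding simulated median.
#'
#' @param x Numeric matrix or data frame of complete cases (rows =
#'   observations, columns = variables, p >= 2).
#' @param n_sims Number of simulated datasets (default 10000).
#' @param seed Integer seed making the simulation deterministic.
#' @return Integer retained factor count, with attributes
#'   `observed_eigenvalues` and `median_simulated`.
#' @export
parallel_analysis <- function(x, n_sims = 10000, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) stop("parallel analysis needs at least 2 columns")
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  sims <- withr::with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      z <- matrix(stats::rnorm(n * p), n, p)
      eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  med <- apply(sims, 1L, stats::median)
  k <- sum(obs > med)
  structure(as.integer(k), observed_eigenvalues = obs,
            median_simulated = med)
}

#' Exploratory factor analysis (least-squares extraction, varimax rotation)
#'
#' Minimum-residual ("minres"/OLS) factor extraction on the correlation
#' matrix: the uniquenesses are chosen to minimize the sum of squared
#' off-diagonal residuals of `R - L L'`, with the loadings taken from the
#' leading eigenstructure of the reduced matrix. Loadings are
#' varimax-rotated, factors ordered by explained variance with a
#' positive-loading sign convention, and scores computed by the regression
#' (Thurstone) method on standardized data. Bootstrap loading intervals
#' resample rows with replacement, refit, align every replicate to the point
#' estimate by the congruence-maximizing signed column permutation, and take
#' percentile 95% intervals.
#'
#' @param x Numeric matrix or data frame of complete cases.
#' @param k Number of factors (>= 1).
#' @param bootstrap_iters Bootstrap replicates for loading CIs (0 = skip;
#'   default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `factor_model`: list with `loadings` (p x k),
#'   `uniquenesses`, `rotation` (k x k orthonormal), `scores` (n x k),
#'   `variance_explained` (per-factor proportion of total variance),
#'   `bootstrap_ci` (array p x k x 2, or NULL).
#' @export
fit_efa <- function(x, k, bootstrap_iters = 1000, seed = 1) {
  x <- as.matrix(x)
  stopifnot(k >= 1, k < ncol(x))
  R <- stats::cor(x)
  fit <- efa_minres(R, k)
  rot <- varimax_sorted(fit$loadings)
  L <- rot$loadings

  z <- scale(x)
  scores <- z %*% solve_ridge(R, L)   # regression (Thurstone) scores

  ci <- NULL
  if (bootstrap_iters > 0) {
    boots <- withr::with_seed(seed, {
      lapply(seq_len(bootstrap_iters), function(b) {
        idx <- sample.int(nrow(x), replace = TRUE)
        Rb <- suppressWarnings(stats::cor(x[idx, , drop = FALSE]))
        if (any(!is.finite(Rb))) return(NULL)
        Lb <- varimax_sorted(efa_minres(Rb, k, warn = FALSE)$loadings)$loadings
        align_loadings(Lb, L)
      })
    })
    boots <- boots[!vapply(boots, is.null, logical(1))]
    arr <- simplify2array(boots)
    ci <- array(NA_real_, c(nrow(L), k, 2),
                dimnames = list(rownames(L), colnames(L), c("lo", "hi")))
    for (i in seq_len(nrow(L)))
      for (j in seq_len(k))
        ci[i, j, ] <- stats::quantile(arr[i, j, ], c(0.025, 0.975),
                                      names = FALSE)
  }

  structure(
    list(loadings = L, uniquenesses = fit$uniquenesses,
         rotation = rot$rotmat, scores = scores,
         variance_explained = colSums(L^2) / nrow(L),
         bootstrap_ci = ci, k = k),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor model: %d factors, %d variables\n", x$k,
              nrow(x$loadings)))
  cat("variance explained:",
      paste(sprintf("%.3f", x$variance_explained), collapse = ", "), "\n")
  print(round(x$loadings, 2))
  invisible(x)
}

# minimum-residual extraction on a correlation matrix
efa_minres <- function(R, k, warn = TRUE) {
  p <- nrow(R)
  loadings_from <- function(psi) {
    Rr <- R
    diag(Rr) <- 1 - psi
    e <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  }
  objective <- function(psi) {
    L <- loadings_from(psi)
    res <- R - tcrossprod(L)
    diag(res) <- 0
    sum(res^2)
  }
  smc <- 1 - 1 / diag(solve_ridge(R))  # squared multiple correlations
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = 0.005, upper = 1,
                      control = list(maxit = 500))
  psi <- opt$par
  if (warn && any(psi <= 0.005 + 1e-12))
    warning("near-Heywood case: uniqueness clipped at 0.005")
  L <- loadings_from(psi)
  rownames(L) <- rownames(R)
  list(loadings = L, uniquenesses = psi, criterion = opt$value)
}

# varimax rotation + deterministic ordering/sign convention
varimax_sorted <- function(L) {
  k <- ncol(L)
  if (k == 1) {
    rot <- diag(1)
  } else {
    vm <- stats::varimax(L)
    L <- L %*% vm$rotmat
    rot <- vm$rotmat
  }
  ss <- colSums(L^2)
  ord <- order(-ss)
  L <- L[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      rot[, j] <- -rot[, j]
    }
  }
  colnames(L) <- paste0("F", seq_len(k))
  list(loadings = L, rotmat = rot)
}

# solve with a small ridge fallback for near-singular correlation matrices
# (possible at small n with many retained statistics)
solve_ridge <- function(R, b = diag(nrow(R))) {
  tryCatch(solve(R, b), error = function(e)
    solve(R + diag(1e-4 * mean(diag(R)), nrow(R)), b))
}

#' Tucker congruence coefficient between two loading vectors
#' @param a,b Numeric vectors of equal length.
#' @return Congruence phi in `[-1, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# align columns of Lb to reference L by the signed permutation maximizing
# total absolute congruence (exhaustive over permutations; k is small)
align_loadings <- function(Lb, L) {
  k <- ncol(L)
  C <- matrix(0, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k))
      C[i, j] <- tucker_congruence(L[, i], Lb[, j])
  perms <- all_perms(k)
  best <- perms[[which.max(vapply(perms, function(pm)
    sum(abs(C[cbind(seq_len(k), pm)])), numeric(1)))]]
  out <- Lb[, best, drop = FALSE]
  for (j in seq_len(k))
    if (C[j, best[j]] < 0) out[, j] <- -out[, j]
  out
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  unlist(lapply(seq_len(k), function(i) {
    lapply(all_perms(k - 1L), function(pm) {
      rest <- setdiff(seq_len(k), i)
      c(i, rest[pm])
    })
  }), recursive = FALSE)
}
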