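# synthetic factor-structured data
factor_data <- function(n, p, k, loading = 0.8, seed = 1) {
  withr::with_seed(seed, {
    L <- matrix(0, p, k)
    per <- floor(p / k)
    for (j in seq_len(k)) L[seq((j - 1) * per + 1, j * per), j] <- loading
    f <- matrix(rnorm(n * k), n, k)
    e <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(pmax(1 - rowSums(L^2),
                                                       0.05)))
    list(x = f %*% t(L) + e, L = L)
  })
}

test_that("complete-case filtering removes exactly the planted rows", {
  sr <- stat_registry()
  n <- 10
  tab <- as.data.frame(matrix(rnorm(n * length(sr)), n,
                              dimnames = list(NULL, sr)))
  tab <- cbind(data.frame(image_id = paste0("im", 1:n),
                          species = "s",
                          distance_cm = rep(c(2, 30), each = 5)), tab)
  tab$VCA.ML[c(2, 7)] <- NaN          # planted uniform backgrounds
  tab$CAA.Asp[9] <- Inf
  out <- filter_complete_cases(tab)
  expect_equal(nrow(out), 7L)
  ex <- attr(out, "exclusions")
  expect_equal(ex$n_excluded[ex$distance_cm == 2], 1L)
  expect_equal(ex$n_excluded[ex$distance_cm == 30], 2L)
  expect_setequal(attr(out, "excluded_images"), c("im2", "im7", "im9"))

  # all-finite table passes through unchanged
  ok <- tab[-c(2, 7, 9), ]
  expect_equal(nrow(filter_complete_cases(ok)), nrow(ok))
  # everything removed errors
  allbad <- tab
  allbad$VCA.ML <- NaN
  expect_error(filter_complete_cases(allbad), "nothing left")
})

test_that("the correlation filter keeps a mutually decorrelated set", {
  sr <- stat_registry()
  withr::with_seed(4, {
    n <- 300
    # 5 blocks of 4 near-duplicate columns
    base <- matrix(rnorm(n * 5), n, 5)
    x <- do.call(cbind, lapply(1:5, function(b)
      base[, b] + matrix(rnorm(n * 4, 0, 0.15), n, 4)))
    colnames(x) <- sr[1:20]
    tab <- cbind(data.frame(image_id = "x", species = "s",
                            distance_cm = 2), as.data.frame(x))
    out <- correlation_filter(tab, threshold = 0.6)
    kept <- attr(out, "kept_stats")
    expect_equal(length(kept), 5L)
    # exhaustive pairwise check of the survivor set
    r <- stats::cor(x[, kept])
    expect_true(all(abs(r[upper.tri(r)]) < 0.6))
  })
})

test_that("duplicate and orthogonal columns behave as expected", {
  sr <- stat_registry()
  withr::with_seed(5, {
    a <- rnorm(100)
    tab <- data.frame(a, a + rnorm(100, 0, 1e-6), rnorm(100))
    names(tab) <- sr[1:3]
    out <- correlation_filter(tab)
    expect_identical(attr(out, "kept_stats"), sr[c(1, 3)])
    zv <- data.frame(rnorm(50), rep(1, 50))
    names(zv) <- sr[1:2]
    expect_warning(correlation_filter(zv), "zero-variance")
  })
})

test_that("parallel analysis recovers planted factor counts", {
  d1 <- factor_data(200, 12, 1, loading = 0.9, seed = 2)
  expect_equal(parallel_analysis(d1$x, n_sims = 300, seed = 1)[1], 1L)
  d4 <- factor_data(200, 17, 4, loading = 0.8, seed = 3)
  expect_equal(parallel_analysis(d4$x, n_sims = 300, seed = 1)[1], 4L)
})

test_that("parallel analysis retains nothing when eigenvalues equal the null",
{
  # strict inequality: a variable equal to the simulated median keeps out
  withr::with_seed(8, {
    x <- matrix(rnorm(100 * 2), 100, 2)
    pa <- parallel_analysis(x, n_sims = 500, seed = 2)
    obs <- attr(pa, "observed_eigenvalues")
    med <- attr(pa, "median_simulated")
    expect_equal(pa[1], sum(obs > med))
    expect_lte(pa[1], 1L)
  })
})

test_that("minres EFA recovers structure and satisfies model identities", {
  d <- factor_data(400, 12, 2, loading = 0.85, seed = 6)
  efa <- fit_efa(d$x, 2, bootstrap_iters = 0)
  # rotation is orthonormal
  expect_equal(t(efa$rotation) %*% efa$rotation, diag(2), tolerance = 1e-8)
  # communality + uniqueness ~ 1 per standardized variable
  expect_equal(rowSums(efa$loadings^2) + efa$uniquenesses,
               rep(1, 12), tolerance = 0.05)
  # reconstruction of the observed correlation matrix
  R <- stats::cor(d$x)
  Rhat <- tcrossprod(efa$loadings) + diag(efa$uniquenesses)
  expect_lt(sqrt(mean((R - Rhat)[upper.tri(R)]^2)), 0.05)
  # congruence with the generating loadings after alignment
  al <- rnlscape:::align_loadings(efa$loadings, d$L)
  for (j in 1:2)
    expect_gte(tucker_congruence(al[, j], d$L[, j]), 0.95)
  # variance shares are sorted
  expect_true(all(diff(efa$variance_explained) <= 0))
})

test_that("EFA is invariant to column order and rescaling", {
  d <- factor_data(300, 10, 2, loading = 0.8, seed = 7)
  a <- fit_efa(d$x, 2, bootstrap_iters = 0)
  perm <- c(3, 1, 2, 4, 6, 5, 10, 9, 7, 8)
  scl <- seq(0.5, 5, length.out = 10)
  b <- fit_efa(sweep(d$x[, perm], 2, scl[perm], "*"), 2,
               bootstrap_iters = 0)
  bl <- b$loadings[order(perm), , drop = FALSE]
  al <- rnlscape:::align_loadings(bl, a$loadings)
  expect_equal(abs(al), abs(a$loadings), tolerance = 1e-6)
})

test_that("minres loadings agree with the ML oracle on clean data", {
  d <- factor_data(500, 10, 2, loading = 0.8, seed = 9)
  efa <- fit_efa(d$x, 2, bootstrap_iters = 0)
  ml <- stats::factanal(d$x, 2, rotation = "varimax")
  al <- rnlscape:::align_loadings(unclass(ml$loadings), efa$loadings)
  for (j in 1:2)
    expect_gte(tucker_congruence(al[, j], efa$loadings[, j]), 0.98)
})

test_that("bootstrap intervals cover the point estimate", {
  d <- factor_data(200, 8, 2, loading = 0.8, seed = 10)
  efa <- fit_efa(d$x, 2, bootstrap_iters = 100, seed = 3)
  ci <- efa$bootstrap_ci
  inside <- mean(efa$loadings >= ci[, , 1] & efa$loadings <= ci[, , 2])
  expect_gte(inside, 0.9)
  expect_true(all(ci[, , 1] <= ci[, , 2]))
})
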