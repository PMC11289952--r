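test_that("phylogenetic correlation matches hand computation", {
  # star tree: no shared history
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_equal(phylo_correlation(star), diag(3),
               ignore_attr = TRUE)

  # sisters splitting at half depth share half their path
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  C <- phylo_correlation(tr, c("a", "b", "c"))
  expect_equal(C["a", "b"], 0.5)
  expect_equal(C["a", "c"], 0)
  expect_equal(diag(C), c(a = 1, b = 1, c = 1))

  # PSD on random pure-birth trees
  for (s in 1:5) {
    tr <- withr::with_seed(s, ape::rphylo(8, 1, 0))
    ev <- eigen(phylo_correlation(tr), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= -1e-10))
  }

  expect_error(phylo_correlation(star, c("a", "zz")), "zz")
})

test_that("simulated factor scores have the declared design", {
  cm <- matrix(c(0, 1, 2, 0, 1, 2), 3, 2)
  sim <- simulate_factor_scores(cell_means = cm, n_images = 4, seed = 3)
  d <- sim$data
  expect_equal(nrow(d), 12 * 4 * 2)
  expect_equal(nlevels(d$group), 3)
  expect_setequal(unique(d$distance_cm), c(2, 30))
  expect_equal(ape::Ntip(sim$tree), 12)
  # reproducible
  sim2 <- simulate_factor_scores(cell_means = cm, n_images = 4, seed = 3)
  expect_identical(sim$data, sim2$data)
  # group means reflect the cell means (coarse check, random effects add
  # species-level noise)
  m <- tapply(d$score, list(d$group, d$distance_cm), mean)
  expect_gt(m["toxic_high", "2"], m["undefended", "2"])
})

test_that("split R-hat separates mixed from unmixed chains", {
  withr::with_seed(2, {
    good <- matrix(rnorm(4000), 1000, 4)
    expect_lt(split_rhat(good), 1.01)
    bad <- good + matrix(rep(c(0, 0, 2, 2), each = 1000), 1000, 4)
    expect_gt(split_rhat(bad), 1.3)
    drift <- matrix(seq(0, 3, length.out = 2000), 1000, 2)
    expect_gt(split_rhat(drift), 1.1)   # within-chain trend is caught
  })
})

# one shared small fit reused by the posterior-summary tests below
small_fit <- local({
  cm <- matrix(c(0, -1, -1.2, 0.3, -0.7, -0.9), 3, 2)
  sim <- simulate_factor_scores(cell_means = cm, n_images = 8, seed = 21)
  fit <- fit_distributional(sim$data, sim$tree, chains = 2,
                            draws_per_chain = 300, thin = 2, adapt = 500,
                            burn = 500, seed = 4, check = "none")
  list(fit = fit, sim = sim)
})

test_that("cell summaries and contrasts are draw-wise linear", {
  fit <- small_fit$fit
  expect_equal(nrow(fit$cells), 6)
  expect_equal(nrow(fit$mean_contrasts), 15)   # C(6,2)
  expect_equal(nrow(fit$sigma_contrasts), 15)

  bcols <- grep("^b\\[", colnames(fit$draws))
  mu <- fit$draws[, bcols] %*% t(fit$X_cells)
  # contrast(a,b) + contrast(b,c) == contrast(a,c) exactly, draw by draw
  d_ab <- mu[, 1] - mu[, 2]
  d_bc <- mu[, 2] - mu[, 3]
  d_ac <- mu[, 1] - mu[, 3]
  expect_equal(d_ab + d_bc, d_ac, tolerance = 1e-12)
  # a cell against itself is identically zero
  expect_equal(max(abs(mu[, 4] - mu[, 4])), 0)
  # interval ordering
  expect_true(all(fit$cells$lower <= fit$cells$median &
                    fit$cells$median <= fit$cells$upper))
  # diagnostics present for every sampled parameter
  expect_setequal(fit$diagnostics$parameter, colnames(fit$draws))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
})

test_that("posterior cell means agree with a Gaussian mixed-model oracle", {
  skip_if_not_installed("lme4")
  fit <- small_fit$fit
  d <- small_fit$sim$data
  ml <- lme4::lmer(score ~ group * factor(distance_cm) +
                     (1 + factor(distance_cm) | species),
                   data = d,
                   control = lme4::lmerControl(check.conv.singular =
                                                 lme4::.makeCC("ignore",
                                                               tol = 1e-4)))
  newd <- expand.grid(group = levels(d$group),
                      distance_cm = factor(c(2, 30)))
  names(newd)[2] <- "distance_cm"
  mlpred <- stats::predict(ml, newdata = data.frame(
    group = newd$group, distance_cm = as.numeric(as.character(
      newd$distance_cm))), re.form = NA)
  expect_equal(unname(fit$cells$median), unname(mlpred), tolerance = 0.35)
})

test_that("input validation catches malformed model data", {
  sim <- simulate_factor_scores(n_images = 2, seed = 5)
  d <- sim$data
  d2 <- d; d2$group <- NULL
  expect_error(fit_distributional(d2, sim$tree), "columns")
  d3 <- d; d3$distance_cm <- 2
  expect_error(fit_distributional(d3, sim$tree), "2 values")
})
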