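test_that("lambda ML matches a dense grid-search oracle", {
  for (seed in 1:5) {
    tree <- simulate_tree(40, seed = seed)
    lam_true <- c(0.2, 0.5, 0.8, 1, 0)[seed]
    y <- simulate_continuous_trait(tree, "lambda", lambda = lam_true,
                                   sigma2 = 1, seed = 100 + seed)
    est <- fit_lambda(y, tree)
    s <- ape::vcv(tree)
    grid <- seq(0, 1, length.out = 1001)
    ll <- vapply(grid, function(l) {
      C <- l * s; diag(C) <- diag(s)
      n <- length(y)
      yv <- y[tree$tip.label]
      Ci <- solve(C)
      one <- rep(1, n)
      z0 <- as.numeric(t(one) %*% Ci %*% yv) / as.numeric(t(one) %*% Ci %*% one)
      r <- yv - z0
      s2 <- as.numeric(t(r) %*% Ci %*% r) / n
      -n / 2 * log(2 * pi) - n / 2 * log(s2) -
        0.5 * determinant(C, logarithm = TRUE)$modulus[1] - n / 2
    }, 1.0)
    expect_lt(abs(est$lambda - grid[which.max(ll)]), 1.5e-3)
    expect_gte(est$logLik, max(ll) - 1e-6)
  }
})

test_that("lambda estimates agree with an established independent fitter", {
  skip_if_not_installed("phytools")
  for (seed in 1:3) {
    tree <- simulate_tree(60, seed = 10 + seed)
    y <- simulate_continuous_trait(tree, "lambda", lambda = 0.6, sigma2 = 1,
                                   seed = 200 + seed)
    est <- fit_lambda(y, tree)
    ref <- phytools::phylosig(tree, y, method = "lambda")
    expect_equal(est$lambda, ref$lambda, tolerance = 1e-3)
    expect_equal(est$logLik, ref$logL, tolerance = 1e-4)
  }
})

test_that("signal estimate satisfies its likelihood invariants", {
  tree <- simulate_tree(50, seed = 9)
  y <- simulate_continuous_trait(tree, "BM", seed = 77)
  est <- fit_lambda(y, tree)
  expect_gte(est$logLik, max(est$logLik_lambda0, est$logLik_lambda1) - 1e-8)
  expect_true(est$lambda >= 0 && est$lambda <= 1)
  expect_error(fit_lambda(setNames(rep(1, 50), tree$tip.label), tree),
               "constant")
})

test_that("Holm correction follows the step-down enumeration", {
  p <- c(0.01, 0.04, 0.03)
  expect_equal(p.adjust(p, "holm"), c(0.03, 0.06, 0.06))
  ests <- list(
    structure(list(lambda = 0.5, p_vs_0 = 0.01, p_vs_1 = 0.2),
              class = "signal_estimate"),
    structure(list(lambda = 0.6, p_vs_0 = 0.04, p_vs_1 = 0.5),
              class = "signal_estimate"),
    structure(list(lambda = 0.7, p_vs_0 = 0.03, p_vs_1 = 0.9),
              class = "signal_estimate")
  )
  tab <- lambda_lrt(ests)
  expect_equal(tab$p_vs_0_holm, c(0.03, 0.06, 0.06))
  # families corrected separately
  expect_equal(tab$p_vs_1_holm, p.adjust(c(0.2, 0.5, 0.9), "holm"))
  single <- lambda_lrt(ests[1])
  expect_equal(single$p_vs_0_holm, single$p_vs_0)
})

test_that("fitted log-likelihoods match a direct MVN density oracle", {
  tree <- simulate_tree(25, seed = 4)
  y <- simulate_continuous_trait(tree, "OU", alpha = 2, sigma2 = 1.5,
                                 z0 = 1, seed = 5)
  for (m in c("BM", "OU", "EB")) {
    fit <- fit_evomodel(y, tree, model = m)
    C <- do.call(model_covariance,
                 c(list(tree = tree, model = m), fit$params[
                   setdiff(names(fit$params), "z0")]))
    ll <- mvn_logdens_oracle(y[tree$tip.label],
                             rep(fit$params$z0, length(y)), unclass(C))
    expect_equal(fit$logLik, ll, tolerance = 1e-8)
  }
})

test_that("degenerate data is flagged, never silently fitted", {
  tree <- toy_tree3()
  y <- setNames(c(0, 0, 0), c("A", "B", "C"))
  expect_error(fit_evomodel(y, tree, "BM"), "at least 4")
  tree4 <- simulate_tree(6, seed = 1)
  y4 <- setNames(rep(2, 6), tree4$tip.label)
  expect_warning(fit <- fit_evomodel(y4, tree4, "BM"), "degenerate")
  expect_equal(fit$params$sigma2, 0)
  expect_equal(fit$convergence, "degenerate")
})

test_that("AICc and Akaike weights follow their formulas", {
  expect_equal(aicc(-10, 2, 50), 24 + 12 / 47)
  expect_error(aicc(-10, 3, 4), "undefined")

  mk_fit <- function(model, ll, k) {
    structure(list(model = model, logLik = ll, k = k, n = 50,
                   convergence = "ok"), class = "evo_fit")
  }
  # equal AICc -> equal weights
  cmp <- compare_models(list(mk_fit("BM", -10, 2), mk_fit("OU", -10, 2)))
  expect_equal(cmp$weight, c(0.5, 0.5))
  cmp3 <- compare_models(list(mk_fit("BM", -10, 2), mk_fit("OU", -9, 3),
                              mk_fit("EB", -12, 3)))
  expect_equal(sum(cmp3$weight), 1)
  expect_equal(cmp3$AICc, c(aicc(-10, 2, 50), aicc(-9, 3, 50),
                            aicc(-12, 3, 50)))
  expect_equal(cmp3$delta_AICc, cmp3$AICc - min(cmp3$AICc))
  expect_equal(which(cmp3$selected), which.min(cmp3$AICc))
  mismatched <- list(mk_fit("BM", -10, 2),
                     structure(list(model = "OU", logLik = -9, k = 3, n = 40),
                               class = "evo_fit"))
  expect_error(compare_models(mismatched), "identical data")
})

test_that("OU recovery: strong selection is estimated within a factor of two", {
  alphas <- vapply(1:10, function(rep) {
    tree <- simulate_tree(150, seed = 300 + rep)
    y <- simulate_continuous_trait(tree, "OU", alpha = 5, sigma2 = 1,
                                   seed = 400 + rep)
    fit_evomodel(y, tree, "OU")$params$alpha
  }, 1.0)
  expect_gt(median(alphas), 2.5)
  expect_lt(median(alphas), 10)
})

test_that("cross-tree summaries report medians and selection percentages", {
  per_tree <- tibble::tibble(
    tree_id = rep(1:4, each = 2),
    dimension = rep(c("Dim1", "Dim2"), 4),
    lambda = c(0.9, 0.1, 0.95, 0.2, 0.92, 0.15, 0.99, 0),
    p_vs_0_holm = rep(c(0.001, 0.8), 4),
    p_vs_1_holm = rep(c(0.5, 0.001), 4),
    best_model = c("OU", "BM", "OU", "BM", "BM", "BM", "OU", "BM")
  )
  out <- summarise_across_trees(per_tree)
  expect_equal(out$pct_BM[out$dimension == "Dim2"], 100)
  expect_equal(out$pct_OU[out$dimension == "Dim1"], 75)
  expect_equal(out$median_lambda[out$dimension == "Dim1"],
               median(c(0.9, 0.95, 0.92, 0.99)))
  expect_equal(out$pct_sig_vs_0[out$dimension == "Dim1"], 100)
})
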