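design_fixture <- function(n = 24, seed = 5, score_kind = "uniqueness") {
  sim <- simulate_study(study_config(n_species = n, n_trees = 2), seed = seed)
  lh <- life_history_score(sim$table)
  space <- retain_kaiser(famd_fit(lh$table))
  scores <- niche_scores(space, k = 3)
  list(design = build_design(lh$table, scores, score_kind),
       table = lh$table, scores = scores, trees = sim$trees)
}

test_that("design matrix scales the response and codes dummies as declared", {
  fx <- design_fixture()
  d <- fx$design
  expect_equal(min(d$y), 0)
  expect_equal(max(d$y), 1)
  cont <- c("life_history", "adult_mass", "diet_breadth", "habitat_breadth",
            "temperature_mean", "temperature_range", "precipitation_mean",
            "precipitation_range")
  for (v in cont) {
    expect_equal(mean(d$X[, v]), 0, tolerance = 1e-10)
    expect_equal(sd(d$X[, v]), 1, tolerance = 1e-10)
  }
  # 1 intercept + 8 continuous + 5 guild + 2 stratum + 2 activity = 18
  expect_equal(ncol(d$X), 18)
  expect_true(all(c("trophic_guild_gummivore", "trophic_guild_insectivore",
                    "trophic_guild_folivore_frugivore",
                    "trophic_guild_frugivore", "trophic_guild_omnivore")
                  %in% colnames(d$X)))
  expect_false("trophic_guild_folivore" %in% colnames(d$X))
  expect_false("foraging_stratum_arboreal" %in% colnames(d$X))
  expect_false("activity_cycle_nocturnal" %in% colnames(d$X))

  # min-max scaling on a hand example
  sc <- tibble::tibble(species = c("a", "b", "c"),
                       uniqueness = c(2, 4, 6), specialisation = c(1, 1, 2))
  tab <- fx$table[1:3, ]
  tab$species <- c("a", "b", "c")
  d2 <- build_design(tab, sc, "uniqueness")
  expect_equal(unname(d2$y), c(0, 0.5, 1))
})

test_that("GLS with identity covariance reduces to ordinary least squares", {
  fx <- design_fixture()
  fit <- pgls_fit(fx$design, C = NULL)
  df <- as.data.frame(fx$design$X[, -1])
  df$y <- fx$design$y
  ref <- summary(lm(y ~ ., data = df))$coefficients
  expect_equal(fit$coefficients$estimate, unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$std_error, unname(ref[, 2]), tolerance = 1e-10)
  expect_equal(fit$coefficients$p_value, unname(ref[, 4]), tolerance = 1e-10)

  fit_eye <- pgls_fit(fx$design, C = diag(nrow(fx$design$X)))
  expect_equal(fit_eye$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("GLS coefficients match the explicit matrix-algebra oracle", {
  set.seed(8)
  n <- 5
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  rownames(X) <- letters[1:n]
  y <- setNames(rnorm(n), letters[1:n])
  A <- matrix(rnorm(n * n), n)
  C <- crossprod(A) + diag(n)
  dimnames(C) <- list(letters[1:n], letters[1:n])
  design <- list(y = y, X = X, species = letters[1:n], terms = colnames(X),
                 score_kind = "uniqueness")
  fit <- pgls_fit(design, C)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  resid <- y - X %*% beta
  s2 <- as.numeric(t(resid) %*% Ci %*% resid) / (n - 3)
  expect_equal(fit$sigma2, s2, tolerance = 1e-10)
  se <- sqrt(s2 * diag(solve(t(X) %*% Ci %*% X)))
  expect_equal(fit$coefficients$std_error, unname(se), tolerance = 1e-10)
})

test_that("GLS agrees with an established independent fitter under BM", {
  skip_if_not_installed("nlme")
  fx <- design_fixture(n = 30, seed = 11)
  tree <- fx$trees[[1]]
  C <- unclass(model_covariance(tree, "BM"))[fx$design$species,
                                             fx$design$species]
  fit <- pgls_fit(fx$design, C)
  df <- as.data.frame(fx$design$X[, -1])
  df$y <- fx$design$y
  df$species <- fx$design$species
  ref <- nlme::gls(
    y ~ . - species,
    data = df,
    correlation = ape::corBrownian(1, phy = tree, form = ~species),
    method = "ML"
  )
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
})

test_that("rank-deficient designs error with the collinear columns named", {
  fx <- design_fixture()
  d <- fx$design
  d$X <- cbind(d$X, dup_col = d$X[, "adult_mass"])
  expect_error(pgls_fit(d), "dup_col")
})

test_that("coefficient recovery: known effects in BM noise are unbiased", {
  fx <- design_fixture(n = 80, seed = 21)
  tree <- fx$trees[[1]]
  beta <- rep(0, ncol(fx$design$X))
  names(beta) <- colnames(fx$design$X)
  beta["adult_mass"] <- 0.5
  beta["trophic_guild_gummivore"] <- 1
  C <- unclass(model_covariance(tree, "BM"))[fx$design$species,
                                             fx$design$species]
  ests <- vapply(1:30, function(rep) {
    y <- simulate_response(fx$design, beta, tree, sigma2 = 0.5,
                           seed = 700 + rep)
    d <- fx$design
    d$y <- y[d$species]
    fit <- pgls_fit(d, C)
    fit$coefficients$estimate[fit$coefficients$term == "adult_mass"]
  }, 1.0)
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.5), 2 * mc_se + 1e-8)
})

test_that("multi-tree PGLS counts significance deterministically", {
  fx <- design_fixture(n = 30, seed = 2)
  trees <- rep(fx$trees[1], 4)
  out <- multi_tree_pgls(fx$table, fx$scores, "uniqueness", trees)
  expect_equal(nrow(out), 18)
  expect_equal(out$term[1], "(Intercept)")
  expect_true(all(out$n_significant %in% c(0L, 4L)))
  expect_true(all(out$n_trees == 4))
  # sign tags consistent with estimates
  tagged <- out[out$effect_sign != "", ]
  expect_true(all(sign(tagged$median_estimate) ==
                    ifelse(tagged$effect_sign == "+", 1, -1)))

  per_tree <- attr(out, "per_tree")
  one <- per_tree[per_tree$tree_id == 1, ]
  expect_equal(one$p_holm, p.adjust(one$p_value, "holm"))
})

test_that("estimates are invariant to dummy reference choice up to reparameterisation", {
  fx <- design_fixture(n = 30, seed = 6)
  d <- fx$design
  fit <- pgls_fit(d)
  # refit with frugivore as the guild reference; folivore dummy appears
  tab <- fx$table
  sch <- niche_schema()
  X2 <- d$X
  keep <- setdiff(colnames(X2), "trophic_guild_frugivore")
  X2 <- X2[, keep]
  X2 <- cbind(X2, trophic_guild_folivore =
                as.numeric(tab$trophic_guild == "folivore"))
  d2 <- list(y = d$y, X = X2, species = d$species, terms = colnames(X2),
             score_kind = d$score_kind)
  fit2 <- pgls_fit(d2)
  g <- function(f, term) f$coefficients$estimate[f$coefficients$term == term]
  # contrasts between non-reference levels are preserved
  expect_equal(g(fit, "trophic_guild_gummivore") - g(fit, "trophic_guild_omnivore"),
               g(fit2, "trophic_guild_gummivore") - g(fit2, "trophic_guild_omnivore"),
               tolerance = 1e-8)
  # old-reference coefficient is minus the new folivore coefficient
  expect_equal(g(fit, "trophic_guild_frugivore"),
               -g(fit2, "trophic_guild_folivore"), tolerance = 1e-8)
})
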