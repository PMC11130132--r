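coords1d <- function(x, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(x))
  tibble::tibble(species = ids, Dim1 = x)
}

test_that("uniqueness reproduces hand-enumerated neighbour distances", {
  sp <- coords1d(c(0, 1, 3))
  expect_equal(uniqueness_scores(sp, k = 1)$uniqueness, c(1, 1, 2))
  expect_equal(uniqueness_scores(sp, k = 2)$uniqueness, c(2, 1.5, 2.5))

  twin <- coords1d(c(0, 0, 5))
  expect_equal(uniqueness_scores(twin, k = 1)$uniqueness[1:2], c(0, 0))

  expect_error(uniqueness_scores(sp, k = 3), "at least 4")
  expect_error(uniqueness_scores(sp, k = 0), ">= 1")
})

test_that("specialisation is distance to the arithmetic centroid", {
  sp <- coords1d(c(0, 1, 3))
  expect_equal(specialisation_scores(sp)$specialisation,
               c(4 / 3, 1 / 3, 5 / 3))
  # species at the centroid scores zero; mirror pair scores equally
  sym <- coords1d(c(-2, 0, 2))
  s <- specialisation_scores(sym)$specialisation
  expect_equal(s[2], 0)
  expect_equal(s[1], s[3])
})

test_that("uniqueness and specialisation match brute-force oracles", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    d <- sample(2:5, 1)
    X <- matrix(rnorm(n * d), n, d,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
    sp <- dplyr::bind_cols(tibble::tibble(species = rownames(X)),
                           tibble::as_tibble(X, .name_repair = "minimal"))
    names(sp)[-1] <- paste0("Dim", 1:d)
    k <- sample(1:4, 1)
    expect_equal(uniqueness_scores(sp, k = k)$uniqueness,
                 uniqueness_oracle(X, k), tolerance = 1e-12)
    centroid <- colMeans(X)
    expect_equal(specialisation_scores(sp)$specialisation,
                 apply(X, 1, function(z) sqrt(sum((z - centroid)^2))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("scores are invariant under translation and rotation", {
  set.seed(12)
  X <- matrix(rnorm(30), 15, 2, dimnames = list(sprintf("s%02d", 1:15), NULL))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- X %*% R + matrix(c(5, -3), 15, 2, byrow = TRUE)
  as_sp <- function(M) {
    out <- dplyr::bind_cols(tibble::tibble(species = rownames(X)),
                            tibble::as_tibble(M, .name_repair = "minimal"))
    names(out)[-1] <- c("Dim1", "Dim2"); out
  }
  expect_equal(uniqueness_scores(as_sp(X), 3)$uniqueness,
               uniqueness_scores(as_sp(Y), 3)$uniqueness, tolerance = 1e-10)
  expect_equal(specialisation_scores(as_sp(X))$specialisation,
               specialisation_scores(as_sp(Y))$specialisation,
               tolerance = 1e-10)
})

test_that("uniqueness is monotone in k and under neighbour removal", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%02d", 1:20), NULL))
  sp <- dplyr::bind_cols(tibble::tibble(species = rownames(X)),
                         tibble::as_tibble(X, .name_repair = "minimal"))
  names(sp)[-1] <- c("Dim1", "Dim2")
  u <- lapply(1:6, function(k) uniqueness_scores(sp, k)$uniqueness)
  for (k in 2:6) expect_true(all(u[[k]] >= u[[k - 1]] - 1e-12))

  # removing the focal species' nearest neighbour cannot decrease its score
  d1 <- sqrt(colSums((t(X[-1, , drop = FALSE]) - X[1, ])^2))
  nn <- rownames(X)[-1][which.min(d1)]
  u_before <- uniqueness_scores(sp, 3)$uniqueness[1]
  u_after <- uniqueness_scores(sp[sp$species != nn, ], 3)$uniqueness[1]
  expect_gte(u_after, u_before - 1e-12)
})

test_that("neighbour robustness correlates uniqueness across k", {
  set.seed(31)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(sprintf("s%02d", 1:30), NULL))
  sp <- dplyr::bind_cols(tibble::tibble(species = rownames(X)),
                         tibble::as_tibble(X, .name_repair = "minimal"))
  names(sp)[-1] <- c("Dim1", "Dim2")
  tab <- neighbour_robustness(sp, ks = c(1, 3, 5, 10))
  expect_equal(tab$r[tab$k == 5], 1)
  expect_true(all(tab$r > 0))
  expect_error(neighbour_robustness(coords1d(c(0, 1, 3)), ks = c(1, 100)),
               "k >= n")
})

test_that("ranks are a permutation and outliers follow the Tukey fence", {
  set.seed(77)
  X <- matrix(rnorm(50), 25, 2, dimnames = list(sprintf("s%02d", 1:25), NULL))
  sp <- dplyr::bind_cols(tibble::tibble(species = rownames(X)),
                         tibble::as_tibble(X, .name_repair = "minimal"))
  names(sp)[-1] <- c("Dim1", "Dim2")
  sc <- niche_scores(sp, k = 3)
  expect_setequal(sc$rank_uniqueness, 1:25)
  expect_setequal(sc$rank_specialisation, 1:25)
  expect_equal(sc$species[sc$rank_uniqueness == 1],
               sc$species[which.max(sc$uniqueness)])
  q <- quantile(sc$uniqueness, c(0.25, 0.75), names = FALSE)
  expect_equal(sc$outlier_uniqueness,
               sc$uniqueness > q[2] + 1.5 * (q[2] - q[1]))

  # equal scores: no spread, no outliers, ranks broken by species id
  grid <- tibble::tibble(species = c("b", "a", "d", "c"),
                         Dim1 = c(0, 1, 0, 1), Dim2 = c(0, 0, 1, 1))
  sg <- niche_scores(grid, k = 1)
  expect_false(any(sg$outlier_uniqueness))
  expect_false(any(sg$outlier_specialisation))
  expect_equal(sg$species[order(sg$rank_uniqueness)], c("a", "b", "c", "d"))
})

test_that("rank_extremes returns ordered top and bottom lists", {
  sp <- coords1d(c(0, 1, 3, 7, 8), ids = letters[1:5])
  sc <- niche_scores(sp, k = 1)
  ex <- rank_extremes(sc, "uniqueness", m = 2)
  expect_equal(nrow(ex$top), 2)
  expect_equal(ex$top$rank, 1:2)
  expect_equal(ex$bottom$rank, 4:5)
})

test_that("subset rerun restricts the neighbour pool, coordinates fixed", {
  set.seed(55)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(sprintf("s%02d", 1:30), NULL))
  sp <- dplyr::bind_cols(tibble::tibble(species = rownames(X)),
                         tibble::as_tibble(X, .name_repair = "minimal"))
  names(sp)[-1] <- c("Dim1", "Dim2")
  full <- subset_rerun(sp, rownames(X), k = 3)
  expect_equal(full$scores$uniqueness, niche_scores(sp, 3)$uniqueness)
  expect_equal(full$n_overlap_bottom, 10)

  sub <- subset_rerun(sp, rownames(X)[1:12], k = 3)
  expect_equal(nrow(sub$scores), 12)
  # fewer candidate neighbours can only raise uniqueness
  full_u <- niche_scores(sp, 3)
  expect_true(all(sub$scores$uniqueness >=
                    full_u$uniqueness[match(sub$scores$species,
                                            full_u$species)] - 1e-12))
  expect_error(subset_rerun(sp, rownames(X)[1:3], k = 5), "too small")
  expect_error(subset_rerun(sp, c("nope"), k = 1), "not in space")
})
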