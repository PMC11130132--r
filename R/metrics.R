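#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
NULL

# Accept a niche_space, a famd coordinates tibble, or a bare species+Dim table
as_coord_matrix <- function(space) {
  if (inherits(space, "niche_space")) space <- space$coordinates
  stopifnot(is.data.frame(space))
  ids <- as.character(space[[1]])
  X <- as.matrix(space[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

# pairwise Euclidean distances; stable ordering by (distance, species id)
ordered_neighbour_dists <- function(X, i, candidates) {
  d <- sqrt(colSums((t(X[candidates, , drop = FALSE]) - X[i, ])^2))
  ord <- order(d, rownames(X)[candidates], method = "radix")
  d[ord]
}

#' Niche uniqueness: mean distance to the k nearest neighbours
#'
#' For each species, the mean Euclidean distance to its `k` nearest
#' neighbours in the retained niche space (self excluded). Low scores mark
#' species whose trait combinations are shared by many others — a proxy for
#' intense interspecific competition; high scores mark isolated, unique
#' niches. Distance ties at the k-th neighbour are broken by species
#' identifier so results are deterministic.
#'
#' @param space A `niche_space`, or a tibble whose first column is the
#'   species id and remaining columns are coordinates.
#' @param k Number of nearest neighbours (default 5).
#' @return A tibble with `species` and `uniqueness`.
#' @export
uniqueness_scores <- function(space, k = 5) {
  X <- as_coord_matrix(space)
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop(sprintf("k = %d requires at least %d species, have %d",
                           k, k + 1, n))
  u <- vapply(seq_len(n), function(i) {
    d <- ordered_neighbour_dists(X, i, setdiff(seq_len(n), i))
    mean(d[seq_len(k)])
  }, 1.0)
  tibble::tibble(species = rownames(X), uniqueness = u)
}

#' Niche specialisation: distance to the centroid of niche space
#'
#' Euclidean distance from each species to the centroid (per-dimension mean
#' of all species' coordinates). Species near the centroid have average,
#' generalist trait combinations; distant species are specialised.
#'
#' @inheritParams uniqueness_scores
#' @return A tibble with `species` and `specialisation`.
#' @export
specialisation_scores <- function(space) {
  X <- as_coord_matrix(space)
  if (nrow(X) < 2) stop("specialisation requires at least 2 species")
  centroid <- colMeans(X)
  s <- sqrt(rowSums(sweep(X, 2, centroid)^2))
  tibble::tibble(species = rownames(X), specialisation = as.numeric(s))
}

#' Robustness of uniqueness to the neighbour count
#'
#' Recomputes uniqueness for several values of `k` and correlates each
#' vector with the reference (`k_ref = 5`) vector. Strong correlations mean
#' the uniqueness ranking does not depend on the choice of `k`.
#'
#' @inheritParams uniqueness_scores
#' @param ks Neighbour counts to compare.
#' @param k_ref Reference neighbour count.
#' @return A tibble with `k` and `r` (Pearson correlation with the
#'   reference scores).
#' @export
neighbour_robustness <- function(space, ks = c(1, 3, 5, 10, 100), k_ref = 5) {
  X <- as_coord_matrix(space)
  n <- nrow(X)
  bad <- ks[ks >= n]
  if (length(bad) > 0) {
    stop(sprintf("k >= n for k = %s (n = %d)", paste(bad, collapse = ", "), n))
  }
  ref <- uniqueness_scores(space, k = k_ref)$uniqueness
  tibble::tibble(
    k = ks,
    r = vapply(ks, function(k) {
      stats::cor(uniqueness_scores(space, k = k)$uniqueness, ref)
    }, 1.0)
  )
}

#' Full per-species niche score table with ranks and outlier flags
#'
#' Combines uniqueness and specialisation, ranks each (rank 1 = highest
#' score, ties broken by species id), and flags outliers by the Tukey upper
#' fence: score greater than `Q3 + 1.5 * IQR`.
#'
#' @inheritParams uniqueness_scores
#' @return A tibble with `species`, `uniqueness`, `specialisation`,
#'   `rank_uniqueness`, `rank_specialisation`, `outlier_uniqueness`,
#'   `outlier_specialisation`. Carries class `niche_scores`.
#' @export
niche_scores <- function(space, k = 5) {
  u <- uniqueness_scores(space, k = k)
  s <- specialisation_scores(space)
  out <- dplyr::inner_join(u, s, by = "species")
  out$rank_uniqueness <- rank_desc(out$uniqueness, out$species)
  out$rank_specialisation <- rank_desc(out$specialisation, out$species)
  out$outlier_uniqueness <- tukey_upper_outlier(out$uniqueness)
  out$outlier_specialisation <- tukey_upper_outlier(out$specialisation)
  class(out) <- c("niche_scores", class(out))
  out
}

rank_desc <- function(x, id) {
  ord <- order(-x, id, method = "radix")
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

tukey_upper_outlier <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  x > q[2] + 1.5 * (q[2] - q[1])
}

#' Top and bottom species by a niche score
#'
#' @param scores A [niche_scores()] tibble.
#' @param score `"uniqueness"` or `"specialisation"`.
#' @param m How many species to list.
#' @return A list with `top` and `bottom` tibbles (rank, species, score).
#' @export
rank_extremes <- function(scores, score = c("uniqueness", "specialisation"),
                          m = 10) {
  score <- match.arg(score)
  rk <- scores[[paste0("rank_", score)]]
  sel <- function(idx) {
    o <- scores[idx, c("species", score)]
    o$rank <- rk[idx]
    o[order(o$rank), c("rank", "species", score)]
  }
  n <- nrow(scores)
  list(top = tibble::as_tibble(sel(which(rk <= m))),
       bottom = tibble::as_tibble(sel(which(rk > n - m))))
}

#' Recompute uniqueness within a species subset
#'
#' Restricts the candidate-neighbour pool to a subset of species (e.g. one
#' radiation) while keeping the coordinates from the full-space fit, and
#' reports overlap between the subset's lowest-scoring species and the
#' full-sample bottom list. Set `refit = TRUE` to instead refit the factor
#' analysis on the subset's rows of a trait table before scoring.
#'
#' @inheritParams uniqueness_scores
#' @param subset Character vector of species ids to keep.
#' @param m Size of the bottom lists compared in the overlap report.
#' @param refit If `TRUE`, `table` must be the 11-element trait table; the
#'   mixed-data factor analysis and Kaiser retention are redone on the
#'   subset before scoring.
#' @param table Reduced trait table, required when `refit = TRUE`.
#' @return A list with `scores` (a [niche_scores()] tibble for the subset),
#'   `overlap_bottom` (species in both bottom-`m` lists), and
#'   `n_overlap_bottom`.
#' @export
subset_rerun <- function(space, subset, k = 5, m = 10, refit = FALSE,
                         table = NULL) {
  X <- as_coord_matrix(space)
  unknown <- setdiff(subset, rownames(X))
  if (length(unknown) > 0) {
    stop("subset species not in space: ", paste(unknown, collapse = ", "))
  }
  if (length(subset) <= k) {
    stop(sprintf("subset of %d species too small for k = %d", length(subset), k))
  }
  full_scores <- niche_scores(space, k = k)
  if (refit) {
    if (is.null(table)) stop("refit = TRUE requires the trait table")
    sub_tab <- table[table[[1]] %in% subset, , drop = FALSE]
    sub_space <- retain_kaiser(famd_fit(sub_tab, id = names(table)[1]))
    sub_scores <- niche_scores(sub_space, k = k)
  } else {
    coords <- if (inherits(space, "niche_space")) space$coordinates else space
    sub_coords <- coords[coords[[1]] %in% subset, , drop = FALSE]
    sub_scores <- niche_scores(sub_coords, k = k)
  }
  full_bottom <- rank_extremes(full_scores, "uniqueness", m = m)$bottom$species
  sub_bottom <- rank_extremes(sub_scores, "uniqueness",
                              m = min(m, nrow(sub_scores)))$bottom$species
  ov <- intersect(sub_bottom, full_bottom)
  list(scores = sub_scores, overlap_bottom = ov, n_overlap_bottom = length(ov))
}

#' Ranked score plot with outlier highlighting
#'
#' @param object A [niche_scores()] tibble.
#' @param score Which score to plot.
#' @param ... Unused.
#' @return A ggplot of ranked scores, outliers in red.
#' @export
autoplot.niche_scores <- function(object,
                                  score = c("uniqueness", "specialisation"),
                                  ...) {
  score <- match.arg(score)
  df <- tibble::tibble(
    rank = object[[paste0("rank_", score)]],
    value = object[[score]],
    outlier = object[[paste0("outlier_", score)]]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                   colour = .data$outlier)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "Rank (1 = highest)", y = score) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
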