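#' Build the PGLS design for a niche-score regression
#'
#' Assembles the regression of a niche score on the 11 niche elements.
#' The response (uniqueness or specialisation) is min-max scaled to
#' `[0, 1]`; continuous elements are centred and scaled to unit variance;
#' categorical elements become treatment dummies with fixed reference
#' levels: folivore for trophic guild (5 dummies), arboreal for foraging
#' stratum (2) and nocturnal for activity cycle (2). With the intercept the
#' design has 18 terms. Column order is deterministic.
#'
#' @param table The reduced 11-element trait tibble (species id first).
#' @param scores A [niche_scores()] tibble (or anything with `species` and
#'   the requested score column).
#' @param score_kind `"uniqueness"` or `"specialisation"`.
#' @param schema A [niche_schema()].
#' @return A `pgls_design` list: `y` (scaled response), `X` (model matrix,
#'   rownames = species), `species`, `terms`, `score_kind`.
#' @export
build_design <- function(table, scores,
                         score_kind = c("uniqueness", "specialisation"),
                         schema = niche_schema()) {
  score_kind <- match.arg(score_kind)
  ids <- as.character(table[[1]])
  sc <- scores[match(ids, scores$species), score_kind, drop = TRUE]
  if (anyNA(sc)) stop("scores missing for some species in the table")
  rng <- range(sc)
  if (rng[1] == rng[2]) stop("constant response: cannot min-max scale")
  y <- (sc - rng[1]) / (rng[2] - rng[1])

  cont <- intersect(schema_element_names(schema),
                    names(table)[vapply(table, is.numeric, TRUE)])
  refs <- c(trophic_guild = "folivore", foraging_stratum = "arboreal",
            activity_cycle = "nocturnal")
  cols <- list(`(Intercept)` = rep(1, nrow(table)))
  for (v in cont) {
    x <- table[[v]]
    if (stats::sd(x) == 0) stop("constant continuous element: ", v)
    cols[[v]] <- as.numeric(scale(x))
  }
  for (v in names(schema$categorical)) {
    x <- as.character(table[[v]])
    unseen <- setdiff(unique(x), schema$categorical[[v]])
    if (length(unseen) > 0) {
      stop("unseen categorical level(s) in '", v, "': ",
           paste(unseen, collapse = ", "))
    }
    for (lev in setdiff(schema$categorical[[v]], refs[[v]])) {
      cols[[paste0(v, "_", lev)]] <- as.numeric(x == lev)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  structure(list(y = stats::setNames(y, ids), X = X, species = ids,
                 terms = colnames(X), score_kind = score_kind),
            class = "pgls_design")
}

#' Phylogenetic generalized least squares fit
#'
#' Fits `y = X beta + e` with `e ~ MVN(0, sigma2 * C)` by generalized least
#' squares: `beta = (X' C^-1 X)^-1 X' C^-1 y`, residual variance from the
#' GLS quadratic form on `n - p` degrees of freedom, standard errors from
#' the inverse weighted cross-product, and two-sided t tests. `C = I`
#' recovers ordinary least squares. Implemented by Cholesky whitening; the
#' covariance scale cancels, so any positive multiple of `C` gives the same
#' fit.
#'
#' @param design A [build_design()] object, or a list with `y` and `X`.
#' @param C Phylogenetic covariance aligned to the design's species order
#'   (e.g. [model_covariance()]); `NULL` means identity.
#' @return A `pgls_fit` object; `tidy()` gives the coefficient table
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`), `glance()`
#'   the fit summary (`sigma2`, `logLik`, `n`, `p`).
#' @export
pgls_fit <- function(design, C = NULL) {
  y <- design$y
  X <- design$X
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need more species than terms (n = ", n, ", p = ", p, ")")
  if (!is.null(C)) {
    C <- as.matrix(C)
    if (!is.null(rownames(C)) && !is.null(rownames(X))) {
      if (!all(rownames(X) %in% rownames(C))) {
        stop("covariance is missing species present in the design")
      }
      C <- C[rownames(X), rownames(X)]
    }
    L <- chol_safe(C)
    yw <- forwardsolve(t(L), y)
    Xw <- forwardsolve(t(L), X)
  } else {
    yw <- y; Xw <- X
  }
  qr_X <- qr(Xw)
  if (qr_X$rank < p) {
    bad <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_X, yw)
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  df <- n - p
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr_X))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  structure(
    list(
      coefficients = tibble::tibble(
        term = colnames(X), estimate = as.numeric(beta),
        std_error = se, statistic = as.numeric(tstat),
        p_value = as.numeric(pval)
      ),
      sigma2 = sigma2, df = df, n = n, p = p,
      score_kind = design$score_kind
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<pgls_fit> ", x$n, " species, ", x$p, " terms, sigma2 = ",
      format(x$sigma2, digits = 4), "\n", sep = "")
  print(x$coefficients, n = x$p)
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, n = x$n, p = x$p, df = x$df)
}

#' Tree-replicated PGLS with Holm correction and significance counting
#'
#' Runs the niche-score PGLS across a sample of phylogenies. Within each
#' tree, p-values are Holm-corrected across the full term family (the
#' intercept included); across trees, per-term medians of estimates and
#' adjusted p-values are reported (rounded to 4 decimals) along with the
#' count of trees in which the term's adjusted p-value is below `alpha`.
#'
#' @inheritParams build_design
#' @param trees List of `ape::phylo` trees covering the table's species.
#' @param alpha Significance level for the counts.
#' @param correlation `"BM"` (Brownian covariance from each tree) or
#'   `"lambda"` (per-tree ML Pagel's-lambda covariance estimated from the
#'   response).
#' @return A `multi_pgls` tibble: `term`, `median_estimate`,
#'   `median_p_holm`, `n_significant`, `n_trees`, `effect_sign` (`"+"`,
#'   `"-"`, or `""` when the median adjusted p is not below `alpha`).
#' @export
multi_tree_pgls <- function(table, scores,
                            score_kind = c("uniqueness", "specialisation"),
                            trees, alpha = 0.05,
                            correlation = c("BM", "lambda"),
                            schema = niche_schema()) {
  score_kind <- match.arg(score_kind)
  correlation <- match.arg(correlation)
  if (inherits(trees, "phylo")) trees <- list(trees)
  design <- build_design(table, scores, score_kind, schema)
  per_tree <- purrr::map_dfr(seq_along(trees), function(ti) {
    tr <- reconcile_trait_tree(trees[[ti]], design$species)
    s <- ape::vcv(tr)[design$species, design$species]
    C <- if (correlation == "BM") {
      s
    } else {
      lam <- fit_lambda(design$y, tr)$lambda
      lambda_C0(s, lam)
    }
    fit <- pgls_fit(design, C)
    tab <- fit$coefficients
    tab$p_holm <- stats::p.adjust(tab$p_value, method = "holm")
    tab$tree_id <- ti
    tab
  })
  out <- per_tree |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median_estimate = round(stats::median(.data$estimate), 4),
      median_p_holm = round(stats::median(.data$p_holm), 4),
      n_significant = sum(.data$p_holm < alpha),
      n_trees = dplyr::n(),
      .groups = "drop"
    )
  out$effect_sign <- ifelse(out$median_p_holm < alpha,
                            ifelse(out$median_estimate > 0, "+", "-"), "")
  out <- out[match(design$terms, out$term), ]
  attr(out, "per_tree") <- per_tree
  attr(out, "score_kind") <- score_kind
  class(out) <- c("multi_pgls", class(out))
  out
}

#' Coefficient dot plot for a tree-replicated PGLS summary
#'
#' @param object A [multi_tree_pgls()] tibble.
#' @param ... Unused.
#' @return A ggplot of median estimates, coloured by significance.
#' @export
autoplot.multi_pgls <- function(object, ...) {
  df <- object[object$term != "(Intercept)", ]
  df$term <- stats::reorder(df$term, df$median_estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_estimate, y = .data$term,
                                   colour = .data$effect_sign != "")) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "Median estimate across trees", y = NULL) +
    ggplot2::theme_minimal()
}
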