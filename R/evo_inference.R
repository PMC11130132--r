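# Profiled multivariate-normal likelihood machinery shared by the signal and
# evolutionary-model fits. Given a unit-rate covariance C0, the mean z0 and
# rate sigma2 have closed-form (GLS) profiles, leaving 1-D searches over the
# remaining shape parameter (lambda, alpha or r). Cholesky solves throughout;
# a singular factorisation triggers a 1e-10 diagonal jitter with a warning.

chol_safe <- function(C) {
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) {
    warning("covariance Cholesky failed; adding 1e-10 diagonal jitter")
    L <- chol(C + diag(1e-10 * mean(diag(C)), nrow(C)))
  }
  L
}

# log-likelihood of y ~ MVN(z0 * 1, sigma2 * C0) with z0, sigma2 profiled out
profile_loglik <- function(y, C0) {
  n <- length(y)
  L <- chol_safe(C0)
  logdet <- 2 * sum(log(diag(L)))
  w1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  wy <- backsolve(L, forwardsolve(t(L), y))
  z0 <- sum(w1 * y) / sum(w1)
  resid <- y - z0
  q <- sum(resid * backsolve(L, forwardsolve(t(L), resid)))
  sigma2 <- q / n
  if (sigma2 <= 0) {
    return(list(logLik = Inf, sigma2 = 0, z0 = z0, degenerate = TRUE))
  }
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - logdet / 2 - n / 2
  list(logLik = ll, sigma2 = sigma2, z0 = z0, degenerate = FALSE)
}

align_trait <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait vector must be named by tip label")
  missing_t <- setdiff(tree$tip.label, names(trait))
  if (length(missing_t) > 0) {
    stop("trait missing for tip(s): ", paste(utils::head(missing_t, 5), collapse = ", "))
  }
  trait[tree$tip.label]
}

lambda_C0 <- function(s, lambda) {
  C <- lambda * s
  diag(C) <- diag(s)
  C
}

#' Maximum-likelihood Pagel's lambda
#'
#' Estimates the phylogenetic signal of a continuous trait as the
#' multiplier `lambda` on the off-diagonal entries of the Brownian-motion
#' covariance, by maximum likelihood over `lambda` in `[0, 1]`. The root
#' state and rate are profiled out in closed form at each `lambda`; the
#' 1-D likelihood is maximised by a grid pre-scan followed by a bounded
#' golden-section refinement, so multimodal profiles are handled.
#' `lambda = 0` corresponds to a star tree (no signal), `lambda = 1` to
#' plain Brownian motion.
#'
#' @param trait Named numeric vector (names = tip labels).
#' @param tree An `ape::phylo`.
#' @param grid_n Pre-scan grid size over `[0, 1]`.
#' @param s Optional precomputed `ape::vcv(tree)` matrix.
#' @return A `signal_estimate` list: `lambda`, `sigma2`, `z0`, `logLik`,
#'   `logLik_lambda0`, `logLik_lambda1`, `p_vs_0`, `p_vs_1` (likelihood
#'   ratio tests against the boundary values, chi-squared df 1), `n`.
#' @export
fit_lambda <- function(trait, tree, grid_n = 21, s = NULL) {
  if (is.null(s)) s <- ape::vcv(tree)
  y <- align_trait(trait, tree)
  n <- length(y)
  if (n < 4) stop("fit_lambda requires at least 4 tips")
  if (stats::sd(y) == 0) stop("constant trait: lambda is unidentifiable")

  f <- function(lam) profile_loglik(y, lambda_C0(s, lam))$logLik
  grid <- seq(0, 1, length.out = grid_n)
  ll_grid <- vapply(grid, f, 1.0)
  i_best <- which.max(ll_grid)
  lo <- grid[max(1, i_best - 1)]
  hi <- grid[min(grid_n, i_best + 1)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(grid[i_best], ll_grid[i_best]),
                c(0, ll_grid[1]), c(1, ll_grid[grid_n]))
  best <- cand[which.max(cand[, 2]), ]
  fit <- profile_loglik(y, lambda_C0(s, best[1]))

  ll0 <- ll_grid[1]; ll1 <- ll_grid[grid_n]
  lrt0 <- max(0, 2 * (fit$logLik - ll0))
  lrt1 <- max(0, 2 * (fit$logLik - ll1))
  structure(
    list(
      lambda = best[1], sigma2 = fit$sigma2, z0 = fit$z0,
      logLik = fit$logLik, logLik_lambda0 = ll0, logLik_lambda1 = ll1,
      p_vs_0 = stats::pchisq(lrt0, df = 1, lower.tail = FALSE),
      p_vs_1 = stats::pchisq(lrt1, df = 1, lower.tail = FALSE),
      n = n
    ),
    class = "signal_estimate"
  )
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("<signal_estimate> lambda = %.4f (logLik %.3f; p vs 0: %.3g, p vs 1: %.3g)\n",
              x$lambda, x$logLik, x$p_vs_0, x$p_vs_1))
  invisible(x)
}

#' @export
tidy.signal_estimate <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, z0 = x$z0, logLik = x$logLik,
    p_vs_0 = x$p_vs_0, p_vs_1 = x$p_vs_1, n = x$n
  )
}

#' Holm-Bonferroni adjusted likelihood-ratio tests across dimensions
#'
#' Collects the boundary tests of a set of [fit_lambda()] estimates (one
#' per niche dimension, fitted on the same tree) and applies the Holm
#' step-down correction within each test family: the `lambda = 0` tests
#' form one family and the `lambda = 1` tests another.
#'
#' @param estimates A list of `signal_estimate` objects.
#' @param dimensions Optional labels (default `Dim1..DimD`).
#' @return A tibble: `dimension`, `lambda`, `p_vs_0`, `p_vs_1`,
#'   `p_vs_0_holm`, `p_vs_1_holm`.
#' @export
lambda_lrt <- function(estimates, dimensions = NULL) {
  if (inherits(estimates, "signal_estimate")) estimates <- list(estimates)
  if (is.null(dimensions)) dimensions <- paste0("Dim", seq_along(estimates))
  p0 <- vapply(estimates, `[[`, 1.0, "p_vs_0")
  p1 <- vapply(estimates, `[[`, 1.0, "p_vs_1")
  tibble::tibble(
    dimension = dimensions,
    lambda = vapply(estimates, `[[`, 1.0, "lambda"),
    p_vs_0 = p0, p_vs_1 = p1,
    p_vs_0_holm = stats::p.adjust(p0, method = "holm"),
    p_vs_1_holm = stats::p.adjust(p1, method = "holm")
  )
}

#' Fit a model of continuous trait evolution by maximum likelihood
#'
#' Fits one of three models of trait evolution on a phylogeny:
#' Brownian motion (BM: constant rate `sigma2`), Ornstein-Uhlenbeck (OU:
#' attraction of strength `alpha` towards an optimum constrained to the
#' root state) or early burst (EB: rate declining through time as
#' `exp(r t)`, `r < 0`). The rate and root state have closed-form profiles,
#' so OU and EB reduce to bounded 1-D searches over `alpha` (log scale,
#' `[1e-8/T, 50/T]`) and `r` (`[-10/T, -1e-8/T]`), each preceded by a
#' log-spaced pre-scan to guard against multimodality. Parameter counts for
#' AICc are 2 (BM) and 3 (OU, EB).
#'
#' @inheritParams fit_lambda
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param n_scan Pre-scan size for the 1-D searches.
#' @return An `evo_fit` list: `model`, `params` (named list), `logLik`,
#'   `k`, `n`, `convergence` (`"ok"`, `"boundary"` or `"degenerate"`).
#' @export
fit_evomodel <- function(trait, tree, model = c("BM", "OU", "EB"),
                         n_scan = 20, s = NULL) {
  model <- match.arg(model)
  if (is.null(s)) s <- ape::vcv(tree)
  y <- align_trait(trait, tree)
  n <- length(y)
  if (n < 4) stop("fit_evomodel requires at least 4 tips")
  T_height <- max(diag(s))

  if (model == "BM") {
    fit <- profile_loglik(y, s)
    conv <- if (fit$degenerate) "degenerate" else "ok"
    if (fit$degenerate) warning("BM fit degenerate: zero residual variance")
    return(structure(list(model = "BM",
                          params = list(sigma2 = fit$sigma2, z0 = fit$z0),
                          logLik = fit$logLik, k = 2L, n = n,
                          convergence = conv),
                     class = "evo_fit"))
  }
  if (!is_ultrametric_tol(tree)) {
    stop(model, " fit requires an ultrametric tree")
  }

  if (model == "OU") {
    C0_of <- function(th) {  # th = log(alpha)
      a <- exp(th)
      1 / (2 * a) * exp(-2 * a * (T_height - s)) * (1 - exp(-2 * a * s))
    }
    lo <- log(1e-8 / T_height); hi <- log(50 / T_height)
    par_name <- "alpha"; par_of <- exp
  } else {
    C0_of <- function(th) {  # th = log(-r)
      r <- -exp(th)
      (exp(r * s) - 1) / r
    }
    lo <- log(1e-8 / T_height); hi <- log(10 / T_height)
    par_name <- "r"; par_of <- function(th) -exp(th)
  }

  f <- function(th) profile_loglik(y, C0_of(th))$logLik
  grid <- seq(lo, hi, length.out = n_scan)
  ll_grid <- vapply(grid, f, 1.0)
  i_best <- which.max(ll_grid)
  opt <- stats::optimize(f, lower = grid[max(1, i_best - 1)],
                         upper = grid[min(n_scan, i_best + 1)],
                         maximum = TRUE, tol = 1e-8)
  th_hat <- if (opt$objective >= ll_grid[i_best]) opt$maximum else grid[i_best]
  fit <- profile_loglik(y, C0_of(th_hat))
  conv <- "ok"
  if (fit$degenerate) conv <- "degenerate"
  else if (i_best %in% c(1L, n_scan) &&
           abs(th_hat - grid[i_best]) < 1e-6) conv <- "boundary"

  params <- list(sigma2 = fit$sigma2, z0 = fit$z0)
  params[[par_name]] <- par_of(th_hat)
  structure(list(model = model, params = params, logLik = fit$logLik,
                 k = 3L, n = n, convergence = conv),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  ps <- paste(names(x$params), format(unlist(x$params), digits = 4),
              sep = " = ", collapse = ", ")
  cat(sprintf("<evo_fit %s> logLik %.3f (%s) [%s]\n", x$model, x$logLik, ps,
              x$convergence))
  invisible(x)
}

#' @export
tidy.evo_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' @export
glance.evo_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, k = x$k, n = x$n,
                 convergence = x$convergence)
}

#' Small-sample AIC
#'
#' `AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param logLik Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size.
#' @return The AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare evolutionary-model fits by AICc weight
#'
#' Computes AICc, delta-AICc and Akaike weights
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` for a set of fits of
#' the same trait on the same tree; the lowest-AICc model is selected.
#'
#' @param fits A list of [fit_evomodel()] objects on identical data.
#' @return A tibble with class `evo_model_comparison`: `model`, `logLik`,
#'   `k`, `AICc`, `delta_AICc`, `weight`, `selected`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "evo_fit")) fits <- list(fits)
  ns <- vapply(fits, function(f) as.numeric(f$n), 1.0)
  if (length(unique(ns)) != 1) stop("fits are not on identical data (n differs)")
  a <- vapply(fits, function(f) aicc(f$logLik, f$k, f$n), 1.0)
  delta <- a - min(a)
  w <- exp(-delta / 2); w <- w / sum(w)
  out <- tibble::tibble(
    model = vapply(fits, `[[`, "", "model"),
    logLik = vapply(fits, `[[`, 1.0, "logLik"),
    k = vapply(fits, function(f) as.integer(f$k), 1L),
    AICc = a, delta_AICc = delta, weight = w,
    selected = a == min(a)
  )
  class(out) <- c("evo_model_comparison", class(out))
  out
}

#' Phylogenetic signal and evolutionary-mode fits across a tree sample
#'
#' For every tree and every retained niche dimension: estimates Pagel's
#' lambda with boundary likelihood-ratio tests (Holm-corrected across
#' dimensions within each tree), fits BM, OU and EB, and selects the best
#' model by AICc. The shared-path matrix is computed once per tree.
#'
#' @param space A `niche_space` (or coordinates tibble, species id first).
#' @param trees A list of `ape::phylo` trees (tips matching the species).
#' @param dims Dimension columns to analyse (default: all).
#' @return A tibble with one row per tree x dimension: `tree_id`,
#'   `dimension`, `lambda`, `p_vs_0`, `p_vs_1`, `p_vs_0_holm`,
#'   `p_vs_1_holm`, `best_model`, per-model AICc weights, and the selected
#'   model's parameters.
#' @export
evo_across_trees <- function(space, trees, dims = NULL) {
  coords <- if (inherits(space, "niche_space")) space$coordinates else space
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(dims)) dims <- setdiff(names(coords), names(coords)[1])
  ids <- as.character(coords[[1]])

  purrr::map_dfr(seq_along(trees), function(ti) {
    tree <- trees[[ti]]
    rec <- reconcile_trait_tree(tree, ids)
    s <- ape::vcv(rec)
    sig <- lapply(dims, function(d) {
      y <- stats::setNames(coords[[d]], ids)
      fit_lambda(y, rec, s = s)
    })
    lrt <- lambda_lrt(sig, dimensions = dims)
    rows <- purrr::map_dfr(seq_along(dims), function(j) {
      y <- stats::setNames(coords[[dims[j]]], ids)
      fits <- lapply(c("BM", "OU", "EB"), function(m)
        fit_evomodel(y, rec, model = m, s = s))
      cmp <- compare_models(fits)
      best <- fits[[which(cmp$selected)[1]]]
      tibble::tibble(
        dimension = dims[j],
        lambda = sig[[j]]$lambda,
        p_vs_0 = lrt$p_vs_0[j], p_vs_1 = lrt$p_vs_1[j],
        p_vs_0_holm = lrt$p_vs_0_holm[j], p_vs_1_holm = lrt$p_vs_1_holm[j],
        best_model = best$model,
        weight_BM = cmp$weight[cmp$model == "BM"],
        weight_OU = cmp$weight[cmp$model == "OU"],
        weight_EB = cmp$weight[cmp$model == "EB"],
        sigma2 = best$params$sigma2,
        alpha = if (best$model == "OU") best$params$alpha else NA_real_,
        r = if (best$model == "EB") best$params$r else NA_real_
      )
    })
    dplyr::mutate(rows, tree_id = ti, .before = 1)
  })
}

# prune/reorder a tree to a set of species ids (quiet; used in loops)
reconcile_trait_tree <- function(tree, ids) {
  norm <- function(x) gsub("_", " ", x, fixed = TRUE)
  keep <- norm(tree$tip.label) %in% norm(ids)
  if (!any(keep)) stop("no overlap between tree tips and species ids")
  tr <- if (all(keep)) tree else ape::drop.tip(tree, tree$tip.label[!keep])
  tr$tip.label <- ids[match(norm(tr$tip.label), norm(ids))]
  tr
}

#' Summarise signal and model selection across trees
#'
#' @param per_tree Output of [evo_across_trees()].
#' @param alpha Significance level applied to the Holm-adjusted boundary
#'   tests.
#' @return A tibble per dimension: `median_lambda`, percentage of trees in
#'   which each of BM/OU/EB is AICc-selected, and the percentage of trees
#'   where each boundary test is significant. Class
#'   `evo_tree_summary`.
#' @export
summarise_across_trees <- function(per_tree, alpha = 0.05) {
  out <- per_tree |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(
      n_trees = dplyr::n(),
      median_lambda = stats::median(.data$lambda),
      pct_BM = 100 * mean(.data$best_model == "BM"),
      pct_OU = 100 * mean(.data$best_model == "OU"),
      pct_EB = 100 * mean(.data$best_model == "EB"),
      pct_sig_vs_0 = 100 * mean(.data$p_vs_0_holm < alpha),
      pct_sig_vs_1 = 100 * mean(.data$p_vs_1_holm < alpha),
      .groups = "drop"
    )
  class(out) <- c("evo_tree_summary", class(out))
  out
}

#' Stacked bar chart of model support across trees
#'
#' @param object An [summarise_across_trees()] tibble.
#' @param ... Unused.
#' @return A ggplot: percentage of trees selecting each model, per
#'   dimension.
#' @export
autoplot.evo_tree_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object,
                            cols = c("pct_BM", "pct_OU", "pct_EB"),
                            names_to = "model", values_to = "pct")
  df$model <- sub("pct_", "", df$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dimension, y = .data$pct,
                                   fill = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Niche dimension", y = "% of trees selecting model") +
    ggplot2::theme_minimal()
}
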