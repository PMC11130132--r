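#' Factor analysis of mixed data on the niche elements
#'
#' Decomposes a table of mixed quantitative and categorical variables into
#' orthogonal components, the PCA-like construction for mixed data:
#' quantitative columns are centred and scaled to unit (population) variance;
#' each categorical level becomes an indicator column divided by the square
#' root of its relative frequency, then centred. The SVD of this expanded
#' matrix (scaled by `1/sqrt(n)`) gives eigenvalues whose total equals
#' `q + sum(K_j - 1)` where `q` is the number of quantitative variables and
#' `K_j` the number of observed levels of categorical variable `j`. With the
#' 11-element primate schema (8 quantitative, levels 3/3/6) the total
#' inertia is 17.
#'
#' Component signs are fixed deterministically: each component is oriented
#' so that its largest-magnitude column loading is positive.
#'
#' @param data A complete tibble: one id column (default `species`), numeric
#'   columns treated as quantitative, character/factor columns as
#'   categorical.
#' @param id Name of the species identifier column.
#' @return An object of class `famd`: list with `eigenvalues`, `coordinates`
#'   (tibble, species by `Dim1..DimM` principal coordinates whose
#'   per-component population variance equals the eigenvalue), `loadings`
#'   (column by component matrix of right singular vectors),
#'   `column_variable` (which input variable each expanded column belongs
#'   to), `expanded` (the centred weighted expanded matrix), `n`, and the
#'   variable typing.
#' @examples
#' tab <- tibble::tibble(species = letters[1:6],
#'                       x = c(1, 2, 3, 4, 5, 6.5),
#'                       g = c("a", "a", "b", "b", "c", "c"))
#' fit <- famd_fit(tab)
#' sum(fit$eigenvalues)  # 1 quantitative + (3 - 1) levels = 3
#' @export
famd_fit <- function(data, id = "species") {
  stopifnot(id %in% names(data))
  ids <- as.character(data[[id]])
  vars <- setdiff(names(data), id)
  if (length(vars) == 0) stop("no variables to analyse")
  n <- nrow(data)
  is_quant <- vapply(data[vars], is.numeric, TRUE)
  quant <- vars[is_quant]
  categ <- vars[!is_quant]
  if (n < 3) stop("famd_fit requires at least 3 rows")
  if (anyNA(data[vars])) stop("famd_fit requires a complete table")

  blocks <- list()
  col_var <- character(0)
  for (v in quant) {
    x <- data[[v]]
    s <- stats::sd(x) * sqrt((n - 1) / n)  # population sd, FAMD convention
    if (s == 0) stop("constant quantitative column: ", v)
    blocks[[v]] <- matrix((x - mean(x)) / s, ncol = 1,
                          dimnames = list(NULL, v))
    col_var <- c(col_var, v)
  }
  for (v in categ) {
    x <- as.character(data[[v]])
    levs <- sort(unique(x))
    observed_levels <- levs
    declared <- levels(data[[v]])
    if (!is.null(declared) && length(setdiff(declared, levs)) > 0) {
      warning(sprintf("famd_fit: dropping unobserved level(s) of '%s': %s",
                      v, paste(setdiff(declared, levs), collapse = ", ")))
    }
    p <- vapply(levs, function(l) mean(x == l), 1.0)
    if (any(p * n == 1)) {
      warning(sprintf("famd_fit: '%s' has singleton level(s): %s",
                      v, paste(levs[p * n == 1], collapse = ", ")))
    }
    ind <- vapply(levs, function(l) as.numeric(x == l) / sqrt(p[[l]]),
                  numeric(n))
    ind <- scale(ind, center = TRUE, scale = FALSE)
    colnames(ind) <- paste0(v, "=", levs)
    blocks[[v]] <- ind
    col_var <- c(col_var, rep(v, length(levs)))
  }
  Z <- do.call(cbind, blocks)

  sv <- svd(Z / sqrt(n))
  eig <- sv$d^2
  V <- sv$v
  # deterministic sign: largest-|loading| column positive per component
  for (j in seq_len(ncol(V))) {
    pivot <- which.max(abs(V[, j]))
    if (V[pivot, j] < 0) {
      V[, j] <- -V[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- Z %*% V   # principal coordinates: per-component pop. variance = eigenvalue
  dim_names <- paste0("Dim", seq_along(eig))
  colnames(coords) <- dim_names
  rownames(V) <- colnames(Z)
  colnames(V) <- dim_names

  structure(
    list(
      eigenvalues = eig,
      coordinates = dplyr::bind_cols(
        tibble::tibble(species = ids),
        tibble::as_tibble(coords)
      ),
      loadings = V,
      column_variable = stats::setNames(col_var, colnames(Z)),
      expanded = Z,
      n = n,
      quantitative = quant,
      categorical = categ,
      id = id
    ),
    class = "famd"
  )
}

#' @export
print.famd <- function(x, ...) {
  cat("<famd> ", x$n, " species, ", length(x$quantitative), " quantitative + ",
      length(x$categorical), " categorical variables\n", sep = "")
  cat("  total inertia: ", format(sum(x$eigenvalues)), "\n", sep = "")
  cat("  eigenvalues:   ", paste(format(round(utils::head(x$eigenvalues, 5), 3)),
                                 collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.famd <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    pct_variance = 100 * x$eigenvalues / sum(x$eigenvalues),
    cum_pct_variance = cumsum(100 * x$eigenvalues / sum(x$eigenvalues))
  )
}

#' @export
glance.famd <- function(x, ...) {
  tibble::tibble(
    n_species = x$n,
    n_quantitative = length(x$quantitative),
    n_categorical = length(x$categorical),
    total_inertia = sum(x$eigenvalues),
    n_kaiser = sum(x$eigenvalues > 1)
  )
}

#' Retain niche dimensions by the Kaiser criterion
#'
#' Keeps every component with eigenvalue strictly greater than 1, the
#' retained components defining the niche space used by all downstream
#' metrics and comparative analyses.
#'
#' @param model A fitted [famd_fit()] object.
#' @return An object of class `niche_space`: list with `coordinates`
#'   (species by retained `Dim` columns), `eigenvalues`, `pct_variance`,
#'   `cum_pct_variance`, `n_dimensions`, and `contributions` (element by
#'   dimension percentages from [variable_contributions()]).
#' @export
retain_kaiser <- function(model) {
  stopifnot(inherits(model, "famd"))
  keep <- which(model$eigenvalues > 1)
  if (length(keep) == 0) {
    stop("Kaiser criterion retains no dimensions (no eigenvalue > 1)")
  }
  D <- max(keep)
  pct <- 100 * model$eigenvalues / sum(model$eigenvalues)
  contrib <- vapply(seq_len(D),
                    function(d) variable_contributions(model, d)$contribution,
                    numeric(length(model$quantitative) + length(model$categorical)))
  colnames(contrib) <- paste0("Dim", seq_len(D))
  contrib_tbl <- dplyr::bind_cols(
    tibble::tibble(element = variable_contributions(model, 1)$element),
    tibble::as_tibble(contrib)
  )
  structure(
    list(
      coordinates = model$coordinates[, c(1, 1 + seq_len(D)), drop = FALSE],
      eigenvalues = model$eigenvalues[seq_len(D)],
      pct_variance = pct[seq_len(D)],
      cum_pct_variance = cumsum(pct)[seq_len(D)],
      n_dimensions = D,
      contributions = contrib_tbl,
      total_inertia = sum(model$eigenvalues)
    ),
    class = "niche_space"
  )
}

#' @export
print.niche_space <- function(x, ...) {
  cat("<niche_space> ", nrow(x$coordinates), " species x ", x$n_dimensions,
      " dimensions (", format(round(x$cum_pct_variance[x$n_dimensions], 1)),
      "% of variance)\n", sep = "")
  invisible(x)
}

#' Per-variable percentage contributions to a component
#'
#' Contribution of each input variable to one component, as a percentage of
#' that component's inertia. The contribution of an expanded column equals
#' its squared loading; columns belonging to the same categorical variable
#' are summed, so a categorical element gets a single figure. Contributions
#' over the 11 elements sum to 100.
#'
#' @param model A fitted [famd_fit()] object.
#' @param dim Component index.
#' @param threshold Reporting threshold in percent for the `major` flag
#'   (default 9, the cut used when describing which elements define each
#'   dimension).
#' @return A tibble with `element`, `contribution` (percent), and `major`.
#' @export
variable_contributions <- function(model, dim, threshold = 9) {
  stopifnot(inherits(model, "famd"))
  if (dim < 1 || dim > length(model$eigenvalues)) {
    stop("index error: dim must be in 1..", length(model$eigenvalues))
  }
  per_col <- 100 * model$loadings[, dim]^2
  agg <- tapply(per_col, model$column_variable, sum)
  elems <- c(model$quantitative, model$categorical)
  tibble::tibble(
    element = elems,
    contribution = as.numeric(agg[elems]),
    major = as.numeric(agg[elems]) > threshold
  )
}

#' Scree plot of a mixed-data factor analysis
#'
#' @param object A fitted [famd_fit()] object.
#' @param ... Unused.
#' @return A ggplot: eigenvalue per component with the Kaiser line at 1.
#' @export
autoplot.famd <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = "Mixed-data factor analysis: scree") +
    ggplot2::theme_minimal()
}

#' Scatter of species in two niche dimensions
#'
#' @param space A [retain_kaiser()] niche space.
#' @param dims Integer vector of length 2: which dimensions to plot.
#' @return A ggplot of species locations.
#' @export
plot_niche_space <- function(space, dims = c(1, 2)) {
  stopifnot(inherits(space, "niche_space"), length(dims) == 2)
  d1 <- paste0("Dim", dims[1]); d2 <- paste0("Dim", dims[2])
  ggplot2::ggplot(space$coordinates,
                  ggplot2::aes(x = .data[[d1]], y = .data[[d2]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", d1, space$pct_variance[dims[1]]),
      y = sprintf("%s (%.1f%%)", d2, space$pct_variance[dims[2]])
    ) +
    ggplot2::theme_minimal()
}
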