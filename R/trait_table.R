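#' Read and validate a species-by-trait table
#'
#' Reads a CSV with one species per row, types every column against the
#' schema, and validates it: species identifiers must be unique, categorical
#' values must come from the declared level sets, and numeric cells must
#' parse. Row order is preserved. Missing cells (empty or `NA`) are allowed
#' at this stage; remove them with [drop_incomplete()].
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [niche_schema()] describing the expected columns.
#' @return A tibble with the id column first, continuous columns as doubles
#'   and categorical columns as characters.
#' @seealso [write_trait_table()], [drop_incomplete()]
#' @export
read_trait_table <- function(path, schema = niche_schema()) {
  if (!file.exists(path)) stop("trait table file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_trait_table(raw, schema)
}

#' Write a trait table to CSV
#'
#' @param table A validated trait tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Validate a trait data frame against a schema
#'
#' Used internally by [read_trait_table()]; exported so that in-memory tables
#' (e.g. from [simulate_study()]) can be checked by the same rules.
#'
#' @inheritParams read_trait_table
#' @param data A data frame with the schema's columns.
#' @return A typed, validated tibble.
#' @export
validate_trait_table <- function(data, schema = niche_schema()) {
  required <- schema_all_columns(schema)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(c(required, schema$extra_continuous), names(data))
  out <- tibble::as_tibble(data)[keep]

  ids <- as.character(out[[schema$id]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("validation error: duplicate species_id: ", paste(dup, collapse = ", "))
  }
  out[[schema$id]] <- ids

  num_cols <- intersect(c(names(schema$continuous), schema$extra_continuous), names(out))
  for (v in num_cols) {
    x <- out[[v]]
    if (!is.numeric(x)) {
      x_chr <- trimws(as.character(x))
      x_chr[x_chr == ""] <- NA_character_
      parsed <- suppressWarnings(as.numeric(x_chr))
      bad <- which(!is.na(x_chr) & is.na(parsed))
      if (length(bad) > 0) {
        stop(sprintf("cell error: unparseable numeric in column '%s', row %d: '%s'",
                     v, bad[1], x_chr[bad[1]]))
      }
      x <- parsed
    }
    if (any(is.infinite(x))) {
      stop(sprintf("validation error: non-finite value in column '%s'", v))
    }
    out[[v]] <- as.double(x)
  }
  if (any(out$adult_mass <= 0, na.rm = TRUE)) {
    stop("validation error: adult_mass must be > 0")
  }
  for (v in grep("_range$", num_cols, value = TRUE)) {
    if (any(out[[v]] < 0, na.rm = TRUE)) {
      stop(sprintf("validation error: '%s' must be >= 0", v))
    }
  }
  for (v in names(schema$categorical)) {
    x <- trimws(as.character(out[[v]]))
    x[x == ""] <- NA_character_
    bad <- setdiff(unique(x[!is.na(x)]), schema$categorical[[v]])
    if (length(bad) > 0) {
      stop(sprintf("validation error: unknown level(s) in '%s': %s (allowed: %s)",
                   v, paste(bad, collapse = ", "),
                   paste(schema$categorical[[v]], collapse = ", ")))
    }
    out[[v]] <- x
  }
  out
}

#' Remove species with any missing trait value
#'
#' Listwise deletion: species with one or more missing cells are dropped and
#' the number removed is reported via a message.
#'
#' @param table A validated trait tibble.
#' @return The complete-case tibble, same column order.
#' @export
drop_incomplete <- function(table) {
  complete <- stats::complete.cases(table)
  n_removed <- sum(!complete)
  if (n_removed == nrow(table)) {
    stop("empty-table error: every species has at least one missing cell")
  }
  if (n_removed > 0) {
    message(sprintf("drop_incomplete: removed %d of %d species with missing cells",
                    n_removed, nrow(table)))
  }
  table[complete, , drop = FALSE]
}

#' Pairwise Pearson correlation screen over continuous traits
#'
#' Computes the full Pearson correlation matrix across the continuous
#' variables and flags pairs whose absolute correlation exceeds the
#' threshold. The default threshold of 0.6 is the conventional cut for
#' treating variables as highly correlated before dimension reduction.
#'
#' @param table A complete trait tibble.
#' @param threshold Absolute correlation above which a pair is flagged.
#' @param vars Variables to screen; default all continuous schema columns
#'   present in the table.
#' @param schema A [niche_schema()].
#' @return A list with `matrix` (symmetric correlation matrix, unit
#'   diagonal) and `flagged` (tibble of pairs with `|r| > threshold`, sorted
#'   by `|r|` descending).
#' @export
correlation_screen <- function(table, threshold = 0.6, vars = NULL,
                               schema = niche_schema()) {
  if (is.null(vars)) vars <- intersect(names(schema$continuous), names(table))
  if (nrow(table) < 3) stop("correlation_screen requires at least 3 species")
  X <- as.matrix(table[vars])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "))
  }
  r <- stats::cor(X)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = vars[pairs[, 1]],
    var2 = vars[pairs[, 2]],
    r = r[pairs]
  )
  flagged <- flagged[abs(flagged$r) > threshold, , drop = FALSE]
  flagged <- flagged[order(-abs(flagged$r)), , drop = FALSE]
  list(matrix = r, flagged = tibble::as_tibble(flagged))
}

#' Collapse the life-history block to a single PCA score
#'
#' The six life-history durations are strongly intercorrelated, so they are
#' summarised by the first principal component of the z-scored block. The
#' PC1 coordinate is appended to the table as the continuous element
#' `life_history`, and the six raw durations are removed, leaving the 11
#' niche elements used downstream. The component sign is oriented so that
#' the loading of maximum longevity is positive: species with slow life
#' histories score high.
#'
#' @param table A complete trait tibble.
#' @param lh_vars The six life-history column names.
#' @param orient_var Variable whose PC1 loading is forced positive.
#' @param schema A [niche_schema()].
#' @return A list with `table` (the reduced 11-element tibble, columns in
#'   canonical order), `scores` (tibble of species and `life_history`),
#'   `pct_variance_pc1` (percent of life-history variance on PC1) and
#'   `loadings` (named PC1 loading vector).
#' @export
life_history_score <- function(table, lh_vars = NULL,
                               orient_var = "max_longevity",
                               schema = niche_schema()) {
  if (is.null(lh_vars)) lh_vars <- schema$life_history
  missing_v <- setdiff(lh_vars, names(table))
  if (length(missing_v) > 0) {
    stop("life-history variable(s) absent: ", paste(missing_v, collapse = ", "))
  }
  if (nrow(table) < 3) stop("life_history_score requires at least 3 species")
  X <- as.matrix(table[lh_vars])
  if (anyNA(X)) stop("life-history block contains missing values; drop_incomplete first")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance life-history variable(s): ",
         paste(lh_vars[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (!orient_var %in% lh_vars) orient_var <- lh_vars[1]
  if (load1[[orient_var]] < 0) {
    load1 <- -load1
  }
  score <- as.numeric(Z %*% load1)
  pct <- 100 * pc$sdev[1]^2 / sum(pc$sdev^2)

  out <- table
  out$life_history <- score
  out <- out[, setdiff(names(out), c(lh_vars, schema$extra_continuous)), drop = FALSE]
  elems <- schema_element_names(schema)
  out <- out[, c(schema$id, elems), drop = FALSE]
  list(
    table = tibble::as_tibble(out),
    scores = tibble::tibble(species = table[[schema$id]], life_history = score),
    pct_variance_pc1 = pct,
    loadings = load1
  )
}
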