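#' Trait-table schema for the primate niche dataset
#'
#' Declares the variable typing used throughout the package: which columns of
#' a species-by-trait table are quantitative (with their units) and which are
#' categorical (with their closed level sets). The default schema describes
#' the 16-trait primate table: six life-history durations in days, adult body
#' mass in grams, three categorical traits (foraging stratum, activity cycle,
#' trophic guild), two breadth counts, and four climate summaries.
#'
#' An `elevation_range` column is tolerated in input files but is not part of
#' the analytical variable set: the reduced table used downstream carries 11
#' niche elements (the life-history score plus 8 continuous and 3 categorical
#' traits minus the six raw durations).
#'
#' @param extra_continuous Character vector of additional continuous columns
#'   to accept (and ignore downstream), e.g. `"elevation_range"`.
#' @return An object of class `niche_schema`: a list with `continuous`
#'   (named character vector of units), `categorical` (named list of level
#'   sets), `life_history` (the six duration columns), and `id` (the species
#'   identifier column name).
#' @examples
#' sch <- niche_schema()
#' names(sch$categorical)
#' @export
niche_schema <- function(extra_continuous = "elevation_range") {
  continuous <- c(
    max_longevity     = "days",
    female_maturity   = "days",
    gestation_length  = "days",
    interbirth_interval = "days",
    weaning_age       = "days",
    generation_length = "days",
    adult_mass        = "g",
    diet_breadth      = "count",
    habitat_breadth   = "count",
    temperature_mean  = "degC",
    temperature_range = "degC",
    precipitation_mean  = "mm",
    precipitation_range = "mm"
  )
  categorical <- list(
    foraging_stratum = c("ground", "scansorial", "arboreal"),
    activity_cycle   = c("nocturnal", "diurnal", "cathemeral"),
    trophic_guild    = c("folivore", "frugivore", "folivore_frugivore",
                         "omnivore", "gummivore", "insectivore")
  )
  structure(
    list(
      id = "species",
      continuous = continuous,
      categorical = categorical,
      life_history = c("max_longevity", "female_maturity", "gestation_length",
                       "interbirth_interval", "weaning_age", "generation_length"),
      extra_continuous = extra_continuous
    ),
    class = "niche_schema"
  )
}

#' @export
print.niche_schema <- function(x, ...) {
  cat("<niche_schema>\n")
  cat("  id column:   ", x$id, "\n")
  cat("  continuous:  ", length(x$continuous), "variables\n")
  cat("  categorical: ", paste0(names(x$categorical), " (",
      vapply(x$categorical, length, 1L), ")", collapse = ", "), "\n")
  invisible(x)
}

# columns of the 11-element reduced table, in canonical order
schema_element_names <- function(schema) {
  cont <- setdiff(names(schema$continuous), schema$life_history)
  c("life_history", cont, names(schema$categorical))
}

schema_all_columns <- function(schema) {
  c(schema$id, names(schema$continuous), names(schema$categorical))
}
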