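# Shared fixtures: all built in code, no stored data.

toy_schema_row <- function(species, guild = "folivore", stratum = "arboreal",
                           activity = "diurnal") {
  tibble::tibble(
    species = species,
    max_longevity = 9000, female_maturity = 1200, gestation_length = 160,
    interbirth_interval = 500, weaning_age = 250, generation_length = 3000,
    adult_mass = 5000, diet_breadth = 3, habitat_breadth = 4,
    temperature_mean = 22, temperature_range = 15,
    precipitation_mean = 1500, precipitation_range = 1000,
    foraging_stratum = stratum, activity_cycle = activity,
    trophic_guild = guild
  )
}

# small valid 16-trait table with some spread in every column
toy_trait_table <- function(n = 8, seed = 42) {
  set.seed(seed)
  tab <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    toy_schema_row(
      sprintf("sp%02d", i),
      guild = rep_len(c("folivore", "frugivore", "omnivore", "gummivore",
                        "insectivore", "folivore_frugivore"), n)[i],
      stratum = rep_len(c("ground", "scansorial", "arboreal"), n)[i],
      activity = rep_len(c("nocturnal", "diurnal", "cathemeral"), n)[i]
    )
  }))
  num <- names(tab)[vapply(tab, is.numeric, TRUE)]
  for (v in num) tab[[v]] <- tab[[v]] * exp(stats::rnorm(n, sd = 0.2))
  tab$diet_breadth <- pmax(1, round(tab$diet_breadth))
  tab$habitat_breadth <- pmax(1, round(tab$habitat_breadth))
  validate_trait_table(tab)
}

# mixed table with random quantitative and categorical columns
random_mixed_table <- function(n = 12, nq = 3, ncat = 2, seed = 1) {
  set.seed(seed)
  tab <- tibble::tibble(species = sprintf("sp%02d", seq_len(n)))
  for (j in seq_len(nq)) tab[[paste0("q", j)]] <- stats::rnorm(n)
  for (j in seq_len(ncat)) {
    k <- sample(2:4, 1)
    repeat {
      x <- sample(letters[seq_len(k)], n, replace = TRUE)
      if (length(unique(x)) == k) break
    }
    tab[[paste0("c", j)]] <- x
  }
  tab
}

toy_tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# independent expanded-matrix construction (explicit loops) for the FAMD oracle
expand_mixed_oracle <- function(data, id = "species") {
  vars <- setdiff(names(data), id)
  n <- nrow(data)
  cols <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      m <- sum(x) / n
      s <- sqrt(sum((x - m)^2) / n)
      cols[[v]] <- (x - m) / s
    } else {
      for (lev in sort(unique(as.character(x)))) {
        ind <- as.numeric(x == lev)
        p <- sum(ind) / n
        w <- ind / sqrt(p)
        cols[[paste0(v, "=", lev)]] <- w - sum(w) / n
      }
    }
  }
  do.call(cbind, cols)
}

# brute-force uniqueness: all-pairs distances, sort, average first k
uniqueness_oracle <- function(X, k) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    d <- numeric(0); lab <- character(0)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- c(d, sqrt(sum((X[i, ] - X[j, ])^2)))
      lab <- c(lab, rownames(X)[j])
    }
    ord <- order(d, lab, method = "radix")
    mean(d[ord][seq_len(k)])
  }, 1.0)
}

# direct MVN log-density without Cholesky shortcuts
mvn_logdens_oracle <- function(y, mu, C) {
  n <- length(y)
  -n / 2 * log(2 * pi) - 0.5 * determinant(C, logarithm = TRUE)$modulus[1] -
    0.5 * as.numeric(t(y - mu) %*% solve(C) %*% (y - mu))
}
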