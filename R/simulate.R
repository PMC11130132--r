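#' Simulate a rooted ultrametric phylogeny
#'
#' Draws a Yule or birth-death tree with `n_tips` extant tips, optionally
#' rescaled to a fixed height so evolutionary parameters are expressed per
#' unit tree height. Reproducible given `seed`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param model `"yule"` (pure birth) or `"birth-death"`.
#' @param birth,death Speciation and extinction rates.
#' @param height If non-`NULL`, rescale the tree to this root-to-tip
#'   height.
#' @return An `ape::phylo`, tips labelled `s001, s002, ...`.
#' @export
simulate_tree <- function(n_tips, seed = NULL, model = c("yule", "birth-death"),
                          birth = 1, death = 0.5, height = 1) {
  model <- match.arg(model)
  if (n_tips < 2) stop("parameter error: n_tips must be >= 2")
  if (birth <= 0) stop("parameter error: birth rate must be > 0")
  if (model == "yule") death <- 0
  if (death < 0 || death >= birth) {
    stop("parameter error: need 0 <= death < birth")
  }
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  tree$tip.label <- sprintf("s%03d", seq_len(n_tips))
  if (!is.null(height)) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (height / depth)
  }
  tree
}

#' Simulate a continuous trait under an evolutionary model
#'
#' One draw from the multivariate normal distribution implied by
#' [model_covariance()]: `MVN(z0 * 1, C_model)`. A zero rate yields the
#' constant trait `z0`.
#'
#' @inheritParams model_covariance
#' @param z0 Root state (MVN mean).
#' @param seed Integer seed.
#' @return A named numeric vector over the tips.
#' @export
simulate_continuous_trait <- function(tree, model = "BM", sigma2 = 1,
                                      lambda = NULL, alpha = NULL, r = NULL,
                                      z0 = 0, seed = NULL, s = NULL) {
  n <- ape::Ntip(tree)
  if (!is.null(seed)) set.seed(seed)
  if (sigma2 == 0) {
    return(stats::setNames(rep(z0, n), tree$tip.label))
  }
  C <- model_covariance(tree, model = model, sigma2 = sigma2, lambda = lambda,
                        alpha = alpha, r = r, s = s)
  L <- chol_safe(unclass(C) + diag(1e-12 * max(diag(C)), n))
  x <- z0 + as.numeric(t(L) %*% stats::rnorm(n))
  stats::setNames(x, tree$tip.label)
}

#' Simulate a discrete trait by a continuous-time Markov walk
#'
#' Evolves a categorical state along the tree under a continuous-time
#' Markov (Mk) process with generator `Q` (rows sum to zero, off-diagonal
#' rates non-negative), starting at `root_state`.
#'
#' @param tree An `ape::phylo`.
#' @param Q Square rate matrix with level names as dimnames.
#' @param root_state Starting level (default: first level).
#' @param seed Integer seed.
#' @return A named character vector of tip states.
#' @export
simulate_categorical_trait <- function(tree, Q, root_state = NULL,
                                       seed = NULL) {
  levels <- rownames(Q)
  if (is.null(levels)) stop("parameter error: Q must have level names as dimnames")
  if (any(Q[row(Q) != col(Q)] < 0)) {
    stop("parameter error: off-diagonal rates must be >= 0")
  }
  if (any(abs(rowSums(Q)) > 1e-8 * max(abs(Q), 1e-12))) {
    stop("parameter error: Q rows must sum to 0")
  }
  if (is.null(root_state)) root_state <- levels[1]
  if (!root_state %in% levels) stop("parameter error: unknown root state")
  if (!is.null(seed)) set.seed(seed)

  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  state <- character(n_tip + tree$Nnode)
  state[root] <- root_state
  # preorder over edges so the parent state is set before the child's
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    st <- state[parent]
    t_left <- lens[e]
    repeat {
      rate <- -Q[st, st]
      if (rate <= 0) break
      wait <- stats::rexp(1, rate)
      if (wait >= t_left) break
      t_left <- t_left - wait
      probs <- Q[st, ]; probs[st] <- 0
      st <- sample(levels, 1, prob = probs)
    }
    state[child] <- st
  }
  stats::setNames(state[seq_len(n_tip)], tree$tip.label)
}

#' Symmetric Mk rate matrix
#'
#' @param levels Character vector of level names.
#' @param rate Transition rate between each ordered pair of levels.
#' @return A valid generator matrix.
#' @export
mk_rate_matrix <- function(levels, rate = 1) {
  K <- length(levels)
  Q <- matrix(rate, K, K, dimnames = list(levels, levels))
  diag(Q) <- -rate * (K - 1)
  Q
}

#' Configuration for the synthetic study generator
#'
#' Declares the generating model for every raw trait of the 16-trait study
#' schema, the structure of the life-history block (one latent Brownian
#' factor shared by the six durations, with the latent factor's share of
#' the block variance set by `lh_share`), the tree sample, and the
#' measurement maps that place simulated values on realistic scales
#' (days, grams, degrees, millimetres, counts).
#'
#' @param n_species Number of species (default 191, the study's sample
#'   size).
#' @param n_trees Number of trees in the sample (default 100).
#' @param lh_share Target share of life-history variance on the latent
#'   factor (default 0.8).
#' @param mk_rate Transition rate of the categorical Mk processes, per unit
#'   tree height.
#' @return A `study_config` list.
#' @export
study_config <- function(n_species = 191, n_trees = 100, lh_share = 0.8,
                         mk_rate = 2) {
  structure(
    list(
      n_species = n_species,
      n_trees = n_trees,
      tree = list(model = "yule", birth = 1, height = 1),
      lh_share = lh_share,
      lh_scale = c(max_longevity = 9000, female_maturity = 1200,
                   gestation_length = 160, interbirth_interval = 500,
                   weaning_age = 250, generation_length = 3000),
      lh_sd_frac = 0.25,
      continuous = list(
        adult_mass = list(model = "BM", sigma2 = 1, z0 = 8, map = "exp"),
        diet_breadth = list(model = "lambda", sigma2 = 1, lambda = 0.5, z0 = 3,
                            map = "count"),
        habitat_breadth = list(model = "lambda", sigma2 = 1, lambda = 0.5,
                               z0 = 4, map = "count"),
        temperature_mean = list(model = "OU", sigma2 = 20, alpha = 3, z0 = 22,
                                map = "identity"),
        temperature_range = list(model = "OU", sigma2 = 30, alpha = 3, z0 = 15,
                                 map = "nonneg"),
        precipitation_mean = list(model = "BM", sigma2 = 250000, z0 = 1500,
                                  map = "nonneg"),
        precipitation_range = list(model = "BM", sigma2 = 90000, z0 = 1000,
                                   map = "nonneg")
      ),
      categorical = list(
        foraging_stratum = c("ground", "scansorial", "arboreal"),
        activity_cycle = c("nocturnal", "diurnal", "cathemeral"),
        trophic_guild = c("folivore", "frugivore", "folivore_frugivore",
                          "omnivore", "gummivore", "insectivore")
      ),
      mk_rate = mk_rate
    ),
    class = "study_config"
  )
}

map_trait <- function(x, map) {
  switch(map,
    exp = exp(x),
    count = pmax(1, round(x)),
    nonneg = pmax(0, x),
    identity = x
  )
}

#' Simulate a full synthetic study dataset
#'
#' Generates, from a [study_config()] and a seed: a reference tree plus a
#' sample of trees on the same tip set (independent draws, emulating a
#' posterior sample of dated phylogenies), a 16-trait table simulated on
#' the reference tree (six correlated life-history durations from one
#' latent Brownian factor, continuous traits under declared BM/lambda/OU
#' models, categorical traits under Mk processes), and a truth record of
#' every generating parameter and seed. Categorical simulations are
#' re-drawn (bounded, deterministic seed offsets) until every declared
#' level is observed, so the study schema's inertia identity holds.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A list: `table` (validated 16-trait tibble), `trees`
#'   (`multiPhylo`, the first tree is the generating tree), `truth`
#'   (serialisable truth record, see [write_truth()]).
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_species
  base_seed <- as.integer(seed)

  tree <- simulate_tree(n, seed = base_seed, model = config$tree$model,
                        birth = config$tree$birth, height = config$tree$height)
  trees <- c(list(tree), lapply(seq_len(config$n_trees - 1), function(i) {
    simulate_tree(n, seed = base_seed + 1000L + i, model = config$tree$model,
                  birth = config$tree$birth, height = config$tree$height)
  }))
  class(trees) <- "multiPhylo"
  s <- ape::vcv(tree)

  # life-history block: shared latent BM factor + iid noise per duration
  latent <- simulate_continuous_trait(tree, "BM", sigma2 = 1, z0 = 0,
                                      seed = base_seed + 1L, s = s)
  v_lat <- stats::var(latent)
  tau2 <- v_lat * (1 / lh_equicorrelation(config$lh_share) - 1)
  tab <- tibble::tibble(species = tree$tip.label)
  set.seed(base_seed + 2L)
  for (v in names(config$lh_scale)) {
    z <- latent + stats::rnorm(n, sd = sqrt(tau2))
    mu <- config$lh_scale[[v]]
    tab[[v]] <- mu + mu * config$lh_sd_frac * z
  }
  for (v in names(config$continuous)) {
    cf <- config$continuous[[v]]
    x <- simulate_continuous_trait(
      tree, model = cf$model, sigma2 = cf$sigma2, lambda = cf$lambda,
      alpha = cf$alpha, z0 = cf$z0,
      seed = base_seed + 10L + which(names(config$continuous) == v), s = s
    )
    tab[[v]] <- map_trait(as.numeric(x), cf$map)
  }
  cat_seeds <- list()
  for (v in names(config$categorical)) {
    levs <- config$categorical[[v]]
    Q <- mk_rate_matrix(levs, rate = config$mk_rate)
    off <- base_seed + 100L * match(v, names(config$categorical))
    for (attempt in 0:49) {
      st <- simulate_categorical_trait(tree, Q, root_state = levs[1],
                                       seed = off + attempt)
      if (length(unique(st)) == length(levs)) break
    }
    if (length(unique(st)) < length(levs)) {
      stop("could not observe every level of ", v, " in 50 attempts; ",
           "raise mk_rate")
    }
    cat_seeds[[v]] <- off + attempt
    tab[[v]] <- as.character(st)
  }
  tab <- validate_trait_table(tab)

  truth <- list(
    seed = base_seed,
    n_species = n,
    n_trees = config$n_trees,
    tree = config$tree,
    lh = list(share = config$lh_share, tau2 = tau2,
              equicorrelation = lh_equicorrelation(config$lh_share)),
    continuous = config$continuous,
    mk_rate = config$mk_rate,
    categorical_seeds = cat_seeds
  )
  list(table = tab, trees = trees, truth = truth)
}

# PC1 share of a z-scored equicorrelated 6-block is (1 + 5 rho)/6;
# invert to get the pairwise correlation giving the target share
lh_equicorrelation <- function(share) {
  rho <- (6 * share - 1) / 5
  if (rho <= 0 || rho > 1) stop("lh_share must be in (1/6, 1]")
  rho
}

#' Simulate a PGLS response with known coefficients
#'
#' `y = X beta + e`, `e ~ MVN(0, sigma2 * C_BM(tree))` — used to verify
#' coefficient recovery by [pgls_fit()].
#'
#' @param design A [build_design()] object (or list with `X`, `species`).
#' @param beta Coefficient vector, length `ncol(X)` (recycled names from
#'   the design terms).
#' @param tree Tree over the design's species.
#' @param sigma2 Residual BM rate.
#' @param seed Integer seed.
#' @return Named numeric response vector.
#' @export
simulate_response <- function(design, beta, tree, sigma2 = 1, seed = NULL) {
  X <- design$X
  stopifnot(length(beta) == ncol(X))
  noise <- simulate_continuous_trait(tree, "BM", sigma2 = sigma2, z0 = 0,
                                     seed = seed)
  mu <- as.numeric(X %*% beta)
  stats::setNames(mu + as.numeric(noise[rownames(X)]), rownames(X))
}

#' Write / read a truth record
#'
#' Serialises the generating parameters and seeds of a synthetic dataset
#' to JSON so any dataset can be reproduced byte-identically.
#'
#' @param truth The `truth` element of [simulate_study()].
#' @param path JSON file path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
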