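#' Load and sample a set of phylogenies
#'
#' Reads rooted trees from one or more Newick (`.nwk`, `.tre`, `.txt`) or
#' NEXUS (`.nex`, `.nexus`) files — a multi-tree file yields all its trees —
#' and optionally draws a uniform sample without replacement, reproducible
#' given a seed. Tiny negative branch lengths (> -1e-9), a common artefact
#' of time-calibration, are clamped to zero with a warning.
#'
#' @param paths Character vector of tree file paths.
#' @param n_sample If non-`NULL`, the number of trees to sample.
#' @param seed Integer seed for the sample.
#' @return A list of `ape::phylo` trees (class `multiPhylo`).
#' @export
load_tree_set <- function(paths, n_sample = NULL, seed = NULL) {
  trees <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("tree file not found: ", p)
    is_nexus <- grepl("\\.(nex|nexus)$", p, ignore.case = TRUE)
    tr <- if (is_nexus) ape::read.nexus(p) else ape::read.tree(p)
    if (is.null(tr)) stop("parse error: could not read trees from ", p)
    if (inherits(tr, "phylo")) tr <- list(tr)
    trees <- c(trees, unname(as.list(tr)))
  }
  trees <- lapply(trees, clamp_tiny_negative_edges)
  if (!is.null(n_sample)) {
    if (n_sample > length(trees)) {
      stop(sprintf("cannot sample %d trees from %d available",
                   n_sample, length(trees)))
    }
    if (!is.null(seed)) {
      idx <- local({set.seed(seed); sample.int(length(trees), n_sample)})
    } else {
      idx <- sample.int(length(trees), n_sample)
    }
    trees <- trees[idx]
  }
  class(trees) <- "multiPhylo"
  trees
}

clamp_tiny_negative_edges <- function(tree) {
  neg <- tree$edge.length < 0
  if (any(neg)) {
    if (any(tree$edge.length < -1e-9)) {
      stop("tree has negative branch length(s) below -1e-9")
    }
    warning("clamping ", sum(neg), " tiny negative branch length(s) to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Check ultrametricity within a relative tolerance
#'
#' @param tree An `ape::phylo`.
#' @param tol Relative tolerance on root-to-tip depth spread.
#' @return Logical.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(depths) - min(depths)) <= tol * max(depths)
}

#' Reconcile tree tip labels with a trait table
#'
#' Matches tip labels to table species ids, translating through an optional
#' synonym map and treating underscores and spaces as equivalent. Tips
#' without trait data are pruned; species without tips are dropped; both are
#' reported. The returned table rows follow the pruned tree's tip order.
#'
#' @param tree An `ape::phylo`.
#' @param table A trait tibble whose first column is the species id.
#' @param synonyms Named character vector mapping tip labels to table ids
#'   (e.g. `c(Cebus_apella = "Sapajus apella")`).
#' @return A list with `tree` (pruned, tip labels rewritten to table ids)
#'   and `table` (rows aligned to tip order), plus `dropped_tips` and
#'   `dropped_species`.
#' @export
reconcile_and_prune <- function(tree, table, synonyms = NULL) {
  ids <- as.character(table[[1]])
  norm <- function(x) gsub("_", " ", x, fixed = TRUE)
  tip_resolved <- tree$tip.label
  if (!is.null(synonyms)) {
    hit <- tip_resolved %in% names(synonyms)
    tip_resolved[hit] <- unname(synonyms[tip_resolved[hit]])
  }
  match_idx <- match(norm(tip_resolved), norm(ids))
  keep <- !is.na(match_idx)
  if (!any(keep)) stop("no overlap between tree tips and trait table species")
  dropped_tips <- tree$tip.label[!keep]
  if (length(dropped_tips) > 0) {
    message(sprintf("reconcile_and_prune: pruning %d tip(s) without trait data",
                    length(dropped_tips)))
  }
  pruned <- if (length(dropped_tips) > 0) ape::drop.tip(tree, dropped_tips) else tree
  # rewrite tip labels to table ids
  resolved_keep <- tip_resolved[keep]
  names(resolved_keep) <- tree$tip.label[keep]
  pruned$tip.label <- ids[match(norm(resolved_keep[pruned$tip.label]), norm(ids))]
  dropped_species <- setdiff(ids, pruned$tip.label)
  if (length(dropped_species) > 0) {
    message(sprintf("reconcile_and_prune: dropping %d species without tips",
                    length(dropped_species)))
  }
  aligned <- table[match(pruned$tip.label, ids), , drop = FALSE]
  list(tree = pruned, table = aligned,
       dropped_tips = dropped_tips, dropped_species = dropped_species)
}

#' Model-implied trait covariance on a phylogeny
#'
#' Builds the tip-by-tip covariance matrix implied by a model of continuous
#' trait evolution. Writing `s_ij` for the shared root-to-MRCA path length of
#' tips i and j and `T` for tree height:
#'
#' * **BM** (Brownian motion, rate `sigma2`): `C_ij = sigma2 * s_ij`;
#'   the diagonal is `sigma2` times tip depth.
#' * **lambda** (Pagel's lambda): off-diagonal BM entries multiplied by
#'   `lambda` in `[0, 1]`; `lambda = 0` gives a diagonal (star-tree) matrix.
#' * **OU** (Ornstein-Uhlenbeck, selection strength `alpha > 0`, root state
#'   fixed, optimum constrained to the root state):
#'   `C_ij = sigma2/(2 alpha) * exp(-2 alpha (T - s_ij)) * (1 - exp(-2 alpha s_ij))`.
#'   Requires an ultrametric tree.
#' * **EB** (early burst, rate declining as `exp(r t)` with `r < 0`): branch
#'   lengths transformed as `(exp(r t2) - exp(r t1)) / r`, equivalent on an
#'   ultrametric tree to `C_ij = sigma2 * (exp(r * s_ij) - 1) / r`.
#'
#' The OU and EB limits (`alpha -> 0`, `r -> 0`) converge to BM.
#'
#' @param tree An `ape::phylo`, rooted with branch lengths.
#' @param model One of `"BM"`, `"lambda"`, `"OU"`, `"EB"`.
#' @param sigma2 Evolutionary rate (variance per unit time), > 0.
#' @param lambda Pagel's lambda in `[0, 1]` (model `"lambda"`).
#' @param alpha OU selection strength, > 0.
#' @param r EB rate-change parameter, < 0 for a decelerating burst.
#' @param s Optional precomputed shared-path matrix (`ape::vcv`), to avoid
#'   recomputation in tight loops.
#' @return A `phylo_covariance` object: the covariance matrix with
#'   attributes `model` and `params`.
#' @export
model_covariance <- function(tree, model = c("BM", "lambda", "OU", "EB"),
                             sigma2 = 1, lambda = NULL, alpha = NULL, r = NULL,
                             s = NULL) {
  model <- match.arg(model)
  if (sigma2 < 0) stop("parameter error: sigma2 must be >= 0")
  if (is.null(s)) s <- ape::vcv(tree)
  C <- switch(model,
    BM = sigma2 * s,
    lambda = {
      if (is.null(lambda) || lambda < 0 || lambda > 1) {
        stop("parameter error: lambda must be in [0, 1]")
      }
      Cl <- lambda * s
      diag(Cl) <- diag(s)
      sigma2 * Cl
    },
    OU = {
      if (is.null(alpha) || alpha <= 0) stop("parameter error: alpha must be > 0")
      if (!is_ultrametric_tol(tree)) stop("OU covariance requires an ultrametric tree")
      T_height <- max(diag(s))
      sigma2 / (2 * alpha) * exp(-2 * alpha * (T_height - s)) *
        (1 - exp(-2 * alpha * s))
    },
    EB = {
      if (is.null(r) || r >= 0) stop("parameter error: r must be < 0")
      if (!is_ultrametric_tol(tree)) stop("EB covariance requires an ultrametric tree")
      sigma2 * (exp(r * s) - 1) / r
    }
  )
  params <- list(sigma2 = sigma2, lambda = lambda, alpha = alpha, r = r)
  structure(C, model = model, params = params[!vapply(params, is.null, TRUE)],
            class = c("phylo_covariance", "matrix", "array"))
}
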