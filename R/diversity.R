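#' Taxonomic Hill number of order q
#'
#' The effective number of clusters
#' `qD = (sum_i p_i^q)^(1/(1-q))` for `q != 1`, with the continuous limit
#' `exp(-sum_i p_i log p_i)` at `q = 1`.  `q = 0` gives richness, `q = 2`
#' the inverse Simpson concentration.  Zeros are excluded and the vector is
#' renormalized internally.
#'
#' @param p Non-negative abundance vector.
#' @param q Diversity order (any non-negative number; typically 0, 1, 2).
#' @return The Hill number `qD`.
#' @export
hill_taxonomic <- function(p, q) {
  if (any(p < 0)) stop("abundances must be non-negative")
  p <- p[p > 0]
  if (!length(p)) stop("all-zero abundance vector")
  p <- p / sum(p)
  if (q == 1) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

# per-edge descendant-abundance vector; edges identified by tree$edge rows
branch_abundances <- function(tree, p) {
  nt <- length(tree$tip.label)
  if (is.null(names(p))) stop("abundances must be named by tip label")
  missing <- setdiff(names(p)[p > 0], tree$tip.label)
  if (length(missing))
    stop("tip absent from the tree: ", missing[1L])
  tipp <- stats::setNames(rep(0, nt), tree$tip.label)
  tipp[names(p)] <- p
  po <- ape::reorder.phylo(tree, "postorder")
  nodep <- c(unname(tipp), rep(0, tree$Nnode))
  for (e in seq_len(nrow(po$edge)))
    nodep[po$edge[e, 1]] <- nodep[po$edge[e, 1]] + nodep[po$edge[e, 2]]
  # an edge's descendant abundance is the accumulated mass of its child node
  nodep[tree$edge[, 2]]
}

#' Phylogenetic Hill number of order q
#'
#' Branch-length-weighted diversity in the Chao-Chiu-Jost formulation: with
#' branch abundances `a_b` (total relative abundance of the tips descending
#' from branch `b`) and mean base change
#' `Tbar = sum_b L_b a_b`, the phylogenetic Hill number is
#' `qPD = Tbar * (sum_b (L_b/Tbar) a_b^q)^(1/(1-q))` for `q != 1` and
#' `Tbar * exp(-sum_b (L_b/Tbar) a_b log a_b)` at `q = 1`.  Zero-abundance
#' branches are excluded.  At `q = 0` this reduces to Faith's PD (the sum of
#' branch lengths spanning the present tips); on a star tree with unit
#' branches it equals the taxonomic `qD`.
#'
#' @param tree An [ape::phylo] tree (or newick string) with tips labeled by
#'   cluster id.
#' @param p Named abundance vector over tips (renormalized internally).
#' @param q Diversity order.
#' @return The phylogenetic Hill number `qPD`, in branch-length units.
#' @export
hill_phylogenetic <- function(tree, p, q) {
  if (is.character(tree)) tree <- parse_newick(tree)
  p <- p[p > 0]
  if (!length(p)) stop("all-zero abundance vector")
  p <- p / sum(p)
  a <- branch_abundances(tree, p)
  L <- tree$edge.length
  keep <- a > 0 & L > 0
  a <- a[keep]; L <- L[keep]
  Tbar <- sum(L * a)
  if (q == 1) Tbar * exp(-sum((L / Tbar) * a * log(a)))
  else Tbar * (sum((L / Tbar) * a^q))^(1 / (1 - q))
}

#' Weighted UniFrac distance between two communities
#'
#' Branch formulation: `raw = sum_b L_b |a_b(A) - a_b(B)|` with branch
#' abundances as in [hill_phylogenetic()]; the normalized form (default)
#' divides by `sum_b L_b (a_b(A) + a_b(B))`, so identical communities give 0
#' and communities on disjoint star-tree tips give 1.
#'
#' @param tree An [ape::phylo] tree or newick string.
#' @param pA,pB Named abundance vectors over tips (renormalized internally).
#' @param normalized Return the normalized (default) or raw form.
#' @return The weighted UniFrac distance.
#' @export
weighted_unifrac <- function(tree, pA, pB, normalized = TRUE) {
  if (is.character(tree)) tree <- parse_newick(tree)
  if (sum(pA) <= 0 || sum(pB) <= 0) stop("all-zero abundance vector")
  aA <- branch_abundances(tree, pA / sum(pA))
  aB <- branch_abundances(tree, pB / sum(pB))
  L <- tree$edge.length
  raw <- sum(L * abs(aA - aB))
  if (!normalized) return(raw)
  denom <- sum(L * (aA + aB))
  if (denom == 0) return(0)
  raw / denom
}

#' All-pairs weighted UniFrac distance matrix
#'
#' @param tree An [ape::phylo] tree or newick string.
#' @param A Abundance matrix, samples as rows, clusters (tips) as columns.
#' @param normalized Normalized or raw form, as in [weighted_unifrac()].
#' @return Symmetric distance matrix with zero diagonal, samples in the row
#'   order of `A`.
#' @export
unifrac_matrix <- function(tree, A, normalized = TRUE) {
  if (is.character(tree)) tree <- parse_newick(tree)
  n <- nrow(A)
  if (n < 2L) stop("need at least two samples")
  # precompute branch abundances per sample
  BA <- apply(A, 1, function(p) {
    p <- stats::setNames(as.numeric(p), colnames(A))
    branch_abundances(tree, p / sum(p))
  })
  L <- tree$edge.length
  D <- matrix(0, n, n, dimnames = list(rownames(A), rownames(A)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    raw <- sum(L * abs(BA[, i] - BA[, j]))
    D[i, j] <- D[j, i] <- if (normalized) {
      den <- sum(L * (BA[, i] + BA[, j]))
      if (den == 0) 0 else raw / den
    } else raw
  }
  D
}

#' Mean nearest taxon distance
#'
#' For each present tip, the patristic distance to its nearest co-occurring
#' tip; averaged uniformly (default) or weighted by relative abundance.
#'
#' @param tree An [ape::phylo] tree or newick string.
#' @param present Character vector of present tips, or a named abundance
#'   vector (positive entries are taken as present and used as weights when
#'   `abundance_weighted`).
#' @param abundance_weighted Weight each tip's nearest-neighbour distance by
#'   its relative abundance.
#' @return The MNTD value.
#' @export
mntd <- function(tree, present, abundance_weighted = FALSE) {
  if (is.character(tree)) tree <- parse_newick(tree)
  if (is.numeric(present)) {
    w <- present[present > 0]
    tips <- names(w)
  } else {
    tips <- present
    w <- stats::setNames(rep(1, length(tips)), tips)
  }
  if (length(tips) < 2L) stop("need at least two present taxa")
  if (!all(tips %in% tree$tip.label))
    stop("tip absent from the tree: ", setdiff(tips, tree$tip.label)[1L])
  D <- patristic_distances(tree)[tips, tips, drop = FALSE]
  nearest <- vapply(seq_along(tips), function(i) min(D[i, -i]), numeric(1))
  if (abundance_weighted) sum((w / sum(w)) * nearest)
  else mean(nearest)
}

#' Diversity profiles for an abundance table
#'
#' Convenience wrapper computing `qD` (and `qPD` when a tree is given) for
#' each sample and each order in `q`.
#'
#' @param A Abundance matrix, samples as rows, clusters as columns.
#' @param q Vector of diversity orders.
#' @param tree Optional tree for the phylogenetic profile.
#' @return Data frame with columns `sample`, `q`, `qD` and (with a tree)
#'   `qPD`.
#' @export
diversity_profiles <- function(A, q = c(0, 1, 2), tree = NULL) {
  if (is.character(tree)) tree <- parse_newick(tree)
  out <- expand.grid(sample = rownames(A), q = q, stringsAsFactors = FALSE)
  out$qD <- mapply(function(s, qq)
    hill_taxonomic(A[s, ], qq), out$sample, out$q)
  if (!is.null(tree)) {
    out$qPD <- mapply(function(s, qq) {
      p <- stats::setNames(as.numeric(A[s, ]), colnames(A))
      hill_phylogenetic(tree, p, qq)
    }, out$sample, out$q)
  }
  out
}
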