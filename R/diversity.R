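#' Nei's standard genetic distance between individuals
#'
#' Individuals are treated as populations of four allele draws: the
#' reference-allele "frequency" of an individual at a locus is its dosage
#' code p (AABB = 0.5), with q = 1 - p. For a pair (x, y) over L loci,
#' J_xy = mean(p_x p_y + q_x q_y), J_x = mean(p_x^2 + q_x^2), J_y likewise,
#' and D = -ln(J_xy / sqrt(J_x J_y)). Averaging the J's over loci makes
#' cohorts with different locus counts comparable. D is invariant to
#' swapping ref/alt coding at any subset of loci.
#'
#' @param dosages complete samples x loci matrix of codes in \[0, 1\]
#'   (impute first).
#' @param cap distance substituted (with a warning) for pairs with
#'   J_xy = 0, whose distance is infinite (default 10).
#' @return symmetric `dist`-compatible square matrix with zero diagonal.
#' @export
nei_distance <- function(dosages, cap = 10) {
  stopifnot(is.matrix(dosages))
  if (anyNA(dosages)) stop_invalid("dosage matrix has missing cells; impute first")
  if (any(dosages < 0 | dosages > 1)) stop_invalid("dosage codes must lie in [0, 1]")
  P <- dosages
  Q <- 1 - dosages
  L <- ncol(P)
  Jxy <- (tcrossprod(P) + tcrossprod(Q)) / L
  Jdiag <- diag(Jxy)
  denom <- sqrt(outer(Jdiag, Jdiag))
  ratio <- Jxy / denom
  D <- -log(ratio)
  if (any(!is.finite(D))) {
    warning(sprintf("%d pair(s) with zero shared identity; distance capped at %g",
                    sum(!is.finite(D)) / 2, cap))
    D[!is.finite(D)] <- cap
  }
  D[D < 0] <- 0  # guard tiny negative rounding
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(dosages), rownames(dosages))
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via \pkg{ape}): iteratively join the
#' pair minimising the Q-criterion and reduce the matrix. Negative branch
#' lengths — an artefact of non-additive distances — are clamped to zero with
#' the deficit moved to the sister branch, preserving the path length
#' between the two leaves of the cherry.
#'
#' @param dist symmetric square distance matrix (>= 3 samples).
#' @return an unrooted `phylo` tree (leaves = sample ids).
#' @export
neighbor_joining <- function(dist) {
  stopifnot(is.matrix(dist))
  if (nrow(dist) < 3) stop_invalid("neighbour joining needs at least 3 samples")
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8))) {
    stop_invalid("distance matrix must be symmetric")
  }
  tree <- ape::nj(stats::as.dist(dist))
  clamp_negative_branches(tree)
}

# Set negative edge lengths to zero, moving the deficit onto a sister edge
# (an edge sharing the same parent node) so pairwise path lengths through
# that node are preserved where possible.
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]  # negative
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    tree$edge.length[e] <- 0
    if (length(sisters)) {
      s <- sisters[1]
      tree$edge.length[s] <- max(0, tree$edge.length[s] + deficit)
    }
  }
  tree
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over \pkg{ape} so pipeline outputs round-trip.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns the path,
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
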