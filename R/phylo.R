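#' Read an ultrametric phylogeny
#'
#' Reads a Newick or NEXUS tree (NEXUS is converted on ingest), checks
#' branch lengths, unique tip labels, and ultrametricity.
#'
#' @param source file path, or a Newick string.
#' @param tol relative tolerance on root-to-tip path equality.
#' @return an `ape::phylo` tree.
#' @export
read_phylogeny <- function(source, tol = 1e-6) {
  if (length(source) == 1 && !file.exists(source) && grepl(";", source)) {
    tree <- ape::read.tree(text = source)
  } else {
    first <- readLines(source, n = 1, warn = FALSE)
    tree <- if (grepl("^#NEXUS", first, ignore.case = TRUE))
      ape::read.nexus(source) else ape::read.tree(source)
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree)) stop("could not parse tree")
  validate_phylogeny(tree, tol = tol)
}

#' @keywords internal
validate_phylogeny <- function(tree, tol = 1e-6) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h <= 0) stop("zero-height tree")
  if (max(abs(depths - h)) / h > tol)
    stop("tree is not ultrametric (relative tip-depth spread ",
         format(max(abs(depths - h)) / h), " exceeds tolerance ", tol, ")")
  tree
}

#' Tree height (root-to-tip path length)
#' @param tree an ultrametric `phylo` tree.
#' @return scalar height.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Scaled phylogenetic covariance matrix
#'
#' The matrix of expected trait covariances under Brownian motion on an
#' ultrametric tree: entry (i, j) is the shared root-to-MRCA path length of
#' tips i and j, scaled by tree height so the diagonal is exactly 1 and
#' the phylogenetic variance component is on the same scale as the i.i.d.
#' species and residual components.
#'
#' @param tree an ultrametric `phylo` tree.
#' @return symmetric positive semi-definite matrix with unit diagonal,
#'   dimnames the tip labels.
#' @export
phylo_covariance <- function(tree) {
  tree <- validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  V <- V / tree_height(tree)
  diag(V) <- 1
  V
}

#' Pagel's lambda from variance components
#'
#' The share of total variance attributable to the phylogenetically
#' structured component: \eqn{\lambda = \sigma_p^2 / (\sigma_p^2 +
#' \sigma_s^2 + \sigma_e^2)}. For Bernoulli models \eqn{\sigma_e^2} is the
#' fixed logistic residual variance \eqn{\pi^2/3}. Vectorized over draws.
#'
#' @param sigma2_p,sigma2_s,sigma2_e non-negative variance components
#'   (phylogenetic, species i.i.d., residual).
#' @return lambda in [0, 1].
#' @export
pagels_lambda <- function(sigma2_p, sigma2_s, sigma2_e) {
  stopifnot(all(sigma2_p >= 0), all(sigma2_s >= 0), all(sigma2_e >= 0))
  tot <- sigma2_p + sigma2_s + sigma2_e
  if (any(tot == 0)) stop("all variance components are zero: lambda undefined")
  sigma2_p / tot
}

#' Match species in a data table against tree tips
#'
#' Exact-string matching after normalizing underscores to spaces on both
#' sides. Any mismatch is fatal and lists the offending names.
#'
#' @param species character vector of species labels from the data.
#' @param tree a `phylo` tree.
#' @return character vector of tip labels (tree spelling) parallel to
#'   `species`.
#' @export
match_taxa <- function(species, tree) {
  norm <- function(x) gsub("_", " ", x, fixed = TRUE)
  idx <- match(norm(species), norm(tree$tip.label))
  if (anyNA(idx)) {
    bad <- unique(species[is.na(idx)])
    stop("species absent from tree: ", paste(bad, collapse = ", "))
  }
  tree$tip.label[idx]
}

#' Prune a tree to a taxon set and rescale to unit height
#'
#' Clade-subset fits re-prune the phylogeny to the retained species and
#' rescale the covariance to the subtree height, so the phylogenetic
#' variance component remains comparable across subsets.
#'
#' @param tree a `phylo` tree.
#' @param species tip labels to keep (data spelling; matched via
#'   [match_taxa()]).
#' @return pruned `phylo` tree.
#' @export
prune_to_species <- function(tree, species) {
  tips <- unique(match_taxa(species, tree))
  if (length(tips) < 2) stop("need at least two species to prune a tree")
  ape::keep.tip(tree, tips)
}
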