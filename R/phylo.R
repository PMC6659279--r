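# Tree handling for the comparative analysis. Trees are plain ape "phylo"
# objects throughout; these wrappers add the validation, determinism and
# lambda machinery the regression layer relies on.

#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: requires unique tip
#' labels, and either fills missing branch lengths with a default (warning)
#' or refuses them. Polytomies are preserved as-is.
#'
#' @param text Newick string (used if `path` is `NULL`).
#' @param path Path to a Newick file.
#' @param missing_length Value substituted for absent branch lengths, with a
#'   warning; set `NULL` (default) to make missing lengths an error.
#' @return An [ape::phylo] object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, path = NULL, missing_length = NULL) {
  if (is.null(text) && is.null(path)) {
    stop("supply either Newick text or a file path", call. = FALSE)
  }
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("Newick file not found: %s", path), call. = FALSE)
    }
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string (unbalanced parentheses or bad syntax)",
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop(sprintf("duplicate tip labels: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (is.null(missing_length)) {
      stop("tree has missing branch lengths", call. = FALSE)
    }
    if (is.null(tree$edge.length)) {
      tree$edge.length <- rep(missing_length, nrow(tree$edge))
    } else {
      tree$edge.length[is.na(tree$edge.length)] <- missing_length
    }
    warning(sprintf("missing branch lengths set to %g", missing_length),
            call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  tree
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on the requested taxa, collapsing degree-2
#' internal nodes and summing their branch lengths, so pairwise tip path
#' distances are preserved. Taxon matching normalises underscores/spaces and
#' case; a requested taxon absent from the tree is an error listing every
#' missing name, never a silent drop.
#'
#' @param tree An [ape::phylo] object.
#' @param taxa Character vector of taxon names to keep.
#' @return Pruned [ape::phylo].
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  key <- normalize_taxon(tree$tip.label)
  want <- normalize_taxon(taxa)
  hit <- match(want, key)
  if (anyNA(hit)) {
    stop(sprintf("taxa absent from tree: %s",
                 paste(taxa[is.na(hit)], collapse = ", ")), call. = FALSE)
  }
  ape::keep.tip(tree, tree$tip.label[hit])
}

#' Randomly resolve polytomies
#'
#' Replaces every multifurcation by a uniformly random binary arrangement
#' (via [ape::multi2di()]), giving the newly created internal edges length
#' zero so that all pairwise tip path distances — and hence the Brownian
#' covariance matrix — are exactly unchanged. Deterministic for a given
#' seed; the caller's RNG stream is left untouched.
#'
#' @param tree An [ape::phylo] object, binary or polytomous.
#' @param seed Integer seed controlling the random resolution.
#' @return Strictly binary [ape::phylo].
#' @export
resolve_polytomies <- function(tree, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (is_binary_rooted(tree)) return(tree)
  with_local_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Is a tree strictly binary (as a rooted tree)?
#'
#' A rooted binary tree on n tips has exactly n - 1 internal nodes; this
#' counts the root trifurcation of an "unrooted-style" Newick string as a
#' polytomy, unlike [ape::is.binary()] on unrooted trees.
#'
#' @param tree An [ape::phylo] object.
#' @return Logical scalar.
#' @export
is_binary_rooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$Nnode == length(tree$tip.label) - 1L
}

#' Phylogenetic variance-covariance matrix
#'
#' The Brownian-motion trait covariance implied by a tree: entry (i, j) is
#' the shared root-to-MRCA path length of tips i and j, the diagonal the
#' root-to-tip distances.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return Symmetric matrix with tip labels as dimnames, in the tree's tip
#'   order.
#' @export
vcv_from_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::vcv(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` returns the full Brownian covariance, `lambda =
#' 0` the diagonal matrix of phylogenetic independence.
#'
#' @param V Symmetric covariance matrix (e.g. from [vcv_from_tree()]).
#' @param lambda Numeric in `[0, 1]`.
#' @return Transformed matrix.
#' @export
apply_lambda <- function(V, lambda) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  }
  W <- lambda * V
  diag(W) <- diag(V)
  W
}
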