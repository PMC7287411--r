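#' Read a species tree in Newick format
#'
#' Parses a rooted Newick tree and validates it for use as a neutral model:
#' every branch must carry a non-negative length (in substitutions per site),
#' leaf labels must be unique, and the total tree length must be positive.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An object of class \code{phylo} (see \pkg{ape}).
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "") else x
  n_open <- nchar(gsub("[^(]", "", txt))
  n_close <- nchar(gsub("[^)]", "", txt))
  if (n_open != n_close) {
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input")
  validate_species_tree(tree)
  tree
}

#' Validate a species tree
#'
#' @param tree A \code{phylo} object.
#' @return The tree, invisibly, if valid; otherwise an error is raised.
#' @export
validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("every branch must carry a length (substitutions/site)")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tl <- sum(tree$edge.length)
  if (!is.finite(tl) || tl <= 0) stop("total tree length must be finite and > 0")
  invisible(tree)
}

#' Total tree length
#'
#' Sum of all branch lengths, i.e. the expected number of substitutions per
#' neutral site over the whole tree.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @return Numeric scalar.
#' @export
tree_total_length <- function(tree) {
  validate_species_tree(tree)
  sum(tree$edge.length)
}

#' The eight-taxon AA-genome Oryza species tree
#'
#' The phylogeny of the eight AA-genome Oryza species (two cultivated, six
#' wild) with branch lengths in substitutions per site, shipped with the
#' package. Leaves are named by compact species tokens
#' (e.g. \code{Osativa}, \code{Orufipogon}, \code{Olongistaminata}).
#' Total tree length is 0.057882 substitutions/site.
#'
#' @return A \code{phylo} object with 8 leaves.
#' @export
oryza_aa_tree <- function() {
  path <- system.file("extdata", "oryza_aa.nwk", package = "cnsevol",
                      mustWork = TRUE)
  read_newick(path)
}

#' Scale all branch lengths of a tree
#'
#' @param tree A \code{phylo} object.
#' @param factor Positive multiplier applied to every branch length.
#' @return The scaled tree.
#' @export
scale_tree <- function(tree, factor) {
  validate_species_tree(tree)
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  tree$edge.length <- tree$edge.length * factor
  tree
}
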