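# Column scoring: observed substitutions by Fitch parsimony against the
# expected substitutions under the neutral tree (rejected-substitutions
# score RS = E - O).

.base_lookup <- local({
  lk <- integer(128)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("a")] <- 1L
  lk[utf8ToInt("C")] <- 2L; lk[utf8ToInt("c")] <- 2L
  lk[utf8ToInt("G")] <- 4L; lk[utf8ToInt("g")] <- 4L
  lk[utf8ToInt("T")] <- 8L; lk[utf8ToInt("t")] <- 8L
  lk
})

#' Encode alignment rows as base bitmasks
#'
#' A/C/G/T (case-insensitive) map to bits 1/2/4/8; gaps, N and any other
#' character map to 0 (missing data).
#'
#' @param block An \code{alignment_block}, or a named character vector of
#'   equal-length gapped sequences.
#' @return Integer matrix (species x columns) with species as rownames.
#' @export
encode_alignment <- function(block) {
  if (inherits(block, "alignment_block")) {
    texts <- block$rows$text
    names(texts) <- block$rows$species
  } else {
    texts <- block
  }
  L <- nchar(texts[[1]])
  m <- matrix(0L, nrow = length(texts), ncol = L,
              dimnames = list(names(texts), NULL))
  for (i in seq_along(texts)) {
    v <- utf8ToInt(texts[[i]])
    v[v > 127L] <- 32L
    m[i, ] <- .base_lookup[v]
  }
  m
}

#' Neutral substitution model
#'
#' Couples a species tree with a scale factor \code{lambda}: the expected
#' number of substitutions at a neutral column with species subset S present
#' is \code{lambda} times the branch-length sum of the tree restricted to S
#' (edges on paths between members of S).
#'
#' @param tree A \code{phylo} species tree with branch lengths.
#' @param lambda Positive scale multiplier (see
#'   \code{\link{estimate_neutral_scale}}).
#' @return An object of class \code{neutral_model}.
#' @export
neutral_model <- function(tree, lambda = 1) {
  validate_species_tree(tree)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            lambda > 0)
  structure(list(tree = tree, lambda = lambda,
                 total_length = sum(tree$edge.length)),
            class = "neutral_model")
}

#' Fitch parsimony counts and restricted tree lengths, vectorized by column
#'
#' For every alignment column: the minimum number of substitutions on the
#' fixed tree topology explaining the observed bases (missing data treated
#' as fully ambiguous, which yields the parsimony score of the tree
#' restricted to present species), the branch-length sum of the tree
#' restricted to present species, and the number of present species.
#'
#' @param codes Integer bitmask matrix from \code{\link{encode_alignment}},
#'   rownames are species (must all occur in the tree).
#' @param tree A \code{phylo} species tree with branch lengths.
#' @return List with numeric vectors \code{O}, \code{restricted_length},
#'   \code{n_present} (one entry per column).
#' @export
fitch_counts <- function(codes, tree) {
  sp <- rownames(codes)
  unknown <- setdiff(sp, tree$tip.label)
  if (length(unknown)) {
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  }
  L <- ncol(codes)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- matrix(0L, nn, L)
  pres <- matrix(0L, nn, L)
  idx <- match(tree$tip.label, sp)
  for (i in seq_len(ntip)) {
    if (is.na(idx[i])) {
      states[i, ] <- 15L                     # species absent from block
    } else {
      ci <- codes[idx[i], ]
      absent <- ci == 0L
      states[i, ] <- ifelse(absent, 15L, ci) # missing base = fully ambiguous
      pres[i, ] <- as.integer(!absent)
    }
  }
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  O <- integer(L)
  seen <- logical(nn)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    if (!seen[p]) {
      states[p, ] <- states[ch, ]
      pres[p, ] <- pres[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(states[p, ], states[ch, ])
      miss <- inter == 0L
      O <- O + miss
      states[p, ] <- ifelse(miss, bitwOr(states[p, ], states[ch, ]), inter)
      pres[p, ] <- pres[p, ] + pres[ch, ]
    }
  }
  root <- ntip + 1L
  npresent <- pres[root, ]
  rlen <- numeric(L)
  for (k in seq_len(nrow(edge))) {
    below <- pres[edge[k, 2], ]
    rlen <- rlen + elen[k] * ((below > 0L) & (below < npresent))
  }
  list(O = as.numeric(O), restricted_length = rlen,
       n_present = as.integer(npresent))
}

#' Score one alignment column
#'
#' Rejected-substitutions score of a single column: \code{RS = E - O} with
#' \code{O} the Fitch parsimony substitution count over present species and
#' \code{E = lambda} times the restricted tree length. A column is usable
#' when at least \code{min_species} species carry a real base (and, in block
#' scoring, when it is not coding-masked); unusable columns carry
#' \code{RS = 0}.
#'
#' @param column Named character vector of single characters (A/C/G/T/N/-),
#'   one per species.
#' @param model A \code{\link{neutral_model}}.
#' @param min_species Minimum number of present species for a usable column.
#' @return List with \code{present}, \code{O}, \code{E}, \code{RS},
#'   \code{usable}.
#' @export
score_column <- function(column, model, min_species = 4) {
  stopifnot(inherits(model, "neutral_model"), min_species >= 3)
  codes <- encode_alignment(column)
  fc <- fitch_counts(codes, model$tree)
  usable <- fc$n_present >= min_species
  E <- model$lambda * fc$restricted_length
  list(present = sort(rownames(codes)[codes[, 1] > 0L]),
       O = fc$O, E = E,
       RS = if (usable) E - fc$O else 0,
       usable = usable)
}

#' Build the coding mask from gene models
#'
#' Union of all CDS intervals, merged per chromosome. Only coding sequence
#' is masked: UTRs and introns remain eligible for conserved-element calls.
#'
#' @param gene_models List of \code{gene_model} objects (on reference
#'   coordinates).
#' @return Named list of \code{IRanges} (one per chromosome; an
#'   \code{IRanges} at position \code{start+1..end} represents the 0-based
#'   half-open interval \code{[start, end)}).
#' @export
build_coding_mask <- function(gene_models) {
  acc <- list()
  for (m in gene_models) {
    if (nrow(m$cds) == 0L) next
    ir <- IRanges::IRanges(m$cds[, 1] + 1, m$cds[, 2])
    acc[[m$chrom]] <- if (is.null(acc[[m$chrom]])) ir else
      c(acc[[m$chrom]], ir)
  }
  lapply(acc, IRanges::reduce)
}

# forward-strand 0-based reference position of every column (NA at ref gaps)
column_ref_positions <- function(block, reference) {
  r <- block$rows[block$rows$species == reference, , drop = FALSE]
  if (nrow(r) != 1L) {
    stop("block ", block$block_id, ": no row for reference species ",
         reference)
  }
  v <- utf8ToInt(r$text)
  nongap <- v != utf8ToInt("-")
  pos <- rep(NA_real_, length(v))
  k <- cumsum(nongap)
  if (r$strand == "+") {
    pos[nongap] <- r$start + k[nongap] - 1
  } else {
    # MAF minus-strand starts count on the reverse strand
    pos[nongap] <- r$src_size - 1 - (r$start + k[nongap] - 1)
  }
  pos
}

#' Score all columns of an alignment block
#'
#' @param block An \code{alignment_block} containing the reference species.
#' @param model A \code{\link{neutral_model}}.
#' @param reference Reference species identifier (element coordinates are
#'   reported on its forward strand).
#' @param mask Coding mask from \code{\link{build_coding_mask}} (or
#'   \code{NULL} for none).
#' @param min_species Minimum present species for a usable column.
#' @return data.frame with one row per column: \code{col}, \code{ref_pos}
#'   (0-based, NA at reference gaps), \code{n_present}, \code{O}, \code{E},
#'   \code{RS}, \code{masked}, \code{usable}.
#' @export
score_block <- function(block, model, reference, mask = NULL,
                        min_species = 4) {
  stopifnot(inherits(block, "alignment_block"),
            inherits(model, "neutral_model"))
  codes <- encode_alignment(block)
  fc <- fitch_counts(codes, model$tree)
  pos <- column_ref_positions(block, reference)
  chrom <- block$rows$chrom[block$rows$species == reference]
  masked <- rep(FALSE, length(pos))
  if (!is.null(mask) && !is.null(mask[[chrom]])) {
    has <- !is.na(pos)
    masked[has] <- IRanges::overlapsAny(
      IRanges::IRanges(pos[has] + 1, width = 1), mask[[chrom]])
  }
  usable <- fc$n_present >= min_species & !masked
  E <- model$lambda * fc$restricted_length
  RS <- ifelse(usable, E - fc$O, 0)
  data.frame(col = seq_along(pos), ref_pos = pos, n_present = fc$n_present,
             O = fc$O, E = E, RS = RS, masked = masked, usable = usable)
}

#' Estimate the neutral scale factor
#'
#' \code{lambda} is the mean observed parsimony substitution count per
#' fully-present, unmasked column divided by the total tree length. At
#' shallow divergences parsimony undercounts multiple hits only negligibly,
#' so on neutral data \code{lambda} is close to 1; on a mixture containing
#' constrained columns it drops below 1.
#'
#' @param blocks List of \code{alignment_block} objects.
#' @param tree Species tree.
#' @param reference Reference species (needed to apply the mask).
#' @param mask Optional coding mask.
#' @param min_columns Minimum number of fully-present unmasked columns
#'   required for a stable estimate.
#' @return Numeric \code{lambda > 0}.
#' @export
estimate_neutral_scale <- function(blocks, tree, reference, mask = NULL,
                                   min_columns = 1000) {
  validate_species_tree(tree)
  ntip <- length(tree$tip.label)
  total <- sum(tree$edge.length)
  n_cols <- 0
  sum_O <- 0
  for (b in blocks) {
    codes <- encode_alignment(b)
    fc <- fitch_counts(codes, tree)
    keep <- fc$n_present == ntip
    if (!is.null(mask)) {
      pos <- column_ref_positions(b, reference)
      chrom <- b$rows$chrom[b$rows$species == reference]
      if (!is.null(mask[[chrom]])) {
        has <- !is.na(pos)
        hit <- rep(FALSE, length(pos))
        hit[has] <- IRanges::overlapsAny(
          IRanges::IRanges(pos[has] + 1, width = 1), mask[[chrom]])
        keep <- keep & !hit
      }
    }
    n_cols <- n_cols + sum(keep)
    sum_O <- sum_O + sum(fc$O[keep])
  }
  if (n_cols < min_columns) {
    stop("too few fully-present unmasked columns for neutral-scale ",
         "estimation (", n_cols, " < ", min_columns,
         "); consider passing lambda = 1 explicitly")
  }
  lambda <- (sum_O / n_cols) / total
  if (lambda <= 0) {
    stop("estimated lambda is 0 (all columns invariant); ",
         "the neutral scale must be positive")
  }
  lambda
}
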