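# Conserved-element calling from per-column rejected-substitutions scores.

#' Call conserved elements from column scores
#'
#' Elements are maximal runs of usable columns with \code{RS > rs_floor},
#' allowing interior runs of at most \code{max_gap_run} columns that are
#' unusable or at/below the floor. A run is kept if its summed RS is positive
#' and it spans at least \code{min_element_length} reference bases. Element
#' coordinates are the reference positions of the first and last non-gap
#' reference base in the span (forward strand, 0-based half-open). Elements
#' never cross block boundaries.
#'
#' @param scores data.frame from \code{\link{score_block}}.
#' @param block The scored \code{alignment_block}.
#' @param reference Reference species identifier.
#' @param min_element_length Minimum element length in reference bases.
#' @param max_gap_run Maximum tolerated interior run of non-positive or
#'   unusable columns.
#' @param rs_floor Columns must score strictly above this RS value to seed
#'   or extend an element.
#' @return data.frame with one row per element: \code{chrom}, \code{start},
#'   \code{end}, \code{block_id}, \code{col_start}, \code{col_end},
#'   \code{n_columns}, \code{sum_rs}, \code{mean_rs}.
#' @export
call_elements <- function(scores, block, reference, min_element_length = 10,
                          max_gap_run = 3, rs_floor = 0) {
  chrom <- block$rows$chrom[block$rows$species == reference]
  if (!length(chrom)) {
    stop("block ", block$block_id, ": no row for reference species ",
         reference)
  }
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), block_id = character(),
                      col_start = integer(), col_end = integer(),
                      n_columns = integer(), sum_rs = numeric(),
                      mean_rs = numeric(), stringsAsFactors = FALSE)
  good <- which(scores$usable & scores$RS > rs_floor)
  if (!length(good)) return(empty)
  new_chain <- c(TRUE, diff(good) > max_gap_run + 1L)
  chain <- cumsum(new_chain)
  out <- lapply(split(good, chain), function(g) {
    a <- g[1]; b <- g[length(g)]
    span <- a:b
    sum_rs <- sum(scores$RS[span])
    pos <- scores$ref_pos[span]
    pos <- pos[!is.na(pos)]
    if (!length(pos) || sum_rs <= 0) return(NULL)
    start <- min(pos); end <- max(pos) + 1
    if (end - start < min_element_length) return(NULL)
    data.frame(chrom = chrom, start = start, end = end,
               block_id = block$block_id, col_start = a, col_end = b,
               n_columns = b - a + 1L, sum_rs = sum_rs,
               mean_rs = sum_rs / (b - a + 1L), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, NA)]
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Detect conserved noncoding elements across alignment blocks
#'
#' End-to-end CNS detection: builds the CDS mask from the gene models,
#' estimates the neutral scale \code{lambda} (unless given), scores every
#' block column by rejected substitutions, and calls elements. Blocks
#' lacking the reference species are skipped with a warning.
#'
#' @param blocks List of \code{alignment_block} objects.
#' @param tree Species tree (\code{phylo}) with branch lengths.
#' @param reference Reference species identifier.
#' @param gene_models Optional list of \code{gene_model} objects used to
#'   mask coding columns.
#' @param lambda Neutral scale; \code{NULL} to estimate from the data.
#' @param min_species Minimum present species for a usable column.
#' @param min_element_length,max_gap_run,rs_floor Element-calling
#'   parameters, see \code{\link{call_elements}}.
#' @param keep_scores If TRUE, per-block score tables are returned as well.
#' @return List with \code{elements} (data.frame sorted by chrom and start,
#'   with \code{element_id}), \code{lambda}, and optionally \code{scores}.
#' @export
detect_cns <- function(blocks, tree, reference, gene_models = NULL,
                       lambda = NULL, min_species = 4,
                       min_element_length = 10, max_gap_run = 3,
                       rs_floor = 0, keep_scores = FALSE) {
  validate_species_tree(tree)
  mask <- if (length(gene_models)) build_coding_mask(gene_models) else NULL
  has_ref <- vapply(blocks, function(b) reference %in% b$rows$species, NA)
  if (any(!has_ref)) {
    warning(sum(!has_ref), " block(s) lack the reference species ",
            reference, " and were skipped")
    blocks <- blocks[has_ref]
  }
  if (!length(blocks)) stop("no blocks contain the reference species")
  if (is.null(lambda)) {
    lambda <- estimate_neutral_scale(blocks, tree, reference, mask)
  }
  model <- neutral_model(tree, lambda)
  score_list <- if (keep_scores) vector("list", length(blocks)) else NULL
  parts <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    sc <- score_block(blocks[[i]], model, reference, mask, min_species)
    if (keep_scores) score_list[[i]] <- sc
    parts[[i]] <- call_elements(sc, blocks[[i]], reference,
                                min_element_length, max_gap_run, rs_floor)
  }
  elements <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  ord <- order(elements$chrom, elements$start)
  elements <- elements[ord, , drop = FALSE]
  rownames(elements) <- NULL
  if (nrow(elements)) {
    elements <- cbind(element_id = sprintf("CNS_%05d", seq_len(nrow(elements))),
                      elements, stringsAsFactors = FALSE)
  } else {
    elements <- cbind(element_id = character(0), elements)
  }
  res <- list(elements = elements, lambda = lambda)
  if (keep_scores) {
    names(score_list) <- vapply(blocks, function(b) b$block_id, "")
    res$scores <- score_list
  }
  res
}
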