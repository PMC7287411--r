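# Independent oracles and small fixture builders used across the test files.

# Brute-force minimum-substitution count for one column on a rooted tree:
# enumerates every assignment of {A,C,G,T} to the internal nodes and counts
# mismatching edges. Absent leaves are free (they can always copy their
# parent at zero cost), so their pendant edges are skipped. This is
# independent of the Fitch implementation under test.
.bf_lab_cache <- new.env(parent = emptyenv())

brute_force_parsimony <- function(codes, tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- c(1L, 2L, 4L, 8L)
  key <- as.character(nnode)
  if (is.null(.bf_lab_cache[[key]])) {
    .bf_lab_cache[[key]] <- as.matrix(expand.grid(rep(list(states), nnode)))
  }
  lab <- .bf_lab_cache[[key]]
  edge <- tree$edge
  tipcode <- integer(ntip)
  tipcode[match(rownames(codes), tree$tip.label)] <- codes[, 1]
  cost <- numeric(nrow(lab))
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1] - ntip
    ch <- edge[k, 2]
    if (ch <= ntip) {
      b <- tipcode[ch]
      if (b > 0L) cost <- cost + (lab[, p] != b)
    } else {
      cost <- cost + (lab[, p] != lab[, ch - ntip])
    }
  }
  min(cost)
}

# Brute-force upper-tail hypergeometric probability P(X >= k).
brute_force_hyper <- function(k, K, m, M) {
  xs <- k:min(K, m)
  sum(choose(m, xs) * choose(M - m, K - xs)) / choose(M, K)
}

# Exhaustive segmentation oracle for element calling on a good/bad column
# vector: enumerates all candidate spans that start and end on good columns
# and contain no interior bad run longer than max_gap, keeps the maximal
# ones, and returns their (start, end) column indices.
brute_force_segments <- function(good, max_gap) {
  idx <- which(good)
  if (!length(idx)) return(matrix(integer(0), ncol = 2))
  valid <- function(i, j) {
    if (i > j) return(FALSE)
    span <- good[i:j]
    if (!span[1] || !span[length(span)]) return(FALSE)
    r <- rle(span)
    all(r$lengths[!r$values] <= max_gap)
  }
  spans <- list()
  for (i in idx) for (j in idx[idx >= i]) {
    if (valid(i, j)) spans[[length(spans) + 1L]] <- c(i, j)
  }
  spans <- do.call(rbind, spans)
  keep <- vapply(seq_len(nrow(spans)), function(r) {
    !any(spans[, 1] <= spans[r, 1] & spans[, 2] >= spans[r, 2] &
           (spans[, 1] < spans[r, 1] | spans[, 2] > spans[r, 2]))
  }, NA)
  spans[keep, , drop = FALSE]
}

# random alignment column over the given species, with missing-data rate
random_column <- function(species, p_missing = 0.2) {
  bases <- c("A", "C", "G", "T", "N", "-")
  probs <- c(rep((1 - p_missing) / 4, 4), p_missing / 2, p_missing / 2)
  stats::setNames(sample(bases, length(species), replace = TRUE,
                         prob = probs), species)
}

# minimal two-species block for functions that only need block metadata
toy_block <- function(ref_text, other_text, chrom = "chr1", start = 0,
                      reference = "ref", id = "b1") {
  alignment_block(id, data.frame(
    species = c(reference, "other"), chrom = chrom,
    start = c(start, 0), size = nchar(gsub("-", "", c(ref_text, other_text))),
    strand = "+", src_size = 10000,
    text = c(ref_text, other_text), stringsAsFactors = FALSE))
}

# fabricate a substitution_profile with given pooled counts on one pair
fake_profile <- function(element_id, diffs, sites, p = NULL) {
  sp <- c("A", "B")
  dm <- matrix(c(0, diffs / sites, diffs / sites, 0), 2, 2,
               dimnames = list(sp, sp))
  structure(list(
    element_id = element_id, species = sp, n = 2, d = dm,
    sites = matrix(c(0, sites, sites, 0), 2, 2, dimnames = list(sp, sp)),
    diffs = matrix(c(0, diffs, diffs, 0), 2, 2, dimnames = list(sp, sp)),
    mean_frequency = diffs / sites,
    col_pairs = rep(1L, sites), col_diffs = c(rep(1L, diffs),
                                              rep(0L, sites - diffs)),
    col_pairs_sp = matrix(1L, 2, sites, dimnames = list(sp, NULL)),
    col_diffs_sp = rbind(c(rep(1L, diffs), rep(0L, sites - diffs)),
                         c(rep(1L, diffs), rep(0L, sites - diffs)))),
    class = "substitution_profile")
}

fake_baseline <- function(p0, species = c("A", "B"), p0_s = NULL) {
  if (is.null(p0_s)) p0_s <- stats::setNames(rep(p0, length(species)),
                                             species)
  structure(list(p0 = p0, D = NA, N = NA, unweighted_mean = p0,
                 species = species, p0_s = p0_s,
                 D_s = NULL, N_s = NULL),
            class = "global_baseline")
}

# base-recovery helper: fraction of 'truth' interval bases covered by
# 'called' intervals (both data.frames with start/end, 0-based half-open)
interval_coverage <- function(called, truth) {
  if (!nrow(truth)) return(NA_real_)
  ir_c <- IRanges::reduce(IRanges::IRanges(called$start + 1, called$end))
  ir_t <- IRanges::reduce(IRanges::IRanges(truth$start + 1, truth$end))
  sum(IRanges::width(IRanges::intersect(ir_c, ir_t))) /
    sum(IRanges::width(ir_t))
}
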