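# Alignment simulator: Jukes-Cantor evolution along a species tree with
# interleaved neutral / conserved / lineage-accelerated segments, plus toy
# gene models so that simulated segments fall into known genomic contexts.

#' Build a simulation configuration
#'
#' Each alignment block is a concatenation of segments. A segment has a rate
#' class: \code{neutral} (branch lengths used as-is), \code{conserved}
#' (all branch lengths multiplied by \code{r_c} in (0,1]), or \code{rapid}
#' (conserved background with the terminal branch of one species multiplied
#' by an additional factor \code{m >= 1}). Columns evolve independently
#' under JC69; no indels are simulated.
#'
#' @param tree Species tree (\code{phylo}) with branch lengths; its leaves
#'   define the species set.
#' @param n_blocks Number of alignment blocks.
#' @param block_length Number of columns per block.
#' @param segments Segment plan: a data.frame with columns \code{class},
#'   \code{length}, and optionally \code{r_c}, \code{accel_species},
#'   \code{m}; either one plan recycled for every block or a list of plans,
#'   one per block. Segment lengths must sum to \code{block_length}.
#' @param base_comp Root base composition (A, C, G, T), default uniform.
#' @param seed Mandatory RNG seed; a fixed seed yields identical output.
#' @param reference Reference species for coordinates (default: first leaf).
#' @param chrom Chromosome name used for all species.
#' @param spacing Unaligned gap (bp) left between consecutive blocks.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(tree, n_blocks, block_length, segments,
                       base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed, reference = NULL, chrom = "chr1",
                       spacing = 100) {
  validate_species_tree(tree)
  stopifnot(n_blocks >= 1, block_length >= 1, spacing >= 0)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(is.numeric(base_comp), length(base_comp) == 4L,
            all(base_comp >= 0), sum(base_comp) > 0)
  if (is.null(reference)) reference <- tree$tip.label[1]
  if (!reference %in% tree$tip.label) {
    stop("reference species ", reference, " not in tree")
  }
  plans <- if (is.data.frame(segments)) {
    rep(list(segments), n_blocks)
  } else {
    if (length(segments) != n_blocks) {
      stop("need one segment plan per block (", n_blocks, "), got ",
           length(segments))
    }
    segments
  }
  plans <- lapply(plans, function(p) {
    p <- as.data.frame(p, stringsAsFactors = FALSE)
    if (is.null(p$r_c)) p$r_c <- 1
    if (is.null(p$accel_species)) p$accel_species <- NA_character_
    if (is.null(p$m)) p$m <- 1
    bad <- setdiff(p$class, c("neutral", "conserved", "rapid"))
    if (length(bad)) stop("unknown segment class: ", paste(bad, collapse = ", "))
    if (sum(p$length) != block_length) {
      stop("segment lengths sum to ", sum(p$length), ", not block_length = ",
           block_length)
    }
    if (any(p$r_c <= 0 | p$r_c > 1)) stop("r_c must be in (0, 1]")
    if (any(p$m < 1)) stop("acceleration multiplier m must be >= 1")
    rapid <- p$class == "rapid"
    if (any(rapid & is.na(p$accel_species))) {
      stop("rapid segments need an accel_species")
    }
    unknown <- setdiff(stats::na.omit(p$accel_species[rapid]), tree$tip.label)
    if (length(unknown)) {
      stop("accelerated branch not in tree: ", paste(unknown, collapse = ", "))
    }
    p
  })
  structure(list(tree = tree, n_blocks = as.integer(n_blocks),
                 block_length = as.integer(block_length), plans = plans,
                 base_comp = base_comp / sum(base_comp), seed = seed,
                 reference = reference, chrom = chrom,
                 spacing = as.integer(spacing)),
            class = "sim_config")
}

#' Simulate alignment blocks with known rate structure
#'
#' Draws a root sequence i.i.d. from the base composition and evolves every
#' column independently down the tree under JC69, with the effective branch
#' length of each branch/segment combination set by the segment class (see
#' \code{\link{sim_config}}). Also returns a ground-truth record and toy
#' gene models placed so that non-neutral segments fall into known context
#' categories (intron for even blocks, upstream-2kb for odd blocks).
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{blocks} (list of \code{alignment_block}),
#'   \code{truth} (list with \code{segments} data.frame and per-block
#'   per-segment per-branch substitution \code{counts}), and
#'   \code{gene_models}.
#' @export
simulate_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- stats::reorder(config$tree, "cladewise")   # parents before children
  tips <- tree$tip.label
  ntip <- length(tips)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  L <- config$block_length
  edge <- tree$edge
  elen <- tree$edge.length
  edge_names <- ifelse(edge[, 2] <= ntip, tips[edge[, 2]],
                       paste0("node_", edge[, 2]))
  src_size <- config$n_blocks * (L + config$spacing)
  bases <- c("A", "C", "G", "T")

  blocks <- vector("list", config$n_blocks)
  counts <- vector("list", config$n_blocks)
  seg_rows <- vector("list", config$n_blocks)
  genes <- vector("list", config$n_blocks)

  for (bi in seq_len(config$n_blocks)) {
    plan <- config$plans[[bi]]
    nseg <- nrow(plan)
    seg_of_col <- rep(seq_len(nseg), plan$length)
    mult <- plan$r_c[seg_of_col]
    mult[plan$class[seg_of_col] == "neutral"] <- 1
    block_start <- (bi - 1L) * (L + config$spacing)

    seqs <- matrix(0L, nn, L)
    seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = config$base_comp)
    cnt <- matrix(0, nseg, nrow(edge), dimnames = list(NULL, edge_names))
    for (k in seq_len(nrow(edge))) {
      p <- edge[k, 1]; ch <- edge[k, 2]
      m_here <- mult
      if (ch <= ntip) {
        boost <- plan$class[seg_of_col] == "rapid" &
          !is.na(plan$accel_species[seg_of_col]) &
          plan$accel_species[seg_of_col] == tips[ch]
        m_here[boost] <- m_here[boost] * plan$m[seg_of_col][boost]
      }
      teff <- elen[k] * m_here
      pch <- 0.75 * (1 - exp(-4 * teff / 3))
      chg <- stats::runif(L) < pch
      s <- seqs[p, ]
      nchg <- sum(chg)
      if (nchg) {
        s[chg] <- 1L + (s[chg] - 1L +
                          sample.int(3L, nchg, replace = TRUE)) %% 4L
        cnt[, k] <- tabulate(seg_of_col[chg], nbins = nseg)
      }
      seqs[ch, ] <- s
    }

    texts <- vapply(seq_len(ntip), function(i) {
      paste(bases[seqs[i, ]], collapse = "")
    }, "")
    rows <- data.frame(species = tips, chrom = config$chrom,
                       start = block_start, size = L, strand = "+",
                       src_size = src_size, text = texts,
                       stringsAsFactors = FALSE)
    blocks[[bi]] <- alignment_block(sprintf("block_%d", bi), rows)
    counts[[bi]] <- cnt
    seg_end <- block_start + cumsum(plan$length)
    seg_rows[[bi]] <- data.frame(
      block_id = sprintf("block_%d", bi), chrom = config$chrom,
      start = seg_end - plan$length, end = seg_end, class = plan$class,
      accel_species = plan$accel_species, m = plan$m,
      stringsAsFactors = FALSE)
    genes[[bi]] <- toy_gene_for_block(seg_rows[[bi]], block_start,
                                      block_start + L,
                                      sprintf("gene_%d", bi),
                                      layout = if (bi %% 2L == 0L) "intron"
                                               else "upstream")
  }
  truth_segments <- do.call(rbind, c(seg_rows, list(make.row.names = FALSE)))
  names(counts) <- sprintf("block_%d", seq_len(config$n_blocks))
  list(blocks = blocks,
       truth = list(segments = truth_segments, counts = counts),
       gene_models = genes[!vapply(genes, is.null, NA)])
}

# place one toy gene relative to the first non-neutral segment of a block,
# so the segment falls into a known context category
toy_gene_for_block <- function(segs, block_start, block_end, gene_id,
                               layout = c("intron", "upstream")) {
  layout <- match.arg(layout)
  i <- which(segs$class != "neutral")
  if (!length(i)) return(NULL)
  s <- segs$start[i[1]]
  e <- segs$end[i[1]]
  chrom <- segs$chrom[1]
  if (layout == "intron" && s - 120 >= block_start && e + 120 <= block_end) {
    return(gene_model(
      gene_id, chrom, "+",
      exons = rbind(c(s - 120, s - 20), c(e + 20, e + 120)),
      cds = rbind(c(s - 100, s - 20), c(e + 20, e + 80)),
      utr5 = rbind(c(s - 120, s - 100)),
      utr3 = rbind(c(e + 80, e + 120))))
  }
  if (e + 150 <= block_end) {
    return(gene_model(
      gene_id, chrom, "+",
      exons = rbind(c(e + 50, e + 150)),
      cds = rbind(c(e + 70, e + 130)),
      utr5 = rbind(c(e + 50, e + 70)),
      utr3 = rbind(c(e + 130, e + 150))))
  }
  NULL
}

#' Write a self-contained simulated fixture set
#'
#' Generates a deterministic alignment fixture along the AA-genome Oryza
#' topology and writes it as standard files: \code{alignment.maf},
#' \code{genes.gff3}, \code{tree.nwk} (the simulation tree) and
#' \code{truth.bed} (segment classes; rapid segments are named
#' \code{rapid:species:m}). Branch lengths are multiplied by
#' \code{tree_scale} so that individual segments carry enough substitutions
#' for element-level validation at desk scale (see the package vignette for
#' the power analysis behind the default).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed; the same seed yields byte-identical files.
#' @param n_blocks Number of blocks; every \code{rapid_every}-th block's
#'   central segment is rapid, the others are conserved.
#' @param block_length Columns per block: a central conserved (or rapid)
#'   segment of \code{block_length - 2 * flank_length} columns between two
#'   neutral flanks. The default central length of 500 bp matches the scale
#'   of real conserved noncoding elements.
#' @param flank_length Length of each neutral flank.
#' @param tree_scale Branch-length multiplier applied to the Oryza tree.
#' @param r_c Conserved rate multiplier.
#' @param m Acceleration multiplier on the accelerated branch of rapid
#'   segments.
#' @param accel_species Species whose terminal branch is accelerated.
#' @param rapid_every Period of rapid blocks.
#' @return Invisibly, a list with the written paths and the
#'   \code{sim_config} used.
#' @export
make_fixture_suite <- function(out_dir, seed, n_blocks = 60,
                               block_length = 900, flank_length = 200,
                               tree_scale = 50, r_c = 0.2, m = 5,
                               accel_species = "Olongistaminata",
                               rapid_every = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(block_length > 2 * flank_length)
  tree <- scale_tree(oryza_aa_tree(), tree_scale)
  plan_for <- function(cls) {
    data.frame(class = c("neutral", cls, "neutral"),
               length = c(flank_length, block_length - 2L * flank_length,
                          flank_length),
               r_c = c(1, r_c, 1),
               accel_species = c(NA, if (cls == "rapid") accel_species else NA,
                                 NA),
               m = c(1, if (cls == "rapid") m else 1, 1),
               stringsAsFactors = FALSE)
  }
  plans <- lapply(seq_len(n_blocks), function(i) {
    # with m = 1 there is no acceleration, so no segment is truly rapid
    plan_for(if (i %% rapid_every == 0L && m > 1) "rapid" else "conserved")
  })
  cfg <- sim_config(tree, n_blocks, block_length, plans, seed = seed,
                    reference = "Osativa")
  sim <- simulate_blocks(cfg)
  paths <- list(
    maf = file.path(out_dir, "alignment.maf"),
    gff3 = file.path(out_dir, "genes.gff3"),
    tree = file.path(out_dir, "tree.nwk"),
    truth_bed = file.path(out_dir, "truth.bed"))
  write_maf(sim$blocks, paths$maf)
  write_gff3(sim$gene_models, paths$gff3)
  ape::write.tree(tree, file = paths$tree)
  tr <- sim$truth$segments
  name <- ifelse(tr$class == "rapid",
                 sprintf("rapid:%s:%s", tr$accel_species, format_num(tr$m)),
                 tr$class)
  write_bed(data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                       name = name, score = 0, strand = "+",
                       stringsAsFactors = FALSE), paths$truth_bed)
  invisible(c(paths, list(config = cfg, truth = sim$truth)))
}
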