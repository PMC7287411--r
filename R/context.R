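# Genomic-context classification of regions relative to gene models
# (upstream 2 kb, 5'UTR, intron, 3'UTR, downstream 2 kb) and generic
# hypergeometric term enrichment of the associated genes.

CONTEXT_CATEGORIES <- c("upstream_2kb", "five_prime_utr", "intron",
                        "three_prime_utr", "downstream_2kb")

#' Build labeled context intervals from gene models
#'
#' Per gene, strand-aware: the upstream window is the \code{flank} bases
#' before the gene span (first to last exon) in transcript orientation and
#' the downstream window the \code{flank} bases after it; introns are the
#' gaps between consecutive exons; UTR intervals come from the model.
#' Intervals are clipped at position 0.
#'
#' @param gene_models List of \code{gene_model} objects.
#' @param flank Flank width in bp (default 2000).
#' @return A \code{GRanges} with metadata columns \code{category} and
#'   \code{gene_id}.
#' @export
build_context_intervals <- function(gene_models, flank = 2000) {
  stopifnot(flank > 0)
  rows <- list()
  add <- function(chrom, s0, e0, category, gene_id) {
    s0 <- max(0, s0)
    if (e0 <= s0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = s0, end = e0, category = category,
      gene_id = gene_id, stringsAsFactors = FALSE)
  }
  for (m in gene_models) {
    sp <- gene_span(m)
    if (m$strand == "+") {
      add(m$chrom, sp[1] - flank, sp[1], "upstream_2kb", m$gene_id)
      add(m$chrom, sp[2], sp[2] + flank, "downstream_2kb", m$gene_id)
    } else {
      add(m$chrom, sp[2], sp[2] + flank, "upstream_2kb", m$gene_id)
      add(m$chrom, sp[1] - flank, sp[1], "downstream_2kb", m$gene_id)
    }
    if (nrow(m$exons) > 1L) {
      for (i in seq_len(nrow(m$exons) - 1L)) {
        add(m$chrom, m$exons[i, 2], m$exons[i + 1L, 1], "intron", m$gene_id)
      }
    }
    if (nrow(m$utr5)) for (i in seq_len(nrow(m$utr5))) {
      add(m$chrom, m$utr5[i, 1], m$utr5[i, 2], "five_prime_utr", m$gene_id)
    }
    if (nrow(m$utr3)) for (i in seq_len(nrow(m$utr3))) {
      add(m$chrom, m$utr3[i, 1], m$utr3[i, 2], "three_prime_utr", m$gene_id)
    }
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges(category = character(),
                                  gene_id = character()))
  }
  d <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(d$start + 1, d$end),
    category = d$category, gene_id = d$gene_id)
}

#' Classify regions by genomic context
#'
#' A region is assigned a category when at least one of its bases overlaps
#' an interval of that category; all overlapping categories are recorded
#' (no precedence), together with the gene through which each association
#' arises. Regions with no overlap get no rows here and are reported as
#' intergenic by \code{\link{summarize_context_distribution}}. With
#' \code{precedence = TRUE} only the highest-priority category per region is
#' kept (5'UTR > 3'UTR > intron > upstream > downstream).
#'
#' @param elements data.frame with \code{element_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param context \code{GRanges} from \code{\link{build_context_intervals}}.
#' @param precedence Collapse to a single category per region?
#' @return data.frame with columns \code{element_id}, \code{category},
#'   \code{gene_id} (one row per association), sorted by element, category,
#'   gene.
#' @export
classify_regions <- function(elements, context, precedence = FALSE) {
  empty <- data.frame(element_id = character(), category = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (!nrow(elements) || !length(context)) return(empty)
  gr <- GenomicRanges::GRanges(
    seqnames = elements$chrom,
    ranges = IRanges::IRanges(elements$start + 1, elements$end))
  # regions on chromosomes absent from the interval set simply get no hits
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, context, ignore.strand = TRUE))
  if (!length(hits)) return(empty)
  out <- data.frame(
    element_id = elements$element_id[S4Vectors::queryHits(hits)],
    category = context$category[S4Vectors::subjectHits(hits)],
    gene_id = context$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  out <- unique(out)
  if (precedence) {
    rank <- match(out$category, c("five_prime_utr", "three_prime_utr",
                                  "intron", "upstream_2kb",
                                  "downstream_2kb"))
    keep <- stats::ave(rank, out$element_id, FUN = min) == rank
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$element_id, out$category, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the context distribution by region length
#'
#' Counts regions per context category and region-length bin, optionally
#' stratified by a grouping column (e.g. the species of species-specific
#' region sets). A region with several categories contributes one count to
#' each (documented double-count); regions with no category are counted as
#' \code{intergenic}.
#'
#' @param contexts Assignment table from \code{\link{classify_regions}}.
#' @param elements Element table with \code{element_id}, \code{start},
#'   \code{end}, and optionally the column named by \code{group}.
#' @param bins Length-bin breakpoints (half-open bins, last bin open-ended).
#' @param group Optional name of a grouping column in \code{elements}.
#' @return data.frame of counts per (group x) category x bin.
#' @export
summarize_context_distribution <- function(contexts, elements,
                                           bins = c(0, 100, 500, 1000, Inf),
                                           group = NULL) {
  cats <- c(CONTEXT_CATEGORIES, "intergenic")
  labels <- paste0("[", bins[-length(bins)], ",",
                   ifelse(is.finite(bins[-1]), bins[-1], "Inf"), ")")
  grp_levels <- if (is.null(group)) "all" else
    sort(unique(as.character(elements[[group]])))
  grid <- expand.grid(group = grp_levels, category = cats,
                      length_bin = labels, stringsAsFactors = FALSE)
  grid$count <- 0L
  if (nrow(elements)) {
    len <- elements$end - elements$start
    bin <- as.character(cut(len, breaks = bins, labels = labels,
                            right = FALSE))
    eg <- if (is.null(group)) rep("all", nrow(elements)) else
      as.character(elements[[group]])
    cat_of <- split(contexts$category, contexts$element_id)
    for (i in seq_len(nrow(elements))) {
      id <- elements$element_id[i]
      cs <- unique(cat_of[[id]])
      if (is.null(cs) || !length(cs)) cs <- "intergenic"
      for (cc in cs) {
        j <- grid$group == eg[i] & grid$category == cc &
          grid$length_bin == bin[i]
        grid$count[j] <- grid$count[j] + 1L
      }
    }
  }
  if (is.null(group)) grid$group <- NULL
  grid
}

#' Hypergeometric term enrichment
#'
#' For every annotation term with at least one study-gene hit: the
#' upper-tail hypergeometric probability of observing at least \code{k}
#' term-carrying genes among \code{K} study genes drawn from a background
#' of \code{M} genes of which \code{m} carry the term, with
#' Benjamini-Hochberg adjustment across tested terms.
#'
#' @param study_genes Character vector (must be a subset of
#'   \code{background_genes}).
#' @param background_genes Character vector of all genes.
#' @param gene2term data.frame with columns \code{gene_id}, \code{term_id}
#'   and optionally \code{term_name}.
#' @return data.frame sorted by adjusted then raw p: \code{term_id},
#'   \code{term_name}, \code{k}, \code{K}, \code{m}, \code{M}, \code{p},
#'   \code{p_adj}.
#' @export
enrich_terms <- function(study_genes, background_genes, gene2term) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  outside <- setdiff(study_genes, background_genes)
  if (length(outside)) {
    stop("study genes not in background: ", paste(outside, collapse = ", "))
  }
  stopifnot(all(c("gene_id", "term_id") %in% names(gene2term)))
  if (is.null(gene2term$term_name)) gene2term$term_name <- gene2term$term_id
  g2t <- unique(gene2term[gene2term$gene_id %in% background_genes,
                          c("gene_id", "term_id", "term_name")])
  K <- length(study_genes)
  M <- length(background_genes)
  terms <- unique(g2t[, c("term_id", "term_name")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- g2t$gene_id[g2t$term_id == terms$term_id[i]]
    k <- length(intersect(tg, study_genes))
    if (k == 0L) return(NULL)
    m <- length(tg)
    p <- stats::phyper(k - 1, m, M - m, K, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, K = K, m = m, M = M, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), m = integer(),
                      M = integer(), p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p_adj, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
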