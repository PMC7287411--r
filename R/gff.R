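#' Construct a gene model
#'
#' Holds the interval structure of one protein-coding gene on reference
#' coordinates. All intervals are 0-based half-open; exons must be sorted and
#' non-overlapping, and every CDS/UTR segment must be contained in an exon.
#' Where a gene has several transcripts the caller is expected to pass the
#' per-class union across transcripts.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons,cds,utr5,utr3 Two-column matrices (start, end), 0-based
#'   half-open; \code{NULL} means none.
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL,
                       utr5 = NULL, utr3 = NULL) {
  if (!strand %in% c("+", "-")) {
    stop("gene ", gene_id, ": unknown strand symbol '", strand, "'")
  }
  exons <- as_ivmat(exons, "exons", gene_id)
  cds <- as_ivmat(cds, "CDS", gene_id)
  utr5 <- as_ivmat(utr5, "5'UTR", gene_id)
  utr3 <- as_ivmat(utr3, "3'UTR", gene_id)
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  for (nm in c("cds", "utr5", "utr3")) {
    m <- get(nm)
    if (nrow(m) == 0L) next
    inside <- vapply(seq_len(nrow(m)), function(i) {
      any(exons[, 1] <= m[i, 1] & m[i, 2] <= exons[, 2])
    }, NA)
    if (!all(inside)) {
      stop("gene ", gene_id, ": ", toupper(nm),
           " segment not contained in any exon")
    }
  }
  if (nrow(cds) && nrow(utr5)) {
    ok <- if (strand == "+") max(utr5[, 2]) <= min(cds[, 1]) else
      min(utr5[, 1]) >= max(cds[, 2])
    if (!ok) stop("gene ", gene_id, ": 5'UTR not upstream of CDS")
  }
  if (nrow(cds) && nrow(utr3)) {
    ok <- if (strand == "+") min(utr3[, 1]) >= max(cds[, 2]) else
      max(utr3[, 2]) <= min(cds[, 1])
    if (!ok) stop("gene ", gene_id, ": 3'UTR not downstream of CDS")
  }
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

as_ivmat <- function(x, what, gene_id) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L)) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  m <- matrix(as.numeric(x), ncol = 2L)
  colnames(m) <- c("start", "end")
  if (any(m[, 2] <= m[, 1])) {
    stop("gene ", gene_id, ": ", what, " interval with end <= start")
  }
  m[order(m[, 1]), , drop = FALSE]
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " ", x$chrom, ":", min(x$exons[, 1]), "-",
      max(x$exons[, 2]), " (", x$strand, "), ", nrow(x$exons), " exon(s)\n",
      sep = "")
  invisible(x)
}

#' Gene span
#'
#' Full transcript extent (first to last exon), 0-based half-open.
#' @param model A \code{gene_model}.
#' @return Numeric vector \code{c(start, end)}.
#' @export
gene_span <- function(model) {
  c(min(model$exons[, 1]), max(model$exons[, 2]))
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features (via
#' \pkg{rtracklayer}) and assembles one \code{gene_model} per gene. File
#' coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention at this boundary. When several transcripts exist the
#' per-class union across transcripts is used. Genes without explicit UTR
#' features but with a CDS get UTRs inferred as the exonic sequence outside
#' the CDS extent, assigned 5' or 3' by strand.
#'
#' @param path Path to a GFF3 file.
#' @return A list of \code{gene_model} objects, ordered by chromosome and
#'   start.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent   # CharacterList

  gene_idx <- which(typ == "gene")
  if (!length(gene_idx)) return(list())
  gene_ids <- ids[gene_idx]
  names(gene_idx) <- gene_ids

  # transcript -> gene
  tx_idx <- which(typ %in% c("mRNA", "transcript"))
  tx2gene <- character(0)
  if (length(tx_idx)) {
    tx2gene <- vapply(tx_idx, function(i) {
      p <- unlist(parents[i])
      p <- p[p %in% gene_ids]
      if (length(p)) p[1] else NA_character_
    }, "")
    names(tx2gene) <- ids[tx_idx]
    tx2gene <- tx2gene[!is.na(tx2gene)]
  }

  resolve_gene <- function(i) {
    p <- unlist(parents[i])
    hit <- p[p %in% names(tx2gene)]
    if (length(hit)) return(unname(tx2gene[hit[1]]))
    hit <- p[p %in% gene_ids]
    if (length(hit)) return(hit[1])
    NA_character_
  }

  classes <- c(exon = "exon", CDS = "cds",
               five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  parts <- lapply(stats::setNames(nm = names(classes)), function(ft) {
    idx <- which(typ == ft)
    if (!length(idx)) return(NULL)
    data.frame(
      gene = vapply(idx, resolve_gene, ""),
      start = GenomicRanges::start(gr)[idx] - 1,  # to 0-based half-open
      end = GenomicRanges::end(gr)[idx],
      stringsAsFactors = FALSE)
  })

  union_class <- function(df, g) {
    if (is.null(df)) return(NULL)
    d <- df[!is.na(df$gene) & df$gene == g, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
    cbind(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  }

  models <- lapply(gene_ids, function(g) {
    i <- gene_idx[[g]]
    strand <- as.character(GenomicRanges::strand(gr))[i]
    if (!strand %in% c("+", "-")) {
      stop("gene ", g, ": unknown strand symbol '", strand, "'")
    }
    chrom <- as.character(GenomicRanges::seqnames(gr))[i]
    exons <- union_class(parts$exon, g)
    if (is.null(exons)) {
      exons <- cbind(start = GenomicRanges::start(gr)[i] - 1,
                     end = GenomicRanges::end(gr)[i])
    }
    cds <- union_class(parts$CDS, g)
    utr5 <- union_class(parts$five_prime_UTR, g)
    utr3 <- union_class(parts$three_prime_UTR, g)
    if (is.null(utr5) && is.null(utr3) && !is.null(cds)) {
      inf <- infer_utrs(exons, cds, strand)
      utr5 <- inf$utr5
      utr3 <- inf$utr3
    }
    gene_model(g, chrom, strand, exons, cds, utr5, utr3)
  })
  ord <- order(vapply(models, function(m) m$chrom, ""),
               vapply(models, function(m) gene_span(m)[1], 0))
  models[ord]
}

# exonic minus CDS-extent, split into 5'/3' by transcript orientation
infer_utrs <- function(exons, cds, strand) {
  ex <- IRanges::IRanges(exons[, 1] + 1, exons[, 2])
  cd <- IRanges::IRanges(min(cds[, 1]) + 1, max(cds[, 2]))
  rest <- IRanges::setdiff(ex, cd)
  if (!length(rest)) return(list(utr5 = NULL, utr3 = NULL))
  s <- IRanges::start(rest) - 1
  e <- IRanges::end(rest)
  before <- e <= min(cds[, 1])
  after <- s >= max(cds[, 2])
  mk <- function(keep) {
    if (!any(keep)) NULL else cbind(start = s[keep], end = e[keep])
  }
  if (strand == "+") {
    list(utr5 = mk(before), utr3 = mk(after))
  } else {
    list(utr5 = mk(after), utr3 = mk(before))
  }
}

#' Write gene models as GFF3
#'
#' Deterministic writer (fixed attribute order, genes sorted by chromosome
#' and start; 0-based half-open internal coordinates converted back to the
#' 1-based closed file convention). One \code{mRNA} per gene is emitted.
#'
#' @param models List of \code{gene_model} objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(..., con = con, sep = "\n")
  w("##gff-version 3")
  ord <- order(vapply(models, function(m) m$chrom, ""),
               vapply(models, function(m) gene_span(m)[1], 0))
  line <- function(chrom, type, s0, e0, strand, attrs, phase = ".") {
    sprintf("%s\tcnsevol\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, as.integer(s0) + 1L, as.integer(e0), strand, phase,
            attrs)
  }
  for (m in models[ord]) {
    sp <- gene_span(m)
    tid <- paste0(m$gene_id, ".t1")
    w(line(m$chrom, "gene", sp[1], sp[2], m$strand,
           paste0("ID=", m$gene_id)))
    w(line(m$chrom, "mRNA", sp[1], sp[2], m$strand,
           paste0("ID=", tid, ";Parent=", m$gene_id)))
    emit <- function(mat, type, with_phase = FALSE) {
      if (is.null(mat) || nrow(mat) == 0L) return()
      mat <- mat[order(mat[, 1]), , drop = FALSE]
      if (with_phase) {
        # phase in transcript orientation
        o <- if (m$strand == "+") seq_len(nrow(mat)) else rev(seq_len(nrow(mat)))
        lens <- mat[o, 2] - mat[o, 1]
        ph <- integer(nrow(mat))
        ph[o] <- c(0, cumsum(lens)[-length(lens)]) %% 3
        ph <- (3 - ph) %% 3
        for (i in seq_len(nrow(mat))) {
          w(line(m$chrom, type, mat[i, 1], mat[i, 2], m$strand,
                 paste0("Parent=", tid), phase = ph[i]))
        }
      } else {
        for (i in seq_len(nrow(mat))) {
          w(line(m$chrom, type, mat[i, 1], mat[i, 2], m$strand,
                 paste0("Parent=", tid)))
        }
      }
    }
    emit(m$exons, "exon")
    emit(m$cds, "CDS", with_phase = TRUE)
    emit(m$utr5, "five_prime_UTR")
    emit(m$utr3, "three_prime_UTR")
  }
  invisible(path)
}
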