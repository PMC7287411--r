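#' Construct an alignment block
#'
#' An alignment block is one orthologous segment: one gapped sequence row per
#' species, with MAF-style coordinates. Internally rows are held in a
#' data.frame with columns \code{species}, \code{chrom}, \code{start}
#' (0-based offset on \code{strand}), \code{size} (ungapped length),
#' \code{strand} (\code{"+"}/\code{"-"}), \code{src_size} (chromosome
#' length) and \code{text} (gapped sequence over A/C/G/T/N/-,
#' case-insensitive).
#'
#' @param block_id Block identifier (string).
#' @param rows data.frame with the columns described above.
#' @param score Numeric alignment score carried on the block line.
#' @return An object of class \code{alignment_block}.
#' @export
alignment_block <- function(block_id, rows, score = 0) {
  needed <- c("species", "chrom", "start", "size", "strand", "src_size", "text")
  miss <- setdiff(needed, names(rows))
  if (length(miss)) stop("rows missing column(s): ", paste(miss, collapse = ", "))
  rows <- as.data.frame(rows[, needed], stringsAsFactors = FALSE)
  if (nrow(rows) < 2) stop("block ", block_id, ": needs >= 2 rows")
  gl <- nchar(rows$text)
  if (length(unique(gl)) != 1L) {
    stop("block ", block_id, ": rows of unequal gapped length (",
         paste(unique(gl), collapse = ", "), ")")
  }
  if (gl[1] < 1L) stop("block ", block_id, ": empty alignment text")
  ungapped <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  bad <- which(ungapped != rows$size)
  if (length(bad)) {
    stop("block ", block_id, ": row for ", rows$species[bad[1]],
         " has ", ungapped[bad[1]], " non-gap characters but size ",
         rows$size[bad[1]])
  }
  dup <- unique(rows$species[duplicated(rows$species)])
  if (length(dup)) {
    stop("block ", block_id, ": more than one row for species ",
         paste(dup, collapse = ", "))
  }
  if (!all(rows$strand %in% c("+", "-"))) {
    stop("block ", block_id, ": strand must be '+' or '-'")
  }
  if (any(rows$start < 0) || any(rows$size < 0)) {
    stop("block ", block_id, ": negative start or size")
  }
  structure(list(block_id = as.character(block_id), score = score, rows = rows),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("<alignment_block> ", x$block_id, ": ", nrow(x$rows), " species, ",
      nchar(x$rows$text[1]), " columns\n", sep = "")
  invisible(x)
}

#' Number of alignment columns in a block
#' @param block An \code{alignment_block}.
#' @return Integer.
#' @export
block_width <- function(block) nchar(block$rows$text[1])

#' Read a MAF alignment file
#'
#' Reads UCSC multiple-alignment-format blocks. The species identifier of a
#' row is the part of the source name before the first \code{"."}; the rest
#' is the chromosome. Minus-strand rows are kept with MAF semantics (start
#' counted on the reverse strand). Lines other than \code{a}/\code{s}
#' (comments, \code{i}/\code{e}/\code{q} lines) are ignored.
#'
#' @param path Path to a MAF file.
#' @param species_map Optional named character vector mapping full source
#'   names to species identifiers, for inputs that do not follow the
#'   \code{species.chrom} convention.
#' @return A list of \code{alignment_block} objects.
#' @export
read_maf <- function(path, species_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL           # list of row lists for the open block
  cur_id <- NULL
  cur_score <- 0
  n_anon <- 0L

  flush <- function() {
    if (is.null(cur) || !length(cur)) return()
    rows <- do.call(rbind, lapply(cur, as.data.frame, stringsAsFactors = FALSE))
    blocks[[length(blocks) + 1L]] <<- alignment_block(cur_id, rows, cur_score)
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "a")) {
      if (!(ln == "a" || substr(ln, 2, 2) %in% c(" ", "\t"))) next  # e.g. '##'
      flush()
      cur <- list()
      n_anon <- n_anon + 1L
      kv <- regmatches(ln, gregexpr("[A-Za-z_]+=[^ \t]+", ln))[[1]]
      kv <- strsplit(kv, "=", fixed = TRUE)
      keys <- vapply(kv, `[`, "", 1L)
      vals <- vapply(kv, `[`, "", 2L)
      cur_id <- if ("id" %in% keys) vals[keys == "id"][1] else
        sprintf("block_%d", n_anon)
      cur_score <- if ("score" %in% keys)
        as.numeric(vals[keys == "score"][1]) else 0
    } else if (startsWith(ln, "s ") || startsWith(ln, "s\t")) {
      if (is.null(cur)) stop("line ", i, ": s-line outside of a block")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L) {
        stop("malformed s-line at line ", i, ": expected 7 fields, got ",
             length(f))
      }
      src <- f[2]
      if (!is.null(species_map) && src %in% names(species_map)) {
        species <- unname(species_map[[src]])
        chrom <- src
      } else if (grepl(".", src, fixed = TRUE)) {
        species <- sub("\\..*$", "", src)
        chrom <- sub("^[^.]*\\.", "", src)
      } else {
        species <- src
        chrom <- src
      }
      start <- suppressWarnings(as.numeric(f[3]))
      size <- suppressWarnings(as.numeric(f[4]))
      src_size <- suppressWarnings(as.numeric(f[6]))
      if (anyNA(c(start, size, src_size))) {
        stop("malformed s-line at line ", i, ": non-numeric coordinate field")
      }
      if (!f[5] %in% c("+", "-")) {
        stop("malformed s-line at line ", i, ": strand must be '+' or '-'")
      }
      cur[[length(cur) + 1L]] <- list(
        species = species, chrom = chrom, start = start, size = size,
        strand = f[5], src_size = src_size, text = f[7])
    }
    # all other line types are ignored
  }
  flush()
  blocks
}

#' Write alignment blocks as MAF
#'
#' Output is byte-stable for identical input: a \code{##maf version=1}
#' header, one \code{a score=... id=...} line per block, s-lines separated by
#' single spaces, and a blank line between blocks. The block identifier is
#' carried in the (MAF-legal) \code{id=} key so that
#' \code{read_maf(write_maf(x))} round-trips all fields.
#'
#' @param blocks List of \code{alignment_block} objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(..., con = con, sep = "\n")
  w("##maf version=1")
  for (b in blocks) {
    w("")
    w(sprintf("a score=%s id=%s", format_num(b$score), b$block_id))
    r <- b$rows
    src <- paste0(r$species, ".", r$chrom)
    w(sprintf("s %s %s %s %s %s %s", src,
              format_num(r$start), format_num(r$size), r$strand,
              format_num(r$src_size), r$text))
  }
  invisible(path)
}

# integer-safe, non-scientific number formatting for writers
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v)) {
      format(v, scientific = FALSE, trim = TRUE)
    } else {
      sprintf("%.6g", v)
    }
  }, "")
}
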