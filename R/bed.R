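#' Write intervals as BED6
#'
#' Rows are sorted by (chrom, start); scores are clamped to the BED-legal
#' integer range 0-1000. Output is byte-stable for identical input.
#'
#' @param x data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and optionally \code{name}, \code{score},
#'   \code{strand}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as.data.frame(x)
  if (nrow(x) && any(x$end <= x$start)) {
    stop("BED interval with end <= start")
  }
  if (is.null(x$name)) x$name <- sprintf("region_%d", seq_len(nrow(x)))
  if (is.null(x$score)) x$score <- 0
  if (is.null(x$strand)) x$strand <- "+"
  score <- as.integer(pmin(1000, pmax(0, round(x$score))))
  ord <- order(x$chrom, x$start)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   x$chrom[ord], as.integer(x$start[ord]),
                   as.integer(x$end[ord]), x$name[ord], score[ord],
                   x$strand[ord])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Read a BED file
#'
#' @param path Path to a BED3+ file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   and \code{name}, \code{score}, \code{strand} when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (file.size(path) == 0) {
    return(stats::setNames(
      data.frame(character(), numeric(), numeric(), character(), numeric(),
                 character(), stringsAsFactors = FALSE), cols))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  names(d) <- cols[seq_len(ncol(d))]
  d
}

#' Write a TSV report
#'
#' Tab-separated with a header row; non-integer numeric columns are
#' serialized with 6 significant digits; byte-stable for identical input.
#' Row ordering is the caller's responsibility.
#'
#' @param records data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(records, path) {
  d <- as.data.frame(records)
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]]) && !is.integer(d[[j]])) {
      v <- d[[j]]
      d[[j]] <- ifelse(is.na(v), "NA",
                       ifelse(v == round(v) & abs(v) < 1e15,
                              format(v, scientific = FALSE, trim = TRUE),
                              sprintf("%.6g", v)))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = "\t"), con = con, sep = "\n")
  if (nrow(d)) {
    body <- do.call(paste, c(lapply(d, as.character), sep = "\t"))
    writeLines(body, con = con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV report written by \code{write_report}
#' @param path Path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
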