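#' @useDynLib nrbpfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Column names of the 12-column tabular hit format
#'
#' The standard tabular output of pairwise sequence search tools
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Coordinates are 1-based inclusive.
#'
#' @export
HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

.hit_numeric_cols <- HIT_COLUMNS[3:12]

#' Construct a hit record
#'
#' One pairwise search alignment: query, subject, identity, coordinates,
#' E-value and bit score. This is the unit the ortholog filters operate on.
#'
#' @param qseqid,sseqid query and subject identifiers.
#' @param pident percent identity (0-100).
#' @param length alignment length in residues.
#' @param mismatch,gapopen mismatch and gap-opening counts.
#' @param qstart,qend,sstart,send 1-based inclusive alignment coordinates on
#'   query and subject.
#' @param evalue expectation value (>= 0).
#' @param bitscore bit score.
#' @return A one-row data.frame with the 12 standard columns.
#' @export
hit_record <- function(qseqid, sseqid, pident, length, mismatch, gapopen,
                       qstart, qend, sstart, send, evalue, bitscore) {
  hits <- data.frame(qseqid = as.character(qseqid),
                     sseqid = as.character(sseqid),
                     pident = as.numeric(pident),
                     length = as.numeric(length),
                     mismatch = as.numeric(mismatch),
                     gapopen = as.numeric(gapopen),
                     qstart = as.numeric(qstart),
                     qend = as.numeric(qend),
                     sstart = as.numeric(sstart),
                     send = as.numeric(send),
                     evalue = as.numeric(evalue),
                     bitscore = as.numeric(bitscore),
                     stringsAsFactors = FALSE)
  validate_hits(hits)
  hits
}

#' Validate a hit table
#'
#' Checks the structural invariants of a hit table: 12 standard columns,
#' qstart <= qend, sstart <= send, evalue >= 0.
#'
#' @param hits a hit-table data.frame.
#' @return The validated data.frame, invisibly on success.
#' @export
validate_hits <- function(hits) {
  if (!is.data.frame(hits) || !all(HIT_COLUMNS %in% names(hits)))
    stop("hit table must contain the 12 standard columns: ",
         paste(HIT_COLUMNS, collapse = " "))
  if (nrow(hits)) {
    if (any(hits$qstart > hits$qend))
      stop("hit table invariant violated: qstart > qend")
    if (any(hits$sstart > hits$send))
      stop("hit table invariant violated: sstart > send")
    if (any(hits$evalue < 0))
      stop("hit table invariant violated: negative evalue")
  }
  invisible(hits)
}

#' Parse a 12-column tabular hit file
#'
#' Reads the tab-separated tabular format written by pairwise search tools.
#' Lines starting with `#` are ignored; record order is preserved.
#'
#' @param x path to a file, or a character vector of lines.
#' @return data.frame with columns [HIT_COLUMNS] and parsed numeric fields.
#' @examples
#' parse_hit_table("q1\ts1\t90.0\t100\t10\t0\t1\t100\t1\t100\t1e-50\t200")
#' @export
parse_hit_table <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x))
    readLines(x) else x
  keep <- !grepl("^#", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, HIT_COLUMNS)))
  for (nm in .hit_numeric_cols) empty[[nm]] <- numeric(0)
  empty$qseqid <- character(0); empty$sseqid <- character(0)
  if (!length(lines)) return(empty[HIT_COLUMNS])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 line_no[bad], nf[bad]))
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (k in 3:12) {
    v <- suppressWarnings(as.numeric(m[, k]))
    bad <- which(is.na(v) & !is.na(m[, k]))
    if (length(bad))
      stop(sprintf("line %d: cannot parse '%s' as numeric (column %s)",
                   line_no[bad[1L]], m[bad[1L], k], HIT_COLUMNS[k]))
    hits[[HIT_COLUMNS[k]]] <- v
  }
  validate_hits(hits)
  hits[HIT_COLUMNS]
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits hit-table data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  validate_hits(hits)
  utils::write.table(hits[HIT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
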