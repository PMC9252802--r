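# seqio: sequence I/O and read collapsing
#
# Collapsed reads are the central read container of the toolkit: a
# data.frame with columns sequence / count / rank where rank 1 is the most
# abundant sequence and ties in count are broken lexicographically.

new_collapsed <- function(df) {
  stopifnot(all(c("sequence", "count", "rank") %in% names(df)))
  df <- as.data.frame(df)[, c("sequence", "count", "rank")]
  rownames(df) <- NULL
  class(df) <- c("collapsed_reads", "data.frame")
  df
}

#' Load sequencing reads from FASTQ or FASTA
#'
#' Reads a (optionally gzipped) FASTQ or FASTA file and returns the read
#' sequences, uppercased.  Records containing characters outside
#' `{A,C,G,T,N}` are rejected and tallied in a single warning.
#'
#' @param path path to the input file; `.gz` is handled transparently.
#' @param format `"auto"` (inferred from the file name), `"fastq"` or
#'   `"fasta"`.
#' @param quality_min optional mean Phred quality (Phred+33) below which a
#'   FASTQ record is discarded; `NULL` (default) disables quality filtering.
#' @return character vector of sequences in file order.
#' @export
load_reads <- function(path, format = c("auto", "fastq", "fasta"),
                       quality_min = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) "fastq"
    else if (grepl("\\.(fasta|fa|fna)$", base, ignore.case = TRUE)) "fasta"
    else stop("cannot infer format from file name '", path,
              "'; pass format explicitly")
  }
  if (format == "fastq" && !is.null(quality_min)) {
    seqs <- read_fastq_qualfilter(path, quality_min)
  } else {
    seqs <- tryCatch(
      as.character(Biostrings::readBStringSet(path, format = format)),
      error = function(e) stop("malformed ", format, " file '", path,
                               "': ", conditionMessage(e), call. = FALSE))
    seqs <- unname(seqs)
  }
  seqs <- toupper(seqs)
  ok <- grepl("^[ACGTN]+$", seqs)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with characters outside {A,C,G,T,N} ",
            "rejected (first at record ", which(!ok)[1L], ")")
    seqs <- seqs[ok]
  }
  seqs
}

# 4-line FASTQ parser used only when a mean-quality filter is requested
read_fastq_qualfilter <- function(path, quality_min) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record ",
         length(lines) %/% 4L + 1L)
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  meanq <- vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                  USE.NAMES = FALSE)
  seqs[meanq >= quality_min]
}

#' Collapse reads to unique sequences with multiplicities
#'
#' One entry per distinct sequence, sorted by count descending with ties
#' broken lexicographically; `rank` is 1 for the most abundant sequence.
#'
#' @param sequences character vector of read sequences.
#' @return a `collapsed_reads` data.frame with columns `sequence`, `count`,
#'   `rank`.
#' @export
#' @examples
#' collapse_reads(c("AAC", "AAC", "GGT"))
collapse_reads <- function(sequences) {
  if (!length(sequences)) {
    return(new_collapsed(data.frame(sequence = character(),
                                    count = integer(), rank = integer())))
  }
  dt <- data.table(sequence = as.character(sequences))
  tab <- dt[, list(count = .N), by = "sequence"]
  setorder(tab, -count, sequence)
  tab[, `:=`(rank = seq_len(nrow(tab)))]
  new_collapsed(tab)
}

# re-collapse sequences that already carry counts (e.g. after trimming)
collapse_weighted <- function(sequences, counts) {
  if (!length(sequences)) return(collapse_reads(character()))
  dt <- data.table(sequence = sequences, count = as.integer(counts))
  tab <- dt[, list(count = sum(count)), by = "sequence"]
  setorder(tab, -count, sequence)
  tab[, `:=`(rank = seq_len(nrow(tab)))]
  new_collapsed(tab)
}

#' Write / read collapsed reads as FASTA
#'
#' The collapsed-FASTA dialect uses headers `>{rank}-{count}`; a
#' write-read round trip is the identity.
#'
#' @param x a `collapsed_reads` data.frame.
#' @param path output (input) file path; `.gz` supported.
#' @return `write_collapsed` returns `path` invisibly; `read_collapsed`
#'   returns a `collapsed_reads` data.frame.
#' @export
write_collapsed <- function(x, path) {
  stopifnot(inherits(x, "collapsed_reads"))
  con <- open_out(path)
  on.exit(close(con))
  if (nrow(x)) {
    lines <- character(2L * nrow(x))
    lines[c(TRUE, FALSE)] <- paste0(">", x$rank, "-", x$count)
    lines[c(FALSE, TRUE)] <- x$sequence
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_collapsed
#' @export
read_collapsed <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (!length(ss)) return(collapse_reads(character()))
  hdr <- names(ss)
  m <- regmatches(hdr, regexec("^([0-9]+)-([0-9]+)$", hdr))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("collapsed-FASTA header not of the form '>rank-count' at record ",
         which(bad)[1L], ": '", hdr[which(bad)[1L]], "'")
  df <- data.frame(
    sequence = toupper(unname(as.character(ss))),
    count = vapply(m, function(v) as.integer(v[3L]), integer(1)),
    rank = vapply(m, function(v) as.integer(v[2L]), integer(1)))
  df <- df[order(df$rank), , drop = FALSE]
  new_collapsed(df)
}

#' Read-length histogram of a collapsed set
#'
#' Counts are multiplicity-weighted, so the histogram total equals the
#' number of raw reads.
#'
#' @param x a `collapsed_reads` data.frame.
#' @return data.frame with columns `length` and `count`, sorted by length.
#' @export
length_histogram <- function(x) {
  stopifnot(inherits(x, "collapsed_reads"))
  if (!nrow(x)) return(data.frame(length = integer(), count = integer()))
  dt <- data.table(length = nchar(x$sequence), count = x$count)
  tab <- dt[, list(count = sum(count)), by = "length"]
  setorder(tab, length)
  as.data.frame(tab)
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat("Collapsed reads: ", nrow(x), " unique sequence(s), ",
      sum(x$count), " read(s) total\n", sep = "")
  if (nrow(x)) print(head(as.data.frame(x), 10L))
  invisible(x)
}
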