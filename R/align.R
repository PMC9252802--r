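# align: full-length ungapped k-mismatch alignment
#
# The mapping contract mirrors bowtie's -v mode: a query matches a reference
# window iff the whole query aligns without gaps with at most m in {0,1,2}
# mismatches, on either strand.  N never matches anything, including N.
# The implementation is seed-and-verify: queries are partitioned into m+1
# disjoint seeds, so any window within the mismatch budget contains at least
# one exact seed (pigeonhole); exact seed lookups against a positional k-mer
# table give candidate offsets which are then verified by Hamming count.

#' Construct a reference library
#'
#' @param sequences named character vector of DNA sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param name library label.
#' @param rna_class RNA class label used by the profiler (e.g. `"mature"`,
#'   `"tRNA"`, `"genome"`).
#' @return a `ref_library` object.
#' @export
ref_library <- function(sequences, name, rna_class = name) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences),
                          sub("\\s.*$", "", names(sequences)))
  }
  stopifnot(is.character(sequences), length(sequences) > 0L)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("reference sequences must carry unique ids")
  sequences <- toupper(sequences)
  structure(list(name = name, rna_class = rna_class,
                 sequences = sequences),
            class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat("Reference library '", x$name, "' (class ", x$rna_class, "): ",
      length(x$sequences), " record(s), ",
      sum(nchar(x$sequences)), " nt\n", sep = "")
  invisible(x)
}

#' Build an alignment index over a reference library
#'
#' Concatenates the records (with a separator that can never match a query)
#' and caches positional k-mer tables on demand; [map_full_length()] chooses
#' the seed length from the query lengths and mismatch budget.
#'
#' @param library a [ref_library()].
#' @param seed_len optional seed length to pre-build a k-mer table for.
#' @return an `srna_index` handle.
#' @export
build_index <- function(library, seed_len = NULL) {
  stopifnot(inherits(library, "ref_library"))
  seqs <- library$sequences
  widths <- nchar(seqs)
  big <- paste(seqs, collapse = "#")
  rec_start0 <- cumsum(c(0L, head(widths + 1L, -1L)))
  idx <- structure(list(library_name = library$name,
                        rna_class = library$rna_class,
                        ids = names(seqs), widths = unname(widths),
                        big = big, rec_start0 = rec_start0,
                        cache = new.env(parent = emptyenv())),
                   class = "srna_index")
  if (!is.null(seed_len)) kmer_table(idx, as.integer(seed_len))
  idx
}

# positional k-mer table of the concatenated reference, cached per k
kmer_table <- function(index, k) {
  key <- as.character(k)
  cached <- index$cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- nchar(index$big)
  if (n < k) {
    dt <- data.table(kmer = character(), pos0 = integer())
  } else {
    starts <- seq_len(n - k + 1L)
    dt <- data.table(kmer = substring(index$big, starts, starts + k - 1L),
                     pos0 = starts - 1L)
  }
  setkey(dt, kmer)
  index$cache[[key]] <- dt
  dt
}

# vectorised Hamming distance between equal-length string vectors;
# a position where either side is N always counts as a mismatch
hamming_count <- function(a, b, len) {
  mm <- integer(length(a))
  for (j in seq_len(len)) {
    ca <- substring(a, j, j)
    cb <- substring(b, j, j)
    mm <- mm + ((ca != cb) | ca == "N" | cb == "N")
  }
  mm
}

#' Map queries full-length against a reference index
#'
#' Reports every position on the requested strands where the entire query
#' matches a reference window with at most `max_mismatches` substitutions
#' (no indels, no end-trimming).  `N` in query or reference never matches.
#'
#' @param queries character vector of query sequences (names used as query
#'   ids; unnamed queries are identified by their sequence), or a
#'   `collapsed_reads` data.frame (sequences become the ids).
#' @param index an [build_index()] handle, or a [ref_library()] (indexed on
#'   the fly).
#' @param max_mismatches 0, 1 or 2.
#' @param strands `"both"`, `"sense"` or `"antisense"`.
#' @return data.frame with columns `query_id`, `ref_id`, `start` (0-based on
#'   the reference forward strand), `strand` (`"+"`/`"-"`), `mismatches`,
#'   `query_len`.
#' @export
map_full_length <- function(queries, index, max_mismatches = 0L,
                            strands = c("both", "sense", "antisense")) {
  strands <- match.arg(strands)
  if (inherits(queries, "collapsed_reads")) {
    queries <- setNames(queries$sequence, queries$sequence)
  }
  if (inherits(index, "ref_library")) index <- build_index(index)
  stopifnot(inherits(index, "srna_index"))
  m <- as.integer(max_mismatches)
  if (!m %in% 0:2) stop("max_mismatches must be 0, 1 or 2")
  if (!length(queries)) stop("no query sequences given")
  qid <- names(queries) %||% unname(queries)
  qseq <- toupper(unname(queries))
  empty <- data.frame(query_id = character(), ref_id = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), query_len = integer())
  want <- switch(strands, both = c("+", "-"), sense = "+", antisense = "-")
  out <- vector("list", length(want))
  for (i in seq_along(want)) {
    s <- want[i]
    oriented <- if (s == "+") qseq else revcomp(qseq)
    out[[i]] <- map_one_strand(oriented, qid, index, m, s)
  }
  res <- rbindlist(c(list(as.data.table(empty)), out))
  setorder(res, query_id, ref_id, start, strand)
  as.data.frame(res)
}

map_one_strand <- function(oriented, qid, index, m, strand_label) {
  qlen <- nchar(oriented)
  k <- max(1L, min(qlen) %/% (m + 1L))
  kt <- kmer_table(index, k)
  nq <- length(oriented)
  seed_dt <- rbindlist(lapply(0:m, function(j) {
    data.table(qi = seq_len(nq), off = j * k,
               kmer = substring(oriented, j * k + 1L, (j + 1L) * k))
  }))
  cand <- kt[seed_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(cand)) return(NULL)
  cand[, `:=`(start0 = pos0 - off)]
  cand <- unique(cand[, list(qi, start0)])
  cand <- cand[start0 >= 0L]
  cand[, `:=`(len = qlen[qi])]
  # locate containing record; windows must not cross record boundaries
  rec <- findInterval(cand$start0, index$rec_start0)
  cand[, `:=`(rec = rec)]
  cand <- cand[start0 + len <= index$rec_start0[rec] + index$widths[rec]]
  if (!nrow(cand)) return(NULL)
  # verify grouped by query length
  res <- cand[, {
    L <- len[1L]
    win <- substring(index$big, start0 + 1L, start0 + L)
    mm <- hamming_count(win, oriented[qi], L)
    keep <- mm <= m
    list(qi = qi[keep], start0 = start0[keep], rec = rec[keep],
         mismatches = mm[keep])
  }, by = "len"]
  if (!nrow(res)) return(NULL)
  data.table(query_id = qid[res$qi],
             ref_id = index$ids[res$rec],
             start = res$start0 - index$rec_start0[res$rec],
             strand = strand_label,
             mismatches = res$mismatches,
             query_len = res$len)
}

#' Export alignment hits
#'
#' `write_hits_tsv` writes the hit table as TSV; `write_hits_sam` writes a
#' minimal SAM file (flags 0/16, full-length match CIGAR, `NM` tag).
#'
#' @param hits hit data.frame from [map_full_length()].
#' @param path output path.
#' @param library the [ref_library()] the hits refer to (for `@SQ` headers).
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_sam <- function(hits, library, path) {
  stopifnot(inherits(library, "ref_library"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(paste0("@SQ\tSN:", names(library$sequences),
                    "\tLN:", nchar(library$sequences)), con)
  if (nrow(hits)) {
    seq_out <- ifelse(hits$strand == "+", hits$query_id,
                      revcomp(hits$query_id))
    writeLines(paste(hits$query_id,
                     ifelse(hits$strand == "+", 0L, 16L),
                     hits$ref_id, hits$start + 1L, 255L,
                     paste0(hits$query_len, "M"), "*", 0L, 0L,
                     seq_out, "*",
                     paste0("NM:i:", hits$mismatches), sep = "\t"), con)
  }
  invisible(path)
}
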