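# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `{A,C,G,T,N}` (N maps to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# multiplicity-weighted mode; ties break toward the smallest value
# (conservative trimming)
weighted_mode <- function(values, weights) {
  stopifnot(length(values) == length(weights), length(values) > 0L)
  tot <- tapply(weights, values, sum)
  keys <- as.integer(names(tot))
  best <- which(tot == max(tot))
  min(keys[best])
}

# random DNA strings: n strings of (single) length len; "" when len == 0
rand_dna <- function(n, len) {
  if (len == 0L || n == 0L) return(rep("", n))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n, ncol = len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# open a (possibly gzipped) text connection for writing
open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}
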