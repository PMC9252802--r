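# protocol: automated library-protocol detection and preprocessing
#
# Five-step detection: (1) decide whether the input is already
# adapter-trimmed from the read-length histogram; (2) probe each catalogue
# adapter, requiring it in >50% of reads and >=20% of the miRNA complement
# covered by the trimmed inserts; (3) fall back to an offset-window k-mer
# vote ("guess adapter"); (4) anchor canonical mature sequences inside the
# trimmed reads and collect flank lengths; (5) take the flank-length modes
# as the randomized-nucleotide lengths.  Preprocessing applies the call
# (adapter + randomized-end trimming) and removes low-complexity reads.

#' Adapter specification
#'
#' @param name kit label.
#' @param adapter3 3' adapter sequence (at least 8 nt).
#' @param declared_rand5,declared_rand3 randomized-nucleotide lengths the kit
#'   declares on each side of the insert (metadata; the detected lengths are
#'   always inferred from the data).
#' @return an `adapter_spec` object.
#' @export
adapter_spec <- function(name, adapter3, declared_rand5 = 0L,
                         declared_rand3 = 0L) {
  adapter3 <- toupper(adapter3)
  if (nchar(adapter3) < 8L) stop("adapter3 must be at least 8 nt")
  structure(list(name = name, adapter3 = adapter3,
                 declared_rand5 = as.integer(declared_rand5),
                 declared_rand3 = as.integer(declared_rand3)),
            class = "adapter_spec")
}

#' Default adapter catalogue
#'
#' Reads the editable catalogue shipped with the package (or a user TSV with
#' columns `name`, `adapter3`, `declared_rand5`, `declared_rand3`).
#'
#' @param path catalogue TSV; defaults to the packaged file.
#' @return list of [adapter_spec()] objects.
#' @export
read_adapter_catalogue <- function(path = system.file("extdata",
                                                      "adapters.tsv",
                                                      package = "srnakit")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    adapter_spec(df$name[i], df$adapter3[i],
                 df$declared_rand5[i], df$declared_rand3[i]))
}

#' Detection thresholds
#'
#' Houses the constants of the detection procedure: an adapter must be found
#' in more than `reads_frac_threshold` of all reads and cover at least
#' `complement_threshold` of the miRNA complement; reads are low-complexity
#' when `complexity_ratio()` is at least `complexity_threshold`.
#'
#' @param reads_frac_threshold minimum multiplicity-weighted fraction of
#'   reads containing the adapter (default 0.5).
#' @param complement_threshold minimum fraction of distinct mature miRNAs
#'   found within the trimmed inserts (default 0.2).
#' @param complexity_threshold low-complexity removal boundary, inclusive
#'   (default 0.8).
#' @param min_insert_len minimum insert length in nt (default 15).
#' @param adapter_probe_len adapter prefix length probed exactly (default 12).
#' @param untrimmed_modal_frac modal-length fraction at or above which a
#'   single-length input is considered raw/untrimmed (default 0.9).
#' @return a `protocol_thresholds` list.
#' @export
protocol_thresholds <- function(reads_frac_threshold = 0.5,
                                complement_threshold = 0.2,
                                complexity_threshold = 0.8,
                                min_insert_len = 15L,
                                adapter_probe_len = 12L,
                                untrimmed_modal_frac = 0.9) {
  structure(list(reads_frac_threshold = reads_frac_threshold,
                 complement_threshold = complement_threshold,
                 complexity_threshold = complexity_threshold,
                 min_insert_len = as.integer(min_insert_len),
                 adapter_probe_len = as.integer(adapter_probe_len),
                 untrimmed_modal_frac = untrimmed_modal_frac),
            class = "protocol_thresholds")
}

#' Decide whether the input reads are already adapter-trimmed
#'
#' Raw small RNA runs have a fixed machine read length; adapter-trimmed
#' input shows heterogeneous, short lengths.  The input is called trimmed
#' when the modal length accounts for less than `untrimmed_modal_frac` of
#' all reads, or when the modal length is below 30 nt.
#'
#' @param hist data.frame from [length_histogram()].
#' @param thresholds a [protocol_thresholds()] list.
#' @return logical.
#' @export
detect_trimmed <- function(hist, thresholds = protocol_thresholds()) {
  if (!nrow(hist)) stop("empty length histogram")
  total <- sum(hist$count)
  i <- which.max(hist$count)
  modal_frac <- hist$count[i] / total
  modal_len <- hist$length[i]
  modal_frac < thresholds$untrimmed_modal_frac || modal_len < 30L
}

# 0-based position of the first occurrence of probe at prefix length
# >= min_insert, or -1; vectorised over sequences
probe_positions <- function(sequences, probe, min_insert) {
  pos <- regexpr(probe, sequences, fixed = TRUE)  # 1-based, -1 if absent
  pos0 <- ifelse(pos > 0L, pos - 1L, -1L)
  early <- pos0 >= 0L & pos0 < min_insert
  if (any(early)) {
    tail_part <- substring(sequences[early], min_insert + 1L)
    p2 <- regexpr(probe, tail_part, fixed = TRUE)
    pos0[early] <- ifelse(p2 > 0L, p2 - 1L + min_insert, -1L)
  }
  pos0
}

#' Probe one candidate adapter
#'
#' Computes the multiplicity-weighted fraction of reads that contain the
#' first `adapter_probe_len` nt of the adapter (exact match, insert of at
#' least `min_insert_len` nt preceding it) and the fraction of the miRNA
#' complement (distinct mature sequences) found as exact substrings of the
#' adapter-trimmed inserts.
#'
#' @param collapsed `collapsed_reads`.
#' @param adapter an [adapter_spec()].
#' @param mirna_library [ref_library()] of mature miRNA sequences.
#' @param thresholds a [protocol_thresholds()] list.
#' @return list with `frac_reads_with_adapter` and `complement_coverage`.
#' @export
probe_adapter <- function(collapsed, adapter, mirna_library,
                          thresholds = protocol_thresholds()) {
  stopifnot(inherits(collapsed, "collapsed_reads"),
            inherits(adapter, "adapter_spec"))
  if (!nrow(collapsed)) stop("empty read set")
  if (!inherits(mirna_library, "ref_library") ||
      !length(mirna_library$sequences))
    stop("empty miRNA library: complement coverage undefined")
  probe <- substr(adapter$adapter3, 1L,
                  min(nchar(adapter$adapter3), thresholds$adapter_probe_len))
  pos0 <- probe_positions(collapsed$sequence, probe,
                          thresholds$min_insert_len)
  has <- pos0 >= thresholds$min_insert_len
  frac <- sum(collapsed$count[has]) / sum(collapsed$count)
  inserts <- substr(collapsed$sequence[has], 1L, pos0[has])
  matures <- unique(toupper(mirna_library$sequences))
  found <- vapply(matures, function(mseq)
    any(grepl(mseq, inserts, fixed = TRUE)), logical(1), USE.NAMES = FALSE)
  list(frac_reads_with_adapter = frac,
       complement_coverage = if (length(inserts)) mean(found) else 0)
}

#' Guess an unknown 3' adapter by an offset-window k-mer vote
#'
#' Among the `top_n` most abundant reads (low-complexity reads excluded, as
#' they carry no adapter signal), every k-mer starting at the given offsets
#' (the plausible 3' ends of a mature insert) is counted with multiplicity,
#' once per read; the winning k-mer is returned if it occurs in at least
#' `min_frac` of the considered reads.
#'
#' @param collapsed `collapsed_reads`.
#' @param k probe length (default 12).
#' @param top_n number of most abundant unique reads considered.
#' @param offsets 0-based start offsets scanned (default 18:26).
#' @param min_frac minimum weighted read fraction for acceptance.
#' @return the guessed adapter prefix, or `NULL`.
#' @export
guess_adapter <- function(collapsed, k = 12L, top_n = 1000L,
                          offsets = 18:26, min_frac = 0.2) {
  stopifnot(inherits(collapsed, "collapsed_reads"))
  if (!nrow(collapsed)) stop("empty read set")
  # low-complexity reads carry no adapter signal and would flood the vote
  # with mononucleotide k-mers; they are excluded as in preprocessing
  collapsed <- filter_low_complexity(collapsed)$kept
  if (!nrow(collapsed)) return(NULL)
  top <- head(collapsed[order(collapsed$rank), , drop = FALSE], top_n)
  total_w <- sum(top$count)
  pieces <- lapply(offsets, function(off) {
    kmer <- substr(top$sequence, off + 1L, off + k)
    ok <- nchar(kmer) == k
    data.table(read = which(ok), kmer = kmer[ok], count = top$count[ok])
  })
  dt <- unique(rbindlist(pieces), by = c("read", "kmer"))
  if (!nrow(dt)) return(NULL)
  votes <- dt[, list(weight = sum(count)), by = "kmer"]
  setorder(votes, -weight, kmer)
  if (votes$weight[1L] / total_w < min_frac) return(NULL)
  anchor_adapter_start(votes$kmer[1L], top$sequence, top$count, k)
}

# The vote cannot distinguish the adapter's first k-mer from a slightly
# 3'-shifted one (both occur in the same reads).  Walk leftward while the
# base preceding the k-mer is near-unanimous: inside the adapter it is
# fixed, at the insert boundary it varies read by read.
anchor_adapter_start <- function(kmer, sequences, counts, k,
                                 consensus_frac = 2 / 3, max_steps = 6L) {
  for (step in seq_len(max_steps)) {
    p <- regexpr(kmer, sequences, fixed = TRUE)
    ok <- p > 1L
    if (!any(ok)) break
    prev <- substr(sequences[ok], p[ok] - 1L, p[ok] - 1L)
    tab <- tapply(counts[ok], prev, sum)
    best <- names(tab)[which.max(tab)]
    if (max(tab) / sum(tab) < consensus_frac || !best %in%
        c("A", "C", "G", "T")) break
    kmer <- paste0(best, substr(kmer, 1L, k - 1L))
  }
  kmer
}

#' Infer randomized-nucleotide lengths from mature-anchored reads
#'
#' For every adapter-trimmed read containing an exact mature miRNA sequence
#' as a substring, the 5' and 3' flank lengths are recorded
#' (multiplicity-weighted); the modes of the two distributions are the
#' inferred randomized-end lengths.  Mode ties break toward the smaller
#' length.  With fewer than `min_anchored` anchored reads the call falls
#' back to (0, 0) with a low-support flag.
#'
#' @param trimmed `collapsed_reads` after adapter removal.
#' @param mirna_library [ref_library()] of mature sequences.
#' @param min_anchored minimum multiplicity-weighted anchored read count.
#' @return list with `rand5`, `rand3`, `n_anchored`, `low_support`.
#' @export
infer_random_lengths <- function(trimmed, mirna_library,
                                 min_anchored = 100L) {
  stopifnot(inherits(trimmed, "collapsed_reads"))
  if (!inherits(mirna_library, "ref_library") ||
      !length(mirna_library$sequences))
    stop("empty miRNA library")
  seqs <- trimmed$sequence
  hit_pos <- rep(-1L, length(seqs))
  hit_len <- rep(0L, length(seqs))
  for (mseq in unique(toupper(mirna_library$sequences))) {
    open <- hit_pos < 0L
    if (!any(open)) break
    p <- regexpr(mseq, seqs[open], fixed = TRUE)
    found <- p > 0L
    idx <- which(open)[found]
    hit_pos[idx] <- p[found]
    hit_len[idx] <- nchar(mseq)
  }
  anchored <- hit_pos > 0L
  n_anchored <- sum(trimmed$count[anchored])
  if (n_anchored < min_anchored) {
    warning("only ", n_anchored, " mature-anchored reads; ",
            "randomized-end lengths defaulted to (0, 0)")
    return(list(rand5 = 0L, rand3 = 0L, n_anchored = n_anchored,
                low_support = TRUE))
  }
  left <- hit_pos[anchored] - 1L
  right <- nchar(seqs[anchored]) - left - hit_len[anchored]
  w <- trimmed$count[anchored]
  list(rand5 = weighted_mode(left, w), rand3 = weighted_mode(right, w),
       n_anchored = n_anchored, low_support = FALSE)
}

new_protocol_call <- function(status, adapter, rand5, rand3, frac, coverage,
                              diagnostics, low_support = FALSE) {
  structure(list(status = status, adapter = adapter,
                 rand5_len = as.integer(rand5), rand3_len = as.integer(rand3),
                 frac_reads_with_adapter = frac,
                 mirna_complement_coverage = coverage,
                 diagnostics = diagnostics, low_support = low_support),
            class = "protocol_call")
}

#' Automated library-protocol detection
#'
#' Runs the full five-step procedure: trimmed-input check, catalogue adapter
#' probing, guess-adapter fallback, mature anchoring and randomized-length
#' inference.  The returned call carries a per-candidate diagnostics table.
#'
#' @param collapsed `collapsed_reads` of the raw input.
#' @param catalogue list of [adapter_spec()]; default the packaged catalogue.
#' @param mirna_library [ref_library()] of mature miRNA sequences.
#' @param thresholds a [protocol_thresholds()] list.
#' @return a `protocol_call` with fields `status` (`"already_trimmed"`,
#'   `"detected"`, `"guessed"` or `"failed"`), `adapter`, `rand5_len`,
#'   `rand3_len`, `frac_reads_with_adapter`, `mirna_complement_coverage`,
#'   `diagnostics`.
#' @export
detect_protocol <- function(collapsed, catalogue = read_adapter_catalogue(),
                            mirna_library,
                            thresholds = protocol_thresholds()) {
  stopifnot(inherits(collapsed, "collapsed_reads"), length(catalogue) > 0L)
  if (!nrow(collapsed)) stop("empty read set")

  # Step 1: already trimmed?
  if (detect_trimmed(length_histogram(collapsed), thresholds)) {
    rl <- infer_random_lengths(collapsed, mirna_library)
    return(new_protocol_call("already_trimmed", NULL, rl$rand5, rl$rand3,
                             NA_real_, NA_real_,
                             empty_diagnostics(), rl$low_support))
  }

  # Step 2: probe the catalogue
  diag <- rbindlist(lapply(catalogue, function(ad) {
    pr <- probe_adapter(collapsed, ad, mirna_library, thresholds)
    data.table(name = ad$name, adapter3 = ad$adapter3,
               frac_reads_with_adapter = pr$frac_reads_with_adapter,
               complement_coverage = pr$complement_coverage,
               pass = pr$frac_reads_with_adapter >
                 thresholds$reads_frac_threshold &
                 pr$complement_coverage >= thresholds$complement_threshold)
  }))
  diag_df <- as.data.frame(diag)
  if (any(diag$pass)) {
    best <- which(diag$pass)[which.max(diag$frac_reads_with_adapter[diag$pass])]
    adapter <- catalogue[[best]]
    rl <- rand_lengths_after_trim(collapsed, adapter, mirna_library,
                                  thresholds)
    return(new_protocol_call("detected", adapter, rl$rand5, rl$rand3,
                             diag$frac_reads_with_adapter[best],
                             diag$complement_coverage[best],
                             diag_df, rl$low_support))
  }

  # Step 3: guess-adapter fallback
  g <- guess_adapter(collapsed, k = thresholds$adapter_probe_len)
  if (!is.null(g)) {
    adapter <- adapter_spec("guessed", g)
    pr <- probe_adapter(collapsed, adapter, mirna_library, thresholds)
    rl <- rand_lengths_after_trim(collapsed, adapter, mirna_library,
                                  thresholds)
    return(new_protocol_call("guessed", adapter, rl$rand5, rl$rand3,
                             pr$frac_reads_with_adapter,
                             pr$complement_coverage,
                             diag_df, rl$low_support))
  }
  new_protocol_call("failed", NULL, 0L, 0L, NA_real_, NA_real_, diag_df)
}

empty_diagnostics <- function() {
  data.frame(name = character(), adapter3 = character(),
             frac_reads_with_adapter = numeric(),
             complement_coverage = numeric(), pass = logical())
}

# Steps 4-5 for a chosen adapter: adapter-trim, then infer flank modes
rand_lengths_after_trim <- function(collapsed, adapter, mirna_library,
                                    thresholds) {
  probe <- substr(adapter$adapter3, 1L,
                  min(nchar(adapter$adapter3), thresholds$adapter_probe_len))
  pos0 <- probe_positions(collapsed$sequence, probe,
                          thresholds$min_insert_len)
  has <- pos0 >= thresholds$min_insert_len
  inserts <- collapse_weighted(substr(collapsed$sequence[has], 1L,
                                      pos0[has]),
                               collapsed$count[has])
  infer_random_lengths(inserts, mirna_library)
}

#' Apply a protocol call: adapter and randomized-end trimming
#'
#' Cuts the read at the first adapter-probe occurrence with at least
#' `min_insert_len` nt preceding it, then removes `rand5_len` nt from the 5'
#' end and `rand3_len` nt from the 3' end of the insert.  Reads lacking the
#' adapter, or shorter than `min_insert_len` after trimming, are rejected
#' and tallied by reason.
#'
#' @param collapsed `collapsed_reads` of the raw input.
#' @param call a `protocol_call` (status must not be `"failed"`).
#' @param thresholds a [protocol_thresholds()] list.
#' @return list with `reads` (trimmed, re-collapsed) and `rejected` (named
#'   integer vector of read counts by reason).
#' @export
trim_reads <- function(collapsed, call,
                       thresholds = protocol_thresholds()) {
  stopifnot(inherits(collapsed, "collapsed_reads"),
            inherits(call, "protocol_call"))
  if (call$status == "failed") stop("cannot trim with a failed protocol call")
  seqs <- collapsed$sequence
  counts <- collapsed$count
  rejected <- c(no_adapter = 0L, too_short = 0L)
  if (!is.null(call$adapter)) {
    probe <- substr(call$adapter$adapter3, 1L,
                    min(nchar(call$adapter$adapter3),
                        thresholds$adapter_probe_len))
    pos0 <- probe_positions(seqs, probe, thresholds$min_insert_len)
    has <- pos0 >= thresholds$min_insert_len
    rejected["no_adapter"] <- sum(counts[!has])
    seqs <- substr(seqs[has], 1L, pos0[has])
    counts <- counts[has]
  }
  if (call$rand5_len > 0L || call$rand3_len > 0L) {
    seqs <- substr(seqs, call$rand5_len + 1L,
                   nchar(seqs) - call$rand3_len)
  }
  long_enough <- nchar(seqs) >= thresholds$min_insert_len
  rejected["too_short"] <- sum(counts[!long_enough])
  list(reads = collapse_weighted(seqs[long_enough], counts[long_enough]),
       rejected = rejected)
}

#' Complexity ratio of sequences
#'
#' Fraction of the sequence taken up by its most frequent character
#' (over `{A,C,G,T,N}`); 1.0 for a mononucleotide run, 0.25 for a perfectly
#' balanced sequence.
#'
#' @param sequence character vector of non-empty sequences.
#' @return numeric vector of ratios in `[0, 1]`.
#' @export
#' @examples
#' complexity_ratio(c("AAAA", "ACGT"))
complexity_ratio <- function(sequence) {
  if (!length(sequence)) return(numeric())
  if (any(!nchar(sequence))) stop("complexity ratio undefined for empty sequence")
  len <- nchar(sequence)
  best <- integer(length(sequence))
  for (b in c("A", "C", "G", "T", "N")) {
    best <- pmax(best, len - nchar(gsub(b, "", sequence, fixed = TRUE)))
  }
  best / len
}

#' Remove low-complexity reads
#'
#' Reads whose [complexity_ratio()] is greater than or equal to `threshold`
#' (boundary inclusive) are removed; such reads map to very many loci and
#' mostly reflect ligation or synthesis artefacts.
#'
#' @param collapsed `collapsed_reads`.
#' @param threshold removal boundary in `(0, 1]` (default 0.8).
#' @return list with `kept` and `removed`, both `collapsed_reads`.
#' @export
filter_low_complexity <- function(collapsed, threshold = 0.8) {
  stopifnot(inherits(collapsed, "collapsed_reads"),
            threshold > 0, threshold <= 1)
  if (!nrow(collapsed)) {
    return(list(kept = collapsed, removed = collapsed))
  }
  ratio <- complexity_ratio(collapsed$sequence)
  rm_idx <- ratio >= threshold
  list(kept = collapse_weighted(collapsed$sequence[!rm_idx],
                                collapsed$count[!rm_idx]),
       removed = collapse_weighted(collapsed$sequence[rm_idx],
                                   collapsed$count[rm_idx]))
}

#' @export
print.protocol_call <- function(x, ...) {
  cat("Protocol call: status=", x$status, sep = "")
  if (!is.null(x$adapter))
    cat(", adapter=", x$adapter$name, " (", x$adapter$adapter3, ")", sep = "")
  cat(", rand5=", x$rand5_len, ", rand3=", x$rand3_len, "\n", sep = "")
  if (!is.na(x$frac_reads_with_adapter))
    cat(sprintf("  reads with adapter: %.1f%%; complement coverage: %.1f%%\n",
                100 * x$frac_reads_with_adapter,
                100 * x$mirna_complement_coverage))
  invisible(x)
}

#' Serialize / restore a protocol call as JSON
#'
#' @param call a `protocol_call`.
#' @param path JSON file path.
#' @return `write_protocol_call` returns `path` invisibly;
#'   `read_protocol_call` returns a `protocol_call`.
#' @export
write_protocol_call <- function(call, path) {
  stopifnot(inherits(call, "protocol_call"))
  obj <- unclass(call)
  if (!is.null(obj$adapter)) obj$adapter <- unclass(obj$adapter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_protocol_call
#' @export
read_protocol_call <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  adapter <- if (!is.null(obj$adapter))
    adapter_spec(obj$adapter$name, obj$adapter$adapter3,
                 obj$adapter$declared_rand5, obj$adapter$declared_rand3)
  new_protocol_call(obj$status, adapter, obj$rand5_len, obj$rand3_len,
                    obj$frac_reads_with_adapter %||% NA_real_,
                    obj$mirna_complement_coverage %||% NA_real_,
                    as.data.frame(obj$diagnostics),
                    isTRUE(obj$low_support))
}
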