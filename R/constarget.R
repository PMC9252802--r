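# constarget: consensus of miRNA target-prediction result sets
#
# Pair consensus intersects the (miRNA, transcript) pair sets of the
# selected methods.  Positional consensus additionally requires spatial
# agreement: a consensus site is a maximal run of transcript positions
# covered by at least one predicted site of EVERY selected method, which
# equals the union of the common intersections over all one-site-per-method
# tuples.  Coordinates in all input and output tables are 1-based inclusive.

#' Read one method's target-site table
#'
#' @param path TSV with columns `mirna_id`, `transcript_id`, `start`, `end`,
#'   `score` (1-based inclusive coordinates).
#' @param method method label attached to the table.
#' @return data.frame of target sites.
#' @export
read_target_sites <- function(path, method) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "transcript_id", "start", "end", "score")
  if (!all(need %in% names(df)))
    stop("target table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  validate_sites(df)
  df$method <- method
  df
}

validate_sites <- function(df) {
  if (nrow(df) && any(df$start < 1L | df$end < df$start))
    stop("invalid target coordinates: need 1 <= start <= end")
  invisible(df)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' @param start,end coordinate vectors.
#' @return data.frame with converted `start` and `end`.
#' @export
to_zero_half_open <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_zero_half_open
#' @export
from_zero_half_open <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

check_methods <- function(method_results, methods) {
  if (is.null(methods)) methods <- names(method_results)
  if (length(methods) < 2L) stop("need at least 2 selected methods")
  missing <- setdiff(methods, names(method_results))
  if (length(missing))
    stop("method(s) not present in results: ",
         paste(missing, collapse = ", "))
  methods
}

pair_key <- function(df) paste(df$mirna_id, df$transcript_id, sep = "\r")

#' Position-free pair consensus
#'
#' (miRNA, transcript) pairs predicted by every selected method, regardless
#' of the predicted position.
#'
#' @param method_results named list of site data.frames (one per method,
#'   columns as in [read_target_sites()]).
#' @param methods methods to intersect; default all.
#' @return data.frame `mirna_id`, `transcript_id`.
#' @export
pair_consensus <- function(method_results, methods = NULL) {
  methods <- check_methods(method_results, methods)
  keys <- Reduce(intersect, lapply(method_results[methods],
                                   function(df) unique(pair_key(df))))
  if (!length(keys))
    return(data.frame(mirna_id = character(), transcript_id = character()))
  parts <- strsplit(sort(keys), "\r", fixed = TRUE)
  data.frame(mirna_id = vapply(parts, `[`, character(1), 1L),
             transcript_id = vapply(parts, `[`, character(1), 2L))
}

#' Positional consensus of target predictions
#'
#' For each (miRNA, transcript) pair predicted by all selected methods, the
#' consensus sites are the maximal intervals in which every method predicts
#' at least one overlapping site (`mode = "intersection"`, the default:
#' non-empty common intersection).  `mode = "pairwise"` relaxes this to
#' merged runs of the pooled sites that contain at least one site of every
#' method (chained overlap).
#'
#' @inheritParams pair_consensus
#' @param mode `"intersection"` or `"pairwise"`.
#' @return data.frame with `mirna_id`, `transcript_id`, `consensus_start`,
#'   `consensus_end` and, per method, member site columns
#'   `<method>_start`, `<method>_end`, `<method>_score` (the first site of
#'   that method, by start, overlapping the consensus interval).
#' @export
positional_consensus <- function(method_results, methods = NULL,
                                 mode = c("intersection", "pairwise")) {
  mode <- match.arg(mode)
  methods <- check_methods(method_results, methods)
  for (m in methods) validate_sites(method_results[[m]])
  sites <- rbindlist(lapply(methods, function(m) {
    df <- method_results[[m]]
    data.table(method = m, mirna_id = df$mirna_id,
               transcript_id = df$transcript_id,
               start = as.integer(df$start), end = as.integer(df$end),
               score = df$score)
  }))
  pairs <- pair_consensus(method_results, methods)
  empty <- consensus_skeleton(methods)
  if (!nrow(pairs)) return(empty)
  setkey(sites, mirna_id, transcript_id)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    ps <- sites[list(pairs$mirna_id[i], pairs$transcript_id[i])]
    per_method <- lapply(methods, function(m) ps[method == m])
    cons <- if (mode == "intersection") {
      Reduce(IRanges::intersect,
             lapply(per_method, function(x)
               IRanges::reduce(IRanges::IRanges(x$start, x$end))))
    } else {
      runs <- IRanges::reduce(IRanges::IRanges(ps$start, ps$end))
      keep <- rep(TRUE, length(runs))
      for (x in per_method) {
        ov <- IRanges::countOverlaps(
          runs, IRanges::IRanges(x$start, x$end)) > 0L
        keep <- keep & ov
      }
      runs[keep]
    }
    if (!length(cons)) next
    for (j in seq_along(cons)) {
      cs <- IRanges::start(cons)[j]
      ce <- IRanges::end(cons)[j]
      row <- list(mirna_id = pairs$mirna_id[i],
                  transcript_id = pairs$transcript_id[i],
                  consensus_start = cs, consensus_end = ce)
      for (mi in seq_along(methods)) {
        x <- per_method[[mi]]
        ov <- x[start <= ce & end >= cs][order(start, end)]
        row[[paste0(methods[mi], "_start")]] <- ov$start[1L]
        row[[paste0(methods[mi], "_end")]] <- ov$end[1L]
        row[[paste0(methods[mi], "_score")]] <- ov$score[1L]
      }
      rows[[length(rows) + 1L]] <- as.data.table(row)
    }
  }
  if (!length(rows)) return(empty)
  out <- rbindlist(rows)
  setorder(out, mirna_id, transcript_id, consensus_start)
  as.data.frame(out)
}

consensus_skeleton <- function(methods) {
  cols <- c("mirna_id", "transcript_id", "consensus_start", "consensus_end",
            unlist(lapply(methods, function(m)
              paste0(m, c("_start", "_end", "_score")))))
  df <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)))
  names(df) <- cols
  df
}

#' Transcripts with multiple consensus sites for one miRNA
#'
#' @param consensus data.frame from [positional_consensus()].
#' @return data.frame `mirna_id`, `transcript_id`, `n_sites`, `sites`
#'   (semicolon-joined `start-end` list), restricted to pairs with at least
#'   two consensus sites.
#' @export
multiple_targets <- function(consensus) {
  if (!nrow(consensus))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      n_sites = integer(), sites = character()))
  dt <- as.data.table(consensus)
  g <- dt[order(consensus_start),
          list(n_sites = .N,
               sites = paste(consensus_start, consensus_end, sep = "-",
                             collapse = ";")),
          by = list(mirna_id, transcript_id)]
  g <- g[n_sites >= 2L]
  setorder(g, mirna_id, transcript_id)
  as.data.frame(g)
}

#' All consensus targets per transcript
#'
#' @param consensus data.frame from [positional_consensus()].
#' @return data.frame `transcript_id`, `n_sites`, `sites`
#'   (semicolon-joined `mirna:start-end`, sorted by start).
#' @export
per_transcript <- function(consensus) {
  if (!nrow(consensus))
    return(data.frame(transcript_id = character(), n_sites = integer(),
                      sites = character()))
  dt <- as.data.table(consensus)
  g <- dt[order(consensus_start, mirna_id),
          list(n_sites = .N,
               sites = paste0(mirna_id, ":", consensus_start, "-",
                              consensus_end, collapse = ";")),
          by = "transcript_id"]
  setorder(g, transcript_id)
  as.data.frame(g)
}

#' Write the three consensus output files
#'
#' Writes `positionalConsensus.tsv`, `multipleTargets.tsv` and
#' `perTranscript.tsv` into `dir`.
#'
#' @param consensus data.frame from [positional_consensus()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_consensus_files <- function(consensus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(consensus, file.path(dir, "positionalConsensus.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(multiple_targets(consensus),
              file.path(dir, "multipleTargets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(per_transcript(consensus),
              file.path(dir, "perTranscript.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
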