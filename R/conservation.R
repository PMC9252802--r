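# conservation: conservation depth of small RNA sequences across a genome
# collection at 0, 1 and 2 mismatches (full-length, ungapped, both strands)

#' Collapse duplicated input sequences to a non-redundant set
#'
#' miRNA annotations frequently carry several ids for one mature sequence;
#' to avoid overestimating conservation, identical sequences are collapsed
#' and one id is picked as representative by a seeded random draw.  The
#' redundancy report records every original id.
#'
#' @param sequences named character vector (ids -> sequence) or
#'   `DNAStringSet`.
#' @param seed RNG seed for the representative draw (recorded in the
#'   report attributes).
#' @return a `nonredundant_set`: `sequences` (representative id ->
#'   sequence) and `report` (data.frame `representative`, `n_ids`, `ids`,
#'   `sequence`).
#' @export
dedupe_sequences <- function(sequences, seed = 1L) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences),
                          sub("\\s.*$", "", names(sequences)))
  if (!length(sequences)) stop("empty input sequence set")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("input sequences must carry unique ids")
  sequences <- toupper(sequences)
  dt <- data.table(id = names(sequences), sequence = unname(sequences))
  setorder(dt, sequence, id)
  groups <- dt[, list(ids = list(id)), by = "sequence"]
  reps <- withr::with_seed(seed, vapply(groups$ids, function(v)
    v[sample.int(length(v), 1L)], character(1)))
  report <- data.frame(representative = reps,
                       n_ids = lengths(groups$ids),
                       ids = vapply(groups$ids, paste, character(1),
                                    collapse = ";"),
                       sequence = groups$sequence)
  report <- report[order(report$representative), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "seed") <- seed
  structure(list(sequences = setNames(groups$sequence, reps),
                 report = report, seed = seed),
            class = "nonredundant_set")
}

#' Scan a genome collection for presence at 0/1/2 mismatches
#'
#' Each query is mapped full-length (both strands by default) against every
#' genome; a single scan at the largest requested mismatch level yields the
#' minimal mismatch count per (sequence, genome), from which presence at
#' each level follows by monotonicity.
#'
#' @param nr a [dedupe_sequences()] result, or a named character vector of
#'   query sequences.
#' @param genomes list of [ref_library()] objects, one per genome (a genome
#'   may hold several records).
#' @param levels mismatch levels, subset of `0:2`.
#' @param strands strands searched (default both, recorded in the result).
#' @return a `conservation_matrix`: `min_mm` (sequences x genomes matrix of
#'   minimal mismatch counts, `NA` when absent at every level), `levels`,
#'   `genome_len`, `query_len`, `strands`.
#' @export
conservation_scan <- function(nr, genomes, levels = 0:2,
                              strands = "both") {
  if (inherits(nr, "nonredundant_set")) nr <- nr$sequences
  stopifnot(is.character(nr), length(nr) > 0L, !is.null(names(nr)),
            length(genomes) > 0L, all(levels %in% 0:2))
  m_max <- max(levels)
  genome_names <- vapply(genomes, function(g) g$name, character(1))
  min_mm <- matrix(NA_integer_, nrow = length(nr), ncol = length(genomes),
                   dimnames = list(names(nr), genome_names))
  for (j in seq_along(genomes)) {
    hits <- map_full_length(nr, genomes[[j]], m_max, strands)
    if (nrow(hits)) {
      dt <- as.data.table(hits)[, list(mm = min(mismatches)),
                                by = "query_id"]
      min_mm[dt$query_id, j] <- dt$mm
    }
  }
  structure(list(min_mm = min_mm, levels = sort(unique(as.integer(levels))),
                 genome_len = vapply(genomes, function(g)
                   sum(nchar(g$sequences)), numeric(1)),
                 query_len = nchar(nr), strands = strands),
            class = "conservation_matrix")
}

#' Presence matrix at one mismatch level
#'
#' @param cm a `conservation_matrix`.
#' @param m mismatch level.
#' @return logical sequences x genomes matrix.
#' @export
presence_at <- function(cm, m) {
  stopifnot(inherits(cm, "conservation_matrix"), m %in% cm$levels)
  p <- !is.na(cm$min_mm) & cm$min_mm <= m
  p
}

#' Conservation depth per sequence
#'
#' Percentage of genomes in which each sequence is found at mismatch level
#' `m`, sorted descending.
#'
#' @inheritParams presence_at
#' @return data.frame `id`, `n_genomes`, `depth_pct`.
#' @export
depth_per_sequence <- function(cm, m) {
  p <- presence_at(cm, m)
  n <- rowSums(p)
  df <- data.frame(id = rownames(p), n_genomes = n,
                   depth_pct = 100 * n / ncol(p))
  df <- df[order(-df$depth_pct, df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Mapped-sequence coverage per genome
#'
#' Percentage of the non-redundant query set present in each genome at
#' mismatch level `m`, with an informational expected random-hit
#' probability per genome, `1 - (1 - 0.25^L)^(2 G)` for mean query length
#' `L` and genome length `G` (very short queries are expected to produce
#' false positive mappings by chance).
#'
#' @inheritParams presence_at
#' @return data.frame `genome`, `n_sequences`, `coverage_pct`,
#'   `expected_random_hit`.
#' @export
coverage_per_genome <- function(cm, m) {
  p <- presence_at(cm, m)
  n <- colSums(p)
  lbar <- mean(cm$query_len)
  df <- data.frame(genome = colnames(p), n_sequences = n,
                   coverage_pct = 100 * n / nrow(p),
                   expected_random_hit =
                     1 - (1 - 0.25^lbar)^(2 * cm$genome_len))
  df <- df[order(-df$coverage_pct, df$genome), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write the conservation reports
#'
#' Writes `depth.tsv`, `coverage.tsv` (one file per requested level, suffix
#' `_m{level}`) and `redundancy_report.tsv`; percentages are written with
#' one decimal place.
#'
#' @param cm a `conservation_matrix`.
#' @param nr the [dedupe_sequences()] result (for the redundancy report);
#'   optional.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_conservation_reports <- function(cm, nr = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in cm$levels) {
    d <- depth_per_sequence(cm, m)
    d$depth_pct <- round(d$depth_pct, 1L)
    write.table(d, file.path(dir, sprintf("depth_m%d.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cv <- coverage_per_genome(cm, m)
    cv$coverage_pct <- round(cv$coverage_pct, 1L)
    write.table(cv, file.path(dir, sprintf("coverage_m%d.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(nr)) {
    write.table(nr$report, file.path(dir, "redundancy_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("Conservation matrix: ", nrow(x$min_mm), " sequence(s) x ",
      ncol(x$min_mm), " genome(s); levels ",
      paste(x$levels, collapse = "/"), "; strands ", x$strands, "\n",
      sep = "")
  invisible(x)
}
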