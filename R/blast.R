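# blast_assign: species disambiguation of BLAST tabular hits
#
# Small RNA reads match many database entries with equal quality.  The
# disambiguation keeps, per read, only the top-scoring hits above the
# identity threshold, ranks species by how many reads retain a match to
# them, and then assigns every read to its highest-ranked kept species so
# that exactly one hit per read is presented.

blast_cols <- c("qseqid", "sseqid", "pident", "align_len", "mismatches",
                "gap_opens", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")

#' Parse a 12-column BLAST tabular file
#'
#' Standard `outfmt 6` columns; subject ids are joined to species labels
#' through `species_map`.  Subjects absent from the map get species
#' `"unknown"` and are tallied in one warning.
#'
#' @param path BLAST tabular file (TSV, 12 columns, no header).
#' @param species_map data.frame with columns `sseqid` and `species`, or a
#'   path to such a TSV (with header).
#' @return data.frame of hits with an added `species` column and a
#'   `.hit_line` column preserving input order.
#' @export
parse_blast_tab <- function(path, species_map) {
  nf <- count.fields(path, sep = "\t", quote = "")
  if (is.null(nf) || !length(nf)) {
    hits <- setNames(as.data.frame(matrix(nrow = 0L, ncol = 12L)),
                     blast_cols)
  } else {
    bad <- which(nf != 12L)
    if (length(bad))
      stop("expected 12 tab-separated columns, got ", nf[bad[1L]],
           " at line ", bad[1L])
    hits <- read.delim(path, header = FALSE, col.names = blast_cols,
                       stringsAsFactors = FALSE)
  }
  if (is.character(species_map) && length(species_map) == 1L)
    species_map <- read.delim(species_map, stringsAsFactors = FALSE)
  stopifnot(all(c("sseqid", "species") %in% names(species_map)))
  idx <- match(hits$sseqid, species_map$sseqid)
  hits$species <- species_map$species[idx]
  n_unknown <- sum(is.na(idx))
  if (n_unknown) {
    warning(n_unknown, " hit(s) with subject id absent from the species ",
            "map; labeled 'unknown'")
    hits$species[is.na(idx)] <- "unknown"
  }
  hits$.hit_line <- seq_len(nrow(hits))
  hits
}

#' Keep top-scoring high-identity hits per read
#'
#' Per query: hits below the identity threshold are discarded (strict `>`
#' by default, `>=` with `inclusive = TRUE`); among the survivors only hits
#' sharing the maximal bitscore for that read are kept.  Reads with no
#' surviving hit disappear from downstream analysis.
#'
#' @param hits data.frame from [parse_blast_tab()].
#' @param identity_threshold percent identity threshold (default 90).
#' @param inclusive if `TRUE`, hits at exactly the threshold are kept.
#' @return filtered hit data.frame.
#' @export
filter_top_hits <- function(hits, identity_threshold = 90,
                            inclusive = FALSE) {
  if (!nrow(hits)) return(hits)
  keep <- if (inclusive) hits$pident >= identity_threshold
  else hits$pident > identity_threshold
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  dt <- as.data.table(hits)
  dt <- dt[, .SD[bitscore == max(bitscore)], by = "qseqid"]
  out <- as.data.frame(dt)
  out[order(out$.hit_line), , drop = FALSE]
}

#' Rank species by number of reads retaining a kept match
#'
#' A species is counted once per read in whose kept set it appears,
#' regardless of how many hits link them.
#'
#' @param kept filtered hits from [filter_top_hits()].
#' @return data.frame `species`, `reads`, ordered by reads descending with
#'   lexicographic tie-break.
#' @export
rank_species <- function(kept) {
  if (!nrow(kept)) return(data.frame(species = character(),
                                     reads = integer()))
  dt <- unique(as.data.table(kept)[, list(qseqid, species)])
  r <- dt[, list(reads = .N), by = "species"]
  setorder(r, -reads, species)
  as.data.frame(r)
}

#' Assign each read to one species
#'
#' Every read with kept hits is assigned to its highest-ranked kept species
#' (rank from [rank_species()]); the presented hit is that species' best
#' hit for the read (maximal bitscore, then maximal percent identity, then
#' first occurrence in the input).
#'
#' @param kept filtered hits from [filter_top_hits()].
#' @param ranking optional precomputed ranking; recomputed when `NULL`.
#' @return a `species_assignment` list with `assignments` (one presented
#'   hit row per read, plus `species`) and `ranking`.
#' @export
assign_reads <- function(kept, ranking = NULL) {
  if (is.null(ranking)) ranking <- rank_species(kept)
  if (!nrow(kept)) {
    return(structure(list(assignments = kept, ranking = ranking),
                     class = "species_assignment"))
  }
  dt <- as.data.table(kept)
  dt[, `:=`(sp_rank = match(species, ranking$species))]
  pick <- dt[order(sp_rank, -bitscore, -pident, .hit_line),
             .SD[1L], by = "qseqid"]
  pick[, `:=`(sp_rank = NULL)]
  out <- as.data.frame(pick)
  out <- out[order(out$.hit_line), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(assignments = out, ranking = ranking),
            class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  cat("BLAST species assignment: ", nrow(x$assignments),
      " read(s) assigned, ", nrow(x$ranking), " species\n", sep = "")
  print(head(x$ranking, 10L))
  invisible(x)
}

#' Full BLAST disambiguation pipeline
#'
#' Convenience wrapper: parse, filter, rank, assign.
#'
#' @inheritParams parse_blast_tab
#' @inheritParams filter_top_hits
#' @return a `species_assignment` (see [assign_reads()]).
#' @export
blast_assign <- function(path, species_map, identity_threshold = 90,
                         inclusive = FALSE) {
  hits <- parse_blast_tab(path, species_map)
  kept <- filter_top_hits(hits, identity_threshold, inclusive)
  assign_reads(kept)
}
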