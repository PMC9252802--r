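# profile: hierarchical read assignment, genome distribution, microbial
# attribution and count-matrix helpers
#
# Hierarchical profiling walks an ordered list of annotation libraries
# (default order: mature miRNA, hairpin, tRNA, RNAcentral-derived classes,
# other ncRNA, cDNA); a read is assigned to the first library it maps to
# and never reconsidered, so classes are mutually exclusive and read counts
# are conserved at every stage.

#' Assemble an ordered annotation library list
#'
#' Convenience constructor for the conventional hierarchy: mature miRNA
#' first with the hairpin library as fallback companion, then tRNA, then
#' further ncRNA classes, then cDNA.  Any `NULL` entry is skipped.
#'
#' @param mature,hairpin,trna,cdna [ref_library()] objects or `NULL`.
#' @param other list of additional [ref_library()] objects placed between
#'   tRNA and cDNA (e.g. RNAcentral-derived classes).
#' @return ordered list of `ref_library` objects.
#' @export
library_order <- function(mature, hairpin = NULL, trna = NULL,
                          other = list(), cdna = NULL) {
  libs <- c(list(mature, hairpin, trna), other, list(cdna))
  libs <- Filter(Negate(is.null), libs)
  stopifnot(all(vapply(libs, inherits, logical(1), "ref_library")))
  libs
}

#' Hierarchical profiling against ordered annotation libraries
#'
#' Libraries are scanned in order; a read with at least one hit in the
#' current library is assigned to that library's class (sense if any sense
#' hit exists, antisense otherwise) and excluded from all later libraries.
#' Within a library the read count is added to every hit record
#' (multiple assignment) and, when the read maps to exactly one record,
#' additionally to that record's unique-mapper tally.
#'
#' @param collapsed `collapsed_reads` (typically trimmed and
#'   complexity-filtered).
#' @param libraries ordered list of [ref_library()] objects (see
#'   [library_order()]); record ids must not collide across libraries.
#' @param max_mismatches mismatch budget per read (0-2).
#' @param strands strands searched, as in [map_full_length()].
#' @return an `srna_profile` list: `class_counts` (class, sense, antisense),
#'   `record_counts` (class, ref_id, count, unique_count), `length_dist`
#'   (class, length, count), `unassigned` (`collapsed_reads`), `total_input`
#'   and `provenance`.
#' @export
hierarchical_profile <- function(collapsed, libraries, max_mismatches = 1L,
                                 strands = "both") {
  stopifnot(inherits(collapsed, "collapsed_reads"), length(libraries) > 0L)
  all_ids <- unlist(lapply(libraries, function(l) names(l$sequences)))
  if (anyDuplicated(all_ids)) {
    stop("record id(s) shared across libraries: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  remaining <- collapsed
  class_counts <- list()
  record_counts <- list()
  length_dist <- list()
  for (lib in libraries) {
    cls <- lib$rna_class
    if (!nrow(remaining)) {
      class_counts[[cls]] <- data.table(class = cls, sense = 0L,
                                        antisense = 0L)
      next
    }
    hits <- map_full_length(remaining, lib, max_mismatches, strands)
    hdt <- as.data.table(hits)
    if (!nrow(hdt)) {
      class_counts[[cls]] <- data.table(class = cls, sense = 0L,
                                        antisense = 0L)
      next
    }
    cnt <- data.table(query_id = remaining$sequence,
                      count = remaining$count)
    per_read <- hdt[, list(sense_read = any(strand == "+"),
                           n_records = uniqueN(ref_id)), by = "query_id"]
    per_read <- cnt[per_read, on = "query_id"]
    class_counts[[cls]] <- data.table(
      class = cls,
      sense = sum(per_read$count[per_read$sense_read]),
      antisense = sum(per_read$count[!per_read$sense_read]))
    # one contribution per distinct (read, record) pair
    pairs <- unique(hdt[, list(query_id, ref_id)])
    pairs <- cnt[pairs, on = "query_id"]
    pairs <- per_read[, list(query_id, n_records)][pairs, on = "query_id"]
    rc <- pairs[, list(count = sum(count),
                       unique_count = sum(count[n_records == 1L])),
                by = "ref_id"]
    rc[, `:=`(class = cls)]
    record_counts[[cls]] <- rc
    ld <- per_read[, list(count = sum(count)),
                   by = list(length = nchar(query_id))]
    ld[, `:=`(class = cls)]
    length_dist[[cls]] <- ld
    assigned_seqs <- per_read$query_id
    remaining <- collapse_weighted(
      remaining$sequence[!remaining$sequence %in% assigned_seqs],
      remaining$count[!remaining$sequence %in% assigned_seqs])
  }
  cc <- as.data.frame(rbindlist(class_counts))
  rcdf <- if (length(record_counts)) {
    out <- rbindlist(record_counts)
    setcolorder(out, c("class", "ref_id", "count", "unique_count"))
    setorder(out, class, -count, ref_id)
    as.data.frame(out)
  } else {
    data.frame(class = character(), ref_id = character(),
               count = integer(), unique_count = integer())
  }
  ld <- if (length(length_dist)) {
    out <- rbindlist(length_dist)
    setcolorder(out, c("class", "length", "count"))
    setorder(out, class, length)
    as.data.frame(out)
  } else {
    data.frame(class = character(), length = integer(), count = integer())
  }
  structure(list(class_counts = cc, record_counts = rcdf,
                 length_dist = ld, unassigned = remaining,
                 total_input = sum(collapsed$count),
                 provenance = list(
                   library_order = vapply(libraries, function(l) l$rna_class,
                                          character(1)),
                   max_mismatches = as.integer(max_mismatches),
                   strands = strands)),
            class = "srna_profile")
}

#' @export
print.srna_profile <- function(x, ...) {
  cat("Hierarchical sRNA profile (", x$total_input, " reads; mm=",
      x$provenance$max_mismatches, ")\n", sep = "")
  tot <- x$class_counts$sense + x$class_counts$antisense
  df <- data.frame(class = x$class_counts$class,
                   sense = x$class_counts$sense,
                   antisense = x$class_counts$antisense,
                   percent = round(100 * tot / x$total_input, 2))
  print(df)
  cat(sprintf("unassigned: %d (%.2f%%)\n", sum(x$unassigned$count),
              100 * sum(x$unassigned$count) / x$total_input))
  invisible(x)
}

#' miRNA expression matrix across samples
#'
#' Builds the records-by-samples count matrix for one RNA class (mature
#' miRNA by default) together with the companion reads-per-million matrix,
#' where RPM normalizes by the total assigned reads of each sample.
#'
#' @param profiles named list of `srna_profile` objects (names = samples).
#' @param rna_class class whose record counts are tabulated.
#' @return list with matrices `counts` and `rpm`.
#' @export
mirna_expression_matrix <- function(profiles, rna_class = "mature") {
  stopifnot(length(profiles) > 0L)
  samples <- names(profiles)
  if (is.null(samples) || anyDuplicated(samples) || any(samples == ""))
    stop("profiles must be uniquely named by sample")
  recs <- lapply(profiles, function(p) {
    df <- p$record_counts
    df[df$class == rna_class, c("ref_id", "count")]
  })
  ids <- sort(unique(unlist(lapply(recs, `[[`, "ref_id"))))
  counts <- matrix(0, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
  rpm <- counts
  for (s in samples) {
    r <- recs[[s]]
    counts[r$ref_id, s] <- r$count
    assigned <- sum(profiles[[s]]$class_counts$sense +
                      profiles[[s]]$class_counts$antisense)
    rpm[, s] <- counts[, s] * 1e6 / assigned
  }
  list(counts = counts, rpm = rpm)
}

#' Per-genome mapped read fractions
#'
#' Maps the read set against each genome independently (genomes are not
#' hierarchical) and reports the multiplicity-weighted fraction of reads
#' with at least one hit, plus the fraction mapping to no genome.
#'
#' @param collapsed `collapsed_reads` (non-empty).
#' @param genomes list of [ref_library()] objects, one per genome.
#' @param max_mismatches mismatch budget.
#' @return data.frame with columns `genome` and `fraction`; the final row
#'   `"*unmapped*"` is the fraction hitting no genome.
#' @export
genome_distribution <- function(collapsed, genomes, max_mismatches = 0L) {
  stopifnot(inherits(collapsed, "collapsed_reads"), length(genomes) > 0L)
  if (!nrow(collapsed)) stop("genome distribution undefined for empty input")
  total <- sum(collapsed$count)
  mapped_any <- rep(FALSE, nrow(collapsed))
  fractions <- vapply(genomes, function(g) {
    hits <- map_full_length(collapsed, g, max_mismatches, "both")
    hit_seqs <- unique(hits$query_id)
    is_hit <- collapsed$sequence %in% hit_seqs
    mapped_any <<- mapped_any | is_hit
    sum(collapsed$count[is_hit]) / total
  }, numeric(1))
  data.frame(
    genome = c(vapply(genomes, function(g) g$name, character(1)),
               "*unmapped*"),
    fraction = c(fractions, sum(collapsed$count[!mapped_any]) / total))
}

#' Attribute reads to grouped microbial collections
#'
#' Each collection (e.g. one multi-FASTA per bacterial phylum or virus
#' group) is profiled independently against the full input; a read counts
#' as sense for a collection if it has at least one sense hit there, as
#' antisense if it only hits in antisense orientation.  Percentages use the
#' input read total as denominator; the residual is the percentage of reads
#' hitting no collection at all.
#'
#' @param collapsed `collapsed_reads`, typically the unassigned reads of a
#'   profiling run.
#' @param collections list of [ref_library()] objects, one per collection.
#' @param max_mismatches mismatch budget.
#' @return a `phylum_report`: `summary` (collection, sense_reads,
#'   antisense_reads, percent), `records` (per-collection per-record table
#'   sorted by sense count), `residual_unmapped_percent`, `total_input`.
#' @export
microbes_profile <- function(collapsed, collections, max_mismatches = 0L) {
  stopifnot(inherits(collapsed, "collapsed_reads"), length(collections) > 0L)
  total <- sum(collapsed$count)
  coll_names <- vapply(collections, function(g) g$name, character(1))
  summary_rows <- list()
  records <- list()
  mapped_any <- rep(FALSE, nrow(collapsed))
  for (i in seq_along(collections)) {
    g <- collections[[i]]
    if (!nrow(collapsed)) {
      summary_rows[[i]] <- data.frame(collection = g$name, sense_reads = 0L,
                                      antisense_reads = 0L, percent = 0)
      records[[g$name]] <- data.frame(ref_id = character(),
                                      sense_count = integer(),
                                      antisense_count = integer())
      next
    }
    hits <- as.data.table(map_full_length(collapsed, g, max_mismatches,
                                          "both"))
    cnt <- data.table(query_id = collapsed$sequence,
                      count = collapsed$count)
    if (nrow(hits)) {
      per_read <- hits[, list(sense_read = any(strand == "+")),
                       by = "query_id"]
      per_read <- cnt[per_read, on = "query_id"]
      mapped_any <- mapped_any | collapsed$sequence %in% per_read$query_id
      s_reads <- sum(per_read$count[per_read$sense_read])
      a_reads <- sum(per_read$count[!per_read$sense_read])
      pr_rec <- unique(hits[, list(query_id, ref_id, strand)])
      pr_rec <- pr_rec[, list(sense_rec = any(strand == "+")),
                       by = list(query_id, ref_id)]
      pr_rec <- cnt[pr_rec, on = "query_id"]
      rec <- pr_rec[, list(sense_count = sum(count[sense_rec]),
                           antisense_count = sum(count[!sense_rec])),
                    by = "ref_id"]
      setorder(rec, -sense_count, -antisense_count, ref_id)
    } else {
      s_reads <- a_reads <- 0L
      rec <- data.table(ref_id = character(), sense_count = integer(),
                        antisense_count = integer())
    }
    summary_rows[[i]] <- data.frame(
      collection = g$name, sense_reads = s_reads, antisense_reads = a_reads,
      percent = if (total) 100 * (s_reads + a_reads) / total else 0)
    records[[g$name]] <- as.data.frame(rec)
  }
  residual <- if (total)
    100 * sum(collapsed$count[!mapped_any]) / total else 0
  structure(list(summary = do.call(rbind, summary_rows),
                 records = records,
                 residual_unmapped_percent = residual,
                 total_input = total,
                 max_mismatches = as.integer(max_mismatches)),
            class = "phylum_report")
}

#' @export
print.phylum_report <- function(x, ...) {
  cat("Microbial attribution report (", x$total_input, " reads; mm=",
      x$max_mismatches, ")\n", sep = "")
  df <- x$summary
  df$percent <- round(df$percent, 2)
  print(df)
  cat(sprintf("residual unmapped: %.2f%%\n", x$residual_unmapped_percent))
  invisible(x)
}

#' Summary tables for a profiling run
#'
#' @param profile an `srna_profile`.
#' @param top_n number of top records per class.
#' @return list of data.frames: `class_distribution` (including the
#'   unassigned row), `length_dist`, `top_records`.
#' @export
summarize_run <- function(profile, top_n = 10L) {
  stopifnot(inherits(profile, "srna_profile"))
  cc <- profile$class_counts
  reads <- cc$sense + cc$antisense
  cd <- data.frame(class = c(cc$class, "unassigned"),
                   reads = c(reads, sum(profile$unassigned$count)))
  cd$percent <- 100 * cd$reads / profile$total_input
  rc <- as.data.table(profile$record_counts)
  top <- if (nrow(rc)) {
    as.data.frame(rc[, head(.SD[order(-count, ref_id)], top_n),
                     by = "class"])
  } else {
    profile$record_counts
  }
  list(class_distribution = cd, length_dist = profile$length_dist,
       top_records = top)
}

#' Write the summary tables of a run as TSV files
#'
#' @param profile an `srna_profile`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_run_summary <- function(profile, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summarize_run(profile)
  for (nm in names(s)) {
    write.table(s[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
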